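#' Bivariate Granger causality
#'
#' Classic two-model Granger causality by ordinary least squares: the target
#' is regressed once on `K` of its own strictly-past lags (restricted model)
#' and once on those lags plus `L` strictly-past lags of the source (full
#' model), both over the common sample window starting at `max(K, L)` (no
#' sample is predicted before all its lags exist). The statistic is the log
#' ratio of residual variances, `GC = ln(var_restricted / var_full)`, which
#' is nonnegative for nested fits up to numerical noise. Because only lags
#' `j >= 1` enter, any instantaneous (lag-0) coupling between the series is
#' invisible to GC by construction — the mechanism behind its divergence
#' from cCCM on systems with instantaneous exchange.
#'
#' @param x source series ("does x help predict y?").
#' @param y target series.
#' @param K number of target autolags (default 5).
#' @param L number of source lags in the full model (default `K`).
#' @param intercept include an intercept column in both models (default
#'   `FALSE`, matching the plain autoregression form).
#' @return Object of class `"gc_result"`: list with `direction`,
#'   `order_restricted`, `order_full`, `var_restricted`, `var_full` (both
#'   population-normalized over the common window), and `gc`.
#' @examples
#' set.seed(1)
#' x <- rnorm(500)
#' y <- c(0, 0.9 * x[-500]) + rnorm(500, 0, 0.1)
#' granger_bivariate(x, y)$gc  # large
#' granger_bivariate(y, x)$gc  # ~0
#' @export
granger_bivariate <- function(x, y, K = 5L, L = K, intercept = FALSE) {
  src_name <- deparse(substitute(x))
  tgt_name <- deparse(substitute(y))
  x <- check_series(x, "x"); y <- check_series(y, "y")
  if (length(x) != length(y)) {
    stop("`x` and `y` must have the same length", call. = FALSE)
  }
  K <- check_count(K, "K"); L <- check_count(L, "L")
  n <- length(y)
  p <- max(K, L)
  if (n <= p + 10L) {
    stop(sprintf("series too short for lag orders K = %d, L = %d: need n > %d",
                 K, L, p + 10L), call. = FALSE)
  }
  i <- (p + 1L):n
  ylags <- vapply(seq_len(K), function(j) y[i - j], numeric(length(i)))
  xlags <- vapply(seq_len(L), function(j) x[i - j], numeric(length(i)))
  fit <- gc_fit(y[i], ylags, xlags, intercept)
  structure(
    list(direction = paste0(src_name, "->", tgt_name),
         order_restricted = K, order_full = c(K = K, L = L),
         var_restricted = fit$var_restricted, var_full = fit$var_full,
         gc = fit$gc),
    class = "gc_result"
  )
}

#' Conditional Granger causality
#'
#' Conditional extension of [granger_bivariate()]: the restricted model
#' regresses the target on `K` lags of itself and of every conditioning
#' series; the full model adds `K` lags of the source. With an empty
#' conditioning set this reduces exactly to the bivariate statistic with
#' `L = K`.
#'
#' @param vars a [variable_set()] (or coercible).
#' @param source,target distinct series names.
#' @param conditioning character vector of conditioning names (may be
#'   empty), excluding `source` and `target`.
#' @param K lag order applied to every series (default 5).
#' @param intercept include an intercept (default `FALSE`).
#' @return A `"gc_result"`, as for [granger_bivariate()], with the
#'   conditioning set recorded in `conditioning`.
#' @export
granger_conditional <- function(vars, source, target, conditioning = character(),
                                K = 5L, intercept = FALSE) {
  vars <- as_variable_set(vars)
  if (identical(source, target)) {
    stop("`source` and `target` must differ", call. = FALSE)
  }
  if (any(c(source, target) %in% conditioning)) {
    stop("`conditioning` may not contain `source` or `target`", call. = FALSE)
  }
  series <- pick_series(vars, c(target, source, conditioning), "conditioning")
  K <- check_count(K, "K")
  n <- attr(vars, "n")
  if (n <= K + 10L) {
    stop(sprintf("series too short for lag order K = %d: need n > %d",
                 K, K + 10L), call. = FALSE)
  }
  i <- (K + 1L):n
  lag_block <- function(s) {
    vapply(seq_len(K), function(j) s[i - j], numeric(length(i)))
  }
  y <- series[[target]][i]
  restricted <- do.call(cbind, lapply(c(target, conditioning), function(nm) {
    lag_block(series[[nm]])
  }))
  fit <- gc_fit(y, restricted, lag_block(series[[source]]), intercept)
  structure(
    list(direction = paste0(source, "->", target),
         conditioning = conditioning,
         order_restricted = K, order_full = c(K = K, L = K),
         var_restricted = fit$var_restricted, var_full = fit$var_full,
         gc = fit$gc),
    class = "gc_result"
  )
}

#' @export
print.gc_result <- function(x, ...) {
  cond <- if (!is.null(x$conditioning) && length(x$conditioning) > 0L) {
    sprintf(" | {%s}", paste(x$conditioning, collapse = ", "))
  } else ""
  cat(sprintf(
    "Granger causality %s%s (K = %d, L = %d)\n  GC = %.4g  [residual variance %.4g -> %.4g]\n",
    x$direction, cond, x$order_restricted, x$order_full[["L"]],
    x$gc, x$var_restricted, x$var_full
  ))
  invisible(x)
}

# Shared OLS machinery: residual variances (population form) of the nested
# fits and their log-ratio. Errors out on rank-deficient designs.
gc_fit <- function(y, restricted, extra, intercept) {
  if (intercept) restricted <- cbind(1, restricted)
  full <- cbind(restricted, extra)
  fit_r <- stats::lm.fit(restricted, y)
  fit_f <- stats::lm.fit(full, y)
  if (fit_r$rank < ncol(restricted) || fit_f$rank < ncol(full)) {
    stop("singular fit: the lag design matrix is rank-deficient", call. = FALSE)
  }
  var_r <- mean(fit_r$residuals^2)
  var_f <- mean(fit_f$residuals^2)
  if (var_f <= 0 || var_r <= 0) {
    stop("zero residual variance: GC log-ratio is undefined (deterministic fit)",
         call. = FALSE)
  }
  list(var_restricted = var_r, var_full = var_f, gc = log(var_r / var_f))
}
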