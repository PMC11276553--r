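#' Bundle equal-length time series into a variable set
#'
#' A variable set is the container for multivariate analyses: a named list of
#' equal-length, finite numeric series. Series containing `NA`/`NaN` are
#' rejected (the method has no missing-data semantics).
#'
#' @param ... either named numeric vectors, a single named list of them, or a
#'   data frame with one column per series.
#' @return Object of class `"variable_set"`: the named list of series, with
#'   attribute `n` (common length).
#' @examples
#' vs <- variable_set(x = rnorm(100), y = rnorm(100))
#' names(vs)
#' @export
variable_set <- function(...) {
  args <- list(...)
  if (length(args) == 1L && (is.list(args[[1L]]) || is.data.frame(args[[1L]]))) {
    args <- as.list(args[[1L]])
  }
  if (length(args) < 1L) stop("no series supplied", call. = FALSE)
  nm <- names(args)
  if (is.null(nm) || any(!nzchar(nm))) {
    stop("all series must be named", call. = FALSE)
  }
  if (anyDuplicated(nm)) {
    stop(sprintf("duplicate series names: %s",
                 paste(unique(nm[duplicated(nm)]), collapse = ", ")),
         call. = FALSE)
  }
  series <- lapply(seq_along(args), function(i) check_series(args[[i]], nm[i]))
  names(series) <- nm
  lens <- lengths(series)
  if (length(unique(lens)) != 1L) {
    stop(sprintf("series lengths differ: %s",
                 paste(sprintf("%s (%d)", nm, lens), collapse = ", ")),
         call. = FALSE)
  }
  structure(series, n = lens[[1L]], class = "variable_set")
}

as_variable_set <- function(x) {
  if (inherits(x, "variable_set")) x else variable_set(x)
}

#' @export
print.variable_set <- function(x, ...) {
  cat(sprintf("Variable set: %d series of length %d [%s]\n",
              length(x), attr(x, "n"), paste(names(x), collapse = ", ")))
  invisible(x)
}

pick_series <- function(vars, which, arg) {
  missing <- setdiff(which, names(vars))
  if (length(missing) > 0L) {
    stop(sprintf("unknown series in `%s`: %s", arg,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  vars[which]
}

#' Joint delay embedding of several series
#'
#' Standardizes each selected series (see [standardize_series()]) and
#' delay-embeds it, then concatenates the per-series delay vectors at the
#' same leading time into one joint state vector of width
#' `E * length(subset)`. The joint manifold drives the multivariate
#' (conditional) nearest-neighbor search.
#'
#' @param vars a [variable_set()] (or coercible).
#' @param subset character vector of series names to embed (nonempty).
#' @param E,tau embedding parameters applied to every series.
#' @return A `"shadow_manifold"` whose `points` have `E * length(subset)`
#'   columns (blocks in `subset` order) and whose `name` joins the subset
#'   names.
#' @export
joint_embed <- function(vars, subset, E, tau) {
  vars <- as_variable_set(vars)
  if (length(subset) < 1L) stop("`subset` must be nonempty", call. = FALSE)
  series <- pick_series(vars, subset, "subset")
  blocks <- lapply(names(series), function(nm) {
    embed_series(standardize_series(series[[nm]]), E, tau, name = nm)
  })
  m <- shadow_manifold(
    do.call(cbind, lapply(blocks, `[[`, "points")),
    blocks[[1L]]$times,
    tau = tau,
    name = paste(subset, collapse = "+")
  )
  m$E_per_series <- as.integer(E)
  m$series <- subset
  m
}

#' Cross-map error variance of a target given a predictor set
#'
#' Reconstructs the (unstandardized) target series by past-only cross
#' mapping from the joint shadow manifold of the predictor series and
#' returns the population variance of the reconstruction-error vector.
#' This is the building block of the conditional causality ratio.
#'
#' @param vars a [variable_set()] (or coercible).
#' @param target name of the series to reconstruct.
#' @param predictors nonempty character vector of predictor names (the
#'   target itself is normally excluded; see [conditional_cccm()]).
#' @param E,tau embedding parameters for the joint manifold.
#' @param k number of neighbors; default `E + 1`, the same count as the
#'   bivariate search, independent of the joint dimension.
#' @param min_query_time optional earliest 0-based time to predict, used to
#'   evaluate several predictor sets over a common range.
#' @param mode `"cccm"` (default, past-only) or `"ccm"`.
#' @return Scalar error variance (population form) with attributes `times`
#'   and `errors` carrying the per-time reconstruction errors.
#' @export
conditional_error_variance <- function(vars, target, predictors, E, tau,
                                       k = NULL, min_query_time = NULL,
                                       mode = c("cccm", "ccm")) {
  mode <- match.arg(mode)
  vars <- as_variable_set(vars)
  if (length(predictors) < 1L) {
    stop("`predictors` must be nonempty", call. = FALSE)
  }
  tgt <- pick_series(vars, target, "target")[[1L]]
  manifold <- joint_embed(vars, predictors, E, tau)
  if (is.null(k)) k <- as.integer(E) + 1L
  k <- check_count(k, "k", min = 1L)
  pred <- crossmap_predict(manifold, tgt, k, mode,
                           min_query_time = min_query_time)
  if (nrow(pred) < 2L) {
    stop("too few predictable points for the conditional error variance",
         call. = FALSE)
  }
  err <- tgt[pred$time + 1L] - pred$predicted
  v <- mean((err - mean(err))^2)
  attr(v, "times") <- pred$time
  attr(v, "errors") <- err
  v
}

#' Multivariate conditional cCCM (causality ratio)
#'
#' Quantifies the influence of `source` on `target` conditioned on a set of
#' other series: the relative reduction in the target's cross-map error
#' variance when the source is added to the predictor set,
#' `ratio = (var_without - var_with) / var_without`,
#' where `var_without` uses the conditioning set only and `var_with` uses
#' the conditioning set plus the source. Both variances are computed over
#' the intersection of the two valid prediction ranges so the comparison is
#' like for like. The ratio is at most 1; small negative values can occur by
#' sampling noise and are reported as-is. A ratio near zero for a pair with
#' large bivariate skill is the signature of a common driver in the
#' conditioning set.
#'
#' @param vars a [variable_set()] (or coercible) with at least 3 series.
#' @param source,target distinct series names.
#' @param conditioning nonempty character vector of conditioning names,
#'   excluding `source` and `target`.
#' @param E,tau embedding parameters.
#' @param k neighbors per query; default `E + 1` for both predictor sets.
#' @param include_target if `TRUE`, the target's own delay block is included
#'   in both predictor sets (literal reading of conditioning on "all
#'   remaining variables"); the default `FALSE` excludes it, since
#'   self-prediction from the target's own current-valued delay vector is
#'   near-perfect and would nullify the ratio for genuine sources.
#' @return Object of class `"conditional_result"`: list with `source`,
#'   `target`, `conditioning`, `var_without`, `var_with`, `ratio`, `E`,
#'   `tau`, `k`.
#' @export
conditional_cccm <- function(vars, source, target, conditioning, E, tau,
                             k = NULL, include_target = FALSE) {
  vars <- as_variable_set(vars)
  if (identical(source, target)) {
    stop("`source` and `target` must differ", call. = FALSE)
  }
  if (length(conditioning) < 1L) {
    stop("`conditioning` must be nonempty: with no conditioning variables the ratio degenerates to a two-set comparison; use cross_map() for the bivariate question",
         call. = FALSE)
  }
  if (any(c(source, target) %in% conditioning)) {
    stop("`conditioning` may not contain `source` or `target`", call. = FALSE)
  }
  invisible(pick_series(vars, c(source, target, conditioning), "conditioning"))
  preds_without <- conditioning
  preds_with <- c(conditioning, source)
  if (include_target) {
    preds_without <- c(target, preds_without)
    preds_with <- c(target, preds_with)
  }
  if (is.null(k)) k <- as.integer(E) + 1L
  # common valid range: both manifolds share leading times; the later of the
  # two earliest admissible query times bounds both
  first_t <- (as.integer(E) - 1L) * as.integer(tau) + k
  var_without <- conditional_error_variance(
    vars, target, preds_without, E, tau, k = k, min_query_time = first_t)
  var_with <- conditional_error_variance(
    vars, target, preds_with, E, tau, k = k, min_query_time = first_t)
  if (var_without == 0) {
    stop("degenerate conditioning: target is perfectly explained without the source (var_without = 0)",
         call. = FALSE)
  }
  structure(
    list(source = source, target = target, conditioning = conditioning,
         var_without = as.numeric(var_without),
         var_with = as.numeric(var_with),
         ratio = (as.numeric(var_without) - as.numeric(var_with)) /
           as.numeric(var_without),
         E = as.integer(E), tau = as.integer(tau), k = as.integer(k)),
    class = "conditional_result"
  )
}

#' @export
print.conditional_result <- function(x, ...) {
  cat(sprintf(
    "Conditional cCCM %s -> %s | {%s} (E = %d, tau = %d, k = %d)\n  causality ratio = %.4f  [Var without source %.4g, with %.4g]\n",
    x$source, x$target, paste(x$conditioning, collapse = ", "),
    x$E, x$tau, x$k, x$ratio, x$var_without, x$var_with
  ))
  invisible(x)
}
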