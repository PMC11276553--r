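#' Nearest-neighbor search on a shadow manifold
#'
#' Finds the `k` nearest rows of a shadow manifold to the row at
#' `query_time`, by Euclidean distance. In `"cccm"` (causalized) mode only
#' rows with a strictly smaller time index are admissible, so the present is
#' never matched against the future; in `"ccm"` mode all rows except the
#' query itself are admissible. Distance ties are broken in favor of the
#' smaller time index so results are deterministic across platforms.
#'
#' @param manifold a `"shadow_manifold"` from [embed_series()] or
#'   [shadow_manifold()].
#' @param query_time 0-based leading-time index of the query row (must be one
#'   of `manifold$times`).
#' @param k number of neighbors to return (the cross-map convention is
#'   `E + 1`).
#' @param mode `"cccm"` for the past-only search, `"ccm"` for the full
#'   library.
#' @param theiler temporal exclusion radius: candidates with
#'   `|time - query_time| <= theiler` are discarded (besides the mode's own
#'   constraint). Default 0, i.e. no exclusion beyond the mode.
#' @return A list of class `"neighbor_set"` with `query_time`, `times`
#'   (neighbor leading times, closest first) and `distances` (nondecreasing).
#' @examples
#' m <- shadow_manifold(matrix(c(0, 1, 4, 9, 16)), times = 0:4)
#' knn_search(m, query_time = 3, k = 2, mode = "cccm")  # times 2, 1
#' @export
knn_search <- function(manifold, query_time, k,
                       mode = c("cccm", "ccm"), theiler = 0L) {
  mode <- match.arg(mode)
  stopifnot(inherits(manifold, "shadow_manifold"))
  k <- check_count(k, "k", min = 1L)
  theiler <- check_count(theiler, "theiler", min = 0L)
  i <- match(as.integer(query_time), manifold$times)
  if (is.na(i)) {
    stop(sprintf("query_time %d is not a manifold leading time", query_time),
         call. = FALSE)
  }
  cand <- admissible_rows(manifold$times, i, mode, theiler)
  if (length(cand) < k) {
    earliest <- earliest_query_time(manifold$times, k, mode, theiler)
    stop(sprintf(
      "not enough neighbors at query_time %d: %d admissible, %d required (earliest admissible query_time is %s)",
      query_time, length(cand), k,
      if (is.na(earliest)) "none" else as.character(earliest)
    ), call. = FALSE)
  }
  d <- row_distances(manifold$points, i, cand)
  o <- order(d, cand)[seq_len(k)]
  structure(
    list(query_time = as.integer(query_time),
         times = manifold$times[cand[o]],
         distances = d[o]),
    class = "neighbor_set"
  )
}

#' @export
print.neighbor_set <- function(x, ...) {
  cat(sprintf("%d nearest neighbors of t = %d: times [%s], distances [%s]\n",
              length(x$times), x$query_time,
              paste(x$times, collapse = ", "),
              paste(signif(x$distances, 4), collapse = ", ")))
  invisible(x)
}

#' Exponential cross-map weights
#'
#' Converts neighbor distances to the simplex weights
#' `u_i = exp(-d_i / d_1)`, `w_i = u_i / sum(u)`, where `d_1` is the distance
#' to the closest neighbor. If the closest distance is exactly zero the
#' weight is split uniformly over all zero-distance neighbors (the limit of
#' the formula as `d_1 -> 0+` for exact matches) and is zero elsewhere.
#'
#' @param distances nondecreasing numeric vector of neighbor distances, or a
#'   `"neighbor_set"` from [knn_search()].
#' @return Numeric weight vector summing to 1, nonincreasing in distance.
#' @examples
#' neighbor_weights(c(1, 2))    # ~0.7311 0.2689
#' neighbor_weights(c(0, 0, 5)) # 0.5 0.5 0
#' @export
neighbor_weights <- function(distances) {
  if (inherits(distances, "neighbor_set")) distances <- distances$distances
  d <- as.numeric(distances)
  if (length(d) < 1L || any(!is.finite(d)) || any(d < 0)) {
    stop("`distances` must be finite and nonnegative", call. = FALSE)
  }
  if (is.unsorted(d)) {
    stop("`distances` must be nondecreasing (closest neighbor first)",
         call. = FALSE)
  }
  if (d[1L] == 0) {
    w <- as.numeric(d == 0)
    return(w / sum(w))
  }
  u <- exp(-d / d[1L])
  u / sum(u)
}

#' Cross mapping between two time series
#'
#' Core CCM/cCCM skill computation. The source series is delay-embedded into
#' its shadow manifold; for every admissible leading time `t` the target's
#' value at `t` is reconstructed as the weighted average of the target values
#' at the times of the `E + 1` nearest manifold neighbors of the source state
#' at `t` (weights from [neighbor_weights()]). Skill is the Pearson
#' correlation between target and reconstruction over the predicted range:
#' high skill in the direction "source maps target" is evidence that the
#' target's dynamics leave a signature in the source, i.e. that the target
#' causally influences the source-observed system (and, symmetrically, that
#' information about the target is recoverable from the source's attractor).
#'
#' In `"cccm"` mode (the default) neighbors are restricted to strictly
#' earlier times, so reconstruction of the present never uses the future;
#' the first predicted time is then `(E - 1) * tau + E + 1` (0-based), the
#' earliest `t` with `E + 1` strictly-past manifold rows. In `"ccm"` mode
#' every manifold time is predicted and only the query itself is excluded
#' from its neighborhood.
#'
#' @param source,target equal-length finite numeric vectors. The convention
#'   for direction labels follows the cross-map definition: the result for
#'   direction `X -> Y` is produced by `cross_map(source = X, target = Y)`,
#'   i.e. `Y` reconstructed from `X`'s manifold.
#' @param E,tau embedding dimension and lag for the source manifold.
#' @param mode `"cccm"` (past-only neighbors) or `"ccm"` (full library,
#'   self excluded).
#' @param library_length optional prefix length: only the first
#'   `library_length` samples of both series are used (the convergence-curve
#'   mechanism).
#' @param theiler optional temporal exclusion radius, see [knn_search()].
#' @return Object of class `"cross_map_result"`: a list with `direction`,
#'   `mode`, `rho` (Pearson skill), `mse` (mean squared reconstruction
#'   error), `predictions` (data frame with 0-based `time`, `observed`,
#'   `predicted`), `valid_range` (first and last predicted time), `E`, `tau`,
#'   `n` (samples used), `library_length`.
#' @examples
#' t <- seq(0, 2 * pi, by = 0.01 * pi)
#' cross_map(sin(t), cos(t), E = 5, tau = 5)$rho  # ~0.9985
#' @export
cross_map <- function(source, target, E, tau,
                      mode = c("cccm", "ccm"),
                      library_length = NULL, theiler = 0L) {
  mode <- match.arg(mode)
  src_name <- deparse(substitute(source))
  tgt_name <- deparse(substitute(target))
  source <- check_series(source, "source")
  target <- check_series(target, "target")
  if (length(source) != length(target)) {
    stop("`source` and `target` must have the same length", call. = FALSE)
  }
  if (!is.null(library_length)) {
    library_length <- check_count(library_length, "library_length", min = 1L)
    if (library_length > length(source)) {
      stop("`library_length` exceeds the series length", call. = FALSE)
    }
    source <- source[seq_len(library_length)]
    target <- target[seq_len(library_length)]
  }
  manifold <- embed_series(source, E, tau, name = src_name)
  k <- manifold$E + 1L
  pred <- crossmap_predict(manifold, target, k, mode, theiler)
  if (nrow(pred) < 3L) {
    stop(sprintf(
      "series too short for mode '%s' with E = %d, tau = %d: only %d predictable points (need >= 3)",
      mode, E, tau, nrow(pred)
    ), call. = FALSE)
  }
  obs <- target[pred$time + 1L]
  if (stats::sd(obs) == 0) {
    stop("target is constant over the predicted range; cross-map skill is undefined",
         call. = FALSE)
  }
  if (stats::sd(pred$predicted) == 0) {
    stop("reconstruction is constant over the predicted range (degenerate source manifold); cross-map skill is undefined",
         call. = FALSE)
  }
  structure(
    list(
      direction = paste0(src_name, "->", tgt_name),
      mode = mode,
      rho = stats::cor(obs, pred$predicted),
      mse = mean((obs - pred$predicted)^2),
      predictions = data.frame(time = pred$time, observed = obs,
                               predicted = pred$predicted),
      valid_range = c(pred$time[1L], pred$time[nrow(pred)]),
      E = E, tau = as.integer(tau),
      n = length(source),
      library_length = length(source)
    ),
    class = "cross_map_result"
  )
}

#' @export
print.cross_map_result <- function(x, ...) {
  cat(sprintf(
    "%s cross mapping %s (E = %d, tau = %d, n = %d)\n  rho = %.4f, MSE = %.4g over times %d..%d (%d predictions)\n",
    if (x$mode == "cccm") "Causalized (past-only)" else "Classic",
    x$direction, x$E, x$tau, x$n, x$rho, x$mse,
    x$valid_range[1L], x$valid_range[2L], nrow(x$predictions)
  ))
  invisible(x)
}

#' Cross-map convergence over library length
#'
#' Evaluates both cross-map directions on truncated prefixes of the data and
#' reports skill as a function of library length. Convergence (skill rising
#' with length) is the operational signature of causal coupling; a pair of
#' independent series fluctuates near zero instead.
#'
#' @param x,y equal-length numeric vectors.
#' @param E,tau embedding parameters, as in [cross_map()].
#' @param mode `"cccm"` or `"ccm"`.
#' @param lengths strictly increasing integer vector of library lengths, all
#'   `<= length(x)`.
#' @param theiler temporal exclusion radius, see [knn_search()].
#' @return Object of class `"convergence_curve"`: a data frame with columns
#'   `library_length`, `rho_xy` (skill of `x -> y`) and `rho_yx`, plus
#'   attributes `mode`, `E`, `tau`.
#' @export
convergence_curve <- function(x, y, E, tau, mode = c("cccm", "ccm"),
                              lengths, theiler = 0L) {
  mode <- match.arg(mode)
  x <- check_series(x, "x"); y <- check_series(y, "y")
  lengths <- as.integer(lengths)
  if (length(lengths) < 1L || any(diff(lengths) <= 0L)) {
    stop("`lengths` must be strictly increasing", call. = FALSE)
  }
  if (max(lengths) > length(x)) {
    stop("`lengths` may not exceed the series length", call. = FALSE)
  }
  one <- function(L, s, t) {
    tryCatch(
      cross_map(s, t, E, tau, mode = mode, library_length = L,
                theiler = theiler)$rho,
      error = function(e) {
        stop(sprintf("library length %d: %s", L, conditionMessage(e)),
             call. = FALSE)
      }
    )
  }
  out <- data.frame(
    library_length = lengths,
    rho_xy = vapply(lengths, one, numeric(1L), s = x, t = y),
    rho_yx = vapply(lengths, one, numeric(1L), s = y, t = x)
  )
  structure(out, mode = mode, E = E, tau = as.integer(tau),
            class = c("convergence_curve", "data.frame"))
}

#' Average directed information implied by cross-map skill
#'
#' For jointly Gaussian, stationary ergodic processes the average directed
#' information per sample is related to the causalized cross-map correlation
#' by `I = -1/2 * log2(1 - rho^2)` bits per sample. The value is nonnegative
#' and strictly increasing in `|rho|`.
#'
#' @param rho correlation value(s), each with `|rho| < 1`.
#' @return Directed information in bits per sample.
#' @examples
#' di_from_rho(0)       # 0 bits
#' di_from_rho(0.5067)  # ~0.214 bits
#' @export
di_from_rho <- function(rho) {
  rho <- as.numeric(rho)
  if (any(!is.finite(rho)) || any(abs(rho) >= 1)) {
    stop("|rho| must be < 1 (|rho| = 1 implies infinite information)",
         call. = FALSE)
  }
  -0.5 * log2(1 - rho^2)
}

#' Correlation between a signal and its noisy reconstruction
#'
#' Closed form for the attenuation of cross-map skill by estimation error:
#' if the reconstruction is the true signal plus independent zero-mean error
#' of standard deviation `sigma_e`, the Pearson correlation between signal
#' and reconstruction is `sigma_y / sqrt(sigma_y^2 + sigma_e^2)`.
#'
#' @param sigma_y signal standard deviation, `> 0`.
#' @param sigma_e estimation-error standard deviation, `>= 0`.
#' @return Correlation in `(0, 1]`.
#' @examples
#' rho_under_error(1, 1)  # 1/sqrt(2)
#' @export
rho_under_error <- function(sigma_y, sigma_e) {
  if (any(!is.finite(sigma_y)) || any(sigma_y <= 0)) {
    stop("`sigma_y` must be positive", call. = FALSE)
  }
  if (any(!is.finite(sigma_e)) || any(sigma_e < 0)) {
    stop("`sigma_e` must be nonnegative", call. = FALSE)
  }
  sigma_y / sqrt(sigma_y^2 + sigma_e^2)
}

# ---- internal cross-map machinery ----

# Admissible candidate row indices for the query row i under a mode.
admissible_rows <- function(times, i, mode, theiler = 0L) {
  if (mode == "cccm") {
    cand <- which(times < times[i] - theiler)
  } else {
    cand <- which(abs(times - times[i]) > theiler)
  }
  cand
}

# Earliest manifold leading time with k admissible candidates, NA if none.
earliest_query_time <- function(times, k, mode, theiler = 0L) {
  if (mode == "cccm") {
    # needs k rows with time < t - theiler; rows are consecutive in `times`
    idx <- which(vapply(seq_along(times), function(i) {
      sum(times < times[i] - theiler) >= k
    }, logical(1L)))
  } else {
    idx <- which(length(times) - 1L >= k)  # all rows equivalent when theiler = 0
    if (theiler > 0L) {
      idx <- which(vapply(seq_along(times), function(i) {
        sum(abs(times - times[i]) > theiler) >= k
      }, logical(1L)))
    }
  }
  if (length(idx) == 0L) NA_integer_ else times[min(idx)]
}

# Euclidean distances from row i of `points` to the rows in `cand`.
row_distances <- function(points, i, cand) {
  diff <- points[cand, , drop = FALSE] -
    matrix(points[i, ], nrow = length(cand), ncol = ncol(points), byrow = TRUE)
  sqrt(rowSums(diff * diff))
}

# Vectorized prediction loop shared by cross_map() and the conditional
# error-variance computation. `target` is indexed 1-based at time + 1.
# Returns a data.frame(time, predicted) over all admissible query rows
# (or those at/after `min_query_time` when given).
crossmap_predict <- function(manifold, target, k, mode, theiler = 0L,
                             min_query_time = NULL) {
  times <- manifold$times
  m <- length(times)
  D <- as.matrix(stats::dist(manifold$points))
  if (mode == "cccm") {
    qidx <- which(vapply(seq_len(m), function(i) {
      sum(times < times[i] - theiler) >= k
    }, logical(1L)))
  } else {
    qidx <- which(vapply(seq_len(m), function(i) {
      sum(abs(times - times[i]) > theiler) >= k
    }, logical(1L)))
  }
  if (!is.null(min_query_time)) {
    qidx <- qidx[times[qidx] >= min_query_time]
  }
  pred <- numeric(length(qidx))
  for (q in seq_along(qidx)) {
    i <- qidx[q]
    cand <- admissible_rows(times, i, mode, theiler)
    d <- D[i, cand]
    o <- order(d, cand)[seq_len(k)]
    nb <- cand[o]
    w <- neighbor_weights(d[o])
    pred[q] <- sum(w * target[times[nb] + 1L])
  }
  data.frame(time = times[qidx], predicted = pred)
}
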