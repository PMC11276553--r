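#' Delay-coordinate embedding (shadow manifold construction)
#'
#' Builds the shadow manifold of a scalar time series: the matrix of delay
#' vectors `[X(t), X(t - tau), ..., X(t - (E-1) tau)]` for every admissible
#' leading time `t`. Time indices are 0-based throughout the package, so the
#' first admissible leading time is `(E-1) * tau` and the manifold has
#' `n - (E-1) * tau` rows.
#'
#' @param x numeric vector, the time series (all values finite).
#' @param E embedding dimension, integer `>= 2`: number of lagged coordinates
#'   per delay vector.
#' @param tau time lag in samples, integer `>= 1`: spacing between successive
#'   coordinates of a delay vector.
#' @param name optional label for the source series.
#' @return An object of class `"shadow_manifold"`: a list with elements
#'   `points` (matrix, one delay vector per row, most-recent coordinate
#'   first), `times` (0-based sample index of each row's leading coordinate),
#'   `E`, `tau`, and `name`.
#' @examples
#' m <- embed_series(1:5, E = 2, tau = 1)
#' m$points   # rows [2,1], [3,2], [4,3], [5,4]
#' m$times    # 1 2 3 4
#' @seealso [knn_search()], [cross_map()]
#' @export
embed_series <- function(x, E, tau, name = deparse(substitute(x))) {
  x <- check_series(x)
  E <- check_count(E, "E", min = 2L)
  tau <- check_count(tau, "tau", min = 1L)
  n <- length(x)
  n_min <- (E - 1L) * tau + 1L
  if (n < n_min) {
    stop(sprintf(
      "series of length %d is too short for E = %d, tau = %d: need n >= %d",
      n, E, tau, n_min
    ), call. = FALSE)
  }
  times <- ((E - 1L) * tau):(n - 1L)
  points <- vapply(
    0:(E - 1L),
    function(j) x[times + 1L - j * tau],
    numeric(length(times))
  )
  if (!is.matrix(points)) points <- matrix(points, nrow = 1L)
  shadow_manifold(points, times, tau = tau, name = name)
}

#' Low-level shadow-manifold constructor
#'
#' Assembles a `"shadow_manifold"` object from an existing matrix of state
#' vectors. Used by [embed_series()] and [joint_embed()]; exposed so that
#' neighbor searches can be run on externally constructed state spaces.
#'
#' @param points numeric matrix, one state vector per row.
#' @param times integer vector of 0-based leading-time indices, one per row,
#'   strictly increasing.
#' @param tau time lag the rows were built with (bookkeeping only).
#' @param name label for the source series.
#' @return An object of class `"shadow_manifold"`.
#' @export
shadow_manifold <- function(points, times, tau = 1L, name = "x") {
  points <- as.matrix(points)
  times <- as.integer(times)
  if (nrow(points) != length(times)) {
    stop("`points` must have one row per entry of `times`", call. = FALSE)
  }
  if (length(times) > 1L && any(diff(times) <= 0L)) {
    stop("`times` must be strictly increasing", call. = FALSE)
  }
  structure(
    list(points = points, times = times, E = ncol(points),
         tau = as.integer(tau), name = name),
    class = "shadow_manifold"
  )
}

#' @export
print.shadow_manifold <- function(x, ...) {
  cat(sprintf(
    "Shadow manifold of '%s': %d points in %d dimensions (tau = %d), leading times %d..%d\n",
    x$name, nrow(x$points), x$E, x$tau, x$times[1L], x$times[length(x$times)]
  ))
  invisible(x)
}

#' Standardize a time series
#'
#' Centers to zero mean and scales to unit population variance (divisor `n`,
#' not `n - 1`). Used to put series on a common distance scale before joint
#' multivariate embedding, where raw variances may differ by orders of
#' magnitude and Euclidean distance would otherwise be dominated by one
#' coordinate block.
#'
#' @param x numeric vector with at least 2 values and nonzero variance.
#' @return The standardized series.
#' @examples
#' standardize_series(c(0, 2))  # -1 1
#' @export
standardize_series <- function(x) {
  x <- check_series(x)
  if (length(x) < 2L) {
    stop("need at least 2 values to standardize", call. = FALSE)
  }
  s <- sqrt(mean((x - mean(x))^2))
  if (s == 0) {
    stop("cannot standardize a constant series (zero variance)", call. = FALSE)
  }
  (x - mean(x)) / s
}

# ---- input checks shared across modules ----

check_series <- function(x, arg = deparse(substitute(x))) {
  x <- as.numeric(x)
  if (length(x) < 1L) stop(sprintf("`%s` is empty", arg), call. = FALSE)
  if (!all(is.finite(x))) {
    stop(sprintf("`%s` contains non-finite values", arg), call. = FALSE)
  }
  x
}

check_count <- function(v, arg, min = 1L) {
  if (length(v) != 1L || !is.finite(v) || v != as.integer(v) || v < min) {
    stop(sprintf("`%s` must be a single integer >= %d", arg, min), call. = FALSE)
  }
  as.integer(v)
}
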