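#' Simulate a benchmark coupled system
#'
#' Seeded generators for the simulated systems used throughout the package's
#' validation suite: each produces a set of named series with a known causal
#' structure, so that cross-map, conditional and Granger analyses can be
#' checked against ground truth. Output is bit-reproducible given the same
#' system, parameters, length and seed.
#'
#' Systems (defaults in parentheses; override any entry via `params`):
#' \describe{
#'   \item{`gauss_sign`}{`X = X0 + n1`, `Y = sgn(X0) + n2` with
#'     `X0 ~ N(0,1)` i.i.d. (`n = 1000`); the sign of 0 is 0. Noise per
#'     `snr_db`.}
#'   \item{`gauss_square`}{as above with `Y = X0^2 + n2`.}
#'   \item{`sin_cos`}{`X = sin(omega t) + n1`, `Y = cos(omega t) + n2` on
#'     `t = seq(0, t_max, by = step)` (`omega = 1`, `step = 0.01 * pi`,
#'     `t_max = 2 * pi`); `n` is ignored, the grid sets the length.}
#'   \item{`ar_coupled`}{`X(t+1) = axx X(t) + axy Y(t) + n1(t)`,
#'     `Y(t+1) = ayx X(t) + ayy Y(t) + n2(t)` with independent
#'     `N(0, noise_sd^2)` innovations (`axx = 0.5, axy = 0.05, ayx = 0.65,
#'     ayy = 0.08, noise_sd = 0.05, init = 1.5, n = 2048`).}
#'   \item{`two_tone`}{`X = amp_low sin(5 pi t) + amp_shared sin(20 pi t) + n1`,
#'     `Y = amp_shared sin(20 pi t) + n2` on `t = seq(0, t_max, by = step)`
#'     (`amp_low = 0.6, amp_shared = 0.1, step = 0.005, t_max = 2`), AWGN per
#'     `snr_db` (default 10 dB for this system).}
#'   \item{`logistic_coupled`}{`X(t+1) = X(t)[rx - rx X(t) - cyx Y(t)]`,
#'     `Y(t+1) = Y(t)[ry - ry Y(t) - cxy X(t)]` (`rx = 3.8, ry = 3.2,
#'     cxy = 0.1, cyx = 0, x0 = 0.7, y0 = 0.1, n = 2048`), iterated with the
#'     arithmetic grouping exactly as written.}
#'   \item{`fir_memory`}{`X` i.i.d. standard normal, `Y(t) = sum_l h(l)
#'     X(t - l) + n(t)` with `X(t) = 0` for `t < 0` (zero pre-history) and
#'     `n ~ N(0, noise_var)` (`taps = c("1" = 0.2, "4" = 0.85)`, tap names
#'     are lags, `noise_var = 0`, `n = 1024`).}
#'   \item{`repetition`}{two independent standard-normal series of length
#'     `n` (default 1000), each concatenated `copies` times (default 3);
#'     `copies = 1` gives the raw independent pair.}
#'   \item{`confounded_trio`}{independent standard-normal `X0, Y0, Z` with
#'     `X = wx X0 + gx Z`, `Y = wy Y0 + gy Z` (`wx = 0.7, gx = 10, wy = 0.4,
#'     gy = 12, n = 1024`): no direct coupling between `X` and `Y`, strong
#'     common driver `Z`.}
#' }
#'
#' @param system system identifier, one of the names above.
#' @param n series length (ignored by grid-based systems).
#' @param seed optional RNG seed applied before generation.
#' @param snr_db optional signal-to-noise ratio in dB for the systems with
#'   additive observation noise; `NULL` means noise-free (except `two_tone`,
#'   whose default is 10 dB).
#' @param params named list overriding the system's default parameters.
#' @return A [variable_set()] with the system's series (`X`, `Y`, and `Z`
#'   where applicable), with attributes `system` and `params` echoing the
#'   full specification.
#' @examples
#' vs <- simulate_system("logistic_coupled", seed = 1)
#' vs$X[2]  # 0.7 * (3.8 - 3.8 * 0.7) = 0.798
#' @export
simulate_system <- function(system, n = NULL, seed = NULL, snr_db = NULL,
                            params = list()) {
  system <- match.arg(system, c(
    "gauss_sign", "gauss_square", "sin_cos", "ar_coupled", "two_tone",
    "logistic_coupled", "fir_memory", "repetition", "confounded_trio"
  ))
  if (!is.null(seed)) set.seed(seed)
  p <- utils::modifyList(system_defaults(system), params)
  if (!is.null(n)) p$n <- check_count(n, "n", min = 1L)
  if (!is.null(snr_db)) {
    if (!is.finite(snr_db)) stop("`snr_db` must be finite", call. = FALSE)
    p$snr_db <- snr_db
  }
  out <- switch(system,
    gauss_sign = ,
    gauss_square = {
      x0 <- stats::rnorm(p$n)
      y <- if (system == "gauss_sign") sign(x0) else x0^2
      list(X = maybe_awgn(x0, p$snr_db), Y = maybe_awgn(y, p$snr_db))
    },
    sin_cos = {
      t <- seq(0, p$t_max, by = p$step)
      list(X = maybe_awgn(sin(p$omega * t), p$snr_db),
           Y = maybe_awgn(cos(p$omega * t), p$snr_db))
    },
    ar_coupled = {
      x <- y <- numeric(p$n)
      x[1L] <- y[1L] <- p$init
      e1 <- stats::rnorm(p$n - 1L, 0, p$noise_sd)
      e2 <- stats::rnorm(p$n - 1L, 0, p$noise_sd)
      for (t in seq_len(p$n - 1L)) {
        x[t + 1L] <- p$axx * x[t] + p$axy * y[t] + e1[t]
        y[t + 1L] <- p$ayx * x[t] + p$ayy * y[t] + e2[t]
      }
      list(X = x, Y = y)
    },
    two_tone = {
      t <- seq(0, p$t_max, by = p$step)
      list(X = maybe_awgn(p$amp_low * sin(5 * pi * t) +
                            p$amp_shared * sin(20 * pi * t), p$snr_db),
           Y = maybe_awgn(p$amp_shared * sin(20 * pi * t), p$snr_db))
    },
    logistic_coupled = {
      x <- y <- numeric(p$n)
      x[1L] <- p$x0; y[1L] <- p$y0
      for (t in seq_len(p$n - 1L)) {
        x[t + 1L] <- x[t] * (p$rx - p$rx * x[t] - p$cyx * y[t])
        y[t + 1L] <- y[t] * (p$ry - p$ry * y[t] - p$cxy * x[t])
      }
      list(X = x, Y = y)
    },
    fir_memory = {
      x <- stats::rnorm(p$n)
      lags <- as.integer(names(p$taps))
      if (length(lags) == 0L || any(is.na(lags)) || any(lags < 0L)) {
        stop("`taps` must be a named vector with nonnegative integer lag names",
             call. = FALSE)
      }
      y <- numeric(p$n)
      for (j in seq_along(lags)) {
        l <- lags[j]
        xl <- if (l == 0L) x else c(rep(0, l), x[seq_len(p$n - l)])
        y <- y + unname(p$taps[j]) * xl
      }
      if (p$noise_var > 0) y <- y + stats::rnorm(p$n, 0, sqrt(p$noise_var))
      list(X = x, Y = y)
    },
    repetition = {
      list(X = repeat_concat(stats::rnorm(p$n), p$copies),
           Y = repeat_concat(stats::rnorm(p$n), p$copies))
    },
    confounded_trio = {
      x0 <- stats::rnorm(p$n); y0 <- stats::rnorm(p$n); z <- stats::rnorm(p$n)
      list(X = p$wx * x0 + p$gx * z, Y = p$wy * y0 + p$gy * z, Z = z)
    }
  )
  vs <- variable_set(out)
  attr(vs, "system") <- system
  attr(vs, "params") <- p
  vs
}

system_defaults <- function(system) {
  switch(system,
    gauss_sign = ,
    gauss_square = list(n = 1000L, snr_db = NULL),
    sin_cos = list(omega = 1, step = 0.01 * pi, t_max = 2 * pi,
                   snr_db = NULL, n = NULL),
    ar_coupled = list(axx = 0.5, axy = 0.05, ayx = 0.65, ayy = 0.08,
                      noise_sd = 0.05, init = 1.5, n = 2048L),
    two_tone = list(amp_low = 0.6, amp_shared = 0.1, step = 0.005,
                    t_max = 2, snr_db = 10, n = NULL),
    logistic_coupled = list(rx = 3.8, ry = 3.2, cxy = 0.1, cyx = 0,
                            x0 = 0.7, y0 = 0.1, n = 2048L),
    fir_memory = list(taps = c("1" = 0.2, "4" = 0.85), noise_var = 0,
                      n = 1024L),
    repetition = list(n = 1000L, copies = 3L),
    confounded_trio = list(wx = 0.7, gx = 10, wy = 0.4, gy = 12, n = 1024L)
  )
}

maybe_awgn <- function(x, snr_db) {
  if (is.null(snr_db)) x else add_awgn(x, snr_db)
}

#' Add white Gaussian noise at a target SNR
#'
#' Adds zero-mean Gaussian noise with variance `mean(x^2) / 10^(snr_db/10)`,
#' i.e. SNR is defined on the mean-square power of the noise-free signal
#' (deterministic offsets count as signal).
#'
#' @param x finite numeric signal with nonzero power.
#' @param snr_db signal-to-noise ratio in dB; `NULL` returns `x` unchanged.
#' @param seed optional RNG seed for the noise draw.
#' @return The noisy signal.
#' @examples
#' x <- sin(seq(0, 10, by = 0.01))
#' xn <- add_awgn(x, 20, seed = 1)
#' @export
add_awgn <- function(x, snr_db, seed = NULL) {
  x <- check_series(x)
  if (is.null(snr_db)) return(x)
  if (length(snr_db) != 1L || !is.finite(snr_db)) {
    stop("`snr_db` must be a single finite value (or NULL for noise-free)",
         call. = FALSE)
  }
  power <- mean(x^2)
  if (power == 0) {
    stop("signal power is zero: SNR is undefined for an all-zero signal",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  x + stats::rnorm(length(x), 0, sqrt(power / 10^(snr_db / 10)))
}

#' Concatenate repeated copies of a series
#'
#' Repeats a series end to end. Used to demonstrate the data-repetition
#' artifact: repetition plants exact recurrences in the shadow manifold, so
#' even two independent series acquire large spurious cross-map skill after
#' concatenation.
#'
#' @param x numeric series.
#' @param copies number of copies, `>= 1`.
#' @return The concatenated series of length `length(x) * copies`.
#' @export
repeat_concat <- function(x, copies) {
  x <- check_series(x)
  copies <- check_count(copies, "copies", min = 1L)
  rep(x, copies)
}

#' Cubic-spline upsampling of a series
#'
#' Interpolates onto a uniform grid with `(n - 1) * factor + 1` points
#' spanning the original sample range, using a cubic spline
#' ([stats::spline()]). Original samples are reproduced exactly at their
#' grid positions; `factor = 1` is the identity.
#'
#' @param x numeric series with at least 4 samples.
#' @param factor integer upsampling factor `>= 1`.
#' @return The interpolated series.
#' @export
resample_spline <- function(x, factor) {
  x <- check_series(x)
  factor <- check_count(factor, "factor", min = 1L)
  if (factor == 1L) return(x)
  n <- length(x)
  if (n < 4L) {
    stop("need at least 4 samples for cubic-spline resampling", call. = FALSE)
  }
  stats::spline(x = seq_len(n), y = x,
                n = (n - 1L) * factor + 1L,
                xmin = 1, xmax = n)$y
}
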