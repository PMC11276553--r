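#' Read a multichannel time-series CSV
#'
#' Reads a CSV with one column per series and one row per sample (RFC 4180,
#' UTF-8, '.' decimal regardless of locale). A header row is detected
#' automatically: if any field of the first line is non-numeric it is taken
#' as the header, otherwise columns are auto-named `col0`, `col1`, ...
#' Ragged rows, non-numeric cells and missing values are rejected with the
#' offending row/column named.
#'
#' @param path path to the CSV file.
#' @return A [variable_set()], one series per column.
#' @export
read_series_csv <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    stop(sprintf("empty file: %s", path), call. = FALSE)
  }
  rows <- strsplit(lines, ",", fixed = TRUE)
  first <- trimws(rows[[1L]])
  has_header <- anyNA(suppressWarnings(as.numeric(first)))
  if (has_header) {
    nm <- first
    rows <- rows[-1L]
    if (length(rows) == 0L) {
      stop(sprintf("no data rows in %s", path), call. = FALSE)
    }
  } else {
    nm <- paste0("col", seq_along(first) - 1L)
  }
  ncols <- length(nm)
  widths <- lengths(rows)
  if (any(widths != ncols)) {
    bad <- which(widths != ncols)[1L]
    stop(sprintf(
      "ragged CSV: row %d has %d fields, expected %d (%s)",
      bad + has_header, widths[bad], ncols, path
    ), call. = FALSE)
  }
  mat <- matrix(trimws(unlist(rows)), ncol = ncols, byrow = TRUE)
  series <- lapply(seq_len(ncols), function(j) {
    v <- suppressWarnings(as.numeric(mat[, j]))
    bad <- which(is.na(v) | is.nan(v))
    if (length(bad) > 0L) {
      stop(sprintf(
        "non-numeric or missing value '%s' at data row %d, column '%s' of %s",
        mat[bad[1L], j], bad[1L], nm[j], path
      ), call. = FALSE)
    }
    v
  })
  names(series) <- nm
  variable_set(series)
}

#' Pairwise directed causality matrix
#'
#' Applies [cross_map()] to every ordered pair of series in a variable set
#' and assembles the skills into a square matrix with rows as source and
#' columns as target (entry `(i, j)` is the skill of direction
#' `name_i -> name_j`). Optional cubic-spline upsampling is applied to every
#' series first, and skills are then reported against the upsampled series.
#' A pair that fails (e.g. a constant column) is recorded as `NaN` with a
#' warning rather than aborting the matrix.
#'
#' @param vars a [variable_set()] (or coercible) with at least 2 series.
#' @param E,tau embedding parameters.
#' @param mode `"cccm"` or `"ccm"`.
#' @param upsample integer spline-upsampling factor (default 1, none).
#' @param library_length optional prefix length passed to [cross_map()].
#' @param theiler temporal exclusion radius.
#' @return Object of class `"causality_matrix"`: list with `values` (square
#'   matrix, `NaN` diagonal), `metric` (`"rho_cccm"` or `"rho_ccm"`), and
#'   `config` (named list echoing E, tau, mode, upsample, n).
#' @export
pairwise_matrix <- function(vars, E, tau, mode = c("cccm", "ccm"),
                            upsample = 1L, library_length = NULL,
                            theiler = 0L) {
  mode <- match.arg(mode)
  vars <- as_variable_set(vars)
  if (length(vars) < 2L) {
    stop("need at least 2 series for a pairwise matrix", call. = FALSE)
  }
  upsample <- check_count(upsample, "upsample", min = 1L)
  series <- lapply(vars, resample_spline, factor = upsample)
  n <- length(series[[1L]])
  if (E * tau > n / 10) {
    warning(sprintf(
      "embedding span E * tau = %d exceeds n/10 = %.0f: an over-long span can degrade cross-map skill",
      E * tau, n / 10
    ), call. = FALSE)
  }
  nm <- names(series)
  L <- length(nm)
  values <- matrix(NaN, L, L, dimnames = list(source = nm, target = nm))
  for (i in seq_len(L)) {
    for (j in seq_len(L)) {
      if (i == j) next
      values[i, j] <- tryCatch(
        cross_map(series[[i]], series[[j]], E, tau, mode = mode,
                  library_length = library_length, theiler = theiler)$rho,
        error = function(e) {
          warning(sprintf("pair %s->%s failed: %s", nm[i], nm[j],
                          conditionMessage(e)), call. = FALSE)
          NaN
        }
      )
    }
  }
  structure(
    list(values = values,
         metric = paste0("rho_", mode),
         config = list(E = as.integer(E), tau = as.integer(tau), mode = mode,
                       upsample = upsample, n = n)),
    class = "causality_matrix"
  )
}

#' @export
print.causality_matrix <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "Causality matrix (%s; rows = source, columns = target; E = %d, tau = %d, upsample = %d, n = %d)\n",
    x$metric, cfg$E, cfg$tau, cfg$upsample, cfg$n
  ))
  print(round(x$values, 4))
  invisible(x)
}

#' Conditional causality of one pair with respect to each other series
#'
#' For a fixed `source -> target` pair, computes the conditional causality
#' given each remaining series in turn: the cCCM causality ratio
#' ([conditional_cccm()]) or, with `metric = "gc"`, conditional Granger
#' causality ([granger_conditional()]). This is the per-conditioner view
#' used to inspect which variables mediate or confound a detected link.
#'
#' @param vars a [variable_set()] (or coercible) with at least 3 series.
#' @param source,target distinct series names.
#' @param E,tau embedding parameters (cCCM metric).
#' @param metric `"cccm"` (causality ratio) or `"gc"`.
#' @param gc_order lag order for the GC metric (default 5).
#' @param upsample integer spline-upsampling factor applied first.
#' @return A data frame with one row per conditioning series (`L - 2` rows
#'   for `L` variables): columns `conditioner`, `value`, and for the cCCM
#'   metric `var_without`/`var_with`; attribute `config` echoes the setup.
#' @export
conditional_matrix <- function(vars, source, target, E = 5L, tau = 1L,
                               metric = c("cccm", "gc"), gc_order = 5L,
                               upsample = 1L) {
  metric <- match.arg(metric)
  vars <- as_variable_set(vars)
  if (length(vars) < 3L) {
    stop("need at least 3 series for conditional analysis", call. = FALSE)
  }
  invisible(pick_series(vars, c(source, target), "source/target"))
  upsample <- check_count(upsample, "upsample", min = 1L)
  if (upsample > 1L) {
    vars <- variable_set(lapply(vars, resample_spline, factor = upsample))
  }
  others <- setdiff(names(vars), c(source, target))
  rows <- lapply(others, function(z) {
    if (metric == "cccm") {
      r <- conditional_cccm(vars, source, target, conditioning = z,
                            E = E, tau = tau)
      data.frame(conditioner = z, value = r$ratio,
                 var_without = r$var_without, var_with = r$var_with)
    } else {
      r <- granger_conditional(vars, source, target, conditioning = z,
                               K = gc_order)
      data.frame(conditioner = z, value = r$gc,
                 var_without = r$var_restricted, var_with = r$var_full)
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "config") <- list(source = source, target = target,
                              metric = metric, E = as.integer(E),
                              tau = as.integer(tau),
                              gc_order = as.integer(gc_order),
                              upsample = upsample)
  out
}

#' Average several causality matrices
#'
#' Element-wise mean of matrices computed on different inputs (e.g. one per
#' subject). Optionally averages on the Fisher z scale
#' (`tanh(mean(atanh(rho)))`), which is variance-stabilizing for
#' correlations.
#'
#' @param matrices list of `"causality_matrix"` objects with identical
#'   series names and metric.
#' @param fisher_z average on the Fisher z scale (default `FALSE`, plain
#'   mean).
#' @return A `"causality_matrix"` with the averaged values.
#' @export
average_matrices <- function(matrices, fisher_z = FALSE) {
  if (length(matrices) < 1L ||
      !all(vapply(matrices, inherits, logical(1L), "causality_matrix"))) {
    stop("`matrices` must be a nonempty list of causality matrices",
         call. = FALSE)
  }
  nm <- colnames(matrices[[1L]]$values)
  for (m in matrices) {
    if (!identical(colnames(m$values), nm) ||
        !identical(m$metric, matrices[[1L]]$metric)) {
      stop("matrices must share series names and metric", call. = FALSE)
    }
  }
  arrs <- lapply(matrices, `[[`, "values")
  avg <- if (fisher_z) {
    tanh(Reduce(`+`, lapply(arrs, atanh)) / length(arrs))
  } else {
    Reduce(`+`, arrs) / length(arrs)
  }
  out <- matrices[[1L]]
  out$values <- avg
  out$config$averaged_over <- length(arrs)
  out$config$fisher_z <- fisher_z
  out
}

#' Map a correlation matrix to directed information
#'
#' Applies [di_from_rho()] entry-wise to a causality matrix of cross-map
#' correlations, leaving the `NaN` diagonal in place.
#'
#' @param matrix a `"causality_matrix"` with a `rho_*` metric.
#' @return A `"causality_matrix"` with metric `"di_bits"`.
#' @export
di_matrix <- function(matrix) {
  stopifnot(inherits(matrix, "causality_matrix"))
  if (!startsWith(matrix$metric, "rho_")) {
    stop("directed information requires a correlation-valued matrix",
         call. = FALSE)
  }
  v <- matrix$values
  ok <- is.finite(v)
  v[ok] <- di_from_rho(v[ok])
  matrix$values <- v
  matrix$metric <- "di_bits"
  matrix
}

#' Write analysis results to CSV or JSON
#'
#' Serializes a causality matrix, a conditional table or a convergence curve.
#' CSV output is RFC 4180 with '.' decimals; for matrices the first column
#' (`source`) holds the row names and the `NaN` diagonal becomes empty
#' cells. JSON output embeds the full configuration echo and serializes
#' `NaN` as `null`. Numeric values round-trip through either format to
#' better than 1e-12.
#'
#' @param x a `"causality_matrix"`, `"convergence_curve"`, or data frame
#'   (e.g. from [conditional_matrix()]).
#' @param path output file path.
#' @param format `"csv"` or `"json"` (default guessed from the extension,
#'   falling back to CSV).
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  format <- match.arg(format, c("csv", "json"))
  if (inherits(x, "causality_matrix")) {
    df <- data.frame(source = rownames(x$values),
                     format_num(x$values),
                     check.names = FALSE)
    payload <- list(metric = x$metric, config = x$config,
                    orientation = "rows = source, columns = target",
                    names = colnames(x$values),
                    values = unname(apply(x$values, 1L, as.list)))
  } else if (is.data.frame(x)) {
    df <- data.frame(lapply(x, function(col) {
      if (is.numeric(col)) format_num(col) else col
    }), check.names = FALSE)
    payload <- list(config = attr(x, "config"),
                    columns = names(x),
                    rows = unname(lapply(seq_len(nrow(x)), function(i) {
                      as.list(x[i, , drop = FALSE])
                    })))
  } else {
    stop("unsupported object for write_results()", call. = FALSE)
  }
  if (format == "csv") {
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  } else {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         na = "null", null = "null", pretty = TRUE)
  }
  invisible(path)
}

# full-precision text rendering (round-trips doubles exactly); NaN -> NA so
# write.csv's `na` handles the empty-cell convention
format_num <- function(v) {
  out <- vapply(as.numeric(v), function(z) {
    if (!is.finite(z)) NA_character_ else format(z, digits = 17)
  }, character(1L))
  if (is.matrix(v)) {
    out <- matrix(out, nrow(v), dimnames = dimnames(v))
  }
  out
}
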