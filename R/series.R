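#' Per-frame order-parameter series
#'
#' A named scalar time series over the frames of one trajectory (e.g. RMSD,
#' Rg, Nc, SASA, H-bond count), carrying its units and the trajectory's
#' temperature label.
#'
#' @param name short series name (e.g. `"rmsd"`).
#' @param units unit string (e.g. `"A"`, `"fraction"`, `"A^2"`, `"count"`).
#' @param values numeric per-frame values.
#' @param times per-frame times in ps, same length as `values`.
#' @param temperature temperature label in K.
#' @return object of class `op_series`.
#' @export
op_series <- function(name, units, values, times, temperature = NA_real_) {
  stopifnot(length(values) == length(times))
  structure(list(name = name, units = units,
                 values = as.numeric(values), times = as.numeric(times),
                 temperature = temperature),
            class = "op_series")
}

#' @export
print.op_series <- function(x, ...) {
  cat(sprintf("op_series '%s' [%s]: %d frames, mean %.4g, sd %.4g\n",
              x$name, x$units, length(x$values), mean(x$values),
              if (length(x$values) > 1) sd(x$values) else NA_real_))
  invisible(x)
}

#' Mean and sample standard deviation of a series
#'
#' Summarises an order-parameter series as mean +/- SD (sample SD, n-1
#' denominator), optionally discarding an initial fraction of frames as
#' equilibration.
#'
#' @param series an [op_series()] or numeric vector.
#' @param discard_initial_fraction fraction of leading frames dropped
#'   before summarising (default 0).
#' @return named numeric vector `c(mean, sd, n)`.
#' @examples
#' summarize_series(op_series("x", "A", c(1, 2, 3), c(0, 10, 20)))
#' @export
summarize_series <- function(series, discard_initial_fraction = 0) {
  v <- if (inherits(series, "op_series")) series$values else as.numeric(series)
  stopifnot(discard_initial_fraction >= 0, discard_initial_fraction < 1)
  drop <- floor(length(v) * discard_initial_fraction)
  v <- v[seq_along(v) > drop]
  if (length(v) < 2) stop("fewer than 2 frames remain after discard")
  c(mean = mean(v), sd = sd(v), n = length(v))
}
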