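#' Luminescence trace container
#'
#' A `lum_trace` is the package's representation of a single reporter channel
#' recorded on a plate luminometer: a strictly increasing time grid (minutes)
#' and a signal (arbitrary luminescence units). All kinetics estimators
#' consume this class. Near-uniform grids (spacing within 1% of the median
#' interval) are accepted as-is; anything more irregular is resampled by
#' linear interpolation onto a uniform grid at the median interval.
#'
#' @param time Numeric vector of time points in minutes, strictly increasing.
#' @param signal Numeric vector of luminescence values, same length as `time`.
#' @param resample If `TRUE` (default), resample irregular grids instead of
#'   erroring.
#'
#' @return A data frame with columns `time` and `signal` and class
#'   `lum_trace`.
#' @export
#' @examples
#' tr <- lum_trace(seq(0, 990, by = 10), cos(2 * pi * seq(0, 990, by = 10) / 200))
#' trace_dt(tr)
lum_trace <- function(time, signal, resample = TRUE) {
  if (length(time) != length(signal)) {
    stop("`time` and `signal` must have the same length", call. = FALSE)
  }
  if (anyNA(time) || anyNA(signal)) {
    stop("lum_trace does not accept missing values", call. = FALSE)
  }
  if (length(time) < 10L) {
    stop("a lum_trace needs at least 10 samples", call. = FALSE)
  }
  if (any(diff(time) <= 0)) {
    stop("`time` must be strictly increasing", call. = FALSE)
  }
  dts <- diff(time)
  dt <- stats::median(dts)
  if (max(abs(dts - dt)) > 0.01 * dt) {
    if (!resample) stop("time grid is not uniform within 1%", call. = FALSE)
    grid <- seq(time[1L], time[length(time)], by = dt)
    signal <- stats::approx(time, signal, xout = grid)$y
    time <- grid
  }
  structure(
    data.frame(time = as.numeric(time), signal = as.numeric(signal)),
    class = c("lum_trace", "data.frame")
  )
}

#' @export
print.lum_trace <- function(x, ...) {
  cat(sprintf(
    "<lum_trace> %d samples, t = [%g, %g] min, dt = %g min\n",
    nrow(x), x$time[1L], x$time[nrow(x)], trace_dt(x)
  ))
  invisible(x)
}

#' Sampling interval of a trace
#'
#' @param trace A [lum_trace()].
#' @return Median sampling interval in minutes.
#' @export
trace_dt <- function(trace) {
  stats::median(diff(trace$time))
}

#' Read / write a luminescence trace
#'
#' Traces are exchanged as 2-column delimited text (`time`, `signal`, minutes
#' and arbitrary units) with a one-line header.
#'
#' @param path File path.
#' @param trace A [lum_trace()].
#' @param sep Field separator (default tab).
#' @return `read_trace` returns a [lum_trace()]; `write_trace` returns `path`
#'   invisibly.
#' @export
read_trace <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep)
  if (ncol(df) < 2L) stop("trace file needs two columns (time, signal)", call. = FALSE)
  lum_trace(df[[1L]], df[[2L]])
}

#' @rdname read_trace
#' @export
write_trace <- function(trace, path, sep = "\t") {
  utils::write.table(
    data.frame(time = trace$time, signal = trace$signal),
    path, sep = sep, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}
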