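#' Kinetic trace
#'
#' A (time, signal) series from a stopped-flow acquisition or a simulation:
#' either a luminescence intensity trace (arbitrary units, non-negative) or a
#' 380-nm absorbance trace.
#'
#' @param t Time grid, s; strictly increasing, `t[1] >= 0`.
#' @param y Signal values, same length as `t`; finite, and non-negative for
#'   luminescence.
#' @param kind `"luminescence"` or `"absorbance"`.
#' @param conditions Optional [assay_conditions()] the trace was recorded
#'   under.
#' @param scale Instrument scale factor the trace was generated with (if
#'   known); used by fitters sharing the generator's scale convention.
#' @return An object of class `kinetic_trace`.
#' @examples
#' kinetic_trace(t = 0:10, y = exp(-(0:10) / 3), kind = "luminescence")
#' @export
kinetic_trace <- function(t, y, kind = c("luminescence", "absorbance"),
                          conditions = NULL, scale = 1.0) {
  kind <- match.arg(kind)
  t <- as.numeric(t); y <- as.numeric(y)
  if (length(t) != length(y) || length(t) < 2L)
    stop("t and y must have equal length >= 2", call. = FALSE)
  if (any(!is.finite(t)) || any(!is.finite(y)))
    stop("t and y must be finite", call. = FALSE)
  if (t[1] < 0 || any(diff(t) <= 0))
    stop("time grid must be strictly increasing with t[1] >= 0", call. = FALSE)
  if (kind == "luminescence" && any(y < -sqrt(.Machine$double.eps)))
    stop("luminescence signal must be non-negative", call. = FALSE)
  if (!is.null(conditions) && !inherits(conditions, "assay_conditions"))
    stop("conditions must be an assay_conditions object", call. = FALSE)
  structure(
    list(t = t, y = y, kind = kind, conditions = conditions, scale = scale),
    class = "kinetic_trace"
  )
}

#' @export
print.kinetic_trace <- function(x, ...) {
  cat(sprintf("Kinetic trace (%s): %d points, t in [%.4g, %.4g] s, signal in [%.4g, %.4g]\n",
              x$kind, length(x$t), min(x$t), max(x$t), min(x$y), max(x$y)))
  if (!is.null(x$conditions)) print(x$conditions)
  invisible(x)
}

#' @export
as.data.frame.kinetic_trace <- function(x, ...) {
  data.frame(t = x$t, y = x$y)
}

# linear interpolation of a trace onto a new grid (rule = 2 clamps the ends,
# only used after callers verify coverage)
resample_trace <- function(trace, t_new) {
  approx(trace$t, trace$y, xout = t_new, rule = 2)$y
}
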