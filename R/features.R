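#' Extract the four empirical curve parameters from a luminescence trace
#'
#' Computes the standard descriptors of a flash-like single-turnover curve:
#' peak intensity `Imax` (maximum signal), total quantum yield `Qstar`
#' (trapezoidal area under the curve), initial velocity `v0` (ordinary
#' least-squares slope of the starting linear rise) and decay constant
#' `kdecay` (rate of the exponential fitted to the final part of the curve).
#'
#' Window conventions: `v0` is fitted from `t = 0` until the signal first
#' reaches `v0_frac * Imax` (default 20%), capturing the rise before
#' curvature sets in; `kdecay` is fitted by linear regression of
#' log-intensity from the first post-peak time the signal falls to
#' `decay_frac * Imax` (default 50%) to the end of the trace, excluding
#' non-positive points. Both thresholds are exposed because the "starting"
#' and "final" parts of a flash curve are conventions, not sharp boundaries.
#'
#' @param trace A luminescence [kinetic_trace()] with at least 50 points and
#'   an interior maximum.
#' @param v0_frac Fraction of `Imax` ending the rise window.
#' @param decay_frac Fraction of `Imax` (post-peak) starting the tail window.
#' @return An object of class `curve_features` with fields `Imax`, `Qstar`,
#'   `v0`, `kdecay` and `windows` (the time windows actually used).
#' @examples
#' k <- rate_constants(7.85, 0.15, 1.55, 400, 0.42, 10.90, 0.46)
#' tr <- simulate_curve(k, assay_conditions(0.95, 15, 40),
#'                      t_grid = seq(0, 15, by = 0.01))
#' extract_features(tr)
#' @export
extract_features <- function(trace, v0_frac = 0.2, decay_frac = 0.5) {
  stopifnot(inherits(trace, "kinetic_trace"))
  if (trace$kind != "luminescence")
    stop("feature extraction requires a luminescence trace", call. = FALSE)
  t <- trace$t; y <- trace$y
  if (length(t) < 50L)
    stop("trace too short for feature extraction (need >= 50 points)", call. = FALSE)

  ipk <- which.max(y)
  if (ipk <= 1L || ipk >= length(y))
    stop("no interior maximum: trace is monotone", call. = FALSE)
  Imax <- y[ipk]

  Qstar <- pracma::trapz(t, y)

  # rise window: from t = 0 to first crossing of v0_frac * Imax
  i_rise_end <- which(y >= v0_frac * Imax)[1]
  if (is.na(i_rise_end) || i_rise_end < 2L) i_rise_end <- 2L
  rise <- seq_len(i_rise_end)
  v0 <- unname(coef(lm(y[rise] ~ t[rise]))[2])

  # tail window: first post-peak drop to decay_frac * Imax, to trace end
  post <- which(seq_along(y) > ipk & y <= decay_frac * Imax)
  if (length(post) == 0L)
    stop("tail too short: signal never falls to the decay threshold", call. = FALSE)
  tail_idx <- post[1]:length(y)
  keep <- tail_idx[y[tail_idx] > 0]
  if (length(keep) < 3L)
    stop("tail too short for an exponential fit", call. = FALSE)
  kdecay <- unname(-coef(lm(log(y[keep]) ~ t[keep]))[2])

  structure(
    list(Imax = Imax, Qstar = Qstar, v0 = v0, kdecay = kdecay,
         windows = list(v0 = c(t[1], t[i_rise_end]),
                        kdecay = c(t[keep[1]], t[length(t)]))),
    class = "curve_features"
  )
}

#' @export
print.curve_features <- function(x, ...) {
  cat("Empirical curve parameters\n")
  cat(sprintf("  Imax   = %.4g a.u.      (peak intensity)\n", x$Imax))
  cat(sprintf("  Q*     = %.4g a.u. s    (total quantum yield, area)\n", x$Qstar))
  cat(sprintf("  v0     = %.4g a.u./s    (initial velocity, window %.3g-%.3g s)\n",
              x$v0, x$windows$v0[1], x$windows$v0[2]))
  cat(sprintf("  kdecay = %.4g 1/s       (tail decay, window %.3g-%.3g s)\n",
              x$kdecay, x$windows$kdecay[1], x$windows$kdecay[2]))
  invisible(x)
}
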