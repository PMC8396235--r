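#' Viscosity table for a cosolvent series
#'
#' @param medium Cosolvent label (e.g. `"glycerol"`).
#' @param fractions Mass fractions, % w/w (0 denotes plain buffer).
#' @param eta Viscosities, cP; strictly increasing with fraction, with the
#'   buffer convention eta = 1.0 cP at fraction 0.
#' @param source Provenance note.
#' @return A data frame of class `viscosity_table`.
#' @export
viscosity_table <- function(medium, fractions, eta, source = "user-supplied") {
  stopifnot(length(fractions) == length(eta), length(eta) >= 1L)
  o <- order(fractions)
  fractions <- fractions[o]; eta <- eta[o]
  if (any(eta <= 0) || any(diff(eta) <= 0))
    stop("eta must be positive and strictly increasing with fraction", call. = FALSE)
  if (fractions[1] == 0 && abs(eta[1] - 1.0) > 1e-8)
    stop("buffer (fraction 0) viscosity must be 1.0 cP by convention", call. = FALSE)
  structure(data.frame(medium = medium, fraction = fractions, eta = eta),
            source = source,
            class = c("viscosity_table", "data.frame"))
}

#' Default handbook viscosities for glycerol and sucrose series
#'
#' Viscosities of aqueous glycerol and sucrose mixtures at 20 °C from
#' standard water-mixture handbook tables, for mass fractions 10--40% w/w,
#' with the buffer (fraction 0) fixed at 1.0 cP by convention. Glucose and
#' sorbitol series are not shipped; supply them via [viscosity_table()].
#'
#' @return Named list of [viscosity_table()] objects (`glycerol`, `sucrose`).
#' @examples
#' default_viscosities()$sucrose
#' @export
default_viscosities <- function() {
  list(
    glycerol = viscosity_table("glycerol", c(0, 10, 20, 30, 40),
                               c(1.00, 1.31, 1.76, 2.50, 3.72),
                               source = "handbook, 20 C"),
    sucrose = viscosity_table("sucrose", c(0, 10, 20, 30, 40),
                              c(1.00, 1.33, 1.95, 3.19, 6.16),
                              source = "handbook, 20 C")
  )
}

#' Power-law fit of a rate constant against viscosity
#'
#' Fits `k = prefactor * eta^(-delta)` by ordinary least squares of `ln k` on
#' `ln eta`. The exponent `delta` quantifies diffusion control of the stage:
#' `delta = 0` means no viscosity sensitivity, `delta = 1` full diffusion
#' limitation, and `delta > 1` an enhanced effect beyond pure diffusion
#' control.
#'
#' @param eta Viscosities, cP (>= 3 values, all positive). Include the
#'   buffer point (eta = 1) when available.
#' @param k Rate constants at each viscosity (same length, all positive).
#' @return An object of class `power_law_fit` with `prefactor`, `delta`
#'   (reported positive for a decreasing power law), `delta_se`, `slope_p`
#'   (t-test p-value of the log-log slope against zero), `n_points` and `r2`.
#' @examples
#' fit_power_law(c(1, 2, 4, 8), 2 / c(1, 2, 4, 8))
#' @export
fit_power_law <- function(eta, k) {
  eta <- as.numeric(eta); k <- as.numeric(k)
  if (length(eta) != length(k) || length(eta) < 3L)
    stop("need >= 3 (eta, k) pairs of equal length", call. = FALSE)
  if (any(eta <= 0) || any(k <= 0))
    stop("eta and k must be strictly positive", call. = FALSE)
  m <- lm(log(k) ~ log(eta))
  # exact power-law inputs are legitimate; silence the perfect-fit notice
  sm <- suppressWarnings(summary(m))
  structure(
    list(prefactor = exp(unname(coef(m)[1])),
         delta = -unname(coef(m)[2]),
         delta_se = unname(sm$coefficients[2, "Std. Error"]),
         slope_p = unname(sm$coefficients[2, "Pr(>|t|)"]),
         n_points = length(eta),
         r2 = sm$r.squared,
         model = m),
    class = "power_law_fit"
  )
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("Power law k ~ eta^-delta: delta = %.3g +/- %.2g (n = %d, R2 = %.3f), prefactor = %.4g\n",
              x$delta, x$delta_se, x$n_points, x$r2, x$prefactor))
  invisible(x)
}

#' Classify the diffusion control of a reaction stage
#'
#' Maps a [fit_power_law()] result onto a qualitative verdict:
#' * `"enhanced"` if `delta - 2*delta_se > 1` (effect beyond diffusion
#'   control);
#' * `"diffusion-limited"` if `|delta - 1| <= 2*delta_se`;
#' * `"viscosity-insensitive"` if `delta < flat_threshold` or the log-log
#'   slope is not distinguishable from zero at alpha = 0.05 (the no-power-law
#'   case);
#' * `"partial"` otherwise (0 < delta < 1, genuine but sub-diffusive
#'   sensitivity).
#'
#' The 2-standard-error bands and the flatness test are package conventions
#' for making the qualitative field classification reproducible.
#'
#' @param fit A `power_law_fit`.
#' @param flat_threshold Exponent below which a stage is called insensitive
#'   outright.
#' @return Character verdict.
#' @examples
#' classify_stage(fit_power_law(c(1, 2, 4, 8), 2 / c(1, 2, 4, 8)))
#' @export
classify_stage <- function(fit, flat_threshold = 0.2) {
  stopifnot(inherits(fit, "power_law_fit"))
  tol <- 1e-9  # guard against ties at the 2-SE boundary
  if (fit$delta - 2 * fit$delta_se > 1 + tol) return("enhanced")
  if (abs(fit$delta - 1) <= 2 * fit$delta_se + tol) return("diffusion-limited")
  if (fit$delta < flat_threshold || fit$slope_p >= 0.05)
    return("viscosity-insensitive")
  "partial"
}
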