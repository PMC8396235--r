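#' Elementary rate constants of the luciferase reaction scheme
#'
#' Bundles the seven elementary rate constants of the single-turnover
#' bioluminescent reaction, plus an optional flavin-dissociation rate that
#' switches on the reversible-first-stage model variant.
#'
#' Concentrations throughout the package are in µM, so the bimolecular
#' constants `k1` and `k3` are interpreted in 1/(µM·s). With that convention
#' the buffer constants reproduce the observed flash-like curve shape (rise
#' within ~1 s, decay over 8--10 s).
#'
#' @param kd FMNH2 autoxidation rate, 1/s (dark pathway).
#' @param kdd Intermediate II dark-decay rate, 1/s (dark pathway).
#' @param k1 Flavin-binding bimolecular rate, 1/(µM·s).
#' @param k2 Intermediate II formation pseudo-first-order rate, 1/s. Oxygen
#'   is folded in because assays run at effectively constant, saturating
#'   oxygen (~120 µM).
#' @param k3 Aldehyde-binding bimolecular rate, 1/(µM·s).
#' @param km3 Intermediate IIA dissociation rate, 1/s.
#' @param k4 Catalytic (excited-emitter formation) rate, 1/s.
#' @param km1 Optional flavin dissociation rate, 1/s. `NULL` (default) selects
#'   the irreversible first stage; a finite value activates the reversible
#'   variant used for sensitivity analysis.
#'
#' @return An object of class `rate_constants`: a named list of rates.
#' @examples
#' k <- rate_constants(kd = 7.85, kdd = 0.15, k1 = 1.55, k2 = 400,
#'                     k3 = 0.42, km3 = 10.90, k4 = 0.46)
#' k
#' @export
rate_constants <- function(kd, kdd, k1, k2, k3, km3, k4, km1 = NULL) {
  vals <- c(kd = kd, kdd = kdd, k1 = k1, k2 = k2, k3 = k3, km3 = km3, k4 = k4)
  if (!is.numeric(vals) || length(vals) != 7L || any(!is.finite(vals)))
    stop("all rate constants must be finite numerics", call. = FALSE)
  if (any(vals < 0))
    stop("rate constants must be >= 0", call. = FALSE)
  if (!is.null(km1)) {
    if (!is.numeric(km1) || length(km1) != 1L || !is.finite(km1) || km1 < 0)
      stop("km1 must be a single finite value >= 0", call. = FALSE)
  }
  structure(
    list(kd = kd, kdd = kdd, k1 = k1, k2 = k2, k3 = k3, km3 = km3, k4 = k4,
         km1 = km1),
    class = "rate_constants"
  )
}

#' @export
print.rate_constants <- function(x, ...) {
  cat("Luciferase reaction rate constants\n")
  cat(sprintf("  kd  = %-8.4g 1/s       (FMNH2 autoxidation)\n", x$kd))
  cat(sprintf("  kdd = %-8.4g 1/s       (Intermediate II dark decay)\n", x$kdd))
  cat(sprintf("  k1  = %-8.4g 1/(uM s)  (flavin binding)\n", x$k1))
  cat(sprintf("  k2  = %-8.4g 1/s       (Intermediate II formation)\n", x$k2))
  cat(sprintf("  k3  = %-8.4g 1/(uM s)  (aldehyde binding)\n", x$k3))
  cat(sprintf("  k-3 = %-8.4g 1/s       (Intermediate IIA dissociation)\n", x$km3))
  cat(sprintf("  k4  = %-8.4g 1/s       (catalytic step)\n", x$k4))
  if (!is.null(x$km1))
    cat(sprintf("  k-1 = %-8.4g 1/s       (flavin dissociation; reversible variant)\n",
                x$km1))
  invisible(x)
}

# numeric parameter vector for the integrator; km1 NULL maps to 0
as_parms <- function(k) {
  stopifnot(inherits(k, "rate_constants"))
  c(kd = k$kd, kdd = k$kdd, k1 = k$k1, k2 = k$k2, k3 = k$k3, km3 = k$km3,
    k4 = k$k4, km1 = if (is.null(k$km1)) 0 else k$km1)
}

#' Assay conditions for a single-turnover run
#'
#' Post-mix initial concentrations and medium descriptors for one
#' stopped-flow acquisition. Typical assay: ~1 µM luciferase mixed with 15 µM
#' reduced flavin and 10--50 µM decanal.
#'
#' @param E0 Total luciferase, µM (> 0).
#' @param F0 Initial FMNH2, µM (> 0).
#' @param A0 Initial decanal, µM (> 0; pass a small positive value or use the
#'   model directly for aldehyde-free controls).
#' @param medium Label for the cosolvent and mass fraction, e.g. `"buffer"`,
#'   `"sucrose_30"`.
#' @param viscosity Solution viscosity, cP; buffer is 1 cP by convention.
#'
#' @return An object of class `assay_conditions`.
#' @examples
#' assay_conditions(E0 = 0.95, F0 = 15, A0 = 40)
#' @export
assay_conditions <- function(E0, F0, A0, medium = "buffer", viscosity = 1.0) {
  conc <- c(E0 = E0, F0 = F0, A0 = A0)
  if (!is.numeric(conc) || any(!is.finite(conc)) || any(conc <= 0))
    stop("E0, F0 and A0 must be finite and > 0 (uM)", call. = FALSE)
  if (!is.numeric(viscosity) || viscosity < 1)
    stop("viscosity must be >= 1 cP (buffer convention is 1 cP)", call. = FALSE)
  structure(
    list(E0 = E0, F0 = F0, A0 = A0, medium = as.character(medium),
         viscosity = viscosity),
    class = "assay_conditions"
  )
}

#' @export
print.assay_conditions <- function(x, ...) {
  cat(sprintf("Assay conditions [%s, %.3g cP]: E0 = %.3g uM, F0 = %.3g uM, A0 = %.3g uM\n",
              x$medium, x$viscosity, x$E0, x$F0, x$A0))
  invisible(x)
}
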