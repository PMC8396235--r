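#' Noise model for synthetic stopped-flow acquisitions
#'
#' Multiplicative Gaussian noise emulating detector noise on a stopped-flow
#' photomultiplier signal. Each recorded curve is the average of
#' `replicates` independent noisy realizations, mirroring the standard
#' acquisition protocol of averaging at least five replicate shots; set
#' `replicates = 1` for single-shot noise.
#'
#' @param sigma_rel Relative standard deviation per replicate (default 0.02).
#' @param floor Additive noise SD in signal units (default 0).
#' @param replicates Number of averaged replicates per curve (default 5).
#' @param seed Integer seed; identical seeds reproduce identical noise.
#' @return A list of class `noise_model`.
#' @examples
#' noise_model(sigma_rel = 0.02, seed = 42)
#' @export
noise_model <- function(sigma_rel = 0.02, floor = 0, replicates = 5L,
                        seed = 1L) {
  stopifnot(sigma_rel >= 0, floor >= 0, replicates >= 1L)
  structure(list(sigma_rel = sigma_rel, floor = floor,
                 replicates = as.integer(replicates),
                 seed = as.integer(seed)),
            class = "noise_model")
}

apply_noise <- function(y, noise) {
  if (noise$sigma_rel == 0 && noise$floor == 0) return(y)
  n <- length(y)
  reps <- vapply(seq_len(noise$replicates), function(i) {
    y * (1 + rnorm(n, 0, noise$sigma_rel)) + rnorm(n, 0, noise$floor)
  }, numeric(n))
  rowMeans(reps)
}

#' Rate-constant presets for every characterized medium
#'
#' Returns the elementary rate constants determined for the buffer and for
#' glycerol and sucrose media at 10--40% w/w: `kd` and `kdd` from separate
#' dark-decay experiments (fixed during fitting; the 30% glycerol values were
#' obtained by interpolation, carried as metadata), and `k1, k2, k3, km3, k4`
#' from global fits of five-concentration curve families.
#'
#' @return Named list of [rate_constants()]; names are `"buffer"`,
#'   `"glycerol_10"` ... `"glycerol_40"`, `"sucrose_10"` ... `"sucrose_40"`.
#'   Entries with interpolated dark rates carry attribute
#'   `"interpolated" = c("kd", "kdd")`.
#' @examples
#' table1_presets()$buffer
#' @export
table1_presets <- function() {
  row <- function(kd, kdd, k1, k2, k3, km3, k4)
    rate_constants(kd = kd, kdd = kdd, k1 = k1, k2 = k2, k3 = k3,
                   km3 = km3, k4 = k4)
  p <- list(
    buffer      = row(7.85, 0.15, 1.55, 400, 0.42, 10.90, 0.46),
    glycerol_10 = row(7.50, 0.15, 1.06, 398, 0.53,  8.95, 0.45),
    glycerol_20 = row(5.05, 0.15, 0.62, 403, 0.30,  7.50, 0.47),
    glycerol_30 = row(3.66, 0.12, 0.38, 403, 0.21,  5.42, 0.43),
    glycerol_40 = row(2.60, 0.10, 0.19, 395, 0.10,  5.30, 0.42),
    sucrose_10  = row(5.69, 0.15, 1.21, 401, 0.31,  7.02, 0.38),
    sucrose_20  = row(4.25, 0.12, 0.82, 403, 0.18,  9.07, 0.64),
    sucrose_30  = row(3.29, 0.09, 0.47, 393, 0.06,  9.40, 1.69),
    sucrose_40  = row(2.64, 0.05, 0.29, 402, 0.02,  4.67, 5.13)
  )
  attr(p$glycerol_30, "interpolated") <- c("kd", "kdd")
  p
}

preset_lookup <- function(medium) {
  p <- table1_presets()
  if (!medium %in% names(p))
    stop("unknown medium '", medium, "'; available: ",
         paste(names(p), collapse = ", "), call. = FALSE)
  p[[medium]]
}

#' Generate a multi-concentration synthetic curve family
#'
#' Simulates the single-turnover luminescence curve for each aldehyde
#' concentration under a medium's preset constants and applies the noise
#' model. Default conditions follow the standard assay: post-mix 0.95 µM
#' luciferase, 15 µM FMNH2, decanal at 10--50 µM, recorded 0--15 s.
#'
#' @param medium Medium key from [table1_presets()].
#' @param noise [noise_model()]; the family is deterministic under a fixed
#'   seed, and a pure function of (medium, aldehydes, grid) at zero noise.
#' @param aldehydes Decanal concentrations, µM.
#' @param E0,F0 Post-mix enzyme and flavin, µM.
#' @param t_grid Time grid, s.
#' @param scale Instrument scale factor shared with the fitter.
#' @return List of [kinetic_trace()] objects, one per aldehyde
#'   concentration, named by concentration.
#' @examples
#' fam <- generate_curve_family("buffer", noise_model(sigma_rel = 0),
#'                              t_grid = seq(0, 15, by = 0.05))
#' sapply(fam, function(tr) max(tr$y))
#' @export
generate_curve_family <- function(medium = "buffer", noise = noise_model(),
                                  aldehydes = c(10, 20, 30, 40, 50),
                                  E0 = 0.95, F0 = 15,
                                  t_grid = seq(0, 15, by = 1e-3),
                                  scale = 1.0) {
  stopifnot(inherits(noise, "noise_model"), length(aldehydes) >= 1L)
  k <- preset_lookup(medium)
  visc <- medium_viscosity(medium)
  clean <- lapply(aldehydes, function(a0)
    simulate_curve(k, assay_conditions(E0 = E0, F0 = F0, A0 = a0,
                                       medium = medium, viscosity = visc),
                   t_grid = t_grid, scale = scale))
  noisy <- withr::with_seed(noise$seed, lapply(clean, function(tr) {
    tr$y <- pmax(apply_noise(tr$y, noise), 0)
    attr(tr, "solution") <- NULL
    tr
  }))
  names(noisy) <- as.character(aldehydes)
  noisy
}

# viscosity for a preset key, from the default handbook tables
medium_viscosity <- function(medium) {
  if (medium == "buffer") return(1.0)
  parts <- strsplit(medium, "_", fixed = TRUE)[[1]]
  vt <- default_viscosities()[[parts[1]]]
  if (is.null(vt)) return(1.0)
  eta <- vt$eta[vt$fraction == as.numeric(parts[2])]
  if (length(eta) == 1L) eta else 1.0
}

#' Generate a synthetic 380-nm absorbance fixture
#'
#' A 0--15 ms monoexponential absorbance decay from [simulate_absorbance()]
#' with noise, emulating the Intermediate II formation experiment. Default
#' amplitude 0.05 and baseline 0.30 are shape-plausible synthetic values.
#'
#' @param k2 Decay rate, 1/s.
#' @param noise [noise_model()]; replicate averaging applies as for
#'   luminescence curves.
#' @param amp,offset Amplitude and baseline, absorbance units.
#' @param t_grid Time grid, s.
#' @return An absorbance [kinetic_trace()].
#' @examples
#' tr <- generate_absorbance_fixture(400, noise_model(sigma_rel = 0))
#' fit_k2_exponential(tr)$k2
#' @export
generate_absorbance_fixture <- function(k2 = 400, noise = noise_model(),
                                        amp = 0.05, offset = 0.30,
                                        t_grid = seq(0, 0.015, by = 1e-4)) {
  stopifnot(inherits(noise, "noise_model"))
  tr <- simulate_absorbance(k2, amp = amp, offset = offset, t_grid = t_grid)
  tr$y <- withr::with_seed(noise$seed, apply_noise(tr$y, noise))
  tr
}
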