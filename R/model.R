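#' Species state of the reaction scheme
#'
#' Builds the concentration state vector of the single-turnover scheme. All
#' components are in µM; `Q` is the cumulative emitted-quanta proxy (the
#' integral of the catalytic flux `k4 * I2A`), and `Sd`/`Sdd` book-keep
#' flavin lost to autoxidation and to Intermediate II dark decay, so that
#' `F + I1 + I2 + I2A + Q + Sd + Sdd` is conserved at `F0` and
#' `E + I1 + I2 + I2A` at `E0`.
#'
#' @param F Free FMNH2, µM.
#' @param E Free luciferase, µM.
#' @param I1 Intermediate I (E·FMNH2), µM.
#' @param I2 Intermediate II (E·FMNHOOH), µM.
#' @param A Free decanal, µM.
#' @param I2A Intermediate IIA (E·FMNOOH·RCOH), µM.
#' @param Q Cumulative emitted-quanta proxy, µM-equivalents.
#' @param Sd Cumulative autoxidized flavin, µM.
#' @param Sdd Cumulative dark-decayed flavin, µM.
#' @return Named numeric vector of length 9.
#' @examples
#' species_state(F = 15, E = 0.95, A = 40)
#' @export
species_state <- function(F = 0, E = 0, I1 = 0, I2 = 0, A = 0, I2A = 0,
                          Q = 0, Sd = 0, Sdd = 0) {
  s <- c(F = F, E = E, I1 = I1, I2 = I2, A = A, I2A = I2A, Q = Q,
         Sd = Sd, Sdd = Sdd)
  if (!is.numeric(s) || any(!is.finite(s)))
    stop("state components must be finite numerics", call. = FALSE)
  s
}

state_names <- c("F", "E", "I1", "I2", "A", "I2A", "Q", "Sd", "Sdd")

#' ODE right-hand side of the luciferase reaction scheme
#'
#' Reference implementation of the time derivatives of the single-turnover
#' scheme. The stages are: flavin binding (`k1`, reversible with `km1` in the
#' opt-in variant), pseudo-first-order Intermediate II formation (`k2`),
#' reversible aldehyde binding (`k3`/`km3`), the catalytic light-emitting
#' step (`k4`), and the two dark pathways (`kd` on free FMNH2, `kdd` on
#' Intermediate II). A C implementation of the same derivative is used by the
#' integrator; this function is the documented reference and is tested
#' against it.
#'
#' @param state Named state vector from [species_state()] (the bookkeeping
#'   components `Q`, `Sd`, `Sdd` may be omitted; they default to 0).
#' @param k A [rate_constants()] object.
#' @return Named numeric vector of derivatives, µM/s, same layout as the
#'   state.
#' @examples
#' k <- rate_constants(7.85, 0.15, 1.55, 400, 0.42, 10.90, 0.46)
#' lux_rhs(species_state(F = 15, E = 0.95), k)
#' @export
lux_rhs <- function(state, k) {
  stopifnot(inherits(k, "rate_constants"))
  if (is.null(names(state)) || !all(c("F", "E", "I1", "I2", "A", "I2A") %in% names(state)))
    stop("state must be a named vector with components F, E, I1, I2, A, I2A",
         call. = FALSE)
  s <- setNames(numeric(length(state_names)), state_names)
  s[names(state)] <- state
  if (any(!is.finite(s)))
    stop("state components must be finite", call. = FALSE)
  km1 <- if (is.null(k$km1)) 0 else k$km1
  bind1 <- k$k1 * s[["E"]] * s[["F"]]
  bind3 <- k$k3 * s[["I2"]] * s[["A"]]
  c(F   = -bind1 - k$kd * s[["F"]] + km1 * s[["I1"]],
    E   = -bind1 + k$kdd * s[["I2"]] + k$k4 * s[["I2A"]] + km1 * s[["I1"]],
    I1  =  bind1 - k$k2 * s[["I1"]] - km1 * s[["I1"]],
    I2  =  k$k2 * s[["I1"]] - k$kdd * s[["I2"]] - bind3 + k$km3 * s[["I2A"]],
    A   = -bind3 + k$km3 * s[["I2A"]],
    I2A =  bind3 - k$km3 * s[["I2A"]] - k$k4 * s[["I2A"]],
    Q   =  k$k4 * s[["I2A"]],
    Sd  =  k$kd * s[["F"]],
    Sdd =  k$kdd * s[["I2"]])
}

#' Instantaneous light intensity
#'
#' Light is emitted by deactivation of the excited species produced in the
#' catalytic step, so the observable intensity is proportional to the
#' catalytic flux: `scale * k4 * I2A`.
#'
#' @inheritParams lux_rhs
#' @param scale Positive instrument scale factor (arbitrary units per
#'   µM/s of catalytic flux).
#' @return Intensity in arbitrary units; zero iff `I2A` is zero.
#' @examples
#' k <- rate_constants(7.85, 0.15, 1.55, 400, 0.42, 10.90, 0.46)
#' lux_intensity(species_state(I2A = 1), k)
#' @export
lux_intensity <- function(state, k, scale = 1.0) {
  stopifnot(inherits(k, "rate_constants"))
  if (!is.numeric(scale) || scale <= 0)
    stop("scale must be > 0", call. = FALSE)
  i2a <- if ("I2A" %in% names(state)) state[["I2A"]] else
    stop("state must contain I2A", call. = FALSE)
  scale * k$k4 * i2a
}
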