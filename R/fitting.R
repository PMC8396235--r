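#' Options for the global curve-family fit
#'
#' @param n_starts Number of multi-starts (first start is the unperturbed
#'   initial guess; the rest are log-uniform perturbations by factors up to
#'   `perturb` in either direction).
#' @param seed Integer seed controlling the multi-start perturbations.
#' @param perturb Maximum multiplicative perturbation factor for starts;
#'   applied to `k1`, `k3`, `km3`, `k4`. The `k2` start is never perturbed
#'   (it is weakly identified and experimentally anchored).
#' @param maxit Maximum Levenberg--Marquardt iterations per start.
#' @param scale Instrument scale shared between simulator and data (the
#'   generator's convention; fixed, not fitted).
#' @param km1 Optional fixed flavin-dissociation rate, 1/s; a finite value
#'   fits the reversible-first-stage model variant.
#' @param window Time window, s, over which the maximum pointwise deviation
#'   is reported (the major part of the reaction time course).
#' @param rtol,atol Integrator tolerances used inside the fit.
#' @return A list of class `fit_options`.
#' @export
fit_options <- function(n_starts = 8L, seed = 1L, perturb = 5, maxit = 100L,
                        scale = 1.0, km1 = NULL, window = c(0.2, 5),
                        rtol = 1e-8, atol = 1e-10) {
  stopifnot(n_starts >= 1L, perturb >= 1, maxit >= 1L, scale > 0,
            length(window) == 2L, window[1] < window[2])
  if (!is.null(km1)) stopifnot(is.numeric(km1), km1 >= 0, km1 <= 5000)
  structure(list(n_starts = as.integer(n_starts), seed = as.integer(seed),
                 perturb = perturb, maxit = as.integer(maxit), scale = scale,
                 km1 = km1, window = window, rtol = rtol, atol = atol),
            class = "fit_options")
}

#' Default box bounds for the fitted constants
#'
#' Bounds span the physically plausible ranges: bimolecular rates
#' `k1`, `k3` in \[1e-4, 1e2\] 1/(µM·s), `km3` in \[1e-3, 1e3\] 1/s,
#' `k2` in \[10, 5000\] 1/s, `k4` in \[1e-3, 1e2\] 1/s.
#' @return A list with elements `lower` and `upper`, named numeric vectors
#'   over `k1, k2, k3, km3, k4`.
#' @export
default_fit_bounds <- function() {
  list(lower = c(k1 = 1e-4, k2 = 10,   k3 = 1e-4, km3 = 1e-3, k4 = 1e-3),
       upper = c(k1 = 1e2,  k2 = 5000, k3 = 1e2,  km3 = 1e3,  k4 = 1e2))
}

fitted_names <- c("k1", "k2", "k3", "km3", "k4")

# assemble a rate_constants object from fixed {kd, kdd}, the fitted vector
# and the (optionally) fixed km1
make_k <- function(p, fixed, km1 = NULL) {
  rate_constants(kd = fixed[["kd"]], kdd = fixed[["kdd"]],
                 k1 = p[["k1"]], k2 = p[["k2"]], k3 = p[["k3"]],
                 km3 = p[["km3"]], k4 = p[["k4"]], km1 = km1)
}

#' Global fit of elementary rate constants to a curve family
#'
#' Recovers one shared set of rate constants \{`k1`, `k2`, `k3`, `km3`,
#' `k4`\} by simultaneously fitting the reaction-scheme ODE model to several
#' luminescence curves recorded at different aldehyde concentrations in the
#' same medium. The dark-decay constants `kd` and `kdd` are determined in
#' separate experiments and held fixed. The objective is the plain summed
#' squared residual between simulated and observed intensity over all
#' curves (uniform weights); optimization is bounded Levenberg--Marquardt in
#' log-parameter space, restarted from `n_starts` perturbed initial guesses
#' with the best start returned.
#'
#' `k2` is not rate-limiting under assay conditions, so it is only weakly
#' identified by luminescence data; its recommended starting value is the
#' buffer absorbance-derived 400 1/s (see [fit_k2_exponential()]). Each start
#' therefore optimizes in two phases: the four identifiable constants first
#' with `k2` pinned at its starting value, then all five jointly from that
#' point. This avoids local minima in which `k2` collapses toward a bound
#' while `k3`/`km3`/`k4` compensate along the aldehyde-binding ridge.
#'
#' @param curves List of luminescence [kinetic_trace()] objects, each
#'   carrying its [assay_conditions()]; at least two, sharing one medium.
#' @param fixed Named numeric with the fixed dark rates `kd` and `kdd`, 1/s.
#' @param init Initial guess: a [rate_constants()] object or named numeric
#'   containing `k1, k2, k3, km3, k4`. Default starts `k2` at 400 1/s with
#'   order-of-magnitude guesses for the rest.
#' @param bounds List with `lower`/`upper` named vectors; see
#'   [default_fit_bounds()].
#' @param options [fit_options()].
#' @return An object of class `global_fit`: fitted constants (`k_hat`, with
#'   `kd`/`kdd` echoed), per-curve relative errors (%), their maximum,
#'   maximum pointwise deviation (%) over the reporting window, optimizer
#'   diagnostics and the multi-start bookkeeping table.
#' @examples
#' \donttest{
#' fam <- generate_curve_family("buffer", noise = noise_model(sigma_rel = 0),
#'                              t_grid = seq(0, 15, by = 0.02))
#' fit <- fit_global(fam, fixed = c(kd = 7.85, kdd = 0.15),
#'                   options = fit_options(n_starts = 2, seed = 1))
#' fit$k_hat
#' }
#' @export
fit_global <- function(curves, fixed, init = NULL,
                       bounds = default_fit_bounds(),
                       options = fit_options()) {
  if (!is.list(curves) || length(curves) < 2L)
    stop("need at least two curves for a global fit", call. = FALSE)
  ok <- vapply(curves, inherits, logical(1), "kinetic_trace")
  if (!all(ok)) stop("curves must be kinetic_trace objects", call. = FALSE)
  if (any(vapply(curves, function(cu) cu$kind != "luminescence", logical(1))))
    stop("global fitting requires luminescence traces", call. = FALSE)
  conds <- lapply(curves, `[[`, "conditions")
  if (any(vapply(conds, is.null, logical(1))))
    stop("every curve must carry its assay_conditions", call. = FALSE)
  media <- vapply(conds, `[[`, character(1), "medium")
  if (length(unique(media)) != 1L)
    stop("curves must share one medium; got: ", paste(unique(media), collapse = ", "),
         call. = FALSE)
  dead <- vapply(curves, function(cu) max(cu$y) <= 0, logical(1))
  if (any(dead))
    stop("curve(s) ", paste(which(dead), collapse = ", "),
         " carry no light; rate constants are unidentifiable from dark traces",
         call. = FALSE)
  if (!all(c("kd", "kdd") %in% names(fixed)))
    stop("fixed must supply kd and kdd", call. = FALSE)

  if (is.null(init))
    init <- c(k1 = 1, k2 = 400, k3 = 0.5, km3 = 10, k4 = 0.5)
  if (inherits(init, "rate_constants"))
    init <- vapply(fitted_names, function(nm) init[[nm]], numeric(1))
  init <- init[fitted_names]
  if (any(is.na(init)))
    stop("init must contain k1, k2, k3, km3, k4", call. = FALSE)
  lb <- bounds$lower[fitted_names]; ub <- bounds$upper[fitted_names]
  init <- pmin(pmax(init, lb), ub)

  opt <- options
  residual_fun <- function(logp) {
    p <- setNames(10^logp, fitted_names)
    k <- make_k(p, fixed, opt$km1)
    res <- lapply(curves, function(cu) {
      tr <- try(simulate_curve(k, cu$conditions, t_grid = cu$t,
                               scale = opt$scale, rtol = opt$rtol,
                               atol = opt$atol), silent = TRUE)
      if (inherits(tr, "try-error")) rep(1e6, length(cu$y)) else tr$y - cu$y
    })
    unlist(res, use.names = FALSE)
  }

  # multi-start: first start is init itself, the rest log-uniform within a
  # factor of `perturb` either way. k2 keeps its starting value in every
  # start: it is weakly identified by luminescence data (not rate-limiting),
  # its guess is anchored by the absorbance experiment, and perturbing it
  # only seeds local minima at the k2 bounds.
  jittered <- c("k1", "k3", "km3", "k4")
  starts <- withr::with_seed(opt$seed, {
    s <- matrix(rep(log10(init), opt$n_starts), nrow = opt$n_starts, byrow = TRUE)
    colnames(s) <- fitted_names
    if (opt$n_starts > 1L) {
      jitter <- matrix(runif((opt$n_starts - 1L) * length(jittered),
                             -log10(opt$perturb), log10(opt$perturb)),
                       ncol = length(jittered))
      s[-1L, jittered] <- s[-1L, jittered, drop = FALSE] + jitter
    }
    s
  })
  starts <- pmin(pmax(starts, rep(log10(lb), each = opt$n_starts)),
                 rep(log10(ub), each = opt$n_starts))

  # each start runs two phases: first the four identifiable constants with
  # k2 pinned at its anchored start (avoiding the k2-collapse ridge), then
  # all five released from the phase-1 endpoint
  ctrl <- minpack.lm::nls.lm.control(maxiter = opt$maxit,
                                     ftol = 1e-12, ptol = 1e-12)
  i4 <- match(jittered, fitted_names)
  run_start <- function(par0) {
    fn4 <- function(lp4) { lp <- par0; lp[i4] <- lp4; residual_fun(lp) }
    ph1 <- minpack.lm::nls.lm(par = par0[i4], lower = log10(lb)[i4],
                              upper = log10(ub)[i4], fn = fn4, control = ctrl)
    lp <- par0; lp[i4] <- ph1$par
    ph2 <- minpack.lm::nls.lm(par = lp, lower = log10(lb), upper = log10(ub),
                              fn = residual_fun, control = ctrl)
    ph2$niter <- ph2$niter + ph1$niter
    ph2
  }
  runs <- vector("list", opt$n_starts)
  for (i in seq_len(opt$n_starts)) {
    runs[[i]] <- try(run_start(starts[i, ]), silent = TRUE)
  }
  failed <- vapply(runs, inherits, logical(1), "try-error")
  if (all(failed))
    stop("optimizer failed on all ", opt$n_starts, " starts:\n",
         paste(vapply(runs, as.character, character(1)), collapse = ""),
         call. = FALSE)
  dev <- vapply(runs, function(r) if (inherits(r, "try-error")) Inf else r$deviance,
                numeric(1))
  best_i <- which.min(dev)
  best <- runs[[best_i]]
  p_hat <- setNames(10^best$par, fitted_names)
  k_hat <- make_k(p_hat, fixed, opt$km1)

  model_curves <- lapply(curves, function(cu)
    simulate_curve(k_hat, cu$conditions, t_grid = cu$t, scale = opt$scale,
                   rtol = opt$rtol, atol = opt$atol))
  per_curve <- mapply(relative_error, model_curves, curves)
  win_dev <- mapply(function(m, d) {
    tryCatch(window_deviation(m, d, window = opt$window),
             error = function(e) NA_real_)
  }, model_curves, curves)

  structure(
    list(k_hat = k_hat,
         per_curve_error = unname(per_curve),
         max_error = max(per_curve),
         window_deviation = if (all(is.na(win_dev))) NA_real_ else
           max(win_dev, na.rm = TRUE),
         window = opt$window,
         n_iter = best$niter,
         converged = best$info %in% 1:4,
         objective = best$deviance,
         starts = data.frame(start = seq_len(opt$n_starts),
                             objective = dev,
                             converged = vapply(runs, function(r)
                               !inherits(r, "try-error") && r$info %in% 1:4,
                               logical(1))),
         seed = opt$seed,
         medium = media[1],
         fixed = c(kd = unname(fixed[["kd"]]), kdd = unname(fixed[["kdd"]])),
         km1 = opt$km1,
         scale = opt$scale),
    class = "global_fit"
  )
}

#' @export
print.global_fit <- function(x, ...) {
  cat(sprintf("Global fit [%s]: %d curves, objective %.4g, %s (%d iterations, best of %d starts)\n",
              x$medium, length(x$per_curve_error), x$objective,
              if (x$converged) "converged" else "NOT converged",
              x$n_iter, nrow(x$starts)))
  cat(sprintf("  k1 = %.4g 1/(uM s), k2 = %.4g 1/s, k3 = %.4g 1/(uM s), k-3 = %.4g 1/s, k4 = %.4g 1/s\n",
              x$k_hat$k1, x$k_hat$k2, x$k_hat$k3, x$k_hat$km3, x$k_hat$k4))
  cat(sprintf("  (kd = %.4g, kdd = %.4g 1/s fixed%s)\n", x$fixed[["kd"]],
              x$fixed[["kdd"]],
              if (is.null(x$km1)) "" else sprintf("; k-1 = %.4g 1/s fixed", x$km1)))
  cat(sprintf("  relative error per curve (%%): %s; max %.3g%%\n",
              paste(sprintf("%.3g", x$per_curve_error), collapse = ", "),
              x$max_error))
  cat(sprintf("  max pointwise deviation over %.3g-%.3g s: %.3g%%\n",
              x$window[1], x$window[2], x$window_deviation))
  invisible(x)
}

#' Fit the monoexponential 380-nm absorbance decay
#'
#' Nonlinear least-squares fit of `D380(t) = A * exp(-k2 * t) + B` to an
#' absorbance trace, yielding the pseudo-first-order Intermediate II
#' formation rate `k2` with standard errors.
#'
#' @param trace An absorbance [kinetic_trace()] with a decaying segment and
#'   at least 10 points.
#' @return A list of class `k2_fit` with `k2`, `amp`, `offset`, `stderr`
#'   (named vector over the three parameters) and the underlying `nls` fit.
#' @examples
#' tr <- simulate_absorbance(400, 0.05, 0.30)
#' fit_k2_exponential(tr)$k2
#' @export
fit_k2_exponential <- function(trace) {
  stopifnot(inherits(trace, "kinetic_trace"))
  if (trace$kind != "absorbance")
    stop("k2 fitting requires an absorbance trace", call. = FALSE)
  t <- trace$t; y <- trace$y
  if (length(t) < 10L)
    stop("need at least 10 points for the exponential fit", call. = FALSE)
  amp0 <- y[1] - y[length(y)]
  if (amp0 <= .Machine$double.eps^0.5 * max(abs(y), 1))
    stop("trace does not decay: cannot fit a decaying exponential", call. = FALSE)
  # initial rate from the half-decay time of the baseline-subtracted signal
  b0 <- min(y)
  i_half <- which(y - b0 <= 0.5 * (y[1] - b0))[1]
  k2_0 <- if (!is.na(i_half) && t[i_half] > 0) log(2) / t[i_half] else
    3 / (t[length(t)] - t[1])
  fit <- minpack.lm::nlsLM(
    y ~ A * exp(-k2 * t) + B,
    data = data.frame(t = t, y = y),
    start = list(A = amp0, k2 = k2_0, B = b0),
    lower = c(A = -Inf, k2 = .Machine$double.eps, B = -Inf),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  est <- coef(fit)
  se <- summary(fit)$coefficients[, "Std. Error"]
  structure(list(k2 = unname(est[["k2"]]), amp = unname(est[["A"]]),
                 offset = unname(est[["B"]]),
                 stderr = c(amp = unname(se[["A"]]), k2 = unname(se[["k2"]]),
                            offset = unname(se[["B"]])),
                 fit = fit),
            class = "k2_fit")
}

#' @export
print.k2_fit <- function(x, ...) {
  cat(sprintf("Monoexponential absorbance fit: k2 = %.4g +/- %.2g 1/s, amp = %.4g, offset = %.4g\n",
              x$k2, x$stderr[["k2"]], x$amp, x$offset))
  invisible(x)
}

#' Normalized root-sum-of-squares relative error between two traces
#'
#' `100 * sqrt( sum((y_model - y_data)^2) / sum(y_data^2) )`, with the model
#' linearly interpolated onto the data grid. Monotone in the least-squares
#' objective minimized by [fit_global()].
#'
#' @param model,data [kinetic_trace()] objects.
#' @return Relative error in percent.
#' @examples
#' tr <- simulate_absorbance(400)
#' relative_error(tr, tr)
#' @export
relative_error <- function(model, data) {
  stopifnot(inherits(model, "kinetic_trace"), inherits(data, "kinetic_trace"))
  yd <- data$y
  if (all(yd == 0))
    stop("relative error undefined for an all-zero data trace", call. = FALSE)
  ym <- resample_trace(model, data$t)
  100 * sqrt(sum((ym - yd)^2) / sum(yd^2))
}

#' Maximum pointwise relative deviation over a time window
#'
#' `max over t in window of 100 * |y_model - y_data| / y_data`, evaluated on
#' the data grid with the model interpolated onto it. The default window,
#' 0.2--5 s, covers the major part of the single-turnover reaction time
#' course.
#'
#' @param model,data [kinetic_trace()] objects; both must cover the window,
#'   and the data must be strictly positive on it.
#' @param window Length-2 numeric, s.
#' @return Deviation in percent.
#' @examples
#' k <- rate_constants(7.85, 0.15, 1.55, 400, 0.42, 10.90, 0.46)
#' tr <- simulate_curve(k, assay_conditions(0.95, 15, 40),
#'                      t_grid = seq(0, 15, by = 0.01))
#' window_deviation(tr, tr)
#' @export
window_deviation <- function(model, data, window = c(0.2, 5)) {
  stopifnot(inherits(model, "kinetic_trace"), inherits(data, "kinetic_trace"),
            length(window) == 2L, window[1] < window[2])
  covers <- function(tr) tr$t[1] <= window[1] && tr$t[length(tr$t)] >= window[2]
  if (!covers(model) || !covers(data))
    stop("both traces must cover the window [", window[1], ", ", window[2], "] s",
         call. = FALSE)
  sel <- data$t >= window[1] & data$t <= window[2]
  yd <- data$y[sel]
  if (any(yd <= 0))
    stop("data trace has non-positive points inside the window; deviation undefined",
         call. = FALSE)
  ym <- resample_trace(model, data$t[sel])
  max(100 * abs(ym - yd) / yd)
}

#' Sensitivity of the fit to the flavin-dissociation rate
#'
#' Refits the reversible-first-stage model variant with the flavin
#' dissociation rate `km1` held fixed at each supplied value, and tabulates
#' the fitted constants and fit errors. Because the Intermediate II formation
#' step is fast, the fit is expected to be insensitive to `km1` over a wide
#' range (roughly 300--2000 1/s).
#'
#' Under rapid pre-equilibrium of Intermediate I, only the effective binding
#' flux `k1 * k2 / (k2 + km1)` is identified, so each refit is started from
#' the flux-equivalent point (the `k1` start is scaled by
#' `(k2_start + km1) / k2_start`); `k1` and `k2` may wander along this ridge
#' while the downstream constants stay put.
#'
#' @inheritParams fit_global
#' @param km1_values Numeric vector of fixed dissociation rates, 1/s, each
#'   within \[0, 5000\].
#' @return A data frame of class `reversibility_sweep`: one row per `km1`
#'   with the fitted `k1, k2, k3, km3, k4`, `max_error` and `converged`. The
#'   full `global_fit` objects are attached as attribute `"fits"`.
#' @export
reversibility_sensitivity <- function(curves, fixed, km1_values,
                                      init = NULL,
                                      bounds = default_fit_bounds(),
                                      options = fit_options()) {
  if (any(km1_values < 0 | km1_values > 5000))
    stop("km1 values must lie in [0, 5000] 1/s", call. = FALSE)
  if (is.null(init))
    init <- c(k1 = 1, k2 = 400, k3 = 0.5, km3 = 10, k4 = 0.5)
  if (inherits(init, "rate_constants"))
    init <- vapply(fitted_names, function(nm) init[[nm]], numeric(1))
  init <- init[fitted_names]
  fits <- lapply(km1_values, function(km1) {
    o <- options
    o$km1 <- if (km1 == 0) NULL else km1
    ini <- init
    ini[["k1"]] <- ini[["k1"]] * (ini[["k2"]] + km1) / ini[["k2"]]
    fit_global(curves, fixed, init = ini, bounds = bounds, options = o)
  })
  out <- data.frame(
    km1 = km1_values,
    k1 = vapply(fits, function(f) f$k_hat$k1, numeric(1)),
    k2 = vapply(fits, function(f) f$k_hat$k2, numeric(1)),
    k3 = vapply(fits, function(f) f$k_hat$k3, numeric(1)),
    km3 = vapply(fits, function(f) f$k_hat$km3, numeric(1)),
    k4 = vapply(fits, function(f) f$k_hat$k4, numeric(1)),
    max_error = vapply(fits, `[[`, numeric(1), "max_error"),
    converged = vapply(fits, `[[`, logical(1), "converged")
  )
  attr(out, "fits") <- fits
  class(out) <- c("reversibility_sweep", "data.frame")
  out
}
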