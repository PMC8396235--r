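#' Build a run configuration
#'
#' A `run_config` drives [run_pipeline()] end to end. Exactly one input mode
#' must be present: a `synthetic` block (media and generator settings) or an
#' `inputs` list of trace files with their assay metadata. The configuration
#' round-trips losslessly through YAML/JSON via [read_run_config()] and
#' [write_run_config()].
#'
#' @param synthetic `NULL`, or a list with elements `media` (character vector
#'   of [table1_presets()] keys), and optionally `aldehydes` (µM),
#'   `sigma_rel`, `replicates`, `noise_floor`, `dt` (s), `t_max` (s),
#'   `E0`, `F0` (µM), `scale`.
#' @param inputs `NULL`, or a list of entries, each a list with `path`,
#'   `medium`, `E0`, `F0`, `A0`, `viscosity`, and optionally `dialect`.
#' @param fixed Named list mapping each medium to its fixed dark rates
#'   `c(kd =, kdd =)`. Defaults to the preset values for preset media.
#' @param fit List of [fit_options()] overrides (`n_starts`, `maxit`,
#'   `perturb`, `window`) plus optional `init` (named vector over
#'   `k1, k2, k3, km3, k4`).
#' @param features List with `v0_frac` and `decay_frac` thresholds.
#' @param viscosities Named list of [viscosity_table()]s per cosolvent;
#'   defaults to [default_viscosities()].
#' @param seed Single integer; every random draw in the run flows from it.
#' @return A list of class `run_config`.
#' @examples
#' cfg <- run_config(synthetic = list(media = c("buffer", "sucrose_20"),
#'                                    dt = 0.05), seed = 7)
#' @export
run_config <- function(synthetic = NULL, inputs = NULL, fixed = NULL,
                       fit = list(), features = list(), viscosities = NULL,
                       seed = 1L) {
  if (is.null(synthetic) == is.null(inputs))
    stop("exactly one of 'synthetic' or 'inputs' must be supplied", call. = FALSE)
  if (!is.null(synthetic)) {
    if (is.null(synthetic$media)) stop("synthetic block needs 'media'", call. = FALSE)
    synthetic <- modifyList(
      list(aldehydes = c(10, 20, 30, 40, 50), sigma_rel = 0.02,
           replicates = 5L, noise_floor = 0, dt = 1e-3, t_max = 15,
           E0 = 0.95, F0 = 15, scale = 1.0),
      synthetic)
  }
  fit <- modifyList(list(n_starts = 4L, maxit = 100L, perturb = 5,
                         window = c(0.2, 5), init = NULL), fit)
  features <- modifyList(list(v0_frac = 0.2, decay_frac = 0.5), features)
  structure(list(schema_version = 1L, synthetic = synthetic, inputs = inputs,
                 fixed = fixed, fit = fit, features = features,
                 viscosities = viscosities, seed = as.integer(seed)),
            class = "run_config")
}

#' Read / write a run configuration
#'
#' YAML (`.yml`/`.yaml`) or JSON (anything else) serialization of a
#' [run_config()].
#'
#' @param path File path.
#' @return For `read_run_config`, a `run_config`; for `write_run_config`,
#'   `path` invisibly.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!is.null(raw$schema_version) && raw$schema_version != 1L)
    stop("unsupported config schema_version: ", raw$schema_version, call. = FALSE)
  raw$schema_version <- NULL
  vt <- raw$viscosities
  if (!is.null(vt))
    raw$viscosities <- lapply(vt, function(v)
      viscosity_table(v$medium, unlist(v$fraction), unlist(v$eta)))
  if (!is.null(raw$fit$window)) raw$fit$window <- unlist(raw$fit$window)
  if (!is.null(raw$fit$init)) raw$fit$init <- unlist(raw$fit$init)
  if (!is.null(raw$synthetic$aldehydes))
    raw$synthetic$aldehydes <- unlist(raw$synthetic$aldehydes)
  if (!is.null(raw$fixed)) raw$fixed <- lapply(raw$fixed, unlist)
  do.call(run_config, raw)
}

#' @rdname read_run_config
#' @param config A [run_config()].
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  x <- unclass(config)
  x$viscosities <- lapply(x$viscosities, function(v)
    list(medium = v$medium[1], fraction = v$fraction, eta = v$eta))
  if (length(x$viscosities) == 0L) x$viscosities <- NULL
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::write_yaml(x, path)
  else
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

# fixed dark rates for a medium: config override, else preset
fixed_for_medium <- function(config, medium) {
  if (!is.null(config$fixed) && medium %in% names(config$fixed))
    return(config$fixed[[medium]])
  k <- preset_lookup(medium)
  c(kd = k$kd, kdd = k$kdd)
}

#' Run the full kinetic-analysis pipeline
#'
#' Executes, per the run configuration: curve acquisition (synthetic
#' generation or file loading), empirical feature extraction per curve,
#' global rate-constant fitting per medium, power-law rate--viscosity
#' regression per rate constant across each cosolvent series, and
#' diffusion-control classification. When `outdir` is given, writes
#' `constants.csv`, `features.csv`, `power_laws.csv`, a `summary.json` and a
#' `run_log.txt` recording seeds and options.
#'
#' @param config A [run_config()] (or a path to one).
#' @param outdir Optional output directory (created if missing).
#' @return A list of class `lux_report` with elements `constants` (one row
#'   per medium), `features` (one row per curve), `power_laws` (one row per
#'   constant and cosolvent series), `fits` (the `global_fit` objects) and
#'   `config`.
#' @examples
#' \donttest{
#' cfg <- run_config(synthetic = list(media = "buffer", sigma_rel = 0,
#'                                    dt = 0.02),
#'                   fit = list(n_starts = 2), seed = 1)
#' rep <- run_pipeline(cfg)
#' rep$constants
#' }
#' @export
run_pipeline <- function(config, outdir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))

  # --- acquire curves, grouped by medium -------------------------------
  families <- tryCatch(acquire_curves(config),
                       error = function(e) stop("[acquire] ", conditionMessage(e),
                                                call. = FALSE))

  # --- empirical features per curve ------------------------------------
  features <- tryCatch(do.call(rbind, lapply(names(families), function(m) {
    fam <- families[[m]]
    do.call(rbind, lapply(names(fam), function(a0) {
      f <- extract_features(fam[[a0]], v0_frac = config$features$v0_frac,
                            decay_frac = config$features$decay_frac)
      data.frame(medium = m, A0 = as.numeric(a0), Imax = f$Imax,
                 Qstar = f$Qstar, v0 = f$v0, kdecay = f$kdecay)
    }))
  })), error = function(e) stop("[features] ", conditionMessage(e), call. = FALSE))

  # --- global fit per medium -------------------------------------------
  scale <- if (!is.null(config$synthetic)) config$synthetic$scale else 1.0
  fits <- tryCatch(lapply(names(families), function(m) {
    fit_global(families[[m]], fixed = fixed_for_medium(config, m),
               init = config$fit$init,
               options = fit_options(n_starts = config$fit$n_starts,
                                     seed = config$seed,
                                     perturb = config$fit$perturb,
                                     maxit = config$fit$maxit,
                                     scale = scale,
                                     window = config$fit$window))
  }), error = function(e) stop("[fit] ", conditionMessage(e), call. = FALSE))
  names(fits) <- names(families)
  constants <- do.call(rbind, lapply(names(fits), function(m) {
    f <- fits[[m]]
    data.frame(medium = m, eta = medium_viscosity(m),
               kd = f$fixed[["kd"]], kdd = f$fixed[["kdd"]],
               k1 = f$k_hat$k1, k2 = f$k_hat$k2, k3 = f$k_hat$k3,
               km3 = f$k_hat$km3, k4 = f$k_hat$k4,
               max_error = f$max_error,
               window_deviation = f$window_deviation,
               converged = f$converged)
  }))

  # --- power-law fits per constant across each cosolvent series --------
  power_laws <- tryCatch(power_law_report(constants),
                         error = function(e) stop("[viscosity] ",
                                                  conditionMessage(e),
                                                  call. = FALSE))

  report <- structure(list(constants = constants, features = features,
                           power_laws = power_laws, fits = fits,
                           config = config),
                      class = "lux_report")
  if (!is.null(outdir)) write_report(report, outdir)
  report
}

acquire_curves <- function(config) {
  if (!is.null(config$synthetic)) {
    syn <- config$synthetic
    grid <- seq(0, syn$t_max, by = syn$dt)
    fams <- lapply(seq_along(syn$media), function(i)
      generate_curve_family(
        syn$media[i],
        noise = noise_model(sigma_rel = syn$sigma_rel, floor = syn$noise_floor,
                            replicates = syn$replicates,
                            seed = config$seed + i - 1L),
        aldehydes = syn$aldehydes, E0 = syn$E0, F0 = syn$F0,
        t_grid = grid, scale = syn$scale))
    names(fams) <- syn$media
    return(fams)
  }
  entries <- config$inputs
  traces <- lapply(entries, function(e) {
    cond <- assay_conditions(E0 = e$E0, F0 = e$F0, A0 = e$A0,
                             medium = e$medium,
                             viscosity = if (is.null(e$viscosity)) 1.0 else e$viscosity)
    read_trace(e$path, dialect = if (is.null(e$dialect)) "auto" else e$dialect,
               conditions = cond)
  })
  media <- vapply(entries, `[[`, character(1), "medium")
  fams <- split(traces, media)
  lapply(fams, function(fam) {
    names(fam) <- vapply(fam, function(tr) as.character(tr$conditions$A0),
                         character(1))
    fam
  })
}

power_law_report <- function(constants, viscosities = NULL) {
  series <- sub("_[0-9]+$", "", constants$medium)
  cosolvents <- setdiff(unique(series), "buffer")
  rows <- list()
  for (cs in cosolvents) {
    sel <- constants[series %in% c(cs, "buffer"), ]
    if (nrow(sel) < 3L) next
    for (const in c("kd", "kdd", "k1", "k2", "k3", "km3", "k4")) {
      kv <- sel[[const]]
      if (any(kv <= 0)) next
      fit <- fit_power_law(sel$eta, kv)
      rows[[length(rows) + 1L]] <- data.frame(
        series = cs, constant = const, delta = fit$delta,
        delta_se = fit$delta_se, r2 = fit$r2, n_points = fit$n_points,
        class = classify_stage(fit))
    }
  }
  if (length(rows) == 0L)
    return(data.frame(series = character(), constant = character(),
                      delta = numeric(), delta_se = numeric(), r2 = numeric(),
                      n_points = integer(), class = character()))
  do.call(rbind, rows)
}

write_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write.csv(report$constants, file.path(outdir, "constants.csv"),
            row.names = FALSE)
  write.csv(report$features, file.path(outdir, "features.csv"),
            row.names = FALSE)
  write.csv(report$power_laws, file.path(outdir, "power_laws.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    list(constants = report$constants, power_laws = report$power_laws,
         seed = report$config$seed),
    file.path(outdir, "summary.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  log <- c(sprintf("seed: %d", report$config$seed),
           sprintf("media: %s", paste(report$constants$medium, collapse = ", ")),
           sprintf("fit: n_starts=%d maxit=%d perturb=%g",
                   report$config$fit$n_starts, report$config$fit$maxit,
                   report$config$fit$perturb),
           sprintf("generated: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")))
  writeLines(log, file.path(outdir, "run_log.txt"))
  invisible(outdir)
}

#' @export
print.lux_report <- function(x, ...) {
  cat("Luciferase kinetics pipeline report\n\n")
  cat("Fitted constants per medium:\n")
  print(x$constants, row.names = FALSE)
  if (nrow(x$power_laws)) {
    cat("\nPower-law viscosity dependence per constant:\n")
    print(x$power_laws, row.names = FALSE)
  }
  invisible(x)
}
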