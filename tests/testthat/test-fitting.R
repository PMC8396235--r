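test_that("relative error matches its closed forms and a brute-force oracle", {
  tr <- simulate_curve(buffer_k(), buffer_cond(), t_grid = grid_coarse)
  expect_equal(relative_error(tr, tr), 0)

  up <- tr; up$y <- 1.01 * tr$y
  expect_equal(relative_error(up, tr), 1.0, tolerance = 1e-9)

  set.seed(3)
  pert <- tr; pert$y <- tr$y + rnorm(length(tr$y), 0, 0.01 * max(tr$y))
  expect_equal(relative_error(pert, tr),
               100 * sqrt(sum((pert$y - tr$y)^2) / sum(tr$y^2)))

  zero <- kinetic_trace(tr$t, rep(0, length(tr$t)), "luminescence")
  expect_error(relative_error(tr, zero), "all-zero")

  # scale consistency: common rescaling leaves the metric unchanged
  m2 <- pert; m2$y <- 5 * pert$y
  d2 <- tr; d2$y <- 5 * tr$y
  expect_equal(relative_error(m2, d2), relative_error(pert, tr))
})

test_that("window deviation is the pointwise maximum over 0.2-5 s", {
  tr <- simulate_curve(buffer_k(), buffer_cond(), t_grid = grid_coarse)
  expect_equal(window_deviation(tr, tr), 0)

  up <- tr; up$y <- 1.05 * tr$y
  expect_equal(window_deviation(up, tr), 5.0, tolerance = 1e-9)

  set.seed(4)
  pert <- tr; pert$y <- tr$y * (1 + rnorm(length(tr$y), 0, 0.02))
  sel <- tr$t >= 0.2 & tr$t <= 5
  expect_equal(window_deviation(pert, tr),
               max(100 * abs(pert$y[sel] - tr$y[sel]) / tr$y[sel]))

  # scale consistency
  m2 <- pert; m2$y <- 3 * pert$y
  d2 <- tr; d2$y <- 3 * tr$y
  expect_equal(window_deviation(m2, d2), window_deviation(pert, tr))

  short <- kinetic_trace(seq(0.5, 5, 0.1), rep(1, 46), "luminescence")
  expect_error(window_deviation(short, short), "cover")
})

test_that("monoexponential k2 fit round-trips noiseless decays within 0.1%", {
  for (k2 in c(50, 400, 1000)) {
    tr <- simulate_absorbance(k2, amp = 0.05, offset = 0.30,
                              t_grid = seq(0, 0.015, by = 1e-4))
    f <- fit_k2_exponential(tr)
    expect_lt(abs(f$k2 - k2) / k2, 0.001)
    expect_equal(f$amp, 0.05, tolerance = 1e-4)
    expect_equal(f$offset, 0.30, tolerance = 1e-4)
    expect_true(all(f$stderr >= 0))
  }
})

test_that("k2 fit rejects flat and non-decaying traces", {
  t <- seq(0, 0.015, 1e-3)
  expect_error(fit_k2_exponential(
    kinetic_trace(t, rep(0.3, length(t)), "absorbance")), "does not decay")
  expect_error(fit_k2_exponential(
    kinetic_trace(t, 0.3 + t, "absorbance")), "does not decay")
  expect_error(fit_k2_exponential(
    kinetic_trace(t[1:5], rep(c(1, 0.5), len = 5), "absorbance")), "10 points")
  expect_error(fit_k2_exponential(simulate_curve(buffer_k(), buffer_cond(),
                                                 t_grid = grid_coarse)),
               "absorbance")
})

test_that("noiseless self-consistency refit recovers the generating constants", {
  fam <- generate_curve_family("buffer", no_noise(), t_grid = grid_coarse)
  fit <- fit_global(fam, fixed = c(kd = 7.85, kdd = 0.15),
                    init = c(k1 = 1, k2 = 400, k3 = 0.5, km3 = 10, k4 = 0.5),
                    options = fast_fit(n_starts = 2))
  truth <- buffer_k()
  for (nm in c("k1", "k3", "km3", "k4"))
    expect_lt(abs(fit$k_hat[[nm]] - truth[[nm]]) / truth[[nm]], 0.02)
  expect_lt(fit$max_error, 0.5)
  expect_true(fit$converged)
  # objective of the winning start is the minimum over starts
  expect_equal(fit$objective, min(fit$starts$objective))
})

test_that("multi-start bookkeeping is reproducible under a fixed seed", {
  fam <- generate_curve_family("buffer", no_noise(),
                               t_grid = seq(0, 15, by = 0.05))
  f1 <- fit_global(fam, c(kd = 7.85, kdd = 0.15),
                   init = buffer_k(), options = fast_fit(n_starts = 3, seed = 9))
  f2 <- fit_global(fam, c(kd = 7.85, kdd = 0.15),
                   init = buffer_k(), options = fast_fit(n_starts = 3, seed = 9))
  expect_identical(f1$starts, f2$starts)
  expect_identical(f1$k_hat, f2$k_hat)
})

test_that("degenerate inputs are rejected", {
  fam <- generate_curve_family("buffer", no_noise(),
                               t_grid = seq(0, 15, by = 0.05))
  dark_k <- rate_constants(7.85, 0.15, 1.55, 400, 0, 10.90, 0.46)
  dark <- simulate_curve(dark_k, buffer_cond(), t_grid = seq(0, 15, by = 0.05))
  expect_error(fit_global(list(dark, dark), c(kd = 7.85, kdd = 0.15)),
               "no light|unidentifiable")
  expect_error(fit_global(fam[1], c(kd = 7.85, kdd = 0.15)), "two curves")
  expect_error(fit_global(fam, c(kd = 7.85)), "kdd")
  mixed <- fam
  mixed[[1]]$conditions$medium <- "sucrose_10"
  expect_error(fit_global(mixed, c(kd = 7.85, kdd = 0.15)), "medium")
})

test_that("fit is insensitive to the fixed flavin-dissociation rate", {
  fam <- generate_curve_family("buffer", no_noise(), t_grid = grid_coarse)
  sweep <- reversibility_sensitivity(
    fam, c(kd = 7.85, kdd = 0.15), km1_values = c(0, 300, 1200, 2000),
    init = buffer_k(), options = fast_fit())
  truth <- buffer_k()
  # downstream constants stay put across the whole sweep...
  for (nm in c("k3", "km3", "k4"))
    expect_true(all(abs(sweep[[nm]] - truth[[nm]]) / truth[[nm]] < 0.05))
  # ...and fit quality stays at the noise floor
  expect_true(all(sweep$max_error < 0.5))
  # km1 = 0 is exactly the irreversible model
  irrev <- fit_global(fam, c(kd = 7.85, kdd = 0.15), init = buffer_k(),
                      options = fast_fit())
  expect_equal(sweep$k1[1], irrev$k_hat$k1, tolerance = 1e-8)
  expect_equal(sweep$k4[1], irrev$k_hat$k4, tolerance = 1e-8)
  expect_error(reversibility_sensitivity(fam, c(kd = 7.85, kdd = 0.15),
                                         km1_values = 6000), "5000")
})
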