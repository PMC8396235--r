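test_that("rhs reproduces hand-derived derivatives on simple states", {
  k <- buffer_k()

  # empty system: no species, no fluxes
  d0 <- lux_rhs(species_state(), k)
  expect_true(all(d0 == 0))

  # only free flavin, no enzyme: pure autoxidation of F
  d <- lux_rhs(species_state(F = 2), k)
  expect_equal(d[["F"]], -7.85 * 2)
  expect_equal(d[["Sd"]], 7.85 * 2)
  expect_true(all(d[c("E", "I1", "I2", "A", "I2A", "Q")] == 0))

  # post-mix initial state: the only active flux is flavin binding
  d <- lux_rhs(species_state(F = 15, E = 0.95, A = 40), k)
  expect_equal(d[["I1"]], 1.55 * 0.95 * 15)  # = 22.09 uM/s, hand-multiplied
  expect_equal(d[["I1"]], 22.0875)
  expect_equal(d[["E"]], -1.55 * 0.95 * 15)
  expect_equal(d[["A"]], 0)
})

test_that("rhs derivatives sum to the conservation laws on random states", {
  set.seed(42)
  k <- buffer_k()
  kr <- buffer_k(km1 = 1200)
  for (i in 1:25) {
    s <- species_state(F = runif(1, 0, 15), E = runif(1, 0, 1),
                       I1 = runif(1, 0, 0.5), I2 = runif(1, 0, 0.5),
                       A = runif(1, 0, 50), I2A = runif(1, 0, 0.5))
    for (kk in list(k, kr)) {
      d <- lux_rhs(s, kk)
      # enzyme pool is closed: E + I1 + I2 + I2A constant
      expect_equal(sum(d[c("E", "I1", "I2", "I2A")]), 0, tolerance = 1e-12)
      # flavin pool closed once the sinks are counted
      expect_equal(sum(d[c("F", "I1", "I2", "I2A", "Q", "Sd", "Sdd")]), 0,
                   tolerance = 1e-12)
      # aldehyde pool closed through the product proxy
      expect_equal(sum(d[c("A", "I2A", "Q")]), 0, tolerance = 1e-12)
    }
  }
})

test_that("reversible variant with km1 = 0 equals the default rhs term by term", {
  set.seed(7)
  k0 <- buffer_k()
  kz <- buffer_k(km1 = 0)
  for (i in 1:10) {
    s <- species_state(F = runif(1, 0, 15), E = runif(1, 0, 1),
                       I1 = runif(1), I2 = runif(1), A = runif(1, 0, 50),
                       I2A = runif(1))
    expect_identical(lux_rhs(s, k0), lux_rhs(s, kz))
  }
})

test_that("compiled integrator and R reference rhs agree along a trajectory", {
  k <- buffer_k()
  tr <- simulate_curve(k, buffer_cond(), t_grid = grid_coarse)
  sol <- attr(tr, "solution")
  # finite-difference derivative of the solution vs the R rhs at interior pts
  for (i in c(50, 200, 800)) {
    s <- sol[i, -1]
    d_r <- lux_rhs(s, k)
    dt <- sol[i + 1, "time"] - sol[i - 1, "time"]
    d_fd <- (sol[i + 1, -1] - sol[i - 1, -1]) / dt
    expect_equal(unname(d_r), unname(d_fd), tolerance = 1e-3)
  }
})

test_that("intensity is the scaled catalytic flux and linear in scale", {
  k <- buffer_k()
  expect_equal(lux_intensity(species_state(I2A = 0), k), 0)
  expect_equal(lux_intensity(species_state(I2A = 1), k, scale = 1), 0.46)
  s <- species_state(I2A = 0.37)
  expect_equal(lux_intensity(s, k, scale = 2), 2 * lux_intensity(s, k, scale = 1))
  expect_error(lux_intensity(s, k, scale = 0), "scale")
})

test_that("total quanta fall monotonically to zero as autoxidation outcompetes binding", {
  kds <- c(7.85, 50, 300, 2000)
  qinf <- vapply(kds, function(kd) {
    k <- rate_constants(kd, 0.15, 1.55, 400, 0.42, 10.90, 0.46)
    sol <- attr(simulate_curve(k, buffer_cond(), t_grid = grid_coarse), "solution")
    sol[nrow(sol), "Q"]
  }, numeric(1))
  expect_true(all(diff(qinf) < 0))
  expect_lt(qinf[length(qinf)] / qinf[1], 0.05)
})

test_that("constructors reject invalid rates and conditions", {
  expect_error(rate_constants(-1, 0.15, 1.55, 400, 0.42, 10.9, 0.46), ">= 0")
  expect_error(rate_constants(7.85, 0.15, 1.55, 400, 0.42, 10.9, 0.46, km1 = -5))
  expect_error(assay_conditions(0, 15, 40))
  expect_error(assay_conditions(0.95, 15, 40, viscosity = 0.5), "viscosity")
})
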