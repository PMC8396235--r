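test_that("no aldehyde pathway means no light", {
  k <- rate_constants(7.85, 0.15, 1.55, 400, 0, 10.90, 0.46)  # k3 = 0
  tr <- simulate_curve(k, buffer_cond(), t_grid = grid_coarse)
  expect_true(all(tr$y == 0))
})

test_that("buffer curve is single-peaked: rises, peaks inside, then decays", {
  tr <- simulate_curve(buffer_k(), buffer_cond(), t_grid = grid_coarse)
  ipk <- which.max(tr$y)
  expect_gt(ipk, 1)
  expect_lt(ipk, length(tr$y))
  expect_true(all(diff(tr$y[1:ipk]) >= 0))
  expect_true(all(diff(tr$y[ipk:length(tr$y)]) <= 0))
})

test_that("more aldehyde captures more Intermediate II: Q*(50) > Q*(10)", {
  q <- vapply(c(10, 50), function(a0) {
    tr <- simulate_curve(buffer_k(), buffer_cond(A0 = a0), t_grid = grid_coarse)
    pracma::trapz(tr$t, tr$y)
  }, numeric(1))
  expect_gt(q[2], q[1])
})

test_that("enzyme and flavin conservation hold along the trajectory", {
  for (a0 in c(10, 40)) {
    sol <- attr(simulate_curve(buffer_k(), buffer_cond(A0 = a0),
                               t_grid = grid_coarse), "solution")
    enz <- sol[, "E"] + sol[, "I1"] + sol[, "I2"] + sol[, "I2A"]
    flav <- sol[, "F"] + sol[, "I1"] + sol[, "I2"] + sol[, "I2A"] +
      sol[, "Q"] + sol[, "Sd"] + sol[, "Sdd"]
    expect_lt(max(abs(enz - 0.95)) / 0.95, 1e-6)
    expect_lt(max(abs(flav - 15)) / 15, 1e-6)
    expect_true(all(sol[, -1] > -1e-9))
  }
})

test_that("cumulative quanta equal the integrated intensity observable", {
  tr <- simulate_curve(buffer_k(), buffer_cond(), t_grid = seq(0, 15, 1e-3))
  sol <- attr(tr, "solution")
  q_trapz <- pracma::trapz(tr$t, tr$y)  # scale = 1, so intensity = k4*I2A
  expect_equal(q_trapz, unname(sol[nrow(sol), "Q"]), tolerance = 1e-5)
})

test_that("free reduced flavin is essentially gone by 0.5 s in buffer", {
  sol <- attr(simulate_curve(buffer_k(), buffer_cond(),
                             t_grid = seq(0, 1, by = 0.01)), "solution")
  expect_lt(sol[sol[, "time"] == 0.5, "F"] / 15, 0.02)
})

test_that("tightening integrator tolerances changes the trace by < 0.1%", {
  cond <- buffer_cond()
  a <- simulate_curve(buffer_k(), cond, t_grid = grid_coarse,
                      rtol = 1e-8, atol = 1e-10)
  b <- simulate_curve(buffer_k(), cond, t_grid = grid_coarse,
                      rtol = 1e-10, atol = 1e-12)
  denom <- max(a$y)
  expect_lt(max(abs(a$y - b$y)) / denom, 1e-3)
})

test_that("absorbance decay matches the closed-form monoexponential", {
  # half-decay identity: at t = ln 2 / k2 the amplitude has halved
  tr <- simulate_absorbance(400, amp = 0.05, offset = 0.30,
                            t_grid = c(0, log(2) / 400, 0.015))
  expect_equal(tr$y[1], 0.35)
  expect_equal(tr$y[2], 0.325)
  # pointwise brute-force evaluation on a dense grid
  g <- seq(0, 0.015, by = 1e-4)
  tr <- simulate_absorbance(400, 0.05, 0.30, t_grid = g)
  expect_equal(tr$y, 0.05 * exp(-400 * g) + 0.30)
  expect_error(simulate_absorbance(-1), "k2")
  expect_error(simulate_absorbance(400, amp = 0), "amplitude")
})

test_that("simulation rejects out-of-contract grids", {
  expect_error(simulate_curve(buffer_k(), buffer_cond(), t_grid = seq(0, 90, 1)),
               "60 s")
  expect_error(simulate_curve(buffer_k(), buffer_cond(),
                              t_grid = c(0, 2, 1)), "increasing")
})
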