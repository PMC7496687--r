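test_that("calibration follows the hyperbola with its anchor points", {
  p <- calibration_params(fmax = 1)
  expect_equal(p$fmin, 1 / 15)
  expect_equal(p$kd, 1.58)

  f <- time_series(c(1 / 15, 0.5, 0.9), dt = 1, unit = "a.u.")
  ca <- calibrate_fluorescence(f, p)
  expect_equal(ca$values[1], 0)                                # F = Fmin
  expect_equal(ca$values[2], 1.58 * (0.5 - 1 / 15) / (1 - 0.5),
               tolerance = 1e-12)                              # 1.369333... uM
  expect_identical(ca$unit, "uM")

  # inverse anchors: ca = 0 -> Fmin; ca = Kd -> midpoint; ca -> Inf -> Fmax
  p2 <- calibration_params(fmax = 10)
  fl <- inverse_calibrate(time_series(c(0, 1.58, 1e6), 1, 0, "uM"), p2)
  expect_equal(fl$values[1], p2$fmin)
  expect_equal(fl$values[2], (p2$fmax + p2$fmin) / 2)
  expect_lt(abs(fl$values[3] - p2$fmax) / p2$fmax, 1e-4)

  expect_error(
    calibrate_fluorescence(time_series(c(0.5, 1.2), 1, 0, "a.u."), p),
    "at/above Fmax at index 2")
  expect_warning(
    ca_clip <- calibrate_fluorescence(time_series(c(0.01, 0.5), 1, 0, "a.u."), p),
    "clipped")
  expect_equal(ca_clip$values[1], 0)
})

test_that("calibration and inverse are mutual inverses on [0, Inf)", {
  p <- calibration_params(fmax = 7.3)
  ca <- time_series(c(0, 10^seq(-3, 3, length.out = 50)), dt = 1, unit = "uM")
  back <- calibrate_fluorescence(inverse_calibrate(ca, p), p)
  expect_equal(back$values, ca$values, tolerance = 1e-9)

  f <- time_series(seq(p$fmin, p$fmax * 0.999, length.out = 40), 1, 0, "a.u.")
  f2 <- inverse_calibrate(calibrate_fluorescence(f, p), p)
  expect_equal(f2$values, f$values, tolerance = 1e-9)
})

test_that("single-exponential fit recovers its generator", {
  tt <- seq(0, 900, 1)
  y <- 0.1 + 1.0 * exp(-tt / 220)
  fit <- fit_single_exponential(time_series(y, 1, 0, "uM"), t_start = 0)
  expect_equal(fit$amplitude, 1.0, tolerance = 1e-6)
  expect_equal(fit$tau, 220, tolerance = 1e-6)
  expect_equal(fit$baseline, 0.1, tolerance = 1e-6)
  expect_lt(fit$rmse, 1e-8)

  # a window offset only shifts the amplitude reference point
  fit2 <- fit_single_exponential(time_series(y, 1, 0, "uM"), t_start = 100)
  expect_equal(fit2$tau, 220, tolerance = 1e-6)

  expect_error(
    fit_single_exponential(time_series(rep(0.5, 60), 1, 0, "uM"), 0),
    "does not decay")

  # 2% additive noise: median tau recovery within 5% over 50 seeds
  taus <- vapply(1:50, function(s) {
    set.seed(s)
    yn <- y + stats::rnorm(length(y), 0, 0.02)
    fit_single_exponential(time_series(yn, 1, 0, "uM"), 0)$tau
  }, numeric(1))
  expect_lt(abs(stats::median(taus) / 220 - 1), 0.05)
})

test_that("submembrane reconstruction matches closed forms", {
  # constant input: derivative term vanishes, trace returned unchanged
  const <- time_series(rep(0.1, 50), dt = 1, unit = "uM")
  ct <- reconstruct_submembrane(const)
  expect_equal(ct$ca_sm$values, const$values)
  expect_null(ct$decay_fit)

  # exponential input: raw_sm = A (1 - gamma/tau) exp(-t/tau)
  dt <- 0.25; tau <- 220; A <- 1
  tt <- seq(0, 800, dt)
  ca <- time_series(A * exp(-tt / tau), dt = dt, unit = "uM")
  ct <- reconstruct_submembrane(ca)
  interior <- 5:(length(tt) - 5)
  expected <- A * (1 - 110 / tau) * exp(-tt[interior] / tau)
  expect_lt(max(abs(ct$raw_sm$values[interior] - expected) / expected), 1e-6)

  # linear segment of slope m: raw_sm - ca_i = gamma * m at interior points
  m <- 0.01
  t1 <- seq(0, 100, 0.5); t2 <- seq(100.5, 600, 0.5)
  v <- c(0.5 + m * t1, (0.5 + m * 100) * exp(-(t2 - 100) / 200))
  ct2 <- reconstruct_submembrane(time_series(v, 0.5, 0, "uM"))
  lin <- 10:150   # inside the ramp, away from edges and the junction
  expect_equal(ct2$raw_sm$values[lin] - v[lin], rep(110 * m, length(lin)),
               tolerance = 1e-9)
})

test_that("reconstructed submembrane calcium leads and tops the bulk", {
  for (amp in c(0.4, 0.8, 1.6)) {
    tp <- transient_params(amp_of_v = function(v) amp)
    tt <- seq(0, 400, 0.5)
    ca <- time_series(sksense:::transient_ca(tt, amp, tp), 0.5, 0, "uM")
    ct <- reconstruct_submembrane(ca)
    expect_gte(max(ct$ca_sm$values), max(ca$values))
    expect_lte(which.max(ct$ca_sm$values), which.max(ca$values))
    # ca_sm == ca_i once the derivative has died out (late decay)
    n <- length(tt)
    expect_equal(ct$ca_sm$values[n], ct$decay_fit$baseline +
                   (max(ct$raw_sm$values) - ct$decay_fit$baseline) *
                   exp(-(tt[n] - tt[which.max(ct$raw_sm$values)]) /
                         ct$decay_fit$tau),
                 tolerance = 1e-9)
  }
})
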