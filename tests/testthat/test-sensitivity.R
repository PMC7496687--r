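test_that("extract_ramp returns the decay-phase pairs exactly", {
  fx <- make_hill_ramp()
  ramp <- extract_ramp(fx$isk, fx$ca, fx$imax)
  # isk proportional to Hill(ca) along the decay: pairs lie on the curve
  expect_equal(ramp$i_norm, hill_curve(ramp$ca, 0.46, 2.6), tolerance = 1e-12)
  expect_equal(ramp$n_dropped, 0)

  # imax = the trace's own peak -> first normalized point is 1
  ramp2 <- extract_ramp(fx$isk, fx$ca, max(fx$isk$values))
  expect_equal(ramp2$i_norm[1], 1)

  # strictly rising calcium: peak at trace end, nothing to extract
  rising <- time_series(seq(0.1, 2, length.out = 100), 1, 0, "uM")
  flat_i <- time_series(rep(1, 100), 1, 0, "pA")
  expect_error(extract_ramp(flat_i, rising, 1), "peak at trace end")

  # time-base mismatch is rejected
  expect_error(extract_ramp(fx$isk, time_series(fx$ca$values[-1], 1, 0, "uM"), 1),
               "time base")
})

test_that("ramp extraction starts at the later of the two peaks and drops rises", {
  # current peaks before calcium: early pairs (bulk != submembrane) excluded
  tt <- seq(0, 300, 1)
  ca <- 0.1 + 1.5 * (1 - exp(-tt / 15))^2 * exp(-tt / 150)
  ik <- c(seq(0, 100, length.out = 20), seq(99, 0, length.out = length(tt) - 20))
  ramp <- extract_ramp(time_series(ik, 1, 0, "pA"),
                       time_series(ca, 1, 0, "uM"), 100)
  expect_equal(ramp$t[1], tt[which.max(ca)])
  expect_true(all(diff(ramp$ca) < 0))

  # non-monotone jitter on the decay is dropped, not smoothed
  ca_j <- ca
  ca_j[120] <- ca_j[119] + 0.05
  ramp_j <- extract_ramp(time_series(ik, 1, 0, "pA"),
                         time_series(ca_j, 1, 0, "uM"), 100)
  expect_gte(ramp_j$n_dropped, 1)
  expect_true(all(diff(ramp_j$ca) < 0))
})

test_that("Hill fit recovers generating parameters exactly without noise", {
  grid <- rbind(c(0.2, 1.5), c(0.46, 2.6), c(1.0, 4), c(0.23, 2.5))
  ca <- exp(seq(log(5), log(0.03), length.out = 60))
  for (k in seq_len(nrow(grid))) {
    y <- hill_curve(ca, grid[k, 1], grid[k, 2])
    fit <- fit_hill(list(ca = ca, i_norm = y, imax = 1))
    expect_equal(fit$ec50, grid[k, 1], tolerance = 1e-6)
    expect_equal(fit$h, grid[k, 2], tolerance = 1e-6)
    expect_true(fit$reliable)
  }
})

test_that("Hill fit is scale-equivariant in (isk, imax)", {
  fx <- make_hill_ramp(ec50 = 0.7, h = 3.1)
  r1 <- extract_ramp(fx$isk, fx$ca, fx$imax)
  scaled <- time_series(3.7 * fx$isk$values, fx$isk$dt, 0, "pA")
  r2 <- extract_ramp(scaled, fx$ca, 3.7 * fx$imax)
  f1 <- fit_hill(r1); f2 <- fit_hill(r2)
  expect_equal(f2$ec50, f1$ec50, tolerance = 1e-9)
  expect_equal(f2$h, f1$h, tolerance = 1e-9)
})

test_that("Hill fit preconditions and noise robustness hold", {
  ca <- exp(seq(log(2), log(0.1), length.out = 40))
  y <- hill_curve(ca, 0.46, 2.6)
  expect_error(fit_hill(list(ca = ca[1:5], i_norm = y[1:5])), "at least 8")
  narrow <- seq(1, 0.5, length.out = 20)
  expect_error(fit_hill(list(ca = narrow,
                             i_norm = hill_curve(narrow, 0.46, 2.6))),
               "3-fold")

  # 2% additive noise on the normalized current: median recovery within 5%
  res <- vapply(1:100, function(s) {
    set.seed(s)
    yn <- y + stats::rnorm(length(y), 0, 0.02)
    fit <- fit_hill(list(ca = ca, i_norm = yn))
    c(fit$ec50, fit$h)
  }, numeric(2))
  expect_lt(abs(stats::median(res[1, ]) / 0.46 - 1), 0.05)
  expect_lt(abs(stats::median(res[2, ]) / 2.6 - 1), 0.05)
})

test_that("inhibition-arm fit recovers the generating IC50", {
  ca <- exp(seq(log(0.05), log(300), length.out = 120))
  po <- open_probability(ca, v = -40)          # IC50(v_ref) = ic50_ref = 20
  kmax <- which.max(po)
  fit <- fit_inhibition(ca[kmax:length(ca)], po[kmax:length(ca)])
  expect_equal(fit$ic50, 20, tolerance = 0.05)
  expect_equal(fit$h_inh, 2, tolerance = 0.05)
})

test_that("timing metrics behave under identity and translation", {
  tt <- seq(0, 200, 1)
  bump <- exp(-((tt - 60)^2) / 300)
  a <- time_series(bump, 1, 0, "pA")
  b <- time_series(bump, 1, 0, "uM")
  tm <- timing_metrics(a, b, onset = 10)
  expect_equal(tm$ttp_isk, tm$ttp_casm)
  expect_equal(tm$ca_sm_at_peak_isk, tm$ca_sm_peak)

  tm5 <- timing_metrics(a, b, onset = 15)
  expect_equal(tm5$ttp_isk, tm$ttp_isk - 5)
  expect_equal(tm5$ttp_casm, tm$ttp_casm - 5)

  expect_error(timing_metrics(a, b, onset = 999), "outside")
})

test_that("calcium at peak I_SK rises monotonically with the inhibition IC50", {
  vals <- vapply(c(4, 8, 20, 40), function(ic50) {
    g <- gating_params(ic50_ref = ic50)
    s <- simulate_sweep(step_protocol(-10), g = g, noise = noiseless())
    tm <- timing_metrics(s$truth$i_sk, s$truth$ca_sm, s$protocol$step_onset)
    tm$ca_sm_at_peak_isk
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("the full ramp assay recovers the generating sensitivity", {
  pp <- preset_params("overexpress")
  set <- simulate_experiment(5, conditions = "ISO", params = pp,
                             noise = noiseless(), seed = 21, dt = 0.5)
  pre <- sksense:::get_sweep(set, "cell01", "ISO", 5)
  post <- sksense:::get_sweep(set, "cell01", "ISO+APA", 5)
  res <- isk_ramp_assay(pre, post)
  expect_s3_class(res, "ramp_assay")
  expect_identical(res$imax_source, "self")
  expect_equal(res$fit$ec50, 0.46, tolerance = 0.02)
  expect_equal(res$fit$h, 2.6, tolerance = 0.02)
})
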