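test_that("blocker subtraction is exact, antisymmetric and linear", {
  a <- 5 * sin(seq(0, 3, length.out = 70))    # 'SK' component
  b <- seq(-3, 1, length.out = 70)            # shared background
  pre <- make_sweep(a + b)
  post <- make_sweep(b, cond = "APA")

  iso <- isolate_isk(pre, post)
  expect_equal(iso$i_sk$values, a, tolerance = 1e-12)      # linearity
  expect_equal(iso$i_residual$values, b)

  same <- isolate_isk(pre, pre)
  expect_true(all(same$i_sk$values == 0))                  # pre == post

  swapped <- isolate_isk(post, pre)
  expect_equal(swapped$i_sk$values, -iso$i_sk$values)      # antisymmetry
})

test_that("mismatched sweeps are rejected before subtraction", {
  pre <- make_sweep(rep(1, 70))
  expect_error(isolate_isk(pre, make_sweep(rep(1, 70), cell = "c2")),
               "different cells")
  expect_error(isolate_isk(pre, make_sweep(rep(1, 70), onset = 12)),
               "protocol mismatch")
  expect_error(isolate_isk(pre, make_sweep(rep(1, 80))),
               "protocol mismatch")
})

test_that("subtraction recovers the simulator's injected SK current", {
  proto <- step_protocol(-10)
  pre <- simulate_sweep(proto, noise = noiseless(), with_sk = TRUE)
  post <- simulate_sweep(proto, noise = noiseless(), with_sk = FALSE)
  iso <- isolate_isk(pre, post)
  expect_equal(iso$i_sk$values, pre$truth$i_sk$values, tolerance = 1e-9)

  # with noise the error stays at the subtraction noise floor (sd sqrt(2) sigma)
  sigma <- 5
  pre_n <- simulate_sweep(proto, noise = noise_params(sigma, 0, seed = 11))
  post_n <- simulate_sweep(proto, noise = noise_params(sigma, 0, seed = 12),
                           with_sk = FALSE)
  iso_n <- isolate_isk(pre_n, post_n)
  rmse <- sqrt(mean((iso_n$i_sk$values - pre_n$truth$i_sk$values)^2))
  expect_lt(rmse, 2 * sigma)
})

test_that("peak_in_window honours polarity and the earliest-tie rule", {
  x <- time_series(c(0, 2, 0, 2, -5, 1), dt = 1, unit = "pA")
  pk <- peak_in_window(x, c(0, 5), "outward")
  expect_equal(pk$amplitude, 2)
  expect_equal(pk$t_peak, 1)            # first of the two equal maxima
  pk_in <- peak_in_window(x, c(0, 5), "inward")
  expect_equal(pk_in$amplitude, 5)      # magnitude
  expect_equal(pk_in$value, -5)
  expect_equal(pk_in$t_peak, 4)

  rising <- time_series(seq_len(10), dt = 1, unit = "pA")
  expect_equal(peak_in_window(rising, c(0, 9), "outward")$t_peak, 9)

  expect_error(peak_in_window(x, c(0, 99), "outward"), "beyond the trace")
})

test_that("build_iv reproduces the simulator's internal record", {
  set <- simulate_experiment(seq(-40, 40, 20), conditions = "baseline",
                             params = preset_params("tab-baseline"),
                             noise = noiseless(), seed = 3, dt = 0.5)
  iv <- build_iv(set)
  expect_identical(iv$voltage_mV, seq(-40, 40, 20))
  expect_true(all(iv$n == 1))
  for (k in seq_len(nrow(iv))) {
    pre <- sksense:::get_sweep(set, "cell01", "baseline", iv$voltage_mV[k])
    w <- c(pre$protocol$step_onset,
           pre$protocol$step_onset + pre$protocol$step_duration)
    truth_peak <- peak_in_window(pre$truth$i_sk, w, "outward")$amplitude
    expect_equal(iv$isk_pApF_mean[k], truth_peak / pre$capacitance,
                 tolerance = 1e-6)
    truth_ica <- peak_in_window(pre$truth$i_ca, w, "inward")$amplitude
    expect_equal(iv$ica_pApF_mean[k], truth_ica / pre$capacitance,
                 tolerance = 1e-6)
  }
  # peak calcium tracks the programmed bell amplitude (monotone where amp is)
  expect_true(all(diff(iv$peak_ca_uM_mean[iv$voltage_mV <= 0]) > 0))
})

test_that("densities scale inversely with capacitance", {
  p1 <- preset_params("tab-baseline")
  p2 <- p1; p2$capacitance <- 2 * p1$capacitance
  s1 <- simulate_experiment(c(-20, 0), conditions = "baseline", params = p1,
                            noise = noiseless(), seed = 7, dt = 1)
  s2 <- simulate_experiment(c(-20, 0), conditions = "baseline", params = p2,
                            noise = noiseless(), seed = 7, dt = 1)
  iv1 <- build_iv(s1); iv2 <- build_iv(s2)
  expect_equal(iv2$isk_pApF_mean, iv1$isk_pApF_mean / 2, tolerance = 1e-12)
  expect_equal(iv2$ica_pApF_mean, iv1$ica_pApF_mean / 2, tolerance = 1e-12)
})

test_that("unmatched pre/post pairs are reported by name", {
  set <- simulate_experiment(c(-20, 0), conditions = "baseline",
                             params = preset_params("tab-baseline"),
                             noise = noiseless(), seed = 1, dt = 2)
  # drop one post sweep
  keep <- Filter(function(s)
    !(s$condition == "APA" && s$protocol$step_potential == 0), set$sweeps)
  expect_error(build_iv(experiment_set(keep)),
               "unmatched pre/post pairs.*cell01 @ \\+0 mV")
})

test_that("rundown normalization is an exact percentage with scale invariance", {
  times <- c(3, 6, 8)
  rd <- normalize_rundown(times, c(500, 400, 390), reference_time = 3)
  expect_equal(rd$normalized_pct, c(100, 80, 78))
  rd_scaled <- normalize_rundown(times, 3.7 * c(500, 400, 390), 3)
  expect_equal(rd_scaled$normalized_pct, rd$normalized_pct)
  expect_equal(normalize_rundown(times, c(7, 7, 7), 6)$normalized_pct,
               c(100, 100, 100))
  expect_error(normalize_rundown(times, c(0, 1, 2), 3), "zero")
  expect_error(normalize_rundown(times, c(1, 1, 1), 99), "not present")
})
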