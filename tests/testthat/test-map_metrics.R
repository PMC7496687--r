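make_ap_trace <- function(t_act = 10, tau = 50, dt = 0.5, t_max = 300,
                          amplitude = 1) {
  tt <- seq(0, t_max, dt)
  v <- ifelse(tt >= t_act, amplitude * exp(-(tt - t_act) / tau), 0)
  time_series(v, dt, 0, "a.u.")
}

test_that("activation time finds the upstroke with the earliest-tie rule", {
  tr <- make_ap_trace(t_act = 10)
  expect_lte(abs(activation_time(tr) - 10), tr$dt)      # within one frame
  ramp <- time_series((0:49) / 64, 0.5, 0, "a.u.")      # exactly equal slopes
  expect_equal(activation_time(ramp), 0)                # constant slope: start
  flat <- time_series(rep(0.3, 50), 0.5, 0, "a.u.")
  expect_true(is.na(activation_time(flat)))             # masked
})

test_that("APD matches closed forms and is monotone in level", {
  # rectangular AP of width 100 ms: APD75 == APD90 == 100 within a frame
  tt <- seq(0, 200, 0.5)
  rect <- time_series(ifelse(tt >= 10 & tt < 110, 1, 0), 0.5, 0, "a.u.")
  a75 <- apd_at_level(rect, 75)
  a90 <- apd_at_level(rect, 90)
  expect_lte(abs(a75 - 100), 0.5)
  expect_lte(abs(a90 - 100), 0.5)
  expect_lte(abs(a90 - a75), 0.5)

  # exponential repolarization tau = 50: APD_L = 50 log(100/(100-L))
  ap <- make_ap_trace(tau = 50)
  expect_lte(abs(apd_at_level(ap, 75) - 50 * log(4)), 0.5)
  expect_lte(abs(apd_at_level(ap, 90) - 50 * log(10)), 0.5)
  levels <- c(30, 50, 75, 90)
  apds <- vapply(levels, function(L) apd_at_level(ap, L), numeric(1))
  expect_true(all(diff(apds) > 0))

  # no crossing before the window end -> NA (caller masks)
  short <- time_series(ifelse(seq(0, 20, 0.5) >= 10, 1, 0), 0.5, 0, "a.u.")
  expect_true(is.na(apd_at_level(short, 90)))
})

test_that("plane-wave conduction velocity is exact and unit-consistent", {
  for (ang in c(0, 30, 63)) {
    vm <- simulate_voltage_map(rows = 30, cols = 30, cv_cm_s = 15,
                               angle_deg = ang)
    am <- apd_map(vm, level = 75)
    expect_true(all(am$mask))
    cv <- conduction_velocity(am$activation, am$mask,
                              pixel_pitch = vm$pixel_pitch)
    expect_lt(abs(cv$cv_cm_s / 15 - 1), 0.01)
    expect_true(cv$plane_ok)
    # doubling the pixel pitch doubles the velocity
    cv2 <- conduction_velocity(am$activation, am$mask,
                               pixel_pitch = 2 * vm$pixel_pitch)
    expect_equal(cv2$cv_cm_s, 2 * cv$cv_cm_s, tolerance = 1e-9)
  }
})

test_that("curved and degenerate wavefronts are flagged, not mis-measured", {
  # off-centre radial wave: directional but curved; plane rmse flags it
  vm <- simulate_voltage_map(rows = 30, cols = 30, cv_cm_s = 10,
                             wave = "radial", radial_origin = c(1, 1))
  am <- apd_map(vm, level = 75)
  cv <- conduction_velocity(am$activation, am$mask,
                            pixel_pitch = vm$pixel_pitch)
  expect_false(cv$plane_ok)

  # centred radial wave: (near-)zero net gradient is either refused or
  # flagged with a non-physiological speed, never reported as a clean CV
  vm0 <- simulate_voltage_map(rows = 21, cols = 21, cv_cm_s = 10,
                              wave = "radial", n_frames = 300)
  am0 <- apd_map(vm0, level = 75)
  res <- tryCatch(conduction_velocity(am0$activation, am0$mask,
                                      pixel_pitch = vm0$pixel_pitch),
                  error = function(e) e)
  if (inherits(res, "error")) {
    expect_match(conditionMessage(res), "no net gradient")
  } else {
    expect_false(res$plane_ok)
    expect_gt(res$cv_cm_s, 100)
  }

  # uniform activation is rank-deficient, not a velocity
  uni <- matrix(5, 20, 20)
  expect_error(conduction_velocity(uni, pixel_pitch = 0.15), "rank-deficient")
})

test_that("homogeneous movies give spatially constant APD and SNR masking works", {
  nr <- 12; nc <- 12
  ap <- make_ap_trace(t_act = 12, tau = 40, t_max = 250)
  frames <- array(rep(ap$values, nr * nc), dim = c(length(ap$values), nr, nc))
  frames[, 3, 4] <- 0.0                      # one dead pixel
  vm <- voltage_map(frames, frame_interval = 0.5, pixel_pitch = 0.15)
  am <- apd_map(vm, level = 90)
  expect_false(am$mask[3, 4])
  expect_true(all(am$mask[-(3 + (4 - 1) * nr)]))
  apds <- am$apd[am$mask]
  expect_lt(max(apds) - min(apds), vm$frame_interval)   # constant to one frame
  expect_lte(abs(mean(apds) - 40 * log(10)), 0.5)
  # activation map is flat for the homogeneous movie
  expect_lt(max(am$activation[am$mask]) - min(am$activation[am$mask]),
            vm$frame_interval)
})

test_that("polarity inversion handles downward optical deflections", {
  ap <- make_ap_trace(t_act = 10, tau = 50)
  down <- array(rep(-ap$values, 4), dim = c(length(ap$values), 2, 2))
  vm <- voltage_map(down, frame_interval = 0.5)
  am <- apd_map(vm, level = 75, polarity = "down")
  expect_true(all(am$mask))
  expect_lte(abs(am$apd[1, 1] - 50 * log(4)), 0.5)
})
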