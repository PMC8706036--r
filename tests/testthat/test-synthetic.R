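test_that("bell_pulse satisfies its shape contract", {
  # peak exactly 1 at the mode, ~0 at the period edges
  expect_equal(bell_pulse(0.5, 0.15), 1)
  expect_equal(bell_pulse(0.5, 0.4), 1)
  expect_lt(bell_pulse(0, 0.15), 0.01)
  expect_lt(bell_pulse(0.999999, 0.15), 0.01)
  # periodic continuation is continuous
  expect_equal(bell_pulse(1 - 1e-9), bell_pulse(0), tolerance = 1e-6)
  expect_equal(bell_pulse(2.3), bell_pulse(0.3))
  # unimodal on a grid
  p <- seq(0, 1, by = 1e-3)
  v <- bell_pulse(p, 0.15)
  expect_equal(which.max(v), which(p == 0.5))
  expect_true(all(diff(v[p <= 0.5]) > 0))
  expect_error(bell_pulse(0.2, -1), "positive")
  expect_error(bell_pulse(NaN), "finite")
})

test_that("bell_pulse integral matches closed-form quadrature oracle", {
  # independent oracle: the generator's bell is a 5-wrap periodised Gaussian,
  # min-max normalised; its integral over one period has a closed form in
  # terms of the normal CDF
  w <- 0.15
  ks <- -2:2
  gauss_int <- sum(vapply(ks, function(k) {
    c0 <- 0.5 - k
    w * sqrt(2 * pi) * (pnorm((1 - c0) / w) - pnorm((0 - c0) / w))
  }, numeric(1)))
  g0 <- sum(exp(-0.5 * ((0 - 0.5 + ks) / w)^2))
  g1 <- sum(exp(-0.5 * ((0.5 - 0.5 + ks) / w)^2))
  oracle <- (gauss_int - g0) / (g1 - g0)
  p <- seq(0, 1, length.out = 2e5 + 1)
  v <- bell_pulse(p, w)
  numint <- sum((v[-1] + v[-length(v)]) / 2) * diff(p)[1]
  expect_equal(numint, oracle, tolerance = 1e-6)
})

test_that("contact_transfer is unimodal with the stated landmarks", {
  opt <- 40; occ <- 60
  expect_equal(contact_transfer(opt, opt, occ), 1)
  expect_equal(contact_transfer(occ, opt, occ), 0)
  expect_equal(contact_transfer(occ + 15, opt, occ), 0)
  # grid-scan oracle: unimodal, argmax at the optimum
  cp <- seq(0, occ + 5, by = 0.05)
  g <- contact_transfer(cp, opt, occ)
  expect_equal(cp[which.max(g)], opt)
  expect_true(all(diff(g[cp <= opt]) > 0))          # strictly increasing
  below <- cp >= opt & cp <= occ
  expect_true(all(diff(g[below]) < 0))              # strictly decreasing
  expect_true(all(g >= 0 & g <= 1))
  expect_error(contact_transfer(10, 50, 40), "optimum_cp < occlusion_cp")
})

test_that("simulate_recording is deterministic under a fixed seed", {
  r1 <- simulate_recording(generator_config(seed = 11))
  r2 <- simulate_recording(generator_config(seed = 11))
  expect_identical(r1$ppg_ir, r2$ppg_ir)
  expect_identical(r1$ppg_red, r2$ppg_red)
  expect_identical(r1$force, r2$force)
  r3 <- simulate_recording(generator_config(seed = 12))
  expect_false(identical(r1$ppg_ir, r3$ppg_ir))
  # caller RNG state untouched
  set.seed(99); before <- .Random.seed
  invisible(simulate_recording(generator_config(seed = 5)))
  expect_identical(.Random.seed, before)
})

test_that("zero noise and zero pulse amplitude give constant channels", {
  cfg <- generator_config(noise_sd = 0, pulse_amplitude_v = 0, seed = 1)
  rec <- simulate_recording(cfg)
  expect_equal(diff(range(rec$ppg_ir)), 0)
  expect_equal(diff(range(rec$ppg_red)), 0)
  expect_equal(rec$ppg_ir[1], cfg$baseline[["ir"]])
})

test_that("truth block carries 1 Hz onsets and consistent landmarks", {
  rec <- fixture_record()
  on30 <- rec$truth$all_onset_times
  expect_lte(abs(sum(on30 >= 0 & on30 < 30) - 30), 1)
  expect_equal(diff(rec$truth$all_onset_times), rep(1, length(
    rec$truth$all_onset_times) - 1))
  tr <- rec$truth
  expect_lt(tr$contact_time, tr$optimum_time)
  expect_lt(tr$optimum_time, tr$occlusion_time)
  # MAP invariant for every state
  for (s in pressure_states()$label) {
    st <- bp_state(s)
    expect_identical(mean_arterial_pressure(st$sbp, st$dbp), st$map)
  }
})

test_that("descent geometry: force ramp, cp landmarks, duration guard", {
  rec <- fixture_record()
  cfg <- rec$config
  # force non-decreasing during descent
  expect_true(all(diff(rec$force) >= -1e-12))
  # cp at the truth occlusion time equals the configured occlusion pressure
  cp <- force_to_mmHg(rec$force, cfg$sensor_area_m2)
  i_occl <- which.min(abs(rec$t - rec$truth$occlusion_time))
  expect_equal(cp[i_occl], cfg$occlusion_cp_mmHg, tolerance = 1e-2)
  expect_error(simulate_recording(generator_config(), duration_s = 50),
               "too short")
})

test_that("pulse amplitude peaks at the cycle nearest the optimum", {
  # a little extra duration so truly occluded samples exist
  rec <- simulate_recording(generator_config(seed = 7), duration_s = 112)
  cp <- force_to_mmHg(rec$force, rec$config$sensor_area_m2)
  onsets_i <- round(rec$truth$onset_times * rec$fs) + 1
  amp <- cp_cycle <- numeric(length(onsets_i) - 1)
  for (i in seq_len(length(onsets_i) - 1)) {
    span <- onsets_i[i]:onsets_i[i + 1]
    amp[i] <- max(rec$ppg_ir[span]) - min(rec$ppg_ir[span])
    cp_cycle[i] <- mean(cp[span])
  }
  best <- which.max(amp)
  nearest <- which.min(abs(cp_cycle - rec$config$optimum_cp_mmHg))
  expect_lte(abs(best - nearest), 1)
  # post-occlusion: pulsatile power below noise power
  occl_idx <- rec$t > rec$truth$occlusion_time
  resid <- rec$ppg_ir[occl_idx] - mean(rec$ppg_ir[occl_idx])
  expect_lt(var(resid), 4 * rec$config$noise_sd^2)
})
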