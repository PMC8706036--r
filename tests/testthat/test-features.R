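test_that("region_centroid matches closed-form shapes", {
  # rectangle h = 1 on [0, 2]
  t <- seq(0, 2, by = 1e-3)
  expect_equal(region_centroid(t, rep(1, length(t)), 0),
               c(x = 1, y = 0.5), tolerance = 1e-9)
  # right triangle rising 0 -> 1 on [0, 3]: centroid (2, 1/3)
  t <- seq(0, 3, by = 1e-3)
  expect_equal(region_centroid(t, t / 3, 0), c(x = 2, y = 1 / 3),
               tolerance = 1e-3)
  # translation equivariance in x; baseline shift in y
  c0 <- region_centroid(t, t / 3, 0)
  c1 <- region_centroid(t + 5, t / 3, 0)
  expect_equal(c1[["x"]], c0[["x"]] + 5, tolerance = 1e-9)
  c2 <- region_centroid(t, t / 3 + 2, 2)
  expect_equal(c2[["y"]], c0[["y"]] + 2, tolerance = 1e-9)
  expect_error(region_centroid(t, rep(0, length(t)), 0), "zero area")
})

# helper: contiguous triangle train (no flat feet), two periods
triangle_train <- function(rise_s, decay_s, amp = 1, fs = 1000) {
  period <- rise_s + decay_s
  nr <- round(rise_s * fs); nd <- round(decay_s * fs)
  one <- c(seq(0, amp, length.out = nr + 1)[-(nr + 1)],
           seq(amp, 0, length.out = nd + 1)[-(nd + 1)])
  x <- c(one, one, 0)
  cycle <- data.frame(onset_index = 1L,
                      max_slope_index = max(2L, round(nr / 2)),
                      peak_index = nr + 1L,
                      next_onset_index = nr + nd + 1L,
                      ti_time = 0)  # linear upstroke: TI = onset
  list(x = x, fs = fs, cycle = cycle, next_ti = period)
}

test_that("triangle-pulse features match analytic geometry", {
  tr <- triangle_train(0.3, 0.7)
  f <- extract_features(tr$x, tr$cycle, tr$next_ti, tr$fs)
  expect_equal(f[["f1"]], 1)
  expect_equal(f[["f2"]], 1)
  expect_equal(f[["f14"]], 0.3)
  expect_equal(f[["f15"]], 0.7)
  expect_equal(f[["f16"]], atan(1 / 0.3), tolerance = 1e-9)
  expect_equal(f[["f17"]], atan(1 / 0.7), tolerance = 1e-9)
  # areas: full 0.5, systolic 0.15, diastolic 0.35
  expect_equal(f[["f4"]], 0.5, tolerance = 1e-3)
  expect_equal(f[["f5"]], 0.15, tolerance = 1e-3)
  expect_equal(f[["f6"]], 0.35, tolerance = 1e-3)
  # centroids (onset-relative x; y of any triangle region is amp/3)
  expect_equal(f[["f7"]], 13 / 30, tolerance = 1e-3)
  expect_equal(f[["f8"]], 1 / 3, tolerance = 1e-3)
  expect_equal(f[["f9"]], 0.2, tolerance = 1e-3)
  expect_equal(f[["f10"]], 1 / 3, tolerance = 1e-3)
  expect_equal(f[["f11"]], 0.3 + 0.7 / 3, tolerance = 1e-3)
  expect_equal(f[["f12"]], 1 / 3, tolerance = 1e-3)
  expect_equal(f[["f13"]], f[["f11"]] - f[["f9"]])
})

test_that("symmetric pulses give symmetric features", {
  tr <- triangle_train(0.5, 0.5)
  f <- extract_features(tr$x, tr$cycle, tr$next_ti, tr$fs)
  expect_equal(f[["f14"]], f[["f15"]])
  expect_equal(f[["f16"]], f[["f17"]])
  expect_equal(f[["f5"]], f[["f6"]], tolerance = 1e-3)
  # systolic/diastolic x-centroids symmetric about the peak time
  expect_equal((f[["f9"]] + f[["f11"]]) / 2, 0.5, tolerance = 1e-3)
})

test_that("amplitude scaling and time dilation act on the right features", {
  tr1 <- triangle_train(0.3, 0.7)
  f1 <- extract_features(tr1$x, tr1$cycle, tr1$next_ti, tr1$fs)
  # amplitude scaling by k
  k <- 3.7
  fk <- extract_features(k * tr1$x, tr1$cycle, tr1$next_ti, tr1$fs)
  for (nm in c("f2", "f3", "f4", "f5", "f6", "f8", "f10", "f12")) {
    expect_equal(fk[[nm]], k * f1[[nm]], tolerance = 1e-9, label = nm)
  }
  for (nm in c("f1", "f7", "f9", "f11", "f13", "f14", "f15")) {
    expect_equal(fk[[nm]], f1[[nm]], tolerance = 1e-9, label = nm)
  }
  # time dilation by 2: temporal features double, pure amplitudes unchanged
  tr2 <- triangle_train(0.6, 1.4)
  f2 <- extract_features(tr2$x, tr2$cycle, tr2$next_ti, tr2$fs)
  for (nm in c("f1", "f7", "f9", "f11", "f13", "f14", "f15")) {
    expect_equal(f2[[nm]], 2 * f1[[nm]], tolerance = 1e-2, label = nm)
  }
  for (nm in c("f2", "f3", "f8", "f10", "f12")) {
    expect_equal(f2[[nm]], f1[[nm]], tolerance = 1e-2, label = nm)
  }
})

test_that("definitional identities hold to machine precision on real data", {
  f <- fixture_analysis()$features
  expect_equal(f$f13, f$f11 - f$f9, tolerance = 1e-12)
  expect_equal(f$f16, atan(f$f2 / f$f14), tolerance = 1e-12)
  expect_equal(f$f17, atan(f$f2 / f$f15), tolerance = 1e-12)
  # approximate area conservation (TI ~ onset on clean pulses)
  expect_lt(max(abs(f$f4 - (f$f5 + f$f6)) / f$f4), 0.1)
  # x-centroids bracketed by their phase
  expect_true(all(f$f9 >= 0 & f$f9 <= f$f14))
  expect_true(all(f$f11 >= f$f14 & f$f11 <= f$f14 + f$f15))
  # positivity and angle range
  for (nm in c("f1", "f4", "f5", "f6", "f13", "f14", "f15")) {
    expect_true(all(f[[nm]] > 0), label = nm)
  }
  expect_true(all(f$f16 > 0 & f$f16 < pi / 2))
  expect_true(all(f$f17 > 0 & f$f17 < pi / 2))
})

test_that("feature_matrix bookkeeping", {
  an <- fixture_analysis()
  expect_equal(nrow(an$features), nrow(an$cycles) - 1)
  expect_true(all(c("cycle_index", "cp_mmHg", paste0("f", 1:17)) %in%
                    names(an$features)))
  # identical cycles give zero-variance features
  tr <- clean_pulse_train(duration_s = 12)
  cyc <- detect_cycles(tr$x, tr$fs)
  fm <- feature_matrix(tr$x, cyc, tr$fs)
  vr <- vapply(fm[paste0("f", 1:17)], var, numeric(1))
  expect_true(all(vr < 1e-12))
  expect_error(feature_matrix(tr$x, cyc[1, ], tr$fs), "at least 2")
  # pulse amplitude column is unimodal in cp with argmax near the optimum
  f <- an$features
  expect_lt(abs(f$cp_mmHg[which.max(f$f2)] -
                  an$rec$truth$optimum_cp_mmHg), 2)
})

test_that("feature class partition is exhaustive and disjoint", {
  cls <- feature_classes()
  expect_equal(sort(cls$feature), sort(paste0("f", 1:17)))
  expect_equal(sum(cls$class == "temporal"), 7)
  expect_equal(sum(cls$class == "amplitude"), 8)
  expect_equal(sum(cls$class == "geometric"), 2)
  expect_equal(cls$feature[cls$class == "temporal"],
               paste0("f", c(1, 7, 9, 11, 13, 14, 15)))
  expect_equal(cls$feature[cls$class == "geometric"], c("f16", "f17"))
})
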