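# independent oracle: rank with base R, then Pearson with base R
spearman_oracle <- function(x, y) {
  cor(rank(x, ties.method = "average"), rank(y, ties.method = "average"))
}

test_that("spearman_rho: textbook cases", {
  expect_equal(spearman_rho(1:4, c(10, 20, 30, 40)), 1)
  expect_equal(spearman_rho(1:4, c(40, 30, 20, 10)), -1)
  # rank displacement d = (1,1,1,1,0): rho = 1 - 6*4/(5*24) = 0.8
  expect_equal(spearman_rho(1:5, c(2, 1, 4, 3, 5)), 0.8)
  expect_error(spearman_rho(1:3, rep(1, 3)), "constant")
  expect_error(spearman_rho(1:2, 1:2), "n >= 3")
  expect_error(spearman_rho(c(1, 2, NA), 1:3), "finite")
})

test_that("spearman_rho agrees with the brute-force oracle to 1e-12", {
  set.seed(101)
  for (i in 1:200) {
    n <- sample(3:60, 1)
    x <- rnorm(n)
    y <- rnorm(n)
    if (i %% 2 == 0) {  # inject ties
      x <- round(x, 1); y <- round(y, 1)
      if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    }
    expect_equal(spearman_rho(x, y), spearman_oracle(x, y),
                 tolerance = 1e-12)
  }
  # long untied series
  set.seed(7)
  x <- rnorm(1000); y <- rnorm(1000)
  expect_equal(spearman_rho(x, y), spearman_oracle(x, y), tolerance = 1e-12)
})

test_that("spearman_rho invariances", {
  set.seed(5)
  x <- rnorm(40); y <- rnorm(40)
  r <- spearman_rho(x, y)
  expect_equal(spearman_rho(y, x), r)
  expect_equal(spearman_rho(x, -y), -r)
  # invariant under strictly monotone transforms
  expect_equal(spearman_rho(exp(x), y), r)
  expect_equal(spearman_rho(x, y^3 + 5 * y), r)
})

test_that("rank_features orders by ascending |rho| with flags", {
  set.seed(9)
  n <- 100
  fm <- as.data.frame(matrix(rnorm(n * 17), n, 17))
  names(fm) <- paste0("f", 1:17)
  fm$cp_mmHg <- seq_len(n)
  fm$f5 <- fm$cp_mmHg          # equals cp: |rho| = 1, ranked last
  fm$f8 <- 3.14                # constant: undefined, flagged
  rk <- rank_features(fm)
  expect_equal(rk$rho[["f5"]], 1)
  expect_equal(rk$ordering[17], "f8")   # undefined sorts after everything
  expect_equal(rk$ordering[16], "f5")
  expect_equal(rk$undefined, "f8")
  expect_setequal(rk$ordering, paste0("f", 1:17))
  expect_true(all(diff(abs(rk$rho[rk$ordering[1:16]])) >= -1e-12))
  # pure-noise features rank early with small |rho|
  expect_lt(abs(rk$rho[["f1"]]), 0.3)
  expect_error(rank_features(fm[1:2, ]), ">= 3")
  fmc <- fm; fmc$cp_mmHg <- 1
  expect_error(rank_features(fmc), "constant")
})

test_that("class_summary reproduces the reference ordering arithmetic", {
  # reference published ordering (hypotension, first replica, infrared):
  # the 7 temporal features occupy the first 7 positions
  published <- c(1, 13, 11, 15, 7, 14, 9, 16, 3, 17, 12, 8, 6, 4, 10, 2, 5)
  rk <- structure(list(rho = setNames(rep(NA_real_, 17), paste0("f", 1:17)),
                       ordering = paste0("f", published),
                       undefined = character(0),
                       channel = "ir", state = "hypotensive", replica = 1L),
                  class = "ranking_result")
  cs <- class_summary(rk)
  med <- setNames(cs$by_class$median_rank, cs$by_class$class)
  expect_equal(med[["temporal"]], 4)
  expect_lt(med[["temporal"]], med[["amplitude"]])
  expect_true(cs$temporal_robust)
  # randomized orderings: flag true in roughly half of runs
  set.seed(13)
  flags <- vapply(1:200, function(i) {
    rnd <- rk
    rnd$ordering <- sample(rk$ordering)
    class_summary(rnd)$temporal_robust
  }, logical(1))
  expect_gt(mean(flags), 0.3)
  expect_lt(mean(flags), 0.7)
})

test_that("temporal features rank as least pressure-affected on simulation", {
  an <- fixture_analysis()
  rk <- rank_features(an$features, channel = "ir")
  cls <- feature_classes()
  pos <- match(cls$feature, rk$ordering)
  expect_lt(max(pos[cls$class == "temporal"]),
            min(pos[cls$class == "amplitude"]))
  cs <- class_summary(rk)
  expect_true(cs$temporal_robust)
})
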