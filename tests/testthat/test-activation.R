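# Independent step-up oracle: literal evaluation of the definition over
# every rank (largest i with P_(i) <= (i/V) q / c), ties at max rank.
stepup_oracle <- function(p, V, q, c_V = 1) {
  ord <- order(p)
  ps <- p[ord]
  k <- 0
  for (i in seq_along(ps)) {
    if (ps[i] <= i * q / (V * c_V)) k <- i
  }
  mask <- rep(FALSE, length(p))
  if (k > 0) mask <- p <= ps[k]
  mask
}

test_that("detrending removes linear trends and preserves constants", {
  des <- toy_design()
  sdim <- c(4, 4, 2)
  const <- bold_series(array(100, c(sdim, 40)), 6)
  out <- detrend_and_smooth(const, fwhm_mm = 0, design = des)
  expect_equal(out$signal, const$signal, tolerance = 1e-12)

  # pure per-voxel ramps: post-detrend slope ~ 0
  set.seed(1)
  slopes <- runif(prod(sdim), -2, 2)
  ramp <- array(outer(slopes, 0:39) + 50, c(sdim, 40))
  out <- detrend_and_smooth(bold_series(ramp, 6), fwhm_mm = 0, design = des)
  Y <- matrix(out$signal, ncol = 40)
  fit_slopes <- apply(Y, 1, function(v) coef(lm(v ~ seq_len(40)))[2])
  expect_true(all(abs(fit_slopes) < 1e-10))
})

test_that("Gaussian smoothing kernel conserves mass on a delta image", {
  vol <- array(0, c(11, 11, 11))
  vol[6, 6, 6] <- 1
  sm <- phbold:::gaussian_smooth_3d(vol, sigma = rep(2 / 2.3548, 3))
  expect_equal(sum(sm), 1, tolerance = 1e-6)
  expect_gt(sm[6, 6, 6], max(sm[1, , ]))  # mass stays centred
})

test_that("percent change matches the definitional re-summation oracle", {
  des <- toy_design()
  at <- toy_atlas(c(4, 4, 2), 2)
  # constant series -> 0% everywhere
  const <- bold_series(array(100, c(4, 4, 2, 40)), 6)
  pc <- percent_change(const, des)
  expect_true(all(abs(pc$trace) < 1e-12))

  # baseline 100, stim value 96 -> -4%
  sig <- array(100, c(4, 4, 2, 40))
  sig[, , , 11:40] <- 96
  pc <- percent_change(bold_series(sig, 6), des)
  expect_equal(unique(as.vector(pc$pct)), -4)

  # random series: summary equals brute-force mean over stim scans
  set.seed(42)
  sig <- array(rnorm(prod(c(4, 4, 2, 40)), 100, 5), c(4, 4, 2, 40))
  pc <- percent_change(bold_series(sig, 6), des)
  v <- sig[2, 3, 1, ]
  b <- mean(v[1:10])
  expect_equal(pc$pct[2, 3, 1], mean(100 * (v[11:40] - b) / b),
               tolerance = 1e-12)

  # zero-baseline voxel flagged and excluded, not NaN
  sig[1, 1, 1, 1:10] <- 0
  pc <- percent_change(bold_series(sig, 6), des)
  expect_equal(pc$n_excluded, 1L)
  expect_true(is.na(pc$pct[1, 1, 1]))
  expect_false(anyNA(pc$pct[-1]))
})

test_that("voxel Welch t matches stats::t.test per voxel", {
  des <- toy_design()
  set.seed(7)
  sig <- array(rnorm(4 * 4 * 2 * 40, 100, 3), c(4, 4, 2, 40))
  tt <- voxel_ttest(bold_series(sig, 6), des)
  for (v in list(c(1, 1, 1), c(3, 2, 2), c(4, 4, 1))) {
    ref <- t.test(sig[v[1], v[2], v[3], 11:40], sig[v[1], v[2], v[3], 1:10],
                  var.equal = FALSE)
    expect_equal(tt$t[v[1], v[2], v[3]], unname(ref$statistic),
                 tolerance = 1e-10)
    expect_equal(tt$p[v[1], v[2], v[3]], ref$p.value, tolerance = 1e-10)
    expect_equal(tt$df[v[1], v[2], v[3]], unname(ref$parameter),
                 tolerance = 1e-8)
  }
  # identical windows -> t = 0, p = 1
  flat <- array(rep(rep(1:16, 40), each = 2), c(4, 4, 2, 40))
  flat[] <- 5
  tt0 <- voxel_ttest(bold_series(flat, 6), des)
  expect_true(all(tt0$t == 0) && all(tt0$p == 1))
})

test_that("windowed Welch t agrees with a permutation oracle on one voxel", {
  set.seed(123)
  x <- c(rnorm(50, 0, 1), rnorm(300, 0.5, 1))
  sig <- array(rep(x, each = 1), c(1, 1, 1, 350))
  des <- scan_design()
  tt <- voxel_ttest(bold_series(sig, 6), des)
  expect_lt(tt$p[1, 1, 1], 0.05)
  # permutation null for the same statistic
  obs <- abs(tt$t[1, 1, 1])
  perm <- replicate(10000, {
    px <- sample(x)
    a <- px[1:50]; b <- px[51:350]
    abs((mean(b) - mean(a)) / sqrt(var(a) / 50 + var(b) / 300))
  })
  p_perm <- (1 + sum(perm >= obs)) / (1 + length(perm))
  # both should be far in the tail; agree within Monte-Carlo resolution
  expect_lt(abs(tt$p[1, 1, 1] - p_perm), 3 / sqrt(10000) + 1e-3)
})

test_that("fp_filter implements the step-up rule", {
  expect_identical(fp_filter(numeric(0), fdr_params(V = 1)), logical(0))
  expect_true(fp_filter(0.001, fdr_params(q = 0.2, V = 1)))
  # thresholds 0.05 / 0.10 / 0.15 / 0.20: all four pass
  expect_identical(fp_filter(c(0.001, 0.01, 0.03, 0.2),
                             fdr_params(q = 0.2, V = 4)),
                   rep(TRUE, 4))
  # all p above q/V stays empty at q = 0.05
  p <- runif(20, 0.3, 1)
  expect_false(any(fp_filter(p, fdr_params(q = 0.05, V = 20))))
})

test_that("fp_filter on the published low-dose negative-arm p-values matches the oracle", {
  # 18 table rows (region-level p-values), screened at V = 173, q = 0.2
  p_tab <- c(0.005, 0.007, 0.007, 0.009, 0.01, 0.012, 0.015, 0.017, 0.02,
             0.025, 0.029, 0.032, 0.033, 0.041, 0.041, 0.041, 0.041, 0.041)
  prm <- fdr_params(q = 0.2, c_V = 1, V = 173)
  expect_identical(fp_filter(p_tab, prm), stepup_oracle(p_tab, 173, 0.2))
})

test_that("fp_filter agrees with BH and stays monotone under new evidence", {
  set.seed(5)
  for (i in 1:25) {
    m <- sample(3:40, 1)
    p <- round(runif(m)^sample(1:3, 1), 3)
    mask <- fp_filter(p, fdr_params(q = 0.2, V = m))
    # independent cross-check: BH adjusted p-values
    expect_identical(mask, p.adjust(p, method = "BH") <= 0.2)
    # monotonicity: prepending a tiny p never drops existing hits
    mask2 <- fp_filter(c(1e-8, p), fdr_params(q = 0.2, V = m + 1))
    expect_true(all(mask2[-1] >= mask | !mask))
  }
})

test_that("classification and counting respect significance, sign and threshold", {
  at <- toy_atlas(c(5, 4, 2), 4)
  des <- toy_design(thr = 1)
  eff <- toy_effect(c(1L, 3L), c("negative", "positive"), c(3, 2))
  ser <- simulate_phmri(at, des, eff, "LSD100", seed = 2)
  m <- activation_analysis(ser, at, des)
  cc <- classify_and_count(m, at, des)
  sizes <- region_sizes(at)

  expect_equal(cc$negative_count[cc$region_id == 1], unname(sizes["1"]))
  expect_equal(cc$positive_count[cc$region_id == 3], unname(sizes["3"]))
  expect_equal(sum(cc$positive_count[cc$region_id %in% c(1, 2, 4)]), 0)
  expect_equal(sum(cc$negative_count[cc$region_id %in% c(2, 3, 4)]), 0)
  # counts never exceed region size
  expect_true(all(cc$positive_count + cc$negative_count <= sizes))

  # sub-threshold effect (0.5% < 1%) is significant but not counted
  eff2 <- toy_effect(1L, "negative", 0.5)
  ser2 <- simulate_phmri(at, des, eff2, "LSD100", seed = 2)
  m2 <- activation_analysis(ser2, at, des)
  cc2 <- classify_and_count(m2, at, des)
  expect_true(any(m2$significant))
  expect_equal(sum(cc2$negative_count) + sum(cc2$positive_count), 0)

  # random mask: counts equal a brute-force per-voxel tally
  set.seed(9)
  m$sign_class[] <- sample(c(-1L, 0L, 1L), length(m$sign_class), TRUE)
  cc3 <- classify_and_count(m, at, des)
  for (rid in 1:4) {
    vox <- at$labels == rid
    expect_equal(cc3$positive_count[cc3$region_id == rid],
                 sum(m$sign_class[vox] == 1L))
    expect_equal(cc3$negative_count[cc3$region_id == rid],
                 sum(m$sign_class[vox] == -1L))
  }

  expect_error(classify_and_count(m, toy_atlas(c(4, 4, 2), 2), des),
               "dimensions differ")
})

test_that("filtered_pct is zero exactly where not significant", {
  at <- toy_atlas(c(5, 4, 2), 4, background_frac = 0.2)
  des <- toy_design()
  eff <- toy_effect(2L, "negative", 3, noise_sd = 1, ar1_rho = 0.2)
  ser <- simulate_phmri(at, des, eff, "LSD100", seed = 31)
  m <- activation_analysis(ser, at, des)
  expect_true(all(m$filtered_pct[!m$significant] == 0))
  expect_true(all(m$filtered_pct[m$significant] ==
                    m$pct_change[m$significant]))
  # sign_class = none wherever not significant or below threshold
  none <- !m$significant | abs(m$pct_change) < des$baseline_threshold_pct
  expect_true(all(m$sign_class[none] == 0L))
})
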