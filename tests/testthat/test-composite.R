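test_that("affine transforms compose and decompose consistently", {
  tr <- affine_transform(translation = c(1.5, -2, 0.25),
                         rotation_deg = c(10, -20, 35),
                         scale = c(1.1, 0.9, 1.3))
  rt <- decompose_affine(tr$matrix)
  expect_equal(rt$matrix, tr$matrix, tolerance = 1e-9)
  expect_equal(rt$translation, tr$translation, tolerance = 1e-9)
  expect_equal(rt$rotation_deg, tr$rotation_deg, tolerance = 1e-9)
  expect_equal(rt$scale, tr$scale, tolerance = 1e-9)

  expect_error(affine_transform(scale = c(1, 0, 1)), "nonzero")
})

test_that("trilinear sampling matches the 8-term formula", {
  set.seed(3)
  vol <- array(rnorm(6 * 5 * 4), c(6, 5, 4))

  # exact grid node
  expect_equal(trilinear_sample(vol, c(2, 3, 1)), vol[3, 4, 2])
  # midpoint of an edge between 2 and 4 -> 3
  v2 <- array(0, c(2, 1, 1)); v2[1] <- 2; v2[2] <- 4
  expect_equal(trilinear_sample(v2, c(0.5, 0, 0)), 3)

  # random interior points vs independent formula evaluation
  pts <- cbind(runif(20, 0, 5), runif(20, 0, 4), runif(20, 0, 3))
  got <- trilinear_sample(vol, pts)
  for (i in seq_len(20)) {
    p <- pts[i, ]; p0 <- floor(p); f <- p - p0
    acc <- 0
    for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
      w <- prod(ifelse(c(cx, cy, cz) == 1, f, 1 - f))
      acc <- acc + w * vol[p0[1] + cx + 1, p0[2] + cy + 1, p0[3] + cz + 1]
    }
    expect_equal(got[i], acc, tolerance = 1e-12)
  }

  # outside the volume -> missing
  expect_true(is.na(trilinear_sample(vol, c(-0.1, 0, 0))))
  expect_true(is.na(trilinear_sample(vol, c(5.01, 0, 0))))
})

test_that("composites average subject contributions through their transforms", {
  set.seed(8)
  G <- array(rnorm(5 * 5 * 3), c(5, 5, 3))
  id <- affine_transform()

  # one subject, identity -> composite equals the subject grid
  cm <- build_composite(list(list(grid = G, transform = id)))
  expect_equal(cm$values, G, tolerance = 1e-12)
  expect_true(all(cm$n_contributors == 1L))

  # G and -G -> zero composite
  cm2 <- build_composite(list(list(grid = G, transform = id),
                              list(grid = -G, transform = id)))
  expect_equal(cm2$values, array(0, dim(G)), tolerance = 1e-12)

  # all-identity transforms = voxel-wise mean (exact)
  H <- array(rnorm(5 * 5 * 3), c(5, 5, 3))
  cm3 <- build_composite(list(list(grid = G, transform = id),
                              list(grid = H, transform = id)))
  expect_equal(cm3$values, (G + H) / 2, tolerance = 1e-12)

  # stored matrix maps composite -> subject: +2 voxel translation on x
  # pulls a subject delta at (5,5,5) 0-based into composite (3,5,5)
  D <- array(0, c(9, 9, 9)); D[6, 6, 6] <- 1  # 0-based (5,5,5)
  tr <- affine_transform(translation = c(2, 0, 0))
  cm4 <- build_composite(list(list(grid = D, transform = tr)))
  expect_equal(cm4$values[4, 6, 6], 1)        # 0-based (3,5,5)
  expect_equal(sum(cm4$values, na.rm = TRUE), 1)

  # out-of-volume samples contribute nothing (count drops, no zero bias)
  big <- affine_transform(translation = c(6, 0, 0))
  cm5 <- build_composite(list(list(grid = G, transform = big),
                              list(grid = H, transform = id)),
                         dims = dim(G))
  # where only H contributes, the value is H, not (H + 0)/2
  expect_equal(cm5$values[5, 1, 1], H[5, 1, 1], tolerance = 1e-12)
  expect_equal(cm5$n_contributors[5, 1, 1], 1L)
})

test_that("transform round trip reproduces the identity composite", {
  set.seed(4)
  G <- array(rnorm(6 * 6 * 4), c(6, 6, 4))
  tr <- affine_transform(translation = c(0.3, -0.2, 0.1),
                         rotation_deg = c(4, -3, 7), scale = c(1.05, 0.95, 1))
  Tinv <- solve(tr$matrix)
  M <- tr$matrix %*% Tinv  # numerically near identity
  rt <- decompose_affine(M)
  cm <- build_composite(list(list(grid = G, transform = rt)))
  expect_equal(cm$values, G, tolerance = 1e-6)
})

test_that("group time course recovers means and the interaction statistic", {
  # identical traces in both groups -> F = 0
  scans <- 1:6
  traces <- expand.grid(subject_id = sprintf("s%d", 1:6), scan = scans)
  traces$group <- ifelse(as.integer(sub("s", "", traces$subject_id)) <= 3,
                         "Veh", "LSD100")
  traces$value <- sin(traces$scan)
  tc <- group_timecourse(traces)
  expect_equal(tc$interaction$F, 0, tolerance = 1e-10)

  # planted divergence, no noise -> significant interaction
  traces2 <- traces
  idx <- traces2$group == "LSD100" & traces2$scan > 3
  jit <- stats::setNames(c(0, 0.001, -0.001), sprintf("s%d", 4:6))
  traces2$value[idx] <- traces2$value[idx] - 2 +
    jit[as.character(traces2$subject_id[idx])]
  tc2 <- group_timecourse(traces2)
  expect_gt(tc2$interaction$F, 0)
  expect_lt(tc2$interaction$p, 0.05)

  # group means and sems in the output table
  sub <- tc$timecourse[tc$timecourse$group == "Veh" &
                         tc$timecourse$scan == 2, ]
  expect_equal(sub$mean, sin(2))
  expect_equal(sub$sem, 0)
  expect_equal(sub$n, 3)
})

test_that("interaction F matches a from-scratch sums-of-squares computation", {
  # balanced 2 groups x 3 subjects x 4 scans with fixed values
  set.seed(12)
  g <- rep(c("A", "B"), each = 12)
  s <- rep(sprintf("s%d", 1:6), each = 4)
  t_ <- rep(1:4, 6)
  y <- round(rnorm(24, 10, 2), 2)
  traces <- data.frame(subject_id = s, group = g, scan = t_, value = y)
  tc <- group_timecourse(traces)

  # textbook mixed-ANOVA sums of squares
  grand <- mean(y)
  cell <- tapply(y, list(g, t_), mean)      # group x time means
  gm <- tapply(y, g, mean); tm <- tapply(y, t_, mean)
  sm <- tapply(y, s, mean)
  n_per_g <- 3; n_t <- 4; n_g <- 2
  ss_g <- n_per_g * n_t * sum((gm - grand)^2)
  ss_t <- n_per_g * n_g * sum((tm - grand)^2)
  ss_cell <- n_per_g * sum((cell - grand)^2)
  ss_gt <- ss_cell - ss_g - ss_t
  ss_subj <- n_t * sum((sm - grand)^2)
  ss_subj_within <- ss_subj - ss_g
  ss_tot <- sum((y - grand)^2)
  ss_err <- ss_tot - ss_cell - ss_subj_within
  df_gt <- (n_g - 1) * (n_t - 1)
  df_err <- (n_t - 1) * (6 - n_g)
  F_oracle <- (ss_gt / df_gt) / (ss_err / df_err)

  expect_equal(tc$interaction$F, F_oracle, tolerance = 1e-10)
  expect_equal(tc$interaction$df1, df_gt)
  expect_equal(tc$interaction$df2, df_err)
})

test_that("desk-scale group traces recover programmed plateaus", {
  at <- toy_atlas(c(8, 8, 4), 8)
  des <- toy_design(n_reps = 60L, ctrl = c(1L, 15L), stim = c(16L, 60L))
  olf <- 1:3
  eff <- toy_effect(olf, rep("negative", 3), rep(4, 3), onset = 16L,
                    ramp = 10L, noise_sd = 3, ar1_rho = 0.2)
  mk_trace <- function(group, seed) {
    ser <- simulate_phmri(at, des, eff, group, seed = seed)
    pc <- percent_change(ser, des)
    regional_pct_trace(pc, at, olf)
  }
  lsd <- vapply(1:7, function(i) mk_trace("LSD100", 100 + i), numeric(60))
  veh <- vapply(1:10, function(i) mk_trace("Veh", 200 + i), numeric(60))
  plateau <- 30:60
  expect_equal(mean(rowMeans(lsd)[plateau]), -4, tolerance = 0.5)
  expect_equal(mean(rowMeans(veh)[plateau]), 0, tolerance = 0.5)
})
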