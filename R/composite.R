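#' Affine registration transform (composite frame -> subject frame)
#'
#' Stores the per-subject spatial registration as a 4x4 homogeneous matrix
#' composed as translation %*% rotation %*% scale. By convention the stored
#' matrix maps composite (atlas-frame) coordinates into the subject's frame;
#' composite building therefore samples each subject directly at the
#' transformed coordinate, which corresponds to populating the composite
#' through the inverse of the subject-to-atlas registration. Coordinates are
#' 0-based continuous voxel indices.
#'
#' @param translation Length-3 translation (voxels).
#' @param rotation_deg Length-3 rotation angles in degrees about the x, y, z
#'   axes, applied in the order Rz %*% Ry %*% Rx.
#' @param scale Length-3 positive scale factors.
#' @return An `affine_transform` with fields `matrix` (4x4) and the stored
#'   components.
#' @export
affine_transform <- function(translation = c(0, 0, 0),
                             rotation_deg = c(0, 0, 0),
                             scale = c(1, 1, 1)) {
  assert_that(length(translation) == 3 && length(rotation_deg) == 3 &&
                length(scale) == 3, "components must each have length 3")
  assert_that(all(scale != 0), "scale factors must be nonzero")
  M <- trans_mat(translation) %*% rot_mat(rotation_deg) %*% scale_mat(scale)
  assert_that(abs(det(M[1:3, 1:3])) > 1e-12,
              "transform is not invertible (singular 3x3 block)")
  structure(list(matrix = M, translation = as.numeric(translation),
                 rotation_deg = as.numeric(rotation_deg),
                 scale = as.numeric(scale)),
            class = "affine_transform")
}

trans_mat <- function(t) {
  M <- diag(4); M[1:3, 4] <- t; M
}
scale_mat <- function(s) diag(c(s, 1))
rot_mat <- function(deg) {
  r <- deg * pi / 180
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  M <- diag(4); M[1:3, 1:3] <- Rz %*% Ry %*% Rx; M
}

#' Recover translation / rotation / scale components from an affine matrix
#'
#' Inverse of the composition used by [affine_transform()] (valid for
#' positive scales and rotations away from gimbal lock at pitch +/-90 deg).
#'
#' @param M 4x4 homogeneous matrix composed as translation-rotation-scale.
#' @return An [affine_transform()] whose `matrix` reproduces `M`.
#' @export
decompose_affine <- function(M) {
  assert_that(is.matrix(M) && all(dim(M) == 4), "M must be 4x4")
  translation <- M[1:3, 4]
  A <- M[1:3, 1:3]
  scale <- sqrt(colSums(A^2))
  R <- A %*% diag(1 / scale)
  # Euler angles from R = Rz Ry Rx
  ry <- asin(pmin(pmax(-R[3, 1], -1), 1))
  rx <- atan2(R[3, 2], R[3, 3])
  rz <- atan2(R[2, 1], R[1, 1])
  affine_transform(translation, c(rx, ry, rz) * 180 / pi, scale)
}

#' Trilinear interpolation of a 3D grid at continuous voxel coordinates
#'
#' Standard 8-neighbour weighting in 0-based voxel coordinates. Points
#' outside `[0, dim - 1]` on any axis return NA ("missing"); NA neighbours
#' propagate to NA.
#'
#' @param volume 3D numeric array.
#' @param points Numeric length-3 vector or n x 3 matrix of 0-based
#'   coordinates.
#' @return Numeric vector of sampled values (NA where outside the volume).
#' @export
trilinear_sample <- function(volume, points) {
  assert_that(is.array(volume) && length(dim(volume)) == 3,
              "volume must be a 3D array")
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  d <- dim(volume)
  # absorb round-off from composed transforms: points within 1e-9 of the
  # valid cube are clamped onto it rather than declared missing
  tol <- 1e-9
  for (ax in 1:3) {
    near_lo <- points[, ax] < 0 & points[, ax] > -tol
    near_hi <- points[, ax] > d[ax] - 1 & points[, ax] < d[ax] - 1 + tol
    points[near_lo, ax] <- 0
    points[near_hi, ax] <- d[ax] - 1
  }
  out <- rep(NA_real_, nrow(points))
  inside <- points[, 1] >= 0 & points[, 1] <= d[1] - 1 &
    points[, 2] >= 0 & points[, 2] <= d[2] - 1 &
    points[, 3] >= 0 & points[, 3] <= d[3] - 1
  if (!any(inside)) return(out)
  p <- points[inside, , drop = FALSE]
  p0 <- floor(p)
  p0 <- pmin(p0, matrix(d - 2, nrow(p), 3, byrow = TRUE))  # upper face
  p0 <- pmax(p0, 0)
  f <- p - p0
  acc <- numeric(nrow(p))
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    w <- (cx * f[, 1] + (1 - cx) * (1 - f[, 1])) *
      (cy * f[, 2] + (1 - cy) * (1 - f[, 2])) *
      (cz * f[, 3] + (1 - cz) * (1 - f[, 3]))
    # clamp the upper neighbour for singleton axes (its weight is then 0)
    idx <- cbind(pmin(p0[, 1] + cx, d[1] - 1), pmin(p0[, 2] + cy, d[2] - 1),
                 pmin(p0[, 3] + cz, d[3] - 1)) + 1
    acc <- acc + w * volume[idx]
  }
  out[inside] <- acc
  out
}

#' Build a group composite percent-change map
#'
#' For each composite voxel, each subject is sampled (trilinear) at the
#' subject-frame coordinate obtained by applying that subject's stored
#' transform to the composite coordinate; non-missing contributions are
#' averaged. Out-of-volume samples contribute nothing (rather than zero,
#' which would bias composites toward null).
#'
#' @param subject_maps List of `list(grid = <3D array>, transform =
#'   <affine_transform>)`, one per subject (typically the `filtered_pct`
#'   grids of [activation_analysis()]).
#' @param dims Composite grid dimensions; defaults to the first subject's.
#' @return A `composite_map`: `values` (3D mean percent change, NA where no
#'   subject contributes) and `n_contributors` (3D counts).
#' @export
build_composite <- function(subject_maps, dims = NULL) {
  assert_that(length(subject_maps) >= 1, "need at least one subject")
  for (j in seq_along(subject_maps)) {
    tr <- subject_maps[[j]]$transform
    assert_that(inherits(tr, "affine_transform"),
                "subject %d: transform must be an affine_transform", j)
    assert_that(abs(det(tr$matrix[1:3, 1:3])) > 1e-12,
                "subject %d: non-invertible transform", j)
  }
  dims <- dims %||% dim(subject_maps[[1]]$grid)
  grid <- as.matrix(expand.grid(x = seq_len(dims[1]) - 1,
                                y = seq_len(dims[2]) - 1,
                                z = seq_len(dims[3]) - 1))
  total <- numeric(nrow(grid))
  count <- integer(nrow(grid))
  gh <- t(cbind(grid, 1))
  for (sm in subject_maps) {
    pts <- t(sm$transform$matrix %*% gh)[, 1:3, drop = FALSE]
    v <- trilinear_sample(sm$grid, pts)
    ok <- !is.na(v)
    total[ok] <- total[ok] + v[ok]
    count[ok] <- count[ok] + 1L
  }
  values <- ifelse(count > 0, total / pmax(count, 1L), NA_real_)
  structure(list(values = array(values, dims),
                 n_contributors = array(count, dims)),
            class = "composite_map")
}

#' Group time-course table and time-by-treatment interaction
#'
#' Takes per-subject regional mean percent-change traces, returns the
#' per-scan group mean +/- standard error, and tests the time-by-treatment
#' interaction with a two-way mixed ANOVA (between factor: treatment; within
#' factor: scan; subjects nested in treatment), the design used for
#' drug-vs-vehicle BOLD time-course comparisons.
#'
#' @param traces Data frame with columns `subject_id`, `group`, `scan`,
#'   `value` (one row per subject per scan; equal scan grids required).
#' @param bin Optional integer binning factor: scans are averaged in
#'   consecutive blocks of `bin` before the ANOVA (1 = no binning).
#' @return List with `timecourse` (data frame scan, group, mean, sem, n) and
#'   `interaction` (data frame with F, df1, df2, p for the scan x group
#'   term).
#' @export
group_timecourse <- function(traces, bin = 1L) {
  required <- c("subject_id", "group", "scan", "value")
  assert_that(is.data.frame(traces) && all(required %in% names(traces)),
              "traces needs columns %s", paste(required, collapse = ", "))
  assert_that(length(unique(traces$group)) >= 2, "need >= 2 groups")
  counts <- table(traces$subject_id)
  assert_that(length(unique(counts)) == 1,
              "subjects have unequal scan counts; align the traces first")
  per_group <- tapply(traces$subject_id, traces$group,
                      function(s) length(unique(s)))
  assert_that(all(per_group >= 2), "need >= 2 subjects per group")

  if (bin > 1L) {
    traces$scan <- (traces$scan - 1L) %/% as.integer(bin) + 1L
    traces <- stats::aggregate(value ~ subject_id + group + scan, traces,
                               mean)
  }
  agg <- stats::aggregate(value ~ scan + group, traces, function(v) {
    c(mean = mean(v), sem = stats::sd(v) / sqrt(length(v)), n = length(v))
  })
  tc <- data.frame(scan = agg$scan, group = agg$group,
                   mean = agg$value[, "mean"], sem = agg$value[, "sem"],
                   n = agg$value[, "n"])
  tc <- tc[order(tc$group, tc$scan), ]
  rownames(tc) <- NULL

  d <- traces
  d$group <- factor(d$group)
  d$scan <- factor(d$scan)
  d$subject_id <- factor(d$subject_id)
  fit <- stats::aov(value ~ group * scan + Error(subject_id), data = d)
  within <- summary(fit)[["Error: Within"]][[1]]
  row_int <- grep("group:scan", rownames(within))
  row_res <- grep("Residuals", rownames(within))
  ss_int <- within[row_int, "Sum Sq"]
  ss_res <- within[row_res, "Sum Sq"]
  df1 <- within[row_int, "Df"]; df2 <- within[row_res, "Df"]
  ss_tol <- 1e-10 * max(sum(within[, "Sum Sq"]), 1)
  if (ss_res <= ss_tol) {                    # zero within-cell variance
    Fint <- if (ss_int <= ss_tol) 0 else Inf
    pint <- if (ss_int <= ss_tol) 1 else 0
  } else {
    Fint <- (ss_int / df1) / (ss_res / df2)
    pint <- stats::pf(Fint, df1, df2, lower.tail = FALSE)
  }
  inter <- data.frame(F = Fint, df1 = df1, df2 = df2, p = pint)
  list(timecourse = tc, interaction = inter)
}

#' Mean regional percent-change trace for one subject
#'
#' Averages the per-scan percent-change traces over all voxels belonging to
#' the given regions (e.g. the olfactory structures pooled in a published
#' time-course figure).
#'
#' @param pc A `pct_change` object from [percent_change()].
#' @param atlas An [atlas_volume()] on the same grid.
#' @param region_ids Regions to pool.
#' @return Numeric vector, one mean percent change per scan.
#' @export
regional_pct_trace <- function(pc, atlas, region_ids) {
  stopifnot(inherits(pc, "pct_change"), inherits(atlas, "atlas_volume"))
  vox <- which(as.vector(atlas$labels) %in% region_ids &
                 !as.vector(pc$excluded))
  assert_that(length(vox) > 0, "no usable voxels in the requested regions")
  colMeans(pc$trace[vox, , drop = FALSE])
}
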