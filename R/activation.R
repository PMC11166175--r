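#' Detrend and spatially smooth a BOLD series
#'
#' Removes each voxel's linear trend fitted over the full series and re-adds
#' the control-window mean (so percent change against the pre-injection
#' baseline stays interpretable), then applies volume-wise spatial Gaussian
#' smoothing with the stated full width at half maximum. `fwhm_mm = 0` skips
#' smoothing.
#'
#' @param series A [bold_series()].
#' @param fwhm_mm Gaussian kernel FWHM in mm (default 0.8).
#' @param voxel_size Voxel size in mm per axis.
#' @param design Optional [scan_design()]; its control window defines the
#'   mean that is re-added after detrending. When `NULL` the full-series
#'   mean is used.
#' @return A [bold_series()] of the same shape.
#' @export
detrend_and_smooth <- function(series, fwhm_mm = 0.8,
                               voxel_size = c(0.3, 0.3, 1), design = NULL) {
  stopifnot(inherits(series, "bold_series"))
  assert_that(fwhm_mm >= 0, "fwhm_mm must be non-negative")
  sdim <- dim(series$signal)[1:3]
  Y <- vox_by_scan(series$signal)
  NR <- ncol(Y)

  tt <- seq_len(NR) - (NR + 1) / 2              # centred time
  denom <- sum(tt^2)
  slope <- as.vector(Y %*% tt) / denom
  mu <- rowMeans(Y)
  fitted <- outer(slope, tt) + mu
  keep <- if (is.null(design)) mu else
    rowMeans(Y[, window_scans(design, "control"), drop = FALSE])
  Y <- Y - fitted + keep

  if (fwhm_mm > 0) {
    sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size
    Y <- vox_by_scan(gaussian_smooth_4d(scan_to_4d(Y, sdim), sigma))
  }
  bold_series(scan_to_4d(Y, sdim), series$tr_seconds, series$subject_id,
              series$modality)
}

#' Separable spatial Gaussian smoothing; per-axis sigma in voxels.
#' Kernels are truncated at 3 sigma and renormalised so mass sums to one;
#' boundaries are zero-padded. Accepts a 3D volume or a 4D series (the
#' kernel is applied volume-wise, vectorised over scans).
#' @noRd
gaussian_smooth_4d <- function(arr, sigma) {
  nd <- length(dim(arr))
  if (nd == 3) arr <- array(arr, c(dim(arr), 1L))
  for (ax in 1:3) {
    if (sigma[ax] <= 0) next
    r <- max(1L, ceiling(3 * sigma[ax]))
    k <- stats::dnorm(seq(-r, r), sd = sigma[ax])
    k <- k / sum(k)
    out <- array(0, dim(arr))
    n <- dim(arr)[ax]
    for (j in seq(-r, r)) {
      src <- seq_len(n) - j
      ok <- src >= 1 & src <= n
      to <- which(ok); from <- src[ok]
      w <- k[j + r + 1]
      if (ax == 1) out[to, , , ] <- out[to, , , ] + w * arr[from, , , ]
      if (ax == 2) out[, to, , ] <- out[, to, , ] + w * arr[, from, , ]
      if (ax == 3) out[, , to, ] <- out[, , to, ] + w * arr[, , from, ]
    }
    arr <- out
  }
  if (nd == 3) arr <- array(arr, dim(arr)[1:3])
  arr
}

# backwards-compatible 3D entry point used by tests
gaussian_smooth_3d <- function(vol, sigma) gaussian_smooth_4d(vol, sigma)

#' Per-voxel BOLD percent change against the control-window baseline
#'
#' For each voxel with control-window mean `b`, the per-scan trace is
#' `100 * (s_t - b) / b` and the per-voxel summary the mean of that trace
#' over the stimulation window. Voxels whose baseline is (numerically) zero
#' are flagged and excluded rather than propagating NaN.
#'
#' @param series A [bold_series()].
#' @param design A [scan_design()].
#' @return A `pct_change` list: `pct` (3D stimulation-window mean percent
#'   change), `trace` (voxel-by-scan percent-change matrix), `baseline`
#'   (3D), `excluded` (3D logical) and `n_excluded`.
#' @export
percent_change <- function(series, design) {
  stopifnot(inherits(series, "bold_series"), inherits(design, "scan_design"))
  assert_that(n_scans(series) == design$n_reps,
              "series has %d scans but design expects %d",
              n_scans(series), design$n_reps)
  sdim <- dim(series$signal)[1:3]
  Y <- vox_by_scan(series$signal)
  b <- rowMeans(Y[, window_scans(design, "control"), drop = FALSE])
  excluded <- abs(b) < 1e-6
  trace <- 100 * (Y - b) / b
  trace[excluded, ] <- NA_real_
  pct <- rowMeans(trace[, window_scans(design, "stim"), drop = FALSE])
  structure(list(pct = array(pct, sdim), trace = trace,
                 baseline = array(b, sdim),
                 excluded = array(excluded, sdim),
                 n_excluded = sum(excluded)),
            class = "pct_change")
}

#' Windowed per-voxel Welch t-test
#'
#' Treats each voxel's control-window and stimulation-window samples as two
#' independent groups and computes the unequal-variance (heteroscedastic)
#' two-sample t statistic with two-tailed p-values via Welch-Satterthwaite
#' degrees of freedom. Positive t means the stimulation window is above
#' baseline. Voxels with zero variance in both windows get t = 0, p = 1 when
#' the means agree, and p = 0 with a degeneracy flag otherwise.
#'
#' @param series A [bold_series()].
#' @param design A [scan_design()]; both windows need >= 2 scans.
#' @return List of 3D arrays `t`, `p`, `df`, plus logical `degenerate`.
#' @export
voxel_ttest <- function(series, design) {
  stopifnot(inherits(series, "bold_series"), inherits(design, "scan_design"))
  i1 <- window_scans(design, "control")
  i2 <- window_scans(design, "stim")
  assert_that(length(i1) >= 2 && length(i2) >= 2,
              "both windows need at least 2 scans")
  sdim <- dim(series$signal)[1:3]
  Y <- vox_by_scan(series$signal)
  n1 <- length(i1); n2 <- length(i2)
  m1 <- rowMeans(Y[, i1, drop = FALSE]); m2 <- rowMeans(Y[, i2, drop = FALSE])
  v1 <- rowSums((Y[, i1, drop = FALSE] - m1)^2) / (n1 - 1)
  v2 <- rowSums((Y[, i2, drop = FALSE] - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m2 - m1) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  degen <- se2 == 0
  eq <- degen & (m1 == m2)
  tstat[eq] <- 0; p[eq] <- 1; df[eq] <- n1 + n2 - 2
  ne <- degen & (m1 != m2)
  tstat[ne] <- sign(m2 - m1)[ne] * Inf; p[ne] <- 0; df[ne] <- n1 + n2 - 2
  list(t = array(tstat, sdim), p = array(p, sdim), df = array(df, sdim),
       degenerate = array(ne, sdim))
}

#' Rank-based step-up false-positive filter
#'
#' Implements the step-up rule on sorted p-values: find the largest rank
#' `i` with \eqn{P_{(i)} \le (i/V) \, q / c(V)}; every test with p-value at
#' or below that order statistic is significant. With `c_V = 1` and `V`
#' equal to the number of tests this is the Benjamini-Hochberg procedure at
#' level `q`. Tied p-values are evaluated at their highest applicable rank,
#' so ties enter or leave the significant set together.
#'
#' @param p_values Numeric vector of p-values in [0, 1] (NA allowed; never
#'   significant).
#' @param params An [fdr_params()]; `params$V` must be at least the number
#'   of non-missing p-values.
#' @return Logical significance mask in the original order.
#' @export
fp_filter <- function(p_values, params = fdr_params(V = length(p_values))) {
  stopifnot(inherits(params, "fdr_params"))
  if (length(p_values) == 0) return(logical(0))
  ok <- !is.na(p_values)
  assert_that(all(p_values[ok] >= 0 & p_values[ok] <= 1),
              "p-values must lie in [0, 1]")
  assert_that(params$V >= sum(ok),
              "V (%d) must be >= number of p-values (%d)", params$V, sum(ok))
  ps <- sort(p_values[ok])
  thr <- seq_along(ps) * params$q / (params$V * params$c_V)
  hits <- which(ps <= thr)
  mask <- rep(FALSE, length(p_values))
  if (length(hits)) {
    cut <- ps[max(hits)]
    mask[ok] <- p_values[ok] <= cut
  }
  mask
}

#' Per-subject activation map
#'
#' Runs the per-voxel statistics for one phMRI session: percent change,
#' windowed Welch t-test, the step-up false-positive filter over the
#' in-brain voxels, and sign classification at the design's baseline
#' threshold. Significant voxels retain their percent-change values in
#' `filtered_pct`; all other voxels are set to zero.
#'
#' @param series A [bold_series()] (already detrended/smoothed if desired;
#'   see [detrend_and_smooth()]).
#' @param atlas An [atlas_volume()] sharing the series' grid; labels > 0
#'   define the in-brain voxels entering the filter.
#' @param design A [scan_design()].
#' @param fdr An [fdr_params()]; `V = NULL` (default) uses the in-brain
#'   voxel count.
#' @param q,c_V Filter level and constant used when `fdr` is NULL.
#' @return An `activation_map`: 3D arrays `pct_change`, `t_stat`, `p_value`,
#'   `significant`, `sign_class` ("positive"/"negative"/"none" coded 1/-1/0),
#'   `filtered_pct`, plus bookkeeping (`V`, excluded-voxel count).
#' @export
activation_analysis <- function(series, atlas, design, fdr = NULL,
                                q = 0.2, c_V = 1) {
  stopifnot(inherits(atlas, "atlas_volume"))
  assert_that(all(dim(series$signal)[1:3] == dim(atlas$labels)),
              "series and atlas grids differ")
  pc <- percent_change(series, design)
  tt <- voxel_ttest(series, design)
  brain <- atlas$labels > 0L & !pc$excluded
  V <- if (is.null(fdr)) sum(brain) else fdr$V
  fdr <- fdr %||% fdr_params(q = q, c_V = c_V, V = V)
  sig <- array(FALSE, dim(atlas$labels))
  sig[brain] <- fp_filter(as.vector(tt$p[brain]), fdr)

  thr <- design$baseline_threshold_pct
  cls <- array(0L, dim(atlas$labels))
  cls[sig & !is.na(pc$pct) & pc$pct >= thr] <- 1L
  cls[sig & !is.na(pc$pct) & pc$pct <= -thr] <- -1L
  fpct <- pc$pct
  fpct[!sig | is.na(fpct)] <- 0
  structure(list(pct_change = pc$pct, t_stat = tt$t, p_value = tt$p,
                 significant = sig, sign_class = cls, filtered_pct = fpct,
                 fdr = fdr, n_brain = sum(brain),
                 n_excluded = pc$n_excluded,
                 subject_id = series$subject_id),
            class = "activation_map")
}

#' @export
print.activation_map <- function(x, ...) {
  cat(sprintf(
    "Activation map '%s': %d in-brain voxels tested (V=%d, q=%g), %d significant (%d+, %d-)\n",
    x$subject_id, x$n_brain, x$fdr$V, x$fdr$q, sum(x$significant),
    sum(x$sign_class == 1L), sum(x$sign_class == -1L)))
  invisible(x)
}

#' Per-region activated-voxel counts (volume of activation)
#'
#' A voxel counts as positively activated iff it is significant and its
#' percent change is at or above `+baseline_threshold_pct`; negatively
#' activated iff significant and at or below the negative threshold. Counts
#' are reported for every atlas region, zeros included.
#'
#' @param map An `activation_map` from [activation_analysis()].
#' @param atlas An [atlas_volume()] on the same grid.
#' @param design A [scan_design()] supplying the baseline threshold.
#' @return Data frame with columns `region_id`, `positive_count`,
#'   `negative_count`.
#' @export
classify_and_count <- function(map, atlas, design) {
  stopifnot(inherits(map, "activation_map"), inherits(atlas, "atlas_volume"))
  assert_that(all(dim(map$pct_change) == dim(atlas$labels)),
              "map and atlas grid dimensions differ")
  ids <- atlas$regions$region_id
  lab <- factor(as.vector(atlas$labels), levels = ids)
  pos <- tapply(as.vector(map$sign_class == 1L), lab, sum)
  neg <- tapply(as.vector(map$sign_class == -1L), lab, sum)
  data.frame(region_id = ids,
             positive_count = as.integer(ifelse(is.na(pos), 0L, pos)),
             negative_count = as.integer(ifelse(is.na(neg), 0L, neg)))
}
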