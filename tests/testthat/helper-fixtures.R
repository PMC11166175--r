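# Small deterministic fixtures shared across the suite.

# Hand-built atlas: dims x regions laid out as contiguous x-slabs inside the
# full grid (no background unless requested), with macro regions cycling
# through the ten categories.
toy_atlas <- function(dims = c(6, 6, 4), n_regions = 6L,
                      background_frac = 0) {
  labels <- array(0L, dim = dims)
  nv <- prod(dims)
  idx <- seq_len(nv)
  n_bg <- floor(nv * background_frac)
  usable <- idx[seq_len(nv - n_bg)]
  cuts <- if (n_regions == 1L) rep(1L, length(usable)) else
    cut(seq_along(usable), n_regions, labels = FALSE)
  labels[usable] <- cuts
  macro <- rep_len(phbold:::MACRO_REGIONS, n_regions)
  regions <- data.frame(
    region_id = seq_len(n_regions),
    name = sprintf("r%02d_%s", seq_len(n_regions), macro),
    macro_region = macro,
    hemisphere = rep_len(c("left", "right", "midline"), n_regions),
    stringsAsFactors = FALSE)
  atlas_volume(labels, regions, voxel_size = c(1, 1, 1))
}

# Short scan design used where the full 350-scan session is overkill.
toy_design <- function(n_reps = 40L, ctrl = c(1L, 10L),
                       stim = c(11L, n_reps), thr = 1) {
  scan_design(n_reps = n_reps, tr_seconds = 6, control_window = ctrl,
              stim_window = stim, baseline_threshold_pct = thr)
}

# Noise-free effect spec over the first regions of an atlas.
toy_effect <- function(region_ids, signs, magnitudes, onset = 11L,
                       ramp = 5L, noise_sd = 0, ar1_rho = 0,
                       drift_slope = 0,
                       mult = c(Veh = 0, LSD10 = 0.4, LSD100 = 1)) {
  effect_spec(
    data.frame(region_id = region_ids, sign = signs,
               magnitude_pct = magnitudes, onset_scan = onset,
               ramp_scans = ramp, stringsAsFactors = FALSE),
    dose_multipliers = mult, noise_sd = noise_sd, ar1_rho = ar1_rho,
    drift_slope = drift_slope)
}

# Node series with an exact target correlation imposed (empirical, via
# whitening), for connectivity tests that need known sample correlations.
exact_cor_nodes <- function(C, n_scan = 200L, seed = 1, tr = 1) {
  set.seed(seed)
  n <- nrow(C)
  X <- matrix(rnorm(n * n_scan), n, n_scan)
  X <- X - rowMeans(X)
  S <- tcrossprod(X) / (n_scan - 1)
  Xw <- t(solve(chol(S))) %*% X        # sample covariance exactly I
  Y <- t(chol(C)) %*% Xw               # sample correlation exactly C
  node_series(Y, seq_len(n), tr)
}
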