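#' One subject's 4D BOLD series
#'
#' @param signal 4D numeric array (x, y, z, scan), all finite.
#' @param tr_seconds Repetition time in seconds.
#' @param subject_id Subject identifier.
#' @param modality "phmri" or "rsfc".
#' @return A `bold_series` object.
#' @export
bold_series <- function(signal, tr_seconds, subject_id = "subject",
                        modality = c("phmri", "rsfc")) {
  modality <- match.arg(modality)
  assert_that(is.array(signal) && length(dim(signal)) == 4,
              "signal must be a 4D array (x, y, z, scan)")
  assert_that(all(is.finite(signal)), "signal must be finite everywhere")
  assert_that(tr_seconds > 0, "tr_seconds must be positive")
  structure(list(signal = signal, tr_seconds = tr_seconds,
                 subject_id = subject_id, modality = modality),
            class = "bold_series")
}

#' @export
print.bold_series <- function(x, ...) {
  d <- dim(x$signal)
  cat(sprintf("BOLD series '%s' (%s): %d x %d x %d voxels, %d scans, TR %g s\n",
              x$subject_id, x$modality, d[1], d[2], d[3], d[4], x$tr_seconds))
  invisible(x)
}

n_scans <- function(series) dim(series$signal)[4]

#' AR(1) Gaussian noise, scans x voxels, stationary marginal sd = sd
#'
#' e_t = rho * e_{t-1} + sqrt(1 - rho^2) * z_t with an independent N(0,1)
#' start, so the marginal variance is exactly sd^2 at every scan.
#' @noRd
ar1_noise <- function(n_scan, n_vox, sd, rho) {
  if (sd == 0) return(matrix(0, n_scan, n_vox))
  z <- matrix(stats::rnorm(n_scan * n_vox), n_scan, n_vox)
  if (rho > 0) {
    innov <- z * sqrt(1 - rho^2)
    init <- stats::rnorm(n_vox)
    out <- matrix(0, n_scan, n_vox)
    prev <- init
    for (t in seq_len(n_scan)) {
      prev <- rho * prev + innov[t, ]
      out[t, ] <- prev
    }
    z <- out
  }
  sd * z
}

#' Simulate a pharmacological MRI session
#'
#' Generates one subject's 4D BOLD series over an atlas. Every voxel starts
#' at `baseline`; voxels inside the regions named by the [effect_spec()]
#' follow a linear ramp from `onset_scan` over `ramp_scans` scans to a
#' plateau of `sign * magnitude_pct * dose_multiplier[group]` percent
#' change. Optional linear drift and (optionally AR(1)-correlated) Gaussian
#' noise are added everywhere, background included. With `noise_sd = 0` and
#' `drift_slope = 0` the programmed percent change is reproduced exactly.
#'
#' @param atlas An [atlas_volume()].
#' @param design A [scan_design()].
#' @param effect An [effect_spec()]; all effect regions must exist in the
#'   atlas.
#' @param group Group label; must name an entry of the effect's
#'   `dose_multipliers`.
#' @param seed RNG seed (per subject).
#' @param baseline Baseline signal level (arbitrary scanner units).
#' @param subject_id Identifier stored in the result.
#' @return A [bold_series()] with modality "phmri".
#' @export
simulate_phmri <- function(atlas, design, effect, group, seed,
                           baseline = 1000, subject_id = group) {
  stopifnot(inherits(atlas, "atlas_volume"), inherits(design, "scan_design"),
            inherits(effect, "effect_spec"))
  assert_that(group %in% names(effect$dose_multipliers),
              "unknown group label '%s'", group)
  bad <- setdiff(effect$effects$region_id, atlas$regions$region_id)
  assert_that(length(bad) == 0, "effect regions not in atlas: %s",
              paste(bad, collapse = ", "))
  mult <- effect$dose_multipliers[[group]]
  sdim <- dim(atlas$labels)
  n_vox <- prod(sdim)
  NR <- design$n_reps
  scans <- seq_len(NR)

  # per-region percent-change time profiles (regions x scans)
  eff <- effect$effects
  profiles <- matrix(0, nrow(eff), NR)
  for (k in seq_len(nrow(eff))) {
    sgn <- if (eff$sign[k] == "positive") 1 else -1
    peak <- sgn * eff$magnitude_pct[k] * mult
    ramp <- pmin(pmax((scans - eff$onset_scan[k]) /
                        max(eff$ramp_scans[k], 1), 0), 1)
    ramp[scans < eff$onset_scan[k]] <- 0
    profiles[k, ] <- peak * ramp
  }

  pct <- matrix(0, n_vox, NR)
  lab <- as.vector(atlas$labels)
  for (k in seq_len(nrow(eff))) {
    vox <- which(lab == eff$region_id[k])
    if (length(vox)) pct[vox, ] <- matrix(profiles[k, ], length(vox), NR,
                                          byrow = TRUE)
  }

  sig <- baseline * (1 + pct / 100)
  if (effect$drift_slope != 0) {
    sig <- sig + matrix(effect$drift_slope * (scans - 1), n_vox, NR,
                        byrow = TRUE)
  }
  with_seed(seed, {
    if (effect$noise_sd > 0) {
      sig <- sig + t(ar1_noise(NR, n_vox, effect$noise_sd, effect$ar1_rho))
    }
  })
  bold_series(scan_to_4d(sig, sdim), design$tr_seconds,
              subject_id = subject_id, modality = "phmri")
}

#' Simulate a resting-state session with planted correlation structure
#'
#' Draws latent node signals from a multivariate normal whose correlation
#' matrix equals the spec's target (per group, if `target_cor` is a named
#' list), writes `signal_amp` times the node's latent trace into every voxel
#' of the corresponding atlas region, and adds nuisance structure (6 motion
#' traces plus white-matter and CSF signals with random per-voxel loadings)
#' and independent voxel noise. The nuisance regressor matrix is returned
#' alongside the series so downstream regression can be verified against
#' ground truth.
#'
#' @param atlas An [atlas_volume()].
#' @param spec An [rsfc_spec()].
#' @param group Group label (selects the target matrix when a list).
#' @param seed RNG seed.
#' @param baseline Baseline signal level.
#' @param subject_id Identifier stored in the result.
#' @return List with elements `series` (a [bold_series()], modality "rsfc"),
#'   `nuisance` (scans x 8 regressor matrix) and `latent` (nodes x scans
#'   ground-truth signals).
#' @export
simulate_rsfc <- function(atlas, spec, group, seed, baseline = 1000,
                          subject_id = group) {
  stopifnot(inherits(atlas, "atlas_volume"), inherits(spec, "rsfc_spec"))
  C <- if (is.list(spec$target_cor)) {
    assert_that(group %in% names(spec$target_cor),
                "no target correlation matrix for group '%s'", group)
    spec$target_cor[[group]]
  } else spec$target_cor
  n_node <- length(spec$node_ids)
  validate_target_cor(C, n_node)
  bad <- setdiff(spec$node_ids, atlas$regions$region_id)
  assert_that(length(bad) == 0, "node regions not in atlas: %s",
              paste(bad, collapse = ", "))

  sdim <- dim(atlas$labels)
  n_vox <- prod(sdim)
  NR <- spec$n_reps
  lab <- as.vector(atlas$labels)

  with_seed(seed, {
    # latent node signals with population correlation C
    ev <- eigen(C, symmetric = TRUE)
    L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), n_node)
    latent <- L %*% matrix(stats::rnorm(n_node * NR), n_node, NR)

    nuis <- matrix(stats::rnorm(NR * 8), NR, 8)
    colnames(nuis) <- c(paste0("motion", 1:6), "wm", "csf")

    sig <- matrix(baseline, n_vox, NR)
    for (j in seq_len(n_node)) {
      vox <- which(lab == spec$node_ids[j])
      if (length(vox)) {
        sig[vox, ] <- sig[vox, ] +
          spec$signal_amp * matrix(latent[j, ], length(vox), NR, byrow = TRUE)
      }
    }
    if (spec$nuisance_load > 0) {
      load <- matrix(stats::rnorm(n_vox * 8, sd = spec$nuisance_load),
                     n_vox, 8)
      sig <- sig + load %*% t(nuis)
    }
    if (spec$noise_sd > 0) {
      sig <- sig + matrix(stats::rnorm(n_vox * NR, sd = spec$noise_sd),
                          n_vox, NR)
    }
    list(series = bold_series(scan_to_4d(sig, sdim), spec$tr_seconds,
                              subject_id = subject_id, modality = "rsfc"),
         nuisance = nuis, latent = latent)
  })
}

#' Default phMRI effect specification
#'
#' The shipped study conditions: 32 negative-BOLD regions at a -3% plateau
#' (the high-dose table's 32-region footprint, at the magnitude scale of the
#' published olfactory time course), plus 6 positive-BOLD regions at +2%.
#' The response ramps linearly from the injection at scan 50 over 50 scans
#' (plateau by 5 min post-injection). Dose multipliers 0 / 0.4 / 1 for
#' Veh / LSD10 / LSD100; voxel noise 1.5% of baseline with mild AR(1)
#' autocorrelation and a small scanner drift.
#'
#' @param atlas An [atlas_volume()] supplying region ids.
#' @param n_negative,n_positive Number of affected regions per sign.
#' @param baseline Baseline signal level the noise scale refers to.
#' @param onset_scan First scan of the response (the injection falls at the
#'   end of the control window, so this defaults to scan 51).
#' @param ramp_scans Scans from onset to plateau (50 = 5 min at TR 6 s).
#' @return An [effect_spec()].
#' @export
default_effect_spec <- function(atlas, n_negative = 32L, n_positive = 6L,
                                baseline = 1000, onset_scan = 51L,
                                ramp_scans = 50L) {
  ids <- atlas$regions$region_id
  assert_that(length(ids) >= n_negative + n_positive,
              "atlas has too few regions for the default effect layout")
  neg <- ids[seq_len(n_negative)]
  pos <- ids[n_negative + seq_len(n_positive)]
  effects <- data.frame(
    region_id = c(neg, pos),
    sign = c(rep("negative", n_negative), rep("positive", n_positive)),
    magnitude_pct = c(rep(3, n_negative), rep(2, n_positive)),
    onset_scan = as.integer(onset_scan), ramp_scans = as.integer(ramp_scans),
    stringsAsFactors = FALSE)
  effect_spec(effects,
              dose_multipliers = c(Veh = 0, LSD10 = 0.4, LSD100 = 1),
              noise_sd = 0.015 * baseline, ar1_rho = 0.3,
              drift_slope = 0.02)
}
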