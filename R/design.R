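#' Scan design for a phMRI session
#'
#' Describes the acquisition schedule of a pharmacological MRI run: the
#' number of repetitions, the repetition time, and the two scan windows the
#' per-voxel statistics compare. The defaults describe a 350-scan session at
#' TR 6 s with the drug injected after scan 50: scans 1-50 form the control
#' (pre-injection) window and scans 51-350 the stimulation window, a 35-min
#' session in total.
#'
#' @param n_reps Number of acquisitions (NR).
#' @param tr_seconds Repetition time in seconds.
#' @param control_window Inclusive 1-based scan range `c(first, last)` of the
#'   pre-injection baseline.
#' @param stim_window Inclusive 1-based scan range of the post-injection
#'   window.
#' @param baseline_threshold_pct Minimum absolute percent change (vs the
#'   control-window baseline) for a voxel to enter the positive/negative
#'   activation tallies. Default 1%.
#' @return A `scan_design` object.
#' @export
scan_design <- function(n_reps = 350L, tr_seconds = 6,
                        control_window = c(1L, 50L),
                        stim_window = c(51L, 350L),
                        baseline_threshold_pct = 1) {
  n_reps <- as.integer(n_reps)
  control_window <- as.integer(control_window)
  stim_window <- as.integer(stim_window)
  assert_that(n_reps >= 2, "n_reps must be at least 2")
  assert_that(tr_seconds > 0, "tr_seconds must be positive")
  for (w in list(control_window, stim_window)) {
    assert_that(length(w) == 2 && w[1] >= 1 && w[2] <= n_reps && w[1] <= w[2],
                "scan windows must be inclusive ranges within [1, n_reps]")
  }
  assert_that(control_window[2] < stim_window[1] ||
                stim_window[2] < control_window[1],
              "control and stimulation windows must be disjoint")
  assert_that(baseline_threshold_pct >= 0,
              "baseline_threshold_pct must be non-negative")
  structure(list(n_reps = n_reps, tr_seconds = tr_seconds,
                 control_window = control_window, stim_window = stim_window,
                 baseline_threshold_pct = baseline_threshold_pct),
            class = "scan_design")
}

#' Total session duration in minutes
#'
#' @param design A [scan_design()].
#' @return Session length `n_reps * tr_seconds / 60` in minutes (35 for the
#'   default 350-scan, TR 6 s design).
#' @export
session_duration_min <- function(design) {
  stopifnot(inherits(design, "scan_design"))
  design$n_reps * design$tr_seconds / 60
}

#' @export
print.scan_design <- function(x, ...) {
  cat(sprintf(
    "phMRI scan design: %d reps, TR %g s (%g min session)\n", x$n_reps,
    x$tr_seconds, session_duration_min(x)))
  cat(sprintf("  control window: scans %d-%d; stimulation window: %d-%d\n",
              x$control_window[1], x$control_window[2],
              x$stim_window[1], x$stim_window[2]))
  cat(sprintf("  baseline threshold: %g%%\n", x$baseline_threshold_pct))
  invisible(x)
}

window_scans <- function(design, which = c("control", "stim")) {
  which <- match.arg(which)
  w <- if (which == "control") design$control_window else design$stim_window
  seq.int(w[1], w[2])
}

#' Parameters of the rank-based false-positive filter
#'
#' Holds the constants of the step-up filter \eqn{P_{(i)} \le (i/V) q /
#' c(V)} used to screen the per-voxel t-test p-values: the filter level `q`
#' (default 0.2), the constant `c_V` (default 1, the conservative choice for
#' independent or positively dependent tests), and the number of tests `V`.
#'
#' @param q Filter level in (0, 1].
#' @param c_V Constant \eqn{c(V) \ge 1}.
#' @param V Number of tests (e.g. in-brain voxel count for voxel maps, 173
#'   for region tables).
#' @return An `fdr_params` object.
#' @export
fdr_params <- function(q = 0.2, c_V = 1, V = 173L) {
  assert_that(q > 0 && q <= 1, "q must lie in (0, 1]")
  assert_that(c_V >= 1, "c_V must be >= 1")
  assert_that(V >= 1, "V must be >= 1")
  structure(list(q = q, c_V = c_V, V = as.integer(V)), class = "fdr_params")
}

#' Dose-response effect specification for the phMRI phantom
#'
#' Defines where and how strongly the simulated drug changes the BOLD
#' signal. Each affected region has a sign, a peak percent-change magnitude,
#' an onset scan and a linear ramp length; group membership scales the
#' magnitude through `dose_multipliers` (vehicle is pinned at exactly 0).
#'
#' @param effects Data frame with columns `region_id`, `sign` ("positive" or
#'   "negative"), `magnitude_pct` (peak percent change, >= 0), `onset_scan`,
#'   `ramp_scans` (scans from onset to plateau).
#' @param dose_multipliers Named numeric vector of per-group multipliers;
#'   must contain "Veh" with value 0.
#' @param noise_sd Voxel noise standard deviation in signal units.
#' @param ar1_rho Lag-1 autocorrelation of the voxel noise, in [0, 1).
#' @param drift_slope Linear scanner drift in signal units per scan.
#' @return An `effect_spec` object.
#' @export
effect_spec <- function(effects,
                        dose_multipliers = c(Veh = 0, LSD10 = 0.4, LSD100 = 1),
                        noise_sd = 0, ar1_rho = 0, drift_slope = 0) {
  required <- c("region_id", "sign", "magnitude_pct", "onset_scan",
                "ramp_scans")
  assert_that(is.data.frame(effects) && all(required %in% names(effects)),
              "effects must be a data frame with columns %s",
              paste(required, collapse = ", "))
  assert_that(all(effects$sign %in% c("positive", "negative")),
              "effect sign must be 'positive' or 'negative'")
  assert_that(all(effects$magnitude_pct >= 0),
              "magnitude_pct must be non-negative")
  assert_that(!anyDuplicated(effects$region_id),
              "one effect entry per region_id")
  assert_that("Veh" %in% names(dose_multipliers) &&
                dose_multipliers[["Veh"]] == 0,
              "dose_multipliers must contain Veh with multiplier exactly 0")
  assert_that(noise_sd >= 0, "noise_sd must be non-negative")
  assert_that(ar1_rho >= 0 && ar1_rho < 1, "ar1_rho must lie in [0, 1)")
  structure(list(effects = effects, dose_multipliers = dose_multipliers,
                 noise_sd = noise_sd, ar1_rho = ar1_rho,
                 drift_slope = drift_slope),
            class = "effect_spec")
}

#' Resting-state phantom specification
#'
#' Describes a resting-state acquisition (defaults: 200 repetitions at TR
#' 1 s, a 15-min scan) and the planted inter-regional correlation structure.
#' `target_cor` gives the population correlation matrix of the latent node
#' signals, either one matrix for all groups or a named list with one matrix
#' per group (e.g. stronger thalamo-cortical coupling under drug). Nuisance
#' structure (6 motion traces, white-matter and CSF signals) is added with
#' known loadings so nuisance regression can be exercised and verified.
#'
#' @param node_ids Region ids (atlas labels) acting as network nodes.
#' @param target_cor Symmetric positive semi-definite correlation matrix
#'   (`length(node_ids)` square), or a named list of such matrices keyed by
#'   group label.
#' @param n_reps Number of repetitions (default 200).
#' @param tr_seconds Repetition time in seconds (default 1).
#' @param signal_amp Amplitude of the latent node signal in each voxel.
#' @param noise_sd Independent voxel noise standard deviation.
#' @param nuisance_load Standard deviation of the random per-voxel loadings
#'   on the 8 nuisance traces (0 disables nuisance structure).
#' @return An `rsfc_spec` object.
#' @export
rsfc_spec <- function(node_ids, target_cor, n_reps = 200L, tr_seconds = 1,
                      signal_amp = 1, noise_sd = 0, nuisance_load = 0) {
  node_ids <- as.integer(node_ids)
  assert_that(length(node_ids) >= 2 && !anyDuplicated(node_ids),
              "node_ids must be >= 2 distinct region ids")
  mats <- if (is.list(target_cor)) target_cor else list(all = target_cor)
  for (nm in names(mats)) validate_target_cor(mats[[nm]], length(node_ids))
  assert_that(n_reps >= 3, "n_reps must be >= 3")
  assert_that(noise_sd >= 0 && signal_amp > 0 && nuisance_load >= 0,
              "amplitudes must be non-negative (signal_amp positive)")
  structure(list(node_ids = node_ids, target_cor = target_cor,
                 n_reps = as.integer(n_reps), tr_seconds = tr_seconds,
                 signal_amp = signal_amp, noise_sd = noise_sd,
                 nuisance_load = nuisance_load),
            class = "rsfc_spec")
}

validate_target_cor <- function(C, n) {
  assert_that(is.matrix(C) && nrow(C) == n && ncol(C) == n,
              "target correlation matrix must be %d x %d", n, n)
  assert_that(max(abs(C - t(C))) < 1e-8, "target matrix must be symmetric")
  assert_that(max(abs(diag(C) - 1)) < 1e-8,
              "target matrix must have unit diagonal")
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop_phbold(
      "target correlation matrix is not positive semi-definite (smallest eigenvalue %.6g)",
      min(ev), class = "phbold_psd_error")
  }
  invisible(TRUE)
}

#' Subject roster for a multi-group study
#'
#' @param subjects Data frame with columns `subject_id`, `group` (one of
#'   "Veh", "LSD10", "LSD100"), `sex`, `seed` (unique per subject), and
#'   optionally `transform` (a list column of [affine_transform()]s mapping
#'   the composite frame into each subject's frame).
#' @return A `group_design` object.
#' @export
group_design <- function(subjects) {
  required <- c("subject_id", "group", "sex", "seed")
  assert_that(is.data.frame(subjects) && all(required %in% names(subjects)),
              "subjects must be a data frame with columns %s",
              paste(required, collapse = ", "))
  assert_that(all(subjects$group %in% c("Veh", "LSD10", "LSD100")),
              "group must be one of Veh, LSD10, LSD100")
  assert_that(!anyDuplicated(subjects$seed), "subject seeds must be unique")
  tab <- table(subjects$group)
  assert_that(all(tab >= 2),
              "each group needs >= 2 subjects for group statistics")
  structure(list(subjects = subjects), class = "group_design")
}

#' Default study roster mirroring the post-exclusion cohort sizes
#'
#' Ten vehicle, nine low-dose and twelve high-dose animals, sexes balanced
#' as closely as the totals allow, each with a unique seed derived from
#' `base_seed`.
#'
#' @param base_seed Integer offset for the per-subject seeds.
#' @return A [group_design()].
#' @export
default_group_design <- function(base_seed = 1000L) {
  sizes <- c(Veh = 10L, LSD10 = 9L, LSD100 = 12L)
  subjects <- do.call(rbind, lapply(names(sizes), function(g) {
    n <- sizes[[g]]
    data.frame(subject_id = sprintf("%s_%02d", g, seq_len(n)),
               group = g,
               sex = rep_len(c("M", "F"), n),
               stringsAsFactors = FALSE)
  }))
  subjects$seed <- base_seed + seq_len(nrow(subjects))
  group_design(subjects)
}
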