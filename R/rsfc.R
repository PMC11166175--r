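#' Node-by-scan time-series matrix
#'
#' @param mat Numeric matrix, nodes in rows, scans in columns.
#' @param node_ids Region ids the rows correspond to.
#' @param tr_seconds Repetition time in seconds.
#' @return A `node_series` object.
#' @export
node_series <- function(mat, node_ids, tr_seconds) {
  assert_that(is.matrix(mat) && nrow(mat) == length(node_ids),
              "mat must be a nodes x scans matrix matching node_ids")
  assert_that(all(is.finite(mat)), "node series must be finite (no missing scans)")
  structure(list(mat = mat, node_ids = as.integer(node_ids),
                 tr_seconds = tr_seconds),
            class = "node_series")
}

#' Average voxel time series within each atlas region
#'
#' Builds the node-level signal matrix by averaging a (residual) 4D series
#' over the voxels of each included atlas region.
#'
#' @param series A [bold_series()].
#' @param atlas An [atlas_volume()] on the same grid.
#' @param node_ids Regions to use as nodes (default: all atlas regions).
#' @return A [node_series()].
#' @export
extract_node_series <- function(series, atlas,
                                node_ids = atlas$regions$region_id) {
  stopifnot(inherits(series, "bold_series"), inherits(atlas, "atlas_volume"))
  assert_that(all(dim(series$signal)[1:3] == dim(atlas$labels)),
              "series and atlas grids differ")
  bad <- setdiff(node_ids, atlas$regions$region_id)
  assert_that(length(bad) == 0, "unknown node regions: %s",
              paste(bad, collapse = ", "))
  Y <- vox_by_scan(series$signal)
  lab <- as.vector(atlas$labels)
  mat <- t(vapply(node_ids, function(id) {
    colMeans(Y[lab == id, , drop = FALSE])
  }, numeric(ncol(Y))))
  node_series(mat, node_ids, series$tr_seconds)
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies a forward-backward (zero-phase) 4th-order Butterworth band-pass,
#' the standard resting-state filter retaining 0.01-0.1 Hz fluctuations
#' while removing slow drift and high-frequency physiological noise. Works
#' on a [node_series()] (per node) or a [bold_series()] (per voxel).
#'
#' @param x A [node_series()] or [bold_series()].
#' @param low_hz,high_hz Passband edges in Hz; requires
#'   `0 <= low_hz < high_hz < ` Nyquist (= 1 / (2 TR)). A TR 6 s phMRI
#'   series is therefore rejected for the default 0.1 Hz band.
#' @param order Butterworth order (default 4).
#' @return Filtered object of the same class.
#' @export
bandpass <- function(x, low_hz = 0.01, high_hz = 0.1, order = 4L) {
  tr <- x$tr_seconds
  nyq <- 1 / (2 * tr)
  assert_that(low_hz >= 0 && low_hz < high_hz,
              "need 0 <= low_hz < high_hz")
  assert_that(high_hz < nyq,
              "high_hz (%g Hz) must be below Nyquist (%g Hz) for TR %g s",
              high_hz, nyq, tr)
  W <- c(low_hz, high_hz) / nyq
  bf <- if (low_hz > 0) signal::butter(order, W, type = "pass")
        else signal::butter(order, W[2], type = "low")
  # demean before filtering: DC is in the stopband anyway, and a large
  # baseline would otherwise leak shared edge transients into every series
  filt_rows <- function(mat) {
    t(apply(mat, 1, function(v) {
      as.numeric(signal::filtfilt(bf, v - mean(v)))
    }))
  }
  if (inherits(x, "node_series")) {
    node_series(filt_rows(x$mat), x$node_ids, tr)
  } else if (inherits(x, "bold_series")) {
    sdim <- dim(x$signal)[1:3]
    Y <- filt_rows(vox_by_scan(x$signal))
    bold_series(scan_to_4d(Y, sdim), tr, x$subject_id, x$modality)
  } else {
    stop_phbold("bandpass expects a node_series or bold_series")
  }
}

#' Nuisance regression (general linear model residuals)
#'
#' Regresses the nuisance structure out of each node (or voxel) time series
#' by ordinary least squares: the design holds an intercept plus the
#' supplied regressors (six motion parameters, mean white-matter and CSF
#' traces, and spike indicators for motion-outlier scans). Residuals are
#' returned; they are orthogonal to every regressor column.
#'
#' @param x A [node_series()], [bold_series()], or plain series-by-scan
#'   matrix.
#' @param regressors Scans-by-regressors numeric matrix.
#' @param outlier_scans Optional integer vector of scan indices to absorb
#'   with one indicator (spike) regressor each.
#' @return Residuals, same class/shape as the input.
#' @export
nuisance_regress <- function(x, regressors, outlier_scans = integer(0)) {
  mat <- if (inherits(x, "node_series")) x$mat
         else if (inherits(x, "bold_series")) vox_by_scan(x$signal)
         else x
  assert_that(is.matrix(mat), "x must be a matrix or series object")
  NR <- ncol(mat)
  assert_that(nrow(regressors) == NR,
              "regressor rows (%d) must equal scan count (%d)",
              nrow(regressors), NR)
  X <- cbind(intercept = 1, regressors)
  if (length(outlier_scans)) {
    spikes <- matrix(0, NR, length(outlier_scans))
    spikes[cbind(outlier_scans, seq_along(outlier_scans))] <- 1
    colnames(spikes) <- paste0("outlier_scan", outlier_scans)
    X <- cbind(X, spikes)
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop_phbold("nuisance design is rank deficient; collinear columns: %s",
                paste(dropped, collapse = ", "))
  }
  res <- t(qr.resid(qx, t(mat)))
  if (inherits(x, "node_series")) {
    node_series(res, x$node_ids, x$tr_seconds)
  } else if (inherits(x, "bold_series")) {
    bold_series(scan_to_4d(res, dim(x$signal)[1:3]), x$tr_seconds,
                x$subject_id, x$modality)
  } else res
}

#' All-pairs Pearson connectivity matrix
#'
#' Computes Pearson correlation between every unordered pair of node time
#' series (n(n-1)/2 pairs, mirrored into a symmetric matrix with unit
#' diagonal). Zero-variance nodes are flagged: their edges are set missing
#' (NA) with a warning rather than propagating NaN.
#'
#' @param nodes A [node_series()] with >= 3 scans.
#' @return A `connectivity_matrix` of kind "pearson_r" with attributes
#'   `n_pairs` and `node_ids`.
#' @export
connectivity <- function(nodes) {
  stopifnot(inherits(nodes, "node_series"))
  assert_that(ncol(nodes$mat) >= 3, "need at least 3 scans")
  sds <- apply(nodes$mat, 1, stats::sd)
  flat <- sds == 0
  r <- suppressWarnings(stats::cor(t(nodes$mat)))
  if (any(flat)) {
    warning(sprintf("%d zero-variance node(s): %s; their edges set missing",
                    sum(flat),
                    paste(nodes$node_ids[flat], collapse = ", ")))
    r[flat, ] <- NA_real_
    r[, flat] <- NA_real_
  }
  diag(r) <- 1
  connectivity_matrix(r, kind = "pearson_r", node_ids = nodes$node_ids)
}

#' Connectivity matrix container
#'
#' @param mat Square symmetric matrix.
#' @param kind "pearson_r" (unit diagonal), "fisher_z" or "group_z" (zero
#'   diagonal, excluded from statistics).
#' @param node_ids Region ids for rows/columns.
#' @return A `connectivity_matrix`.
#' @export
connectivity_matrix <- function(mat, kind = c("pearson_r", "fisher_z",
                                              "group_z"),
                                node_ids = seq_len(nrow(mat))) {
  kind <- match.arg(kind)
  assert_that(is.matrix(mat) && nrow(mat) == ncol(mat),
              "mat must be square")
  assert_that(max(abs(mat - t(mat)), na.rm = TRUE) < 1e-12 ||
                all(is.na(mat)), "matrix must be symmetric")
  if (kind == "pearson_r") {
    assert_that(all(abs(mat[!is.na(mat)]) <= 1 + 1e-12),
                "pearson_r entries must lie in [-1, 1]")
  }
  n <- nrow(mat)
  structure(list(mat = mat, kind = kind, node_ids = as.integer(node_ids),
                 n_nodes = n, n_pairs = n_node_pairs(n)),
            class = "connectivity_matrix")
}

#' Unordered node-pair count n(n-1)/2
#'
#' Bookkeeping for the all-pairs correlation stage: 171 nodes give 14 535
#' pairs; a 166-node matrix gives 13 695. (Published node counts are
#' internally inconsistent -- 173 atlas regions, 166 x 166 matrices, but
#' 14 535 pairs, which corresponds to 171 nodes; see the methods vignette.)
#'
#' @param n_nodes Number of network nodes.
#' @return Integer pair count.
#' @export
n_node_pairs <- function(n_nodes) {
  as.integer(round(n_nodes * (n_nodes - 1) / 2))
}

#' Fisher Z transform of a correlation matrix
#'
#' `z = atanh(r)` with |r| clipped to `1 - 1e-7` so unit correlations map to
#' a large finite value instead of infinity. Diagonal set to 0 (excluded
#' from statistics).
#'
#' @param cm A `connectivity_matrix` of kind "pearson_r".
#' @return A `connectivity_matrix` of kind "fisher_z".
#' @export
fisher_z <- function(cm) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  assert_that(cm$kind == "pearson_r", "fisher_z expects a pearson_r matrix")
  r <- pmin(pmax(cm$mat, -1 + 1e-7), 1 - 1e-7)
  z <- atanh(r)
  diag(z) <- 0
  connectivity_matrix(z, kind = "fisher_z", node_ids = cm$node_ids)
}

#' Group-level edge Z matrix from one-sample t-tests
#'
#' For every edge, the subjects' Fisher-Z values are tested against zero
#' with a one-sample t-test; the two-tailed p-value is converted back to a
#' signed standard-normal score (inverse-normal of p/2, carrying the t's
#' sign) so the fixed |Z| threshold applies on a common scale. |Z| is capped
#' at 8; edges with zero variance across subjects and nonzero mean hit the
#' cap and are flagged degenerate.
#'
#' @param z_matrices List of >= 2 per-subject "fisher_z"
#'   `connectivity_matrix` objects over the same node set.
#' @return A `connectivity_matrix` of kind "group_z" with a logical
#'   `degenerate` attribute matrix.
#' @export
group_edge_z <- function(z_matrices) {
  assert_that(length(z_matrices) >= 2, "need >= 2 subjects")
  for (m in z_matrices) {
    stopifnot(inherits(m, "connectivity_matrix"))
    assert_that(m$kind == "fisher_z", "inputs must be fisher_z matrices")
    assert_that(identical(m$node_ids, z_matrices[[1]]$node_ids),
                "node sets differ across subjects")
  }
  S <- length(z_matrices)
  n <- z_matrices[[1]]$n_nodes
  arr <- vapply(z_matrices, function(m) m$mat, matrix(0, n, n))
  mu <- apply(arr, c(1, 2), mean)
  sdv <- apply(arr, c(1, 2), stats::sd)
  tmat <- mu / (sdv / sqrt(S))
  p <- 2 * stats::pt(-abs(tmat), df = S - 1)
  Z <- sign(tmat) * stats::qnorm(p / 2, lower.tail = FALSE)
  degen <- sdv == 0 & mu != 0
  Z[sdv == 0 & mu == 0] <- 0
  Z[degen] <- sign(mu[degen]) * Inf
  Z <- pmin(pmax(Z, -8), 8)
  diag(Z) <- 0
  Z <- (Z + t(Z)) / 2  # kill numerically asymmetric round-off
  out <- connectivity_matrix(Z, kind = "group_z",
                             node_ids = z_matrices[[1]]$node_ids)
  attr(out, "degenerate") <- degen
  out
}
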