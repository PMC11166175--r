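MACRO_REGIONS <- c("cortex", "olfactory", "thalamus", "hippocampus",
                   "amygdala", "basal_ganglia", "brainstem_pons",
                   "cerebellum", "cerebellar_nuclei", "other")

#' Atlas volume: integer label grid plus region table
#'
#' The spatial frame all statistics aggregate over: a 3D grid of
#' non-negative integer labels (0 = background, outside the brain) and a
#' table describing each region.
#'
#' @param labels 3D integer array; 0 marks background.
#' @param regions Data frame with columns `region_id` (positive integer),
#'   `name`, `macro_region` (one of cortex, olfactory, thalamus,
#'   hippocampus, amygdala, basal_ganglia, brainstem_pons, cerebellum,
#'   cerebellar_nuclei, other) and `hemisphere` (left/right/midline).
#' @param voxel_size Numeric length-3, voxel edge length in mm per axis.
#' @return An `atlas_volume` object.
#' @export
atlas_volume <- function(labels, regions, voxel_size = c(0.3, 0.3, 1)) {
  assert_that(is.array(labels) && length(dim(labels)) == 3,
              "labels must be a 3D array")
  storage.mode(labels) <- "integer"
  assert_that(all(labels >= 0), "labels must be non-negative")
  required <- c("region_id", "name", "macro_region", "hemisphere")
  assert_that(is.data.frame(regions) && all(required %in% names(regions)),
              "regions must be a data frame with columns %s",
              paste(required, collapse = ", "))
  assert_that(!anyDuplicated(regions$region_id),
              "region ids must be unique in the region table")
  assert_that(all(regions$macro_region %in% MACRO_REGIONS),
              "unknown macro_region value")
  assert_that(all(regions$hemisphere %in% c("left", "right", "midline")),
              "hemisphere must be left, right or midline")
  present <- sort(unique(as.vector(labels[labels > 0L])))
  missing <- setdiff(present, regions$region_id)
  assert_that(length(missing) == 0,
              "labels present in grid but absent from region table: %s",
              paste(missing, collapse = ", "))
  empty <- setdiff(regions$region_id, present)
  assert_that(length(empty) == 0,
              "regions with zero voxels: %s", paste(empty, collapse = ", "))
  assert_that(length(voxel_size) == 3 && all(voxel_size > 0),
              "voxel_size must be three positive lengths (mm)")
  structure(list(labels = labels, regions = regions,
                 voxel_size = as.numeric(voxel_size)),
            class = "atlas_volume")
}

#' @export
print.atlas_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("Atlas volume: %d x %d x %d voxels, %d regions, voxel %s mm\n",
              d[1], d[2], d[3], nrow(x$regions),
              paste(signif(x$voxel_size, 3), collapse = " x ")))
  invisible(x)
}

#' Number of voxels per atlas region
#' @param atlas An [atlas_volume()].
#' @return Named integer vector keyed by region_id.
#' @export
region_sizes <- function(atlas) {
  lab <- atlas$labels[atlas$labels > 0L]
  tab <- table(factor(lab, levels = atlas$regions$region_id))
  stats::setNames(as.integer(tab), atlas$regions$region_id)
}

#' Generate a synthetic brain atlas
#'
#' Builds a compact, contiguous parcellation inside an ellipsoidal "brain"
#' mask: `n_regions` seed voxels are sampled inside the mask and every
#' in-mask voxel is assigned to its nearest seed, producing Voronoi-style
#' compact regions. Voxels outside the ellipsoid stay background (0). Region
#' names, macro-region assignments (cycling through the ten macro
#' categories) and hemispheres (by the seed's position along x) populate the
#' region table. Deterministic for a fixed seed.
#'
#' @param dims Integer length-3 grid size.
#' @param n_regions Number of regions to create (default 173, matching a
#'   fully segmented rat atlas).
#' @param seed RNG seed.
#' @param voxel_size Voxel size in mm per axis.
#' @return An [atlas_volume()].
#' @export
generate_atlas <- function(dims, n_regions = 173L, seed = 1L,
                           voxel_size = c(0.3, 0.3, 1)) {
  dims <- as.integer(dims)
  n_regions <- as.integer(n_regions)
  assert_that(length(dims) == 3 && all(dims >= 1), "dims must be 3 positive")
  assert_that(n_regions >= 1, "n_regions must be >= 1")
  assert_that(prod(dims) >= n_regions,
              "grid too small to host %d non-empty regions", n_regions)

  centre <- (dims + 1) / 2
  semi <- pmax(dims / 2 - 0.5, 0.5)
  gx <- seq_len(dims[1]); gy <- seq_len(dims[2]); gz <- seq_len(dims[3])
  ex <- ((gx - centre[1]) / semi[1])^2
  ey <- ((gy - centre[2]) / semi[2])^2
  ez <- ((gz - centre[3]) / semi[3])^2
  mask <- outer(outer(ex, ey, `+`), ez, `+`) <= 1
  if (sum(mask) < n_regions) mask[] <- TRUE  # tiny grids: use every voxel
  assert_that(sum(mask) >= n_regions,
              "grid too small to host %d non-empty regions", n_regions)

  idx <- which(mask)
  coords <- arrayInd(idx, dims)
  with_seed(seed, {
    seeds <- sample(nrow(coords), n_regions)
    # nearest-seed assignment in voxel units (isotropic growth)
    sc <- coords[seeds, , drop = FALSE]
    nearest <- integer(nrow(coords))
    best <- rep(Inf, nrow(coords))
    for (r in seq_len(n_regions)) {
      d2 <- (coords[, 1] - sc[r, 1])^2 + (coords[, 2] - sc[r, 2])^2 +
        (coords[, 3] - sc[r, 3])^2
      upd <- d2 < best
      nearest[upd] <- r
      best[upd] <- d2[upd]
    }
    nearest[seeds] <- seq_len(n_regions)  # seeds always own their voxel
    labels <- array(0L, dim = dims)
    labels[idx] <- nearest
    macro <- rep_len(MACRO_REGIONS, n_regions)
    hemi <- ifelse(abs(sc[, 1] - centre[1]) < 0.75, "midline",
                   ifelse(sc[, 1] < centre[1], "left", "right"))
    regions <- data.frame(
      region_id = seq_len(n_regions),
      name = sprintf("region_%03d_%s", seq_len(n_regions), macro),
      macro_region = macro, hemisphere = hemi, stringsAsFactors = FALSE)
    atlas_volume(labels, regions, voxel_size)
  })
}
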