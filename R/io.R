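#' Write / read volumes as NIfTI-1
#'
#' Atlas label grids are written as integer volumes together with their
#' region table (TSV sidecar); BOLD series as 4D float volumes carrying the
#' repetition time in the header. Round trips preserve integer labels
#' bit-exactly and signals within float32 representation.
#'
#' @param x An [atlas_volume()] or [bold_series()].
#' @param path Output `.nii`/`.nii.gz` path. For an atlas, the region table
#'   goes to `<path without extension>_regions.tsv` unless `table_path` is
#'   given.
#' @param table_path Optional explicit region-table path (atlas only).
#' @return The main path written, invisibly.
#' @export
write_volume <- function(x, path, table_path = NULL) {
  if (inherits(x, "atlas_volume")) {
    img <- RNifti::asNifti(structure(x$labels, pixdim = x$voxel_size),
                           datatype = "int32")
    RNifti::writeNifti(img, path)
    tp <- table_path %||% paste0(sub("\\.nii(\\.gz)?$", "", path),
                                 "_regions.tsv")
    write_region_table(x$regions, tp)
  } else if (inherits(x, "bold_series")) {
    img <- RNifti::asNifti(structure(x$signal,
                                     pixdim = c(1, 1, 1, x$tr_seconds)),
                           datatype = "float")
    RNifti::writeNifti(img, path)
  } else {
    stop_phbold("write_volume expects an atlas_volume or bold_series")
  }
  invisible(path)
}

#' @rdname write_volume
#' @param type "atlas" or "series": the declared content of the file.
#' @param tr_seconds Repetition time for a series (overrides the header).
#' @param modality Modality tag for a series.
#' @param subject_id Subject id for a series.
#' @param voxel_size Voxel size for an atlas (overrides the header).
#' @export
read_volume <- function(path, type = c("series", "atlas"),
                        table_path = NULL, tr_seconds = NULL,
                        modality = "phmri", subject_id = "subject",
                        voxel_size = NULL) {
  type <- match.arg(type)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  nd <- length(dim(arr))
  pdim <- RNifti::pixdim(img)
  if (type == "atlas") {
    assert_that(nd == 3, "atlas volumes must be 3D; '%s' has %d dimensions",
                path, nd)
    tp <- table_path %||% paste0(sub("\\.nii(\\.gz)?$", "", path),
                                 "_regions.tsv")
    assert_that(file.exists(tp), "region table not found: %s", tp)
    regions <- read_region_table(tp)
    labs <- array(as.integer(round(arr)), dim(arr))
    atlas_volume(labs, regions, voxel_size %||% pdim[1:3])
  } else {
    assert_that(nd == 4, "BOLD series must be 4D; '%s' has %d dimensions",
                path, nd)
    tr <- tr_seconds %||% unname(pdim[4])
    bold_series(array(as.numeric(arr), dim(arr)), tr,
                subject_id = subject_id, modality = modality)
  }
}

#' Region label table IO (TSV)
#'
#' Columns: region_id, name, macro_region, hemisphere.
#' @param regions Region data frame.
#' @param path TSV path.
#' @export
write_region_table <- function(regions, path) {
  utils::write.table(regions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_region_table
#' @export
read_region_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Serialize / deserialize affine transforms as JSON
#'
#' Stores both the components (translation voxels, rotation degrees, scale)
#' and the composed 4x4 matrix.
#' @param transform An [affine_transform()] or named list of them.
#' @param path JSON path.
#' @export
write_transforms <- function(transform, path) {
  one <- function(tr) list(translation = tr$translation,
                           rotation_deg = tr$rotation_deg,
                           scale = tr$scale,
                           matrix = tr$matrix)
  obj <- if (inherits(transform, "affine_transform")) one(transform)
         else lapply(transform, one)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_transforms
#' @export
read_transforms <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  one <- function(o) affine_transform(o$translation, o$rotation_deg, o$scale)
  if (!is.null(obj$translation)) one(obj) else lapply(obj, one)
}

#' Export a connectivity matrix as TSV and MatrixMarket
#'
#' @param cm A `connectivity_matrix`.
#' @param tsv_path,mm_path Output paths (either may be NULL to skip).
#' @export
write_connectivity <- function(cm, tsv_path = NULL, mm_path = NULL) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  m <- cm$mat
  dimnames(m) <- list(cm$node_ids, cm$node_ids)
  if (!is.null(tsv_path)) {
    utils::write.table(m, tsv_path, sep = "\t", quote = FALSE,
                       col.names = NA)
  }
  if (!is.null(mm_path)) {
    m0 <- m
    m0[is.na(m0)] <- 0
    Matrix::writeMM(Matrix::Matrix(m0, sparse = TRUE), mm_path)
  }
  invisible(cm)
}

#' Export a network graph as edge-list CSV and GraphML
#'
#' @param graph A [network_graph()].
#' @param csv_path,graphml_path Output paths (either may be NULL to skip).
#' @export
write_graph_files <- function(graph, csv_path = NULL, graphml_path = NULL) {
  stopifnot(inherits(graph, "network_graph"))
  A <- graph$adjacency
  ij <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
  edges <- data.frame(from = graph$node_ids[ij[, 1]],
                      to = graph$node_ids[ij[, 2]],
                      weight = A[ij])
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  if (!is.null(csv_path)) {
    utils::write.csv(edges, csv_path, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(graphml_path)) {
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                             weighted = TRUE)
    igraph::V(g)$name <- as.character(graph$node_ids)
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  invisible(edges)
}

#' Default run configuration ("awake-rat-default" profile)
#'
#' All pipeline parameters with their standard values: 350-scan TR 6 s
#' phMRI sessions with control window 1-50 and stimulation window 51-350,
#' 1% baseline threshold, filter level q = 0.2 with c(V) = 1, 0.8 mm
#' smoothing, 173-region atlas on a 20 x 20 x 12 grid, resting-state
#' sessions of 200 scans at TR 1 s band-passed 0.01-0.1 Hz, |Z| = 2.3 graph
#' threshold, and the post-exclusion group sizes 10/9/12.
#'
#' @param out_dir Output directory recorded in the config.
#' @param seed Base seed.
#' @return A `run_config` list.
#' @export
default_config <- function(out_dir = tempdir(), seed = 1L) {
  structure(list(
    profile = "awake-rat-default",
    out_dir = out_dir, seed = as.integer(seed), log_level = "info",
    atlas = list(dims = c(20L, 20L, 12L), n_regions = 173L,
                 voxel_size = c(0.3, 0.3, 1)),
    scan = list(n_reps = 350L, tr_seconds = 6, control_window = c(1L, 50L),
                stim_window = c(51L, 350L), baseline_threshold_pct = 1),
    fdr = list(q = 0.2, c_V = 1),
    # 0 at desk scale: regions are only ~3 voxels across, so any spatially
    # matched kernel dilutes region signal into background far more than in
    # real whole-brain geometry (see the methods vignette)
    smoothing_fwhm_mm = 0,
    rsfc = list(n_reps = 200L, tr_seconds = 1, band_hz = c(0.01, 0.1),
                z_cut = 2.3, knn_k = NA_integer_),
    groups = list(Veh = 10L, LSD10 = 9L, LSD100 = 12L)),
    class = "run_config")
}

#' Read / write a run configuration (YAML)
#' @param config A `run_config`.
#' @param path YAML path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  assert_that(file.exists(path), "config file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "run_config")
}

validate_config <- function(config) {
  stopifnot(inherits(config, "run_config"))
  sd <- do.call(scan_design, config$scan)  # validates windows
  assert_that(config$fdr$q > 0 && config$fdr$q <= 1, "q out of range")
  assert_that(config$fdr$c_V >= 1, "c_V out of range")
  assert_that(config$rsfc$band_hz[1] < config$rsfc$band_hz[2],
              "band edges out of order")
  assert_that(config$rsfc$z_cut >= 0, "z_cut must be non-negative")
  invisible(sd)
}
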