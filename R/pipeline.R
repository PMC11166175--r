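#' Default resting-state specification over an atlas
#'
#' Builds the shipped resting-state study conditions: nodes are all atlas
#' regions except the "other" macro region (mirroring the exclusion of
#' non-neural regions from connectivity matrices), and the planted
#' correlation structure holds two effects whose strength differs by group:
#' a thalamo-cortical block (5 thalamic + 5 cortical nodes, within-set
#' correlation 0.7, cross-set coupling 0.7 under high-dose drug, 0.45 low
#' dose, 0.2 vehicle) and a cerebellar-nuclei hub (2 nuclei coupled 0.7 to
#' each other and 0.35 / 0.2 / 0.1 to 6 brainstem partner nodes for
#' LSD100 / LSD10 / Veh). All other nodes are uncorrelated. The hub
#' coupling is the strongest star coupling keeping the target matrix
#' positive semi-definite at these set sizes.
#'
#' @param atlas An [atlas_volume()] whose macro regions include thalamus,
#'   cortex, cerebellar_nuclei and brainstem_pons.
#' @param n_reps,tr_seconds Acquisition schedule (defaults 200 scans, TR
#'   1 s).
#' @param noise_sd Independent voxel noise sd (latent signal has unit sd).
#'   The default of 4 puts voxel-level contrast-to-noise in the low range
#'   typical of single-shot rodent EPI, so that after node averaging the
#'   vehicle-level coupling sits near the group detection limit of the
#'   fixed |Z| threshold while drug-level coupling is comfortably above it.
#' @param nuisance_load Per-voxel nuisance loading sd.
#' @return An [rsfc_spec()] with attribute `sets` naming the planted node
#'   sets (`thalamus`, `cortex`, `nuclei`, `partners`).
#' @export
default_rsfc_spec <- function(atlas, n_reps = 200L, tr_seconds = 1,
                              noise_sd = 4, nuisance_load = 0.3) {
  reg <- atlas$regions
  node_ids <- reg$region_id[reg$macro_region != "other"]
  pick <- function(macro, k) {
    ids <- reg$region_id[reg$macro_region == macro]
    assert_that(length(ids) >= 1, "atlas has no %s regions", macro)
    ids[seq_len(min(k, length(ids)))]  # smaller atlases get smaller sets
  }
  sets <- list(thalamus = pick("thalamus", 5L), cortex = pick("cortex", 5L),
               nuclei = pick("cerebellar_nuclei", 2L),
               partners = pick("brainstem_pons", 6L))
  build <- function(cross_tc, cross_hub) {
    n <- length(node_ids)
    C <- diag(n)
    it <- match(sets$thalamus, node_ids); ic <- match(sets$cortex, node_ids)
    C[it, it] <- 0.7; C[ic, ic] <- 0.7
    C[it, ic] <- cross_tc; C[ic, it] <- cross_tc
    ih <- match(sets$nuclei, node_ids); ip <- match(sets$partners, node_ids)
    C[ih, ih] <- 0.7
    C[ih, ip] <- cross_hub; C[ip, ih] <- cross_hub
    diag(C) <- 1
    C
  }
  targets <- list(Veh = build(0.2, 0.1), LSD10 = build(0.45, 0.2),
                  LSD100 = build(0.7, 0.35))
  spec <- rsfc_spec(node_ids, targets, n_reps = n_reps,
                    tr_seconds = tr_seconds, signal_amp = 1,
                    noise_sd = noise_sd, nuisance_load = nuisance_load)
  attr(spec, "sets") <- sets
  spec
}

#' Run the analysis pipeline
#'
#' Ties the stages into the two arms of the study. Commands:
#' \describe{
#'   \item{simulate}{Generate the synthetic dataset (atlas, roster,
#'     per-subject phMRI and resting-state volumes, ground-truth sidecar)
#'     and write it under `out_dir`.}
#'   \item{activate}{Per-subject activation maps and per-region
#'     activated-voxel counts (TSV).}
#'   \item{composite}{Per-group composite filtered percent-change maps
#'     (NIfTI).}
#'   \item{voa}{Ranked volume-of-activation tables, both arms, vehicle vs
#'     each dose (TSV + JSON).}
#'   \item{rsfc}{Resting-state arm through group edge Z matrices (TSV +
#'     MatrixMarket).}
#'   \item{graph}{Thresholded networks, degrees, planted subnetwork
#'     summaries (CSV/GraphML/TSV).}
#'   \item{report}{All of the above plus the pooled olfactory-style group
#'     time course, and a JSON run manifest.}
#' }
#' Deterministic given `config$seed`: per-subject seeds derive from it, so
#' two runs from the same config produce byte-identical numeric tables.
#'
#' @param config A `run_config` (see [default_config()]).
#' @param command One of simulate, activate, composite, voa, rsfc, graph,
#'   report.
#' @return Invisibly, a list of in-memory results (atlas, counts, tables,
#'   matrices, graphs, manifest path) for the stages that ran.
#' @export
run_pipeline <- function(config,
                         command = c("report", "simulate", "activate",
                                     "composite", "voa", "rsfc", "graph")) {
  command <- match.arg(command)
  validate_config(config)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_msg <- function(fmt, ...) {
    if (identical(config$log_level, "quiet")) return(invisible())
    message(sprintf(paste0("[phbold] ", fmt), ...))
  }

  design <- do.call(scan_design, config$scan)
  atlas <- generate_atlas(config$atlas$dims, config$atlas$n_regions,
                          seed = config$seed,
                          voxel_size = config$atlas$voxel_size)
  roster <- group_roster_from_config(config)
  stim_len <- design$stim_window[2] - design$stim_window[1] + 1L
  effect <- default_effect_spec(
    atlas,
    n_negative = min(32L, config$atlas$n_regions %/% 3),
    n_positive = min(6L, config$atlas$n_regions %/% 6),
    onset_scan = design$stim_window[1],
    ramp_scans = max(1L, min(50L, stim_len %/% 6L)))
  res <- list(atlas = atlas, design = design, roster = roster,
              effect = effect)
  artifacts <- character(0)

  phmri_subject <- function(i) {
    s <- roster$subjects[i, ]
    simulate_phmri(atlas, design, effect, s$group, seed = s$seed,
                   subject_id = s$subject_id)
  }

  if (command == "simulate") {
    write_volume(atlas, file.path(out, "atlas.nii.gz"))
    jsonlite::write_json(
      list(profile = config$profile, groups = unique(roster$subjects$group),
           subjects = roster$subjects,
           effects = effect$effects,
           dose_multipliers = as.list(effect$dose_multipliers)),
      file.path(out, "ground_truth.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    for (i in seq_len(nrow(roster$subjects))) {
      s <- roster$subjects[i, ]
      write_volume(phmri_subject(i),
                   file.path(out, sprintf("phmri_%s.nii.gz", s$subject_id)))
    }
    log_msg("simulate: wrote %d phMRI sessions and atlas to %s",
            nrow(roster$subjects), out)
    artifacts <- list.files(out)
    res$manifest <- write_manifest(config, command, artifacts, out)
    return(invisible(res))
  }

  need_counts <- command %in% c("activate", "voa", "report", "composite")
  if (need_counts) {
    maps <- list(); counts <- list()
    for (i in seq_len(nrow(roster$subjects))) {
      s <- roster$subjects[i, ]
      ser <- phmri_subject(i)
      ser <- detrend_and_smooth(ser, config$smoothing_fwhm_mm,
                                config$atlas$voxel_size, design)
      m <- activation_analysis(ser, atlas, design, q = config$fdr$q,
                               c_V = config$fdr$c_V)
      cc <- classify_and_count(m, atlas, design)
      cc$subject_id <- s$subject_id
      maps[[s$subject_id]] <- m
      counts[[s$subject_id]] <- cc
    }
    counts <- do.call(rbind, counts)
    res$maps <- maps
    res$counts <- counts
    log_msg("activate: %d subjects, %d voxels tested each, median %d significant",
            nrow(roster$subjects), maps[[1]]$n_brain,
            as.integer(stats::median(vapply(maps,
                                            function(m) sum(m$significant),
                                            numeric(1)))))
    if (command %in% c("activate", "report")) {
      utils::write.table(
        counts[, c("subject_id", "region_id", "positive_count",
                   "negative_count")],
        file.path(out, "voxel_counts.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
    }
  }

  if (command %in% c("composite", "report")) {
    for (g in unique(roster$subjects$group)) {
      sel <- roster$subjects$subject_id[roster$subjects$group == g]
      sm <- lapply(sel, function(sid) {
        list(grid = res$maps[[sid]]$filtered_pct,
             transform = roster$transforms[[sid]])
      })
      comp <- build_composite(sm)
      res$composites[[g]] <- comp
      vals <- comp$values
      vals[is.na(vals)] <- 0
      img <- RNifti::asNifti(vals, datatype = "float")
      RNifti::writeNifti(img, file.path(out,
                                        sprintf("composite_%s.nii.gz", g)))
    }
    log_msg("composite: wrote %d group maps",
            length(unique(roster$subjects$group)))
  }

  if (command %in% c("voa", "report")) {
    rn <- stats::setNames(atlas$regions$name,
                          atlas$regions$region_id)
    fdrp <- fdr_params(q = config$fdr$q, c_V = config$fdr$c_V,
                       V = nrow(atlas$regions))
    for (dose in intersect(c("LSD10", "LSD100"),
                           unique(roster$subjects$group))) {
      for (arm in c("positive", "negative")) {
        vt <- build_voa_table(res$counts, roster$design, arm = arm,
                              compare = c("Veh", dose), fdr = fdrp,
                              region_names = rn)
        key <- sprintf("voa_%s_%s", arm, dose)
        res$voa[[key]] <- vt
        tab <- vt$table
        utils::write.table(tab, file.path(out, paste0(key, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        jsonlite::write_json(
          list(arm = vt$arm, groups = vt$groups, V = vt$V, q = vt$q,
               n_rows = nrow(tab), fdr_critical = vt$fdr_critical,
               fdr_critical_rounded = vt$fdr_critical_rounded,
               table = tab),
          file.path(out, paste0(key, ".json")), auto_unbox = TRUE,
          digits = NA, pretty = TRUE)
        log_msg("voa: %s %s -> %d rows (FDR P = %.3f)", arm, dose,
                nrow(tab), vt$fdr_critical_rounded)
      }
    }
  }

  if (command == "report") {
    olf <- effect$effects$region_id[effect$effects$sign == "negative"]
    olf <- olf[seq_len(min(6, length(olf)))]
    traces <- do.call(rbind, lapply(seq_len(nrow(roster$subjects)),
                                    function(i) {
      s <- roster$subjects[i, ]
      if (!s$group %in% c("Veh", "LSD100")) return(NULL)
      ser <- phmri_subject(i)
      pc <- percent_change(ser, design)
      data.frame(subject_id = s$subject_id, group = s$group,
                 scan = seq_len(design$n_reps),
                 value = regional_pct_trace(pc, atlas, olf))
    }))
    tc <- group_timecourse(traces, bin = config$timecourse_bin %||% 1L)
    res$timecourse <- tc
    utils::write.table(tc$timecourse, file.path(out, "timecourse.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log_msg("timecourse: interaction F = %.3f (df %d, %d)",
            tc$interaction$F, tc$interaction$df1, tc$interaction$df2)
  }

  if (command %in% c("rsfc", "graph", "report")) {
    spec <- default_rsfc_spec(atlas, n_reps = config$rsfc$n_reps,
                              tr_seconds = config$rsfc$tr_seconds)
    res$rsfc_spec <- spec
    zs <- list()
    for (i in seq_len(nrow(roster$subjects))) {
      s <- roster$subjects[i, ]
      sim <- simulate_rsfc(atlas, spec, s$group, seed = s$seed + 500000L,
                           subject_id = s$subject_id)
      nodes <- extract_node_series(sim$series, atlas, spec$node_ids)
      nodes <- bandpass(nodes, config$rsfc$band_hz[1],
                        config$rsfc$band_hz[2])
      nodes <- nuisance_regress(nodes, sim$nuisance)
      zs[[s$subject_id]] <- list(group = s$group,
                                 z = fisher_z(connectivity(nodes)))
    }
    for (g in unique(roster$subjects$group)) {
      zg <- lapply(Filter(function(e) e$group == g, zs), `[[`, "z")
      gz <- group_edge_z(zg)
      res$group_z[[g]] <- gz
      write_connectivity(gz,
                         tsv_path = file.path(out,
                                              sprintf("group_z_%s.tsv", g)),
                         mm_path = file.path(out,
                                             sprintf("group_z_%s.mtx", g)))
    }
    log_msg("rsfc: %d nodes, %d pairs per matrix",
            length(spec$node_ids), n_node_pairs(length(spec$node_ids)))
  }

  if (command %in% c("graph", "report")) {
    sets <- attr(res$rsfc_spec, "sets")
    for (g in names(res$group_z)) {
      gr <- threshold_graph(res$group_z[[g]], z_cut = config$rsfc$z_cut)
      res$graphs[[g]] <- gr
      write_graph_files(gr,
                        csv_path = file.path(out,
                                             sprintf("edges_%s.csv", g)),
                        graphml_path = file.path(out,
                                                 sprintf("graph_%s.graphml",
                                                         g)))
      deg <- degree_centrality(gr)
      utils::write.table(
        data.frame(region_id = gr$node_ids, degree = deg$degree,
                   strength = deg$strength),
        file.path(out, sprintf("degree_%s.tsv", g)), sep = "\t",
        quote = FALSE, row.names = FALSE)
      res$subnetworks[[g]] <- list(
        thalamo_cortical = subnetwork_analysis(gr, sets$thalamus,
                                               sets$cortex),
        cerebellar = subnetwork_analysis(gr, sets$nuclei,
                                         union_nodes = sets$partners))
    }
    log_msg("graph: thresholded at |Z| >= %g", config$rsfc$z_cut)
  }

  artifacts <- sort(list.files(out))
  res$manifest <- write_manifest(config, command, artifacts, out)
  invisible(res)
}

group_roster_from_config <- function(config) {
  sizes <- unlist(config$groups)
  subjects <- do.call(rbind, lapply(names(sizes), function(g) {
    n <- sizes[[g]]
    data.frame(subject_id = sprintf("%s_%02d", g, seq_len(n)),
               group = g, sex = rep_len(c("M", "F"), n),
               stringsAsFactors = FALSE)
  }))
  subjects$seed <- config$seed * 131L + seq_len(nrow(subjects))
  design <- group_design(subjects)
  transforms <- stats::setNames(
    replicate(nrow(subjects), affine_transform(), simplify = FALSE),
    subjects$subject_id)
  list(subjects = subjects, design = design, transforms = transforms)
}

write_manifest <- function(config, command, artifacts, out) {
  path <- file.path(out, "manifest.json")
  jsonlite::write_json(
    list(package = "phbold",
         version = as.character(utils::packageVersion("phbold")),
         command = command, seed = config$seed, profile = config$profile,
         parameters = unclass(config), artifacts = artifacts),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  path
}
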