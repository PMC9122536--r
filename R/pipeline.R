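#' Analysis parameters for the thalamo-cortical pipeline
#'
#' All thresholds, counts and toggles of the analysis, with the motivating
#' design's values as defaults: FD > 0.2 mm and DVARS > 0.38% censoring, 20
#' ICA components, FDR-adjusted p < 0.05.
#'
#' @param fd_thresh,dvars_thresh censoring thresholds (mm, % signal change).
#' @param rotation_radius_mm rotation-to-displacement radius for FD.
#' @param extend_before,extend_after censor-flag extension (frames).
#' @param min_frames_frac minimum fraction of frames that must survive
#'   censoring.
#' @param n_components ICA component count.
#' @param min_match_r minimum |spatial r| to accept a template match.
#' @param alpha FDR significance level.
#' @param clip Fisher-z clipping constant.
#' @param flip flip right-lesion subjects along the midsagittal plane?
#' @param include_thalamus keep thalamus voxels among the brain columns of
#'   the seed maps?
#' @param betas_on `"selected"` (regress seed maps on the matched networks
#'   only, the default) or `"all"` (all ICA components; betas are then
#'   subset to the matched ones).
#' @param fdr_family `"per_network"` or `"global"`.
#' @param seed seed for the ICA.
#' @param exclude_subjects subject ids for a sensitivity rerun.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(fd_thresh = 0.2, dvars_thresh = 0.38,
                            rotation_radius_mm = 50,
                            extend_before = 0L, extend_after = 0L,
                            min_frames_frac = 0.5,
                            n_components = 20L, min_match_r = 0.3,
                            alpha = 0.05, clip = 1e-7,
                            flip = TRUE, include_thalamus = FALSE,
                            betas_on = c("selected", "all"),
                            fdr_family = c("per_network", "global"),
                            seed = 1L, exclude_subjects = character(0)) {
  betas_on <- match.arg(betas_on)
  fdr_family <- match.arg(fdr_family)
  stopifnot(fd_thresh > 0, dvars_thresh > 0, rotation_radius_mm > 0,
            min_frames_frac > 0, min_frames_frac <= 1,
            n_components >= 1, min_match_r >= 0, min_match_r <= 1,
            alpha > 0, alpha < 1, clip > 0, clip < 1)
  structure(list(fd_thresh = fd_thresh, dvars_thresh = dvars_thresh,
                 rotation_radius_mm = rotation_radius_mm,
                 extend_before = as.integer(extend_before),
                 extend_after = as.integer(extend_after),
                 min_frames_frac = min_frames_frac,
                 n_components = as.integer(n_components),
                 min_match_r = min_match_r, alpha = alpha, clip = clip,
                 flip = flip, include_thalamus = include_thalamus,
                 betas_on = betas_on, fdr_family = fdr_family,
                 seed = as.integer(seed),
                 exclude_subjects = exclude_subjects),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Unknown keys are rejected; values override [pipeline_config()] defaults.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop_thalcor("unknown config keys: ", paste(unknown, collapse = ", "),
                 class = "thalcor_validation_error")
  if ("exclude_subjects" %in% names(vals))
    vals$exclude_subjects <- as.character(unlist(vals$exclude_subjects))
  do.call(pipeline_config, vals)
}

## Per-subject preprocessing: flip, mode-1000, motion QC, lesion masking,
## 27-regressor residualization, seed-map stack on the common brain mask.
process_subject <- function(run, motion, lesion, lesion_side, geometry,
                            params, subject, apply_lesion = TRUE) {
  if (params$flip && identical(lesion_side, "right")) {
    run <- flip_array(run)
    lesion <- flip_array(lesion)
  }
  run <- mode1000_normalize(run)
  fd <- framewise_displacement(motion, params$rotation_radius_mm)
  dv <- dvars(run, geometry$brain_mask)
  censor <- build_censor_mask(fd, dv, params$fd_thresh, params$dvars_thresh,
                              params$extend_before, params$extend_after,
                              min_frames = ceiling(params$min_frames_frac *
                                                     length(fd)),
                              subject = subject)
  if (apply_lesion && any(lesion)) run <- apply_lesion_mask(run, lesion)
  tis <- tissue_signals(run, geometry$csf_mask, geometry$wm_mask)
  nuis <- build_nuisance(motion, tis)
  run <- residualize(run, nuis, censor)
  stack <- seed_correlation_stack(run, geometry$thal_mask,
                                  include_thalamus = params$include_thalamus,
                                  brain_mask = geometry$brain_mask,
                                  drop_invalid_seeds = FALSE,
                                  subject = subject)
  list(stack = stack, censor = censor, fd = fd, dvars = dv,
       n_valid = sum(run$mask))
}

#' Run the full thalamo-cortical analysis on a simulated (or loaded) cohort
#'
#' Executes, per subject: midsagittal flipping of right-lesion patients,
#' mode-1000 normalization, FD/DVARS censoring, lesion masking, 27-regressor
#' nuisance residualization and per-thalamic-voxel seed correlation maps;
#' then concatenates all subjects' Fisher-z maps, decomposes them with group
#' spatial ICA, labels components against the template network maps,
#' computes per-voxel network betas per subject, and derives the group
#' statistics: one-sample t maps, the paired patient-control difference map,
#' and brain-behaviour regressions (age and lesion size as covariates) per
#' cognitive score.
#'
#' @param cohort a [simulate_cohort()] / [read_cohort()] result.
#' @param params a [pipeline_config()].
#' @param templates brain-voxels x L labelled template maps; defaults to the
#'   cohort's true network maps restricted to the analysis columns.
#' @param apply_lesions integrate the lesion masks (default TRUE)?
#' @param subjects optional subject-id subset to analyse.
#' @param scores phenotype score columns for the brain-behaviour maps;
#'   default: the z-scored versions of all raw scores.
#' @return object of class `tc_result`: censor summaries, `components`,
#'   `betas` (named list of beta maps), `one_sample`, `paired`, `behavior`
#'   (list of stat maps), `clusters`, and bookkeeping.
#' @export
analyze_cohort <- function(cohort, params = pipeline_config(),
                           templates = NULL, apply_lesions = TRUE,
                           subjects = NULL, scores = NULL) {
  geometry <- cohort$geometry
  ph <- validate_phenotypes(cohort$subjects)
  ids <- subjects %||% setdiff(ph$subject_id, params$exclude_subjects)
  ph <- ph[ph$subject_id %in% ids, , drop = FALSE]
  ids <- ph$subject_id

  proc <- lapply(ids, function(id) {
    i <- match(id, names(cohort$runs))
    process_subject(cohort$runs[[id]], cohort$motion[[id]],
                    cohort$lesions[[id]],
                    ph$lesion_side[match(id, ph$subject_id)],
                    geometry, params, subject = id,
                    apply_lesion = apply_lesions)
  })
  names(proc) <- ids
  stacks <- lapply(proc, `[[`, "stack")
  group <- concatenate_group(stacks)

  n_comp <- min(params$n_components, nrow(group$z))
  ## the fixed-point iteration can oscillate when a component is noise-
  ## dominated; retry with deterministically shifted seeds before giving up
  comps <- NULL
  for (attempt in 0:2) {
    comps <- tryCatch(
      decompose_ica(group, n_components = n_comp,
                    seed = params$seed + attempt),
      thalcor_convergence_error = function(e) NULL)
    if (!is.null(comps)) break
  }
  if (is.null(comps))
    comps <- decompose_ica(group, n_components = n_comp,
                           seed = params$seed + 3L)
  if (is.null(templates)) {
    templates <- geometry$map_matrix
    if (params$include_thalamus) {
      sel <- geometry$brain_mask
      templates <- do.call(cbind, lapply(cohort$geometry$maps,
                                         function(m) m[sel]))
      colnames(templates) <- colnames(geometry$map_matrix)
    }
  }
  labelled <- match_components(comps, templates,
                               min_match_r = params$min_match_r)
  beta_source <- if (params$betas_on == "selected") labelled else comps
  betas <- lapply(ids, function(id) {
    b <- voxel_network_betas(stacks[[id]], beta_source)
    if (params$betas_on == "all") {
      sel <- match(labelled$labels, colnames(b))
      b <- structure(unclass(b)[, sel, drop = FALSE],
                     class = class(b), subject = id)
      colnames(b) <- labelled$labels
    }
    b
  })
  names(betas) <- ids

  thal_coords <- stacks[[1]]$thal_coords
  pat <- ph$subject_id[ph$group == "patient"]
  con <- ph$subject_id[ph$group == "control"]
  one_sample <- NULL
  if (length(ids) >= 3) {
    one_sample <- one_sample_tmap(betas, alpha = params$alpha,
                                  fdr_family = params$fdr_family)
    one_sample$thal_coords <- thal_coords
  }
  paired <- NULL
  pairing <- phenotype_pairing(ph)
  if (nrow(pairing) >= 2) {
    paired <- paired_difference_map(betas[pat], betas[con],
                                    pairing = pairing, alpha = params$alpha,
                                    fdr_family = params$fdr_family)
    paired$thal_coords <- thal_coords
  }
  score_cols <- scores %||% sub("_raw$", "_z",
                                grep("^score_.*_raw$", names(ph), value = TRUE))
  behavior <- list()
  if (length(pat) >= 6) {
    for (sc in score_cols) {
      bb <- brain_behavior_map(betas[pat], ph, sc, alpha = params$alpha,
                               fdr_family = params$fdr_family)
      bb$thal_coords <- thal_coords
      behavior[[sc]] <- bb
    }
  }
  clusters <- if (!is.null(paired))
    summarize_clusters(paired, geometry$subdiv_labels) else NULL
  censor_summary <- data.frame(
    subject = ids,
    n_fd = vapply(proc, function(p) p$censor$n_fd, integer(1)),
    n_dvars = vapply(proc, function(p) p$censor$n_dvars, integer(1)),
    n_flagged = vapply(proc, function(p) p$censor$n_flagged, integer(1)),
    n_kept = vapply(proc, function(p) p$censor$n_kept, integer(1)),
    n_valid_voxels = vapply(proc, function(p) p$n_valid, integer(1)),
    row.names = NULL)
  structure(list(params = params, subjects = ph, censor = censor_summary,
                 components = labelled, betas = betas,
                 one_sample = one_sample, paired = paired,
                 behavior = behavior, clusters = clusters,
                 thal_coords = thal_coords,
                 provenance = group$provenance),
            class = "tc_result")
}

#' @export
print.tc_result <- function(x, ...) {
  cat("<tc_result> ", nrow(x$subjects), " subjects, ",
      length(x$components$labels), " labelled networks (",
      paste(x$components$labels, collapse = ", "), ")\n", sep = "")
  if (!is.null(x$paired)) {
    cat("paired patient-control difference map:\n")
    print(x$paired)
  }
  invisible(x)
}

#' Lesion-mask control analysis on healthy controls
#'
#' Applies each patient's lesion mask to the matched healthy control and
#' reruns the full seed-map to beta pipeline on the controls twice, with and
#' without the lesion masks, returning the paired difference map. Under a
#' correct lesion-masking implementation no systematic difference is
#' expected.
#'
#' @param cohort a cohort object.
#' @param params a [pipeline_config()].
#' @return list with `statmap` (paired difference), and the two `tc_result`
#'   objects `with_lesion` and `without_lesion`.
#' @export
lesion_mask_control <- function(cohort, params = pipeline_config()) {
  ph <- validate_phenotypes(cohort$subjects)
  pairing <- phenotype_pairing(ph)
  con <- pairing$control
  ## controls inherit their matched patient's lesion mask (and side, so the
  ## same subjects are flipped in both runs)
  lesioned <- cohort
  for (i in seq_len(nrow(pairing))) {
    lesioned$lesions[[pairing$control[i]]] <-
      cohort$lesions[[pairing$patient[i]]]
    lesioned$subjects$lesion_side[
      lesioned$subjects$subject_id == pairing$control[i]] <-
      ph$lesion_side[ph$subject_id == pairing$patient[i]]
  }
  cohort$subjects$lesion_side[cohort$subjects$group == "control"] <-
    lesioned$subjects$lesion_side[lesioned$subjects$group == "control"]
  without <- analyze_cohort(cohort, params, subjects = con)
  with_les <- analyze_cohort(lesioned, params, subjects = con)
  common <- intersect(colnames(with_les$betas[[1]]),
                      colnames(without$betas[[1]]))
  sub_cols <- function(lst) lapply(lst, function(b)
    structure(unclass(b)[, common, drop = FALSE], class = class(b)))
  statmap <- paired_difference_map(sub_cols(with_les$betas),
                                   sub_cols(without$betas),
                                   pairing = data.frame(patient = con,
                                                        control = con),
                                   alpha = params$alpha,
                                   fdr_family = params$fdr_family)
  statmap$thal_coords <- with_les$thal_coords
  list(statmap = statmap, with_lesion = with_les, without_lesion = without)
}

#' Sensitivity rerun excluding listed subjects
#'
#' Re-executes the group analysis without the listed subjects (for example
#' patients with thalamic infarcts) and compares the FDR-flagged voxel sets
#' of the paired difference maps between the main and subset runs.
#'
#' @param cohort a cohort object.
#' @param params a [pipeline_config()].
#' @param exclude subject ids to drop (their matched partners are dropped
#'   too, preserving the paired design).
#' @param main optional precomputed main-run `tc_result`.
#' @return list with `main`, `subset`, and `comparison` (per-network Jaccard
#'   overlap of flagged voxels).
#' @export
subset_rerun <- function(cohort, params = pipeline_config(),
                         exclude = character(0), main = NULL) {
  ph <- validate_phenotypes(cohort$subjects)
  if (length(exclude)) {
    bad_pairs <- ph$pair_id[ph$subject_id %in% exclude]
    drop_ids <- ph$subject_id[ph$pair_id %in% bad_pairs]
  } else drop_ids <- character(0)
  keep <- setdiff(ph$subject_id, drop_ids)
  n_pat <- sum(ph$group[ph$subject_id %in% keep] == "patient")
  n_con <- sum(ph$group[ph$subject_id %in% keep] == "control")
  if (length(drop_ids) && (n_pat < 3 || n_con < 3))
    stop_thalcor("subset leaves fewer than 3 subjects per group",
                 class = "thalcor_validation_error")
  main <- main %||% analyze_cohort(cohort, params)
  subset <- analyze_cohort(cohort, params, subjects = keep)
  comparison <- NULL
  if (!is.null(main$paired) && !is.null(subset$paired)) {
    nets <- intersect(colnames(main$paired$flag), colnames(subset$paired$flag))
    comparison <- data.frame(network = nets, jaccard = vapply(nets, function(nw) {
      a <- main$paired$flag[, nw]; b <- subset$paired$flag[, nw]
      if (!any(a | b)) return(1)
      sum(a & b) / sum(a | b)
    }, numeric(1)), row.names = NULL)
  }
  list(main = main, subset = subset, comparison = comparison)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir cohort directory.
#' @return a cohort object as produced by [simulate_cohort()] (without the
#'   ground-truth element).
#' @export
read_cohort <- function(dir) {
  need <- file.path(dir, c("mask_brain.nii.gz", "mask_thalamus.nii.gz",
                           "phenotypes.tsv"))
  if (!all(file.exists(need)))
    stop_thalcor("not a cohort directory: ", dir, class = "thalcor_io_error")
  brain <- read_volume(file.path(dir, "mask_brain.nii.gz"), mask = TRUE)
  thal <- read_volume(file.path(dir, "mask_thalamus.nii.gz"), mask = TRUE)
  subdiv <- read_volume(file.path(dir, "labels_subdivisions.nii.gz"))
  csf <- read_volume(file.path(dir, "mask_csf.nii.gz"), mask = TRUE)
  wm <- read_volume(file.path(dir, "mask_wm.nii.gz"), mask = TRUE)
  tmpl_files <- sort(list.files(dir, "^template_network", full.names = TRUE))
  maps <- lapply(tmpl_files, read_volume)
  ph <- read_phenotypes(file.path(dir, "phenotypes.tsv"))
  sel <- brain & !thal
  map_matrix <- if (length(maps))
    do.call(cbind, lapply(maps, function(m) m[sel])) else NULL
  if (!is.null(map_matrix))
    colnames(map_matrix) <- paste0("network", seq_along(maps))
  geometry <- list(maps = maps, brain_mask = brain, thal_mask = thal,
                   subdiv_labels = array(as.integer(round(subdiv)),
                                         dim = dim(subdiv)),
                   csf_mask = csf, wm_mask = wm, map_matrix = map_matrix)
  ids <- ph$subject_id
  runs <- motion <- lesions <- stats::setNames(vector("list", length(ids)), ids)
  for (id in ids) {
    arr <- read_volume(file.path(dir, paste0("sub-", id, "_bold.nii.gz")))
    tr <- attr(arr, "tr") %||% 1
    runs[[id]] <- bold_run(array(arr, dim = dim(arr)), brain,
                           voxel_size = attr(arr, "voxel_size")[1:3], tr = tr)
    motion[[id]] <- read_motion_table(file.path(dir,
                                                paste0("sub-", id, "_motion.txt")))
    lf <- file.path(dir, paste0("sub-", id, "_lesion.nii.gz"))
    lesions[[id]] <- if (file.exists(lf)) read_volume(lf, mask = TRUE)
    else array(FALSE, dim = dim(brain))
  }
  structure(list(config = NULL, geometry = geometry, truth = NULL,
                 subjects = as.data.frame(ph), runs = runs, motion = motion,
                 lesions = lesions),
            class = "sim_cohort")
}

#' Run the end-to-end pipeline on a cohort directory
#'
#' Loads the cohort, executes the analysis and writes results (beta TSV,
#' stat-map TSVs, cluster table, censor summary) plus a manifest recording
#' input checksums, parameters and seeds to `out_dir`. Rerunning with an
#' identical configuration reproduces identical outputs.
#'
#' @param cohort_dir cohort directory (see [write_cohort()]).
#' @param out_dir output directory.
#' @param params a [pipeline_config()].
#' @return the `tc_result`, invisibly.
#' @export
run_pipeline <- function(cohort_dir, out_dir, params = pipeline_config()) {
  cohort <- read_cohort(cohort_dir)
  res <- analyze_cohort(cohort, params)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  beta_tall <- do.call(rbind, lapply(names(res$betas), function(id) {
    b <- res$betas[[id]]
    data.frame(subject = id, voxel = rep(seq_len(nrow(b)), ncol(b)),
               network = rep(colnames(b), each = nrow(b)),
               beta = as.vector(unclass(b)))
  }))
  utils::write.table(beta_tall, file.path(out_dir, "betas.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  write_stat_map <- function(sm, name) {
    df <- do.call(rbind, lapply(colnames(sm$t), function(nw) {
      data.frame(network = nw, voxel = seq_len(nrow(sm$t)),
                 t = sm$t[, nw], p = sm$p[, nw], q = sm$q[, nw],
                 flag = sm$flag[, nw])
    }))
    utils::write.table(df, file.path(out_dir, paste0(name, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  write_stat_map(res$one_sample, "one_sample")
  if (!is.null(res$paired)) write_stat_map(res$paired, "paired_difference")
  for (sc in names(res$behavior))
    write_stat_map(res$behavior[[sc]], paste0("behavior_", sc))
  if (!is.null(res$clusters))
    utils::write.table(res$clusters, file.path(out_dir, "clusters.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(res$censor, file.path(out_dir, "censor_summary.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("thalcor")),
    params = unclass(params),
    inputs = as.list(tools::md5sum(sort(list.files(cohort_dir,
                                                   full.names = TRUE)))),
    networks = res$components$labels)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(res)
}
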