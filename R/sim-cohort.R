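## Ground-truth cohort simulator.
##
## Geometry: an ellipsoidal brain on the grid; a central thalamus block
## partitioned into contiguous subdivision slabs along y; K bilateral
## (mirror-symmetric) cortical network blobs on a ring around the midline;
## small CSF and white-matter boxes. Signal: each network has a unit-variance
## AR(1) time course; cortical voxels mix all networks through the spatial
## maps, thalamic voxels follow their subdivision's network scaled by the
## subject's coupling. Patients get per-subdivision coupling factors (< 1
## hypo, > 1 hyper) and a unilateral ellipsoidal lesion whose voxels carry
## pure noise. Scheduled motion spikes add a step to the motion trace and an
## in-brain intensity step, so FD and DVARS flag exactly the spike frames.

#' Generate the cortical network maps and cohort geometry
#'
#' Lays out `n_networks` non-negative, spatially disjoint bilateral Gaussian
#' blob maps plus the brain ellipsoid, the central thalamus block with its
#' subdivision labels, and CSF / white-matter boxes. Raises a sizing error if
#' the grid cannot hold the requested structures without overlap.
#'
#' @param config a [sim_config()].
#' @return list with `maps` (list of K 3-D arrays, peak value 1),
#'   `brain_mask`, `thal_mask`, `subdiv_labels` (integer 3-D array, 0 outside
#'   the thalamus), `csf_mask`, `wm_mask`, and `map_matrix` (brain voxels x K).
#' @export
make_network_maps <- function(config) {
  g <- config$grid
  mid <- (g + 1) / 2
  r_brain <- 0.42 * g
  ax <- seq_len(g[1]); ay <- seq_len(g[2]); az <- seq_len(g[3])
  dx2 <- ((ax - mid[1]) / r_brain[1])^2
  dy2 <- ((ay - mid[2]) / r_brain[2])^2
  dz2 <- ((az - mid[3]) / r_brain[3])^2
  brain <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= 1

  ## thalamus: central block, subdivisions = contiguous slabs along y
  half <- config$thal_dim / 2
  tx <- abs(ax - mid[1]) <= half[1] - 0.5 + 1e-9
  ty <- abs(ay - mid[2]) <= half[2] - 0.5 + 1e-9
  tz <- abs(az - mid[3]) <= half[3] - 0.5 + 1e-9
  thal <- outer(outer(tx, ty, `&`), tz, `&`)
  if (!all(thal <= brain))
    stop_thalcor("thalamus block extends outside the brain",
                 class = "thalcor_sizing_error")
  subdiv <- array(0L, dim = g)
  ys <- which(ty)
  slab <- if (config$n_subdiv == 1L) rep(1L, length(ys)) else
    as.integer(cut(seq_along(ys), breaks = config$n_subdiv))
  for (i in seq_along(ys)) {
    sl <- thal[, ys[i], , drop = FALSE]
    tmp <- subdiv[, ys[i], , drop = FALSE]
    tmp[sl] <- slab[i]
    subdiv[, ys[i], ] <- tmp
  }

  ## tissue boxes, mirror-symmetric about the midline
  csf <- box_mask(g, mid + c(half[1] + 3, 0, 0), c(1, 1, 1)) |
    box_mask(g, mid - c(half[1] + 3, 0, 0), c(1, 1, 1))
  wm <- box_mask(g, mid + c(0, 0, half[3] + 3), c(1, 1, 1)) |
    box_mask(g, mid - c(0, 0, half[3] + 3), c(1, 1, 1))

  ## bilateral network blobs on a ring in the (y, z) plane at x = +-dx
  k <- config$n_networks
  sigma <- 0.08 * min(g)
  cutoff <- 1.75 * sigma
  dxoff <- 0.5 * r_brain[1]
  ring <- c(0.6 * r_brain[2], 0.6 * r_brain[3])
  theta <- 2 * pi * (seq_len(k) - 1) / max(k, 1) + pi / (2 * max(k, 1))
  centers <- lapply(seq_len(k), function(j) {
    yz <- c(ring[1] * cos(theta[j]), ring[2] * sin(theta[j]))
    list(pos = mid + c(dxoff, yz), neg = mid + c(-dxoff, yz))
  })
  maps <- vector("list", k)
  supports <- vector("list", k)
  for (j in seq_len(k)) {
    m <- gauss_blob(g, centers[[j]]$pos, sigma, cutoff) +
      gauss_blob(g, centers[[j]]$neg, sigma, cutoff)
    m[!brain] <- 0
    if (!any(m > 0))
      stop_thalcor("network blob ", j, " falls outside the brain; grid too small",
                   class = "thalcor_sizing_error")
    maps[[j]] <- m / max(m)
    supports[[j]] <- maps[[j]] > 0
  }
  for (j in seq_len(k)) {
    if (any(supports[[j]] & (thal | csf | wm)))
      stop_thalcor("network blob ", j, " overlaps the thalamus or tissue boxes; ",
                   "grid too small for ", k, " networks",
                   class = "thalcor_sizing_error")
    for (l in seq_len(k)) {
      if (l <= j) next
      if (any(supports[[j]] & supports[[l]]))
        stop_thalcor("network blobs ", j, " and ", l, " overlap; grid too small ",
                     "for ", k, " networks", class = "thalcor_sizing_error")
    }
  }
  map_matrix <- do.call(cbind, lapply(maps, function(m) m[brain & !thal]))
  colnames(map_matrix) <- paste0("network", seq_len(k))
  list(maps = maps, brain_mask = brain, thal_mask = thal,
       subdiv_labels = subdiv, csf_mask = csf, wm_mask = wm,
       map_matrix = map_matrix)
}

box_mask <- function(g, center, half) {
  ax <- abs(seq_len(g[1]) - center[1]) <= half[1] + 1e-9
  ay <- abs(seq_len(g[2]) - center[2]) <= half[2] + 1e-9
  az <- abs(seq_len(g[3]) - center[3]) <= half[3] + 1e-9
  outer(outer(ax, ay, `&`), az, `&`)
}

gauss_blob <- function(g, center, sigma, cutoff) {
  dx2 <- (seq_len(g[1]) - center[1])^2
  dy2 <- (seq_len(g[2]) - center[2])^2
  dz2 <- (seq_len(g[3]) - center[3])^2
  d2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
  out <- exp(-d2 / (2 * sigma^2))
  out[d2 > cutoff^2] <- 0
  out
}

ellipsoid_mask <- function(g, center, radii) {
  dx2 <- ((seq_len(g[1]) - center[1]) / radii[1])^2
  dy2 <- ((seq_len(g[2]) - center[2]) / radii[2])^2
  dz2 <- ((seq_len(g[3]) - center[3]) / radii[3])^2
  outer(outer(dx2, dy2, `+`), dz2, `+`) <= 1
}

## Draw every random ground-truth quantity of the cohort from the master
## seed: subject ids and pairing, ages/sex, per-subject couplings, spike
## frames, lesion geometry, behaviour scores, and per-subject run seeds.
make_truth <- function(config, geometry) {
  set.seed(config$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  np <- config$n_patients; nc <- config$n_controls
  n_pairs <- min(np, nc)
  pat_ids <- sprintf("P%02d", seq_len(np))
  con_ids <- sprintf("C%02d", seq_len(nc))
  ids <- c(pat_ids, con_ids)
  group <- c(rep("patient", np), rep("control", nc))
  pair_id <- c(sprintf("pair%02d", seq_len(np)), sprintf("pair%02d", seq_len(nc)))
  pair_age <- round(stats::runif(max(np, nc), 6, 22), 1)
  age <- c(pair_age[seq_len(np)], pair_age[seq_len(nc)])
  pair_sex <- rep(c("M", "F"), length.out = max(np, nc))
  sex <- c(pair_sex[seq_len(np)], pair_sex[seq_len(nc)])
  ns <- config$n_subdiv
  coupling <- matrix(NA_real_, np + nc, ns,
                     dimnames = list(ids, paste0("subdiv", seq_len(ns))))
  for (i in seq_len(np + nc)) {
    base <- 1 + stats::rnorm(ns, 0, config$coupling_sd)
    if (group[i] == "patient") base <- base * config$patient_factors
    coupling[i, ] <- pmax(base, 0.05)
  }
  spike_frames <- lapply(seq_len(np + nc), function(i) {
    nsp <- config$spikes$n_per_subject
    if (nsp < 1) return(integer(0))
    sort(sample(seq(5L, config$frames - 4L), nsp))
  })
  names(spike_frames) <- ids
  n_right <- round(config$lesion$right_fraction * np)
  side <- c(rep("right", n_right), rep("left", np - n_right))
  side <- sample(side)
  g <- config$grid; mid <- (g + 1) / 2; rb <- 0.42 * g
  lesion_centers <- t(vapply(seq_len(np), function(i) {
    sgn <- if (side[i] == "right") 1 else -1
    c(mid[1] + sgn * stats::runif(1, 0.4, 0.55) * rb[1],
      mid[2] + stats::runif(1, -0.25, 0.25) * rb[2],
      mid[3] + stats::runif(1, -0.25, 0.25) * rb[3])
  }, numeric(3)))
  scores <- list()
  for (sc in names(config$behaviour)) {
    b <- config$behaviour[[sc]]
    mc <- rowMeans(coupling[, b$subdivisions, drop = FALSE])
    scores[[sc]] <- b$intercept + b$slope * mc +
      stats::rnorm(np + nc, 0, b$noise_sd)
  }
  subject_seeds <- sample.int(2^31 - 2, np + nc)
  list(ids = ids, group = group, pair_id = pair_id, age = age, sex = sex,
       coupling = coupling, spike_frames = spike_frames,
       lesion_side = side, lesion_centers = lesion_centers,
       scores = scores, behaviour = config$behaviour,
       subject_seeds = subject_seeds, seed = config$seed)
}

#' Simulate one subject's BOLD run and motion trace
#'
#' Voxel time series follow
#' `baseline(v) + amplitude * sum_k map_k(v) a_k(t) c(subject, subdiv(v)) + noise`
#' with AR(1) network time courses `a_k`. Scheduled spike frames add a motion
#' step and an in-brain intensity step; patient lesion voxels carry pure
#' noise and are recorded in the returned lesion mask.
#'
#' @param config a [sim_config()].
#' @param subject_index index into the cohort truth.
#' @param group `"patient"` or `"control"`.
#' @param truth the cohort ground truth (from [simulate_cohort()]).
#' @param geometry result of [make_network_maps()] (recomputed if NULL).
#' @return list with `run` (a [bold_run()]), `motion` (frames x 6),
#'   `lesion_mask` (3-D logical), `timecourses` (frames x K), `spike_frames`.
#' @export
make_subject_run <- function(config, subject_index, group, truth,
                             geometry = NULL) {
  if (!group %in% c("patient", "control"))
    stop_thalcor("group must be 'patient' or 'control', got '", group, "'",
                 class = "thalcor_validation_error")
  geometry <- geometry %||% make_network_maps(config)
  set.seed(truth$subject_seeds[subject_index],
           kind = "Mersenne-Twister", normal.kind = "Inversion")
  g <- config$grid; nt <- config$frames; k <- config$n_networks
  phi <- config$ar_coef
  a <- matrix(0, nt, k)
  a[1, ] <- stats::rnorm(k)
  innov_sd <- sqrt(1 - phi^2)
  for (t in 2:nt) a[t, ] <- phi * a[t - 1, ] + stats::rnorm(k, 0, innov_sd)

  brain <- geometry$brain_mask
  thal <- geometry$thal_mask
  nvox <- prod(g)
  ## baseline with a mild z gradient so mode-1000 scaling is nontrivial
  zgrad <- rep(seq(-0.05, 0.05, length.out = g[3]), each = g[1] * g[2])
  baseline_v <- config$baseline * (1 + zgrad)

  flat <- matrix(0, nvox, nt)
  bidx <- which(brain & !thal)
  tidx <- which(thal)
  mapm <- do.call(cbind, lapply(geometry$maps, function(m) m[bidx]))
  flat[bidx, ] <- baseline_v[bidx] +
    config$amplitude * tcrossprod(mapm, a) +
    stats::rnorm(length(bidx) * nt, 0, config$noise_sd)
  subdiv_of <- geometry$subdiv_labels[tidx]
  coup <- truth$coupling[subject_index, subdiv_of]
  net_of <- config$subdiv_networks[subdiv_of]
  flat[tidx, ] <- baseline_v[tidx] +
    config$amplitude * (coup * t(a)[net_of, , drop = FALSE]) +
    stats::rnorm(length(tidx) * nt, 0, config$noise_sd)

  lesion <- array(FALSE, dim = g)
  if (group == "patient") {
    lesion <- ellipsoid_mask(g, truth$lesion_centers[subject_index, ],
                             config$lesion$radii) & brain
    lidx <- which(lesion)
    flat[lidx, ] <- baseline_v[lidx] +
      stats::rnorm(length(lidx) * nt, 0, config$noise_sd)
  }

  ## motion: slow random walk plus step excursions at spike frames
  motion <- apply(matrix(stats::rnorm(nt * 6, 0,
                                      rep(c(5e-3, 5e-5), each = 3 * nt)),
                         nt, 6), 2, cumsum)
  spikes <- truth$spike_frames[[subject_index]]
  for (f in spikes) {
    motion[f:nt, 1] <- motion[f:nt, 1] + config$spikes$translation_mm
    jump <- config$spikes$intensity_pct / 100 * config$baseline
    flat[which(brain), f:nt] <- flat[which(brain), f:nt] + jump
  }
  colnames(motion) <- c("tx", "ty", "tz", "pitch", "yaw", "roll")

  run <- bold_run(array(flat, dim = c(g, nt)), mask = brain,
                  voxel_size = c(3, 3, 3), tr = config$tr)
  list(run = run, motion = motion, lesion_mask = lesion,
       timecourses = a, spike_frames = spikes)
}

#' Simulate a full two-group matched cohort
#'
#' Builds the cohort geometry and ground truth, generates every subject's
#' run, motion trace and (for patients) lesion mask, assembles the phenotype
#' table (raw and z-scaled cognitive scores, pair ids linking each patient to
#' one control), and optionally writes everything to a cohort directory
#' (NIfTI runs and masks, whitespace motion tables, phenotype TSV, JSON truth
#' report).
#'
#' @param config a [sim_config()].
#' @param dir optional output directory.
#' @return object of class `sim_cohort`: list with `config`, `geometry`,
#'   `truth`, `subjects` (phenotype data.frame), `runs`, `motion`, `lesions`.
#' @export
simulate_cohort <- function(config, dir = NULL) {
  geometry <- make_network_maps(config)
  truth <- make_truth(config, geometry)
  n <- length(truth$ids)
  runs <- motion <- lesions <- stats::setNames(vector("list", n), truth$ids)
  for (i in seq_len(n)) {
    sub <- make_subject_run(config, i, truth$group[i], truth, geometry)
    runs[[i]] <- sub$run
    motion[[i]] <- sub$motion
    lesions[[i]] <- sub$lesion_mask
  }
  lesion_frac <- vapply(seq_len(n), function(i)
    if (truth$group[i] == "patient")
      sum(lesions[[i]]) / sum(geometry$brain_mask) else 0, numeric(1))
  ph <- data.frame(subject_id = truth$ids, group = truth$group,
                   pair_id = truth$pair_id, age = truth$age, sex = truth$sex,
                   lesion_side = ifelse(truth$group == "patient",
                                        truth$lesion_side[pmin(seq_len(n), config$n_patients)],
                                        "none"),
                   lesion_frac = round(lesion_frac, 6))
  for (sc in names(truth$scores))
    ph[[paste0("score_", sc, "_raw")]] <- round(truth$scores[[sc]], 4)
  for (sc in names(truth$scores)) {
    raw <- ph[[paste0("score_", sc, "_raw")]]
    ph[[paste0("score_", sc, "_scaled")]] <-
      round((raw - mean(raw)) / stats::sd(raw), 4)
  }
  cohort <- structure(list(config = config, geometry = geometry,
                           truth = truth, subjects = ph, runs = runs,
                           motion = motion, lesions = lesions),
                      class = "sim_cohort")
  if (!is.null(dir)) write_cohort(cohort, dir)
  cohort
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("<sim_cohort> ", x$config$n_patients, " patients + ",
      x$config$n_controls, " controls, ",
      paste(x$config$grid, collapse = "x"), " grid, ", x$config$frames,
      " frames, seed ", x$config$seed, "\n", sep = "")
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' NIfTI-1 runs and masks, 6-column whitespace motion tables, a phenotype
#' TSV, and a JSON truth report.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(dir, 2) != 0)
    stop_thalcor("cannot write to directory ", dir, class = "thalcor_io_error")
  cfg <- cohort$config
  geom <- cohort$geometry
  write_volume(geom$brain_mask, file.path(dir, "mask_brain.nii.gz"))
  write_volume(geom$thal_mask, file.path(dir, "mask_thalamus.nii.gz"))
  write_volume(geom$subdiv_labels, file.path(dir, "labels_subdivisions.nii.gz"))
  write_volume(geom$csf_mask, file.path(dir, "mask_csf.nii.gz"))
  write_volume(geom$wm_mask, file.path(dir, "mask_wm.nii.gz"))
  for (j in seq_along(geom$maps))
    write_volume(geom$maps[[j]],
                 file.path(dir, sprintf("template_network%02d.nii.gz", j)))
  for (id in names(cohort$runs)) {
    write_volume(cohort$runs[[id]]$data,
                 file.path(dir, paste0("sub-", id, "_bold.nii.gz")),
                 tr = cfg$tr)
    utils::write.table(format(cohort$motion[[id]], digits = 10),
                       file.path(dir, paste0("sub-", id, "_motion.txt")),
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
    if (any(cohort$lesions[[id]]))
      write_volume(cohort$lesions[[id]],
                   file.path(dir, paste0("sub-", id, "_lesion.nii.gz")))
  }
  utils::write.table(cohort$subjects, file.path(dir, "phenotypes.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  truth_out <- cohort$truth
  truth_out$coupling <- as.data.frame(truth_out$coupling)
  truth_out$lesion_centers <- as.data.frame(truth_out$lesion_centers)
  jsonlite::write_json(truth_out, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Write pinned test fixture cohorts
#'
#' `tiny` = 2+2 subjects on a 16^3 x 60 grid; `small` = 10+10 subjects on a
#' 24x28x24 x 200 grid. Regenerating with the same seed reproduces identical
#' files; MD5 checksums are returned for pinning.
#'
#' @param scale `"tiny"` or `"small"`.
#' @param dir output directory.
#' @param seed master seed.
#' @return named vector of MD5 checksums of the emitted files.
#' @export
write_fixture_set <- function(scale, dir, seed = 20220428) {
  if (!scale %in% c("tiny", "small"))
    stop_thalcor("unknown fixture scale '", scale, "'",
                 class = "thalcor_validation_error")
  cfg <- sim_preset(scale, seed = seed)
  simulate_cohort(cfg, dir = dir)
  files <- sort(list.files(dir, full.names = TRUE))
  tools::md5sum(files)
}
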