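#' Configuration for the synthetic cohort generator
#'
#' Collects every knob of the ground-truth simulator: grid and run geometry,
#' the network/coupling model, noise, motion spikes, lesions, and the
#' behaviour model linking cognition to coupling strength. Defaults define a
#' two-group matched cohort with network-structured BOLD, thalamic
#' subdivisions coupled to distinct cortical networks, group-dependent
#' coupling changes in both directions, unilateral lesions, motion spikes and
#' cognition scores linearly related to coupling strength.
#'
#' @param grid x, y, z voxel counts.
#' @param frames frames per run.
#' @param tr repetition time in seconds.
#' @param n_networks number K of cortical networks; each network is a
#'   bilateral (mirror-symmetric) pair of Gaussian blobs, so midsagittal
#'   flipping leaves the true maps invariant.
#' @param thal_dim x, y, z extent of the central thalamus block.
#' @param n_subdiv number of thalamic subdivisions (contiguous slabs along
#'   y, mimicking anterior/medial/lateral/posterior nuclei groups); must not
#'   exceed `n_networks`.
#' @param subdiv_networks integer vector mapping subdivision -> network.
#' @param patient_factors per-subdivision multiplicative coupling factors for
#'   patients (values < 1 give hypo-, > 1 hyper-connectivity).
#' @param coupling_sd between-subject SD of the coupling (unitless, around a
#'   control mean of 1).
#' @param amplitude cortical network amplitude in raw intensity units.
#' @param baseline mean baseline intensity in raw units (the mode-1000 step
#'   rescales it, so it is deliberately not 1000).
#' @param noise_sd thermal noise SD in raw units; the default keeps clean
#'   frames below the DVARS censoring threshold while satisfying
#'   noise_sd <= amplitude / 2.
#' @param ar_coef temporal autocorrelation of the AR(1) network time courses.
#' @param spikes list: `n_per_subject` motion spikes, each a step of
#'   `translation_mm` in x plus an in-brain intensity step of
#'   `intensity_pct` percent of baseline, so FD and DVARS flag the same
#'   frames.
#' @param lesion list: ellipsoid `radii` (voxels) and `right_fraction`, the
#'   fraction of patients whose lesion falls in the right hemisphere.
#' @param behaviour named list of score models, each
#'   `list(intercept, slope, noise_sd, subdivisions)`: raw score =
#'   intercept + slope * mean true coupling over the designated
#'   subdivisions + Gaussian noise.
#' @param n_patients,n_controls subjects per group.
#' @param seed master random seed; every random quantity flows from it.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(grid = c(24, 28, 24), frames = 200, tr = 0.3,
                       n_networks = 5, thal_dim = c(6, 8, 4),
                       n_subdiv = min(4, n_networks),
                       subdiv_networks = seq_len(n_subdiv),
                       patient_factors = default_factors(n_subdiv),
                       coupling_sd = 0.10,
                       amplitude = 1.2, baseline = 800, noise_sd = 1.2,
                       ar_coef = 0.3,
                       spikes = list(n_per_subject = 2, translation_mm = 0.6,
                                     intensity_pct = 2),
                       lesion = list(radii = c(2, 3, 2), right_fraction = 0.2),
                       behaviour = default_behaviour(n_subdiv),
                       n_patients = 10, n_controls = 10, seed = 1) {
  cfg <- list(grid = as.integer(grid), frames = as.integer(frames), tr = tr,
              n_networks = as.integer(n_networks),
              thal_dim = as.integer(thal_dim),
              n_subdiv = as.integer(n_subdiv),
              subdiv_networks = as.integer(subdiv_networks),
              patient_factors = patient_factors, coupling_sd = coupling_sd,
              amplitude = amplitude, baseline = baseline, noise_sd = noise_sd,
              ar_coef = ar_coef, spikes = spikes, lesion = lesion,
              behaviour = behaviour,
              n_patients = as.integer(n_patients),
              n_controls = as.integer(n_controls), seed = as.integer(seed))
  validate_sim_config(cfg)
}

default_factors <- function(n_subdiv) {
  ## hypo in the first subdivision, hyper in the third (or second if only 2),
  ## so both directions of group change are recoverable
  f <- rep(1, n_subdiv)
  f[1] <- 0.5
  if (n_subdiv >= 3) f[3] <- 1.5 else if (n_subdiv >= 2) f[2] <- 1.5
  f
}

default_behaviour <- function(n_subdiv) {
  link <- min(2, n_subdiv)
  base <- list(intercept = 10, slope = 10, noise_sd = 1.33, subdivisions = link)
  list(attention = base, wm = base, inhibition = base,
       flexibility = list(intercept = 10, slope = 0, noise_sd = 1.33,
                          subdivisions = link))
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (any(c(grid, frames, n_networks, n_subdiv, n_patients, n_controls) < 1))
      stop_thalcor("all counts must be >= 1", class = "thalcor_validation_error")
    if (n_networks < 1)
      stop_thalcor("need at least one network", class = "thalcor_validation_error")
    if (length(subdiv_networks) != n_subdiv ||
        any(subdiv_networks < 1 | subdiv_networks > n_networks))
      stop_thalcor("subdivision assignment must map each subdivision to a network",
                   class = "thalcor_validation_error")
    if (length(patient_factors) != n_subdiv || any(patient_factors < 0))
      stop_thalcor("patient coupling factors must be non-negative, one per subdivision",
                   class = "thalcor_validation_error")
    if (noise_sd <= 0)
      stop_thalcor("noise sd must be positive", class = "thalcor_validation_error")
    if (any(thal_dim >= grid))
      stop_thalcor("thalamus block does not fit in the grid",
                   class = "thalcor_sizing_error")
  })
  structure(cfg, class = "sim_config")
}

#' Preset simulation configurations
#'
#' `tiny` is a 2+2-subject cohort on a 16x16x16 grid with 60 frames, three
#' cortical networks and two coupled thalamic subdivisions; `small` is a
#' 10+10 cohort on a 24x28x24 grid with 200 frames, five cortical networks
#' and four coupled subdivisions. One cortical network is deliberately left
#' uncoupled from the thalamus in each preset, mirroring the fact that not
#' every cortical network has a strong thalamic representation.
#'
#' @param scale `"tiny"` or `"small"`.
#' @param ... overrides passed on to [sim_config()].
#' @return a `sim_config`.
#' @export
sim_preset <- function(scale = c("tiny", "small"), ...) {
  scale <- match.arg(scale)
  args <- switch(scale,
    tiny = list(grid = c(16, 16, 16), frames = 60, n_networks = 3,
                thal_dim = c(4, 4, 4), n_subdiv = 2,
                lesion = list(radii = c(1, 2, 1), right_fraction = 0.25),
                n_patients = 2, n_controls = 2),
    small = list())
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", paste(x$grid, collapse = "x"), " grid, ", x$frames,
      " frames, ", x$n_networks, " networks, ", x$n_subdiv,
      " thalamic subdivisions, ", x$n_patients, "+", x$n_controls,
      " subjects, seed ", x$seed, "\n", sep = "")
  invisible(x)
}
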