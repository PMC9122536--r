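#' Construct a BOLD run container
#'
#' Bundles a 4-D intensity array with its voxel geometry, repetition time and
#' the valid-voxel mask (brain minus lesion) that every downstream statistic
#' respects.
#'
#' @param data 4-D numeric array (x, y, z, frames).
#' @param mask logical 3-D array of valid voxels.
#' @param voxel_size numeric length-3, voxel edge lengths in mm.
#' @param tr repetition time in seconds.
#' @return object of class `bold_run`.
#' @export
bold_run <- function(data, mask, voxel_size = c(3, 3, 3), tr = 0.3) {
  d <- dim(data)
  if (length(d) != 4L)
    stop_thalcor("BOLD data must be 4-D", class = "thalcor_validation_error")
  if (d[4] < 2L)
    stop_thalcor("a BOLD run needs at least 2 frames",
                 class = "thalcor_validation_error")
  mask <- as_mask(mask)
  if (!identical(dim(mask), d[1:3]))
    stop_thalcor("mask grid does not match the data grid",
                 class = "thalcor_validation_error")
  if (!any(mask))
    stop_thalcor("valid-voxel mask is empty", class = "thalcor_validation_error")
  structure(list(data = data, mask = mask,
                 voxel_size = voxel_size, tr = tr),
            class = "bold_run")
}

#' @export
print.bold_run <- function(x, ...) {
  d <- dim(x$data)
  cat("<bold_run> ", paste(d[1:3], collapse = "x"), " grid, ", d[4],
      " frames, TR ", x$tr, " s, ", sum(x$mask), " valid voxels\n", sep = "")
  invisible(x)
}

#' Mode-1000 intensity normalization
#'
#' Applies one global factor so that the in-mask intensity norm statistic
#' equals 1000; on that scale 10 units correspond to 1% BOLD signal. The norm
#' statistic is the median of the per-voxel mean intensities over the valid
#' mask, a binning-free stand-in for the intensity mode.
#'
#' @param run a [bold_run()].
#' @param target norm value, default 1000.
#' @return the rescaled `bold_run`, with the applied factor in attribute
#'   `"scale_factor"`.
#' @export
mode1000_normalize <- function(run, target = 1000) {
  stopifnot(inherits(run, "bold_run"))
  vox_means <- rowMeans(mask_matrix(run$data, run$mask))
  stat <- stats::median(vox_means)
  if (!is.finite(stat) || stat <= 0)
    stop_thalcor("in-mask norm statistic must be positive, got ", stat,
                 class = "thalcor_validation_error")
  factor <- target / stat
  run$data <- run$data * factor
  attr(run, "scale_factor") <- factor
  run
}

#' Expand six motion estimates into 24 nuisance columns
#'
#' Produces the Friston-style expansion of the realignment parameters R:
#' the six parameters, their squares, the one-frame-lagged parameters and
#' the lagged squares. The lag row at frame 1 is zero-filled, matching the
#' backward-difference convention that the first frame has no predecessor.
#'
#' @param motion frames x 6 matrix (see [framewise_displacement()]).
#' @return frames x 24 matrix with labelled columns.
#' @export
motion_expansion <- function(motion) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6L)
    stop_thalcor("motion trace must have 6 columns, got ", ncol(motion),
                 class = "thalcor_validation_error")
  if (nrow(motion) < 2L)
    stop_thalcor("motion trace needs at least 2 frames",
                 class = "thalcor_validation_error")
  lag1 <- rbind(0, motion[-nrow(motion), , drop = FALSE])
  out <- cbind(motion, motion^2, lag1, lag1^2)
  base <- c("tx", "ty", "tz", "pitch", "yaw", "roll")
  colnames(out) <- c(base, paste0(base, "_sq"),
                     paste0(base, "_lag"), paste0(base, "_sq_lag"))
  out
}

#' Mean tissue signals for nuisance regression
#'
#' Per-frame mean intensity over the CSF, white-matter and global masks, each
#' intersected with the run's valid mask so lesion voxels never contribute.
#' The global mask defaults to the whole valid mask.
#'
#' @param run a [bold_run()].
#' @param csf_mask,wm_mask logical 3-D arrays.
#' @param global_mask optional logical 3-D array.
#' @return frames x 3 matrix with columns csf, wm, global.
#' @export
tissue_signals <- function(run, csf_mask, wm_mask, global_mask = NULL) {
  stopifnot(inherits(run, "bold_run"))
  global_mask <- global_mask %||% run$mask
  masks <- list(csf = as_mask(csf_mask), wm = as_mask(wm_mask),
                global = as_mask(global_mask))
  cols <- lapply(names(masks), function(nm) {
    m <- masks[[nm]] & run$mask
    if (!any(m))
      stop_thalcor("mask '", nm, "' is empty after intersection with the valid mask",
                   class = "thalcor_validation_error")
    colMeans(mask_matrix(run$data, m))
  })
  out <- do.call(cbind, cols)
  colnames(out) <- names(masks)
  out
}

#' Assemble the 27-column nuisance design
#'
#' Combines the 24 motion-derived indices with the CSF, white-matter and
#' global signals into the design matrix used for voxelwise nuisance
#' regression.
#'
#' @param motion frames x 6 motion matrix.
#' @param tissue frames x 3 tissue-signal matrix from [tissue_signals()].
#' @return frames x 27 labelled matrix of class `nuisance_set`.
#' @export
build_nuisance <- function(motion, tissue) {
  mx <- motion_expansion(motion)
  if (nrow(tissue) != nrow(mx))
    stop_thalcor("tissue signals and motion trace differ in frame count",
                 class = "thalcor_validation_error")
  out <- cbind(mx, as.matrix(tissue))
  class(out) <- c("nuisance_set", class(out))
  out
}

#' Voxelwise nuisance regression (residualization)
#'
#' For every valid voxel, fits ordinary least squares of the voxel time
#' series on an intercept plus the nuisance columns, using kept frames only,
#' and replaces the series by the residuals. Censored frames are dropped from
#' the output run (scrubbing, not interpolation). Rank-deficient designs are
#' handled by pivoting (the projection onto the column space is still
#' well-defined) with a warning.
#'
#' @param run a [bold_run()].
#' @param nuisance frames x k design matrix (no intercept column).
#' @param censor optional [build_censor_mask()] result; default keeps all
#'   frames.
#' @return a `bold_run` holding residuals at the kept frames; attribute
#'   `"kept_frames"` records which original frames survive.
#' @export
residualize <- function(run, nuisance, censor = NULL) {
  stopifnot(inherits(run, "bold_run"))
  nuisance <- as.matrix(nuisance)
  nt <- dim(run$data)[4]
  if (nrow(nuisance) != nt)
    stop_thalcor("nuisance rows (", nrow(nuisance),
                 ") do not match frame count (", nt, ")",
                 class = "thalcor_validation_error")
  keep <- if (is.null(censor)) rep(TRUE, nt) else censor$keep
  X <- cbind(intercept = 1, nuisance[keep, , drop = FALSE])
  if (sum(keep) <= ncol(X))
    stop_thalcor("kept frames (", sum(keep),
                 ") must exceed regressor count (", ncol(X), ")",
                 class = "thalcor_dof_error")
  Y <- t(mask_matrix(run$data, run$mask)[, keep, drop = FALSE])
  fit <- stats::lm.fit(X, Y)
  if (fit$rank < ncol(X))
    warning("nuisance design is rank deficient (rank ", fit$rank, " of ",
            ncol(X), "); using the pivoted least-squares projection")
  res <- as.matrix(fit$residuals)
  d <- dim(run$data)
  out <- array(0, dim = c(d[1:3], sum(keep)))
  flat <- matrix(out, nrow = prod(d[1:3]), ncol = sum(keep))
  flat[as.vector(run$mask), ] <- t(res)
  out <- array(flat, dim = c(d[1:3], sum(keep)))
  new_run <- bold_run(out, run$mask, run$voxel_size, run$tr)
  attr(new_run, "kept_frames") <- which(keep)
  new_run
}

#' Exclude lesioned tissue from the valid mask
#'
#' Restricts the run's valid-voxel mask to healthy tissue: valid := valid AND
#' NOT lesion. Every downstream statistic (tissue means, seed maps, ICA,
#' betas) reads only valid voxels, so connectivity is measured in healthy
#' tissue only.
#'
#' @param run a [bold_run()].
#' @param lesion_mask logical 3-D array on the same grid.
#' @return the `bold_run` with the restricted mask.
#' @export
apply_lesion_mask <- function(run, lesion_mask) {
  stopifnot(inherits(run, "bold_run"))
  lesion_mask <- as_mask(lesion_mask)
  if (!identical(dim(lesion_mask), dim(run$mask)))
    stop_thalcor("lesion mask grid does not match the run grid",
                 class = "thalcor_validation_error")
  run$mask <- run$mask & !lesion_mask
  if (!any(run$mask))
    stop_thalcor("lesion mask removes every valid voxel",
                 class = "thalcor_analysis_error")
  run
}

#' Midsagittal (left-right) flip
#'
#' Mirrors a volume, 4-D run or mask along the first voxel axis (assumed
#' left-right) when the subject's lesion lies in the right hemisphere, so the
#' affected hemisphere corresponds to the left hemisphere in the whole
#' sample. Applying the flip twice restores the input exactly.
#'
#' @param x 3-D array, 4-D array, or `bold_run`.
#' @param lesion_side `"left"`, `"right"`, `"none"`; only `"right"` flips.
#' @return same type as `x`.
#' @export
flip_midsagittal <- function(x, lesion_side) {
  if (!lesion_side %in% c("left", "right", "none", "bilateral"))
    stop_thalcor("unknown lesion side '", lesion_side, "'",
                 class = "thalcor_validation_error")
  if (lesion_side != "right") return(x)
  flip_array(x)
}

flip_array <- function(x) {
  if (inherits(x, "bold_run")) {
    x$data <- flip_array(x$data)
    x$mask <- flip_array(x$mask)
    return(x)
  }
  d <- dim(x)
  idx <- rev(seq_len(d[1]))
  if (length(d) == 3L) x[idx, , , drop = FALSE]
  else if (length(d) == 4L) x[idx, , , , drop = FALSE]
  else stop_thalcor("expected a 3-D or 4-D array",
                    class = "thalcor_validation_error")
}
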