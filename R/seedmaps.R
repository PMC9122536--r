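#' Fisher z transform of a correlation coefficient
#'
#' z = 0.5 * ln((1 + r) / (1 - r)), an odd, variance-stabilizing map.
#' Magnitudes are clipped to 1 - 1e-7 before the log so perfect correlations
#' stay finite with negligible bias.
#'
#' @param r correlations in \[-1, 1\] (vectorized).
#' @param clip clipping constant subtracted from 1.
#' @return Fisher z values.
#' @examples
#' fisher_z(0.5)   # 0.5493
#' fisher_z(-0.5)  # -0.5493
#' @export
fisher_z <- function(r, clip = 1e-7) {
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE))
    stop_thalcor("correlations must lie in [-1, 1]",
                 class = "thalcor_validation_error")
  r <- pmin(pmax(r, -(1 - clip)), 1 - clip)
  0.5 * log((1 + r) / (1 - r))
}

#' Per-thalamic-voxel seed correlation maps
#'
#' Correlates the time series of every thalamic voxel with every voxel of the
#' rest of the brain (Pearson, over kept frames), then Fisher-transforms the
#' correlations. One row per thalamic seed voxel, one column per brain voxel.
#' Brain-voxel columns exclude the thalamus mask itself so trivial
#' self-correlations do not dominate the downstream decomposition (set
#' `include_thalamus = TRUE` to keep them). Zero-variance series yield z = 0
#' with a warning so voxel indexing stays uniform across subjects.
#'
#' @param run a residualized [bold_run()].
#' @param thalamus_mask logical 3-D array of thalamic seed voxels.
#' @param censor optional [build_censor_mask()] result (if the run has not
#'   already been scrubbed).
#' @param include_thalamus keep thalamic voxels among the brain columns?
#' @param brain_mask optional column mask overriding the run's valid mask;
#'   a group analysis passes the common brain mask here so that voxel
#'   indexing is identical across subjects (lesion-excluded voxels carry
#'   all-zero residual series and therefore map to z = 0).
#' @param drop_invalid_seeds drop thalamic voxels outside the valid mask
#'   (with a warning)? If FALSE they are kept as z = 0 rows so the row
#'   indexing stays uniform across subjects.
#' @param subject optional subject id stored with the stack.
#' @return object of class `seed_stack`: list with matrix `z`
#'   (n_thalamic x n_brain), coordinate tables `thal_coords` and
#'   `brain_coords`, and `subject`.
#' @export
seed_correlation_stack <- function(run, thalamus_mask, censor = NULL,
                                   include_thalamus = FALSE,
                                   brain_mask = NULL,
                                   drop_invalid_seeds = TRUE,
                                   subject = NULL) {
  stopifnot(inherits(run, "bold_run"))
  thalamus_mask <- as_mask(thalamus_mask)
  if (!identical(dim(thalamus_mask), dim(run$mask)))
    stop_thalcor("thalamus mask grid does not match the run grid",
                 class = "thalcor_validation_error")
  thal <- if (drop_invalid_seeds) thalamus_mask & run$mask else thalamus_mask
  n_dropped <- sum(thalamus_mask) - sum(thal)
  if (n_dropped > 0)
    warning(n_dropped, " thalamic voxels fall outside the valid mask and are dropped")
  if (!any(thal & run$mask))
    stop_thalcor("no thalamic voxels remain inside the valid mask",
                 class = "thalcor_analysis_error")
  brain <- if (is.null(brain_mask)) run$mask else as_mask(brain_mask)
  if (!include_thalamus) brain <- brain & !thalamus_mask
  nt <- dim(run$data)[4]
  keep <- if (is.null(censor)) rep(TRUE, nt) else censor$keep
  n <- sum(keep)
  if (n < 3L)
    stop_thalcor("need at least 3 kept frames to correlate, got ", n,
                 class = "thalcor_dof_error")
  ts_thal <- standardize_rows(mask_matrix(run$data, thal)[, keep, drop = FALSE])
  ts_brain <- standardize_rows(mask_matrix(run$data, brain)[, keep, drop = FALSE])
  nzv <- attr(ts_thal, "n_zero_var") + attr(ts_brain, "n_zero_var")
  if (nzv > 0)
    warning(nzv, " zero-variance voxel series mapped to z = 0")
  r <- tcrossprod(ts_thal, ts_brain) / (n - 1)
  structure(list(z = fisher_z(r),
                 thal_coords = mask_coords(thal),
                 brain_coords = mask_coords(brain),
                 subject = subject),
            class = "seed_stack")
}

## Row-standardize (mean 0, sd 1); zero-variance rows become all-zero.
standardize_rows <- function(m) {
  mu <- rowMeans(m)
  m <- m - mu
  s <- sqrt(rowSums(m^2) / (ncol(m) - 1))
  zero <- s <= 0 | !is.finite(s)
  s[zero] <- 1
  m <- m / s
  m[zero, ] <- 0
  attr(m, "n_zero_var") <- sum(zero)
  m
}

#' @export
print.seed_stack <- function(x, ...) {
  cat("<seed_stack> ", nrow(x$z), " thalamic seeds x ", ncol(x$z),
      " brain voxels", if (!is.null(x$subject)) paste0(" (", x$subject, ")"),
      "\n", sep = "")
  invisible(x)
}

#' Concatenate per-subject seed stacks into one group stack
#'
#' Stacks the Fisher-z maps of all subjects subject-major (all rows of
#' subject 1, then subject 2, ...), the layout the group spatial ICA
#' decomposes. A provenance index maps every row back to its
#' (subject, thalamic voxel) origin, so concatenation is lossless.
#'
#' @param stacks list of [seed_correlation_stack()] results sharing voxel
#'   indexing.
#' @return object of class `group_stack`: list with matrix `z`, `provenance`
#'   data.frame (subject, thal_voxel), and the shared coordinate tables.
#' @export
concatenate_group <- function(stacks) {
  stopifnot(length(stacks) >= 1L, all(vapply(stacks, inherits, TRUE, "seed_stack")))
  ref <- stacks[[1]]
  for (s in stacks[-1]) {
    if (!identical(unname(s$thal_coords), unname(ref$thal_coords)) ||
        !identical(unname(s$brain_coords), unname(ref$brain_coords)))
      stop_thalcor("seed stacks do not share voxel indexing",
                   class = "thalcor_validation_error")
  }
  subjects <- vapply(seq_along(stacks), function(i)
    stacks[[i]]$subject %||% paste0("S", i), character(1))
  z <- do.call(rbind, lapply(stacks, `[[`, "z"))
  nthal <- nrow(ref$z)
  prov <- data.frame(
    subject = rep(subjects, each = nthal),
    thal_voxel = rep(seq_len(nthal), times = length(stacks)))
  structure(list(z = z, provenance = prov,
                 thal_coords = ref$thal_coords,
                 brain_coords = ref$brain_coords),
            class = "group_stack")
}

#' Split a group stack back into per-subject matrices
#'
#' @param group a [concatenate_group()] result.
#' @return named list of per-subject z matrices.
#' @export
split_group_stack <- function(group, subject = NULL) {
  stopifnot(inherits(group, "group_stack"))
  split_idx <- split(seq_len(nrow(group$z)), group$provenance$subject)
  ## preserve first-appearance order, not alphabetical
  split_idx <- split_idx[unique(group$provenance$subject)]
  out <- lapply(split_idx, function(i) group$z[i, , drop = FALSE])
  if (!is.null(subject)) out[[subject]] else out
}
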