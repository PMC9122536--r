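#' Framewise displacement from rigid-body motion estimates
#'
#' Summarizes head motion between consecutive frames as the sum of absolute
#' backward differences of the six rigid-body realignment parameters, with
#' rotations converted to millimetres of arc on a sphere of radius
#' `rotation_radius_mm`. The first frame has no predecessor and gets FD = 0.
#'
#' @param motion numeric matrix with one row per frame and six columns:
#'   translations x, y, z in mm, then rotations pitch, yaw, roll in radians.
#' @param rotation_radius_mm radius (mm) used to convert radians of rotation
#'   into displacement; 50 mm approximates the distance from the centre of the
#'   head to the cortical surface.
#' @return numeric vector of per-frame FD values in mm (first element 0).
#' @examples
#' m <- rbind(c(0, 0, 0, 0, 0, 0), c(0.1, -0.05, 0, 0.002, 0, 0))
#' framewise_displacement(m)  # 0, 0.25 with the default 50 mm radius
#' @export
framewise_displacement <- function(motion, rotation_radius_mm = 50) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6L)
    stop_thalcor("motion trace must have 6 columns, got ", ncol(motion),
                 class = "thalcor_validation_error")
  if (nrow(motion) < 2L)
    stop_thalcor("motion trace needs at least 2 frames",
                 class = "thalcor_validation_error")
  check_finite(motion, "motion trace")
  d <- abs(diff(motion))
  fd <- rowSums(d[, 1:3, drop = FALSE]) +
    rotation_radius_mm * rowSums(d[, 4:6, drop = FALSE])
  c(0, fd)
}

#' DVARS: RMS of the backward-differenced BOLD signal
#'
#' Computes, per frame, the root mean square across in-mask voxels of the
#' frame-to-frame intensity difference. The run is first rescaled so that the
#' mean in-mask intensity equals 100, putting DVARS in percent-signal-change
#' units (on a mode-1000 scale, 10 raw units = 1% BOLD). The first frame has
#' DVARS = 0.
#'
#' @param run a `bold_run` (see [bold_run()]) or a 4-D array.
#' @param brain_mask logical 3-D array; defaults to the run's valid mask.
#' @return numeric vector of per-frame DVARS values in % signal change.
#' @export
dvars <- function(run, brain_mask = NULL) {
  data4d <- if (inherits(run, "bold_run")) run$data else run
  brain_mask <- brain_mask %||% (if (inherits(run, "bold_run")) run$mask else NULL)
  if (is.null(brain_mask))
    stop_thalcor("a brain mask is required", class = "thalcor_validation_error")
  brain_mask <- as_mask(brain_mask)
  if (!any(brain_mask))
    stop_thalcor("brain mask is empty", class = "thalcor_validation_error")
  y <- mask_matrix(data4d, brain_mask)
  mu <- mean(y)
  if (mu <= 0)
    stop_thalcor("mean in-mask intensity must be positive",
                 class = "thalcor_validation_error")
  y <- y * (100 / mu)
  dy <- y[, -1, drop = FALSE] - y[, -ncol(y), drop = FALSE]
  c(0, sqrt(colMeans(dy^2)))
}

#' Build a frame-censoring (scrubbing) mask from FD and DVARS
#'
#' Flags every frame whose framewise displacement exceeds `fd_thresh` or whose
#' DVARS exceeds `dvars_thresh` (the defaults are the geometrical and
#' physiological criteria FD > 0.2 mm, DVARS > 0.38%). Flags can be extended
#' to neighbouring frames. The keep mask is the complement of the flags.
#'
#' @param fd per-frame framewise displacement (mm).
#' @param dvars per-frame DVARS (% signal change).
#' @param fd_thresh,dvars_thresh censoring thresholds.
#' @param extend_before,extend_after number of neighbouring frames to flag on
#'   each side of an exceedance (default 0: flag-only censoring).
#' @param min_frames minimum number of frames that must survive; defaults to
#'   half the run length, below which correlation estimates are unstable.
#' @param subject optional subject label used in error messages.
#' @return an object of class `censor_mask`: list with logical `keep`, and
#'   counts `n_fd`, `n_dvars`, `n_flagged`, `n_kept`.
#' @export
build_censor_mask <- function(fd, dvars, fd_thresh = 0.2, dvars_thresh = 0.38,
                              extend_before = 0L, extend_after = 0L,
                              min_frames = NULL, subject = NULL) {
  if (length(fd) != length(dvars))
    stop_thalcor("fd and dvars series differ in length",
                 class = "thalcor_validation_error")
  n <- length(fd)
  min_frames <- min_frames %||% ceiling(n / 2)
  over_fd <- fd > fd_thresh
  over_dv <- dvars > dvars_thresh
  flag <- over_fd | over_dv
  if ((extend_before > 0L || extend_after > 0L) && any(flag)) {
    idx <- which(flag)
    ext <- unlist(lapply(idx, function(i)
      seq(max(1L, i - extend_before), min(n, i + extend_after))))
    flag[unique(ext)] <- TRUE
  }
  keep <- !flag
  if (sum(keep) < min_frames)
    stop_thalcor("censoring leaves ", sum(keep), " of ", n,
                 " frames (minimum ", min_frames, ")",
                 if (!is.null(subject)) paste0(" for subject ", subject) else "",
                 class = "thalcor_censoring_error")
  structure(list(keep = keep, n_fd = sum(over_fd), n_dvars = sum(over_dv),
                 n_flagged = sum(flag), n_kept = sum(keep)),
            class = "censor_mask")
}

#' @export
print.censor_mask <- function(x, ...) {
  cat("<censor_mask> ", x$n_kept, "/", length(x$keep), " frames kept (",
      x$n_fd, " FD exceedances, ", x$n_dvars, " DVARS exceedances)\n", sep = "")
  invisible(x)
}

#' Read a 6-column realignment-parameter table
#'
#' Whitespace-delimited text, one row per frame: translations x, y, z (mm)
#' followed by rotations pitch, yaw, roll (radians).
#'
#' @param path file path.
#' @return numeric matrix with 6 named columns.
#' @export
read_motion_table <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  if (ncol(m) != 6L)
    stop_thalcor("motion table must have 6 columns, got ", ncol(m),
                 class = "thalcor_validation_error")
  dimnames(m) <- list(NULL, c("tx", "ty", "tz", "pitch", "yaw", "roll"))
  m
}

#' Per-subject motion QC report
#'
#' @param fd,dvars per-frame series.
#' @param censor a [build_censor_mask()] result.
#' @return data.frame with columns frame, fd, dvars, kept.
#' @export
motion_qc_report <- function(fd, dvars, censor) {
  data.frame(frame = seq_along(fd), fd = fd, dvars = dvars, kept = censor$keep)
}
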