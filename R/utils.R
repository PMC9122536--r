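`%||%` <- function(a, b) if (is.null(a)) b else a

stop_thalcor <- function(..., class = "thalcor_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_finite <- function(x, what) {
  if (!all(is.finite(x)))
    stop_thalcor(what, " contains non-finite values", class = "thalcor_validation_error")
  invisible(x)
}

#' @keywords internal
as_mask <- function(x) {
  if (is.logical(x)) return(x)
  array(x != 0, dim = dim(x))
}

## Flatten a 4-D array (x,y,z,t) to a voxels-in-mask x frames matrix.
mask_matrix <- function(data4d, mask) {
  d <- dim(data4d)
  stopifnot(length(d) == 4L)
  m <- matrix(data4d, nrow = prod(d[1:3]), ncol = d[4])
  m[as.vector(mask), , drop = FALSE]
}

## Voxel coordinates (one row per TRUE voxel, column-major order).
mask_coords <- function(mask) {
  which(mask, arr.ind = TRUE)
}
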