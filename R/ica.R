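## Spatial ICA of the concatenated seed-map stack.
##
## The stack X (maps x voxels) is modelled as X ~ A S with spatially
## independent, unit-variance source maps S (components x voxels). Estimation
## is the classic two-step scheme: PCA reduction of the map dimension to the
## requested component count (via a seeded randomized SVD, cheap at tall-thin
## sizes), followed by fixed-point negentropy maximization with the log-cosh
## contrast and symmetric decorrelation (parallel estimation of all
## components).

#' Randomized truncated SVD
#'
#' Range-finder with oversampling and power iterations; deterministic under
#' the supplied seed. Adequate for the strongly low-rank stacks produced by
#' seed-map concatenation.
#'
#' @param x numeric matrix.
#' @param k number of singular triplets.
#' @param oversample extra random probes beyond `k`.
#' @param power subspace (power) iterations.
#' @param seed integer seed for the Gaussian probe matrix.
#' @return list with `u`, `d`, `v` as in [svd()].
#' @keywords internal
#' @export
rsvd <- function(x, k, oversample = 10L, power = 2L, seed = 1L) {
  m <- nrow(x); n <- ncol(x)
  l <- min(k + oversample, m, n)
  rs <- local_rng(seed)
  omega <- matrix(rs$norm(n * l), n, l)
  y <- x %*% omega
  q <- qr.Q(qr(y))
  for (i in seq_len(power)) {
    q <- qr.Q(qr(crossprod(x, q)))
    q <- qr.Q(qr(x %*% q))
  }
  b <- crossprod(q, x)
  sv <- svd(b, nu = k, nv = k)
  list(u = q %*% sv$u, d = sv$d[seq_len(k)], v = sv$v)
}

## Small deterministic RNG wrapper that does not disturb the global stream.
local_rng <- function(seed) {
  env <- new.env()
  env$state <- {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    s
  }
  draw <- function(fn, n) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    out <- fn(n)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    out
  }
  list(norm = function(n) draw(stats::rnorm, n),
       unif = function(n) draw(stats::runif, n))
}

#' Decompose a group seed-map stack into spatially independent components
#'
#' Fits the spatial ICA model stack ~ mixing x sources: dimensionality
#' reduction of the map dimension to `n_components` principal components,
#' then fixed-point independence maximization (log-cosh negentropy contrast,
#' symmetric decorrelation). Each component's sign is fixed so its spatial
#' skewness is non-negative, making maps and mixing weights comparable across
#' runs. Deterministic under a fixed seed.
#'
#' @param group a [concatenate_group()] result, or a plain maps x voxels
#'   matrix.
#' @param n_components number of components (the group analysis of the
#'   motivating design uses 20).
#' @param seed integer seed for the random initial unmixing matrix and the
#'   randomized SVD.
#' @param max_iter,tol fixed-point iteration limit and convergence tolerance.
#' @return object of class `component_set`: list with `maps`
#'   (n_components x n_brain, unit-variance rows), `mixing`
#'   (n_maps x n_components), `labels` (NULL until [match_components()]),
#'   `iterations`, `converged`, plus the brain coordinate table when
#'   available.
#' @export
decompose_ica <- function(group, n_components = 20L, seed = 1L,
                          max_iter = 500L, tol = 1e-4) {
  x <- if (inherits(group, "group_stack")) group$z else as.matrix(group)
  m <- nrow(x); v <- ncol(x)
  if (m < n_components || v < n_components)
    stop_thalcor("stack of ", m, " maps x ", v,
                 " voxels cannot support ", n_components, " components",
                 class = "thalcor_validation_error")
  center <- rowMeans(x)
  xc <- x - center
  sv <- rsvd(xc, n_components, seed = seed)
  ## Whitened data: rows are unit-variance decorrelated spatial signals.
  z <- t(sv$v[, seq_len(n_components), drop = FALSE]) * sqrt(v)
  rs <- local_rng(seed + 1L)
  w <- matrix(rs$norm(n_components^2), n_components, n_components)
  w <- sym_decorrelate(w)
  it <- 0L; converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    wz <- w %*% z
    g <- tanh(wz)
    gp <- rowMeans(1 - g^2)
    w_new <- sym_decorrelate(tcrossprod(g, z) / v - gp * w)
    delta <- max(abs(abs(rowSums(w_new * w)) - 1))
    w <- w_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    stop_thalcor("ICA did not converge after ", it,
                 " iterations (last delta ", signif(delta, 3), ")",
                 class = "thalcor_convergence_error")
  s <- w %*% z                                  # components x voxels, unit variance
  ## mixing for the centred stack: A = Xc S' / v  (rows of S orthonormal * sqrt(v))
  a <- xc %*% t(s) / v
  ## sign convention: non-negative spatial skewness
  skew <- rowMeans(s^3)
  flip <- skew < 0
  s[flip, ] <- -s[flip, , drop = FALSE]
  a[, flip] <- -a[, flip, drop = FALSE]
  structure(list(maps = s, mixing = a, labels = NULL,
                 center = center, iterations = it, converged = converged,
                 brain_coords = if (inherits(group, "group_stack")) group$brain_coords else NULL,
                 seed = seed),
            class = "component_set")
}

sym_decorrelate <- function(w) {
  e <- eigen(tcrossprod(w), symmetric = TRUE)
  vals <- pmax(e$values, .Machine$double.eps)
  e$vectors %*% (t(e$vectors) / sqrt(vals)) %*% w
}

#' @export
print.component_set <- function(x, ...) {
  cat("<component_set> ", nrow(x$maps), " spatial components over ",
      ncol(x$maps), " brain voxels (", x$iterations, " iterations)\n", sep = "")
  if (!is.null(x$labels))
    cat("  labelled: ", paste(x$labels, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Label components by matching against template network maps
#'
#' Greedy one-to-one assignment: component-template pairs are matched in
#' descending order of absolute spatial correlation, each template and each
#' component used at most once; pairs below `min_match_r` stay unassigned.
#' This automates the expert identification of well-known networks among the
#' components; on synthetic data the generator's true maps serve as
#' templates.
#'
#' @param components a [decompose_ica()] result.
#' @param templates voxels x L matrix of template maps with column names as
#'   labels (same brain-voxel indexing as the components).
#' @param min_match_r minimum absolute spatial correlation to accept a match.
#' @return a `component_set` restricted to the matched components, in
#'   template-label order, with `labels` set and the full correlation table
#'   in `match_table`.
#' @export
match_components <- function(components, templates, min_match_r = 0.3) {
  stopifnot(inherits(components, "component_set"))
  templates <- as.matrix(templates)
  if (is.null(colnames(templates)))
    colnames(templates) <- paste0("network", seq_len(ncol(templates)))
  n_comp <- nrow(components$maps)
  if (ncol(templates) > n_comp)
    stop_thalcor("more templates (", ncol(templates), ") than components (",
                 n_comp, ")", class = "thalcor_validation_error")
  if (nrow(templates) != ncol(components$maps))
    stop_thalcor("templates are on a different brain-voxel indexing",
                 class = "thalcor_validation_error")
  rtab <- stats::cor(t(components$maps), templates)   # components x templates
  assign <- rep(NA_integer_, ncol(templates))
  names(assign) <- colnames(templates)
  ord <- order(abs(rtab), decreasing = TRUE)
  used_comp <- logical(n_comp)
  for (k in ord) {
    ci <- (k - 1L) %% n_comp + 1L
    ti <- (k - 1L) %/% n_comp + 1L
    if (abs(rtab[k]) < min_match_r) break
    if (used_comp[ci] || !is.na(assign[ti])) next
    assign[ti] <- ci
    used_comp[ci] <- TRUE
  }
  matched <- !is.na(assign)
  sel <- assign[matched]
  out <- components
  out$maps <- components$maps[sel, , drop = FALSE]
  out$mixing <- components$mixing[, sel, drop = FALSE]
  out$labels <- names(sel)
  out$match_table <- rtab
  out$match_r <- rtab[cbind(sel, which(matched))]
  out
}

#' Per-voxel network beta regression
#'
#' For each thalamic voxel, ordinary least squares of its Fisher-z seed map
#' on an intercept plus the selected component maps; the component
#' coefficients (one beta per network per voxel) quantify that voxel's
#' connectivity strength with each network. The intercept absorbs map
#' offsets and is discarded.
#'
#' @param stack a [seed_correlation_stack()] result or a thalamic-voxels x
#'   brain-voxels z matrix.
#' @param components a labelled [match_components()] result (or any
#'   `component_set`).
#' @return object of class `beta_map`: matrix n_thalamic_voxels x n_networks
#'   with network labels as column names; subject id carried through.
#' @export
voxel_network_betas <- function(stack, components) {
  z <- if (inherits(stack, "seed_stack")) stack$z else as.matrix(stack)
  stopifnot(inherits(components, "component_set"))
  maps <- components$maps
  if (ncol(maps) != ncol(z))
    stop_thalcor("component maps and seed maps differ in brain-voxel count",
                 class = "thalcor_validation_error")
  X <- cbind(intercept = 1, t(maps))
  if (kappa(crossprod(X), exact = FALSE) > 1e16)
    stop_thalcor("component maps are collinear; reduce the component count",
                 class = "thalcor_collinearity_error")
  coefs <- qr.coef(qr(X), t(z))                  # (1 + L) x n_thal
  betas <- t(coefs[-1, , drop = FALSE])
  colnames(betas) <- components$labels %||% paste0("component", seq_len(nrow(maps)))
  structure(betas,
            subject = if (inherits(stack, "seed_stack")) stack$subject else NULL,
            class = c("beta_map", "matrix", "array"))
}

#' @export
print.beta_map <- function(x, ...) {
  cat("<beta_map> ", nrow(x), " thalamic voxels x ", ncol(x), " networks (",
      paste(colnames(x), collapse = ", "), ")\n", sep = "")
  invisible(x)
}
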