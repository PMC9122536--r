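#' Benjamini-Hochberg FDR correction
#'
#' Step-up adjustment with monotonicity enforcement (via [stats::p.adjust()]);
#' significance flags are `q <= alpha`. `NA` p values (zero-variance sentinel
#' voxels) propagate to `NA` q and are never flagged.
#'
#' @param p vector of p values in \[0, 1\] (NA allowed).
#' @param alpha significance level, default 0.05.
#' @return list with `q` (adjusted values) and `reject` (logical flags).
#' @export
fdr_correct <- function(p, alpha = 0.05) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    stop_thalcor("p values must lie in [0, 1]",
                 class = "thalcor_validation_error")
  q <- rep(NA_real_, length(p))
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  list(q = q, reject = !is.na(q) & q <= alpha)
}

## Build a stat_map from per-voxel-per-network t, df matrices.
make_stat_map <- function(t_mat, df, labels, alpha, thal_coords = NULL,
                          fdr_family = c("per_network", "global")) {
  fdr_family <- match.arg(fdr_family)
  p <- 2 * stats::pt(abs(t_mat), df = df, lower.tail = FALSE)
  p[!is.finite(t_mat)] <- NA          # zero-variance sentinel voxels
  q <- flag <- array(NA, dim = dim(p))
  if (fdr_family == "per_network") {
    for (j in seq_len(ncol(p))) {
      fc <- fdr_correct(p[, j], alpha)
      q[, j] <- fc$q; flag[, j] <- fc$reject
    }
  } else {
    fc <- fdr_correct(as.vector(p), alpha)
    q <- array(fc$q, dim = dim(p)); flag <- array(fc$reject, dim = dim(p))
  }
  dimnames(t_mat) <- dimnames(p) <- dimnames(q) <- dimnames(flag) <-
    list(NULL, labels)
  structure(list(t = t_mat, df = df, p = p, q = q,
                 flag = flag & !is.na(flag),
                 sign = sign(t_mat), alpha = alpha,
                 thal_coords = thal_coords),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat("<stat_map> ", nrow(x$t), " voxels x ", ncol(x$t), " networks, df = ",
      x$df, ", alpha = ", x$alpha, "\n", sep = "")
  n_pos <- colSums(x$flag & x$sign > 0, na.rm = TRUE)
  n_neg <- colSums(x$flag & x$sign < 0, na.rm = TRUE)
  for (j in seq_len(ncol(x$t)))
    cat(sprintf("  %-12s %4d voxels up, %4d down\n",
                colnames(x$t)[j], n_pos[j], n_neg[j]))
  invisible(x)
}

## Stack a list of beta_maps into subjects x voxels x networks.
beta_array <- function(betamaps) {
  stopifnot(length(betamaps) >= 1L)
  d <- dim(betamaps[[1]])
  labels <- colnames(betamaps[[1]])
  for (b in betamaps)
    if (!identical(dim(b), d) || !identical(colnames(b), labels))
      stop_thalcor("beta maps differ in shape or network labels",
                   class = "thalcor_validation_error")
  arr <- array(NA_real_, dim = c(length(betamaps), d[1], d[2]))
  for (i in seq_along(betamaps)) arr[i, , ] <- unclass(betamaps[[i]])
  dimnames(arr) <- list(names(betamaps), NULL, labels)
  arr
}

#' One-sample t map over subjects' beta maps
#'
#' Per thalamic voxel and network: t = mean / (sd / sqrt(n)), df = n - 1,
#' two-sided p, FDR adjusted per network across thalamic voxels.
#' Zero-variance voxels get a signed infinite sentinel t, are assigned no p
#' value and are never flagged.
#'
#' @param betamaps list of [voxel_network_betas()] results (one per subject).
#' @param alpha significance level for the FDR flags.
#' @param fdr_family `"per_network"` (default) or `"global"`.
#' @return a `stat_map`.
#' @export
one_sample_tmap <- function(betamaps, alpha = 0.05,
                            fdr_family = "per_network") {
  arr <- beta_array(betamaps)
  if (dim(arr)[1] < 3L)
    stop_thalcor("need at least 3 subjects, got ", dim(arr)[1],
                 class = "thalcor_validation_error")
  tmap_core(arr, alpha, fdr_family)
}

## Shared one-sample machinery (paired maps reuse it with n >= 2 pairs).
tmap_core <- function(arr, alpha, fdr_family) {
  n <- dim(arr)[1]
  mu <- apply(arr, c(2, 3), mean)
  sd <- apply(arr, c(2, 3), stats::sd)
  t_mat <- mu / (sd / sqrt(n))
  zv <- sd == 0
  if (any(zv)) {
    warning(sum(zv), " zero-variance voxels set to sentinel t")
    t_mat[zv] <- sign(mu[zv]) * Inf
    t_mat[zv & mu == 0] <- NaN
  }
  make_stat_map(t_mat, df = n - 1, labels = dimnames(arr)[[3]],
                alpha = alpha, fdr_family = fdr_family)
}

#' Paired patient-control difference map
#'
#' Paired t test on within-pair beta differences (patient minus control) per
#' thalamic voxel and network, df = n_pairs - 1, FDR per network. The sign
#' records direction: positive = higher connectivity in patients (hyper),
#' negative = lower (hypo).
#'
#' @param betas_patients,betas_controls named lists of beta maps.
#' @param pairing data.frame with columns `patient` and `control` giving the
#'   matched names; defaults to positional pairing.
#' @param alpha,fdr_family see [one_sample_tmap()].
#' @return a `stat_map`.
#' @export
paired_difference_map <- function(betas_patients, betas_controls,
                                  pairing = NULL, alpha = 0.05,
                                  fdr_family = "per_network") {
  if (is.null(pairing)) {
    if (length(betas_patients) != length(betas_controls))
      stop_thalcor("groups differ in size and no pairing was given",
                   class = "thalcor_validation_error")
    pairing <- data.frame(patient = names(betas_patients) %||%
                            seq_along(betas_patients),
                          control = names(betas_controls) %||%
                            seq_along(betas_controls))
  }
  miss_p <- setdiff(pairing$patient, names(betas_patients) %||% pairing$patient)
  miss_c <- setdiff(pairing$control, names(betas_controls) %||% pairing$control)
  if (length(miss_p) || length(miss_c))
    stop_thalcor("unpaired subjects: ",
                 paste(c(miss_p, miss_c), collapse = ", "),
                 class = "thalcor_validation_error")
  diffs <- lapply(seq_len(nrow(pairing)), function(i) {
    bp <- betas_patients[[pairing$patient[i]]]
    bc <- betas_controls[[pairing$control[i]]]
    structure(unclass(bp) - unclass(bc), class = class(bp))
  })
  if (length(diffs) < 2L)
    stop_thalcor("need at least 2 pairs, got ", length(diffs),
                 class = "thalcor_validation_error")
  tmap_core(beta_array(diffs), alpha = alpha, fdr_family = fdr_family)
}

#' Voxelwise brain-behaviour regression
#'
#' Per thalamic voxel and network, ordinary least squares of the connectivity
#' beta on an intercept, the cognitive score and the covariates (age and
#' lesion-size fraction by default). Reports the t statistic of the score
#' coefficient with df = n - (number of model columns); FDR per network.
#' Positive and negative associations are distinguished by the sign.
#'
#' @param betamaps named list of beta maps (names must match
#'   `phenotypes$subject_id`).
#' @param phenotypes a phenotype data.frame (see [read_phenotypes()]).
#' @param score_name column of `phenotypes` used as the predictor of
#'   interest (e.g. `"score_wm_z"`).
#' @param covariates character vector of covariate columns.
#' @param alpha,fdr_family see [one_sample_tmap()].
#' @return a `stat_map` for the score coefficient, with the coefficient
#'   estimates in `$coef`.
#' @export
brain_behavior_map <- function(betamaps, phenotypes, score_name,
                               covariates = c("age", "lesion_frac"),
                               alpha = 0.05, fdr_family = "per_network") {
  ids <- names(betamaps)
  if (is.null(ids))
    stop_thalcor("betamaps must be a named list keyed by subject id",
                 class = "thalcor_validation_error")
  ph <- phenotypes[match(ids, phenotypes$subject_id), , drop = FALSE]
  if (any(is.na(ph$subject_id)))
    stop_thalcor("phenotypes missing for: ",
                 paste(ids[is.na(ph$subject_id)], collapse = ", "),
                 class = "thalcor_validation_error")
  need <- c(score_name, covariates)
  for (v in need)
    if (!v %in% names(ph) || any(is.na(ph[[v]])))
      stop_thalcor("missing or incomplete column '", v, "'",
                   class = "thalcor_validation_error")
  keep_cov <- covariates[vapply(covariates,
                                function(v) stats::sd(ph[[v]]) > 0, TRUE)]
  dropped <- setdiff(covariates, keep_cov)
  if (length(dropped))
    warning("zero-variance covariates dropped: ", paste(dropped, collapse = ", "))
  X <- cbind(intercept = 1, score = ph[[score_name]],
             as.matrix(ph[keep_cov]))
  n <- nrow(X); k <- ncol(X)
  if (n < k + 1L)
    stop_thalcor("need at least ", k + 1L, " subjects, got ", n,
                 class = "thalcor_validation_error")
  if (kappa(crossprod(scale(X[, -1, drop = FALSE])), exact = FALSE) > 1e16)
    stop_thalcor("score and covariates are collinear",
                 class = "thalcor_collinearity_error")
  arr <- beta_array(betamaps)
  nv <- dim(arr)[2]; nn <- dim(arr)[3]
  qrx <- qr(X)
  xtxinv_score <- solve(crossprod(X))[2, 2]
  t_mat <- coef_mat <- matrix(NA_real_, nv, nn)
  for (j in seq_len(nn)) {
    Y <- arr[, , j, drop = TRUE]             # subjects x voxels
    if (is.null(dim(Y))) Y <- matrix(Y, nrow = n)
    fit_coef <- qr.coef(qrx, Y)              # k x nv
    res <- Y - X %*% fit_coef
    rss <- colSums(res^2)
    sigma2 <- rss / (n - k)
    se <- sqrt(sigma2 * xtxinv_score)
    coef_mat[, j] <- fit_coef[2, ]
    t_mat[, j] <- ifelse(se > 0, fit_coef[2, ] / se,
                         sign(fit_coef[2, ]) * Inf)
  }
  sm <- make_stat_map(t_mat, df = n - k, labels = dimnames(arr)[[3]],
                      alpha = alpha, fdr_family = fdr_family)
  sm$coef <- coef_mat
  sm$score <- score_name
  sm
}

#' Cohen's d from a two-group t statistic
#'
#' d = t * sqrt(1/n1 + 1/n2); linear in t and symmetric in the group sizes.
#'
#' @param t t statistic.
#' @param n1,n2 group sizes (>= 2).
#' @return Cohen's d (full precision; round to 2 decimals for reporting).
#' @examples
#' round(cohens_d_from_t(2.51, 20, 20), 2)  # 0.79
#' @export
cohens_d_from_t <- function(t, n1, n2) {
  if (any(c(n1, n2) < 2))
    stop_thalcor("group sizes must be at least 2",
                 class = "thalcor_validation_error")
  t * sqrt(1 / n1 + 1 / n2)
}

#' Connected-cluster summary of a significance map
#'
#' Groups FDR-flagged thalamic voxels into connected components under
#' 6-connectivity (face neighbours only, the most conservative standard
#' choice), separately per network and sign, and labels each cluster by the
#' majority label of an integer-labelled volume (e.g. thalamic subdivisions).
#'
#' @param statmap a `stat_map` carrying `thal_coords`.
#' @param label_volume integer 3-D array on the same grid.
#' @param thal_coords voxel coordinates (rows matching the map's voxel rows);
#'   defaults to the map's own table.
#' @return data.frame: network, direction, cluster, size, peak_t,
#'   majority_label.
#' @export
summarize_clusters <- function(statmap, label_volume, thal_coords = NULL) {
  stopifnot(inherits(statmap, "stat_map"))
  coords <- thal_coords %||% statmap$thal_coords
  if (is.null(coords))
    stop_thalcor("no thalamic voxel coordinates available",
                 class = "thalcor_validation_error")
  coords <- as.matrix(coords)
  if (nrow(coords) != nrow(statmap$t))
    stop_thalcor("coordinate table does not match the map's voxel count",
                 class = "thalcor_validation_error")
  if (max(coords) > max(dim(label_volume)))
    stop_thalcor("label volume grid does not cover the coordinates",
                 class = "thalcor_validation_error")
  out <- list()
  key <- paste(coords[, 1], coords[, 2], coords[, 3])
  for (j in seq_len(ncol(statmap$t))) {
    for (dir in c(1, -1)) {
      sel <- which(statmap$flag[, j] & statmap$sign[, j] == dir)
      if (!length(sel)) next
      comp <- connected_components(coords[sel, , drop = FALSE])
      for (cl in unique(comp)) {
        vox <- sel[comp == cl]
        labs <- label_volume[coords[vox, , drop = FALSE]]
        tt <- statmap$t[vox, j]
        out[[length(out) + 1L]] <- data.frame(
          network = colnames(statmap$t)[j],
          direction = if (dir > 0) "hyper" else "hypo",
          cluster = cl, size = length(vox),
          peak_t = tt[which.max(abs(tt))],
          majority_label = as.integer(names(which.max(table(labs)))))
      }
    }
  }
  if (!length(out))
    return(data.frame(network = character(), direction = character(),
                      cluster = integer(), size = integer(),
                      peak_t = numeric(), majority_label = integer()))
  do.call(rbind, out)
}

## 6-connectivity connected components by label propagation over face
## neighbours; returns an integer component id per coordinate row.
connected_components <- function(coords) {
  n <- nrow(coords)
  key <- function(m) paste(m[, 1], m[, 2], m[, 3], sep = ",")
  lookup <- stats::setNames(seq_len(n), key(coords))
  offsets <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                   c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  comp <- integer(n); cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] > 0L) next
    cur <- cur + 1L
    queue <- i
    comp[i] <- cur
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      nb <- sweep(offsets, 2, as.numeric(coords[v, ]), `+`)
      hit <- lookup[key(nb)]
      hit <- hit[!is.na(hit)]
      new <- hit[comp[hit] == 0L]
      comp[new] <- cur
      queue <- c(queue, new)
    }
  }
  comp
}
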