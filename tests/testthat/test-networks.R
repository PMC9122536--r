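## Sparse non-Gaussian source maps for blind-source-separation tests.
make_sources <- function(n_sources, nvox, seed = 1) {
  set.seed(seed)
  s <- matrix(0, n_sources, nvox)
  width <- floor(nvox / n_sources)
  for (k in seq_len(n_sources)) {
    idx <- ((k - 1) * width + 1):(k * width)
    s[k, idx] <- rgamma(length(idx), shape = 1.5, scale = 2)
  }
  s
}

test_that("a rank-1 stack is recovered by a single component", {
  set.seed(7)
  map <- make_sources(1, 400)[1, ]
  a <- rnorm(30)
  x <- outer(a, map)
  cs <- decompose_ica(x, n_components = 1, seed = 3)
  expect_gte(abs(cor(cs$maps[1, ], map)), 0.999)
})

test_that("ICA separates sparse non-Gaussian maps mixed into a stack", {
  set.seed(8)
  s <- make_sources(3, 600, seed = 8)
  a <- matrix(rnorm(60 * 3), 60, 3)
  x <- a %*% s + matrix(rnorm(60 * 600, 0, 0.05), 60, 600)
  cs <- decompose_ica(x, n_components = 3, seed = 5)
  rtab <- abs(cor(t(cs$maps), t(s)))
  ## after greedy matching every true map has a dedicated component
  expect_true(all(apply(rtab, 2, max) >= 0.95))
  expect_equal(sort(apply(rtab, 2, which.max)), 1:3)

  ## unit-variance sources with non-negative spatial skewness
  expect_equal(unname(rowMeans(cs$maps^2)), rep(1, 3), tolerance = 1e-6)
  expect_true(all(rowMeans(cs$maps^3) >= 0))

  ## reconstruction explains nearly all stack variance
  xc <- x - rowMeans(x)
  recon <- cs$mixing %*% cs$maps
  expect_gte(1 - sum((xc - recon)^2) / sum(xc^2), 0.95)

  ## deterministic under a fixed seed
  cs2 <- decompose_ica(x, n_components = 3, seed = 5)
  expect_identical(cs$maps, cs2$maps)
})

test_that("ICA input validation and convergence guards fire", {
  x <- matrix(rnorm(20), 4, 5)
  expect_error(decompose_ica(x, n_components = 6),
               class = "thalcor_validation_error")
  s <- make_sources(2, 200, seed = 2)
  x2 <- matrix(rnorm(10 * 2), 10, 2) %*% s
  expect_error(decompose_ica(x2, n_components = 2, seed = 1, max_iter = 1,
                             tol = 1e-12),
               class = "thalcor_convergence_error")
})

test_that("template matching is greedy, one-to-one, and thresholded", {
  s <- make_sources(3, 500, seed = 4)
  a <- matrix(rnorm(45 * 3), 45, 3)
  cs <- decompose_ica(a %*% s + matrix(rnorm(45 * 500, 0, 0.05), 45, 500),
                      n_components = 3, seed = 2)
  templates <- t(s)
  colnames(templates) <- c("alpha", "beta", "gamma")
  lab <- match_components(cs, templates)
  expect_equal(lab$labels, c("alpha", "beta", "gamma"))
  expect_true(all(abs(lab$match_r) >= 0.9))
  ## label order follows the template order
  for (j in 1:3)
    expect_gte(abs(cor(lab$maps[j, ], templates[, j])), 0.9)

  ## a duplicated template cannot reuse the same component
  dup <- templates[, c(1, 1, 2)]
  colnames(dup) <- c("a1", "a2", "b")
  lab2 <- match_components(cs, dup, min_match_r = 0)
  expect_equal(anyDuplicated(lab2$labels), 0L)
  expect_equal(length(lab2$labels), 3L)

  ## below-threshold assignments stay unlabelled
  noise_t <- matrix(rnorm(500), ncol = 1)
  colnames(noise_t) <- "junk"
  lab3 <- match_components(cs, noise_t, min_match_r = 0.3)
  expect_equal(length(lab3$labels), 0L)

  expect_error(match_components(cs, cbind(templates, templates)),
               class = "thalcor_validation_error")
})

test_that("voxel betas solve the per-voxel least-squares problem", {
  set.seed(10)
  nvox <- 200
  ## orthogonal zero-mean component maps
  m1 <- rep(c(1, -1), length.out = nvox)
  m2 <- rep(c(1, 1, -1, -1), length.out = nvox)
  maps <- rbind(m1 / sd(m1), m2 / sd(m2))
  cs <- structure(list(maps = maps, labels = c("n1", "n2")),
                  class = "component_set")
  z <- rbind(2 * maps[1, ], 0.5 * maps[2, ] + 3)
  b <- voxel_network_betas(z, cs)
  expect_equal(unclass(b), rbind(c(2, 0), c(0, 0.5)),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(colnames(b), c("n1", "n2"))

  ## random instance against the explicit normal-equations solution
  z2 <- matrix(rnorm(9 * nvox), 9, nvox)
  b2 <- voxel_network_betas(z2, cs)
  X <- cbind(1, t(maps))
  oracle <- t(solve(crossprod(X), crossprod(X, t(z2)))[-1, ])
  expect_equal(unclass(b2), oracle, tolerance = 1e-10, ignore_attr = TRUE)

  ## nine selected networks give nine betas per voxel
  s9 <- make_sources(9, 900, seed = 9)
  cs9 <- structure(list(maps = s9, labels = paste0("net", 1:9)),
                   class = "component_set")
  b9 <- voxel_network_betas(matrix(rnorm(4 * 900), 4, 900), cs9)
  expect_equal(dim(b9), c(4L, 9L))

  ## collinear maps are rejected
  csc <- structure(list(maps = rbind(m1, m1 * 2), labels = c("a", "b")),
                   class = "component_set")
  expect_error(voxel_network_betas(z, csc),
               class = "thalcor_collinearity_error")
})

test_that("labelled networks are stable across ICA seeds on a tiny cohort", {
  co <- tiny_cohort()
  r1 <- suppressWarnings(analyze_cohort(co, tiny_params(seed = 1)))
  r2 <- suppressWarnings(analyze_cohort(co, tiny_params(seed = 99)))
  common <- intersect(r1$components$labels, r2$components$labels)
  expect_gte(length(common), 2L)
  for (nw in common) {
    m1 <- r1$components$maps[match(nw, r1$components$labels), ]
    m2 <- r2$components$maps[match(nw, r2$components$labels), ]
    expect_gte(abs(cor(m1, m2)), 0.95)
  }
})

test_that("mean betas peak on the coupled network and track group factors", {
  hyper_ok <- hypo_ok <- logical(0)
  frac_correct <- numeric(0)
  for (seed in 1:3) {
    co <- simulate_cohort(sim_preset("tiny", seed = seed, noise_sd = 0.6))
    res <- suppressWarnings(analyze_cohort(co, tiny_params()))
    subdiv <- co$geometry$subdiv_labels[co$geometry$thal_mask]
    nets <- paste0("network", co$config$subdiv_networks)
    sel <- match(intersect(nets, colnames(res$betas[[1]])), colnames(res$betas[[1]]))
    avg <- Reduce(`+`, lapply(res$betas, unclass)) / length(res$betas)
    correct <- vapply(seq_len(nrow(avg)), function(v) {
      want <- nets[subdiv[v]]
      want %in% colnames(avg) && colnames(avg)[which.max(avg[v, ])] == want
    }, TRUE)
    frac_correct <- c(frac_correct, mean(correct))
    ## group factors < 1 / > 1 move patient betas down / up
    ph <- res$subjects
    pats <- ph$subject_id[ph$group == "patient"]
    cons <- ph$subject_id[ph$group == "control"]
    bp <- Reduce(`+`, lapply(res$betas[pats], unclass)) / length(pats)
    bc <- Reduce(`+`, lapply(res$betas[cons], unclass)) / length(cons)
    fac <- co$config$patient_factors
    for (sdv in seq_along(fac)) {
      nw <- nets[sdv]
      if (!nw %in% colnames(bp)) next
      d <- mean(bp[subdiv == sdv, nw] - bc[subdiv == sdv, nw])
      if (fac[sdv] < 1) hypo_ok <- c(hypo_ok, d < 0)
      if (fac[sdv] > 1) hyper_ok <- c(hyper_ok, d > 0)
    }
  }
  expect_gte(mean(frac_correct), 0.9)
  expect_true(all(hypo_ok))
  expect_true(all(hyper_ok))
})
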