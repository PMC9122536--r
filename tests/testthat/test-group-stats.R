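mk_beta <- function(values, labels = "net1") {
  m <- matrix(values, ncol = length(labels))
  colnames(m) <- labels
  structure(m, class = c("beta_map", "matrix", "array"))
}

test_that("one-sample t map matches the hand-computed statistic", {
  bms <- lapply(c(1, 2, 3), mk_beta)
  sm <- one_sample_tmap(bms)
  expect_equal(unname(sm$t[1, 1]), 2 / (1 / sqrt(3)))
  expect_equal(round(unname(sm$t[1, 1]), 4), 3.4641)
  expect_equal(sm$df, 2)
  expect_equal(unname(sm$p[1, 1]),
               2 * pt(3.4641016, df = 2, lower.tail = FALSE),
               tolerance = 1e-6)

  ## all-zero betas: sentinel, never flagged
  expect_warning(sm0 <- one_sample_tmap(lapply(c(0, 0, 0), mk_beta)),
                 "zero-variance")
  expect_false(any(sm0$flag))

  expect_error(one_sample_tmap(bms[1:2]), class = "thalcor_validation_error")
})

test_that("one-sample t against t.test on random instances", {
  set.seed(14)
  for (i in 1:20) {
    vals <- rnorm(5 + i %% 4)
    sm <- one_sample_tmap(lapply(vals, mk_beta))
    tt <- t.test(vals)
    expect_equal(unname(sm$t[1, 1]), unname(tt$statistic), tolerance = 1e-10)
    expect_equal(unname(sm$p[1, 1]), tt$p.value, tolerance = 1e-10)
  }
})

test_that("null betas keep the one-sample false-positive rate near alpha", {
  set.seed(15)
  n_sub <- 40; n_vox <- 400
  bms <- lapply(seq_len(n_sub), function(i) mk_beta(rnorm(n_vox)))
  arr_p <- one_sample_tmap(bms)$p
  ## uncorrected type-I at 5% within binomial error
  expect_lt(abs(mean(arr_p <= 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / n_vox))
})

test_that("paired difference map is the one-sample map of within-pair differences", {
  bp <- lapply(c(2, 4, 6), mk_beta)
  bc <- lapply(c(1, 2, 3), mk_beta)
  sm <- paired_difference_map(bp, bc)
  expect_equal(round(unname(sm$t[1, 1]), 4), 3.4641)  # diffs (1, 2, 3)
  expect_equal(sm$df, 2)
  expect_equal(unname(sm$sign[1, 1]), 1)

  suppressWarnings(same <- paired_difference_map(bp, bp))
  expect_true(all(is.nan(same$t)) || all(same$t == 0, na.rm = TRUE))
  expect_false(any(same$flag))

  names(bp) <- paste0("P", 1:3); names(bc) <- paste0("C", 1:3)
  pairing <- data.frame(patient = c("P1", "P2", "P4"),
                        control = c("C1", "C2", "C3"))
  expect_error(paired_difference_map(bp, bc, pairing),
               class = "thalcor_validation_error")
})

test_that("brain-behaviour regression reports the score coefficient", {
  set.seed(16)
  n <- 12
  ph <- data.frame(subject_id = sprintf("P%02d", 1:n), group = "patient",
                   pair_id = sprintf("pair%02d", 1:n),
                   age = runif(n, 6, 20), sex = "M", lesion_side = "left",
                   lesion_frac = runif(n, 0.001, 0.05),
                   score_wm_raw = rnorm(n))
  score <- ph$score_wm_raw
  bms <- lapply(seq_len(n), function(i) mk_beta(score[i]))
  names(bms) <- ph$subject_id
  sm <- brain_behavior_map(bms, ph, "score_wm_raw")
  expect_equal(unname(sm$coef[1, 1]), 1, tolerance = 1e-8)

  ## random case against an independent lm fit
  bms2 <- lapply(seq_len(n), function(i) mk_beta(rnorm(3)))
  names(bms2) <- ph$subject_id
  sm2 <- brain_behavior_map(bms2, ph, "score_wm_raw")
  for (v in 1:3) {
    y <- sapply(bms2, function(b) unclass(b)[v, 1])
    fit <- summary(lm(y ~ score + age + lesion_frac, data = ph))
    expect_equal(unname(sm2$coef[v, 1]), fit$coefficients["score", 1],
                 tolerance = 1e-10)
    expect_equal(unname(sm2$t[v, 1]), fit$coefficients["score", 3],
                 tolerance = 1e-10)
  }
  expect_equal(sm2$df, n - 4)

  ## a zero-variance covariate is dropped with a warning
  ph3 <- ph; ph3$age <- 10
  expect_warning(brain_behavior_map(bms2, ph3, "score_wm_raw"),
                 "zero-variance")
})

test_that("the score coefficient keeps its type-I level under the null", {
  set.seed(17)
  n <- 20; reps <- 100
  hits <- 0
  for (r in seq_len(reps)) {
    ph <- data.frame(subject_id = sprintf("P%02d", 1:n), group = "patient",
                     pair_id = sprintf("pair%02d", 1:n),
                     age = runif(n, 6, 20), sex = "M", lesion_side = "left",
                     lesion_frac = runif(n, 0, 0.05),
                     score_wm_raw = rnorm(n))
    bms <- lapply(seq_len(n), function(i) mk_beta(rnorm(1)))
    names(bms) <- ph$subject_id
    sm <- brain_behavior_map(bms, ph, "score_wm_raw")
    hits <- hits + (sm$p[1, 1] <= 0.05)
  }
  expect_gte(reps - hits, 93 * reps / 100 - 2 * sqrt(reps * 0.05 * 0.95))
})

test_that("FDR correction follows the step-up rule", {
  fc <- fdr_correct(c(0.01, 0.02, 0.03, 0.04), alpha = 0.05)
  expect_true(all(fc$reject))
  expect_equal(fc$q, c(0.04, 0.04, 0.04, 0.04))

  fc1 <- fdr_correct(rep(1, 5))
  expect_false(any(fc1$reject))
  expect_true(all(fc1$q == 1))

  fc2 <- fdr_correct(0.04)
  expect_equal(fc2$q, 0.04)
  expect_true(fc2$reject)

  ## NA p values (sentinel voxels) propagate and never reject
  fc3 <- fdr_correct(c(0.01, NA, 0.5))
  expect_true(is.na(fc3$q[2]) && !fc3$reject[2])

  expect_error(fdr_correct(c(0.5, 1.2)), class = "thalcor_validation_error")

  ## q is never below p
  set.seed(18)
  p <- runif(50)
  expect_true(all(fdr_correct(p)$q >= p))
})

test_that("Cohen's d from t matches the reported group comparison", {
  expect_equal(round(cohens_d_from_t(2.51, 20, 20), 2), 0.79)
  expect_equal(cohens_d_from_t(0, 10, 12), 0)
  expect_equal(round(cohens_d_from_t(2.05, 20, 20), 4), 0.6483)
  ## linear in t, symmetric in group sizes
  expect_equal(cohens_d_from_t(3, 8, 14), 3 * cohens_d_from_t(1, 8, 14))
  expect_equal(cohens_d_from_t(1.7, 8, 14), cohens_d_from_t(1.7, 14, 8))
  expect_error(cohens_d_from_t(1, 1, 20), class = "thalcor_validation_error")
})

test_that("cluster summaries use 6-connectivity and majority labels", {
  coords <- as.matrix(expand.grid(dim1 = 1:4, dim2 = 1:4, dim3 = 1:2))
  nvox <- nrow(coords)
  t_mat <- matrix(0.1, nvox, 1); colnames(t_mat) <- "net1"
  sm <- thalcor:::make_stat_map(t_mat, df = 9, labels = "net1", alpha = 0.05,
                                thal_coords = coords)
  labels <- array(1L, dim = c(4, 4, 2))

  expect_equal(nrow(summarize_clusters(sm, labels)), 0L)

  ## one 5-voxel block inside label 2
  block <- which(coords[, "dim1"] <= 2 & coords[, "dim2"] <= 3 &
                   coords[, "dim3"] == 1)[1:5]
  sm$flag[block, 1] <- TRUE
  sm$sign[block, 1] <- 1
  sm$t[block, 1] <- c(3, 5, 4, 3.5, 3.2)
  labels[coords[block, , drop = FALSE]] <- 2L
  tab <- summarize_clusters(sm, labels)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$size, 5L)
  expect_equal(tab$peak_t, 5)
  expect_equal(tab$majority_label, 2L)
  expect_equal(tab$direction, "hyper")

  ## diagonal neighbours are separate clusters under 6-connectivity
  sm2 <- thalcor:::make_stat_map(t_mat, df = 9, labels = "net1", alpha = 0.05,
                                 thal_coords = coords)
  diagpair <- c(which(coords[, 1] == 1 & coords[, 2] == 1 & coords[, 3] == 2),
                which(coords[, 1] == 2 & coords[, 2] == 2 & coords[, 3] == 2))
  sm2$flag[diagpair, 1] <- TRUE
  sm2$sign[diagpair, 1] <- 1
  tab2 <- summarize_clusters(sm2, array(1L, dim = c(4, 4, 2)))
  expect_equal(nrow(tab2), 2L)
  expect_true(all(tab2$size == 1L))
})
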