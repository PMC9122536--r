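test_that("network maps are disjoint, non-negative, and cover the geometry", {
  cfg <- sim_config(n_networks = 2, n_subdiv = 2, n_patients = 1,
                    n_controls = 1)
  g <- make_network_maps(cfg)
  expect_length(g$maps, 2L)
  m <- sapply(g$maps, function(x) x[g$brain_mask & !g$thal_mask])
  expect_true(all(m >= 0))
  expect_lte(abs(cor(m[, 1], m[, 2])), 0.2)

  ## K = 1: degenerate single-network case, one subdivision label
  cfg1 <- sim_config(n_networks = 1, n_subdiv = 1, patient_factors = 0.5,
                     behaviour = list(s = list(intercept = 0, slope = 1,
                                               noise_sd = 1, subdivisions = 1)),
                     n_patients = 1, n_controls = 1)
  g1 <- make_network_maps(cfg1)
  expect_length(g1$maps, 1L)
  expect_equal(sort(unique(g1$subdiv_labels[g1$thal_mask])), 1L)

  ## K = 5 on the default grid: zero pairwise overlap of peak regions
  cfg5 <- sim_config(n_networks = 5, n_patients = 1, n_controls = 1)
  g5 <- make_network_maps(cfg5)
  supports <- sapply(g5$maps, function(x) x > 0)
  overlap <- crossprod(supports)
  expect_true(all(overlap[upper.tri(overlap)] == 0))

  ## every thalamic voxel belongs to exactly one subdivision
  expect_true(all(g5$subdiv_labels[g5$thal_mask] %in% 1:4))
  expect_true(all(g5$subdiv_labels[!g5$thal_mask] == 0))

  ## a grid too small for the requested networks raises a sizing error
  expect_error(make_network_maps(sim_config(grid = c(10, 10, 10),
                                            thal_dim = c(4, 4, 4),
                                            n_networks = 8,
                                            n_patients = 1, n_controls = 1)),
               class = "thalcor_sizing_error")
})

test_that("subject runs follow the coupling model in the low-noise limit", {
  cfg <- sim_preset("tiny", seed = 3, noise_sd = 1e-9,
                    spikes = list(n_per_subject = 0, translation_mm = 0,
                                  intensity_pct = 0))
  geom <- make_network_maps(cfg)
  truth <- thalcor:::make_truth(cfg, geom)
  sub <- make_subject_run(cfg, 3, "control", truth, geom)
  thal_idx <- which(geom$thal_mask, arr.ind = TRUE)
  v <- thal_idx[1, ]
  subdiv <- geom$subdiv_labels[v[1], v[2], v[3]]
  net <- cfg$subdiv_networks[subdiv]
  series <- sub$run$data[v[1], v[2], v[3], ]
  expect_gte(cor(series, sub$timecourses[, net]), 1 - 1e-9)

  expect_error(make_subject_run(cfg, 1, "sibling", truth, geom),
               class = "thalcor_validation_error")
})

test_that("motion spikes raise FD above threshold at the scheduled frames", {
  cfg <- sim_preset("tiny", seed = 5,
                    spikes = list(n_per_subject = 1, translation_mm = 0.5,
                                  intensity_pct = 2))
  geom <- make_network_maps(cfg)
  truth <- thalcor:::make_truth(cfg, geom)
  sub <- make_subject_run(cfg, 1, "patient", truth, geom)
  fd <- framewise_displacement(sub$motion)
  expect_true(all(fd[sub$spike_frames] > 0.2))
})

test_that("lesions are unilateral ellipsoids carrying no network coupling", {
  cfg <- sim_preset("tiny", seed = 9, lesion = list(radii = c(2, 3, 2),
                                                    right_fraction = 0))
  co <- simulate_cohort(cfg)
  mid <- (cfg$grid[1] + 1) / 2
  for (id in c("P01", "P02")) {
    les <- co$lesions[[id]]
    expect_gt(sum(les), 0)
    lc <- which(les, arr.ind = TRUE)
    expect_true(all(lc[, 1] < mid))   # all left-hemisphere voxels
    ## lesion series are pure noise: no correlation with any network
    sub <- make_subject_run(cfg, match(id, co$truth$ids), "patient",
                            co$truth, co$geometry)
    v <- lc[1, ]
    series <- sub$run$data[v[1], v[2], v[3], ]
    rs <- abs(cor(series, sub$timecourses))
    expect_true(all(rs < 0.5))
  }
  ## expected ellipsoid volume for the configured radii
  expect_lte(abs(sum(co$lesions[["P01"]]) - 4 / 3 * pi * 2 * 3 * 2), 20)
})

test_that("lesion-voxel network correlations are centred on zero", {
  cfg <- sim_preset("tiny", seed = 31)
  co <- simulate_cohort(cfg)
  rs <- c()
  for (id in c("P01", "P02")) {
    sub <- make_subject_run(cfg, match(id, co$truth$ids), "patient",
                            co$truth, co$geometry)
    lc <- which(co$lesions[[id]], arr.ind = TRUE)
    for (i in seq_len(min(10, nrow(lc)))) {
      v <- lc[i, ]
      rs <- c(rs, cor(sub$run$data[v[1], v[2], v[3], ], sub$timecourses))
    }
  }
  expect_lt(abs(mean(rs)), 0.1)
})

test_that("cohort counts, pairing, and determinism hold", {
  cfg <- sim_preset("tiny", seed = 77, n_patients = 20, n_controls = 20)
  co <- simulate_cohort(cfg)
  expect_length(co$runs, 40L)
  expect_equal(nrow(co$subjects), 40L)
  expect_equal(sum(co$subjects$group == "patient"), 20L)
  pairing <- phenotype_pairing(co$subjects)
  expect_equal(nrow(pairing), 20L)

  ## same seed twice: byte-identical phenotype TSV
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  cfg_t <- sim_preset("tiny", seed = 12)
  simulate_cohort(cfg_t, dir = d1)
  simulate_cohort(cfg_t, dir = d2)
  expect_identical(readBin(file.path(d1, "phenotypes.tsv"), "raw", 1e6),
                   readBin(file.path(d2, "phenotypes.tsv"), "raw", 1e6))
  ## volumes identical within floating tolerance
  a1 <- read_volume(file.path(d1, "sub-P01_bold.nii.gz"))
  a2 <- read_volume(file.path(d2, "sub-P01_bold.nii.gz"))
  expect_equal(as.vector(a1), as.vector(a2), tolerance = 1e-12)
})

test_that("zero behaviour slope decouples scores from coupling", {
  cfg <- sim_preset("tiny", seed = 1, n_patients = 20, n_controls = 20)
  geom <- make_network_maps(cfg)
  rs <- sapply(1:100, function(i) {
    cfg_i <- sim_preset("tiny", seed = 1000 + i, n_patients = 20,
                        n_controls = 20)
    truth <- thalcor:::make_truth(cfg_i, geom)
    link <- cfg_i$behaviour$flexibility$subdivisions
    cor(truth$scores$flexibility,
        rowMeans(truth$coupling[, link, drop = FALSE]))
  })
  expect_gte(mean(abs(rs) <= 0.3), 0.8)
  expect_lt(abs(mean(rs)), 0.1)
})

test_that("coupled network time courses dominate thalamic voxel series", {
  ## identifiability at noise sd = amplitude / 2 and 150 frames
  ok <- numeric(0)
  for (seed in 1:10) {
    cfg <- sim_config(frames = 150, noise_sd = 0.6, amplitude = 1.2,
                      spikes = list(n_per_subject = 0, translation_mm = 0,
                                    intensity_pct = 0),
                      n_patients = 1, n_controls = 1, seed = seed)
    geom <- if (seed == 1) make_network_maps(cfg) else geom
    truth <- thalcor:::make_truth(cfg, geom)
    sub <- make_subject_run(cfg, 2, "control", truth, geom)
    tidx <- which(geom$thal_mask, arr.ind = TRUE)
    subdiv <- geom$subdiv_labels[geom$thal_mask]
    nets <- cfg$subdiv_networks[subdiv]
    flat <- apply(tidx, 1, function(v) sub$run$data[v[1], v[2], v[3], ])
    rmat <- abs(cor(flat, sub$timecourses))
    ok <- c(ok, mean(max.col(rmat) == nets))
  }
  expect_gte(mean(ok), 0.95)
})

test_that("fixture sets are pinned by checksums", {
  d1 <- withr::local_tempdir()
  sums1 <- write_fixture_set("tiny", d1)
  expect_equal(sum(grepl("_bold\\.nii\\.gz$", names(sums1))), 4L)

  d2 <- withr::local_tempdir()
  sums2 <- write_fixture_set("tiny", d2)
  expect_identical(unname(sums1), unname(sums2))

  expect_error(write_fixture_set("medium", withr::local_tempdir()),
               class = "thalcor_validation_error")
})

test_that("simulation config invariants are enforced", {
  expect_error(sim_config(n_patients = 0), class = "thalcor_validation_error")
  expect_error(sim_config(noise_sd = 0), class = "thalcor_validation_error")
  expect_error(sim_config(subdiv_networks = c(1, 9, 2, 3)),
               class = "thalcor_validation_error")
  expect_error(sim_config(patient_factors = c(1, 1)),
               class = "thalcor_validation_error")
  expect_error(sim_config(thal_dim = c(30, 8, 4)),
               class = "thalcor_sizing_error")
})
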