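## Shared fixtures, built once per test run and cached in this environment.
.fixtures <- new.env(parent = emptyenv())

tiny_cohort <- function(seed = 42) {
  key <- paste0("tiny_", seed)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- simulate_cohort(sim_preset("tiny", seed = seed))
  .fixtures[[key]]
}

tiny_params <- function(...) {
  args <- list(...)
  if (is.null(args$n_components)) args$n_components <- 3
  if (is.null(args$seed)) args$seed <- 7
  do.call(pipeline_config, args)
}

small_params <- function(...) {
  args <- list(...)
  if (is.null(args$n_components)) args$n_components <- 5
  if (is.null(args$seed)) args$seed <- 7
  do.call(pipeline_config, args)
}

## A minimal bold_run with iid noise, for unit tests that do not need
## network structure.
noise_run <- function(dim3 = c(6, 6, 6), frames = 40, mean = 100, sd = 1,
                      seed = 1) {
  set.seed(seed)
  data <- array(stats::rnorm(prod(dim3) * frames, mean, sd),
                dim = c(dim3, frames))
  bold_run(data, array(TRUE, dim3))
}

## Brute-force Benjamini-Hochberg step-up, straight from the definition.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- rep(NA_real_, m)
  prev <- 1
  for (i in m:1) {
    val <- min(prev, p[o[i]] * m / i)
    q[o[i]] <- val
    prev <- val
  }
  q
}

## Paired/one-sample recovery metrics for a paired stat map against the
## generator's ground truth.
recovery_metrics <- function(statmap, cohort) {
  cfg <- cohort$config
  sd_lab <- cohort$geometry$subdiv_labels[cohort$geometry$thal_mask]
  truthnet <- cfg$subdiv_networks[sd_lab]
  fac <- cfg$patient_factors
  tp <- fp <- 0
  for (j in seq_len(ncol(statmap$flag))) {
    f <- statmap$flag[, j]
    sg <- statmap$sign[, j]
    istrue <- truthnet == j & fac[sd_lab] != 1
    want <- sign(fac[sd_lab] - 1)
    tp <- tp + sum(f & istrue & sg == want)
    fp <- fp + sum(f & !(istrue & sg == want))
  }
  c(sensitivity = tp / sum(fac[sd_lab] != 1),
    fdp = fp / max(tp + fp, 1))
}
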