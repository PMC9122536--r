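---
title: "Mapping lesion-aware thalamo-cortical connectivity: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping lesion-aware thalamo-cortical connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thalcor)
```

## The analysis in one paragraph

The thalamus is a hub whose sub-nuclei couple to distinct cortical
resting-state networks; after a focal ischaemic lesion this coupling can
weaken or strengthen, and its strength relates to cognitive outcome. The
package estimates that coupling from resting-state BOLD runs in a cohort of
patients with unilateral lesions and matched controls. Per subject it (i)
flips right-lesion subjects across the midsagittal plane so all lesions share
a hemisphere, (ii) scales intensities to the mode-1000 convention (10 units =
1% BOLD), (iii) censors high-motion frames (FD > 0.2 mm or DVARS > 0.38%),
(iv) removes the lesion from the analysis mask so connectivity is measured in
healthy tissue only, (v) residualizes every voxel on 27 nuisance regressors
(24 motion-derived indices plus CSF, white-matter and global signals), and
(vi) correlates every thalamic voxel with every voxel of the rest of the
brain, Fisher-transforming the Pearson correlations
(\(z = \tfrac12\log\frac{1+r}{1-r}\)). The per-subject seed maps are stacked
across subjects and decomposed by spatial ICA; components are labelled
against template network maps; each thalamic voxel's seed map is regressed
on the labelled component maps, giving one beta per network per voxel — the
connectivity-strength measure. Group inference is voxelwise: one-sample t
maps, paired patient–control differences, and per-score brain–behaviour
regressions with age and lesion-size fraction as covariates, all with
Benjamini–Hochberg FDR control at 0.05 per network.

## The model the simulator implements

Ground-truth cohorts make every stage testable. The generative model is

\[ I(v, t) = B(v) + A \sum_k M_k(v)\, a_k(t)\, c_{s, \mathrm{sub}(v)} + \varepsilon(v, t), \]

where \(B(v)\) is a baseline around 800 raw units with a mild spatial
gradient (so mode-1000 scaling is a real operation), \(M_k\) are K disjoint
bilateral Gaussian blob maps (peak 1), \(a_k(t)\) are unit-variance AR(1)
time courses with coefficient 0.3 (the simplest autocorrelated stand-in for
band-limited BOLD — no haemodynamic model is attempted), and
\(\varepsilon\) is white Gaussian noise. Cortical voxels mix all networks
through \(M_k\); thalamic voxels follow only their subdivision's network,
scaled by the subject's coupling \(c_{s,\cdot}\) (mean 1 in controls,
multiplied by per-subdivision group factors in patients — 0.5 and 1.5 by
default, so hypo- and hyper-connectivity are both present). The thalamus is
a central block split into contiguous slabs along the anterior–posterior
axis, mimicking anterior/medial/lateral/posterior nuclei groups; real
nucleus geometry is not reproduced. Patients carry a unilateral ellipsoidal
lesion whose voxels contain pure noise. Motion spikes add a step to the
realignment trace and a simultaneous in-brain intensity step, so the
geometric (FD) and physiological (DVARS) criteria flag the same frames.
Cognitive raw scores are linear in the subject's mean coupling over a
designated subdivision set plus Gaussian noise; scaled twins are linear
rescalings.

### Why these default numbers

* **Amplitude 1.2, noise SD 1.2 (ratio 1).** At high SNR the Fisher-z seed
  maps saturate: a coupling increase of 1.5x changes z barely at all while a
  0.5x decrease is enormous, making the hyper-connectivity direction
  untestable. A ratio of 1 (thalamic r ≈ 0.71 at control coupling) balances
  the detectability of both directions. The same noise level keeps
  clean-frame DVARS near 0.25%, safely under the 0.38% censoring threshold,
  so the flagged-frame set equals the injected spike schedule.
* **Between-subject coupling SD 0.10.** Large enough to make subjects
  heterogeneous, small enough that the paired design retains power at 10
  pairs.
* **Behaviour slope 10, noise 1.33.** With coupling SD 0.10 this puts the
  true score–coupling correlation near 0.6; the flexibility score has slope
  0, mirroring a cognitive domain with no connectivity association.
* **One uncoupled cortical network per preset** (tiny: 3 networks for 2
  subdivisions; small: 5 for 4). Global signal regression removes one
  dimension of the network time-course space; if every network were coupled
  to the thalamus, the seed maps would span only K−1 contrasts and no
  decomposition could separate them. The spare network keeps the coupled
  ones identifiable — and resembles reality, where not every cortical
  network has a strong thalamic representation.
* **Blob geometry.** Networks are mirror-symmetric blob pairs on a ring
  around the midline, so the midsagittal flip leaves true maps invariant
  (real networks are largely bilateral). The generator verifies that blob
  supports are pairwise disjoint and clear of the thalamus and tissue boxes,
  and raises a sizing error otherwise.

## What passing tests do and do not show

The simulator emulates the statistical structure the analysis assumes:
network-structured autocorrelated signal, coupling differences in both
directions, censorable motion artefacts, lesions as signal voids, and
score–coupling links. It does not emulate haemodynamic response shapes,
scanner drift or physiological noise spectra, spatial autocorrelation of
thermal noise, registration error, or realistic lesion shapes. Recovery on
these cohorts therefore demonstrates the correctness of the estimator chain,
not its field performance on real scanner data.

## Numerical and procedural choices

* **Mode-1000 norm statistic**: median of in-mask per-voxel mean intensities
  — a binning-free stand-in for the intensity mode; the empirical mode
  depends on histogram binning.
* **Motion-parameter lag**: the lagged columns are zero-filled at frame 1,
  matching the backward-difference convention that frame 1 has no
  predecessor (FD and DVARS are defined as 0 there, and the first frame is
  kept by default).
* **Censoring**: frames are dropped, not interpolated; the default is
  flag-only censoring (no neighbour extension), with `extend_before` /
  `extend_after` exposed for stricter scrubbing protocols. At least half the
  run must survive, because correlation estimates below that are unstable.
  The 0.38 DVARS threshold is interpreted on the percent scale (mean
  in-brain intensity rescaled to 100); the threshold is configurable because
  the units convention is ambiguous in the censoring literature.
* **"Rest of the brain"**: thalamus-mask voxels are excluded from the brain
  columns of the seed maps (configurable), preventing trivial
  self-correlations from dominating the ICA.
* **Uniform voxel indexing**: zero-variance series (fully censored or
  lesion-excluded voxels) map to z = 0 instead of being dropped, so all
  subjects share one column indexing and concatenation is well defined; the
  per-subject analysis masks still exclude lesions from every statistic that
  feeds the maps (tissue means, global signal, residualization).
* **ICA**: PCA reduction via a seeded randomized SVD, then the fixed-point
  log-cosh negentropy iteration with symmetric decorrelation, at most 500
  iterations and tolerance 1e-4 (the long-standing default of the classic
  fastICA implementation; a tighter 1e-5 makes noise-dominated components
  oscillate indefinitely). Component signs are fixed to non-negative spatial
  skewness; ICA sign is otherwise arbitrary and betas would not be
  comparable across runs. The pipeline retries non-convergent
  decompositions with deterministically shifted seeds.
* **Network selection** is template-driven (greedy one-to-one matching by
  absolute spatial correlation, minimum 0.3): the original analysis
  identified well-known networks by expert inspection, which a pipeline
  cannot reproduce; synthetic truth maps serve as templates in tests and
  users supply template maps for real data.
* **Subject-level betas** regress each voxel's z map on an intercept plus
  the selected (labelled) component maps; the intercept absorbs map offsets
  and regressors are not standardized. Using all components instead is a
  config switch (`betas_on = "all"`); the selected-set reading matches the
  design's "nine beta values per voxel".
* **FDR family**: per network across thalamic voxels (per score for
  brain–behaviour maps), matching per-network thresholded maps; a global
  family is a config switch.
* **Degenerate inputs**: zero-variance voxels get sentinel t values and are
  never flagged; rank-deficient nuisance designs fall back to the pivoted
  least-squares projection with a warning; collinear component maps or
  covariates raise errors.
* **Cluster summaries** use 6-connectivity (face neighbours), the most
  conservative standard choice, with majority labels from any
  integer-labelled volume (synthetic subdivision labels in tests; a nucleus
  atlas label image on real data).
* **Paired design**: group cognition comparisons and difference maps use the
  matched-pair design implied by one-to-one age/sex matching and report
  df = n_pairs − 1. Published tables in this design space sometimes print
  other df conventions; the package reports its own.

## Problem sizes used in the tests

Tests and the acceptance script run two cohort presets chosen for
desk-scale reproducibility: `tiny` (2+2 subjects, 16x16x16 voxels, 60
frames) for smoke, determinism and null-control checks (50 replicates), and
`small` (10+10 subjects, 24x28x24, 200 frames) for parameter recovery (10
seeds), the lesion-mask control, and — with 20+20 subjects and coupling SD
0.5 — the brain–behaviour sign-recovery check. The brain–behaviour check
widens the coupling spread because with SD 0.10 the subject-level beta
estimation noise would swamp the coupling signal and no behaviour link would
be recoverable at n = 20; the slope/noise pair is then recalibrated so the
true score–beta correlation stays near 0.6.

## Known limitations

* Spatial registration, segmentation, slice timing and smoothing are out of
  scope; inputs are assumed co-registered on a common grid.
* The lesion-aware pipeline measures connectivity only in healthy tissue but
  does not model partial-volume effects at lesion borders.
* Component count is user-fixed (20 by default); no automatic dimensionality
  estimation is attempted.
* Inference is voxelwise FDR; cluster-extent and permutation inference are
  not implemented.
* Global signal regression removes one network dimension; analyses of
  cohorts where every modelled network couples to the thalamus will fold
  that dimension into the others (see the design note above).
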