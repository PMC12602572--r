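---
title: "Quantifying hemispheric laterality of resting-state connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying hemispheric laterality of resting-state connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemilat)
```

## The question and the measurement model

The two cerebral hemispheres are not functionally symmetric. A natural way
to quantify asymmetry from resting-state fMRI is to compute, for every
region of a parcellation that has a mirror-hemisphere counterpart, some
connectivity metric on the left member (`L`) and its homologue on the
right (`R`), and summarise their imbalance with the laterality index

$$LI = \frac{L - R}{L + R},$$

which is 0 under perfect symmetry, positive for leftward dominance and
negative for rightward dominance, and bounded in $[-1, 1]$ whenever both
inputs are nonnegative. hemilat implements this analysis end to end: ten
node-level metrics per region (seven binary-graph metrics — global and
local efficiency, betweenness centrality, average path length, clustering
coefficient, degree, cost — plus three voxel-based metrics aggregated to
regions: intrinsic connectivity IC, local correlation LCOR, and fALFF),
paired and one-sample t-tests per homologous pair with Bonferroni
correction and signed Cohen's d, and a direction-concordance report
between two independent cohorts.

The sign convention is fixed throughout: the paired contrast is `L - R`,
so a positive Cohen's d means leftward lateralisation.

## Pipeline stages and their parameters

**Timeseries denoising** (`preprocess_subject()`) follows the common
outlier-detection + nuisance-regression + band-pass recipe, in that fixed
order:

* framewise displacement (Power-style: sum of absolute backward
  differences, rotations scaled by a 50 mm head radius) with frames
  flagged strictly above 0.9 mm — the conservative preset of the widely
  used ART implementation, which is defined on this FD scale;
* global-signal outliers at |z| > 5 of the frame-to-frame change of the
  spatial mean, z-scored over the run;
* nuisance regressors: 5 white-matter and 5 CSF CompCor components
  (principal components of noise-region series orthogonalised against
  their average), 6 motion parameters and their backward differences, one
  spike regressor per flagged frame, a linear trend and a constant;
* band-pass 0.008–0.09 Hz. The default filter is a discrete-Fourier
  brick-wall filter applied to the full run: it is exactly reproducible
  and has a flat passband; a 4th-order zero-phase Butterworth is available
  via `method = "butterworth"` for users who prefer finite roll-off.

**Graph metrics** (`correlation_matrix()`, `threshold_graph()`,
`node_metrics()`): Pearson correlations are clipped at
$\pm(1-10^{-7})$ and Fisher-z transformed; the graph is built by
retaining the strongest positive edges at a fixed cost (default 0.15,
i.e. 15% of all possible edges), with deterministic lexicographic
tie-breaking. Publications in this area rarely state their adjacency
rule; fixed-cost thresholding keeps density comparable across subjects,
and the threshold is recorded in results metadata. Graphs are binary and
unweighted because the metric definitions used (inverse distances, edge
counts) presuppose unit edge lengths. Conventions for degenerate cases:
unreachable node pairs contribute 0 to efficiency; the average path
length of an isolated node is missing rather than 0 (a 0 would fake
better-than-perfect integration); clustering and local efficiency are 0
below degree 2; tied shortest paths share betweenness credit fractionally
(the Brandes resolution), normalised by $(N-1)(N-2)/2$.

**Voxel metrics** (`intrinsic_connectivity()`, `local_correlation()`,
`falff()`): IC is the root-mean-square of a voxel's correlations with all
other in-mask voxels, computed in a rank-64 SVD subspace of the z-scored
voxel-by-time matrix (with full rank this reduces exactly to the direct
computation — tested); LCOR is the Gaussian-weighted mean correlation
with the neighbourhood at 25 mm FWHM, distances in mm between voxel
centres at `(index + 0.5) * voxel_size`; fALFF is the ratio of
band-limited to broadband RMS, with the denominator deliberately taken
from the confound-regressed but *unfiltered* series, per its printed
definition. Self-correlations are excluded from the IC and LCOR sums:
including the constant 1 inflates both without information. This may
diverge from toolbox implementations whose edge handling is undocumented;
we state our choice rather than claim equivalence. When no voxel data are
available, an ROI-level fALFF computed on the region-mean series is
offered through `compute_node_metrics(..., metrics = "fALFF")` as the
voxel-free analogue.

**Statistics** (`paired_lr_tests()`, `li_one_sample_tests()`,
`concordance()`, `compare_demographics()`): two-sided tests at
$\alpha = 0.05$; Cohen's d is the standardised mean of differences
($d_z$), matching the paired-test machinery and carrying the
lateralisation sign. The Bonferroni divisor defaults to the *total number
of atlas regions* (132 in the full configuration) rather than the number
of homologous pairs — mirroring the common reporting convention of
dividing the alpha level by the region count — and is configurable; the
result object records both the divisor and the pair count. Cost and
degree differ by the constant $N-1$, so their tests are identical and are
best read as one family. Demographic comparisons use pooled-variance t
(Welch by option) and a Pearson chi-square without continuity correction,
with the phi coefficient for 2-level factors.

A practical caveat the package guards against: LI is unstable when
`L + R` approaches 0, which happens for metrics that can be negative
(e.g. Fisher-z summaries). Cells with $|L+R| < 10^{-12}$ are reported
missing rather than propagated as huge ratios; handling of this case is
rarely stated in the literature, so the guard threshold is our choice and
is documented here.

## What the synthetic-data generator emulates

Real multi-site cohorts of the sizes this analysis targets (on the order
of 100 subjects per cohort) are access-restricted, so every stage is
exercised against `simulate_cohort()`, whose defaults mirror those
conditions: 102 subjects at TR 2 s with 300 frames (a 10-minute run) for
the "local"-style cohort, 86 subjects at TR 3 s for the "public
database"-style cohort, and a 66-pair (132-region) paired atlas.

Each subject's ROI series is a band-limited (0.008–0.09 Hz) latent-signal
mixture: a global process shared by all regions, one process per
homologous pair, and white noise (baseline loadings 0.6/0.6, noise sd 1).
This makes the three effect families separable:

* **connectivity** effects multiply the favoured hemisphere's loading on
  the *global* shared process, raising that region's correlation with the
  rest of the network (node strength, degree, efficiency). Scaling the
  pair-private loading instead would leave the L–R contrast untouched,
  since `corr(L, R)` is symmetric in its arguments;
* **band_power** effects multiply the whole band-limited part on the
  favoured side, raising fALFF;
* **coherence** effects raise the within-region voxel mixing weight `w`
  (within-region voxel correlation $w^2$, baseline $w = 0.7$) on the
  favoured side, raising LCOR in `simulate_voxel_session()`.

Effect sizes are specified as the *target paired Cohen's d of the
downstream L–R contrast*. The mapping from a generator multiplier to that
d has no convenient closed form (it runs through correlation and RMS
estimators on finite runs), so it is calibrated by simulation: a small
surrogate of the relevant contrast is simulated at a fixed multiplier
grid (300 draws per grid point, fixed internal seed independent of the
cohort seed) and the target d is interpolated. The calibration is
deterministic, cached per run-length/TR/noise configuration, and accurate
to a few percent at d = 0.8 in our tests.

Randomness is organised as one RNG stream per subject and purpose,
derived from the master seed by fixed ordinals, so any subject subset —
and the voxel session of any single subject — is reproducible
independently of cohort size. Identical configurations give bit-identical
outputs, which the run manifest verifies by md5 checksum.

What the generator does **not** emulate: scanner physics, image-space
artifacts, anatomical variability, spatial autocorrelation beyond the
block-parcellation structure, heavy-tailed motion, or any disease effect.
Passing tests therefore demonstrate that the estimators and the testing
procedure behave correctly under a known, plausible signal model — not
that any particular real dataset is lateralised.

## Numerical and design choices

* Band-limited processes are generated in the frequency domain
  (independent complex-Gaussian coefficients on in-band DFT bins,
  conjugate-symmetrised), giving exact band limitation and unit variance.
* Correlation clipping at $\pm(1-10^{-7})$ keeps Fisher z finite for
  numerically identical series.
* `threshold_graph()` rounds `cost * N(N-1)/2` to the nearest integer and
  warns (keeping all positive edges) when fewer positive correlations
  exist than requested.
* Degenerate test cells: sd of differences 0 with mean 0 is reported as
  `degenerate` with missing p (not a silent t = 0); sd 0 with nonzero
  mean is reported p = 0 and flagged.
* Agreement over an empty cohort intersection is missing, not 0: absence
  of overlap is not evidence of discordance.
* Tests and examples run at reduced sizes (typically 50 subjects, 120
  frames, and 100–200 replicates for Monte-Carlo checks); these sizes are
  stated in the test files and keep the full suite in the minutes range
  while leaving the statistical conclusions unchanged.

## Worked example

```{r example, eval = FALSE}
eff <- data.frame(pair_id = 1:2, family = "band_power",
                  direction = "left", effect_size = 0.8)
cfgA <- simulation_config(n_subjects = 60, n_timepoints = 150,
                          n_pairs = 10, effects = eff, seed = 1)
cfgB <- simulation_config(n_subjects = 50, n_timepoints = 150, tr = 3,
                          n_pairs = 10, effects = eff, seed = 2)
manifest <- run_pipeline(run_config(
  out_dir = "laterality_run",
  cohorts = list(local = cfgA, public = cfgB),
  metrics = c("GE", "degree", "cost", "fALFF")))
```

This writes per-cohort node metrics, laterality tables, paired and
one-sample test results, demographics, a between-cohort concordance
report and a checksummed manifest under `laterality_run/`.

## Known limitations

* Graph metrics on fixed-cost binary graphs are sensitive to the cost
  choice; only one default (0.15) is exercised by the shipped tests.
* The voxel simulator shares one latent per region, so LCOR and IC are
  more homogeneous within regions than in real data.
* No FDR or permutation alternatives to Bonferroni in this version; the
  divisor is configurable but the correction family is not.
* LI on metrics that can be negative remains intrinsically fragile; the
  guard makes it safe, not meaningful — prefer strictly positive metrics.
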