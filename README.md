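# hemilat

Hemispheric laterality analysis of resting-state functional connectivity.

Resting-state fMRI connectivity is not symmetric between the two cerebral
hemispheres. `hemilat` quantifies that asymmetry for every homologous
left/right region pair of a parcellation: it computes node-level
connectivity metrics per region, summarises each pair's imbalance with the
laterality index

```
LI = (L - R) / (L + R)
```

(0 = symmetric, positive = leftward, negative = rightward dominance), tests
lateralisation with paired and one-sample t-tests under Bonferroni
correction with signed Cohen's d (positive d = leftward), and reports
whether two independent cohorts agree on the *direction* of lateralisation
region by region. It is aimed at neuroimaging researchers who have
per-subject ROI timeseries (or 4-D voxel data with an integer
parcellation) and want a tested, reproducible laterality pipeline — plus a
synthetic-data generator with known lateralisation ground truth so the
whole pipeline can be validated without access-restricted data.

Metrics implemented per region:

* graph (binary, fixed-cost thresholded Fisher-z correlation graphs):
  global efficiency, local efficiency, betweenness centrality, average
  path length, clustering coefficient, degree, cost;
* voxel-based, aggregated to regions: intrinsic connectivity (IC), local
  correlation (LCOR, 25 mm FWHM Gaussian neighbourhood), fALFF
  (0.008–0.09 Hz band fraction);
* timeseries denoising: motion/global-signal outlier detection (0.9 mm
  FD, 5 SD), CompCor-style nuisance components, confound regression,
  band-pass filtering.

## Worked example

Simulate two cohorts with a known leftward band-power effect (target
paired Cohen's d 0.8) in pairs 1–2, run the pipeline, and inspect the
laterality tests:

```r
library(hemilat)

eff <- data.frame(pair_id = 1:2, family = "band_power",
                  direction = "left", effect_size = 0.8)
cfgA <- simulation_config(n_subjects = 60, n_timepoints = 150,
                          n_pairs = 10, effects = eff, seed = 1)
co <- simulate_cohort(cfgA)
nm <- compute_node_metrics(co$panel, co$atlas, metrics = "fALFF")
res <- paired_lr_tests(nm, co$atlas)
res[res$pair_id %in% 1:3, c("pair_id", "metric", "t", "p_bonferroni",
                            "cohens_d", "direction")]
```

```
  pair_id metric         t p_bonferroni   cohens_d direction
1       1  fALFF 6.6017052 2.546161e-07 0.85227647      left
2       2  fALFF 4.4782811 7.012027e-04 0.57814360      left
3       3  fALFF 0.1573959 1.000000e+00 0.02031973      none
```

The two implanted pairs are recovered with adjusted p < 0.05, effect sizes
around the 0.8 target (subject sampling moves individual estimates) and
direction `left`; the null pair is not flagged.
`run_pipeline()` does the same end to end for one or two cohorts (writing
metrics, laterality tables, test results, a concordance report and a
checksummed manifest), and `inst/cli/hemilat.R` wraps it for shell use.

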