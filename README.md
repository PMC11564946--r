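# cicadaclock

Rate–time analysis, fossil calibration priors, and relaxed-clock simulation
for dated phylogenies.

## The problem

Bayesian relaxed-clock dating yields an ultrametric timetree whose nodes
carry posterior ages (Ma), posterior probabilities, and rate medians
(substitutions/site/Myr, s/s/Myr). For groups like cicadas, plotting those
node rate medians against node ages suggests the substitution rate has not
been constant: it appears to increase roughly exponentially toward the
present. `cicadaclock` is for molecular phylogeneticists who want to build
and audit such analyses end to end:

* **Calibration priors.** Minimum-age (tMRCA) normal priors from geological
  stage bounds (mean = stage midpoint, SD = half-range), radio-isotopic
  dates, or dated geological events (island isolation/emergence), plus a
  packaged transcription of a published cicada/Hemiptera calibration table
  and a posterior-vs-prior consistency report.
* **Annotated tree I/O.** A reader/writer for the FigTree/NEXUS
  metadata-comment dialect (`[&posterior=...,rate_median=...]`), with a
  uniform per-node table of ages, rate medians, and posteriors.
* **The rate–time model.** Least squares of log(rate) on node age fits
  `r(t) = r0·e^(b·t)`; with ages in Ma before present, `b < 0` means rates
  increase toward the present. Free and fixed-intercept variants.
* **Saturation diagnostics.** Per-pair transition/transversion counts
  against Kimura two-parameter (or TN93) corrected distances, and a
  binned-slope trend statistic that flags the flattening of transition
  counts that signals saturation.
* **A generative simulator.** Yule timetrees, uncorrelated-lognormal branch
  rates with an optional exponentially time-dependent mean, and HKY+Γ₄
  sequences — the ground truth against which every stage above is
  validated.

## Worked example

Simulate a 64-taxon, 250-Myr timetree whose mean rate rises from
`0.0128·e^(-0.02·250) ≈ 8.6e-5` s/s/Myr at the root to 0.0128 s/s/Myr at
the present, with lognormal branch-rate noise (σ = 0.3), then refit the
trend from the node points:

```r
library(cicadaclock)

cfg  <- sim_config(n_taxa = 64, root_age = 250, clock_r0 = 0.0128,
                   clock_b = -0.02, sigma_ln = 0.3, seed = 1)
tree <- assign_branch_rates(simulate_yule_tree(cfg), cfg)
tree
#> Annotated time-tree: 64 tips, 63 internal nodes, root age 250 Ma
#>   annotations: rate_median at 127 node(s), posterior at 63 node(s)

pts <- rate_age_points(tree, node_rate_mode = "median_of_adjacent")
head(pts, 3)
#>   node_id    age_ma         rate
#> 1  node65 250.00000 0.0002121908
#> 2  node66  77.01290 0.0031489119
#> 3  node67  23.32111 0.0132044985

fit_exponential(pts)
#> Exponential rate-time fit: r(t) = r0 * exp(b * t)
#>   r0 = 0.013002 s/s/Myr (free intercept)
#>   b  = -0.0179177 per Myr (rate increases toward the present)
#>   r^2 (log-linear) = 0.9128 on 63 points
```

The fitted intercept (0.0130 s/s/Myr) and decay coefficient (−0.0179/Myr)
recover the generating values (0.0128, −0.02) from a single tree; the test
suite checks that over 50 replicates the median fitted `b` lands within 20%
of truth, and that constant-clock simulations fit `b ≈ 0`.

Calibration priors from stage bounds:

```r
prior_from_stage(201.3, 199.3)   # Hettangian
#> $prior_mean [1] 200.3
#> $prior_sd   [1] 1
```

The whole workflow — simulate or ingest, node table, rate–time fit,
saturation check, calibration report, checksummed manifest — runs as one
deterministic pipeline:

```r
run_pipeline(pipeline_config(mode = "simulate",
                             scenario = "accelerating_clock",
                             node_rate_mode = "median_of_adjacent",
                             out_dir = "out", seed = 1))
```

Thin command-line wrappers live in `inst/scripts/` (`pipeline.R`,
`ratescan.R`, `satcheck.R`).

## Scope

The package constructs and checks calibration priors and analyses the
*output* of Bayesian dating; it does not run the MCMC itself, align
sequences, or attempt to reproduce any specific published timetree. The
methods vignette (`vignettes/rate-time-methods.Rmd`) documents the models,
conventions, simulator design, and known limitations.
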