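---
title: "Rate-time analysis of relaxed-clock timetrees: models, conventions, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rate-time analysis of relaxed-clock timetrees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cicadaclock)
```

## The scientific problem

Bayesian relaxed-clock dating produces an ultrametric timetree whose nodes
carry posterior summaries: a posterior age (Ma before present), a posterior
probability, and a "rate median" in substitutions per site per million years
(s/s/Myr). Plotting the node rate medians against node ages asks a simple
question with large consequences for molecular dating: has the substitution
rate been constant through time, or does it vary systematically — for
example, increasing toward the present, as has been repeatedly reported for
insect mitochondrial data on Quaternary timescales?

`cicadaclock` packages the full desk workflow around that question:

1. **calibration priors** (`prior_from_stage()`, `prior_from_date()`,
   `load_calibration_table()`): turning fossil stage assignments,
   radio-isotopic dates, and dated geological events (island isolation,
   island emergence) into normal tMRCA priors in the minimum-age sense;
2. **annotated tree I/O** (`parse_annotated_nexus()`,
   `write_annotated_nexus()`, `node_table()`): the FigTree/NEXUS
   metadata-comment dialect;
3. **the rate-time model** (`rate_age_points()`, `fit_exponential()`):
   the exponential trend `r(t) = r0 e^{b t}`;
4. **saturation diagnostics** (`saturation_table()`,
   `plateau_statistic()`): transition/transversion counts against
   corrected distances;
5. **a generative simulator** (`sim_config()` and friends) providing ground
   truth for all of the above;
6. **a pipeline driver** (`run_pipeline()`) tying the stages together
   deterministically.

## Calibration priors

A minimum-age calibration equates the tMRCA of a clade with the age of the
oldest fossil assignable to it. Two constructors cover the evidence types:

* **Stage-based** fossils are dated only to a geological stage. The prior
  is normal with mean the stage midpoint and SD the half-range, so that
  mean ± SD recovers the stage bounds exactly. Hettangian bounds
  201.3–199.3 Ma give 200.3 ± 1.0 Ma; Rupelian bounds 33.9–28.1 Ma give
  31 ± 2.9 Ma:

```{r}
prior_from_stage(201.3, 199.3)
prior_from_stage(33.9, 28.1)
```

* **Directly dated** horizons (U-Pb, Ar-Ar, K-Ar, fission-track) and dated
  geological events pass their published mean ± SD through unchanged
  (`prior_from_date(98.79, 0.62)`); midpoint arithmetic would be wrong
  here — a weighted-average radio-isotopic age is not the midpoint of the
  enclosing stage.

The packaged table (`inst/extdata/table2_calibrations.tsv`) transcribes a
published cicada/Hemiptera calibration set: 17 active calibrations
(A1–A6 on hemipteran outgroups, B–H on cicada clades, and Quaternary
geological-event calibrations at 1.55 ± 0.15 Ma for Ryukyu island isolation
plus one island-emergence point) and 5 inactive rows. The inactive rows are
kept deliberately: three are calibrations the original analysis considered
and rejected ("not applied"), and two record conflicting printed variants of
the same calibration (the Rupelian point appears both as Oligocene-wide
28.465 ± 5.435 and as Rupelian 31 ± 2.9; one Quaternary point appears as
both 0.024 ± 0.0024 and 0.24 Ma). The table is a faithful transcription, so
both variants are carried and neither is adjudicated; the `active` flag
selects the ones the analysis used. Serialization is canonical (rows sorted
by id, four fixed decimals), so load-then-write is byte-stable.

`check_posterior_vs_prior()` closes the loop after dating: for each
calibration it finds the calibrated node (crown = MRCA of the ingroup; stem
= its parent) and reports the z-score of the posterior node age against the
prior. Under minimum-age semantics only strong *younger-than-prior*
deviations (z below −3 by default) are flagged; an older posterior age is
legitimate. Calibrations whose taxa are missing from the tree degrade to an
`"unresolvable"` status rather than an error, because a calibration table
routinely spans more taxa than any one tree.

## Annotated tree I/O

The parser reads newick with `[&key=value,...]` comments — the dialect
written by Bayesian dating software and read by FigTree — bare or inside a
NEXUS `TREES` block with a `TRANSLATE` table. Conventions, each a deliberate
choice:

* **Ages come from branch lengths**, by the max-path-to-descendant-leaf
  rule, never from a `height` annotation; this makes one code path serve
  simulator output and external files. A `height` key that disagrees beyond
  tolerance triggers a warning and loses.
* **Tips sit at age 0**; age increases into the past (the FigTree "Node
  ages" convention). Non-ultrametric input warns and falls back to the
  max-path rule.
* **Node numbering is canonicalized** to what a newick reader produces
  (tips left-to-right, internal nodes in preorder). Because the writer
  emits that same order with 17-significant-digit branch lengths,
  `parse(write(T))` is the identity and `write ∘ parse ∘ write` is
  idempotent — properties the test suite checks on simulated trees.
* Unknown annotation keys are preserved verbatim; `rate` is accepted as a
  synonym for `rate_median`.

Only the first tree of a multi-tree file is used unless an index is given:
MCC summary files carry one tree.

## The exponential rate-time model

`fit_exponential()` fits `r(t) = r0 e^{b t}` by ordinary least squares of
`log(rate)` on age — the estimator class of a spreadsheet "exponential
trendline", which is what the rate-versus-age insets this analysis mirrors
were drawn with. The goodness of fit `r²` is likewise reported on the
log-linear scale. With ages positive into the past, `b < 0` means rates
increase toward the present. A nonlinear least-squares refinement on the
natural scale is available behind `nonlinear_refine = TRUE` but the
log-linear fit is the reference estimator.

Two node-rate conventions are exposed because annotated trees conflate
them:

* `annotation` (default): the `rate_median` value stored at each node —
  what an MCC tree actually carries;
* `median_of_adjacent`: the median of the three adjacent branch rates
  (parent edge plus two child edges; the root uses its two child edges),
  the convention described for node rates in relaxed-clock summaries. The
  simulator writes true branch rates, so this mode is exact there.

Tips are excluded by default: every tip has age 0, so tip points carry no
temporal signal and act purely as intercept ballast; `include_tips = TRUE`
restores them. The fixed-intercept variant (`intercept_mode = "fixed"`)
constrains `r0` to a supplied value — e.g. a posterior mean clock rate —
and regresses through the origin. Both modes are provided because a
published curve with a stated intercept can arise either way, and the
package does not presume which; on exactly exponential data with the true
intercept they coincide, which is tested.

A caveat the package states rather than solves: node points on one tree are
phylogenetically non-independent, and relaxed-clock node rates can show
age-correlated artifacts. The simulator makes this testable — the
constant-clock recovery property below is exactly that test — but no
phylogenetic correction is applied to the regression.

## Saturation diagnostics

`saturation_table()` computes, per unordered sequence pair: compared sites
(both unambiguous A/C/G/T; anything else excludes the site pairwise, the
standard distance-matrix practice), transition and transversion counts,
p-distance, and a corrected distance. The default correction is Kimura's
two-parameter distance

> d = −½ ln(1 − 2P − Q) − ¼ ln(1 − 2Q)

the natural companion of a transition/transversion plot; TN93 (which
separates purine and pyrimidine transitions and uses alignment-wide base
frequencies) is available where unequal frequencies matter. Outside the
admissible region the distance is *undefined*: such pairs are retained and
flagged `saturated = TRUE` rather than dropped, so saturation is visible
in the output, not censored.

`plateau_statistic()` operationalizes "is the transition curve flattening?"
— records are binned by corrected distance (10 equal-width bins by
default), the within-bin OLS slope of the transition count against distance
is computed, and the trend of those slopes across bins is summarized by a
Spearman rank correlation in [−1, 1]. Clearly negative = flattening =
saturation. Degenerate cases are defined, not left to numerical noise:
bins with fewer than two points or zero distance spread are skipped, and if
the usable slopes are constant up to numerical tolerance the trend is 0 by
definition (exactly linear accumulation has no curvature).

Two properties of this statistic shaped the validation design. First, a
rank correlation is scale-free: any *consistent* mild curvature — even the
gentle convexity that the distance correction itself induces at moderate
divergence — eventually registers as a negative trend. "Shallow" in the
tests therefore means genuinely shallow: maximum pairwise divergence around
0.05 substitutions/site (a 2-Myr-deep tree at COI-like rates), where
within-bin slope noise dominates and the trend scatters around zero.
Second, single-run trends on pair data are noisy (pairs sharing tree paths
are correlated), so the deep-versus-shallow contrast is asserted on means
over replicate simulations, not on single runs.

## The simulator: what it emulates, and what it does not

`sim_config()` fixes the generative model that the validation rests on —
deliberately the same model class a Bayesian relaxed-clock analysis
assumes:

* **Topology/times**: Yule (pure-birth) trees conditioned on the number of
  tips, optionally rescaled so the root age is exact. Default birth rate
  0.05/Myr — with 64 taxa and a 100-Myr root this gives node ages spread
  over the whole depth rather than piled at the root.
* **Branch rates**: uncorrelated lognormal. Each branch draws an
  independent multiplier `L` with log-SD `sigma_ln` (default 0.3, a
  moderate relaxed-clock dispersion) and log-mean `−sigma_ln²/2`, so
  `E[L] = 1` — the noise is *mean*-centered, which makes
  recovery tests unambiguous: the expected branch rate equals the
  deterministic trend. (Median-centering, the other common UCLN
  parameterization, would bias mean rates upward by `e^{σ²/2}`; the choice
  is documented here precisely because summary trees rarely say which was
  used.)
* **Time dependence**: the deterministic trend is `r0 e^{b t}` evaluated at
  the branch temporal midpoint (default), or its exact time-average over
  the branch behind `rate_integration = "exact"`. Midpoint evaluation keeps
  the truth model analytically simple; branches are short relative to tree
  depth, and the recovery tests pass under either.
* **Sequences**: HKY (default κ = 8 and base frequencies
  A 0.30 / C 0.25 / G 0.15 / T 0.30, typical of insect mitochondrial COI)
  with discrete-Gamma rate variation across sites — 4 categories using
  category *means* (mean exactly 1; default shape 0.5, strong site
  heterogeneity), root states drawn from the stationary frequencies,
  default length 1,534 sites (a full COI alignment). Transition matrices
  come from the spectral decomposition of the reversible generator, exact
  to machine precision and cross-checked against direct matrix
  exponentiation in the tests.
* **Reproducibility**: one master seed feeds four named streams (topology,
  rates, site categories, states), so each stage is independently
  reproducible and fixtures are byte-identical for a fixed seed.

Three standard scenarios parameterize `generate_fixture_suite()` and the
pipeline: `constant_clock` (64 taxa, 100 Myr, 0.01 s/s/Myr, b = 0),
`accelerating_clock` (64 taxa, 250 Myr, r0 = 0.0128 s/s/Myr, b = −0.02/Myr
— the parameter scale of the published COI rate-time curve, with rates
rising ~150-fold from 250 Ma to the present), and `deep_saturation`
(32 taxa, 250 Myr at the constant COI-like rate, deep enough to saturate
transitions).

What the simulator does **not** emulate — and therefore what passing tests
do not show about real data: taxon sampling is uniform Yule (no
clade-biased sampling, no population-level sampling of island endemics);
rates are branchwise-independent (no autocorrelation); sequences have no
indels, no ambiguity codes, no alignment error; and, most importantly, the
simulator hands the analysis *true* node ages and rates, whereas a real
analysis consumes posterior point summaries whose errors are correlated
with the ages on the same tree. Recovery under simulation is a necessary
check of the machinery, not evidence that a rate-age trend estimated from
one empirical MCC tree is unbiased.

## Validation properties and problem sizes

The test suite asserts, among others:

* exact prior reconstruction for the four stage-based calibrations, and
  byte-stable round-tripping of the packaged calibration table;
* `parse(write(T))` identity and node-count identities (n − 1 internal,
  2n − 1 total) on simulated trees up to 64 taxa;
* `fit_exponential()` equal to an independently coded closed-form OLS
  oracle to 1e-10 on random inputs; exact recovery on noiseless
  exponential points; scale and age-shift equivariance;
* clock recovery at the study's scale: over 50 replicate 64-taxon,
  100-Myr trees with σ = 0.3, the median fitted `b` is within 20% of the
  true −0.02/Myr, and under a constant clock the mean fitted `b` is within
  2 standard errors of zero;
* K2P equal to its closed form (0.170181... at P = 0.1, Q = 0.05) and to
  its small-divergence expansion `P + Q` within 1e-4 for P, Q ≤ 0.005 (at
  0.01 the quadratic term itself exceeds 1e-4); K2P and TN93 equal to the
  corresponding `ape::dist.dna()` reference distances on simulated
  alignments;
* transition fraction ≈ 1/3 of differences at κ = 1 with equal
  frequencies, strictly increasing in κ;
* the saturation contrast: mean transition-slope trend below −0.3 on
  250-Myr COI-like alignments versus within ±0.3 of zero on 2-Myr ones
  (3 and 5 replicates, 32 taxa × 1,534 sites each).

These sizes — 50 fit-only replicates, a handful of sequence simulations of
32–64 taxa × 1,534 sites — were chosen as the smallest designs that
exercise every property at the study's parameter scale; the whole suite
runs in well under a minute.

## Known limitations

* The rate-time regression treats node points as independent; see above.
* The plateau trend is qualitative (sign and rough magnitude), not a
  likelihood-based saturation test.
* The NEXUS reader targets the metadata-comment dialect of dating software
  summary trees; it does not read full posterior `.trees` logs, tracer
  logs, or perform rerooting.
* Calibration priors are constructed and checked post hoc; no Bayesian
  node dating happens inside this package — the MCMC is consumed, not
  re-implemented.
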