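---
title: "Estimating causal effects of impairments on gross motor function"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating causal effects of impairments on gross motor function}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gmfmcausal)
```

## The problem

Children with spastic cerebral palsy (CP) present a tangle of interrelated
impairments: reduced selective and dynamic motor control, weakness,
spasticity, joint contractures, long-bone torsions, and degraded gait. The
clinical question is which of these actually *drives* gross motor function,
measured by the 66-item Gross Motor Function Measure (GMFM-66). Bivariate
association studies cannot answer it: with a common upstream neurological
injury, every impairment correlates with every other, and a single-predictor
regression inherits all of that shared variation.

`gmfmcausal` encodes an explicit causal diagram over thirteen routinely
collected gait-laboratory measures and four latent constructs (the injury
itself, an overall motor-control construct, and shared contracture and
torsion liabilities), and provides the full chain of machinery that a causal
analysis of such a model needs:

1. **Graph layer** — a validated DAG type (`CausalGraph`) with d-separation
   queries, implemented twice (an efficient moralized-ancestral-graph
   routine and an exhaustive path enumerator) so each algorithm checks the
   other.
2. **Identification layer** — the model's testable implications
   (`impliedIndependencies`) and minimal covariate adjustment sets
   (`adjustmentSets`) for total and direct effects.
3. **Estimation layer** — partial-correlation tests of the implications,
   standardized total/direct/bivariate effect estimates by covariate-adjusted
   ordinary least squares, a raw-unit predictive model, and k-fold
   cross-validation.
4. **Simulation layer** — a linear-Gaussian structural equation system over
   the same graph with closed-form true effects, so every estimator can be
   validated end to end without patient data.

## The model

`cpModel()` ships the diagram as data: 17 nodes (13 observed, 4 latent) and
66 edges. Age influences motor control measures, spasticity, deformities,
gait and GMFM-66 directly; the latent injury drives motor control,
spasticity and strength; the neurological factors and age cause the four
contractures and two torsions (each group also sharing its own latent
liability); everything feeds gait quality (GDI); and GMFM-66 is caused by
the neurological factors, age, the contractures and GDI. Two deliberate
structural choices matter downstream:

* **No Age → Strength edge.** The strength score is age-normalized at
  measurement, so age acts on strength only through the latent pathways.
  This is what makes `Strength _||_ Age` (marginally) one of the model's
  testable implications.
* **No torsion → GMFM edges.** Long-bone torsion is assumed to act on gross
  motor function only through gait. Consequently the total and direct
  effects of GDI coincide, and each torsion is conditionally independent of
  GMFM-66 given a set containing GDI.

### Units, orientation and sign conventions

Raw variables keep their clinical conventions: contracture variables are
degrees relative to typically developing end ranges (ankle dorsiflexion
21.3°, knee extension 4° of recurvatum, popliteal angle 25.6°, hip extension
0°), so a contracted joint scores *negative*; torsional deviations are
degrees relative to typical femoral anteversion (26.9°) and tibial torsion
(16.0°); spasticity is a 0–5 composite where larger is worse; SCALE (0–10),
Walk-DMC and GDI (both scaled to 100 ± 10 in typically developing children),
strength (0–5) and GMFM-66 score larger-is-better already.

For standardized analyses, `standardizeAndOrient()` z-scores each column
with the sample mean and sample SD (n−1) and then flips signs where a larger
raw value means more impairment, so that *positive standardized effects
always read as beneficial*. On these conventions only spasticity needs
flipping: contractures and torsion deviations are already negative-coded
(more negative = more impaired — the severity gradient across GMFCS levels
confirms this for the torsions), and age keeps its conventional direction.
The raw-unit predictive model (`predictiveModel()`) instead reports the
degree-valued deformities in the clinic's "limitation" convention (positive
degrees of deviation, negative coefficients), which is how such coefficient
tables are usually printed; the recoding is metadata
(`variableMeta(cpModel())$predictive_flip`), not a change of model.

## Identification choices

**Testable implications.** `impliedIndependencies()` uses the missing-edge
basis: one statement per non-adjacent observed pair that admits an observed
separating set. This is the convention of the standard graphical-model
toolchain and gives the model's 11 implications; pairs separable only by
conditioning on a latent node are correctly omitted (they are not testable).
An exhaustive `basis = "all"` is available for small graphs.

**Minimal separators.** The search seeds with the observed ancestors of the
pair — a subset of the candidate pool separates the pair if and only if this
ancestral restriction does — then greedily deletes elements in lexicographic
order. The tie-break makes the reported conditioning sets deterministic,
e.g. hip extension ⊥ tibial torsion given {Age, DMC, SCALE, Spasticity,
Strength}.

**Adjustment sets.** Total effects use the generalized backdoor criterion
(no descendants of nodes on proper causal paths; all non-causal paths
blocked, checked as d-separation in the proper backdoor graph). Direct
effects use the single-door criterion for the controlled direct effect
under linearity: the adjustment set must block every path once the direct
edge is removed, and avoid descendants of the outcome. `adjustmentSets()`
enumerates *all* minimal valid observed sets by exhaustive search over the
permissible pool (capped at 16 candidates — ample for 13 observed
variables) and nominates the smallest, ties broken lexicographically.
Effects with no valid observed adjustment set raise an explicit
"not identifiable" error rather than returning a best effort.

## Estimation choices

* Ordinary least squares with main effects only — no interactions; the
  standardized exposure coefficient is the effect size.
* Classical (model-based) standard errors; 95% CIs use the normal quantile
  1.96. At n = 300 the difference from t quantiles is negligible.
* Implication tests are two-sided Fisher-z partial-correlation tests at
  α = 0.05 with **no multiplicity correction** — each implication is a
  separate falsification opportunity for the model, so per-test level is
  the quantity of interest.
* Cross-validation refits the raw-unit predictive model per fold; fold
  assignment is simple random (sizes within one), controlled by a required,
  logged seed. Standardization/orientation parameters are computed once on
  the full sample, before CV, matching the analysis sequence the estimation
  layer documents; a sensitivity analysis could move standardization inside
  the folds, but the predictive model is fit in raw units so only the
  orientation metadata would be affected.
* Missing data are a hard error with a row report (complete-case analysis;
  no imputation). Zero-variance columns and exactly collinear designs abort
  with the offending column named.

## The simulator and what passing tests mean

`defaultSEM()` is a linear-Gaussian structural equation system over the
built-in graph. Each node is `intercept + Σ coefficient·parent + N(0, σ)`,
generated in topological order with deterministic per-node seed substreams.
Its calibration:

* The edges into GMFM-66 carry the published per-unit predictive
  coefficients (recoded onto the raw sign conventions), with a residual SD
  of 6 GMFM-66 points.
* All upstream path strengths are package constants, set once so that the
  implied marginal means and SDs sit near a pooled clinical gait-laboratory
  population (e.g. GMFM-66 ≈ 75.5 ± 13, GDI ≈ 74 ± 12, SCALE ≈ 5.4 ± 1.9).
  `cohortFixture(level, n, seed)` re-places the means and SDs at the
  embedded GMFCS-level strata (I/II/III GMFM-66 means 87/73/57), which the
  intercept calibration hits exactly in expectation.

These are *fixtures*, not estimates of any cohort. The simulator reproduces
first and second moments and — because it is Gaussian and faithful — the
model's conditional-independence structure exactly. It does **not**
reproduce ordinal floors and ceilings (SCALE, spasticity and strength are
continuous here), the GMFCS mixture's bimodality, skewness, or any
nonlinearity in age. Passing the parameter-recovery and null-calibration
suites therefore demonstrates that the estimators are correct *under the
model's own assumptions* (linearity, Gaussian errors, faithfulness); it
says nothing about robustness to the ordinal, mixed, non-Gaussian character
of real clinic data.

## Numerical and validation choices

* **Dual d-separation oracles.** The efficient routine (moralized ancestral
  subgraph + reachability) is checked against exhaustive simple-path
  enumeration on 1,000 random DAGs of up to 8 nodes, over *all* (x, y, z)
  triples. The built-in clinical graph is far too dense for path
  enumeration (every observed pair exceeds 3·10⁵ simple paths, against the
  enumerator's 2¹⁶ budget), so its 11 implications are cross-checked by a
  third, algebraic oracle: in a linear-Gaussian system with random
  coefficients over the graph, a partial correlation computed directly from
  the implied covariance vanishes iff the corresponding d-separation holds.
* **Parameter recovery.** Standardized total-effect estimates on 20
  simulated cohorts of n = 20,000 are required to match the closed-form
  path-product truths within 3 Monte-Carlo standard errors for every
  exposure, and the bivariate–total gap must be nonzero exactly for the
  exposures with an open non-causal path (all but age).
* **Null calibration.** Across 500 simulated null cohorts of n = 300 (the
  implications hold by construction), each of the 11 Fisher-z tests must
  reject at a rate within a 99.9% binomial band of α = 0.05.
* Problem sizes throughout (20 × 20,000; 500 × 300; 1,000 random DAGs;
  n = 10⁵ for the moment checks) were chosen to make Monte-Carlo error a
  small fraction of the tolerances being asserted.

## Limitations

* Linearity everywhere, by design: no interactions, no splines in age, no
  ordinal link functions. The upstream analysis this package operationalizes
  states the same limitation.
* The identification layer covers covariate adjustment only — no
  instrumental variables, front-door identification, bidirected-edge
  (ADMG) machinery, or structure learning. Latent confounding is expressed
  through explicit latent nodes.
* Direct effects are controlled direct effects under linearity; with
  effect modification these would not equal natural direct effects.
* The simulator's Gaussian world makes its null calibration exact; on real
  ordinal clinic data the Fisher-z reference distribution is approximate.

## A worked run

```{r example, eval = FALSE}
cfg <- cpModel()
formatCI(impliedIndependencies(causalGraph(cfg)))

spec <- defaultSEM()
cohort <- simulateCohort(spec, n = 300, seed = 1)
report <- analyzeCohort(variableTable(cohortData(cohort)), cfg, seed = 1)
report$cv
subset(report$effects, effect_type == "total")
```

The same pipeline runs from a shell via the script in
`system.file("scripts", "gmfmcausal.R", package = "gmfmcausal")`, with
`validate`, `simulate`, `analyze`, `effects`, `cis` and `crossval`
subcommands.
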