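# gmfmcausal

Causal effect estimation for gross motor function in children with spastic
cerebral palsy.

## What it does and for whom

Clinicians treating cerebral palsy (CP) can target spasticity, strength,
contractures, bony torsions or gait — but association studies cannot say
which of these *causes* better gross motor function, because all of them
share the upstream neurological injury. `gmfmcausal` is for biostatisticians
and motion-laboratory researchers who want to make the causal hypothesis
explicit and test it. It encodes a directed acyclic graph (DAG) over
thirteen measures routinely collected at a clinical gait analysis — age,
selective motor control (SCALE, 0–10), dynamic motor control (Walk-DMC,
100 ± 10 in typically developing children), composite strength (0–5) and
spasticity (0–5) scales, four joint contractures (degrees relative to
typically developing end ranges), femoral anteversion and tibial torsion
deviations (degrees), the Gait Deviation Index (GDI, 100 ± 10) — and the
outcome, the 66-item Gross Motor Function Measure (GMFM-66), plus four
latent nodes (Injury, Motor Control, Contracture, Torsion) carrying the
unmeasured common causes.

From the graph the package derives and executes the whole analysis:

* **Testable implications.** The missing-edge basis of conditional
  independencies among observed variables, `X ⫫ Y | Z`, each testable as a
  partial correlation that must be ≈ 0 (Fisher-z test,
  `z = atanh(r)·√(n−k−3)`). The built-in model implies exactly **11**
  statements.
* **Minimal sufficient adjustment sets** for total effects (generalized
  backdoor criterion) and controlled direct effects (single-door criterion),
  enumerated exhaustively with deterministic tie-breaking.
* **Effect sizes.** For each exposure X, the standardized coefficient β̂ of
  X in the OLS fit `GMFM ~ X + Z` with Z the chosen adjustment set (total or
  direct), and the unadjusted `GMFM ~ X` bivariate coefficient for
  comparison — the gap `bivariate − total` is the overestimation a naive
  association analysis would commit.
* **Prediction.** A raw-unit linear model
  `GMFM-66 = β₀ + Σᵢ βᵢ·Variableᵢ` over all twelve predictors, with k-fold
  cross-validated out-of-sample r² and mean absolute error.
* **Simulation.** A linear-Gaussian structural equation model
  (`Xᵥ = μᵥ + Σ βᵤᵥ Xᵤ + ε`) over any `CausalGraph`, with closed-form true
  total effects (path-coefficient products) for validating every estimator.

Everything is implemented twice where correctness matters: d-separation has
an efficient moral-graph routine and an exhaustive path-enumeration oracle,
and the clinical model's implications are additionally verified against
partial correlations computed algebraically from implied covariances.

## Worked example

```r
library(gmfmcausal)

cfg <- cpModel()                       # the built-in CP impairment model
cfg
#> ModelConfig
#> CausalGraph: 17 nodes (13 observed, 4 latent), 66 edges
#>   latent: Injury, MC, Contracture, Torsion
#>   outcome: GMFM

head(formatCI(impliedIndependencies(causalGraph(cfg))), 3)
#> Age _||_ Strength
#> AnkleDF _||_ FemRot | Age, DMC, SCALE, Spasticity, Strength
#> AnkleDF _||_ TibRot | Age, DMC, SCALE, Spasticity, Strength

adjustmentSets(causalGraph(cfg), "Strength", "GMFM", "total")
#> Adjustment sets for the total effect of Strength on GMFM:
#>   { Age, DMC, SCALE, Spasticity }
#> chosen: { Age, DMC, SCALE, Spasticity }

# a synthetic cohort from the calibrated simulator, analyzed end to end
cohort <- simulateCohort(defaultSEM(), n = 300, seed = 1)
report <- analyzeCohort(variableTable(cohortData(cohort)), cfg, seed = 1)

sum(report$ci_tests$rejected)          # implications rejected at alpha = .05
#> 0
report$cv$r2_oos; report$cv$mae
#> 0.807
#> 4.95
subset(report$effects, effect_type == "total", c(exposure, beta, se))[2:4, ]
#>  exposure  beta    se
#>     SCALE 0.399 0.038
#>       DMC 0.307 0.039
#>  Strength 0.245 0.042
```

Reading: on this simulated cohort none of the 11 implied independencies is
rejected (the data are consistent with the graph, as they must be here); the
twelve-predictor model predicts held-out GMFM-66 with r² ≈ 0.81 and a mean
absolute error of ≈ 5 points; and one sample SD of selective motor control
is worth ≈ 0.40 SD of GMFM-66 after adjustment, with strength at ≈ 0.25 —
while the corresponding bivariate coefficients (in
`report$overestimation`) run ≈ 0.3–0.5 higher, illustrating how unadjusted
associations inflate apparent importance.

Real data enter the same way: a CSV whose header names the thirteen
variables (aliases `Walk-DMC` and `GMFM-66` are accepted) via
`readVariableTable(path, cfg)`, or from a shell through the bundled script

```sh
Rscript $(Rscript -e 'cat(system.file("scripts","gmfmcausal.R",package="gmfmcausal"))') \
    analyze --data cohort.csv --out report.json --seed 1
```

with sibling subcommands `validate`, `simulate`, `effects`, `cis`,
`crossval`.

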