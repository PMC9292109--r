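Package: gmfmcausal
Title: Causal Effect Estimation for Gross Motor Function in Cerebral Palsy
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Encodes a hypothesized causal diagram of neurological and
    orthopedic impairments affecting the 66-item Gross Motor Function Measure
    (GMFM-66) in children with spastic cerebral palsy, and provides the
    machinery to work with it: d-separation queries on directed acyclic
    graphs with latent nodes, derivation of the model's testable implied
    conditional independencies, minimal covariate adjustment sets for total
    and direct effects, partial-correlation tests, standardized and raw-unit
    effect estimation by covariate-adjusted linear regression, a predictive
    model of GMFM-66 with k-fold cross-validation, and a linear-Gaussian
    structural equation simulator with closed-form true effects for
    validating every stage without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'causal-graph.R'
    'd-separation.R'
    'identification.R'
    'model-spec.R'
    'sem.R'
    'variable-table.R'
    'estimation.R'
    'report.R'
    'cli.R'
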