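#' @include model-spec.R
NULL

#' Construct a linear-Gaussian SEM specification
#'
#' @param graph a \linkS4class{CausalGraph}.
#' @param coefficients named numeric, one \code{"from->to"} entry per edge.
#' @param noiseSD named numeric, positive noise SD per node.
#' @param nodeMean named numeric intercept per node (default all 0).
#' @return a \linkS4class{SEMSpec}.
#' @examples
#' g <- CausalGraph(c("A -> B"))
#' s <- semSpec(g, c("A->B" = 2), c(A = 1, B = 1))
#' trueTotalEffect(s, "A", "B")
#' @export
semSpec <- function(graph, coefficients, noiseSD,
                    nodeMean = stats::setNames(rep(0, length(graph@nodes)),
                                               graph@nodes)) {
  methods::new("SEMSpec", graph = graph, coefficients = coefficients,
               noiseSD = noiseSD, nodeMean = nodeMean)
}

#' @rdname causalGraph
#' @aliases causalGraph,SEMSpec-method
#' @export
setMethod("causalGraph", "SEMSpec", function(x) x@graph)

#' Edge coefficients of a SEM specification
#' @param spec a \linkS4class{SEMSpec}.
#' @return named numeric vector (names \code{"from->to"}).
#' @export
edgeCoefficients <- function(spec) spec@coefficients

## coefficient matrix B[u, v] = coefficient on edge u -> v
.coefMatrix <- function(spec) {
  g <- spec@graph
  B <- matrix(0, length(g@nodes), length(g@nodes),
              dimnames = list(g@nodes, g@nodes))
  if (nrow(g@edges) > 0)
    B[g@edges] <- spec@coefficients[paste0(g@edges[, 1], "->", g@edges[, 2])]
  B
}

#' Implied first and second moments of a SEM
#'
#' Closed-form mean vector and covariance matrix of the joint (observed and
#' latent) distribution, from the recursion \eqn{X = B^T X + \mu + \epsilon}:
#' \eqn{E[X] = (I-B^T)^{-1}\mu}, \eqn{Cov[X] = (I-B^T)^{-1} D (I-B^T)^{-T}}.
#'
#' @param spec a \linkS4class{SEMSpec}.
#' @return list with \code{mean} (named numeric) and \code{cov} (matrix).
#' @export
impliedMoments <- function(spec) {
  nodes <- spec@graph@nodes
  B <- .coefMatrix(spec)
  Inv <- solve(diag(length(nodes)) - t(B))
  mu <- drop(Inv %*% spec@nodeMean[nodes])
  S <- Inv %*% diag(spec@noiseSD[nodes]^2, length(nodes)) %*% t(Inv)
  dimnames(S) <- list(nodes, nodes)
  list(mean = stats::setNames(mu, nodes), cov = S)
}

#' True total causal effect under a SEM
#'
#' Sum over all directed paths from \code{exposure} to \code{outcome} of the
#' product of edge coefficients (a closed-form oracle; equals the
#' \code{(exposure, outcome)} entry of \eqn{(I-B)^{-1}}). The standardized
#' variant multiplies by the ratio of implied SDs, matching the coefficient
#' targeted by regression on standardized variables.
#'
#' @param spec a \linkS4class{SEMSpec}.
#' @param exposure,outcome node names.
#' @param standardized logical; return the standardized effect.
#' @return numeric scalar (0 when no directed path exists).
#' @export
trueTotalEffect <- function(spec, exposure, outcome, standardized = FALSE) {
  .checkNode(spec@graph, c(exposure, outcome))
  B <- .coefMatrix(spec)
  Tm <- solve(diag(nrow(B)) - B)
  eff <- Tm[exposure, outcome]
  if (exposure == outcome) eff <- eff - 1 # exclude the trivial empty path
  if (standardized) {
    S <- impliedMoments(spec)$cov
    eff <- eff * sqrt(S[exposure, exposure] / S[outcome, outcome])
  }
  eff
}

#' True bivariate (marginal regression) coefficient under a SEM
#'
#' The population coefficient of a single-predictor regression of
#' \code{outcome} on \code{exposure}; standardized it equals the implied
#' correlation.
#'
#' @inheritParams trueTotalEffect
#' @return numeric scalar.
#' @export
trueBivariateEffect <- function(spec, exposure, outcome, standardized = FALSE) {
  .checkNode(spec@graph, c(exposure, outcome))
  S <- impliedMoments(spec)$cov
  if (standardized)
    S[exposure, outcome] / sqrt(S[exposure, exposure] * S[outcome, outcome])
  else S[exposure, outcome] / S[exposure, exposure]
}

#' True standardized effects on the analysis (oriented) scale
#'
#' Closed-form total and bivariate standardized effects of every non-outcome
#' model variable on the outcome, expressed on the oriented scale used by the
#' estimation layer (sign-flipped variables have their effect signs flipped
#' accordingly), together with whether the graph leaves an open non-causal
#' path for the exposure (in which case bivariate and total differ in the
#' population).
#'
#' @param spec a \linkS4class{SEMSpec}.
#' @param config a \linkS4class{ModelConfig} over the same graph.
#' @return data.frame with columns \code{exposure}, \code{total},
#'   \code{bivariate}, \code{confounded}.
#' @export
trueEffectsTable <- function(spec, config = cpModel()) {
  outcome <- config@outcome
  exposures <- setdiff(config@variables$name, outcome)
  g <- spec@graph
  flip <- stats::setNames(ifelse(config@variables$sign_flip, -1, 1),
                          config@variables$name)
  rows <- lapply(exposures, function(e) {
    orient <- flip[[e]] * flip[[outcome]]
    ## open non-causal path <=> x and y remain connected marginally after
    ## severing every edge out of the exposure
    gx <- g
    gx@edges <- gx@edges[gx@edges[, 1] != e, , drop = FALSE]
    confounded <- !dSeparated(gx, e, outcome)
    data.frame(exposure = e,
               total = orient * trueTotalEffect(spec, e, outcome,
                                                standardized = TRUE),
               bivariate = orient * trueBivariateEffect(spec, e, outcome,
                                                        standardized = TRUE),
               confounded = confounded, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

## deterministic per-node substream: one integer seed expands to a distinct
## RNG state per node (node identity taken from the sorted name list so the
## stream does not depend on internal node order)
.nodeSeed <- function(seed, i) {
  as.integer((as.numeric(seed) %% 2147483647) * 1009 + i * 7919) %% 2147483629L
}

#' Simulate a cohort from a linear-Gaussian SEM
#'
#' Generates nodes in topological order as
#' \code{intercept + sum(coefficient * parent) + Normal(0, noise_sd)}.
#' Reproducible: one integer seed expands deterministically into independent
#' per-node noise substreams. Latent columns are simulated like any other
#' node but stripped from the default export.
#'
#' @param spec a \linkS4class{SEMSpec}.
#' @param n number of subjects (>= 1).
#' @param seed integer seed.
#' @param keepLatent retain latent columns (for oracle tests).
#' @return a \linkS4class{SimulatedCohort}.
#' @export
simulateCohort <- function(spec, n, seed = 1L, keepLatent = FALSE) {
  if (!is.numeric(n) || length(n) != 1 || n < 1)
    stop("n must be a single integer >= 1")
  n <- as.integer(n)
  g <- spec@graph
  A <- .adjMatrix(g@nodes, g@edges)
  ord <- .topoOrder(A)
  sortedNodes <- sort(g@nodes)
  X <- matrix(0, n, length(g@nodes), dimnames = list(NULL, g@nodes))
  for (vi in ord) {
    v <- g@nodes[vi]
    set.seed(.nodeSeed(seed, match(v, sortedNodes)))
    x <- spec@nodeMean[v] + stats::rnorm(n, 0, spec@noiseSD[v])
    pa <- g@edges[g@edges[, 2] == v, 1]
    for (p in pa)
      x <- x + spec@coefficients[paste0(p, "->", v)] * X[, p]
    X[, v] <- x
  }
  obs <- observedNodes(g)
  lat <- latentNodes(g)
  methods::new("SimulatedCohort",
               data = as.data.frame(X[, obs, drop = FALSE]),
               latentData = if (keepLatent)
                 as.data.frame(X[, lat, drop = FALSE])
               else as.data.frame(matrix(numeric(0), n, 0)),
               spec = spec)
}

#' @rdname cohortData
#' @aliases cohortData,SimulatedCohort-method
#' @export
setMethod("cohortData", "SimulatedCohort", function(x, latent = FALSE) {
  if (!latent) return(x@data)
  if (ncol(x@latentData) == 0)
    stop("latent columns were not retained; simulate with keepLatent = TRUE")
  cbind(x@data, x@latentData)
})

## ---- calibration of the built-in SEM ---------------------------------------

## Participant summary targets by severity level (GMFCS I-III): mean and SD
## per observed variable, plus level sizes, used to place the simulator's
## marginal scales. These are fixtures describing a plausible clinic
## population, not estimates from any individual-level data.
.CP_LEVEL_N <- c(I = 115, II = 132, III = 53)
.cpLevelTargets <- function() {
  m <- function(I, II, III) c(I = I[1], II = II[1], III = III[1])
  tab <- list(
    Age        = list(c(10.5, 3.5), c(11.6, 3.5), c(10.9, 3.3)),
    DMC        = list(c(91, 10.0),  c(80, 12.2),  c(66, 9.8)),
    GDI        = list(c(82, 10.7),  c(71, 9.4),   c(63, 8.5)),
    SCALE      = list(c(6.8, 1.4),  c(5.2, 1.4),  c(3.0, 1.4)),
    Spasticity = list(c(1.6, 0.9),  c(2.1, 1.1),  c(2.9, 1.1)),
    Strength   = list(c(4.6, 0.3),  c(4.2, 0.5),  c(3.5, 0.6)),
    GMFM       = list(c(87, 6.2),   c(73, 7.0),   c(57, 4.6)),
    AnkleDF    = list(c(-17, 6.1),  c(-20, 8.1),  c(-20, 8.2)),
    KneeExt    = list(c(1, 4.9),    c(-2, 7.2),   c(-7, 8.8)),
    Popliteal  = list(c(-13, 17.4), c(-24, 18.7), c(-31, 18.3)),
    HipExt     = list(c(-1, 2.7),   c(-4, 5.1),   c(-8, 7.6)),
    FemRot     = list(c(-1, 24.1),  c(-4, 25.7),  c(-11, 24.9)),
    TibRot     = list(c(-1, 5.8),   c(-2, 6.7),   c(-3, 7.0)))
  tab
}

## pooled mean/SD across levels (mixture moments)
.cpPooledTargets <- function() {
  tab <- .cpLevelTargets()
  w <- .CP_LEVEL_N / sum(.CP_LEVEL_N)
  out <- lapply(tab, function(lv) {
    ms <- vapply(lv, `[`, numeric(1), 1L)
    ss <- vapply(lv, `[`, numeric(1), 2L)
    mu <- sum(w * ms)
    v <- sum(w * (ss^2 + ms^2)) - mu^2
    c(mu, sqrt(v))
  })
  out
}

## standardized path strengths for all upstream edges; hand-set once so that
## implied marginal SDs sit near the clinic targets. GMFM's incoming edges
## are not here: they carry the raw-unit predictive coefficients directly.
.cpPathStrengths <- function() {
  s <- c("Injury->MC" = -0.80,
         "MC->SCALE" = 0.75, "Age->SCALE" = 0.10,
         "MC->DMC" = 0.80, "Age->DMC" = 0.05,
         "Injury->Strength" = -0.40, "MC->Strength" = 0.50,
         "Injury->Spasticity" = 0.70, "Age->Spasticity" = 0.05)
  for (v in .CP_CONTRACTURES)
    s[paste0(c("Strength", "Spasticity", "DMC", "SCALE", "Age", "Contracture"),
             "->", v)] <- c(0.10, -0.15, 0.10, 0.10, -0.15, -0.45)
  for (v in .CP_TORSIONS)
    s[paste0(c("Strength", "Spasticity", "DMC", "SCALE", "Age", "Torsion"),
             "->", v)] <- c(0.05, -0.10, 0.05, 0.05, -0.05, -0.45)
  s[paste0(c("Strength", "Spasticity", "DMC", "SCALE", "Age",
             "AnkleDF", "KneeExt", "Popliteal", "HipExt", "TibRot", "FemRot"),
           "->", "GDI")] <-
    c(0.15, -0.10, 0.25, 0.15, -0.05, 0.10, 0.05, 0.05, 0.05, 0.10, 0.10)
  s
}

## GMFM structural coefficients in raw units, i.e. the published per-unit
## predictive coefficients recoded onto the raw scale (contracture
## coefficients change sign because raw contractures are negative-coded
## while the predictive model reports positive "limitation" degrees)
.cpGmfmRawCoefs <- function() {
  c("Age->GMFM" = 0.08, "SCALE->GMFM" = 2.3, "DMC->GMFM" = 0.24,
    "Strength->GMFM" = 4.5, "Spasticity->GMFM" = -0.57, "GDI->GMFM" = 0.17,
    "AnkleDF->GMFM" = 0.13, "KneeExt->GMFM" = 0.11, "Popliteal->GMFM" = 0.01,
    "HipExt->GMFM" = 0.17)
}

## build a SEMSpec over `graph` hitting target (mean, sd) per node:
## raw coefficient for u -> v = strength * sd_v / implied_sd_u; noise variance
## absorbs the unexplained remainder. Nodes in `fixedRaw`/`fixedNoise` keep
## those raw coefficients / noise SDs and let their variance float.
.calibrateSEM <- function(graph, strengths, targets, fixedRaw = numeric(0),
                          fixedNoise = numeric(0)) {
  nodes <- graph@nodes
  A <- .adjMatrix(nodes, graph@edges)
  ord <- .topoOrder(A)
  S <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  mu <- stats::setNames(rep(0, length(nodes)), nodes)
  coefs <- stats::setNames(numeric(0), character(0))
  noise <- stats::setNames(rep(NA_real_, length(nodes)), nodes)
  icept <- stats::setNames(rep(NA_real_, length(nodes)), nodes)
  for (vi in ord) {
    v <- nodes[vi]
    tgt <- targets[[v]]
    pa <- graph@edges[graph@edges[, 2] == v, 1]
    keys <- paste0(pa, "->", v)
    b <- numeric(length(pa))
    for (k in seq_along(pa)) {
      b[k] <- if (keys[k] %in% names(fixedRaw)) fixedRaw[[keys[k]]]
      else strengths[[keys[k]]] * tgt[2] / sqrt(S[pa[k], pa[k]])
    }
    expl <- if (length(pa) > 0) drop(t(b) %*% S[pa, pa, drop = FALSE] %*% b) else 0
    if (v %in% names(fixedNoise)) {
      nv <- fixedNoise[[v]]^2
    } else {
      nv <- tgt[2]^2 - expl
      if (nv <= 1e-8)
        stop("calibration infeasible at node ", v,
             ": explained variance exceeds the target")
    }
    S[v, v] <- expl + nv
    if (length(pa) > 0) {
      cross <- drop(t(S[pa, , drop = FALSE]) %*% b)
      S[v, ] <- S[v, ] + cross
      S[, v] <- S[, v] + cross
      S[v, v] <- expl + nv # restore (cross added it twice on the diagonal)
    }
    muV <- tgt[1]
    icept[v] <- muV - if (length(pa) > 0) sum(b * mu[pa]) else 0
    mu[v] <- muV
    coefs[keys] <- b
    noise[v] <- sqrt(nv)
  }
  semSpec(graph, coefs, noise, icept)
}

#' Built-in calibrated SEM for the cerebral-palsy model
#'
#' A linear-Gaussian structural equation system over the built-in causal
#' graph. GMFM-66's incoming edges carry the published per-unit predictive
#' coefficients (recoded to the raw sign conventions); all upstream path
#' strengths are fixed package constants chosen once so that the implied
#' marginal means and SDs resemble a pooled clinical gait-laboratory cohort.
#' GMFM's residual SD is 6 points. The spec is a test fixture for the
#' pipeline, not an estimate of any real cohort.
#'
#' @return a \linkS4class{SEMSpec}.
#' @examples
#' spec <- defaultSEM()
#' trueTotalEffect(spec, "Strength", "GMFM", standardized = TRUE)
#' @export
defaultSEM <- function() {
  pooled <- .cpPooledTargets()
  targets <- lapply(pooled, function(x) x)
  for (l in .CP_LATENT) targets[[l]] <- c(0, 1)
  .calibrateSEM(cpModel()@graph, .cpPathStrengths(), targets,
                fixedRaw = .cpGmfmRawCoefs(), fixedNoise = c(GMFM = 6))
}

#' Severity-level cohort fixture
#'
#' Builds the calibrated SEM with node means and SDs placed at the embedded
#' per-level participant summaries (GMFCS levels I-III) and simulates
#' \code{n} subjects, so marginal scales resemble that severity stratum.
#'
#' @param level \code{"I"}, \code{"II"} or \code{"III"}.
#' @param n number of subjects.
#' @param seed integer seed.
#' @return a \linkS4class{SimulatedCohort}.
#' @export
cohortFixture <- function(level = c("I", "II", "III"), n, seed = 1L) {
  level <- match.arg(level)
  lv <- match(level, c("I", "II", "III"))
  tab <- .cpLevelTargets()
  targets <- lapply(tab, function(x) x[[lv]])
  for (l in .CP_LATENT) targets[[l]] <- c(0, 1)
  spec <- .calibrateSEM(cpModel()@graph, .cpPathStrengths(), targets,
                        fixedRaw = .cpGmfmRawCoefs(), fixedNoise = c(GMFM = 6))
  simulateCohort(spec, n, seed = seed)
}

## ---- SEMSpec YAML round-trip ------------------------------------------------

#' Write a SEM specification to YAML
#' @param spec a \linkS4class{SEMSpec}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeSEMSpec <- function(spec, path) {
  g <- spec@graph
  yaml::write_yaml(list(
    latent = as.list(latentNodes(g)),
    nodes = as.list(nodeNames(g)),
    edges = as.list(paste(edgeMatrix(g)[, 1], "->", edgeMatrix(g)[, 2])),
    coefficients = as.list(spec@coefficients),
    noise_sd = as.list(spec@noiseSD),
    node_mean = as.list(spec@nodeMean)), path, precision = 17)
  invisible(path)
}

#' Read a SEM specification from YAML
#' @param path file written by \code{\link{writeSEMSpec}}.
#' @return a \linkS4class{SEMSpec}.
#' @export
readSEMSpec <- function(path) {
  y <- yaml::read_yaml(path)
  g <- CausalGraph(unlist(y$edges), latent = unlist(y$latent),
                   nodes = unlist(y$nodes))
  semSpec(g,
          unlist(y$coefficients),
          unlist(y$noise_sd)[nodeNames(g)],
          unlist(y$node_mean)[nodeNames(g)])
}
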