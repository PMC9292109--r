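# shared fixtures: tiny canonical graphs and a random-DAG generator

chainGraph <- function() CausalGraph(c("A -> B", "B -> C"))
colliderGraph <- function() CausalGraph(c("A -> B", "C -> B"))
confounderGraph <- function() CausalGraph(c("C -> X", "C -> Y", "X -> Y"))
mediatorGraph <- function() CausalGraph(c("X -> M", "M -> Y", "X -> Y"))

# random DAG on n nodes, edges respect a fixed topological order
randomDag <- function(n, p = 0.3) {
  nodes <- LETTERS[seq_len(n)]
  up <- which(upper.tri(matrix(0, n, n)) & matrix(stats::runif(n * n) < p, n, n),
              arr.ind = TRUE)
  CausalGraph(edges = cbind(nodes[up[, 1]], nodes[up[, 2]]), nodes = nodes)
}

# algebraic d-separation oracle, independent of any graph-traversal code:
# draw a linear-Gaussian SEM with random coefficients bounded away from zero,
# compute the implied covariance in closed form, and read the partial
# correlation of (x, y) given z off the inverse covariance. In such a system
# the partial correlation vanishes iff x and y are d-separated by z (almost
# surely in the coefficients). Returns the partial correlation.
gaussianPartialR <- function(g, x, y, z = character(0), seed = 1) {
  set.seed(seed)
  em <- edgeMatrix(g)
  keys <- if (nrow(em) > 0) paste0(em[, 1], "->", em[, 2]) else character(0)
  coefs <- stats::setNames(
    stats::runif(nrow(em), 0.3, 0.9) * sample(c(-1, 1), nrow(em), TRUE), keys)
  nn <- nodeNames(g)
  spec <- semSpec(g, coefs,
                  stats::setNames(stats::runif(length(nn), 0.5, 1.5), nn))
  S <- impliedMoments(spec)$cov
  idx <- c(x, y, z)
  P <- solve(S[idx, idx, drop = FALSE])
  -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
}

# TRUE/FALSE verdict from the algebraic oracle over two coefficient draws
gaussianSeparated <- function(g, x, y, z = character(0)) {
  r <- vapply(c(1, 2), function(s) gaussianPartialR(g, x, y, z, seed = s),
              numeric(1))
  if (all(abs(r) < 1e-9)) TRUE
  else if (all(abs(r) > 1e-6)) FALSE
  else stop("algebraic oracle is ambiguous for (", x, ", ", y, ")")
}

# all subsets of an index pool as a list of integer vectors
allSubsets <- function(pool) {
  lapply(0:(2^length(pool) - 1), function(m)
    pool[bitwAnd(bitwShiftR(m, seq_along(pool) - 1L), 1L) == 1L])
}

# simulated, standardized built-in cohort (memoised per test file run)
stdCohort <- local({
  cache <- new.env()
  function(n = 5000, seed = 101) {
    key <- paste0("n", n, "s", seed)
    if (is.null(cache[[key]])) {
      co <- simulateCohort(defaultSEM(), n, seed = seed)
      cache[[key]] <- standardizeAndOrient(variableTable(cohortData(co)),
                                           cpModel())
    }
    cache[[key]]
  }
})
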