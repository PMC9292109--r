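#' @include AllGenerics.R
NULL

## ---- internal graph primitives (plain matrices, used by validity) ----------

## adjacency matrix from node vector + 2-col edge matrix
.adjMatrix <- function(nodes, edges) {
  n <- length(nodes)
  A <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  if (nrow(edges) > 0) A[edges] <- TRUE
  A
}

## Kahn topological sort; returns node order or NULL when cyclic
.topoOrder <- function(A) {
  n <- nrow(A)
  indeg <- colSums(A)
  order <- integer(0)
  active <- rep(TRUE, n)
  repeat {
    src <- which(active & indeg == 0)
    if (length(src) == 0) break
    order <- c(order, src)
    active[src] <- FALSE
    if (length(src) == 1) indeg <- indeg - A[src, ] else indeg <- indeg - colSums(A[src, , drop = FALSE])
  }
  if (any(active)) NULL else order
}

## reflexive-transitive closure: R[u, v] TRUE iff directed path u -> ... -> v
## (or u == v); boolean matrix squaring, fine at the graph sizes used here
.reachClosure <- function(A) {
  R <- A | diag(TRUE, nrow(A))
  repeat {
    R2 <- (R %*% R) > 0
    if (identical(R2, R)) break
    R <- R2
  }
  dimnames(R) <- dimnames(A)
  R
}

.validCausalGraph <- function(object) {
  msg <- character(0)
  nodes <- object@nodes
  edges <- object@edges
  if (anyDuplicated(nodes)) msg <- c(msg, "duplicate node names")
  if (length(object@latent) != length(nodes) ||
      !identical(names(object@latent), nodes))
    msg <- c(msg, "latent flags must be named after, and parallel to, nodes")
  if (!is.matrix(edges) || ncol(edges) != 2)
    msg <- c(msg, "edges must be a two-column character matrix")
  else {
    bad <- setdiff(c(edges), nodes)
    if (length(bad) > 0)
      msg <- c(msg, paste0("edge endpoint(s) not declared as nodes: ",
                           paste(unique(bad), collapse = ", ")))
    if (nrow(edges) > 0 && any(edges[, 1] == edges[, 2]))
      msg <- c(msg, "self-loops are not allowed")
    if (anyDuplicated(paste(edges[, 1], edges[, 2], sep = "\r")))
      msg <- c(msg, "duplicate edges are not allowed")
    if (length(msg) == 0) {
      A <- .adjMatrix(nodes, edges)
      if (is.null(.topoOrder(A)))
        msg <- c(msg, "graph contains a directed cycle")
    }
  }
  if (length(msg) == 0) TRUE else msg
}

#' Causal directed acyclic graph with latent-node flags
#'
#' A DAG over named variables, each flagged observed or latent. Acyclicity,
#' absence of self-loops and duplicate edges, and declaration of every edge
#' endpoint are enforced by the validity method on construction and after
#' every mutation. Node names are case-sensitive exact strings.
#'
#' @slot nodes character vector of node names.
#' @slot latent named logical vector parallel to \code{nodes}.
#' @slot edges two-column character matrix (\code{from}, \code{to}).
#'
#' @seealso \code{\link{CausalGraph}} (constructor), \code{\link{dSeparated}},
#'   \code{\link{cpModel}}
#' @export
setClass("CausalGraph",
         representation(nodes = "character", latent = "logical",
                        edges = "matrix"),
         validity = .validCausalGraph)

#' Model configuration: graph plus variable metadata
#'
#' Bundles a \linkS4class{CausalGraph} with per-variable measurement metadata
#' (units, orientation flags, typically-developing offsets, plausible ranges)
#' and the outcome name.
#'
#' @slot graph a \linkS4class{CausalGraph}.
#' @slot variables data.frame, one row per observed variable: \code{name},
#'   \code{role} (\code{exposure}/\code{outcome}/\code{age}), \code{units},
#'   \code{sign_flip} (TRUE when larger raw value means more impairment),
#'   \code{predictive_flip} (TRUE when the raw-unit predictive model recodes
#'   the variable by -1 into impairment-positive units), \code{td_offset}
#'   (typically-developing reference subtracted upstream of the raw data),
#'   \code{lo}, \code{hi} (plausible raw range).
#' @slot outcome character scalar, the outcome node name.
#' @export
setClass("ModelConfig",
         representation(graph = "CausalGraph", variables = "data.frame",
                        outcome = "character"),
         validity = function(object) {
           msg <- character(0)
           need <- c("name", "role", "units", "sign_flip", "predictive_flip",
                     "td_offset", "lo", "hi")
           if (!all(need %in% names(object@variables)))
             msg <- c(msg, paste("variables must have columns:",
                                 paste(need, collapse = ", ")))
           obs <- object@graph@nodes[!object@graph@latent]
           if (length(msg) == 0 && !setequal(object@variables$name, obs))
             msg <- c(msg, "variable metadata must cover exactly the observed nodes")
           if (length(object@outcome) != 1 ||
               !(object@outcome %in% object@graph@nodes))
             msg <- c(msg, "outcome must be a single declared node")
           if (length(msg) == 0 && object@graph@latent[object@outcome])
             msg <- c(msg, "outcome must be observed")
           if (length(msg) == 0) TRUE else msg
         })

#' Linear-Gaussian structural equation specification
#'
#' Each node is generated as
#' \code{intercept + sum(coefficient * parent) + Normal(0, noise_sd)}.
#' Coefficient keys must match the graph's edges exactly and every node needs
#' a positive noise SD; the implied covariance is then positive definite by
#' construction.
#'
#' @slot graph a \linkS4class{CausalGraph}.
#' @slot coefficients named numeric, names \code{"from->to"} for every edge.
#' @slot noiseSD named numeric, one positive entry per node.
#' @slot nodeMean named numeric, per-node intercept.
#' @seealso \code{\link{simulateCohort}}, \code{\link{trueTotalEffect}},
#'   \code{\link{defaultSEM}}
#' @export
setClass("SEMSpec",
         representation(graph = "CausalGraph", coefficients = "numeric",
                        noiseSD = "numeric", nodeMean = "numeric"),
         validity = function(object) {
           msg <- character(0)
           g <- object@graph
           keys <- if (nrow(g@edges) > 0)
             paste0(g@edges[, 1], "->", g@edges[, 2]) else character(0)
           if (!setequal(names(object@coefficients), keys) ||
               length(object@coefficients) != length(keys))
             msg <- c(msg, paste0(
               "coefficient keys must match graph edges exactly; offending: ",
               paste(c(setdiff(names(object@coefficients), keys),
                       setdiff(keys, names(object@coefficients))),
                     collapse = ", ")))
           if (!setequal(names(object@noiseSD), g@nodes))
             msg <- c(msg, "noiseSD must name every node exactly once")
           else if (any(object@noiseSD <= 0))
             msg <- c(msg, paste0("noise SD must be positive; offending: ",
                                  paste(names(object@noiseSD)[object@noiseSD <= 0],
                                        collapse = ", ")))
           if (!setequal(names(object@nodeMean), g@nodes))
             msg <- c(msg, "nodeMean must name every node exactly once")
           if (length(msg) == 0) TRUE else msg
         })

#' Subjects-by-variables table with transformation provenance
#'
#' Thin wrapper around a numeric data.frame recording whether columns are in
#' raw clinical units or have been standardized (mean 0, SD 1) and oriented
#' (larger value = less impairment). Standardized tables must be complete
#' cases with each column holding mean 0 and SD 1 to within 1e-9.
#'
#' @slot data data.frame of numeric columns.
#' @slot state \code{"raw"} or \code{"standardized"}.
#' @seealso \code{\link{variableTable}}, \code{\link{standardizeAndOrient}}
#' @export
setClass("VariableTable",
         representation(data = "data.frame", state = "character"),
         validity = function(object) {
           msg <- character(0)
           if (!object@state %in% c("raw", "standardized"))
             msg <- c(msg, "state must be 'raw' or 'standardized'")
           if (!all(vapply(object@data, is.numeric, logical(1))))
             msg <- c(msg, "all columns must be numeric")
           if (identical(object@state, "standardized")) {
             if (anyNA(object@data))
               msg <- c(msg, "standardized tables must be complete cases")
             else if (ncol(object@data) > 0 && nrow(object@data) > 1) {
               m <- vapply(object@data, mean, numeric(1))
               s <- vapply(object@data, stats::sd, numeric(1))
               if (any(abs(m) > 1e-9) || any(abs(s - 1) > 1e-9))
                 msg <- c(msg, "standardized columns must have mean 0 and SD 1 (tol 1e-9)")
             }
           }
           if (length(msg) == 0) TRUE else msg
         })

#' Simulated cohort with its generating specification
#'
#' @slot data data.frame of observed columns (the default export).
#' @slot latentData data.frame of latent columns (zero columns unless
#'   requested at simulation; intended for oracle tests only).
#' @slot spec the generating \linkS4class{SEMSpec}.
#' @export
setClass("SimulatedCohort",
         representation(data = "data.frame", latentData = "data.frame",
                        spec = "SEMSpec"))

## ---- show methods ----------------------------------------------------------

setMethod("show", "CausalGraph", function(object) {
  nl <- sum(object@latent)
  cat(sprintf("CausalGraph: %d nodes (%d observed, %d latent), %d edges\n",
              length(object@nodes), length(object@nodes) - nl, nl,
              nrow(object@edges)))
  if (nl > 0)
    cat("  latent:", paste(object@nodes[object@latent], collapse = ", "), "\n")
})

setMethod("show", "ModelConfig", function(object) {
  cat("ModelConfig\n")
  methods::show(object@graph)
  cat("  outcome:", object@outcome, "\n")
  cat("  variables:", nrow(object@variables), "observed measures\n")
})

setMethod("show", "SEMSpec", function(object) {
  cat(sprintf("SEMSpec: %d nodes, %d edge coefficients\n",
              length(object@graph@nodes), length(object@coefficients)))
})

setMethod("show", "VariableTable", function(object) {
  cat(sprintf("VariableTable (%s): %d subjects x %d variables\n",
              object@state, nrow(object@data), ncol(object@data)))
})

setMethod("show", "SimulatedCohort", function(object) {
  cat(sprintf("SimulatedCohort: %d subjects x %d observed variables%s\n",
              nrow(object@data), ncol(object@data),
              if (ncol(object@latentData) > 0) " (+latent columns)" else ""))
})
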