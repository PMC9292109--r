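#' Node names of a causal graph
#'
#' @param x a \linkS4class{CausalGraph} (or object containing one).
#' @return character vector of node names.
#' @export
setGeneric("nodeNames", function(x) standardGeneric("nodeNames"))

#' Edge matrix of a causal graph
#'
#' @param x a \linkS4class{CausalGraph}.
#' @return two-column character matrix with columns \code{from}, \code{to}.
#' @export
setGeneric("edgeMatrix", function(x) standardGeneric("edgeMatrix"))

#' Latent node names
#' @param x a \linkS4class{CausalGraph}.
#' @return character vector.
#' @export
setGeneric("latentNodes", function(x) standardGeneric("latentNodes"))

#' Observed node names
#' @param x a \linkS4class{CausalGraph}.
#' @return character vector.
#' @export
setGeneric("observedNodes", function(x) standardGeneric("observedNodes"))

#' Ancestors of a node (reflexive-transitive)
#'
#' Every node with a directed path into \code{v}, including \code{v} itself.
#'
#' @param x a \linkS4class{CausalGraph}.
#' @param v node name.
#' @return character vector of node names (graph order).
#' @export
setGeneric("ancestors", function(x, v) standardGeneric("ancestors"))

#' Descendants of a node (reflexive-transitive)
#' @inheritParams ancestors
#' @return character vector of node names (graph order).
#' @export
setGeneric("descendants", function(x, v) standardGeneric("descendants"))

#' Direct causes (parents) of a node
#' @inheritParams ancestors
#' @return character vector.
#' @export
setGeneric("parentsOf", function(x, v) standardGeneric("parentsOf"))

#' Direct effects (children) of a node
#' @inheritParams ancestors
#' @return character vector.
#' @export
setGeneric("childrenOf", function(x, v) standardGeneric("childrenOf"))

#' Add a directed edge
#'
#' Acyclicity is re-checked immediately; adding a cycle-creating edge fails.
#'
#' @param x a \linkS4class{CausalGraph}.
#' @param from,to node names.
#' @return a new \linkS4class{CausalGraph}.
#' @export
setGeneric("addEdge", function(x, from, to) standardGeneric("addEdge"))

#' Remove a directed edge
#' @inheritParams addEdge
#' @return a new \linkS4class{CausalGraph}.
#' @export
setGeneric("removeEdge", function(x, from, to) standardGeneric("removeEdge"))

#' Extract the causal graph from a container
#' @param x a \linkS4class{ModelConfig} or \linkS4class{SEMSpec}.
#' @return a \linkS4class{CausalGraph}.
#' @export
setGeneric("causalGraph", function(x) standardGeneric("causalGraph"))

#' Export a graph or model as DOT
#'
#' Latent nodes are rendered with dashed borders; node and edge ordering is
#' deterministic so output is reproducible byte-for-byte.
#'
#' @param x a \linkS4class{CausalGraph} or \linkS4class{ModelConfig}.
#' @param name digraph name.
#' @return a single character string of DOT source.
#' @export
setGeneric("exportDot", function(x, name = "model") standardGeneric("exportDot"))

#' Export a graph as GraphML
#' @param x a \linkS4class{CausalGraph} or \linkS4class{ModelConfig}.
#' @return a single character string of GraphML XML.
#' @export
setGeneric("exportGraphML", function(x) standardGeneric("exportGraphML"))

#' Export a graph as an edge-list text block
#'
#' One \code{"cause -> effect"} line per edge; latent and isolated nodes are
#' declared on their own lines (\code{"X [latent]"} / \code{"X"}). The format
#' round-trips through \code{\link{parseEdgeList}}.
#'
#' @param x a \linkS4class{CausalGraph} or \linkS4class{ModelConfig}.
#' @return a single character string.
#' @export
setGeneric("exportEdgeList", function(x) standardGeneric("exportEdgeList"))

#' Subject data of a simulated cohort
#' @param x a \linkS4class{SimulatedCohort}.
#' @param latent logical; include latent columns (if retained at simulation).
#' @return data.frame of subjects by variables.
#' @export
setGeneric("cohortData", function(x, latent = FALSE) standardGeneric("cohortData"))

#' Variable metadata of a model configuration
#' @param x a \linkS4class{ModelConfig}.
#' @return data.frame with one row per observed model variable.
#' @export
setGeneric("variableMeta", function(x) standardGeneric("variableMeta"))

#' Outcome variable of a model configuration
#' @param x a \linkS4class{ModelConfig}.
#' @return character scalar.
#' @export
setGeneric("outcomeName", function(x) standardGeneric("outcomeName"))
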