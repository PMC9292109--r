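#' @include AllClasses.R
NULL

#' Construct a causal DAG
#'
#' Construction is all-or-nothing: any violation (cycle, undeclared endpoint,
#' self-loop, duplicate edge) aborts with a validity error.
#'
#' @param edges either a character vector of \code{"A -> B"} strings or a
#'   two-column character matrix / data.frame (\code{from}, \code{to}).
#' @param latent character vector of node names to flag latent.
#' @param nodes optional additional (possibly isolated) node names; endpoints
#'   of \code{edges} are declared automatically.
#' @return a \linkS4class{CausalGraph}.
#' @examples
#' g <- CausalGraph(c("A -> B", "B -> C"))
#' ancestors(g, "C")
#' @export
CausalGraph <- function(edges = character(0), latent = character(0),
                        nodes = character(0)) {
  if (is.character(edges) && is.null(dim(edges))) {
    if (length(edges) == 0) {
      em <- matrix(character(0), 0, 2)
    } else {
      parts <- strsplit(edges, "->", fixed = TRUE)
      if (any(lengths(parts) != 2))
        stop("edge strings must have the form 'cause -> effect'")
      em <- cbind(trimws(vapply(parts, `[`, "", 1L)),
                  trimws(vapply(parts, `[`, "", 2L)))
    }
  } else {
    em <- as.matrix(edges)
    if (ncol(em) != 2) stop("edge matrix must have two columns")
    em <- cbind(trimws(em[, 1]), trimws(em[, 2]))
  }
  storage.mode(em) <- "character"
  allNodes <- unique(c(em[, 1], em[, 2], nodes, latent))
  lat <- stats::setNames(allNodes %in% latent, allNodes)
  colnames(em) <- c("from", "to")
  methods::new("CausalGraph", nodes = allNodes, latent = lat, edges = em)
}

.checkNode <- function(g, v) {
  miss <- setdiff(v, g@nodes)
  if (length(miss) > 0)
    stop("unknown node(s): ", paste(miss, collapse = ", "))
  invisible(v)
}

## cached index of derived matrices; cheap enough to recompute per call at
## the sizes handled here
.graphIndex <- function(g) {
  A <- .adjMatrix(g@nodes, g@edges)
  list(nodes = g@nodes, latent = g@latent, adj = A, reach = .reachClosure(A))
}

#' @describeIn CausalGraph node names
#' @aliases nodeNames,CausalGraph-method
#' @param x a \code{CausalGraph}.
#' @export
setMethod("nodeNames", "CausalGraph", function(x) x@nodes)

#' @rdname CausalGraph
#' @aliases edgeMatrix,CausalGraph-method
#' @export
setMethod("edgeMatrix", "CausalGraph", function(x) x@edges)

#' @rdname CausalGraph
#' @aliases latentNodes,CausalGraph-method
#' @export
setMethod("latentNodes", "CausalGraph", function(x) x@nodes[x@latent])

#' @rdname CausalGraph
#' @aliases observedNodes,CausalGraph-method
#' @export
setMethod("observedNodes", "CausalGraph", function(x) x@nodes[!x@latent])

#' @rdname ancestors
#' @aliases ancestors,CausalGraph-method
#' @export
setMethod("ancestors", "CausalGraph", function(x, v) {
  .checkNode(x, v)
  R <- .reachClosure(.adjMatrix(x@nodes, x@edges))
  x@nodes[R[, v]]
})

#' @rdname descendants
#' @aliases descendants,CausalGraph-method
#' @export
setMethod("descendants", "CausalGraph", function(x, v) {
  .checkNode(x, v)
  R <- .reachClosure(.adjMatrix(x@nodes, x@edges))
  x@nodes[R[v, ]]
})

#' @rdname parentsOf
#' @aliases parentsOf,CausalGraph-method
#' @export
setMethod("parentsOf", "CausalGraph", function(x, v) {
  .checkNode(x, v)
  unique(x@edges[x@edges[, 2] == v, 1])
})

#' @rdname childrenOf
#' @aliases childrenOf,CausalGraph-method
#' @export
setMethod("childrenOf", "CausalGraph", function(x, v) {
  .checkNode(x, v)
  unique(x@edges[x@edges[, 1] == v, 2])
})

#' @rdname addEdge
#' @aliases addEdge,CausalGraph-method
#' @export
setMethod("addEdge", "CausalGraph", function(x, from, to) {
  .checkNode(x, c(from, to))
  g <- x
  g@edges <- rbind(g@edges, c(from, to))
  methods::validObject(g) # re-runs acyclicity/duplicate checks immediately
  g
})

#' @rdname removeEdge
#' @aliases removeEdge,CausalGraph-method
#' @export
setMethod("removeEdge", "CausalGraph", function(x, from, to) {
  hit <- x@edges[, 1] == from & x@edges[, 2] == to
  if (!any(hit)) stop("no such edge: ", from, " -> ", to)
  g <- x
  g@edges <- g@edges[!hit, , drop = FALSE]
  methods::validObject(g)
  g
})

## ---- serialization ---------------------------------------------------------

#' Parse an edge-list text block into a CausalGraph
#'
#' Inverse of \code{\link{exportEdgeList}}: one \code{"cause -> effect"} per
#' line; standalone lines declare nodes, with \code{"X [latent]"} marking
#' latents. Blank lines and \code{#} comments are ignored.
#'
#' @param text character vector of lines (or a single string with newlines).
#' @return a \linkS4class{CausalGraph}.
#' @export
parseEdgeList <- function(text) {
  lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  edges <- lines[grepl("->", lines, fixed = TRUE)]
  decls <- lines[!grepl("->", lines, fixed = TRUE)]
  latent <- trimws(sub("\\[latent\\]\\s*$", "", decls[grepl("\\[latent\\]\\s*$", decls)]))
  plain <- trimws(decls[!grepl("\\[latent\\]\\s*$", decls)])
  CausalGraph(edges, latent = latent, nodes = plain)
}

.quoteDot <- function(x) paste0('"', gsub('"', '\\\\"', x), '"')

#' @rdname exportEdgeList
#' @aliases exportEdgeList,CausalGraph-method
#' @export
setMethod("exportEdgeList", "CausalGraph", function(x) {
  lat <- x@nodes[x@latent]
  attached <- unique(c(x@edges))
  isolated <- setdiff(x@nodes[!x@latent], attached)
  lines <- c(paste0(sort(lat), " [latent]"), sort(isolated),
             if (nrow(x@edges) > 0) paste(x@edges[, 1], "->", x@edges[, 2]))
  paste0(paste(lines, collapse = "\n"), "\n")
})

#' @rdname exportDot
#' @aliases exportDot,CausalGraph-method
#' @export
setMethod("exportDot", "CausalGraph", function(x, name = "model") {
  decl <- vapply(x@nodes, function(v) {
    if (x@latent[v]) paste0("  ", .quoteDot(v), " [style=dashed];")
    else paste0("  ", .quoteDot(v), ";")
  }, "")
  el <- if (nrow(x@edges) > 0)
    paste0("  ", .quoteDot(x@edges[, 1]), " -> ", .quoteDot(x@edges[, 2]), ";")
  else character(0)
  paste0("digraph ", .quoteDot(name), " {\n",
         paste(c(decl, el), collapse = "\n"),
         if (length(decl) + length(el) > 0) "\n" else "", "}\n")
})

.xmlEscape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub('"', "&quot;", x, fixed = TRUE)
}

#' @rdname exportGraphML
#' @aliases exportGraphML,CausalGraph-method
#' @export
setMethod("exportGraphML", "CausalGraph", function(x) {
  nodes <- vapply(x@nodes, function(v) paste0(
    '    <node id="', .xmlEscape(v), '"><data key="latent">',
    tolower(as.character(x@latent[v])), "</data></node>"), "")
  edges <- if (nrow(x@edges) > 0) paste0(
    '    <edge source="', .xmlEscape(x@edges[, 1]),
    '" target="', .xmlEscape(x@edges[, 2]), '"/>') else character(0)
  paste0('<?xml version="1.0" encoding="UTF-8"?>\n',
         '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">\n',
         '  <key id="latent" for="node" attr.name="latent" attr.type="boolean"/>\n',
         '  <graph id="G" edgedefault="directed">\n',
         paste(c(nodes, edges), collapse = "\n"), "\n",
         "  </graph>\n</graphml>\n")
})

## graph equality up to node order and edge order
.graphEqual <- function(a, b) {
  setequal(a@nodes, b@nodes) &&
    setequal(a@nodes[a@latent], b@nodes[b@latent]) &&
    setequal(paste(a@edges[, 1], a@edges[, 2], sep = "\r"),
             paste(b@edges[, 1], b@edges[, 2], sep = "\r"))
}
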