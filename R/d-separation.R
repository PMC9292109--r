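#' @include causal-graph.R
NULL

## ---- efficient kernel: moralized-ancestral-subgraph reachability -----------
## indices are integer positions into the node vector; `reach` is the
## reflexive-transitive closure (reach[u, v] TRUE iff u is an ancestor-or-self
## of v)
.dsepKernel <- function(adj, reach, xi, yi, zi) {
  n <- nrow(adj)
  relevant <- reach[, xi] | reach[, yi]
  if (length(zi) > 0)
    relevant <- relevant | (rowSums(reach[, zi, drop = FALSE]) > 0)
  A <- adj & outer(relevant, relevant)
  ## moralize: skeleton plus marriages between co-parents of a common child
  M <- A | t(A) | ((A %*% t(A)) > 0)
  diag(M) <- FALSE
  if (length(zi) > 0) {
    M[zi, ] <- FALSE
    M[, zi] <- FALSE
  }
  ## reachability from x in the undirected moral graph
  seen <- rep(FALSE, n)
  seen[xi] <- TRUE
  frontier <- seen
  while (any(frontier)) {
    nxt <- (colSums(M[frontier, , drop = FALSE]) > 0) & !seen
    if (nxt[yi]) return(FALSE)
    seen <- seen | nxt
    frontier <- nxt
  }
  TRUE
}

.dsepValidate <- function(g, x, y, z, allowLatentConditioning) {
  .checkNode(g, c(x, y, z))
  if (identical(x, y)) stop("x and y must be distinct nodes")
  if (x %in% z || y %in% z)
    stop("conditioning set must not contain x or y")
  if (!allowLatentConditioning) {
    latZ <- z[g@latent[z]]
    if (length(latZ) > 0)
      stop("latent node(s) in conditioning set: ",
           paste(latZ, collapse = ", "),
           " (set allowLatentConditioning = TRUE to permit)")
  }
}

#' Test d-separation in a causal DAG
#'
#' Decides whether every path between \code{x} and \code{y} is blocked by the
#' conditioning set \code{z} under the standard d-separation rules (a chain or
#' fork is blocked when its middle node is conditioned on; a collider is
#' blocked unless it or one of its descendants is conditioned on). Implemented
#' by reachability in the moralized ancestral subgraph (the Bayes-ball /
#' Lauritzen construction); \code{\link{dSeparatedBrute}} is an independent
#' exhaustive implementation of the same contract kept as a cross-check.
#'
#' @param g a \linkS4class{CausalGraph}.
#' @param x,y distinct node names, neither in \code{z}.
#' @param z character vector of conditioning nodes (default empty). Latent
#'   nodes are rejected unless \code{allowLatentConditioning = TRUE}.
#' @param allowLatentConditioning logical; permit latent nodes in \code{z}.
#' @return logical scalar.
#' @examples
#' g <- CausalGraph(c("A -> B", "B -> C"))
#' dSeparated(g, "A", "C", "B")   # chain blocked by its middle node
#' @export
dSeparated <- function(g, x, y, z = character(0),
                       allowLatentConditioning = FALSE) {
  .dsepValidate(g, x, y, z, allowLatentConditioning)
  ix <- .graphIndex(g)
  .dsepKernel(ix$adj, ix$reach,
              match(x, g@nodes), match(y, g@nodes), match(z, g@nodes))
}

## ---- brute-force oracle: exhaustive simple-path enumeration -----------------

## enumerate all simple paths between xi and yi over the skeleton; each path
## is an integer vector of node indices. Aborts when more than `budget` paths
## are found.
.enumPaths <- function(adj, xi, yi, budget = 65536L) {
  skel <- adj | t(adj)
  n <- nrow(adj)
  paths <- vector("list", 0)
  stack <- list(xi)
  ## iterative DFS keeping the current path
  recurse <- function(path, visited) {
    last <- path[length(path)]
    for (nb in which(skel[last, ])) {
      if (nb == yi) {
        paths[[length(paths) + 1L]] <<- c(path, yi)
        if (length(paths) > budget)
          stop("path budget exceeded (> ", budget,
               " simple paths); use dSeparated() instead")
      } else if (!visited[nb]) {
        visited[nb] <- TRUE
        recurse(c(path, nb), visited)
        visited[nb] <- FALSE
      }
    }
  }
  visited <- rep(FALSE, n)
  visited[xi] <- TRUE
  recurse(xi, visited)
  paths
}

## per-path descriptor: indices of non-colliders (interior), and for each
## collider the set of its descendants-or-self
.pathDescriptor <- function(path, adj, reach) {
  k <- length(path)
  if (k <= 2) return(list(noncol = integer(0), colDesc = list()))
  interior <- path[2:(k - 1)]
  prev <- path[1:(k - 2)]
  nxt <- path[3:k]
  isCol <- adj[cbind(prev, interior)] & adj[cbind(nxt, interior)]
  list(noncol = interior[!isCol],
       colDesc = lapply(interior[isCol], function(c) which(reach[c, ])))
}

## blocked given conditioning indices zi?
.pathBlocked <- function(desc, zi) {
  if (length(desc$noncol) > 0 && any(desc$noncol %in% zi)) return(TRUE)
  for (d in desc$colDesc) if (!any(d %in% zi)) return(TRUE)
  FALSE
}

#' Exhaustive d-separation oracle
#'
#' Identical contract to \code{\link{dSeparated}}, computed by enumerating
#' every simple path between \code{x} and \code{y} and applying the per-path
#' blocking rules directly. Exists as an independent cross-check of the
#' efficient routine; only usable on graphs sparse enough to enumerate
#' (default budget 2^16 simple paths; densely connected graphs like the
#' built-in clinical model exceed any practical budget, so cross-checks there
#' go through an algebraic covariance oracle instead).
#'
#' @inheritParams dSeparated
#' @param budget maximum number of simple paths to enumerate before aborting.
#' @return logical scalar.
#' @export
dSeparatedBrute <- function(g, x, y, z = character(0),
                            allowLatentConditioning = FALSE,
                            budget = 65536L) {
  .dsepValidate(g, x, y, z, allowLatentConditioning)
  ix <- .graphIndex(g)
  xi <- match(x, g@nodes); yi <- match(y, g@nodes); zi <- match(z, g@nodes)
  paths <- .enumPaths(ix$adj, xi, yi, budget = budget)
  for (p in paths) {
    desc <- .pathDescriptor(p, ix$adj, ix$reach)
    if (!.pathBlocked(desc, zi)) return(FALSE)
  }
  TRUE
}

## ---- bitmask batch evaluation (used by the randomized equivalence suite) ---
## For graphs with <= 30 nodes: evaluate the brute-force criterion for a pair
## (xi, yi) across a vector of conditioning sets encoded as bitmasks
## (bit i-1 set <=> node i conditioned). Same blocking rules as above.
.bruteSepMasks <- function(adj, reach, xi, yi, zmasks) {
  paths <- .enumPaths(adj, xi, yi)
  sep <- rep(TRUE, length(zmasks))
  for (p in paths) {
    desc <- .pathDescriptor(p, adj, reach)
    nonMask <- sum(bitwShiftL(1L, desc$noncol - 1L))
    blocked <- bitwAnd(zmasks, nonMask) != 0L
    for (d in desc$colDesc) {
      dMask <- sum(bitwShiftL(1L, d - 1L))
      blocked <- blocked | (bitwAnd(zmasks, dMask) == 0L)
    }
    sep <- sep & blocked
    if (!any(sep)) break
  }
  sep
}
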