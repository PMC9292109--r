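#' @include d-separation.R
NULL

## one-row statement record; `given` is a list column holding a character
## vector, kept sorted; (x, y) stored in lexicographic order (statements are
## unordered in x, y)
.ciStatement <- function(x, y, given) {
  if (x > y) { tmp <- x; x <- y; y <- tmp }
  data.frame(x = x, y = y,
             given = I(list(sort(given))),
             stringsAsFactors = FALSE)
}

#' Render conditional-independence statements as text
#'
#' @param statements data.frame as returned by
#'   \code{\link{impliedIndependencies}}.
#' @return character vector, one \code{"X _||_ Y | Z1, Z2"} line each.
#' @export
formatCI <- function(statements) {
  vapply(seq_len(nrow(statements)), function(i) {
    z <- statements$given[[i]]
    paste0(statements$x[i], " _||_ ", statements$y[i],
           if (length(z) > 0) paste0(" | ", paste(z, collapse = ", ")) else "")
  }, "")
}

.adjacent <- function(g, x, y) {
  any(g@edges[, 1] == x & g@edges[, 2] == y) ||
    any(g@edges[, 1] == y & g@edges[, 2] == x)
}

#' Minimal observed separating set
#'
#' Finds a subset of \code{candidates} that d-separates \code{x} and \code{y}
#' and is minimal (no element can be removed), or \code{NULL} when no subset
#' of \code{candidates} separates the pair. The search seeds with the
#' candidates that are ancestors of \code{x} or \code{y} (a separator within
#' the candidate pool exists if and only if this ancestral restriction
#' separates) and then greedily deletes removable elements scanning in
#' lexicographic order, which makes the returned set deterministic.
#'
#' @param g a \linkS4class{CausalGraph}.
#' @param x,y observed, non-adjacent node names.
#' @param candidates character vector of observed candidate nodes
#'   (defaults to all observed nodes except \code{x}, \code{y}).
#' @return character vector (possibly empty) or \code{NULL}.
#' @export
minimalSeparator <- function(g, x, y,
                             candidates = setdiff(observedNodes(g), c(x, y))) {
  .checkNode(g, c(x, y, candidates))
  if (identical(x, y)) stop("x and y must be distinct")
  if (.adjacent(g, x, y))
    stop("nodes are adjacent (", x, ", ", y, "); no separating set exists")
  candidates <- setdiff(candidates, c(x, y))
  ix <- .graphIndex(g)
  xi <- match(x, g@nodes); yi <- match(y, g@nodes)
  anc <- ix$reach[, xi] | ix$reach[, yi]
  z <- sort(intersect(candidates, g@nodes[anc]))
  zi <- match(z, g@nodes)
  if (!.dsepKernel(ix$adj, ix$reach, xi, yi, zi)) return(NULL)
  for (v in z) { # z is sorted, so deletion scan is lexicographic
    trial <- setdiff(z, v)
    if (.dsepKernel(ix$adj, ix$reach, xi, yi, match(trial, g@nodes)))
      z <- trial
  }
  z
}

#' Testable implications of a causal DAG with latent nodes
#'
#' Derives the conditional independencies among observed variables implied by
#' the graph. The default \code{"missing-edge"} basis emits one statement per
#' non-adjacent observed pair that admits an observed separating set, using
#' the deterministic minimal separator of \code{\link{minimalSeparator}};
#' pairs whose every separator would require a latent node are omitted.
#' \code{basis = "all"} enumerates every observed conditioning set that
#' separates each pair (exhaustive; only sensible for small graphs).
#'
#' @param g a \linkS4class{CausalGraph} with at least two observed nodes.
#' @param basis \code{"missing-edge"} (default) or \code{"all"}.
#' @return data.frame with columns \code{x}, \code{y} (lexicographically
#'   ordered within and across rows) and list column \code{given}.
#' @examples
#' g <- CausalGraph(c("A -> B", "B -> C"))
#' formatCI(impliedIndependencies(g))
#' @export
impliedIndependencies <- function(g, basis = c("missing-edge", "all")) {
  basis <- match.arg(basis)
  obs <- sort(observedNodes(g))
  if (length(obs) < 2) stop("need at least two observed nodes")
  out <- list()
  for (i in seq_len(length(obs) - 1)) {
    for (j in seq((i + 1), length(obs))) {
      x <- obs[i]; y <- obs[j]
      if (.adjacent(g, x, y)) next
      if (basis == "missing-edge") {
        sep <- minimalSeparator(g, x, y)
        if (!is.null(sep)) out[[length(out) + 1L]] <- .ciStatement(x, y, sep)
      } else {
        pool <- setdiff(obs, c(x, y))
        if (length(pool) > 15)
          stop("basis = 'all' is limited to 15 observed candidates")
        ix <- .graphIndex(g)
        xi <- match(x, g@nodes); yi <- match(y, g@nodes)
        for (m in 0:(2^length(pool) - 1)) {
          z <- pool[bitwAnd(bitwShiftR(m, seq_along(pool) - 1L), 1L) == 1L]
          if (.dsepKernel(ix$adj, ix$reach, xi, yi, match(z, g@nodes)))
            out[[length(out) + 1L]] <- .ciStatement(x, y, z)
        }
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(x = character(0), y = character(0),
                      given = I(list())))
  res <- do.call(rbind, out)
  res[order(res$x, res$y), , drop = FALSE]
}

## forbidden set for total-effect adjustment: descendants of any node on a
## proper causal path from x to y, plus x itself
.forbiddenTotal <- function(ix, xi, yi) {
  cn <- which(ix$reach[xi, ] & ix$reach[, yi])
  cn <- setdiff(cn, xi)
  if (length(cn) == 0) return(xi)
  unique(c(xi, which(colSums(ix$reach[cn, , drop = FALSE]) > 0)))
}

## proper backdoor graph: remove the first edge of every proper causal path
.pbdGraph <- function(ix, xi, yi) {
  cn <- setdiff(which(ix$reach[xi, ] & ix$reach[, yi]), xi)
  adj <- ix$adj
  adj[xi, cn] <- FALSE
  list(adj = adj, reach = .reachClosure(adj))
}

## graph with the direct edge x -> y removed (single-door construction)
.sdGraph <- function(ix, xi, yi) {
  adj <- ix$adj
  adj[xi, yi] <- FALSE
  list(adj = adj, reach = .reachClosure(adj))
}

#' Verify a covariate adjustment set
#'
#' For \code{effectType = "total"}, applies the generalized backdoor
#' (adjustment) criterion: \code{z} must avoid descendants of nodes on proper
#' causal paths from exposure to outcome, and must block every non-causal
#' path (checked as d-separation in the proper backdoor graph). For
#' \code{effectType = "direct"}, applies the single-door criterion for the
#' controlled direct effect under linearity: \code{z} must avoid descendants
#' of the outcome and d-separate exposure and outcome once the direct edge is
#' removed, so that only the direct edge transmits association.
#'
#' @param g a \linkS4class{CausalGraph}.
#' @param exposure,outcome distinct observed node names.
#' @param z character vector of observed covariates (latents are an error).
#' @param effectType \code{"total"} or \code{"direct"}.
#' @return logical scalar.
#' @export
verifyAdjustment <- function(g, exposure, outcome, z = character(0),
                             effectType = c("total", "direct")) {
  effectType <- match.arg(effectType)
  .checkNode(g, c(exposure, outcome, z))
  if (identical(exposure, outcome)) stop("exposure and outcome must differ")
  if (g@latent[exposure] || g@latent[outcome])
    stop("exposure and outcome must be observed")
  if (any(g@latent[z]))
    stop("latent node(s) in adjustment set: ",
         paste(z[g@latent[z]], collapse = ", "))
  if (exposure %in% z || outcome %in% z)
    stop("adjustment set must exclude exposure and outcome")
  ix <- .graphIndex(g)
  xi <- match(exposure, g@nodes); yi <- match(outcome, g@nodes)
  zi <- match(z, g@nodes)
  if (effectType == "total") {
    if (any(zi %in% .forbiddenTotal(ix, xi, yi))) return(FALSE)
    pbd <- .pbdGraph(ix, xi, yi)
    .dsepKernel(pbd$adj, pbd$reach, xi, yi, zi)
  } else {
    deY <- which(ix$reach[yi, ])
    if (any(zi %in% setdiff(deY, yi))) return(FALSE)
    sd <- .sdGraph(ix, xi, yi)
    .dsepKernel(sd$adj, sd$reach, xi, yi, zi)
  }
}

#' Minimal sufficient adjustment sets
#'
#' Enumerates every minimal observed adjustment set for the requested effect
#' (a set is minimal when no proper subset is itself valid) by exhaustive
#' search over the permissible covariate pool, and nominates one for use
#' downstream: the smallest set, ties broken lexicographically.
#'
#' @inheritParams verifyAdjustment
#' @return list with elements \code{exposure}, \code{outcome},
#'   \code{effectType}, \code{sets} (list of character vectors, each sorted)
#'   and \code{chosen}.
#' @examples
#' g <- CausalGraph(c("C -> X", "C -> Y", "X -> Y"))
#' adjustmentSets(g, "X", "Y")$chosen
#' @export
adjustmentSets <- function(g, exposure, outcome,
                           effectType = c("total", "direct")) {
  effectType <- match.arg(effectType)
  .checkNode(g, c(exposure, outcome))
  ix <- .graphIndex(g)
  xi <- match(exposure, g@nodes); yi <- match(outcome, g@nodes)
  if (effectType == "total") {
    forb <- .forbiddenTotal(ix, xi, yi)
    mg <- .pbdGraph(ix, xi, yi)
  } else {
    forb <- setdiff(which(ix$reach[yi, ]), yi)
    mg <- .sdGraph(ix, xi, yi)
  }
  pool <- setdiff(which(!g@latent), c(xi, yi, forb))
  if (length(pool) > 16)
    stop("adjustment-set enumeration limited to 16 candidate covariates")
  masks <- 0:(2^length(pool) - 1)
  valid <- vapply(masks, function(m) {
    zi <- pool[bitwAnd(bitwShiftR(m, seq_along(pool) - 1L), 1L) == 1L]
    .dsepKernel(mg$adj, mg$reach, xi, yi, zi)
  }, logical(1))
  vm <- masks[valid]
  if (length(vm) == 0)
    stop("effect of ", exposure, " on ", outcome,
         " is not identifiable by covariate adjustment over observed nodes")
  minimal <- vapply(vm, function(m) {
    !any(vm != m & bitwAnd(vm, m) == vm)
  }, logical(1))
  sets <- lapply(vm[minimal], function(m) {
    sort(g@nodes[pool[bitwAnd(bitwShiftR(m, seq_along(pool) - 1L), 1L) == 1L]])
  })
  sizes <- lengths(sets)
  keys <- vapply(sets, paste, "", collapse = ",")
  ord <- order(sizes, keys)
  sets <- sets[ord]
  structure(list(exposure = exposure, outcome = outcome,
                 effectType = effectType, sets = sets, chosen = sets[[1]]),
            class = "adjustmentResult")
}

#' @export
print.adjustmentResult <- function(x, ...) {
  cat(sprintf("Adjustment sets for the %s effect of %s on %s:\n",
              x$effectType, x$exposure, x$outcome))
  for (s in x$sets)
    cat("  {", paste(s, collapse = ", "), "}\n")
  cat("chosen: {", paste(x$chosen, collapse = ", "), "}\n")
  invisible(x)
}
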