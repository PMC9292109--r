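#' @include identification.R
NULL

## canonical node groups of the cerebral-palsy impairment model
.CP_NEURO <- c("Strength", "Spasticity", "DMC", "SCALE", "Age")
.CP_CONTRACTURES <- c("AnkleDF", "KneeExt", "Popliteal", "HipExt")
.CP_TORSIONS <- c("TibRot", "FemRot")
.CP_LATENT <- c("Injury", "MC", "Contracture", "Torsion")

## canonical edge list; strength is age-normalized upstream, so there is no
## Age -> Strength edge, and long-bone torsions have no direct edge into GMFM
.cpEdges <- function() {
  e <- c("Injury -> MC",
         "MC -> SCALE", "Age -> SCALE",
         "MC -> DMC", "Age -> DMC",
         "Injury -> Strength", "MC -> Strength",
         "Injury -> Spasticity", "Age -> Spasticity")
  for (v in .CP_CONTRACTURES)
    e <- c(e, paste(c(.CP_NEURO, "Contracture"), "->", v))
  for (v in .CP_TORSIONS)
    e <- c(e, paste(c(.CP_NEURO, "Torsion"), "->", v))
  e <- c(e, paste(c(.CP_NEURO, .CP_CONTRACTURES, .CP_TORSIONS), "->", "GDI"))
  c(e, paste(c(.CP_NEURO, .CP_CONTRACTURES, "GDI"), "->", "GMFM"))
}

## per-variable measurement metadata. sign_flip: larger raw value = more
## impairment (flipped during orientation). predictive_flip: recoded by -1
## into impairment-positive units for the raw-unit predictive model
## (contractures are recorded as negative degrees but reported as positive
## "limitation"). td_offset: typically-developing reference already
## subtracted upstream of the raw table (degrees).
.cpVariables <- function() {
  v <- function(name, role, units, sf, pf, td, lo, hi)
    data.frame(name = name, role = role, units = units, sign_flip = sf,
               predictive_flip = pf, td_offset = td, lo = lo, hi = hi,
               stringsAsFactors = FALSE)
  rbind(
    v("Age",        "age",      "years",         FALSE, FALSE,  0,     0,  21),
    v("SCALE",      "exposure", "scale points",  FALSE, FALSE,  0,     0,  10),
    v("DMC",        "exposure", "index points",  FALSE, FALSE,  0,    22, Inf),
    v("Strength",   "exposure", "scale points",  FALSE, FALSE,  0,     0,   5),
    v("Spasticity", "exposure", "scale points",  TRUE,  FALSE,  0,     0,   5),
    v("AnkleDF",    "exposure", "deg",           FALSE, TRUE,  21.3, -90,  30),
    v("KneeExt",    "exposure", "deg",           FALSE, TRUE,   4.0, -90,  30),
    v("Popliteal",  "exposure", "deg",           FALSE, TRUE,  25.6, -120, 40),
    v("HipExt",     "exposure", "deg",           FALSE, TRUE,   0.0, -60,  30),
    v("TibRot",     "exposure", "deg",           FALSE, TRUE,  16.0, -60,  60),
    v("FemRot",     "exposure", "deg",           FALSE, TRUE,  26.9, -60,  60),
    v("GDI",        "exposure", "index points",  FALSE, FALSE,  0,    20, 130),
    v("GMFM",       "outcome",  "GMFM-66 points", FALSE, FALSE, 0,     0, 100))
}

## aliases accepted in CSV headers for model variables
.CP_ALIASES <- c("Walk-DMC" = "DMC", "WalkDMC" = "DMC", "GMFM-66" = "GMFM",
                 "GMFM66" = "GMFM")

#' Built-in cerebral-palsy impairment model
#'
#' The hypothesized causal diagram linking neurological impairments
#' (selective and dynamic motor control, strength, spasticity), orthopedic
#' impairments (four joint contractures, two long-bone torsions), gait
#' quality (GDI) and age to gross motor function (GMFM-66), with four latent
#' nodes (\code{Injury}, \code{MC}, \code{Contracture}, \code{Torsion})
#' inducing dependence among their observed children. 17 nodes (13 observed),
#' 66 edges. Strength carries no explicit age edge (it is age-normalized at
#' measurement) and the torsions have no direct edge into GMFM.
#'
#' @return a \linkS4class{ModelConfig}.
#' @examples
#' cfg <- cpModel()
#' nrow(impliedIndependencies(causalGraph(cfg)))
#' @export
cpModel <- function() {
  g <- CausalGraph(.cpEdges(), latent = .CP_LATENT)
  cfg <- methods::new("ModelConfig", graph = g, variables = .cpVariables(),
                      outcome = "GMFM")
  ## defensive cross-check against the canonical counts
  stopifnot(length(nodeNames(g)) == 17, sum(g@latent) == 4,
            nrow(edgeMatrix(g)) == 66)
  cfg
}

#' Load a model configuration
#'
#' Reads a YAML model file with top-level keys \code{name}, \code{outcome},
#' \code{latent}, \code{edges} (list of \code{"cause -> effect"} strings),
#' \code{nodes} (optional isolated nodes) and \code{variables} (list of
#' per-variable metadata maps with keys \code{name}, \code{role},
#' \code{units}, \code{sign_flip}, \code{predictive_flip}, \code{td_offset},
#' \code{range}). Unknown keys are rejected. The name
#' \code{"cp-impairment"} returns the built-in model without touching the
#' file system.
#'
#' @param path file path, or the built-in model name.
#' @return a validated \linkS4class{ModelConfig}.
#' @export
loadModel <- function(path = "cp-impairment") {
  if (identical(path, "cp-impairment")) return(cpModel())
  if (!file.exists(path)) stop("model config not found: ", path)
  cfg <- yaml::read_yaml(path)
  allowed <- c("name", "outcome", "latent", "edges", "nodes", "variables")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown) > 0)
    stop("unknown key(s) in model config: ", paste(unknown, collapse = ", "))
  if (is.null(cfg$outcome)) stop("model config must declare an outcome")
  if (!is.character(cfg$outcome))
    stop("outcome must be a node name; quote YAML-reserved names like \"Y\"")
  g <- CausalGraph(unlist(cfg$edges),
                   latent = unlist(cfg$latent),
                   nodes = unlist(cfg$nodes))
  vars <- if (is.null(cfg$variables)) {
    obs <- observedNodes(g)
    data.frame(name = obs, role = ifelse(obs == cfg$outcome, "outcome", "exposure"),
               units = "", sign_flip = FALSE, predictive_flip = FALSE,
               td_offset = 0, lo = -Inf, hi = Inf, stringsAsFactors = FALSE)
  } else {
    do.call(rbind, lapply(cfg$variables, function(v) {
      rng <- if (is.null(v$range)) c(-Inf, Inf) else as.numeric(unlist(v$range))
      data.frame(name = v$name,
                 role = if (is.null(v$role)) "exposure" else v$role,
                 units = if (is.null(v$units)) "" else v$units,
                 sign_flip = isTRUE(v$sign_flip),
                 predictive_flip = isTRUE(v$predictive_flip),
                 td_offset = if (is.null(v$td_offset)) 0 else as.numeric(v$td_offset),
                 lo = rng[1], hi = rng[2], stringsAsFactors = FALSE)
    }))
  }
  methods::new("ModelConfig", graph = g, variables = vars,
               outcome = cfg$outcome)
}

#' Write a model configuration to YAML
#'
#' @param config a \linkS4class{ModelConfig}.
#' @param path output file.
#' @param name model name recorded in the file.
#' @return \code{path}, invisibly.
#' @export
writeModel <- function(config, path, name = "model") {
  g <- config@graph
  vars <- lapply(seq_len(nrow(config@variables)), function(i) {
    r <- config@variables[i, ]
    list(name = r$name, role = r$role, units = r$units,
         sign_flip = r$sign_flip, predictive_flip = r$predictive_flip,
         td_offset = r$td_offset, range = c(r$lo, r$hi))
  })
  attached <- unique(c(edgeMatrix(g)))
  yaml::write_yaml(list(
    name = name,
    outcome = config@outcome,
    latent = as.list(latentNodes(g)),
    nodes = as.list(setdiff(nodeNames(g), c(attached, latentNodes(g)))),
    edges = as.list(paste(edgeMatrix(g)[, 1], "->", edgeMatrix(g)[, 2])),
    variables = vars), path, precision = 17)
  invisible(path)
}

#' @rdname causalGraph
#' @aliases causalGraph,ModelConfig-method
#' @export
setMethod("causalGraph", "ModelConfig", function(x) x@graph)

#' @rdname variableMeta
#' @aliases variableMeta,ModelConfig-method
#' @export
setMethod("variableMeta", "ModelConfig", function(x) x@variables)

#' @rdname outcomeName
#' @aliases outcomeName,ModelConfig-method
#' @export
setMethod("outcomeName", "ModelConfig", function(x) x@outcome)

#' @rdname exportDot
#' @aliases exportDot,ModelConfig-method
#' @export
setMethod("exportDot", "ModelConfig", function(x, name = "model")
  exportDot(x@graph, name = name))

#' @rdname exportGraphML
#' @aliases exportGraphML,ModelConfig-method
#' @export
setMethod("exportGraphML", "ModelConfig", function(x) exportGraphML(x@graph))

#' @rdname exportEdgeList
#' @aliases exportEdgeList,ModelConfig-method
#' @export
setMethod("exportEdgeList", "ModelConfig", function(x) exportEdgeList(x@graph))
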