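#' @include estimation.R
NULL

## round every numeric leaf to 6 significant digits for serialization
.signif6 <- function(x) {
  if (is.data.frame(x)) {
    for (j in seq_along(x)) if (is.numeric(x[[j]])) x[[j]] <- signif(x[[j]], 6)
    return(x)
  }
  if (is.list(x)) return(lapply(x, .signif6))
  if (is.numeric(x)) return(signif(x, 6))
  x
}

#' Run manifest for reproducible reports
#'
#' @param command command name.
#' @param model model path or built-in name.
#' @param dataPath input data file (digested with MD5) or \code{NULL}.
#' @param seed integer seed or \code{NULL}.
#' @return named list embedded in every report; two runs with the same
#'   manifest fields and inputs produce byte-identical JSON apart from the
#'   timestamp.
#' @export
runManifest <- function(command, model = "cp-impairment", dataPath = NULL,
                        seed = NULL) {
  list(command = command,
       model = model,
       input_md5 = if (!is.null(dataPath) && file.exists(dataPath))
         unname(tools::md5sum(dataPath)) else NULL,
       seed = seed,
       package_version = as.character(utils::packageVersion("gmfmcausal")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

#' Full analysis pipeline on a raw cohort
#'
#' Runs the whole analysis in the study's sequence: standardize and orient on
#' the full sample, test the model's implied conditional independencies,
#' estimate total/direct/bivariate standardized effects for every exposure,
#' fit the raw-unit predictive model, and cross-validate it.
#'
#' @param raw a raw-state \linkS4class{VariableTable}.
#' @param config a \linkS4class{ModelConfig}.
#' @param alpha level for the independence tests.
#' @param k cross-validation folds.
#' @param seed integer seed for the fold assignment.
#' @param manifest optional list from \code{\link{runManifest}}.
#' @return list with elements \code{manifest}, \code{model} (node/edge
#'   counts), \code{ci_tests}, \code{effects}, \code{overestimation},
#'   \code{predictive}, \code{cv}.
#' @export
analyzeCohort <- function(raw, config = cpModel(), alpha = 0.05, k = 10,
                          seed = 1L, manifest = NULL) {
  raw <- .asTable(raw)
  std <- standardizeAndOrient(raw, config)
  g <- config@graph
  statements <- impliedIndependencies(g)
  ci <- testImpliedIndependencies(std, statements, alpha = alpha)
  eff <- effectTable(std, config)
  pm <- predictiveModel(raw, config)
  cv <- crossValidate(raw, config, k = k, seed = seed)
  list(manifest = if (is.null(manifest)) runManifest("analyze", seed = seed)
       else manifest,
       model = list(nodes = length(nodeNames(g)),
                    observed = length(observedNodes(g)),
                    latent = length(latentNodes(g)),
                    edges = nrow(edgeMatrix(g)),
                    implied_independencies = nrow(statements)),
       alpha = alpha,
       ci_tests = ci,
       effects = eff,
       overestimation = attr(eff, "overestimation"),
       predictive = pm,
       cv = list(k = cv$k, seed = cv$seed, r2_oos = cv$r2_oos, mae = cv$mae))
}

#' Write an analysis report as JSON
#'
#' Floats are serialized at 6 significant digits. The timestamp lives only
#' in the manifest, so reports from identical inputs and seeds differ in
#' that field alone.
#'
#' @param report list from \code{\link{analyzeCohort}} (or any list).
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeReportJSON <- function(report, path) {
  json <- jsonlite::toJSON(.signif6(report), auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, null = "null")
  writeLines(json, path)
  invisible(path)
}

#' Write the effect table as a flat CSV
#'
#' @param effects data.frame from \code{\link{effectTable}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeEffectsCSV <- function(effects, path) {
  utils::write.csv(.signif6(as.data.frame(effects)), path, row.names = FALSE)
  invisible(path)
}
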