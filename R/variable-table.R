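#' @include sem.R
NULL

#' Construct a subjects-by-variables table
#'
#' @param data data.frame (or coercible) of numeric columns.
#' @param state \code{"raw"} (default) or \code{"standardized"}.
#' @return a \linkS4class{VariableTable}.
#' @export
variableTable <- function(data, state = "raw") {
  methods::new("VariableTable", data = as.data.frame(data), state = state)
}

#' Subject data of a variable table
#' @param t a \linkS4class{VariableTable}.
#' @return data.frame.
#' @export
tableData <- function(t) t@data

.asTable <- function(t, state = NULL) {
  if (is.data.frame(t)) t <- variableTable(t, state = if (is.null(state)) "raw" else state)
  if (!methods::is(t, "VariableTable")) stop("expected a VariableTable or data.frame")
  t
}

#' Read a cohort CSV into a raw VariableTable
#'
#' The header must name the model's observed variables; the conventional
#' long-form aliases \code{"Walk-DMC"} and \code{"GMFM-66"} are mapped onto
#' the model's node names. Extra columns are dropped with a warning; missing
#' model columns are an error, as are missing values (rows reported; no
#' imputation).
#'
#' @param path CSV file with a header row.
#' @param config a \linkS4class{ModelConfig} naming the expected columns.
#' @return a \linkS4class{VariableTable} in raw state.
#' @export
readVariableTable <- function(path, config = cpModel()) {
  if (!file.exists(path)) stop("data file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  hits <- names(df) %in% names(.CP_ALIASES)
  names(df)[hits] <- .CP_ALIASES[names(df)[hits]]
  want <- config@variables$name
  missingCols <- setdiff(want, names(df))
  if (length(missingCols) > 0)
    stop("missing model column(s): ", paste(missingCols, collapse = ", "))
  extra <- setdiff(names(df), want)
  if (length(extra) > 0) {
    warning("ignoring extra column(s): ", paste(extra, collapse = ", "))
    df <- df[, want, drop = FALSE]
  } else df <- df[, want, drop = FALSE]
  badRows <- which(!stats::complete.cases(df))
  if (length(badRows) > 0)
    stop("missing values in row(s): ",
         paste(utils::head(badRows, 20), collapse = ", "),
         if (length(badRows) > 20) " ..." else "",
         " (complete cases are required; no imputation is performed)")
  variableTable(df, state = "raw")
}

#' Write a cohort to CSV
#'
#' Writes observed columns with the model's node names as header, matching
#' the schema \code{\link{readVariableTable}} expects.
#'
#' @param x a \linkS4class{SimulatedCohort}, \linkS4class{VariableTable} or
#'   data.frame.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeCohortCSV <- function(x, path) {
  df <- if (methods::is(x, "SimulatedCohort")) x@data
  else if (methods::is(x, "VariableTable")) x@data
  else as.data.frame(x)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Standardize and orient a raw variable table
#'
#' Implements the study's variable transformation: each model column is
#' centred on its sample mean and scaled by its sample SD (n-1 denominator),
#' then multiplied by -1 where the variable's \code{sign_flip} metadata says
#' a larger raw value means more impairment -- so that in the result larger
#' always means less impairment and positive effects on the outcome read as
#' beneficial. Age is standardized but never flipped (older stays larger).
#'
#' @param raw a raw-state \linkS4class{VariableTable} (or data.frame).
#' @param config a \linkS4class{ModelConfig} carrying orientation metadata.
#' @return a standardized \linkS4class{VariableTable}.
#' @export
standardizeAndOrient <- function(raw, config = cpModel()) {
  raw <- .asTable(raw)
  if (raw@state != "raw") stop("input table must be in raw state")
  vars <- config@variables
  missingCols <- setdiff(vars$name, names(raw@data))
  if (length(missingCols) > 0)
    stop("missing model column(s): ", paste(missingCols, collapse = ", "))
  df <- raw@data[, vars$name, drop = FALSE]
  badRows <- which(!stats::complete.cases(df))
  if (length(badRows) > 0)
    stop("missing values in row(s): ",
         paste(utils::head(badRows, 20), collapse = ", "))
  for (i in seq_len(nrow(vars))) {
    v <- vars$name[i]
    s <- stats::sd(df[[v]])
    if (!is.finite(s) || s == 0)
      stop("zero-variance column: ", v)
    z <- (df[[v]] - mean(df[[v]])) / s
    if (vars$sign_flip[i]) z <- -z
    df[[v]] <- z
  }
  variableTable(df, state = "standardized")
}
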