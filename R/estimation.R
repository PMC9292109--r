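#' @include variable-table.R
NULL

## OLS with intercept via QR; returns coefficients, classical SEs, p-values,
## fitted values. Errors on rank deficiency, naming the offending columns.
.ols <- function(X, y) {
  X <- cbind(`(Intercept)` = 1, X)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("collinear (rank-deficient) design; offending column(s): ",
         paste(drop, collapse = ", "))
  }
  beta <- qr.coef(qrX, y)
  res <- y - X %*% beta
  df <- length(y) - ncol(X)
  if (df <= 0) stop("not enough observations for the design")
  sigma2 <- sum(res^2) / df
  XtXinv <- chol2inv(qr.R(qrX))
  se <- sqrt(sigma2 * diag(XtXinv))
  names(se) <- colnames(X)
  tval <- beta / se
  list(beta = beta, se = se,
       p = 2 * stats::pt(-abs(tval), df),
       fitted = drop(X %*% beta), df = df)
}

#' Partial correlation given a conditioning set
#'
#' Pearson correlation of the residuals of \code{x} and \code{y} after
#' least-squares projection on \code{z} plus an intercept; with an empty
#' \code{z} this is the plain Pearson correlation.
#'
#' @param t a standardized \linkS4class{VariableTable} (or data.frame of
#'   standardized columns).
#' @param x,y column names, not in \code{z}.
#' @param z character vector of conditioning columns.
#' @return numeric scalar in [-1, 1].
#' @export
partialCorrelation <- function(t, x, y, z = character(0)) {
  t <- .asTable(t, state = "standardized")
  if (t@state != "standardized") stop("table must be standardized")
  df <- t@data
  miss <- setdiff(c(x, y, z), names(df))
  if (length(miss) > 0) stop("unknown column(s): ", paste(miss, collapse = ", "))
  if (x %in% z || y %in% z) stop("x and y must not appear in z")
  n <- nrow(df)
  if (n <= length(z) + 3)
    stop("need n > |z| + 3 observations (n = ", n, ", |z| = ", length(z), ")")
  if (length(z) == 0) return(stats::cor(df[[x]], df[[y]]))
  Z <- cbind(1, as.matrix(df[, z, drop = FALSE]))
  qrZ <- qr(Z)
  if (qrZ$rank < ncol(Z))
    stop("collinear (rank-deficient) conditioning set: ",
         paste(z, collapse = ", "))
  rx <- qr.resid(qrZ, df[[x]])
  ry <- qr.resid(qrZ, df[[y]])
  stats::cor(rx, ry)
}

#' Fisher z test for a (partial) correlation
#'
#' Two-sided p-value for the null of zero (partial) correlation:
#' \eqn{z = \mathrm{atanh}(r)\sqrt{n - k - 3}} referred to the standard
#' normal, where \code{k} is the conditioning-set size.
#'
#' @param r correlation in (-1, 1); an exact |r| = 1 returns p = 0 with a
#'   degeneracy warning.
#' @param n sample size (needs \code{n - k - 3 > 0}).
#' @param k conditioning-set size (default 0).
#' @return p-value in [0, 1].
#' @export
fisherZTest <- function(r, n, k = 0) {
  if (n - k - 3 <= 0) stop("need n - k - 3 > 0")
  if (abs(r) >= 1) {
    warning("degenerate correlation |r| = 1; returning p = 0")
    return(0)
  }
  z <- atanh(r) * sqrt(n - k - 3)
  2 * stats::pnorm(-abs(z))
}

#' Test implied conditional independencies against data
#'
#' One partial-correlation test per statement at level \code{alpha}, two
#' sided, with no multiple-comparison adjustment (the model-checking
#' convention: each implied independency is a separate falsification test).
#'
#' @param t a standardized \linkS4class{VariableTable}.
#' @param statements data.frame from \code{\link{impliedIndependencies}}.
#' @param alpha rejection level (default 0.05).
#' @return data.frame with columns \code{x}, \code{y}, \code{given}
#'   (comma-joined), \code{r}, \code{p}, \code{n}, \code{rejected}.
#' @export
testImpliedIndependencies <- function(t, statements, alpha = 0.05) {
  t <- .asTable(t, state = "standardized")
  n <- nrow(t@data)
  rows <- lapply(seq_len(nrow(statements)), function(i) {
    x <- statements$x[i]; y <- statements$y[i]; z <- statements$given[[i]]
    r <- tryCatch(partialCorrelation(t, x, y, z), error = function(e)
      stop("testing ", x, " _||_ ", y, " | {",
           paste(z, collapse = ", "), "}: ", conditionMessage(e), call. = FALSE))
    p <- fisherZTest(r, n, length(z))
    data.frame(x = x, y = y, given = paste(z, collapse = ", "),
               r = r, p = p, n = n, rejected = p < alpha,
               stringsAsFactors = FALSE)
  })
  if (length(rows) == 0)
    return(data.frame(x = character(0), y = character(0), given = character(0),
                      r = numeric(0), p = numeric(0), n = integer(0),
                      rejected = logical(0)))
  do.call(rbind, rows)
}

.effectRow <- function(exposure, type, beta, se, adjustment, n) {
  data.frame(exposure = exposure, effect_type = type, beta = beta, se = se,
             ci_lo = beta - 1.96 * se, ci_hi = beta + 1.96 * se,
             adjustment = paste(adjustment, collapse = ", "), n = n,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Estimate a standardized causal or bivariate effect
#'
#' Ordinary least squares of the outcome on the exposure plus the chosen
#' minimal adjustment set (main effects only, no interactions); the
#' exposure's coefficient on standardized, oriented data is the standardized
#' effect size, reported with its classical SE and normal-quantile 95 percent
#' CI. \code{"bivariate"} fits the outcome on the exposure alone (the
#' association-study estimate, for comparison); its adjustment set is empty
#' by definition.
#'
#' @param t a standardized \linkS4class{VariableTable}.
#' @param config a \linkS4class{ModelConfig}.
#' @param exposure observed exposure name.
#' @param effectType \code{"total"}, \code{"direct"} or \code{"bivariate"}.
#' @return one-row data.frame: \code{exposure}, \code{effect_type},
#'   \code{beta}, \code{se}, \code{ci_lo}, \code{ci_hi}, \code{adjustment},
#'   \code{n}.
#' @export
estimateEffect <- function(t, config, exposure,
                           effectType = c("total", "direct", "bivariate")) {
  effectType <- match.arg(effectType)
  t <- .asTable(t, state = "standardized")
  if (t@state != "standardized")
    stop("effects are standardized coefficients; standardize the table first")
  outcome <- config@outcome
  adj <- if (effectType == "bivariate") character(0)
  else adjustmentSets(config@graph, exposure, outcome, effectType)$chosen
  df <- t@data
  miss <- setdiff(c(exposure, outcome, adj), names(df))
  if (length(miss) > 0) stop("unknown column(s): ", paste(miss, collapse = ", "))
  X <- as.matrix(df[, c(exposure, adj), drop = FALSE])
  fit <- .ols(X, df[[outcome]])
  .effectRow(exposure, effectType, unname(fit$beta[exposure]),
             unname(fit$se[exposure]), adj, nrow(df))
}

#' Causal and bivariate effect table
#'
#' Total, direct and bivariate standardized effect estimates for every
#' non-outcome model variable, plus the per-exposure bivariate
#' overestimation (bivariate minus total), attached as attribute
#' \code{"overestimation"}. Per-exposure failures are recorded in an
#' \code{error} column rather than aborting the table.
#'
#' @inheritParams estimateEffect
#' @return data.frame of effect rows (3 per exposure).
#' @export
effectTable <- function(t, config) {
  t <- .asTable(t, state = "standardized")
  exposures <- setdiff(config@variables$name, config@outcome)
  rows <- list()
  for (e in exposures) {
    for (ty in c("total", "direct", "bivariate")) {
      rows[[length(rows) + 1L]] <- tryCatch({
        r <- estimateEffect(t, config, e, ty)
        r$error <- NA_character_
        r
      }, error = function(err) {
        r <- .effectRow(e, ty, NA_real_, NA_real_, character(0), nrow(t@data))
        r$error <- conditionMessage(err)
        r
      })
    }
  }
  out <- do.call(rbind, rows)
  ov <- do.call(rbind, lapply(exposures, function(e) {
    b <- out$beta[out$exposure == e & out$effect_type == "bivariate"]
    tt <- out$beta[out$exposure == e & out$effect_type == "total"]
    data.frame(exposure = e, overestimation = b - tt, stringsAsFactors = FALSE)
  }))
  attr(out, "overestimation") <- ov
  out
}

## predictive design matrix: raw columns recoded into the reporting
## convention of the published coefficient table (contractures flipped to
## positive "limitation" degrees); outcome left in raw points
.predictiveDesign <- function(raw, config) {
  raw <- .asTable(raw)
  if (raw@state != "raw")
    stop("the predictive model is fit in raw units; pass the raw table")
  vars <- config@variables
  miss <- setdiff(vars$name, names(raw@data))
  if (length(miss) > 0) stop("missing model column(s): ", paste(miss, collapse = ", "))
  df <- raw@data[, vars$name, drop = FALSE]
  badRows <- which(!stats::complete.cases(df))
  if (length(badRows) > 0)
    stop("missing values in row(s): ", paste(utils::head(badRows, 20), collapse = ", "))
  for (i in seq_len(nrow(vars)))
    if (vars$predictive_flip[i]) df[[vars$name[i]]] <- -df[[vars$name[i]]]
  preds <- setdiff(vars$name, config@outcome)
  for (v in c(preds, config@outcome))
    if (stats::sd(df[[v]]) == 0) stop("zero-variance column: ", v)
  list(X = as.matrix(df[, preds, drop = FALSE]), y = df[[config@outcome]],
       predictors = preds)
}

#' Raw-unit predictive model of the outcome
#'
#' OLS of the outcome on all non-outcome model variables in raw clinical
#' units (orientation recoding applied, no z-scoring), giving per-unit
#' coefficients: predicted outcome = intercept + sum(beta_i * variable_i).
#' This is a deliberately non-causal companion to \code{\link{effectTable}}:
#' it conditions on every measured variable at once (torsions included, even
#' though the causal model gives them no direct edge into the outcome).
#'
#' @param raw a raw-state \linkS4class{VariableTable}.
#' @param config a \linkS4class{ModelConfig}.
#' @return list with \code{coefficients} (data.frame: \code{term},
#'   \code{beta}, \code{se}, \code{p}), \code{r2} (in-sample), and \code{n}.
#' @export
predictiveModel <- function(raw, config = cpModel()) {
  d <- .predictiveDesign(raw, config)
  fit <- .ols(d$X, d$y)
  co <- data.frame(term = names(fit$beta), beta = unname(fit$beta),
                   se = unname(fit$se), p = unname(fit$p),
                   stringsAsFactors = FALSE, row.names = NULL)
  r2 <- 1 - sum((d$y - fit$fitted)^2) / sum((d$y - mean(d$y))^2)
  list(coefficients = co, r2 = r2, n = length(d$y))
}

#' k-fold cross-validation of the predictive model
#'
#' Subjects are assigned to \code{k} folds at random (sizes differing by at
#' most one); for each fold the predictive model is refit on the remaining
#' subjects and the held-out subjects predicted, so every subject is
#' predicted exactly once. Out-of-sample \eqn{r^2 = 1 - SSE/SST} and the
#' mean absolute error are computed over the pooled predictions.
#'
#' @inheritParams predictiveModel
#' @param k number of folds (default 10; needs \code{n >= k}).
#' @param seed integer seed controlling the fold assignment (required: the
#'   assignment is the only randomness and is logged in reports).
#' @return list of class \code{cvReport}: \code{k}, \code{seed},
#'   \code{r2_oos}, \code{mae}, and \code{predictions} (data.frame with
#'   \code{fold}, \code{observed}, \code{predicted} per subject).
#' @export
crossValidate <- function(raw, config = cpModel(), k = 10, seed) {
  if (missing(seed)) stop("a seed is required for the fold assignment")
  d <- .predictiveDesign(raw, config)
  n <- length(d$y)
  if (k > n) stop("k (", k, ") exceeds the number of subjects (", n, ")")
  if (k < 2) stop("need k >= 2 folds")
  set.seed(as.integer(seed))
  fold <- sample(rep_len(seq_len(k), n))
  pred <- numeric(n)
  for (f in seq_len(k)) {
    test <- fold == f
    fit <- .ols(d$X[!test, , drop = FALSE], d$y[!test])
    pred[test] <- drop(cbind(1, d$X[test, , drop = FALSE]) %*% fit$beta)
  }
  sse <- sum((d$y - pred)^2)
  sst <- sum((d$y - mean(d$y))^2)
  structure(list(k = k, seed = as.integer(seed),
                 r2_oos = 1 - sse / sst,
                 mae = mean(abs(d$y - pred)),
                 predictions = data.frame(fold = fold, observed = d$y,
                                          predicted = pred)),
            class = "cvReport")
}

#' @export
print.cvReport <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (seed %d): out-of-sample r2 = %.3f, MAE = %.2f points\n",
              x$k, x$seed, x$r2_oos, x$mae))
  invisible(x)
}
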