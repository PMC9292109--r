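test_that("standardization centres, scales by sample SD, and orients", {
  p <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("outcome: \"Y\"",
               "edges:", "  - X -> Y",
               "variables:",
               "  - {name: X, role: exposure, sign_flip: true}",
               "  - {name: \"Y\", role: outcome}"), p)
  cfg3 <- loadModel(p)
  raw <- variableTable(data.frame(X = c(1, 3), Y = c(1, 2)))
  std <- standardizeAndOrient(raw, cfg3)
  # sample-SD convention: [1,2,3] standardizes to [-1,0,1]; flip negates
  expect_equal(tableData(std)$X, c(0.7071068, -0.7071068), tolerance = 1e-6)
  raw3 <- variableTable(data.frame(X = c(1, 2, 3), Y = c(5, 6, 9)))
  expect_equal(tableData(standardizeAndOrient(raw3, cfg3))$X, c(1, 0, -1))
  # flipping twice is the identity on the standardized scale
  vm <- cfg3@variables; vm$sign_flip <- FALSE
  cfgNoFlip <- methods::new("ModelConfig", graph = causalGraph(cfg3),
                            variables = vm, outcome = "Y")
  expect_equal(tableData(standardizeAndOrient(raw3, cfgNoFlip))$X,
               -tableData(standardizeAndOrient(raw3, cfg3))$X)
  expect_error(standardizeAndOrient(
    variableTable(data.frame(X = c(1, 1, 1), Y = 1:3)), cfg3),
    "zero-variance column: X")
  expect_error(standardizeAndOrient(
    variableTable(data.frame(X = c(1, NA, 3), Y = 1:3)), cfg3),
    "row\\(s\\): 2")
})

test_that("orientation makes harmful raw codings positively associated with the outcome", {
  # a harmful exposure coded 'larger = worse' correlates negatively raw,
  # positively once oriented
  g <- CausalGraph("X -> Y")
  spec <- semSpec(g, c("X->Y" = -2), c(X = 1, Y = 1))
  d <- cohortData(simulateCohort(spec, 4000, seed = 4))
  cfgP <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("outcome: \"Y\"", "edges:", "  - X -> Y",
               "variables:",
               "  - {name: X, role: exposure, sign_flip: true}",
               "  - {name: \"Y\", role: outcome}"), cfgP)
  cfg <- loadModel(cfgP)
  std <- standardizeAndOrient(variableTable(d), cfg)
  expect_gt(cor(tableData(std)$X, tableData(std)$Y), 0)
})

test_that("partial correlation matches the single-z recursion and plain Pearson", {
  set.seed(9)
  df <- as.data.frame(matrix(rnorm(300 * 3), ncol = 3))
  names(df) <- c("x", "y", "z")
  df <- as.data.frame(scale(df))
  t <- variableTable(df, state = "standardized")
  expect_equal(partialCorrelation(t, "x", "y"), cor(df$x, df$y))
  rxy <- cor(df$x, df$y); rxz <- cor(df$x, df$z); ryz <- cor(df$y, df$z)
  oracle <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  expect_equal(partialCorrelation(t, "x", "y", "z"), oracle, tolerance = 1e-12)
  expect_equal(partialCorrelation(t, "x", "y", "z"),
               partialCorrelation(t, "y", "x", "z"), tolerance = 1e-12)
  # identical columns give r = 1
  df2 <- df; df2$y <- df2$x
  expect_equal(partialCorrelation(variableTable(df2, state = "standardized"),
                                  "x", "y"), 1)
  expect_error(partialCorrelation(t, "x", "y", c("z", "z")), "collinear|x and y")
})

test_that("a strong mediated chain has near-zero partial correlation given the mediator", {
  g <- CausalGraph(c("x -> m", "m -> y"))
  spec <- semSpec(g, c("x->m" = 2, "m->y" = 2), c(x = 1, m = 1, y = 1))
  d <- cohortData(simulateCohort(spec, 10000, seed = 2))
  d <- as.data.frame(scale(d))
  t <- variableTable(d, state = "standardized")
  expect_gt(abs(partialCorrelation(t, "x", "y")), 0.5)
  expect_lt(abs(partialCorrelation(t, "x", "y", "m")), 0.05)
})

test_that("Fisher z test matches its closed form", {
  expect_equal(fisherZTest(0, 100), 1)
  expect_equal(fisherZTest(0.3, 200, 2), fisherZTest(-0.3, 200, 2))
  # frozen value recomputed by numerical integration of the normal density
  expect_equal(fisherZTest(0.2, 300, 5), 0.00053162237, tolerance = 1e-6)
  z <- atanh(0.2) * sqrt(300 - 5 - 3)
  expect_equal(fisherZTest(0.2, 300, 5), 2 * integrate(dnorm, z, Inf)$value,
               tolerance = 1e-6)
  expect_warning(p1 <- fisherZTest(1, 50), "degenerate")
  expect_equal(p1, 0)
  expect_error(fisherZTest(0.5, 5, 3), "n - k - 3")
})

test_that("implied-independence testing flags rejections at alpha without correction", {
  st <- impliedIndependencies(causalGraph(cpModel()))
  res <- testImpliedIndependencies(stdCohort(), st)
  expect_equal(nrow(res), 11)
  expect_true(all(res$rejected == (res$p < 0.05)))
  res01 <- testImpliedIndependencies(stdCohort(), st, alpha = 0.01)
  expect_identical(res01$r, res$r) # alpha only moves the flags
  empty <- testImpliedIndependencies(stdCohort(), st[0, , drop = FALSE])
  expect_equal(nrow(empty), 0)
})

test_that("effect estimation returns the exposure coefficient with 95% CI", {
  std <- stdCohort()
  est <- estimateEffect(std, cpModel(), "Strength", "total")
  expect_equal(est$ci_lo, est$beta - 1.96 * est$se)
  expect_equal(est$ci_hi, est$beta + 1.96 * est$se)
  expect_setequal(strsplit(est$adjustment, ", ")[[1]],
                  c("Age", "DMC", "SCALE", "Spasticity"))
  biv <- estimateEffect(std, cpModel(), "Strength", "bivariate")
  expect_identical(biv$adjustment, "")
  # bivariate regression of a variable on itself has slope one
  g <- CausalGraph("X -> Y")
  dfc <- data.frame(X = scale(rnorm(50))[, 1])
  dfc$Y <- dfc$X
  cfgP <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("outcome: \"Y\"", "edges:", "  - X -> Y"), cfgP)
  cfg <- loadModel(cfgP)
  tt <- standardizeAndOrient(variableTable(dfc), cfg)
  expect_equal(estimateEffect(tt, cfg, "X", "bivariate")$beta, 1)
})

test_that("the effect table covers all exposures and reports overestimation", {
  std <- stdCohort()
  et <- effectTable(std, cpModel())
  expect_equal(nrow(et), 12 * 3)
  expect_setequal(unique(et$effect_type), c("total", "direct", "bivariate"))
  ov <- attr(et, "overestimation")
  expect_equal(nrow(ov), 12)
  b <- et$beta[et$effect_type == "bivariate"]
  tt <- et$beta[et$effect_type == "total"]
  expect_equal(ov$overestimation, b - tt)
  # GDI: identical adjustment makes total and direct numerically identical
  expect_equal(et$beta[et$exposure == "GDI" & et$effect_type == "total"],
               et$beta[et$exposure == "GDI" & et$effect_type == "direct"],
               tolerance = 1e-12)
})

test_that("without confounding, bivariate equals total up to sampling error", {
  g <- mediatorGraph()
  spec <- semSpec(g, c("X->M" = 1, "M->Y" = 1, "X->Y" = 0.5),
                  c(X = 1, M = 1, Y = 1))
  d <- cohortData(simulateCohort(spec, 20000, seed = 8))
  cfgP <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("outcome: \"Y\"", "edges:", "  - X -> M", "  - M -> Y", "  - X -> Y"),
             cfgP)
  cfg <- loadModel(cfgP)
  std <- standardizeAndOrient(variableTable(d), cfg)
  tot <- estimateEffect(std, cfg, "X", "total")$beta
  biv <- estimateEffect(std, cfg, "X", "bivariate")$beta
  expect_equal(biv, tot, tolerance = 0.02)
  expect_equal(tot, trueTotalEffect(spec, "X", "Y", standardized = TRUE),
               tolerance = 0.03)
})

test_that("the predictive model recovers known raw-unit coefficients", {
  set.seed(31)
  n <- 10000
  df <- data.frame(A = rnorm(n, 10, 2), B = rnorm(n, 0, 5))
  df$Y <- 3 + 1.5 * df$A - 0.4 * df$B + rnorm(n, 0, 1)
  cfgP <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("outcome: \"Y\"", "edges:", "  - A -> Y", "  - B -> Y"), cfgP)
  cfg <- loadModel(cfgP)
  pm <- predictiveModel(variableTable(df), cfg)
  co <- pm$coefficients
  for (tm in c("A", "B", "(Intercept)")) {
    truth <- c(A = 1.5, B = -0.4, `(Intercept)` = 3)[[tm]]
    row <- co[co$term == tm, ]
    expect_lt(abs(row$beta - truth), 3 * row$se)
  }
  # a single predictor equal to the outcome fits exactly
  df2 <- data.frame(A = rnorm(20))
  df2$Y <- df2$A
  cfgP2 <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("outcome: \"Y\"", "edges:", "  - A -> Y"), cfgP2)
  pm2 <- predictiveModel(variableTable(df2), loadModel(cfgP2))
  expect_equal(pm2$coefficients$beta[pm2$coefficients$term == "A"], 1)
  expect_equal(pm2$coefficients$beta[pm2$coefficients$term == "(Intercept)"], 0,
               tolerance = 1e-10)
})

test_that("cross-validation partitions subjects evenly and scores honestly", {
  # noiseless linear data: near-perfect out-of-sample prediction
  set.seed(5)
  df <- data.frame(A = rnorm(200))
  df$Y <- 2 + 3 * df$A
  cfgP <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("outcome: \"Y\"", "edges:", "  - A -> Y"), cfgP)
  cfg <- loadModel(cfgP)
  cv <- crossValidate(variableTable(df), cfg, k = 10, seed = 1)
  expect_gt(cv$r2_oos, 0.999)
  expect_lt(cv$mae, 1e-8)
  expect_equal(nrow(cv$predictions), 200)
  expect_true(max(table(cv$predictions$fold)) -
                min(table(cv$predictions$fold)) <= 1)
  expect_error(crossValidate(variableTable(df[1:5, ]), cfg, k = 10, seed = 1),
               "exceeds")
  expect_error(crossValidate(variableTable(df), cfg, k = 10), "seed")
})

test_that("cross-validated accuracy is stable across fold seeds", {
  co <- simulateCohort(defaultSEM(), 300, seed = 21)
  raw <- variableTable(cohortData(co))
  r1 <- crossValidate(raw, cpModel(), k = 10, seed = 1)$r2_oos
  r2 <- crossValidate(raw, cpModel(), k = 10, seed = 2)$r2_oos
  expect_lt(abs(r1 - r2), 0.05)
})
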