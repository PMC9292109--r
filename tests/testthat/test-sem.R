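test_that("SEM specs validate their coefficient keys and noise SDs", {
  g <- CausalGraph("A -> B")
  expect_error(semSpec(g, c("A->C" = 1), c(A = 1, B = 1)), "coefficient keys")
  expect_error(semSpec(g, c("A->B" = 1), c(A = 1, B = 0)), "positive")
  expect_error(semSpec(g, c("A->B" = 1), c(A = 1)), "every node")
  s <- semSpec(g, c("A->B" = 2), c(A = 1, B = 1))
  expect_s4_class(s, "SEMSpec")
})

test_that("simulation is seed-deterministic and respects sample size bounds", {
  s <- defaultSEM()
  a <- cohortData(simulateCohort(s, 100, seed = 7))
  b <- cohortData(simulateCohort(s, 100, seed = 7))
  expect_identical(a, b)
  c <- cohortData(simulateCohort(s, 100, seed = 8))
  expect_false(identical(a, c))
  expect_error(simulateCohort(s, 0, seed = 1), "n must be")
  one <- simulateCohort(s, 1, seed = 1)
  expect_equal(nrow(cohortData(one)), 1)
  expect_setequal(names(cohortData(one)), observedNodes(causalGraph(s)))
  expect_error(cohortData(one, latent = TRUE), "keepLatent")
  withLat <- simulateCohort(s, 5, seed = 1, keepLatent = TRUE)
  expect_true(all(c("Injury", "MC") %in% names(cohortData(withLat, latent = TRUE))))
})

test_that("zero coefficients produce mutually independent columns", {
  g <- CausalGraph(c("A -> B", "B -> C"))
  s <- semSpec(g, c("A->B" = 0, "B->C" = 0), c(A = 1, B = 1, C = 1))
  n <- 20000
  d <- cohortData(simulateCohort(s, n, seed = 3))
  cm <- cor(d)
  expect_true(all(abs(cm[upper.tri(cm)]) < 4 / sqrt(n)))
})

test_that("regression on simulated data recovers a chain coefficient", {
  g <- CausalGraph("A -> B")
  s <- semSpec(g, c("A->B" = 2), c(A = 1, B = 1))
  d <- cohortData(simulateCohort(s, 50000, seed = 13))
  expect_equal(cov(d$A, d$B) / var(d$A), 2, tolerance = 0.025)
})

test_that("true total effects sum coefficient products over directed paths", {
  g <- mediatorGraph()
  s <- semSpec(g, c("X->M" = 2, "M->Y" = 3, "X->Y" = 1),
               c(X = 1, M = 1, Y = 1))
  expect_equal(trueTotalEffect(s, "X", "Y"), 7)
  expect_equal(trueTotalEffect(s, "Y", "X"), 0) # no path
  expect_equal(trueTotalEffect(s, "M", "X"), 0)
  b <- defaultSEM()
  co <- edgeCoefficients(b)
  expect_equal(trueTotalEffect(b, "TibRot", "GMFM"),
               co[["TibRot->GDI"]] * co[["GDI->GMFM"]]) # single path
})

test_that("implied moments match sample moments of large simulations", {
  s <- defaultSEM()
  mom <- impliedMoments(s)
  n <- 100000
  d <- cohortData(simulateCohort(s, n, seed = 17))
  obs <- names(d)
  expect_equal(unname(colMeans(d)), unname(mom$mean[obs]), tolerance = 0.02)
  impliedSD <- sqrt(diag(mom$cov))[obs]
  expect_equal(unname(apply(d, 2, sd)) / unname(impliedSD), rep(1, length(obs)),
               tolerance = 0.02)
  # simulator faithfulness: every implied independency vanishes empirically
  st <- impliedIndependencies(causalGraph(cpModel()))
  std <- standardizeAndOrient(variableTable(d), cpModel())
  res <- testImpliedIndependencies(std, st)
  expect_true(all(abs(res$r) < 4 / sqrt(n)))
})

test_that("the calibrated spec places marginals at the clinic targets", {
  mom <- impliedMoments(defaultSEM())
  expect_equal(mom$mean[["GMFM"]], 75.5, tolerance = 0.1)
  expect_equal(mom$mean[["GDI"]], 73.8, tolerance = 0.1)
  expect_equal(mom$mean[["SCALE"]], 5.42, tolerance = 0.02)
  sd <- sqrt(diag(mom$cov))
  expect_equal(sd[["SCALE"]], 1.94, tolerance = 0.05)
  expect_equal(sd[["DMC"]], 14.1, tolerance = 0.3)
  # outcome edges carry the published per-unit coefficients (raw coding)
  co <- edgeCoefficients(defaultSEM())
  expect_equal(co[["Strength->GMFM"]], 4.5)
  expect_equal(co[["SCALE->GMFM"]], 2.3)
  expect_equal(co[["Spasticity->GMFM"]], -0.57)
  expect_equal(co[["AnkleDF->GMFM"]], 0.13) # sign-recoded for raw units
})

test_that("severity-level fixtures land on their stratum means", {
  d2 <- cohortData(cohortFixture("II", 10000, seed = 5))
  expect_equal(mean(d2$GMFM), 73, tolerance = 1)
  d1 <- cohortData(cohortFixture("I", 10000, seed = 5))
  expect_equal(mean(d1$DMC), 91, tolerance = 1)
  expect_equal(nrow(cohortData(cohortFixture("III", 1, seed = 1))), 1)
})

test_that("SEM specs round-trip through YAML", {
  s <- defaultSEM()
  path <- withr::local_tempfile(fileext = ".yaml")
  writeSEMSpec(s, path)
  s2 <- readSEMSpec(path)
  expect_true(gmfmcausal:::.graphEqual(causalGraph(s), causalGraph(s2)))
  # text serialization is faithful to ~1 ulp (decimal round-trip)
  expect_equal(edgeCoefficients(s2)[names(edgeCoefficients(s))],
               edgeCoefficients(s), tolerance = 1e-14)
  a <- cohortData(simulateCohort(s, 10, seed = 3))
  b <- cohortData(simulateCohort(s2, 10, seed = 3))
  expect_equal(a, b, tolerance = 1e-12)
})
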