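test_that("minimal separators match the textbook cases", {
  expect_identical(minimalSeparator(chainGraph(), "A", "C", "B"), "B")
  expect_identical(minimalSeparator(colliderGraph(), "A", "C", "B"),
                   character(0))
  expect_error(minimalSeparator(chainGraph(), "A", "B"), "adjacent")
  # latent confounding with no observed candidate: no separator exists
  g <- CausalGraph(c("L -> A", "L -> B"), latent = "L")
  expect_null(minimalSeparator(g, "A", "B"))
})

test_that("minimal separator search agrees with exhaustive subset search", {
  set.seed(77)
  for (rep in 1:60) {
    g <- randomDag(sample(4:7, 1))
    nn <- nodeNames(g)
    pick <- sample(nn, 2)
    x <- pick[1]; y <- pick[2]
    em <- edgeMatrix(g)
    if (any((em[, 1] == x & em[, 2] == y) | (em[, 1] == y & em[, 2] == x))) next
    cand <- setdiff(nn, c(x, y))
    sep <- minimalSeparator(g, x, y, cand)
    anySep <- any(vapply(allSubsets(seq_along(cand)), function(zi)
      dSeparatedBrute(g, x, y, cand[zi]), logical(1)))
    if (is.null(sep)) {
      expect_false(anySep)
    } else {
      expect_true(anySep)
      expect_true(dSeparatedBrute(g, x, y, sep))
      for (v in sep) # minimality: every element is load-bearing
        expect_false(dSeparatedBrute(g, x, y, setdiff(sep, v)))
    }
  }
})

test_that("implied independencies use the missing-edge basis over observed pairs", {
  expect_identical(formatCI(impliedIndependencies(chainGraph())),
                   "A _||_ C | B")
  g <- CausalGraph(c("L -> A", "L -> B"), latent = "L")
  expect_equal(nrow(impliedIndependencies(g)), 0)
  # exhaustive basis lists every separating set
  gAll <- CausalGraph(c("A -> B", "B -> C", "A -> D"))
  allSt <- impliedIndependencies(gAll, basis = "all")
  expect_true(all(vapply(seq_len(nrow(allSt)), function(i)
    dSeparatedBrute(gAll, allSt$x[i], allSt$y[i], allSt$given[[i]]),
    logical(1))))
  expect_gt(nrow(allSt), nrow(impliedIndependencies(gAll)))
})

test_that("the clinical model implies exactly the derived 11 statements", {
  g <- causalGraph(cpModel())
  st <- impliedIndependencies(g)
  expect_equal(nrow(st), 11)
  neuro <- c("Age", "DMC", "SCALE", "Spasticity", "Strength")
  lines <- formatCI(st)
  # 8 contracture-by-torsion statements share the five neurological covariates
  for (ctr in c("AnkleDF", "KneeExt", "Popliteal", "HipExt"))
    for (tor in c("TibRot", "FemRot")) {
      row <- st[(st$x == ctr & st$y == tor) | (st$x == tor & st$y == ctr), ]
      expect_equal(nrow(row), 1)
      expect_setequal(row$given[[1]], neuro)
    }
  # both torsions separate from the outcome only behind the gait index
  for (tor in c("TibRot", "FemRot")) {
    row <- st[st$x == tor | st$y == tor, ]
    row <- row[row$x == "GMFM" | row$y == "GMFM", ]
    expect_equal(nrow(row), 1)
    expect_true("GDI" %in% row$given[[1]])
  }
  # age-normalized strength is marginally independent of age
  expect_true(any(st$x == "Age" & st$y == "Strength" &
                    lengths(st$given) == 0))
  # every statement is confirmed by the covariance-algebra oracle (the graph
  # is too dense for exhaustive path enumeration)
  for (i in seq_len(nrow(st)))
    expect_true(gaussianSeparated(g, st$x[i], st$y[i], st$given[[i]]))
  expect_identical(minimalSeparator(g, "HipExt", "TibRot"),
                   sort(neuro))
})

test_that("implied statements on random latent DAGs pass the exhaustive oracle", {
  set.seed(404)
  for (rep in 1:40) {
    n <- sample(4:7, 1)
    g0 <- randomDag(n, p = 0.35)
    lat <- sample(nodeNames(g0), sample(0:2, 1))
    g <- CausalGraph(edgeMatrix(g0), latent = lat, nodes = nodeNames(g0))
    if (length(observedNodes(g)) < 2) next
    st <- impliedIndependencies(g)
    for (i in seq_len(nrow(st)))
      expect_true(dSeparatedBrute(g, st$x[i], st$y[i], st$given[[i]]))
  }
})

test_that("adjustment verification follows the backdoor and single-door criteria", {
  g <- confounderGraph()
  expect_true(verifyAdjustment(g, "X", "Y", "C", "total"))
  expect_false(verifyAdjustment(g, "X", "Y", character(0), "total"))
  gm <- mediatorGraph()
  expect_false(verifyAdjustment(gm, "X", "Y", "M", "total")) # mediator forbidden
  expect_true(verifyAdjustment(gm, "X", "Y", character(0), "total"))
  expect_true(verifyAdjustment(gm, "X", "Y", "M", "direct"))
  expect_false(verifyAdjustment(gm, "X", "Y", character(0), "direct"))
  cp <- causalGraph(cpModel())
  expect_true(verifyAdjustment(cp, "Strength", "GMFM",
                               c("SCALE", "DMC", "Spasticity", "Age"), "total"))
  # dropping Age leaves the collider-opened backdoor unblocked
  expect_false(verifyAdjustment(cp, "Strength", "GMFM",
                                c("SCALE", "DMC", "Spasticity"), "total"))
  expect_error(verifyAdjustment(cp, "Strength", "GMFM", "MC", "total"), "latent")
  expect_error(verifyAdjustment(cp, "Strength", "Strength"), "differ")
})

test_that("adjustment sets are minimal, correctly chosen, and fail loudly", {
  expect_identical(adjustmentSets(CausalGraph("X -> Y"), "X", "Y")$chosen,
                   character(0))
  cp <- causalGraph(cpModel())
  gdi <- adjustmentSets(cp, "GDI", "GMFM", "total")
  expect_setequal(gdi$chosen,
                  c("Age", "DMC", "SCALE", "Spasticity", "Strength",
                    "AnkleDF", "KneeExt", "Popliteal", "HipExt"))
  expect_identical(gdi$sets, adjustmentSets(cp, "GDI", "GMFM", "direct")$sets)
  # minimality: every returned set validates and loses validity per element
  strength <- adjustmentSets(cp, "Strength", "GMFM", "total")
  for (s in strength$sets) {
    expect_true(verifyAdjustment(cp, "Strength", "GMFM", s, "total"))
    for (v in s)
      expect_false(verifyAdjustment(cp, "Strength", "GMFM", setdiff(s, v),
                                    "total"))
  }
  # latent confounding without observed blockers is not identifiable
  gl <- CausalGraph(c("L -> X", "L -> Y", "X -> Y"), latent = "L")
  expect_error(adjustmentSets(gl, "X", "Y", "total"), "not identifiable")
})
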