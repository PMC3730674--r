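test_that("model construction enforces the structural invariants", {
  m <- makeFixture("linear_chain", n = 3)$model
  expect_true(validObject(m))
  expect_identical(rownames(stoichiometry(m)), metaboliteIds(m))
  expect_identical(colnames(stoichiometry(m)), reactionIds(m))
  expect_true(all(bounds(m)[, "lb"] <= bounds(m)[, "ub"]))
  ## every exchange is a one-metabolite boundary column
  ex <- exchangeReactions(m)
  expect_true(all(Matrix::colSums(stoichiometry(m)[, ex] != 0) == 1))
  ## duplicated reaction ids are rejected
  expect_error(buildModel(data.frame(id = c("X", "X"),
                                     equation = c("A[c] ->", "B[c] ->")),
                          objective = "X"), "duplicated")
})

test_that("reversible reactions split into opposite irreversible children", {
  m <- buildModel(data.frame(id = c("REV", "BIO"),
                             equation = c("A[c] <-> B[c]", "B[c] ->"),
                             lb = c(-1000, 0), ub = c(1000, 1000)),
                  objective = "BIO")
  im <- splitReversible(m)
  rxn <- reactions(im)
  expect_setequal(rxn$id, c("REV__fwd", "REV__rev", "BIO"))
  expect_equal(c(rxn$lb[rxn$id == "REV__fwd"], rxn$ub[rxn$id == "REV__fwd"]),
               c(0, 1000))
  expect_equal(c(rxn$lb[rxn$id == "REV__rev"], rxn$ub[rxn$id == "REV__rev"]),
               c(0, 1000))
  expect_equal(as.numeric(stoichiometry(im)[, "REV__rev"]),
               -as.numeric(stoichiometry(im)[, "REV__fwd"]))
  ## annotations copied to both children
  expect_identical(rxn$gpr[rxn$id == "REV__fwd"],
                   rxn$gpr[rxn$id == "REV__rev"])
})

test_that("splitting a fully irreversible model is the identity up to metadata", {
  m <- makeFixture("dead_end", n = 2)$model
  im <- splitReversible(m)
  ## exchanges are reversible; everything else should be untouched
  keep <- setdiff(reactionIds(m), exchangeReactions(m))
  expect_true(all(keep %in% reactionIds(im)))
  expect_equal(as.matrix(stoichiometry(im)[, keep]),
               as.matrix(stoichiometry(m)[, keep]))
  im2 <- splitReversible(im)
  expect_identical(reactionIds(im2), reactionIds(im))
})

test_that("merged child fluxes satisfy the parent steady state", {
  for (seed in 1:5) {
    m <- randomModel(nMets = 5, nRxns = 10, seed = seed)
    opened <- farm:::.openNutrients(m, "all", 1000)
    im <- splitReversible(opened)
    ## a feasible child flux from maximizing a random objective over Sv=0
    set.seed(seed)
    cc <- runif(nrow(reactions(im)))
    sol <- farm:::.solveLP(cc, Aeq = as.matrix(stoichiometry(im)),
                           beq = rep(0, nrow(stoichiometry(im))),
                           ub = pmin(reactions(im)$ub, 1000))
    expect_identical(sol$status, "optimal")
    merged <- mergeFluxes(im, stats::setNames(sol$x, reactionIds(im)))
    resid <- stoichiometry(opened) %*% merged[reactionIds(opened)]
    expect_lt(max(abs(resid)), 1e-6)
  }
})

test_that("model editing keeps the object consistent", {
  m <- makeFixture("linear_chain", n = 2)$model
  m2 <- removeReactions(m, "EX_M1", dropOrphans = TRUE)
  expect_false("EX_M1" %in% reactionIds(m2))
  expect_true(validObject(m2))
  expect_error(removeReactions(m, "BIOMASS"), "biomass")
  m3 <- addSink(m, "M1[c]", cap = 5)
  j <- grep("^SINK_", reactionIds(m3))
  expect_length(j, 1)
  expect_equal(unname(bounds(m3)[j, ]), c(0, 5))
})
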