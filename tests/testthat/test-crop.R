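test_that("reaction weights integrate evidence on the log scale", {
  expect_equal(reactionWeight(1, 1, 1), 0)
  expect_equal(reactionWeight(0.5, 1, 1), log(2))
  ## halving any one probability adds exactly log(2), independent of the rest
  base <- reactionWeight(0.8, 0.6, 0.9)
  expect_equal(reactionWeight(0.4, 0.6, 0.9), base + log(2))
  expect_equal(reactionWeight(0.8, 0.3, 0.9), base + log(2))
  expect_equal(reactionWeight(0.8, 0.6, 0.45), base + log(2))
  expect_error(reactionWeight(0, 1, 1), "probabilities")
  expect_error(reactionWeight(1, -0.2, 1), "probabilities")
})

test_that("model weights apply defaults and protect curated reactions", {
  fx <- makeFixture("dual_route_sl")
  m <- fx$model
  m@reactions$curated[1] <- TRUE
  m@reactions$pBiochem[2] <- 0.5
  m@reactions$pathwaySupport[2] <- 1
  m@reactions$pThermo[2] <- 1
  wAdd <- modelReactionWeights(m)
  wRem <- modelReactionWeights(m, forRemoval = TRUE)
  expect_equal(unname(wAdd[1]), 0)
  expect_identical(unname(wRem[1]), Inf)
  expect_equal(unname(wRem[2]), log(2))
  ## unannotated reactions carry the uninformative pathway prior
  expect_equal(unname(wAdd[3]), -log(0.5))
})

.chainWithDb <- function() {
  fx <- makeFixture("linear_chain", n = 3)
  broken <- removeReactions(fx$model, "STEP2", dropOrphans = FALSE)
  db <- buildModel(data.frame(
    id = c("CAND_direct", "CAND_costly", "CAND_half1", "CAND_half2"),
    equation = c("M1[c] -> M2[c]", "M1[c] -> M2[c] ",
                 "M1[c] -> H[c]", "H[c] -> M2[c]"),
    pBiochem = c(0.9, 0.1, 0.8, 0.8), pThermo = 1, pathwaySupport = 1),
    objective = "CAND_direct")
  list(model = broken, db = db, media = fx$media)
}

test_that("gap filling finds the unique and the lightest single repair", {
  cw <- .chainWithDb()
  w <- modelReactionWeights(cw$db)
  rec <- restoreGrowth(cw$model, cw$db, cw$media)
  expect_true(rec@resolved)
  expect_identical(rec@suggestions$reaction, "CAND_direct")
  expect_gt(rec@postBiomass, 0.02)
  ## matches exhaustive minimum-weight enumeration
  ref <- bruteForceRestore(cw$model, cw$db, cw$media, character(), w)
  expect_equal(sum(w[rec@suggestions$reaction]), ref$weight)
  expect_true(any(vapply(ref$sets, setequal, logical(1),
                         rec@suggestions$reaction)))
})

test_that("gap filling assembles multi-reaction repairs when needed", {
  cw <- .chainWithDb()
  db2 <- removeReactions(cw$db, "CAND_direct", allowObjective = TRUE)
  db2 <- removeReactions(db2, "CAND_costly", allowObjective = TRUE)
  w <- modelReactionWeights(db2)
  rec <- restoreGrowth(cw$model, db2, cw$media)
  expect_true(rec@resolved)
  expect_setequal(rec@suggestions$reaction, c("CAND_half1", "CAND_half2"))
  ref <- bruteForceRestore(cw$model, db2, cw$media, character(), w,
                           maxSize = 2)
  expect_equal(sum(w[rec@suggestions$reaction]), ref$weight)
})

test_that("every accepted repair verifiably flips the growth call", {
  cw <- .chainWithDb()
  rec <- restoreGrowth(cw$model, cw$db, cw$media)
  m2 <- addReactions(cw$model, cw$db, only = rec@suggestions$reaction)
  expect_gt(limedFBA(m2, cw$media)@objective, 0.02)
  ## a growing phenotype is rejected outright
  fx <- makeFixture("linear_chain", n = 3)
  expect_error(restoreGrowth(fx$model, cw$db, fx$media), "already grows")
})

test_that("gap filling reports unresolvable phenotypes", {
  fx <- makeFixture("dual_route_sl")
  broken <- applyKnockout(fx$model, c("gA", "gB"))
  useless <- buildModel(data.frame(id = "NOP", equation = "Q1[c] -> Q2[c]"),
                        objective = "NOP")
  rec <- restoreGrowth(broken, useless, fx$media)
  expect_false(rec@resolved)
  expect_identical(nrow(rec@suggestions), 0L)
})

.bypassFixture <- function(nBypass = 1) {
  ## curated trunk to biomass plus low-evidence bypass route(s)
  bypass <- do.call(rbind, lapply(seq_len(nBypass), function(i) data.frame(
    id = paste0("BYPASS", i),
    equation = "N[c] -> E[c]",
    gpr = "",
    curated = FALSE, pBiochem = 0.4, pThermo = 1, pathwaySupport = 1)))
  rx <- rbind(
    data.frame(id = c("EX_N", "T_N", "TRUNK", "BIOMASS"),
               equation = c("N[e] <->", "N[e] -> N[c]", "N[c] -> E[c]",
                            "E[c] ->"),
               gpr = c("", "", "g_trunk", ""),
               curated = TRUE, pBiochem = 1, pThermo = 1,
               pathwaySupport = 1),
    bypass)
  list(model = buildModel(rx, objective = "BIOMASS"),
       media = Media(c("N[e]" = 1.5), name = "minimal"))
}

test_that("growth suppression cuts the single low-evidence bypass", {
  bf <- .bypassFixture(1)
  ## observed inviable for the trunk knockout, but the bypass grows
  rec <- suppressGrowth(bf$model, bf$media, genes = "g_trunk")
  expect_true(rec@resolved)
  expect_identical(rec@suggestions$reaction, "BYPASS1")
  expect_lte(rec@postBiomass, 0.02)
})

test_that("growth suppression cuts parallel bypasses at minimum total weight", {
  bf <- .bypassFixture(2)
  w <- modelReactionWeights(bf$model, forRemoval = TRUE)
  rec <- suppressGrowth(bf$model, bf$media, genes = "g_trunk")
  expect_true(rec@resolved)
  expect_setequal(rec@suggestions$reaction, c("BYPASS1", "BYPASS2"))
  ref <- bruteForceSuppress(bf$model, bf$media, "g_trunk", w)
  expect_equal(sum(w[rec@suggestions$reaction]), ref$weight)
  expect_true(any(vapply(ref$sets, setequal, logical(1),
                         rec@suggestions$reaction)))
})

test_that("curated reactions are never suggested for removal", {
  bf <- .bypassFixture(1)
  ## make even the bypass curated: growth flows only through protected
  ## reactions, so the phenotype is unresolvable
  m <- bf$model
  m@reactions$curated[match("BYPASS1", reactionIds(m))] <- TRUE
  rec <- suppressGrowth(m, bf$media, genes = "g_trunk")
  expect_false(rec@resolved)
  ## and with the default fixture, no curated reaction ever appears
  rec2 <- suppressGrowth(bf$model, bf$media, genes = "g_trunk")
  expect_false(any(reactions(bf$model)$curated[
    match(rec2@suggestions$reaction, reactionIds(bf$model))]))
  ## a non-growing phenotype is rejected outright
  lc <- makeFixture("linear_chain", n = 2)
  expect_error(suppressGrowth(lc$model, lc$media, genes = "g1"),
               "fails to grow")
})

test_that("raising a candidate's weight never pulls it into the optimum", {
  cw <- .chainWithDb()
  w <- modelReactionWeights(cw$db)
  rec1 <- restoreGrowth(cw$model, cw$db, cw$media, weights = w)
  expect_false("CAND_costly" %in% rec1@suggestions$reaction)
  w2 <- w; w2["CAND_costly"] <- w2["CAND_costly"] + 5
  rec2 <- restoreGrowth(cw$model, cw$db, cw$media, weights = w2)
  expect_false("CAND_costly" %in% rec2@suggestions$reaction)
  expect_identical(rec1@suggestions$reaction, rec2@suggestions$reaction)
})
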