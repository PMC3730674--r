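test_that("media construction caps supplements and validates metabolites", {
  fx <- makeFixture("linear_chain", n = 3)
  base <- fx$media
  sup <- buildMedia(base, "M2[e]", model = fx$model)
  expect_equal(unname(uptakeRates(sup)["M2[e]"]), 3)   # supplement cap
  expect_equal(unname(uptakeRates(sup)["M0[e]"]), 1.5) # base carbon cap kept
  expect_identical(buildMedia(base, character()), base)
  expect_error(buildMedia(base, "NOT_A_MET[e]", model = fx$model),
               "NOT_A_MET")
  ## media referencing metabolites without exchange reactions are refused
  expect_error(applyMedia(fx$model, Media(c("GHOST[e]" = 1))), "GHOST")
})

test_that("essentiality screen recovers planted essential genes", {
  fx <- makeFixture("linear_chain", n = 3)
  res <- predictEssentiality(fx$model, fx$media)
  expect_true(all(res[fx$truth$stepGenes, "essential"]))
  ## every chain gene is essential; transporter genes are orphans here
  expect_setequal(res$gene[res$essential], fx$truth$stepGenes)
})

test_that("dilution-driven essentiality differs between limed-FBA and FBA", {
  fx <- makeFixture("input_cycle", n = 3)
  limed <- predictEssentiality(fx$model, fx$media, method = "limed")
  plain <- predictEssentiality(fx$model, fx$media, method = "fba")
  expect_setequal(limed$gene[limed$essential], fx$truth$essentialLimed)
  expect_setequal(plain$gene[plain$essential], fx$truth$essentialFba)
  ## the cycle-input gene is exactly the disagreement
  expect_true(fx$truth$inputGene %in%
                setdiff(limed$gene[limed$essential],
                        plain$gene[plain$essential]))
})

test_that("screen summaries score sensitivity and specificity correctly", {
  fx <- makeFixture("linear_chain", n = 4)
  truth <- c(g1 = FALSE, g2 = FALSE, g3 = TRUE, g4 = FALSE,
             ghost = TRUE)  # ghost is absent from the model
  expect_warning(
    res <- predictEssentiality(fx$model, fx$media, truth = truth),
    "absent")
  sm <- S4Vectors::metadata(res)$summary
  ## prediction: all four step genes inviable; observed: g3 viable
  expect_identical(sm@tn, 3L)
  expect_identical(sm@fn, 1L)
  expect_identical(sm@tp, 0L)
  expect_equal(sm@specificity, 1)
  expect_equal(sm@sensitivity, 0)
  ## sensitivity times the experimentally viable count is the TP integer
  expect_equal(sm@sensitivity * (sm@tp + sm@fn), sm@tp)
})

test_that("lowering the viability threshold never flips viable to inviable", {
  fx <- makeFixture("dual_route_sl")
  res02 <- predictEssentiality(fx$model, fx$media, threshold = 0.02)
  res0 <- predictEssentiality(fx$model, fx$media, threshold = 0)
  expect_true(all(res0$viable[res02$viable]))
})

test_that("supplements rescue lesions upstream, not downstream, of them", {
  fx <- makeFixture("linear_chain", n = 4)
  spec <- dilutionSpec(fx$model)
  for (step in c(2, 3)) {
    res <- predictRescue(fx$model, fx$media, paste0("g", step),
                         fx$truth$supplements, spec = spec)
    for (i in seq_len(nrow(res))) {
      supplIdx <- match(res$supplement[i], fx$truth$supplements) - 1
      expect_identical(res$rescued[i], fx$truth$rescues(step, supplIdx),
                       info = paste("step", step, res$supplement[i]))
    }
    ## soundness: re-simulate every call independently
    for (i in seq_len(nrow(res))) {
      m2 <- buildMedia(fx$media, res$supplement[i])
      biomass <- limedFBA(applyKnockout(fx$model, paste0("g", step)),
                          m2, spec)@objective
      expect_identical(biomass > 0.02, res$rescued[i])
    }
  }
})

test_that("branch-point lesions are rescued only by their own product", {
  fx <- makeFixture("branch_rescue")
  res <- predictRescue(fx$model, fx$media, "g_b1",
                       c("P1[e]", "P2[e]", "M1[e]"))
  expect_identical(unname(res$rescued),
                   c(TRUE, FALSE, FALSE))
})

test_that("multi-substrate supplements are implied by rescuing singles", {
  fx <- makeFixture("linear_chain", n = 3)
  res <- predictRescue(fx$model, fx$media, "g2",
                       list("M2[e]", "M0[e]", c("M2[e]", "M0[e]")))
  multi <- res[res$supplement == "M2[e];M0[e]", ]
  expect_true(multi$rescued)
  expect_true(multi$implied)      # not re-simulated: M2 alone suffices
  expect_error(predictRescue(fx$model, fx$media, "g_none_essential",
                             "M1[e]"),
               "viable|absent")
})

test_that("rescue is undefined for mutants viable on the base media", {
  fx <- makeFixture("dual_route_sl")
  expect_error(predictRescue(fx$model, fx$media, "gA", "E[e]"), "viable")
})

test_that("the SL screen recovers the planted pair in all three classes", {
  for (cls in c("same_pathway", "interacting_pathways", "isozyme")) {
    fx <- makeFixture("dual_route_sl", slClass = cls)
    scr <- syntheticLethalScreen(fx$model, fx$media)
    sl <- scr[scr$syntheticLethal, ]
    expect_identical(nrow(sl), 1L, info = cls)
    expect_setequal(c(sl$gene1, sl$gene2), fx$truth$slPair)
    expect_identical(sl$classification, cls)
    ## the planted supplement rescues the double mutant
    resc <- predictRescue(fx$model, fx$media, fx$truth$slPair,
                          fx$truth$rescueSupplement)
    expect_true(all(resc$rescued))
  }
})

test_that("triple redundancy yields no synthetic-lethal pair", {
  rx <- data.frame(
    id = c("EX_N", "T_N", "R1", "R2", "R3", "BIO"),
    equation = c("N[e] <->", "N[e] -> N[c]", "N[c] -> E[c]",
                 "N[c] -> E[c] ", "N[c] ->  E[c]", "E[c] ->"),
    gpr = c("", "", "gA", "gB", "gC", ""))
  m <- buildModel(rx, objective = "BIO")
  scr <- syntheticLethalScreen(m, Media(c("N[e]" = 1.5)),
                               genes = c("gA", "gB", "gC"))
  expect_identical(nrow(scr), 3L)
  expect_false(any(scr$syntheticLethal))
})

test_that("screen results are symmetric in gene order and shortcut-invariant", {
  fx <- makeFixture("dual_route_sl")
  s1 <- syntheticLethalScreen(fx$model, fx$media, genes = c("gA", "gB"))
  s2 <- syntheticLethalScreen(fx$model, fx$media, genes = c("gB", "gA"))
  expect_equal(as.data.frame(s1), as.data.frame(s2))
  expect_identical(classifySLPair(fx$model, "gA", "gB"),
                   classifySLPair(fx$model, "gB", "gA"))
  ## the disabled-set shortcut must not change any call
  m <- fx$model
  full <- syntheticLethalScreen(m, fx$media, exhaustive = TRUE)
  fast <- syntheticLethalScreen(m, fx$media, exhaustive = FALSE)
  expect_equal(as.data.frame(full)[, c("gene1", "gene2", "syntheticLethal")],
               as.data.frame(fast)[, c("gene1", "gene2", "syntheticLethal")])
})

test_that("individually inviable genes are dropped from the pair universe", {
  fx <- makeFixture("linear_chain", n = 2)
  expect_warning(
    scr <- syntheticLethalScreen(fx$model, fx$media,
                                 genes = c("g1", "g2")),
    "inviable")
  expect_identical(nrow(scr), 0L)
})
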