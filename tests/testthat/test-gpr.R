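test_that("complex and isozyme rules evaluate correctly under knockouts", {
  expect_false(evaluateGpr("g1 and g2", "g1"))   # complex loses a subunit
  expect_false(evaluateGpr("g1 and g2", "g2"))
  expect_true(evaluateGpr("g1 or g2", "g1"))     # surviving isozyme
  expect_false(evaluateGpr("g1 or g2", c("g1", "g2")))
  expect_true(evaluateGpr("", "g1"))             # orphan reaction
  expect_true(evaluateGpr("G1 AND (g2 Or g3)", "g2"))  # case-insensitive ops
  expect_false(evaluateGpr("g1 and (g2 or g3)", c("g2", "g3")))
})

test_that("parser rejects malformed rules and handles nesting", {
  expect_error(parseGpr("g1 and"), "unexpected end")
  expect_error(parseGpr("(g1 or g2"), "unbalanced")
  expect_error(parseGpr("g1 g2"), "trailing")
  tree <- parseGpr("(a and b) or (c and d)")
  expect_identical(tree$op, "or")
  expect_setequal(gprGenes("(a and b) or (c and d)"), c("a", "b", "c", "d"))
})

test_that("evaluator agrees with direct truth-table evaluation", {
  set.seed(11)
  genes <- paste0("gn", 1:6)
  for (rep in 1:25) {
    rule <- randomGprRule(genes, depth = sample(1:3, 1))
    used <- gprGenes(rule)
    subsets <- if (length(used) <= 4) {
      unlist(lapply(0:length(used), function(k)
        utils::combn(used, k, simplify = FALSE)), recursive = FALSE)
    } else {
      lapply(1:12, function(i) sample(used, sample(0:length(used), 1)))
    }
    for (ko in subsets) {
      expect_identical(evaluateGpr(rule, ko),
                       gprTruthOracle(rule, genes, ko),
                       info = paste(rule, "| ko:", paste(ko, collapse = ",")))
    }
  }
})

test_that("knockout closes exactly the reactions whose rules fail", {
  fx <- makeFixture("dual_route_sl", slClass = "isozyme")
  m <- fx$model
  ## one isozyme down: reaction survives
  m1 <- applyKnockout(m, "gA")
  expect_equal(bounds(m1)[match("ROUTE", reactionIds(m1)), ],
               bounds(m)[match("ROUTE", reactionIds(m)), ])
  ## both isozymes down: bounds pinched to zero
  m2 <- applyKnockout(m, c("gA", "gB"))
  expect_equal(unname(bounds(m2)[match("ROUTE", reactionIds(m2)), ]),
               c(0, 0))
  ## unknown genes are reported and ignored
  expect_message(m3 <- applyKnockout(m, "not_a_gene"), "absent")
  expect_identical(bounds(m3), bounds(m))
})

test_that("double knockouts disable a superset of either single knockout", {
  set.seed(12)
  genes <- paste0("h", 1:5)
  rxns <- data.frame(
    id = paste0("R", 1:8),
    equation = paste0("A", 1:8, "[c] -> B", 1:8, "[c]"),
    gpr = vapply(1:8, function(i) randomGprRule(genes, 2), character(1)))
  rxns <- rbind(rxns, data.frame(id = "BIO", equation = "B1[c] ->", gpr = ""))
  m <- buildModel(rxns, objective = "BIO")
  for (i in 1:10) {
    g1 <- sample(genes, 1); g2 <- sample(setdiff(genes, g1), 1)
    d1 <- reactionsDisabledBy(m, g1)
    d2 <- reactionsDisabledBy(m, g2)
    dd <- reactionsDisabledBy(m, c(g1, g2))
    expect_true(all(d1 %in% dd) && all(d2 %in% dd))
  }
})

test_that("adding knockouts never increases the optimal biomass", {
  fx <- makeFixture("dual_route_sl")
  spec <- dilutionSpec(fx$model)
  gsets <- list(character(), "gA", "gB", c("gA", "gB"))
  obj <- vapply(gsets, function(g)
    limedFBA(applyKnockout(fx$model, g), fx$media, spec)@objective,
    numeric(1))
  expect_true(obj[2] <= obj[1] + 1e-8)
  expect_true(obj[4] <= obj[2] + 1e-8)
  expect_true(obj[4] <= obj[3] + 1e-8)
})
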