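test_that("binary stoichiometry marks participants and zeroes exempt transports", {
  rx <- data.frame(
    id = c("R1", "T1", "PUMP", "BIO"),
    equation = c("A[c] -> B[c]",
                 "A[c] <-> A[n]",
                 "B[c] + ATP[c] -> B[e] + ADP[c]",
                 "B[c] ->"))
  m <- buildModel(rx, objective = "BIO")
  spec <- dilutionSpec(m)
  im <- splitReversible(m)
  B <- binaryStoichiometry(im, spec)
  ## conversion column: 1 exactly in the rows of its two participants
  expect_equal(sum(B[, "R1"]), 2)
  expect_equal(unname(B[c("A[c]", "B[c]"), "R1"]), c(1, 1))
  ## simple transport (no chemical change): all-zero columns
  expect_identical(detectSimpleTransport(m), "T1")
  expect_equal(sum(B[, "T1__fwd"]) + sum(B[, "T1__rev"]), 0)
  ## ATP-driven transport changes cofactors: kept in the pattern matrix
  expect_gt(sum(B[, "PUMP"]), 0)
})

test_that("simple-transport detection follows the no-chemical-change rule", {
  rx <- data.frame(
    id = c("UNI", "ANTI", "PUMP", "CONV", "BIO"),
    equation = c("A[c] <-> A[e]",
                 "A[c] + B[e] -> A[e] + B[c]",
                 "A[c] + ATP[c] -> A[e] + ADP[c] + P[c]",
                 "A[c] -> B[c]",
                 "A[c] ->"))
  m <- buildModel(rx, objective = "BIO")
  det <- detectSimpleTransport(m)
  expect_true("UNI" %in% det)
  expect_true("ANTI" %in% det)     # two species, both unchanged
  expect_false("PUMP" %in% det)    # cofactor turnover = chemical change
  expect_false("CONV" %in% det)
})

test_that("epsilon assignment makes the dilution cap tight at d_max", {
  rx <- data.frame(
    id = c("R1", "R2", "BIO"),
    equation = c("A[c] -> B[c]", "A[c] -> C[c]", "B[c] ->"))
  m <- buildModel(rx, objective = "BIO")
  spec <- dilutionSpec(m, dMax = 0.1, vMax = 1000)
  ## A participates in 2 non-exempt reactions -> d_max/(2 v_max)
  expect_equal(unname(spec@epsilon["A[c]"]), 5e-5)
  ## exempt metabolite (in biomass): zero
  expect_equal(unname(spec@epsilon["B[c]"]), 0)
  ## worst-case dilution over the flux box equals d_max exactly
  im <- splitReversible(m)
  Bm <- binaryStoichiometry(im, spec)
  worst <- spec@epsilon * as.numeric(Bm %*% pmin(reactions(im)$ub, spec@vMax))
  expect_lte(max(worst), spec@dMax + 1e-12)
  expect_equal(max(worst), spec@dMax)   # tight for the most-connected row
  ## an isolated metabolite gets zero
  rx2 <- rbind(rx, data.frame(id = "TLONE", equation = "Z[c] <-> Z[n]"))
  spec2 <- dilutionSpec(buildModel(rx2, objective = "BIO"))
  expect_equal(unname(spec2@epsilon[c("Z[c]", "Z[n]")]), c(0, 0))
})

test_that("metabolic cycles require an input flux under dilution but not FBA", {
  fx <- makeFixture("input_cycle", n = 3)
  spec <- dilutionSpec(fx$model)
  noInput <- fx$truth$mediaNoInput
  expect_gt(fba(fx$model, noInput)@objective, 0.02)
  expect_equal(limedFBA(fx$model, noInput, spec)@objective, 0)
  ## restoring the input makes the cycle run under dilution
  expect_gt(limedFBA(fx$model, fx$media, spec)@objective, 0.02)
  ## the cycle-input enzyme is essential only when dilution is modeled
  ko <- applyKnockout(fx$model, fx$truth$inputGene)
  expect_lte(limedFBA(ko, fx$media, spec)@objective, 0.02)
  expect_gt(fba(ko, fx$media)@objective, 0.02)
})

test_that("chain throughput is proportional to the uptake bound under FBA", {
  fx <- makeFixture("linear_chain", n = 3)
  for (u in c(0.5, 1.5, 4)) {
    sol <- fba(fx$model, Media(c("M0[e]" = u)))
    expect_equal(sol@objective, u, tolerance = 1e-8)
  }
})

test_that("FBA optimum matches exhaustive vertex enumeration on tiny networks", {
  for (seed in c(2, 5, 8)) {
    m <- randomModel(nMets = 4, nRxns = 5, seed = seed)
    opened <- farm:::.openNutrients(m, "all", 10)  # small box keeps it exact
    im <- splitReversible(opened)
    S <- as.matrix(stoichiometry(im))
    ub <- pmin(reactions(im)$ub, 10)
    cc <- farm:::.objectiveVector(im)
    ref <- bruteForceLPMax(S, ub, cc)
    sol <- fba(opened, vMax = 10)
    expect_equal(sol@objective, ref, tolerance = 1e-6,
                 info = paste("seed", seed))
  }
})

test_that("realized dilution never exceeds d_max in optimal solutions", {
  for (motif in c("input_cycle", "linear_chain", "branch_rescue",
                  "dual_route_sl", "transport_cheat", "dead_end")) {
    fx <- makeFixture(motif)
    sol <- limedFBA(fx$model, fx$media)
    expect_lte(max(sol@dilution), 0.1 + 1e-9)
    expect_true(all(sol@dilution >= -1e-9))
  }
})

test_that("zeroing epsilon makes limed-FBA and FBA agree", {
  for (motif in c("input_cycle", "linear_chain", "dual_route_sl")) {
    fx <- makeFixture(motif)
    off <- dilutionSpec(fx$model, scale = 0)
    expect_equal(limedFBA(fx$model, fx$media, off)@objective,
                 fba(fx$model, fx$media)@objective, tolerance = 1e-6)
  }
})

test_that("the transport-shuttle cheat is closed by the exemption", {
  fx <- makeFixture("transport_cheat")
  ## exemption on (default): the by-product has no outlet, growth impossible
  expect_equal(limedFBA(fx$model, fx$media)@objective, 0)
  ## exemption off: the shuttle loop manufactures dilution capacity
  leaky <- dilutionSpec(fx$model, exemptTransport = character(0))
  expect_gt(limedFBA(fx$model, fx$media, leaky)@objective, 0.02)
})

test_that("infeasible media yield a no-growth solution, not an error", {
  fx <- makeFixture("transport_cheat")
  sol <- limedFBA(fx$model, fx$media)
  expect_identical(sol@status, "optimal")   # v = 0 is feasible
  expect_equal(sol@objective, 0)
})
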