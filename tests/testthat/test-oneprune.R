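test_that("dead-end reactions are blocked and the core survives", {
  fx <- makeFixture("dead_end", n = 3)
  res <- findUnblocked(fx$model)
  expect_setequal(intersect(res@blocked, fx$truth$blocked), fx$truth$blocked)
  expect_true(all(!fx$truth$core %in% res@parentBlocked))
  ## witness sends positive flux through every unblocked reaction
  expect_true(all(res@witness[res@unblocked] > 1e-9))
})

test_that("a disconnected reversible pair is blocked: its two-cycle is diluted", {
  rx <- data.frame(
    id = c("EX_M0", "T_M0", "CORE", "BIO", "LONE"),
    equation = c("M0[e] <->", "M0[e] -> M0[c]", "M0[c] -> M1[c]",
                 "M1[c] ->", "P[c] <-> Q[c]"))
  m <- buildModel(rx, objective = "BIO")
  res <- findUnblocked(m)
  expect_true(all(c("LONE__fwd", "LONE__rev") %in% res@blocked))
  expect_true("LONE" %in% res@parentBlocked)
})

test_that("blocked classification equals the FVA oracle on random networks", {
  for (seed in 1:30) {
    m <- randomModel(nMets = 4 + seed %% 4, nRxns = 6 + seed %% 7,
                     seed = seed)
    spec <- dilutionSpec(m)
    res <- findUnblocked(m, spec)
    expect_setequal(res@blocked, fvaBlockedChildren(m, spec))
    ## the goal variables are binary at the optimum, to the numerical
    ## resolution of the coupling: flux noise below the 1e-6 feasibility
    ## tolerance enters t scaled by 1/delta, so binariness is certifiable
    ## to tol/delta = 1e-3
    expect_true(all(pmin(abs(res@t), abs(res@t - 1)) < 1e-3))
  }
})

test_that("the whole classification costs exactly one LP solve", {
  fx <- makeFixture("dead_end", n = 2)
  lpSolveCount(reset = TRUE)
  spec <- dilutionSpec(fx$model)
  before <- lpSolveCount()
  res <- findUnblocked(fx$model, spec)
  expect_identical(lpSolveCount() - before, 1L)
  expect_equal(unname(res@nLpSolves), 1)
})

test_that("pruning removes blocked reactions, orphans, and is idempotent", {
  fx <- makeFixture("dead_end", n = 4)
  p1 <- suppressMessages(pruneModel(fx$model))
  expect_setequal(setdiff(reactionIds(fx$model), reactionIds(p1)),
                  fx$truth$blocked)
  ## dead-end products disappear with their reactions
  expect_false(any(paste0("Z", 1:4, "[c]") %in% metaboliteIds(p1)))
  p2 <- suppressMessages(pruneModel(p1))
  expect_identical(reactionIds(p2), reactionIds(p1))
  expect_identical(metaboliteIds(p2), metaboliteIds(p1))
})

test_that("pruning refuses to delete the biomass reaction", {
  rx <- data.frame(id = c("EX_A", "BIO"),
                   equation = c("A[e] <->", "Q[c] ->"))
  m <- buildModel(rx, objective = "BIO")   # Q is unproducible
  expect_error(suppressMessages(pruneModel(m)), "biomass")
})

test_that("exempt transport self-cycles survive OnePrune; parent FVA catches them", {
  rx <- data.frame(
    id = c("EX_M0", "T_M0", "CORE", "BIO", "SHUT"),
    equation = c("M0[e] <->", "M0[e] -> M0[c]", "M0[c] -> M1[c]",
                 "M1[c] ->", "W[c] <-> W[n]"))
  m <- buildModel(rx, objective = "BIO")
  spec <- dilutionSpec(m)
  expect_setequal(detectSimpleTransport(m), c("T_M0", "SHUT"))
  res <- findUnblocked(m, spec)
  ## not penalized in the limed stoichiometry -> free to spin -> not pruned
  expect_true(all(c("SHUT__fwd", "SHUT__rev") %in% res@unblocked))
  expect_false("SHUT" %in% res@parentBlocked)
  ## the documented fallback: net-flux FVA on the parent model finds it
  fv <- fluxVariability(m, spec = spec)
  expect_true(fv$blocked[fv$reaction == "SHUT"])
  pruned <- suppressMessages(pruneModel(m, spec, fvaCheck = TRUE))
  expect_false("SHUT" %in% reactionIds(pruned))
})

test_that("a reversible reaction with one zero-capacity direction survives pruning", {
  ## REV is capped to its reverse direction (ub = 0): the forward child has
  ## zero capacity and is blocked, but the reaction itself must survive in
  ## its feasible direction and keep supporting growth
  rx <- data.frame(
    id = c("EX_B", "T_B", "REV", "BIO"),
    equation = c("B[e] <->", "B[e] -> B[c]", "A[c] <-> B[c]", "A[c] ->"),
    lb = c(NA, NA, -1000, NA), ub = c(NA, NA, 0, NA))
  m <- buildModel(rx, objective = "BIO")
  res <- findUnblocked(m)
  expect_true("REV__fwd" %in% res@blocked)    # zero-capacity child
  expect_true("REV__rev" %in% res@unblocked)  # B -> A carries the pathway
  pruned <- suppressMessages(pruneModel(m))
  expect_true("REV" %in% reactionIds(pruned))
  expect_gt(limedFBA(pruned, Media(c("B[e]" = 1.5)))@objective, 0.02)
})
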