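#' @include AllClasses.R build.R media.R
NULL

## Synthetic test networks.
##
## Each motif reproduces a canonical failure mode or screening scenario of
## constraint-based modeling on a handful of reactions, together with
## machine-readable ground truth, so that every algorithm in the package is
## testable with no external data:
##
##   input_cycle      a catalytic metabolite cycle (conserved carrier pool)
##                    with an optional input enzyme: plain FBA grows without
##                    the input flux, dilution-aware FBA does not
##   linear_chain     a linear biosynthesis pathway; knockouts upstream of a
##                    supplement are rescued, downstream ones are not
##   branch_rescue    a branch point where both branch products are
##                    essential; only supplementing the blocked branch's
##                    product rescues
##   dual_route_sl    two routes to one essential metabolite; the planted
##                    gene pair is synthetic lethal, with a rescuing
##                    supplement and a configurable mechanistic class
##   transport_cheat  a growth by-product with no exporter plus a 1:1
##                    shuttle: growth must stay impossible unless the
##                    simple-transport dilution exemption is dropped
##   dead_end         a viable core plus k dead-end reactions, exactly
##                    which are blocked

.fixtureMotifs <- c("input_cycle", "linear_chain", "branch_rescue",
                    "dual_route_sl", "transport_cheat", "dead_end")

#' Generate a synthetic fixture network
#'
#' Builds a small, fully annotated [MetabolicModel-class] realising one of
#' the package's pedagogical motifs, together with the medium it is meant
#' to be grown on and machine-readable ground truth (known essential genes,
#' blocked reactions, synthetic-lethal pairs, rescuing supplements).
#'
#' @param motif one of \code{"input_cycle"}, \code{"linear_chain"},
#'   \code{"branch_rescue"}, \code{"dual_route_sl"},
#'   \code{"transport_cheat"}, \code{"dead_end"}.
#' @param n motif size parameter: cycle length, chain length, or number of
#'   dead ends.
#' @param slClass for \code{dual_route_sl}: the planted mechanistic class,
#'   \code{"same_pathway"}, \code{"interacting_pathways"} or
#'   \code{"isozyme"}.
#' @return list with elements \code{model}, \code{media} (a
#'   [Media-class]), and \code{truth} (a list of motif-specific ground
#'   truth entries).
#' @examples
#' fx <- makeFixture("input_cycle")
#' limedFBA(fx$model, fx$media)
#' @export
makeFixture <- function(motif = .fixtureMotifs, n = 3,
                        slClass = c("same_pathway", "interacting_pathways",
                                    "isozyme")) {
  motif <- match.arg(motif)
  slClass <- match.arg(slClass)
  switch(motif,
    input_cycle = .fxInputCycle(max(2, n)),
    linear_chain = .fxLinearChain(max(2, n)),
    branch_rescue = .fxBranchRescue(),
    dual_route_sl = .fxDualRouteSL(slClass),
    transport_cheat = .fxTransportCheat(),
    dead_end = .fxDeadEnd(max(1, n)))
}

## A catalytic cycle of carrier metabolites C1..Cn: the carriers are
## conserved (the cycle converts substrate S to product P while
## regenerating them), so plain FBA can run the pathway with no carrier
## input. The input enzyme (gene g_in) synthesises C1 de novo.
.fxInputCycle <- function(n) {
  carriers <- paste0("C", seq_len(n), "[c]")
  cyc <- data.frame(
    id = paste0("CYC", seq_len(n)),
    equation = c(
      paste0(carriers[1], " + S[c] -> ", carriers[min(2, n)]),
      if (n > 2) paste0(carriers[2:(n - 1)], " -> ", carriers[3:n]),
      paste0(carriers[n], " -> ", carriers[1], " + P[c]")),
    gpr = paste0("g_cyc", seq_len(n)),
    pathways = "product-biosynthesis")
  rx <- rbind(
    data.frame(id = "EX_S", equation = "S[e] <->", gpr = "", pathways = ""),
    data.frame(id = "T_S", equation = "S[e] -> S[c]", gpr = "g_ts",
               pathways = "transport"),
    data.frame(id = "EX_X", equation = "X[e] <->", gpr = "", pathways = ""),
    data.frame(id = "T_X", equation = "X[e] -> X[c]", gpr = "g_tx",
               pathways = "transport"),
    data.frame(id = "R_IN", equation = paste0("X[c] -> ", carriers[1]),
               gpr = "g_in", pathways = "carrier-biosynthesis"),
    cyc,
    data.frame(id = "BIOMASS", equation = "P[c] ->", gpr = "",
               pathways = ""))
  model <- buildModel(rx, objective = "BIOMASS")
  list(model = model,
       media = Media(c("S[e]" = 1.5, "X[e]" = 1.5), name = "minimal+X"),
       truth = list(
         inputGene = "g_in",
         mediaNoInput = Media(c("S[e]" = 1.5), name = "minimal"),
         carrierMetabolites = carriers,
         essentialLimed = c("g_ts", "g_tx", "g_in",
                            paste0("g_cyc", seq_len(n))),
         essentialFba = c("g_ts", paste0("g_cyc", seq_len(n)))))
}

## M0 -> M1 -> ... -> Mn, every intermediate importable as a supplement.
.fxLinearChain <- function(n) {
  mets <- paste0("M", 0:n)
  steps <- data.frame(
    id = paste0("STEP", seq_len(n)),
    equation = paste0(mets[1:n], "[c] -> ", mets[2:(n + 1)], "[c]"),
    gpr = paste0("g", seq_len(n)),
    pathways = "chain-biosynthesis")
  io <- do.call(rbind, lapply(0:n, function(i) data.frame(
    id = c(paste0("EX_M", i), paste0("T_M", i)),
    equation = c(paste0("M", i, "[e] <->"),
                 paste0("M", i, "[e] -> M", i, "[c]")),
    gpr = "", pathways = c("", "transport"))))
  rx <- rbind(io, steps,
              data.frame(id = "BIOMASS",
                         equation = paste0(mets[n + 1], "[c] ->"),
                         gpr = "", pathways = ""))
  model <- buildModel(rx, objective = "BIOMASS")
  list(model = model,
       media = Media(c("M0[e]" = 1.5), name = "minimal"),
       truth = list(
         stepGenes = paste0("g", seq_len(n)),
         supplements = paste0("M", 0:n, "[e]"),
         ## knocking out step i is rescued by supplementing M_j iff j >= i
         rescues = function(step, supplIdx) supplIdx >= step))
}

## M0 -> M1; M1 -> P1 (g_b1) and M1 -> P2 (g_b2); biomass needs P1 + P2.
.fxBranchRescue <- function() {
  rx <- data.frame(
    id = c("EX_M0", "T_M0", "CORE", "BRANCH1", "BRANCH2",
           "EX_P1", "T_P1", "EX_P2", "T_P2", "EX_M1", "T_M1", "BIOMASS"),
    equation = c("M0[e] <->", "M0[e] -> M0[c]", "M0[c] -> M1[c]",
                 "M1[c] -> P1[c]", "M1[c] -> P2[c]",
                 "P1[e] <->", "P1[e] -> P1[c]",
                 "P2[e] <->", "P2[e] -> P2[c]",
                 "M1[e] <->", "M1[e] -> M1[c]",
                 "P1[c] + P2[c] ->"),
    gpr = c("", "", "g_core", "g_b1", "g_b2", "", "", "", "", "", "", ""),
    pathways = c("", "transport", "core", "branch-one", "branch-two",
                 "", "transport", "", "transport", "", "transport", ""))
  model <- buildModel(rx, objective = "BIOMASS")
  list(model = model,
       media = Media(c("M0[e]" = 1.5), name = "minimal"),
       truth = list(
         branchGenes = c("g_b1", "g_b2"),
         rescuedBy = list(g_b1 = "P1[e]", g_b2 = "P2[e]"),
         notRescuedBy = list(g_b1 = c("M1[e]", "P2[e]"),
                             g_b2 = c("M1[e]", "P1[e]"))))
}

## Two routes from nutrient N to essential metabolite E. The planted gene
## pair is synthetic lethal; supplementing E rescues the double mutant.
.fxDualRouteSL <- function(slClass) {
  common <- data.frame(
    id = c("EX_N", "T_N", "EX_E", "T_E", "BIOMASS"),
    equation = c("N[e] <->", "N[e] -> N[c]", "E[e] <->", "E[e] -> E[c]",
                 "E[c] ->"),
    gpr = "", pathways = c("", "transport", "", "transport", ""))
  routes <- switch(slClass,
    isozyme = data.frame(
      id = "ROUTE", equation = "N[c] -> E[c]", gpr = "gA or gB",
      pathways = "assimilation"),
    same_pathway = data.frame(
      id = c("ROUTE_A", "ROUTE_B1", "ROUTE_B2"),
      equation = c("N[c] -> E[c]", "N[c] -> B[c]", "B[c] -> E[c]"),
      gpr = c("gA", "gB", ""),
      pathways = "assimilation"),
    interacting_pathways = data.frame(
      id = c("ROUTE_A", "ROUTE_B1", "ROUTE_B2"),
      equation = c("N[c] -> E[c]", "N[c] -> B[c]", "B[c] -> E[c]"),
      gpr = c("gA", "gB", ""),
      pathways = c("biosynthesis-one", "degradation-two",
                   "degradation-two")))
  model <- buildModel(rbind(common, routes), objective = "BIOMASS")
  list(model = model,
       media = Media(c("N[e]" = 1.5), name = "minimal"),
       truth = list(slPair = c("gA", "gB"), classification = slClass,
                    rescueSupplement = "E[e]"))
}

## Growth produces by-product W with no exporter; a 1:1 shuttle
## W[c] <-> W[n] is the only other reaction touching W. With the
## simple-transport exemption the shuttle cannot absorb W's production,
## so growth is impossible; without the exemption the shuttle loop
## manufactures dilution capacity and growth leaks through.
.fxTransportCheat <- function() {
  rx <- data.frame(
    id = c("EX_S", "T_S", "CONV", "SHUTTLE", "BIOMASS"),
    equation = c("S[e] <->", "S[e] -> S[c]", "S[c] -> P[c] + W[c]",
                 "W[c] <-> W[n]", "P[c] ->"),
    gpr = c("", "", "g_conv", "", ""),
    pathways = c("", "transport", "core", "transport", ""))
  model <- buildModel(rx, objective = "BIOMASS")
  list(model = model,
       media = Media(c("S[e]" = 1.5), name = "minimal"),
       truth = list(shuttle = "SHUTTLE", byProduct = "W[c]"))
}

## Viable core chain plus k dead-end reactions M1 -> Z_j.
.fxDeadEnd <- function(k) {
  dead <- data.frame(
    id = paste0("DEAD", seq_len(k)),
    equation = paste0("M1[c] -> Z", seq_len(k), "[c]"),
    gpr = "", pathways = "")
  rx <- rbind(
    data.frame(id = c("EX_M0", "T_M0", "CORE", "BIOMASS"),
               equation = c("M0[e] <->", "M0[e] -> M0[c]",
                            "M0[c] -> M1[c]", "M1[c] ->"),
               gpr = "", pathways = ""),
    dead)
  model <- buildModel(rx, objective = "BIOMASS")
  list(model = model,
       media = Media(c("M0[e]" = 1.5), name = "minimal"),
       truth = list(blocked = paste0("DEAD", seq_len(k)),
                    core = c("EX_M0", "T_M0", "CORE", "BIOMASS")))
}

#' Generate a random stoichiometric network
#'
#' Builds a connected random model with a guaranteed backbone (one uptake,
#' a short chain, a biomass drain) plus random reactions over the existing
#' metabolites with small integer coefficients (so brute-force oracles
#' stay exact). Some of the random reactions are reversible. Generation is
#' deterministic for a given seed and leaves the caller's RNG state
#' untouched.
#'
#' @param nMets number of intracellular metabolites.
#' @param nRxns total number of reactions (>= 4).
#' @param seed integer seed.
#' @param density mean number of participants per random reaction is
#'   \code{2 + 2 * density}.
#' @return a [MetabolicModel-class].
#' @export
randomModel <- function(nMets = 6, nRxns = 10, seed = 1, density = 0.3) {
  stopifnot(nRxns >= 4, nMets >= 2)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  mets <- paste0("m", seq_len(nMets), "[c]")
  backbone <- data.frame(
    id = c("EX_n", "T_n", "BIOMASS"),
    equation = c("n[e] <->", paste0("n[e] -> ", mets[1]),
                 paste0(mets[sample(nMets, 1)], " ->")),
    gpr = "", stringsAsFactors = FALSE)
  nRandom <- nRxns - nrow(backbone)
  rand <- lapply(seq_len(nRandom), function(j) {
    k <- min(nMets, 2 + stats::rpois(1, 2 * density))
    who <- sample(mets, max(2, k))
    split <- sample(length(who) - 1, 1)
    coefs <- sample(c(1, 1, 2), length(who), replace = TRUE)
    lhs <- paste(paste(coefs[1:split], who[1:split]), collapse = " + ")
    rhs <- paste(paste(coefs[(split + 1):length(who)],
                       who[(split + 1):length(who)]), collapse = " + ")
    data.frame(id = paste0("RR", j),
               equation = paste(lhs, if (stats::runif(1) < 0.3) "<->" else "->",
                                rhs),
               gpr = paste0("rg", j), stringsAsFactors = FALSE)
  })
  buildModel(rbind(backbone, do.call(rbind, rand)), objective = "BIOMASS")
}
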