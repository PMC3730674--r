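#' @import methods
#' @importClassesFrom Matrix dgCMatrix
#' @importClassesFrom S4Vectors DataFrame
NULL

#' MetabolicModel: a constraint-based metabolic network
#'
#' The central container of the package. It holds the stoichiometric matrix
#' \eqn{S} (metabolites x reactions, sparse), per-reaction flux bounds in
#' mmol/gDW/h, one biomass objective reaction, gene-protein-reaction (GPR)
#' rules, and per-reaction pathway and evidence annotations.
#'
#' @slot S sparse stoichiometric matrix (\code{dgCMatrix}); rows are
#'   metabolites, columns are reactions, dimnames carry the identifiers.
#' @slot metabolites \code{DataFrame} with one row per metabolite and columns
#'   \code{id}, \code{name}, \code{compartment}, \code{species} (the
#'   compartment-free chemical identity used for transport detection),
#'   \code{formula}, \code{charge}.
#' @slot reactions \code{DataFrame} with one row per reaction and columns
#'   \code{id}, \code{name}, \code{lb}, \code{ub}, \code{gpr} (boolean rule
#'   over gene ids; \code{""} for orphan/spontaneous reactions),
#'   \code{pathways} (\code{CharacterList}), \code{isExchange}, plus the
#'   evidence columns \code{curated}, \code{pBiochem}, \code{pThermo},
#'   \code{pathwaySupport} (NA when unknown).
#' @slot objective id of the biomass reaction (single reaction).
#' @slot genes character vector of all gene ids.
#'
#' @seealso [buildModel()] for the user-facing constructor,
#'   [readCobraSbml()] for SBML import.
#' @export
setClass("MetabolicModel",
  slots = c(
    S = "dgCMatrix",
    metabolites = "DataFrame",
    reactions = "DataFrame",
    objective = "character",
    genes = "character"
  )
)

.validMetabolicModel <- function(object) {
  msg <- character()
  S <- object@S
  met <- object@metabolites
  rxn <- object@reactions
  if (nrow(S) != nrow(met))
    msg <- c(msg, "nrow(S) does not match the metabolite table")
  if (ncol(S) != nrow(rxn))
    msg <- c(msg, "ncol(S) does not match the reaction table")
  if (nrow(met) > 0 && !identical(rownames(S), met$id))
    msg <- c(msg, "rownames(S) must equal metabolites$id")
  if (nrow(rxn) > 0 && !identical(colnames(S), rxn$id))
    msg <- c(msg, "colnames(S) must equal reactions$id")
  if (anyDuplicated(met$id)) msg <- c(msg, "duplicated metabolite ids")
  if (anyDuplicated(rxn$id)) msg <- c(msg, "duplicated reaction ids")
  if (nrow(rxn) > 0) {
    if (any(rxn$lb > rxn$ub))
      msg <- c(msg, "lower bound exceeds upper bound for some reaction")
    if (any(!is.finite(rxn$lb)) || any(!is.finite(rxn$ub)))
      msg <- c(msg, "bounds must be finite (use a v_max cap, not Inf)")
  }
  if (length(object@objective) != 1L || is.na(object@objective) ||
      !(object@objective %in% rxn$id))
    msg <- c(msg, "objective must name exactly one reaction in the model")
  gpr_genes <- unique(unlist(lapply(rxn$gpr, gprGenes), use.names = FALSE))
  if (length(setdiff(gpr_genes, object@genes)) > 0)
    msg <- c(msg, paste("GPR genes missing from the gene set:",
                        paste(setdiff(gpr_genes, object@genes), collapse = ", ")))
  if (length(msg)) msg else TRUE
}
setValidity("MetabolicModel", .validMetabolicModel)

#' IrreversibleModel: a model with all reactions irreversible
#'
#' Produced by [splitReversible()]. Every reaction has \code{lb == 0}, so
#' all feasible fluxes are non-negative. Reactions derived from a reversible
#' parent carry a back-reference: the reaction table gains the columns
#' \code{parentId} and \code{direction} (\code{"fwd"} or \code{"rev"}), and
#' the \code{"rev"} child's stoichiometry is the negation of the parent's.
#'
#' @seealso [splitReversible()], [mergeFluxes()]
#' @export
setClass("IrreversibleModel", contains = "MetabolicModel")

setValidity("IrreversibleModel", function(object) {
  msg <- character()
  rxn <- object@reactions
  if (!all(c("parentId", "direction") %in% colnames(rxn)))
    return("reaction table must carry parentId and direction")
  if (nrow(rxn) > 0) {
    if (any(rxn$lb < 0))
      msg <- c(msg, "all lower bounds must be non-negative")
    if (!all(rxn$direction %in% c("fwd", "rev")))
      msg <- c(msg, "direction must be 'fwd' or 'rev'")
    rev <- which(rxn$direction == "rev")
    for (j in rev) {
      fwd <- which(rxn$parentId == rxn$parentId[j] & rxn$direction == "fwd")
      if (length(fwd) != 1L) {
        msg <- c(msg, paste0("rev child without fwd sibling: ", rxn$id[j]))
      } else if (!isTRUE(all.equal(object@S[, j], -object@S[, fwd]))) {
        msg <- c(msg, paste0("rev child is not the negation of fwd: ", rxn$id[j]))
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Media: an in-silico growth condition
#'
#' A named set of maximum uptake rates (mmol/gDW/h) for extracellular
#' metabolites. Applying a medium to a model opens the uptake direction of
#' the matching exchange reactions and closes all other uptakes; secretion
#' is never restricted.
#'
#' @slot name label for the condition.
#' @slot uptake named non-negative numeric; names are extracellular
#'   metabolite ids, values are maximum uptake rates.
#' @seealso [Media()], [buildMedia()], [applyMedia()]
#' @export
setClass("Media", slots = c(name = "character", uptake = "numeric"))

setValidity("Media", function(object) {
  msg <- character()
  if (length(object@uptake) > 0) {
    if (is.null(names(object@uptake)) || any(names(object@uptake) == ""))
      msg <- c(msg, "uptake must be a fully named numeric vector")
    if (any(object@uptake < 0) || any(!is.finite(object@uptake)))
      msg <- c(msg, "uptake caps must be finite and >= 0")
    if (anyDuplicated(names(object@uptake)))
      msg <- c(msg, "duplicated metabolite in media")
  }
  if (length(msg)) msg else TRUE
})

#' DilutionSpec: the dilution coefficients of limed-FBA
#'
#' Holds the diagonal \eqn{\epsilon} of per-metabolite dilution
#' coefficients together with the two exemption sets: simple transport
#' reactions (whose columns of the binary stoichiometry are zeroed so that
#' shuttling cannot manufacture dilution capacity) and biomass metabolites
#' (whose growth-associated dilution is already captured by the biomass
#' reaction, so \eqn{\epsilon_{ii} = 0}).
#'
#' @slot epsilon named non-negative numeric, one entry per metabolite.
#' @slot dMax maximum allowed dilution rate per metabolite (flux units).
#' @slot vMax global flux cap used both in the LPs and in the epsilon
#'   normalisation.
#' @slot exemptTransport reaction ids (parent-level) excluded from the
#'   binary stoichiometry.
#' @slot exemptMetabolites metabolite ids with \eqn{\epsilon_{ii} = 0}.
#' @seealso [dilutionSpec()], [limedFBA()]
#' @export
setClass("DilutionSpec",
  slots = c(
    epsilon = "numeric",
    dMax = "numeric",
    vMax = "numeric",
    exemptTransport = "character",
    exemptMetabolites = "character"
  )
)

setValidity("DilutionSpec", function(object) {
  msg <- character()
  if (any(object@epsilon < 0)) msg <- c(msg, "epsilon must be >= 0")
  if (length(object@epsilon) && is.null(names(object@epsilon)))
    msg <- c(msg, "epsilon must be named by metabolite id")
  if (length(object@exemptMetabolites) &&
      any(object@epsilon[intersect(names(object@epsilon),
                                   object@exemptMetabolites)] != 0))
    msg <- c(msg, "exempt metabolites must have epsilon == 0")
  if (object@dMax <= 0 || object@vMax <= 0)
    msg <- c(msg, "dMax and vMax must be > 0")
  if (length(msg)) msg else TRUE
})

#' FluxSolution: the outcome of an FBA or limed-FBA solve
#'
#' @slot fluxes named numeric, net flux per reaction of the original
#'   (reversible) model, mmol/gDW/h.
#' @slot objective optimal biomass flux (0 when infeasible).
#' @slot status \code{"optimal"} or \code{"infeasible"}.
#' @slot dilution named numeric, realized dilution
#'   \eqn{b = \epsilon S^{binary} v} per metabolite (all zero for plain FBA).
#' @slot method \code{"limed"} or \code{"fba"}.
#' @export
setClass("FluxSolution",
  slots = c(
    fluxes = "numeric",
    objective = "numeric",
    status = "character",
    dilution = "numeric",
    method = "character"
  )
)

#' PruneResult: the outcome of a OnePrune run
#'
#' Classification of every irreversible reaction as able (t = 1) or unable
#' (t = 0) to carry flux given unlimited nutrients, plus the witness flux
#' vector of the single goal-programming LP.
#'
#' @slot unblocked ids of irreversible reactions with optimal t at 1.
#' @slot blocked ids of irreversible reactions with optimal t at 0.
#' @slot t named numeric of optimal goal variables.
#' @slot witness named numeric witness flux (child-level).
#' @slot parentBlocked ids of original-model reactions all of whose
#'   directions are blocked.
#' @slot nLpSolves number of LP-layer invocations consumed by the call.
#' @export
setClass("PruneResult",
  slots = c(
    unblocked = "character",
    blocked = "character",
    t = "numeric",
    witness = "numeric",
    parentBlocked = "character",
    nLpSolves = "numeric"
  )
)

#' ScreenSummary: confusion counts of a viability screen
#'
#' Sensitivity is the proportion of experimentally viable mutants predicted
#' viable; specificity the proportion of experimentally inviable mutants
#' predicted inviable.
#'
#' @slot tp,tn,fp,fn confusion counts (positive = viable).
#' @slot sensitivity,specificity proportions in [0, 1].
#' @export
setClass("ScreenSummary",
  slots = c(
    tp = "integer", tn = "integer", fp = "integer", fn = "integer",
    sensitivity = "numeric", specificity = "numeric"
  )
)

#' Reconciliation: a CROP suggestion for one phenotype
#'
#' A ranked set of reaction additions (to restore growth) or removals (to
#' suppress growth) that flips the model's growth call for one observed
#' phenotype. Suggestions are never auto-applied; the \code{accepted} flag
#' is a hook for manual review.
#'
#' @slot action \code{"add"} or \code{"remove"}.
#' @slot genes knocked-out genes of the phenotype.
#' @slot media name of the growth condition.
#' @slot observed observed phenotype, \code{"viable"} or \code{"inviable"}.
#' @slot suggestions \code{DataFrame} with columns \code{reaction},
#'   \code{weight} and (for additions) \code{y}, the LP-relaxation
#'   indicator value.
#' @slot resolved whether a suggestion set flipping the growth call exists.
#' @slot postBiomass biomass flux after applying the suggestions.
#' @slot accepted manual-review flag, FALSE until reviewed.
#' @export
setClass("Reconciliation",
  slots = c(
    action = "character",
    genes = "character",
    media = "character",
    observed = "character",
    suggestions = "DataFrame",
    resolved = "logical",
    postBiomass = "numeric",
    accepted = "logical"
  )
)
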