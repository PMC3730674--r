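#' @include AllClasses.R AllGenerics.R
NULL

#' Split reversible reactions into irreversible pairs
#'
#' Transforms a model so that every reaction is irreversible: reactions
#' with \code{lb >= 0} are copied unchanged; a reaction with \code{lb < 0}
#' becomes two children, \code{<id>__fwd} with bounds \code{[0, ub]} and
#' \code{<id>__rev} with bounds \code{[0, -lb]} and negated stoichiometry.
#' GPR, pathway and evidence annotations are copied to both children. Any
#' feasible flux of the child model maps back to a feasible flux of the
#' parent via \code{fwd - rev} (see [mergeFluxes()]).
#'
#' @param model a [MetabolicModel-class].
#' @return an [IrreversibleModel-class]; its reaction table carries
#'   \code{parentId} and \code{direction} back-references.
#' @rdname splitReversible
#' @export
setMethod("splitReversible", "MetabolicModel", function(model) {
  rxn <- model@reactions
  revIdx <- which(rxn$lb < 0)
  fwd <- rxn
  fwd$parentId <- rxn$id
  fwd$direction <- "fwd"
  fwd$lb <- pmax(rxn$lb, 0)
  ## a reaction with ub < 0 runs strictly backwards: its fwd child is empty
  fwd$ub <- pmax(rxn$ub, 0)

  Sf <- model@S
  if (length(revIdx) > 0) {
    rev <- rxn[revIdx, ]
    rev$parentId <- rev$id
    rev$direction <- "rev"
    rev$ub <- -rxn$lb[revIdx]
    rev$lb <- 0
    rev$id <- paste0(rev$parentId, "__rev")
    fwd$id[revIdx] <- paste0(fwd$parentId[revIdx], "__fwd")
    Sr <- -model@S[, revIdx, drop = FALSE]
    S <- cbind(Sf, Sr)
    rxn2 <- rbind(fwd, rev)
  } else {
    S <- Sf
    rxn2 <- fwd
  }
  colnames(S) <- rxn2$id
  rownames(rxn2) <- rxn2$id
  S <- methods::as(methods::as(S, "CsparseMatrix"), "generalMatrix")

  objChildren <- rxn2$id[rxn2$parentId == model@objective &
                           rxn2$direction == "fwd"]
  out <- methods::new("IrreversibleModel", S = S,
                      metabolites = model@metabolites, reactions = rxn2,
                      objective = objChildren, genes = model@genes)
  validObject(out)
  out
})

setMethod("splitReversible", "IrreversibleModel", function(model) model)

#' Merge irreversible child fluxes back to the parent model
#'
#' Folds a flux vector over the children of [splitReversible()] into net
#' parent fluxes, \code{fwd - rev}.
#'
#' @param imodel an [IrreversibleModel-class].
#' @param v named (or positionally ordered) child flux vector.
#' @return named numeric of net fluxes over the parent reaction ids.
#' @export
mergeFluxes <- function(imodel, v) {
  rxn <- imodel@reactions
  if (is.null(names(v))) names(v) <- rxn$id
  sgn <- ifelse(rxn$direction == "rev", -1, 1)
  out <- tapply(unname(v[rxn$id]) * sgn, rxn$parentId, sum)
  res <- stats::setNames(as.numeric(out), names(out))
  res[unique(rxn$parentId)]
}

#' Net flux of the objective reaction in a child-level flux vector
#' @noRd
.objectiveNetFlux <- function(imodel, v) {
  rxn <- imodel@reactions
  parent <- rxn$parentId[match(imodel@objective[1], rxn$id)]
  kids <- which(rxn$parentId == parent)
  sum(v[kids] * ifelse(rxn$direction[kids] == "rev", -1, 1))
}

#' Objective coefficient vector at child level (fwd +1, rev -1)
#' @noRd
.objectiveVector <- function(imodel) {
  rxn <- imodel@reactions
  parent <- rxn$parentId[match(imodel@objective[1], rxn$id)]
  cc <- numeric(nrow(rxn))
  kids <- rxn$parentId == parent
  cc[kids] <- ifelse(rxn$direction[kids] == "rev", -1, 1)
  cc
}
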