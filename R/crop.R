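#' @include AllClasses.R limedFBA.R
NULL

#' Evidence-based reaction weight
#'
#' Integrates independent reaction evidence on a probabilistic scale:
#' \deqn{w = -\log(p_{biochem} \cdot p_{thermo} \cdot p_{pathway})}
#' the negative log of the product of the probabilities that the reaction
#' is biochemically plausible, thermodynamically plausible, and part of a
#' pathway present in the organism. Motivated by the maximum a posteriori
#' estimator: minimising a sum of weights maximises the joint probability
#' of the selected reactions. Fully supported reactions cost nothing
#' (\eqn{w = 0}); halving any single probability adds exactly
#' \eqn{\ln 2} regardless of the others.
#'
#' @param pBiochem,pThermo,pathwaySupport probabilities in (0, 1]
#'   (vectorised; recycled to a common length).
#' @return numeric vector of non-negative weights.
#' @examples
#' reactionWeight(1, 1, 1)      # 0
#' reactionWeight(0.5, 1, 1)    # log(2)
#' @export
reactionWeight <- function(pBiochem = 1, pThermo = 1, pathwaySupport = 1) {
  n <- max(length(pBiochem), length(pThermo), length(pathwaySupport))
  p <- cbind(rep_len(pBiochem, n), rep_len(pThermo, n),
             rep_len(pathwaySupport, n))
  if (any(is.na(p)) || any(p <= 0) || any(p > 1))
    stop("evidence probabilities must lie in (0, 1]")
  -log(p[, 1] * p[, 2] * p[, 3])
}

#' Reaction weights for a whole model
#'
#' Applies [reactionWeight()] to the evidence columns of the reaction
#' table. Missing biochemical or thermodynamic probabilities default to 1;
#' a missing pathway prediction defaults to the uninformative 0.5. Curated
#' reactions (manually confirmed against the literature) get weight 0 when
#' weighting candidate additions, and infinite weight — i.e. they are never
#' candidates — when weighting removals.
#'
#' @param model a [MetabolicModel-class].
#' @param forRemoval weights for removal candidates (curated reactions
#'   excluded via \code{Inf}) rather than addition candidates.
#' @param defaultPathwaySupport value used where no pathway prediction
#'   exists.
#' @return named numeric vector over reaction ids.
#' @export
modelReactionWeights <- function(model, forRemoval = FALSE,
                                 defaultPathwaySupport = 0.5) {
  rxn <- model@reactions
  pB <- ifelse(is.na(rxn$pBiochem), 1, rxn$pBiochem)
  pT <- ifelse(is.na(rxn$pThermo), 1, rxn$pThermo)
  pS <- ifelse(is.na(rxn$pathwaySupport), defaultPathwaySupport,
               rxn$pathwaySupport)
  w <- reactionWeight(pB, pT, pS)
  w[rxn$curated] <- if (forRemoval) Inf else 0
  stats::setNames(w, rxn$id)
}

.reconciliation <- function(action, genes, media, observed, suggestions,
                            resolved, postBiomass) {
  methods::new("Reconciliation", action = action, genes = genes,
               media = if (methods::is(media, "Media")) media@name else
                 as.character(media),
               observed = observed, suggestions = suggestions,
               resolved = resolved, postBiomass = postBiomass,
               accepted = FALSE)
}

#' Suggest reaction additions that restore growth (CROP)
#'
#' For a phenotype observed viable but predicted inviable, selects a
#' minimum-total-weight set of reactions from a candidate database whose
#' addition lets the knocked-out model grow. The combinatorial add-set
#' problem is solved through its LP relaxation — candidate indicators
#' \eqn{y_r \in [0,1]} with flux coupling \eqn{v_r \le v_{max} y_r},
#' biomass \eqn{\ge} the growth threshold under the limed-FBA constraints,
#' objective \eqn{\min \sum_r w_r y_r} — which is orders of magnitude
#' faster than the mixed-integer formulation. Indicators above the rounding
#' threshold are taken; the rounded set is verified by re-simulation,
#' extended greedily by descending \eqn{y} if verification fails, and
#' finally stripped of redundant members (heaviest first). Suggestions are
#' returned ranked, never auto-applied.
#'
#' @param model a [MetabolicModel-class] that (after the knockout) fails
#'   to grow.
#' @param database a [MetabolicModel-class] holding candidate reactions in
#'   the same metabolite namespace (its objective is ignored), or a
#'   data.frame accepted by [buildModel()].
#' @param media a [Media-class].
#' @param genes knocked-out genes of the phenotype (may be empty: the
#'   model itself fails to grow).
#' @param weights named weights for the database reactions; computed from
#'   their evidence columns by default.
#' @param threshold biomass flux above which the model counts as growing.
#' @param roundThreshold indicator value above which a candidate is taken.
#' @param spec a [DilutionSpec-class] for the merged model (recomputed by
#'   default).
#' @return a [Reconciliation-class] (action \code{"add"}); unresolvable
#'   phenotypes are flagged, not errors.
#' @export
restoreGrowth <- function(model, database, media, genes = character(),
                          weights = NULL, threshold = 0.02,
                          roundThreshold = 0.5, spec = NULL) {
  if (is.data.frame(database))
    database <- buildModel(database, objective = database$id[1])
  if (is.null(weights)) weights <- modelReactionWeights(database)
  cand <- database@reactions$id
  weights <- weights[cand]
  if (any(is.na(weights)))
    stop("weights must cover every database reaction")

  base <- limedFBA(applyKnockout(model, genes), media)
  if (base@objective > threshold)
    stop("phenotype already grows (biomass ", format(base@objective),
         "); nothing to restore")

  merged <- applyKnockout(addReactions(model, database), genes)
  merged <- applyMedia(merged, media)
  if (is.null(spec)) spec <- dilutionSpec(merged)
  im <- splitReversible(merged)
  B <- binaryStoichiometry(im, spec)
  eps <- spec@epsilon[rownames(im@S)]
  Slim <- as.matrix(im@S - Matrix::Diagonal(x = eps) %*% B)

  n <- nrow(im@reactions)
  k <- length(cand)
  Aeq <- cbind(Slim, matrix(0, nrow(Slim), k))
  ## biomass >= threshold
  growRow <- c(-.objectiveVector(im), rep(0, k))
  ## candidate flux coupling v_child <= vMax * y_parent
  childIdx <- which(im@reactions$parentId %in% cand)
  couple <- matrix(0, length(childIdx), n + k)
  for (r in seq_along(childIdx)) {
    couple[r, childIdx[r]] <- 1
    couple[r, n + match(im@reactions$parentId[childIdx[r]], cand)] <- -spec@vMax
  }
  sol <- .solveLP(obj = c(rep(0, n), unname(weights)),
                  Aeq = Aeq, beq = rep(0, nrow(Slim)),
                  Aineq = rbind(growRow, couple),
                  bineq = c(-threshold, rep(0, length(childIdx))),
                  lb = rep(0, n + k),
                  ub = c(pmin(im@reactions$ub, spec@vMax), rep(1, k)),
                  maximize = FALSE)

  empty <- DataFrame(reaction = character(), weight = numeric(),
                     y = numeric())
  if (sol$status != "optimal")
    return(.reconciliation("add", genes, media, "viable", empty,
                           FALSE, 0))

  y <- stats::setNames(sol$x[n + seq_len(k)], cand)
  ord <- names(sort(y, decreasing = TRUE))
  sel <- names(y)[y >= roundThreshold]
  verify <- function(set) {
    if (length(set) == 0) return(0)
    m2 <- applyKnockout(addReactions(model, database, only = set), genes)
    limedFBA(m2, media)@objective
  }
  post <- verify(sel)
  extend <- setdiff(ord[y[ord] > 1e-9], sel)
  while (post <= threshold && length(extend) > 0) {
    sel <- c(sel, extend[1]); extend <- extend[-1]
    post <- verify(sel)
  }
  if (post <= threshold)
    return(.reconciliation("add", genes, media, "viable", empty, FALSE, 0))

  ## strip redundant members, heaviest first
  for (r in sel[order(weights[sel], decreasing = TRUE)]) {
    if (length(sel) == 1) break
    trial <- setdiff(sel, r)
    if (verify(trial) > threshold) sel <- trial
  }
  post <- verify(sel)
  sel <- sel[order(weights[sel], sel)]
  .reconciliation("add", genes, media, "viable",
                  DataFrame(reaction = sel, weight = unname(weights[sel]),
                            y = unname(y[sel])),
                  TRUE, post)
}

#' Suggest reaction removals that suppress growth (CROP)
#'
#' For a phenotype observed inviable but predicted viable, finds a
#' minimum-total-weight set of non-curated reactions whose removal drives
#' the maximal biomass below the growth threshold. The underlying
#' indicator program is solved exactly within a size cap: removal subsets
#' are enumerated in order of increasing total weight (ties broken
#' lexicographically) and each candidate set is verified by an embedded
#' limed-FBA solve, pruned by the necessary condition that any suppressing
#' set must intersect the support of the current optimal flux. Curated
#' reactions carry infinite weight and are never selected.
#'
#' @param model a [MetabolicModel-class] that (after the knockout) grows.
#' @param media a [Media-class].
#' @param genes knocked-out genes of the phenotype.
#' @param weights named removal weights; [modelReactionWeights()] with
#'   \code{forRemoval = TRUE} by default.
#' @param threshold biomass flux above which the model counts as growing.
#' @param maxChanges largest removal set considered (the small-change
#'   scale of comparable reconciliation tools).
#' @param spec optional [DilutionSpec-class].
#' @return a [Reconciliation-class] (action \code{"remove"}).
#' @export
suppressGrowth <- function(model, media, genes = character(),
                           weights = NULL, threshold = 0.02,
                           maxChanges = 3, spec = NULL) {
  if (is.null(weights)) weights <- modelReactionWeights(model, forRemoval = TRUE)
  ko <- applyKnockout(model, genes)
  if (is.null(spec)) spec <- dilutionSpec(model)
  base <- limedFBA(ko, media, spec)
  if (base@objective <= threshold)
    stop("phenotype already fails to grow (biomass ",
         format(base@objective), "); nothing to suppress")

  removable <- setdiff(model@reactions$id[!model@reactions$curated],
                       model@objective)
  removable <- removable[is.finite(weights[removable])]
  removable <- removable[order(weights[removable], removable)]

  closeAndSolve <- function(set) {
    m2 <- ko
    j <- match(set, m2@reactions$id)
    m2@reactions$lb[j] <- 0
    m2@reactions$ub[j] <- 0
    limedFBA(m2, media, spec)
  }
  ## any suppressing set must intersect the support of the current optimum;
  ## a reversible reaction can carry gross flux at zero net flux, so keep
  ## reversible reactions in the support superset unconditionally
  support <- union(names(base@fluxes)[abs(base@fluxes) > 1e-9],
                   model@reactions$id[model@reactions$lb < 0])

  empty <- DataFrame(reaction = character(), weight = numeric())
  if (length(removable) == 0)
    return(.reconciliation("remove", genes, media, "inviable", empty,
                           FALSE, base@objective))

  ## enumerate subsets by increasing total weight
  subsets <- list()
  for (size in seq_len(min(maxChanges, length(removable)))) {
    cmb <- utils::combn(removable, size, simplify = FALSE)
    subsets <- c(subsets, cmb)
  }
  tw <- vapply(subsets, function(s) sum(weights[s]), numeric(1))
  keys <- vapply(subsets, paste, character(1), collapse = "\r")
  ord <- order(tw, lengths(subsets), keys)
  for (idx in ord) {
    set <- subsets[[idx]]
    if (!any(set %in% support)) next   # cannot cut the current optimum
    solv <- closeAndSolve(set)
    if (solv@objective <= threshold) {
      return(.reconciliation("remove", genes, media, "inviable",
                             DataFrame(reaction = set,
                                       weight = unname(weights[set])),
                             TRUE, solv@objective))
    }
  }
  .reconciliation("remove", genes, media, "inviable", empty, FALSE,
                  base@objective)
}
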