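#' @include AllClasses.R limedFBA.R
NULL

## Open unrestricted uptake (up to vMax) for the requested nutrient
## metabolites' exchange reactions; close the rest.
.openNutrients <- function(model, nutrients, vMax) {
  if (methods::is(nutrients, "Media"))
    nutrients <- names(nutrients@uptake)
  if (identical(nutrients, "all"))
    nutrients <- extracellularMetabolites(model)
  applyMedia(model, Media(stats::setNames(rep(vMax, length(nutrients)),
                                          nutrients)))
}

#' Identify all reactions able to carry flux with a single LP (OnePrune)
#'
#' Solves the goal program
#' \deqn{\max \sum_i t_i \quad s.t. \quad S_{limed} v = 0,\;
#'   0 \le v \le v_{max},\; 0 \le t_i \le 1,\; t_i \le v_i / \delta}
#' on the irreversible model with unlimited nutrients. Once a reaction
#' reaches one unit of flux its goal variable saturates at 1 and the
#' optimization is free to pursue flux through other reactions, so a single
#' compact LP classifies every reaction: at the optimum each \eqn{t_i} is
#' binary — 1 for reactions that can carry flux, 0 for blocked reactions.
#' Using the dilution-corrected \eqn{S_{limed}} disallows two-cycles from
#' split reversible reactions (they lack an input flux), which plain FBA
#' would let carry flux. Exempt simple-transport self-cycles are not
#' penalized and therefore survive; see [fluxVariability()] on the parent
#' model for the documented fallback that catches them.
#'
#' @param model a [MetabolicModel-class] (split internally after opening
#'   nutrients) or an [IrreversibleModel-class] with bounds already set.
#' @param spec a [DilutionSpec-class]; computed from the model by default.
#' @param nutrients \code{"all"} (every extracellular metabolite, the
#'   setting used to prune a final model), a character vector of
#'   extracellular metabolite ids, or a [Media-class].
#' @param tol threshold on \eqn{1 - t_i} for calling a reaction unblocked.
#' @param delta flux scale that saturates a goal variable (\eqn{t_i \le
#'   v_i/\delta}): "can carry \eqn{\delta} flux units" is the operational
#'   definition of unblocked. The default 1e-3 lies well below the fluxes
#'   that the dilution constraints cap (a dead-end metabolite's feeder can
#'   legally carry only its small dilution leak) and well above solver
#'   noise, which keeps the optimal t binary (to the numerical resolution
#'   tol/delta: flux noise enters t scaled by 1/delta) and the
#'   classification identical to the FVA oracle.
#' @return a [PruneResult-class].
#' @export
findUnblocked <- function(model, spec = NULL, nutrients = "all",
                          tol = 1e-6, delta = 1e-3) {
  if (is.null(spec)) spec <- dilutionSpec(model)
  if (!methods::is(model, "IrreversibleModel")) {
    model <- .openNutrients(model, nutrients, spec@vMax)
    im <- splitReversible(model)
  } else im <- model

  n <- nrow(im@reactions)
  B <- binaryStoichiometry(im, spec)
  eps <- spec@epsilon[rownames(im@S)]
  Slim <- im@S - Matrix::Diagonal(x = eps) %*% B

  n0 <- lpSolveCount()
  ## variables x = [v (n), t (n)]
  Aeq <- cbind(as.matrix(Slim), matrix(0, nrow(Slim), n))
  Aineq <- cbind(-diag(n), delta * diag(n))     # delta * t - v <= 0
  sol <- .solveLP(obj = c(rep(0, n), rep(1, n)),
                  Aeq = Aeq, beq = rep(0, nrow(Slim)),
                  Aineq = Aineq, bineq = rep(0, n),
                  lb = c(im@reactions$lb, rep(0, n)),
                  ub = c(pmin(im@reactions$ub, spec@vMax), rep(1, n)),
                  maximize = TRUE)
  if (sol$status != "optimal")
    stop("OnePrune goal program did not solve (status ", sol$status, ")")
  nlp <- lpSolveCount() - n0

  tvals <- stats::setNames(sol$x[(n + 1):(2 * n)], im@reactions$id)
  v <- stats::setNames(sol$x[1:n], im@reactions$id)
  unblocked <- names(tvals)[tvals >= 1 - tol]
  blocked <- setdiff(names(tvals), unblocked)
  byParent <- split(im@reactions$id %in% blocked, im@reactions$parentId)
  parentBlocked <- names(byParent)[vapply(byParent, all, logical(1))]

  methods::new("PruneResult", unblocked = unblocked, blocked = blocked,
               t = tvals, witness = v,
               parentBlocked = parentBlocked[
                 order(match(parentBlocked, model@reactions$id))],
               nLpSolves = nlp)
}

#' Functional pruning: remove blocked reactions
#'
#' Runs [findUnblocked()] and removes every reaction of the original model
#' none of whose directions can carry flux; a reversible reaction with only
#' one blocked direction is tightened to the surviving direction.
#' Metabolites left orphaned by the removal are dropped. Counts are
#' reported via \code{message()}.
#'
#' @inheritParams findUnblocked
#' @param fvaCheck additionally run [fluxVariability()] on the parent model
#'   and remove reactions it finds blocked (catches exempt-transport
#'   self-cycles the goal program leaves untouched).
#' @return the pruned [MetabolicModel-class].
#' @export
pruneModel <- function(model, spec = NULL, nutrients = "all",
                       tol = 1e-6, fvaCheck = FALSE) {
  if (is.null(spec)) spec <- dilutionSpec(model)
  res <- findUnblocked(model, spec, nutrients, tol = tol)
  toDrop <- res@parentBlocked
  if (fvaCheck) {
    fv <- fluxVariability(model, spec = spec, nutrients = nutrients, tol = tol)
    toDrop <- union(toDrop, fv$reaction[fv$blocked])
  }
  if (model@objective %in% toDrop)
    stop("the biomass reaction itself is blocked: the model cannot grow ",
         "on any nutrients")
  ## direction-tighten reversible reactions with one blocked child
  rxn <- model@reactions
  im <- splitReversible(.openNutrients(model, nutrients, spec@vMax))
  keepDrop <- setdiff(unique(im@reactions$parentId), toDrop)
  for (p in keepDrop) {
    kids <- im@reactions$id[im@reactions$parentId == p]
    if (length(kids) < 2) next
    bl <- intersect(kids, res@blocked)
    if (length(bl) == 0) next
    dirs <- im@reactions$direction[match(bl, im@reactions$id)]
    j <- match(p, rxn$id)
    if ("rev" %in% dirs) rxn$lb[j] <- max(rxn$lb[j], 0)
    if ("fwd" %in% dirs) rxn$ub[j] <- min(rxn$ub[j], 0)
  }
  model@reactions <- rxn
  out <- removeReactions(model, toDrop, dropOrphans = TRUE)
  message("pruned ", length(toDrop), " blocked reactions (",
          nrow(model@reactions), " -> ", nrow(out@reactions),
          "); ", nrow(model@metabolites) - nrow(out@metabolites),
          " orphaned metabolites removed")
  out
}

#' Flux variability analysis
#'
#' Per-reaction flux extrema over the (dilution-corrected) feasible region
#' with unlimited nutrients — the brute-force oracle for blocked-reaction
#' detection. On an [IrreversibleModel-class] one LP per reaction maximizes
#' its flux (the minimum is 0 by construction); on a
#' [MetabolicModel-class] two LPs per reaction maximize and minimize the
#' net (fwd - rev) flux, which also catches reversible self-cycles that the
#' child-level view lets spin.
#'
#' @param model a [MetabolicModel-class] or [IrreversibleModel-class].
#' @param spec a [DilutionSpec-class]; computed from the model by default.
#' @param nutrients as in [findUnblocked()] (ignored for a pre-bounded
#'   irreversible model).
#' @param tol absolute flux below which a reaction is called blocked.
#' @param dilute use \eqn{S_{limed}} (TRUE) or plain \eqn{S}.
#' @param ... unused.
#' @return data.frame with columns \code{reaction}, \code{min}, \code{max},
#'   \code{blocked}.
#' @rdname fluxVariability
#' @export
setMethod("fluxVariability", "MetabolicModel",
  function(model, spec = NULL, nutrients = "all", tol = 1e-6,
           dilute = TRUE, ...) {
  if (is.null(spec)) spec <- dilutionSpec(model)
  opened <- .openNutrients(model, nutrients, spec@vMax)
  im <- splitReversible(opened)
  prep <- .fvaPrep(im, spec, dilute)
  rxn <- im@reactions
  parents <- model@reactions$id
  res <- lapply(parents, function(p) {
    kids <- which(rxn$parentId == p)
    cc <- numeric(nrow(rxn))
    cc[kids] <- ifelse(rxn$direction[kids] == "rev", -1, 1)
    hi <- .solveLP(cc, Aeq = prep$Aeq, beq = prep$beq, lb = prep$lb,
                   ub = prep$ub, maximize = TRUE)
    lo <- .solveLP(cc, Aeq = prep$Aeq, beq = prep$beq, lb = prep$lb,
                   ub = prep$ub, maximize = FALSE)
    if (hi$status != "optimal" || lo$status != "optimal")
      stop("FVA solve failed for reaction ", p)
    c(min = lo$objective, max = hi$objective)
  })
  res <- do.call(rbind, res)
  data.frame(reaction = parents, min = res[, "min"], max = res[, "max"],
             blocked = abs(res[, "min"]) <= tol & abs(res[, "max"]) <= tol,
             row.names = NULL)
})

#' @rdname fluxVariability
#' @export
setMethod("fluxVariability", "IrreversibleModel",
  function(model, spec = NULL, tol = 1e-6, dilute = TRUE, ...) {
  if (is.null(spec)) spec <- dilutionSpec(model)
  prep <- .fvaPrep(model, spec, dilute)
  n <- nrow(model@reactions)
  mx <- vapply(seq_len(n), function(j) {
    cc <- numeric(n); cc[j] <- 1
    sol <- .solveLP(cc, Aeq = prep$Aeq, beq = prep$beq, lb = prep$lb,
                    ub = prep$ub, maximize = TRUE)
    if (sol$status != "optimal")
      stop("FVA solve failed for reaction ", model@reactions$id[j])
    sol$objective
  }, numeric(1))
  data.frame(reaction = model@reactions$id, min = 0, max = mx,
             blocked = mx <= tol, row.names = NULL)
})

.fvaPrep <- function(im, spec, dilute) {
  B <- binaryStoichiometry(im, spec)
  eps <- spec@epsilon[rownames(im@S)]
  Slim <- if (dilute) im@S - Matrix::Diagonal(x = eps) %*% B else im@S
  list(Aeq = as.matrix(Slim), beq = rep(0, nrow(Slim)),
       lb = im@reactions$lb, ub = pmin(im@reactions$ub, spec@vMax))
}
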