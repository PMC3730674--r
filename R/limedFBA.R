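#' @include AllClasses.R convert.R
NULL

#' Detect simple transport reactions
#'
#' Simple transport reactions move metabolites between compartments with no
#' chemical change: every consumed species reappears unchanged on the
#' product side in a different compartment, all coefficients have magnitude
#' one, and no other participants are involved. Antiporters of two
#' unchanged species qualify; transport coupled to cofactor turnover (e.g.
#' ATP-driven pumps) does not. These reactions are exempted from the
#' dilution machinery: a shuttle loop must not be able to manufacture
#' dilution capacity.
#'
#' @param model a [MetabolicModel-class].
#' @return character vector of reaction ids.
#' @export
detectSimpleTransport <- function(model) {
  S <- model@S
  met <- model@metabolites
  out <- character()
  for (j in seq_len(ncol(S))) {
    st <- S[, j]
    nz <- which(st != 0)
    if (length(nz) < 2) next                       # boundary reaction
    if (any(abs(st[nz]) != 1)) next
    cons <- nz[st[nz] < 0]; prod <- nz[st[nz] > 0]
    if (length(cons) != length(prod) || length(cons) == 0) next
    spC <- sort(met$species[cons]); spP <- sort(met$species[prod])
    if (!identical(spC, spP)) next                  # chemical change
    if (length(unique(met$compartment[nz])) < 2) next
    ## each species must change compartment between the two sides
    ok <- TRUE
    for (sp in unique(spC)) {
      cc <- met$compartment[cons[met$species[cons] == sp]]
      cp <- met$compartment[prod[met$species[prod] == sp]]
      if (length(cc) != length(cp) || any(sort(cc) == sort(cp))) { ok <- FALSE; break }
    }
    if (ok) out <- c(out, model@reactions$id[j])
  }
  out
}

#' Binary stoichiometric pattern matrix
#'
#' \eqn{S^{binary}} has a 1 wherever the (irreversible) stoichiometric
#' matrix is nonzero, except that columns of exempt simple-transport
#' reactions are all zero. For a non-negative flux vector \eqn{v}, row
#' \eqn{i} of \eqn{S^{binary} v} is the summed absolute flux through the
#' reactions metabolite \eqn{i} participates in (twice its turnover), the
#' quantity the dilution term is proportional to.
#'
#' @param imodel an [IrreversibleModel-class].
#' @param spec a [DilutionSpec-class] (only the exempt transport set is
#'   used); may be NULL for no exemptions.
#' @return sparse 0/1 matrix with the dimensions of the model's S.
#' @export
binaryStoichiometry <- function(imodel, spec = NULL) {
  B <- methods::as(1 * (imodel@S != 0), "generalMatrix")
  if (!is.null(spec) && length(spec@exemptTransport) > 0) {
    zero <- imodel@reactions$parentId %in% spec@exemptTransport |
      imodel@reactions$id %in% spec@exemptTransport
    if (any(zero)) B[, zero] <- 0
  }
  methods::as(methods::as(B, "CsparseMatrix"), "generalMatrix")
}

#' Construct the dilution specification for a model
#'
#' Assigns the per-metabolite dilution coefficients
#' \eqn{\epsilon_{ii} = d_{max} / (k_i \, v_{max})}, where \eqn{k_i} is the
#' number of (non-exempt, irreversible) reactions metabolite \eqn{i}
#' participates in. Since each of those reactions contributes at most
#' \eqn{v_{max}} to row \eqn{i} of \eqn{S^{binary} v}, this is the unique
#' simple choice making the guarantee \eqn{b_i \le d_{max}} tight: no
#' metabolite's dilution rate can exceed \eqn{d_{max}} (0.1 by default)
#' for any flux in the box \eqn{0 \le v \le v_{max}}.
#'
#' Two exemption sets get \eqn{\epsilon_{ii} = 0} or a zeroed column:
#' metabolites drained by the biomass reaction (their growth-associated
#' dilution is already in the objective; defaults to the biomass reaction's
#' substrates) and simple transport reactions (defaults to
#' [detectSimpleTransport()]).
#'
#' @param model a [MetabolicModel-class].
#' @param dMax maximum dilution rate per metabolite (flux units).
#' @param vMax global flux cap.
#' @param exemptMetabolites override for the biomass-diluted metabolite set.
#' @param exemptTransport override for the simple-transport set
#'   (\code{character(0)} disables the exemption).
#' @param scale optional multiplier on epsilon, for exploring alternative
#'   normalisations; 1 keeps the \eqn{b_i \le d_{max}} guarantee tight.
#' @return a [DilutionSpec-class].
#' @export
dilutionSpec <- function(model, dMax = 0.1, vMax = .DEFAULT_VMAX,
                         exemptMetabolites = NULL, exemptTransport = NULL,
                         scale = 1) {
  if (is.null(exemptTransport))
    exemptTransport <- detectSimpleTransport(model)
  if (is.null(exemptMetabolites)) {
    st <- model@S[, model@objective]
    exemptMetabolites <- rownames(model@S)[st != 0]
  }
  im <- splitReversible(model)
  tmp <- methods::new("DilutionSpec",
                      epsilon = stats::setNames(numeric(nrow(im@S)),
                                                rownames(im@S)),
                      dMax = dMax, vMax = vMax,
                      exemptTransport = exemptTransport,
                      exemptMetabolites = exemptMetabolites)
  B <- binaryStoichiometry(im, tmp)
  k <- Matrix::rowSums(B)
  eps <- ifelse(k > 0, scale * dMax / (k * vMax), 0)
  names(eps) <- rownames(im@S)
  eps[names(eps) %in% exemptMetabolites] <- 0
  methods::new("DilutionSpec", epsilon = eps, dMax = dMax, vMax = vMax,
               exemptTransport = exemptTransport,
               exemptMetabolites = exemptMetabolites)
}

## Shared growth LP: max c'v on the irreversible model with
## (S - eps S_binary) v = 0 (eps = 0 recovers plain FBA).
.growthLP <- function(model, media = NULL, spec = NULL, dilute = TRUE,
                      vMax = NULL) {
  if (!is.null(media)) model <- applyMedia(model, media)
  if (is.null(spec)) spec <- dilutionSpec(model)
  if (is.null(vMax)) vMax <- spec@vMax
  im <- splitReversible(model)
  B <- binaryStoichiometry(im, spec)
  eps <- spec@epsilon[rownames(im@S)]
  Slim <- if (dilute) im@S - Matrix::Diagonal(x = eps) %*% B else im@S
  cc <- .objectiveVector(im)
  ub <- pmin(im@reactions$ub, vMax)
  lb <- im@reactions$lb   # >= 0; usually all zero

  sol <- .solveLP(obj = cc, Aeq = as.matrix(Slim),
                  beq = rep(0, nrow(Slim)), lb = lb, ub = ub,
                  maximize = TRUE)
  if (sol$status == "error")
    stop("LP solver failed after the full fallback chain")
  if (sol$status == "infeasible") {
    v <- stats::setNames(rep(0, nrow(im@reactions)), im@reactions$id)
    return(methods::new("FluxSolution",
                        fluxes = mergeFluxes(im, v), objective = 0,
                        status = "infeasible",
                        dilution = stats::setNames(rep(0, nrow(im@S)),
                                                   rownames(im@S)),
                        method = if (dilute) "limed" else "fba"))
  }
  v <- stats::setNames(sol$x, im@reactions$id)
  b <- if (dilute) as.numeric(Matrix::Diagonal(x = eps) %*% B %*% sol$x)
       else rep(0, nrow(im@S))
  methods::new("FluxSolution", fluxes = mergeFluxes(im, v),
               objective = sol$objective, status = "optimal",
               dilution = stats::setNames(b, rownames(im@S)),
               method = if (dilute) "limed" else "fba")
}

#' Flux balance analysis with linear metabolite dilution (limed-FBA)
#'
#' Solves \eqn{\max c^T v} subject to
#' \eqn{(S - \epsilon S^{binary}) v = 0}, \eqn{0 \le v \le v_{max}} on the
#' irreversible form of the model, with media-derived exchange bounds.
#' Every metabolite participating in active reactions must be net-produced
#' at the small \eqn{\epsilon}-scaled rate, modeling growth-associated
#' dilution. In contrast to plain FBA this disallows metabolic cycles that
#' lack an input flux, so enzymes feeding such cycles are correctly
#' predicted essential.
#'
#' @param model a [MetabolicModel-class].
#' @param media optional [Media-class]; when NULL the model's current
#'   exchange bounds are used as-is.
#' @param spec a [DilutionSpec-class]; computed from the model by default.
#' @param vMax global flux cap (defaults to the spec's).
#' @return a [FluxSolution-class]; infeasibility yields status
#'   \code{"infeasible"} and objective 0 (no growth).
#' @seealso [fba()] for the undiluted baseline, [dilutionSpec()].
#' @export
limedFBA <- function(model, media = NULL, spec = NULL, vMax = NULL) {
  .growthLP(model, media, spec, dilute = TRUE, vMax = vMax)
}

#' Classical flux balance analysis
#'
#' Solves \eqn{\max c^T v} subject to \eqn{S v = 0},
#' \eqn{lb \le v \le ub}. Serves as the undiluted baseline against
#' [limedFBA()].
#'
#' @inheritParams limedFBA
#' @return a [FluxSolution-class].
#' @export
fba <- function(model, media = NULL, vMax = .DEFAULT_VMAX) {
  spec <- dilutionSpec(model, vMax = vMax)
  .growthLP(model, media, spec, dilute = FALSE, vMax = vMax)
}
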