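#' @include AllClasses.R
#' @importFrom S4Vectors DataFrame
#' @importFrom IRanges CharacterList
#' @importFrom Matrix sparseMatrix Matrix
NULL

.DEFAULT_VMAX <- 1000

## Parse one side of a reaction equation: "2 A[c] + B[c]" ->
## named coefficient vector. Empty side -> empty vector.
.parseSide <- function(side) {
  side <- trimws(side)
  if (!nzchar(side)) return(numeric())
  terms <- strsplit(side, "\\s*\\+\\s*")[[1]]
  out <- numeric()
  for (tm in terms) {
    tm <- trimws(tm)
    m <- regmatches(tm, regexec("^([0-9]*\\.?[0-9]+)\\s+(.*)$", tm))[[1]]
    if (length(m) == 3L) {
      coef <- as.numeric(m[2]); met <- m[3]
    } else {
      coef <- 1; met <- tm
    }
    out[met] <- (if (met %in% names(out)) out[[met]] else 0) + coef
  }
  out
}

## "2 A[c] + B[c] -> C[c]" -> list(stoich = named vector, reversible = flag)
.parseEquation <- function(eq) {
  arrow <- if (grepl("<->", eq, fixed = TRUE)) "<->" else
           if (grepl("->", eq, fixed = TRUE)) "->" else
           stop("equation lacks an arrow ('->' or '<->'): ", eq)
  parts <- strsplit(eq, arrow, fixed = TRUE)[[1]]
  if (length(parts) == 1L) parts <- c(parts, "")
  lhs <- .parseSide(parts[1])
  rhs <- .parseSide(parts[2])
  mets <- union(names(lhs), names(rhs))
  st <- stats::setNames(numeric(length(mets)), mets)
  st[names(lhs)] <- st[names(lhs)] - lhs
  st[names(rhs)] <- st[names(rhs)] + rhs
  st <- st[st != 0]
  list(stoich = st, reversible = arrow == "<->")
}

.metCompartment <- function(ids) {
  m <- regmatches(ids, regexec("^(.*)\\[([^][]+)\\]$", ids))
  species <- vapply(seq_along(ids), function(i)
    if (length(m[[i]]) == 3L) m[[i]][2] else ids[i], character(1))
  comp <- vapply(seq_along(ids), function(i)
    if (length(m[[i]]) == 3L) m[[i]][3] else "c", character(1))
  list(species = species, compartment = comp)
}

.emptyReactionDF <- function() {
  DataFrame(id = character(), name = character(),
            lb = numeric(), ub = numeric(), gpr = character(),
            pathways = CharacterList(), isExchange = logical(),
            curated = logical(), pBiochem = numeric(),
            pThermo = numeric(), pathwaySupport = numeric())
}

.emptyMetaboliteDF <- function() {
  DataFrame(id = character(), name = character(), compartment = character(),
            species = character(), formula = character(), charge = integer())
}

#' Build a metabolic model from reaction equations
#'
#' The user-facing constructor. Reactions are given as equation strings in
#' the usual biochemical notation, e.g. \code{"2 A[c] + B[c] -> C[c]"};
#' \code{"<->"} marks a reversible reaction (default bounds
#' \code{[-vMax, vMax]}), \code{"->"} an irreversible one
#' (\code{[0, vMax]}). A one-sided equation such as \code{"A[e] <->"}
#' defines a boundary (exchange) reaction. Compartments are tagged in
#' square brackets on the metabolite id (\code{"e"} = extracellular); the
#' part before the bracket is the chemical species, used to recognise
#' transport without chemical change.
#'
#' @param reactions data.frame with column \code{equation} and optional
#'   columns \code{id}, \code{name}, \code{lb}, \code{ub}, \code{gpr},
#'   \code{pathways} (";"-separated), \code{curated}, \code{pBiochem},
#'   \code{pThermo}, \code{pathwaySupport}.
#' @param objective id of the biomass reaction.
#' @param genes optional extra gene ids beyond those referenced by GPRs.
#' @param vMax default flux cap for unspecified bounds.
#' @param metaboliteData optional data.frame with columns \code{id} and any
#'   of \code{name}, \code{formula}, \code{charge} to annotate metabolites.
#' @return a validated [MetabolicModel-class].
#' @examples
#' m <- buildModel(
#'   data.frame(id = c("EX_a", "T_a", "R1", "BIO"),
#'              equation = c("A[e] <->", "A[e] -> A[c]",
#'                           "A[c] -> B[c]", "B[c] ->"),
#'              gpr = c("", "", "g1", "")),
#'   objective = "BIO")
#' m
#' @export
buildModel <- function(reactions, objective, genes = character(),
                       vMax = .DEFAULT_VMAX, metaboliteData = NULL) {
  stopifnot(is.data.frame(reactions), "equation" %in% colnames(reactions),
            nrow(reactions) > 0)
  n <- nrow(reactions)
  getcol <- function(col, default) {
    if (col %in% colnames(reactions)) reactions[[col]]
    else rep_len(default, n)
  }
  ids <- as.character(getcol("id", NA))
  if (anyNA(ids)) ids <- paste0("R", seq_len(n))

  parsed <- lapply(reactions$equation, .parseEquation)
  lb <- suppressWarnings(as.numeric(getcol("lb", NA)))
  ub <- suppressWarnings(as.numeric(getcol("ub", NA)))
  revs <- vapply(parsed, `[[`, logical(1), "reversible")
  lb[is.na(lb)] <- ifelse(revs[is.na(lb)], -vMax, 0)
  ub[is.na(ub)] <- vMax

  metIds <- unique(unlist(lapply(parsed, function(p) names(p$stoich))))
  triplets <- do.call(rbind, lapply(seq_len(n), function(j) {
    st <- parsed[[j]]$stoich
    if (length(st) == 0) return(NULL)
    cbind(i = match(names(st), metIds), j = j, x = unname(st))
  }))
  S <- sparseMatrix(i = triplets[, "i"], j = triplets[, "j"],
                    x = triplets[, "x"], dims = c(length(metIds), n),
                    dimnames = list(metIds, ids))
  S <- methods::as(methods::as(S, "CsparseMatrix"), "generalMatrix")

  cc <- .metCompartment(metIds)
  met <- DataFrame(id = metIds, name = cc$species,
                   compartment = cc$compartment, species = cc$species,
                   formula = NA_character_, charge = NA_integer_,
                   row.names = metIds)
  if (!is.null(metaboliteData)) {
    k <- match(metIds, metaboliteData$id)
    for (col in intersect(c("name", "formula", "charge"),
                          colnames(metaboliteData))) {
      hit <- !is.na(k)
      met[[col]][hit] <- metaboliteData[[col]][k[hit]]
    }
  }

  pw <- getcol("pathways", "")
  pw[is.na(pw)] <- ""
  pwList <- CharacterList(lapply(strsplit(pw, ";"), function(x)
    trimws(x[nzchar(trimws(x))])))
  gpr <- as.character(getcol("gpr", ""))
  gpr[is.na(gpr)] <- ""

  rxn <- DataFrame(
    id = ids,
    name = as.character(getcol("name", ids)),
    lb = lb, ub = ub, gpr = gpr,
    pathways = pwList,
    isExchange = Matrix::colSums(S != 0) == 1L,
    curated = as.logical(getcol("curated", FALSE)),
    pBiochem = suppressWarnings(as.numeric(getcol("pBiochem", NA))),
    pThermo = suppressWarnings(as.numeric(getcol("pThermo", NA))),
    pathwaySupport = suppressWarnings(as.numeric(getcol("pathwaySupport", NA))),
    row.names = ids)
  rxn$name[is.na(rxn$name)] <- ids[is.na(rxn$name)]
  rxn$curated[is.na(rxn$curated)] <- FALSE

  allGenes <- union(genes,
                    unique(unlist(lapply(gpr, gprGenes), use.names = FALSE)))
  obj <- methods::new("MetabolicModel", S = S, metabolites = met,
                      reactions = rxn, objective = objective,
                      genes = allGenes)
  validObject(obj)
  obj
}

#' Add reactions to a model
#'
#' Merges the reactions (and any new metabolites) of \code{extra} into
#' \code{model}. Reaction ids must not collide. Used by the gap-filling
#' machinery to graft candidate database reactions onto a model.
#'
#' @param model a [MetabolicModel-class].
#' @param extra a [MetabolicModel-class] whose reactions are added, or a
#'   data.frame accepted by [buildModel()].
#' @param only optional character vector restricting which reactions of
#'   \code{extra} are added.
#' @return the merged [MetabolicModel-class].
#' @export
addReactions <- function(model, extra, only = NULL) {
  if (is.data.frame(extra))
    extra <- buildModel(extra, objective = extra$id[1])
  if (!is.null(only))
    extra <- removeReactions(extra, setdiff(extra@reactions$id, only),
                             dropOrphans = TRUE, allowObjective = TRUE)
  dup <- intersect(model@reactions$id, extra@reactions$id)
  if (length(dup) > 0)
    stop("reaction ids already present in the model: ",
         paste(dup, collapse = ", "))
  if (nrow(extra@reactions) == 0) return(model)

  newMets <- setdiff(extra@metabolites$id, model@metabolites$id)
  met <- rbind(model@metabolites, extra@metabolites[newMets, ])
  allMet <- met$id
  pad <- function(S, who) {
    miss <- setdiff(allMet, rownames(S))
    if (length(miss) > 0) {
      Z <- Matrix(0, length(miss), ncol(S), sparse = TRUE,
                  dimnames = list(miss, colnames(S)))
      S <- rbind(S, Z)
    }
    S[allMet, , drop = FALSE]
  }
  S <- cbind(pad(model@S), pad(extra@S))
  S <- methods::as(methods::as(S, "CsparseMatrix"), "generalMatrix")
  rxn <- rbind(model@reactions, extra@reactions)
  out <- methods::new("MetabolicModel", S = S, metabolites = met,
                      reactions = rxn, objective = model@objective,
                      genes = union(model@genes, extra@genes))
  validObject(out)
  out
}

#' Remove reactions from a model
#'
#' @param model a [MetabolicModel-class].
#' @param ids reaction ids to remove.
#' @param dropOrphans also remove metabolites left without any reaction.
#' @param allowObjective permit removal of the biomass reaction (used
#'   internally when subsetting reaction databases).
#' @return the reduced [MetabolicModel-class].
#' @export
removeReactions <- function(model, ids, dropOrphans = TRUE,
                            allowObjective = FALSE) {
  ids <- intersect(ids, model@reactions$id)
  if (!allowObjective && model@objective %in% ids)
    stop("refusing to remove the biomass reaction '", model@objective, "'")
  keep <- setdiff(model@reactions$id, ids)
  S <- model@S[, keep, drop = FALSE]
  rxn <- model@reactions[keep, ]
  met <- model@metabolites
  if (dropOrphans && nrow(met) > 0) {
    used <- Matrix::rowSums(S != 0) > 0
    S <- S[used, , drop = FALSE]
    met <- met[used, ]
  }
  obj <- methods::new("MetabolicModel", S = S, metabolites = met,
                      reactions = rxn,
                      objective = if (allowObjective && !(model@objective %in% keep))
                        rxn$id[1] else model@objective,
                      genes = model@genes)
  ## skip validity when the caller subsets a reaction database to nothing
  if (nrow(rxn) > 0) validObject(obj)
  obj
}

#' Add a sink (accumulation allowance) for a metabolite
#'
#' Adds an irreversible drain for an intracellular metabolite, allowing it
#' to accumulate in silico. This reproduces the relaxation used when a
#' mutant is known to accumulate a compound (e.g. AICAR) that steady-state
#' analysis would otherwise force to be consumed.
#'
#' @param model a [MetabolicModel-class].
#' @param metabolite metabolite id to drain.
#' @param cap maximum accumulation rate (default unbounded up to v_max).
#' @return the extended [MetabolicModel-class].
#' @export
addSink <- function(model, metabolite, cap = .DEFAULT_VMAX) {
  if (!(metabolite %in% model@metabolites$id))
    stop("unknown metabolite: ", metabolite)
  sid <- paste0("SINK_", gsub("[^A-Za-z0-9_]", "_", metabolite))
  extra <- buildModel(
    data.frame(id = c(sid, "..dummy.."),
               equation = c(paste0(metabolite, " ->"), "..x[c] ->"),
               ub = c(cap, 1)),
    objective = "..dummy..")
  extra <- removeReactions(extra, "..dummy..", allowObjective = TRUE)
  addReactions(model, extra)
}
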