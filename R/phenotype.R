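#' @include AllClasses.R limedFBA.R
NULL

.VIABILITY_THRESHOLD <- 0.02   # biomass flux above which a strain is viable

#' Simulate one growth phenotype
#'
#' Applies a gene knockout and a medium, runs limed-FBA (or plain FBA) and
#' calls viability: a strain is viable when its biomass flux exceeds the
#' threshold (0.02 by default).
#'
#' @param model a [MetabolicModel-class].
#' @param media a [Media-class].
#' @param genes knocked-out genes (may be empty for wild type).
#' @param method \code{"limed"} or \code{"fba"}.
#' @param threshold viability threshold on biomass flux.
#' @param spec optional [DilutionSpec-class] (reused across screens).
#' @return list with \code{biomass}, \code{viable}, \code{threshold},
#'   \code{genes}, \code{media}.
#' @export
growthPhenotype <- function(model, media, genes = character(),
                            method = c("limed", "fba"),
                            threshold = .VIABILITY_THRESHOLD, spec = NULL) {
  method <- match.arg(method)
  ko <- applyKnockout(model, genes)
  sol <- if (method == "limed") limedFBA(ko, media, spec)
         else fba(ko, media)
  list(biomass = sol@objective, viable = sol@objective > threshold,
       threshold = threshold, genes = genes, media = media@name)
}

#' Summarise a viability screen against experimental truth
#'
#' Sensitivity is the proportion of experimentally viable mutants predicted
#' viable in silico; specificity the proportion of experimentally inviable
#' mutants predicted inviable.
#'
#' @param predictedViable,observedViable parallel logical vectors.
#' @return a [ScreenSummary-class].
#' @export
screenSummary <- function(predictedViable, observedViable) {
  stopifnot(length(predictedViable) == length(observedViable))
  tp <- sum(predictedViable & observedViable)
  tn <- sum(!predictedViable & !observedViable)
  fp <- sum(predictedViable & !observedViable)
  fn <- sum(!predictedViable & observedViable)
  methods::new("ScreenSummary",
               tp = as.integer(tp), tn = as.integer(tn),
               fp = as.integer(fp), fn = as.integer(fn),
               sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
               specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

#' Gene essentiality screen
#'
#' Simulates the knockout of each gene with one limed-FBA solve and calls
#' viability at the biomass-flux threshold. Knockouts that disable the same
#' reaction set share one solve. When an experimental truth table is given,
#' genes absent from the model are skipped with a warning and a
#' [ScreenSummary-class] is attached as metadata.
#'
#' @param model a [MetabolicModel-class].
#' @param media a [Media-class].
#' @param genes genes to screen; all model genes by default.
#' @param truth optional experimental truth: a named logical vector
#'   (TRUE = viable) or a data.frame with columns \code{gene},
#'   \code{viable}.
#' @param method \code{"limed"} or \code{"fba"}.
#' @param threshold viability threshold.
#' @param spec optional [DilutionSpec-class].
#' @return \code{DataFrame} with columns \code{gene}, \code{biomass},
#'   \code{viable}, \code{essential} (and \code{observed} when truth is
#'   given); \code{S4Vectors::metadata()} carries the summary under
#'   \code{"summary"}.
#' @export
predictEssentiality <- function(model, media, genes = NULL, truth = NULL,
                                method = c("limed", "fba"),
                                threshold = .VIABILITY_THRESHOLD,
                                spec = NULL) {
  method <- match.arg(method)
  if (is.null(spec) && method == "limed") spec <- dilutionSpec(model)
  if (is.null(genes)) genes <- sort(model@genes)
  if (is.data.frame(truth))
    truth <- stats::setNames(as.logical(truth$viable), truth$gene)
  if (!is.null(truth)) {
    absent <- setdiff(names(truth), model@genes)
    if (length(absent) > 0)
      warning(length(absent), " truth genes absent from the model, skipped: ",
              paste(utils::head(absent, 5), collapse = ", "),
              if (length(absent) > 5) ", ...")
    genes <- union(genes, intersect(names(truth), model@genes))
  }

  prep <- applyMedia(model, media)
  solveFor <- function(off) {
    m2 <- prep
    if (length(off) > 0) {
      j <- match(off, m2@reactions$id)
      m2@reactions$lb[j] <- 0
      m2@reactions$ub[j] <- 0
    }
    if (method == "limed") limedFBA(m2, spec = spec)@objective
    else fba(m2)@objective
  }
  cache <- new.env(parent = emptyenv())
  biomass <- vapply(genes, function(g) {
    off <- sort(reactionsDisabledBy(model, g))
    key <- paste0("k:", paste(off, collapse = "\r"))
    if (is.null(cache[[key]])) cache[[key]] <- solveFor(off)
    cache[[key]]
  }, numeric(1))

  out <- DataFrame(gene = genes, biomass = unname(biomass),
                   viable = unname(biomass) > threshold,
                   essential = unname(biomass) <= threshold,
                   row.names = genes)
  if (!is.null(truth)) {
    out$observed <- unname(truth[genes])
    have <- !is.na(out$observed)
    S4Vectors::metadata(out)$summary <-
      screenSummary(out$viable[have], out$observed[have])
  }
  out
}

#' Nutrient rescue of an inviable mutant
#'
#' Takes a mutant predicted inviable on the base medium, supplements the
#' medium with candidate nutrients (capped at the supplement uptake rate),
#' and applies limed-FBA to each supplemented condition. A combination
#' containing a supplement that already rescues on its own is reported as
#' implied without re-simulation: the multi-substrate case adds no
#' information beyond the single-substrate one.
#'
#' @param model a [MetabolicModel-class].
#' @param media the base (minimal) medium; the mutant must be inviable on
#'   it, otherwise rescue is undefined and an error is raised.
#' @param gene knocked-out gene (or several, e.g. a synthetic-lethal pair).
#' @param supplements character vector of single supplements and/or a list
#'   mixing singles with multi-nutrient combinations.
#' @param cap uptake cap for each supplement (mmol/gDW/h).
#' @param threshold viability threshold.
#' @param spec optional [DilutionSpec-class].
#' @return \code{DataFrame} with columns \code{supplement} (";"-joined),
#'   \code{biomass}, \code{rescued}, \code{implied}.
#' @export
predictRescue <- function(model, media, gene, supplements,
                          cap = .SUPPLEMENT_CAP,
                          threshold = .VIABILITY_THRESHOLD, spec = NULL) {
  if (is.null(spec)) spec <- dilutionSpec(model)
  base <- growthPhenotype(model, media, gene, threshold = threshold,
                          spec = spec)
  if (base$viable)
    stop("gene(s) [", paste(gene, collapse = ", "),
         "] are viable on the base media (biomass ",
         format(base$biomass, digits = 4), "); rescue is undefined")
  if (!is.list(supplements)) supplements <- as.list(supplements)
  sets <- lapply(supplements, as.character)
  labels <- vapply(sets, paste, character(1), collapse = ";")

  sizes <- lengths(sets)
  biomass <- rep(NA_real_, length(sets))
  rescued <- logical(length(sets))
  implied <- logical(length(sets))
  rescuingSingles <- character()
  for (i in order(sizes)) {
    if (sizes[i] > 1 && any(sets[[i]] %in% rescuingSingles)) {
      rescued[i] <- TRUE
      implied[i] <- TRUE
      next
    }
    m2 <- buildMedia(media, sets[[i]], cap = cap, model = model)
    res <- growthPhenotype(model, m2, gene, threshold = threshold,
                           spec = spec)
    biomass[i] <- res$biomass
    rescued[i] <- res$viable
    if (res$viable && sizes[i] == 1)
      rescuingSingles <- c(rescuingSingles, sets[[i]])
  }
  DataFrame(supplement = labels, biomass = biomass, rescued = rescued,
            implied = implied)
}

#' Genome-wide synthetic-lethal screen
#'
#' Tests all unordered pairs of individually viable genes for synthetic
#' lethality: both single knockouts grow, the double knockout does not.
#' A pair whose combined disabled-reaction set equals one single knockout's
#' adds no constraint beyond that single, so its solve is skipped (the LP
#' would be identical); \code{exhaustive = TRUE} disables the shortcut.
#' Synthetic-lethal pairs are classified mechanistically by
#' [classifySLPair()].
#'
#' @param model a [MetabolicModel-class].
#' @param media a [Media-class].
#' @param genes genes to screen; by default, all model genes individually
#'   viable on the medium. Individually inviable genes in an explicit list
#'   are dropped with a warning.
#' @param threshold viability threshold.
#' @param exhaustive solve every pair even when the shortcut applies.
#' @param spec optional [DilutionSpec-class].
#' @return \code{DataFrame} of all tested pairs with columns \code{gene1},
#'   \code{gene2}, \code{biomass}, \code{syntheticLethal},
#'   \code{classification} (NA for viable pairs).
#' @export
syntheticLethalScreen <- function(model, media, genes = NULL,
                                  threshold = .VIABILITY_THRESHOLD,
                                  exhaustive = TRUE, spec = NULL) {
  if (is.null(spec)) spec <- dilutionSpec(model)
  singles <- predictEssentiality(model, media,
                                 genes = genes %||% sort(model@genes),
                                 threshold = threshold, spec = spec)
  if (!is.null(genes)) {
    bad <- singles$gene[!singles$viable]
    if (length(bad) > 0)
      warning("dropping individually inviable genes: ",
              paste(bad, collapse = ", "))
  }
  viable <- singles$gene[singles$viable]
  if (length(viable) < 2)
    return(DataFrame(gene1 = character(), gene2 = character(),
                     biomass = numeric(), syntheticLethal = logical(),
                     classification = character()))

  prep <- applyMedia(model, media)
  solveFor <- function(off) {
    m2 <- prep
    if (length(off) > 0) {
      j <- match(off, m2@reactions$id)
      m2@reactions$lb[j] <- 0
      m2@reactions$ub[j] <- 0
    }
    limedFBA(m2, spec = spec)@objective
  }
  disabled <- lapply(stats::setNames(viable, viable),
                     function(g) sort(reactionsDisabledBy(model, g)))

  pairs <- utils::combn(sort(viable), 2)
  nres <- ncol(pairs)
  biomass <- numeric(nres)
  for (p in seq_len(nres)) {
    g1 <- pairs[1, p]; g2 <- pairs[2, p]
    ## evaluated under the joint knockout: an isozyme pair disables
    ## reactions that neither single knockout touches
    off <- sort(reactionsDisabledBy(model, c(g1, g2)))
    if (!exhaustive &&
        (identical(off, disabled[[g1]]) || identical(off, disabled[[g2]]))) {
      ## the double knockout's LP is identical to a single's
      single <- if (identical(off, disabled[[g1]])) g1 else g2
      biomass[p] <- singles[single, "biomass"]
    } else {
      biomass[p] <- solveFor(off)
    }
  }
  sl <- biomass <= threshold
  cls <- rep(NA_character_, nres)
  for (p in which(sl))
    cls[p] <- classifySLPair(model, pairs[1, p], pairs[2, p])
  DataFrame(gene1 = pairs[1, ], gene2 = pairs[2, ], biomass = biomass,
            syntheticLethal = sl, classification = cls)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mechanistic classification of a synthetic-lethal pair
#'
#' Synthetic-lethal interactions fall into three mechanistic classes:
#' \describe{
#'   \item{isozyme}{the genes encode isozymes of a common reaction — some
#'     reaction survives either single knockout but not the double;}
#'   \item{same_pathway}{the reactions unique to each gene share a pathway
#'     annotation;}
#'   \item{interacting_pathways}{otherwise — the genes act in different
#'     pathways that produce an essential metabolite through alternate
#'     routes.}
#' }
#'
#' @param model a [MetabolicModel-class].
#' @param gene1,gene2 the pair.
#' @return character(1) classification.
#' @export
classifySLPair <- function(model, gene1, gene2) {
  rxn <- model@reactions
  both <- reactionsDisabledBy(model, c(gene1, gene2))
  d1 <- reactionsDisabledBy(model, gene1)
  d2 <- reactionsDisabledBy(model, gene2)
  if (length(setdiff(both, union(d1, d2))) > 0)
    return("isozyme")
  p1 <- unique(unlist(rxn[match(d1, rxn$id), "pathways"]))
  p2 <- unique(unlist(rxn[match(d2, rxn$id), "pathways"]))
  if (length(intersect(p1, p2)) > 0) return("same_pathway")
  "interacting_pathways"
}
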