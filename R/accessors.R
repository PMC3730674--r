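#' @include AllClasses.R AllGenerics.R
NULL

#' Accessors for MetabolicModel objects
#'
#' Slot access goes through these accessors rather than \code{@}.
#' \code{bounds} returns (and \code{bounds<-} replaces) a two-column matrix
#' of flux bounds; \code{exchangeReactions} returns the ids of boundary
#' reactions (single-metabolite columns), through which all uptake and
#' secretion happens.
#'
#' @param x a [MetabolicModel-class].
#' @param value for \code{bounds<-}, a numeric matrix with columns
#'   \code{lb}, \code{ub} and one row per reaction (rownames optional).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("stoichiometry", "MetabolicModel", function(x) x@S)

#' @rdname accessors
#' @export
setMethod("metabolites", "MetabolicModel", function(x) x@metabolites)

#' @rdname accessors
#' @export
setMethod("reactions", "MetabolicModel", function(x) x@reactions)

#' @rdname accessors
#' @export
setMethod("objectiveReaction", "MetabolicModel", function(x) x@objective)

#' @rdname accessors
#' @export
setMethod("modelGenes", "MetabolicModel", function(x) x@genes)

#' @rdname accessors
#' @export
setMethod("metaboliteIds", "MetabolicModel", function(x) x@metabolites$id)

#' @rdname accessors
#' @export
setMethod("reactionIds", "MetabolicModel", function(x) x@reactions$id)

#' @rdname accessors
#' @export
setMethod("bounds", "MetabolicModel", function(x) {
  cbind(lb = x@reactions$lb, ub = x@reactions$ub)
})

#' @rdname accessors
#' @export
setReplaceMethod("bounds", "MetabolicModel", function(x, value) {
  stopifnot(is.matrix(value), ncol(value) == 2L,
            nrow(value) == nrow(x@reactions))
  x@reactions$lb <- value[, 1]
  x@reactions$ub <- value[, 2]
  validObject(x)
  x
})

#' @rdname accessors
#' @param model a [MetabolicModel-class].
#' @export
exchangeReactions <- function(model) {
  if (ncol(model@S) == 0) return(character())
  nzero <- Matrix::colSums(model@S != 0)
  model@reactions$id[nzero == 1L]
}

#' Extracellular metabolites of a model
#'
#' Metabolites whose compartment is the extracellular space (compartment
#' code \code{"e"} or a name starting with "extracellular").
#'
#' @param model a [MetabolicModel-class].
#' @return character vector of metabolite ids.
#' @export
extracellularMetabolites <- function(model) {
  comp <- model@metabolites$compartment
  model@metabolites$id[comp == "e" | startsWith(tolower(comp), "extracellular")]
}

setMethod("show", "MetabolicModel", function(object) {
  cat(class(object), "with", nrow(object@metabolites), "metabolites,",
      nrow(object@reactions), "reactions,", length(object@genes), "genes\n")
  cat("  objective:", object@objective, "\n")
  nex <- length(exchangeReactions(object))
  cat("  exchange reactions:", nex, "\n")
})

setMethod("show", "Media", function(object) {
  cat("Media", if (nzchar(object@name)) paste0("'", object@name, "'"),
      "with", length(object@uptake), "uptake caps (mmol/gDW/h)\n")
  if (length(object@uptake)) {
    u <- utils::head(object@uptake, 8)
    cat(paste0("  ", names(u), ": ", u, collapse = "\n"), "\n")
    if (length(object@uptake) > 8) cat("  ...\n")
  }
})

setMethod("show", "DilutionSpec", function(object) {
  nz <- sum(object@epsilon > 0)
  cat("DilutionSpec: d_max =", object@dMax, ", v_max =", object@vMax, "\n")
  cat("  ", nz, "diluted metabolites;", length(object@exemptMetabolites),
      "exempt metabolites;", length(object@exemptTransport),
      "exempt simple transports\n")
})

setMethod("show", "FluxSolution", function(object) {
  cat("FluxSolution (", object@method, "): status ", object@status,
      ", objective ", format(object@objective, digits = 6), "\n", sep = "")
  if (length(object@dilution))
    cat("  max realized dilution:",
        format(max(object@dilution), digits = 4), "\n")
})

setMethod("show", "PruneResult", function(object) {
  cat("PruneResult:", length(object@unblocked), "unblocked,",
      length(object@blocked), "blocked irreversible reactions\n")
  cat("  blocked at parent level:", length(object@parentBlocked), "\n")
})

setMethod("show", "ScreenSummary", function(object) {
  cat("ScreenSummary: TP", object@tp, "FN", object@fn,
      "TN", object@tn, "FP", object@fp, "\n")
  cat(sprintf("  sensitivity %.1f%%, specificity %.1f%%\n",
              100 * object@sensitivity, 100 * object@specificity))
})

setMethod("show", "Reconciliation", function(object) {
  cat("Reconciliation (", object@action, "): genes [",
      paste(object@genes, collapse = ", "), "] on ", object@media,
      ", observed ", object@observed, "\n", sep = "")
  if (!object@resolved) {
    cat("  UNRESOLVABLE\n")
  } else {
    cat("  suggestions:\n")
    s <- object@suggestions
    for (i in seq_len(nrow(s)))
      cat(sprintf("    %s %s (weight %.4g)\n", object@action,
                  s$reaction[i], s$weight[i]))
    cat("  post-change biomass:", format(object@postBiomass, digits = 5), "\n")
  }
})
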