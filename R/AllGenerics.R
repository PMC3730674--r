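#' @include AllClasses.R
NULL

#' @rdname accessors
#' @export
setGeneric("stoichiometry", function(x) standardGeneric("stoichiometry"))

#' @rdname accessors
#' @export
setGeneric("metabolites", function(x) standardGeneric("metabolites"))

#' @rdname accessors
#' @export
setGeneric("reactions", function(x) standardGeneric("reactions"))

#' @rdname accessors
#' @export
setGeneric("objectiveReaction", function(x) standardGeneric("objectiveReaction"))

#' @rdname accessors
#' @export
setGeneric("modelGenes", function(x) standardGeneric("modelGenes"))

#' @rdname accessors
#' @export
setGeneric("metaboliteIds", function(x) standardGeneric("metaboliteIds"))

#' @rdname accessors
#' @export
setGeneric("reactionIds", function(x) standardGeneric("reactionIds"))

#' @rdname accessors
#' @export
setGeneric("bounds", function(x) standardGeneric("bounds"))

#' @rdname accessors
#' @export
setGeneric("bounds<-", function(x, value) standardGeneric("bounds<-"))

#' @rdname splitReversible
#' @export
setGeneric("splitReversible", function(model) standardGeneric("splitReversible"))

#' @rdname fluxVariability
#' @export
setGeneric("fluxVariability", function(model, ...) standardGeneric("fluxVariability"))
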