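#' @include AllClasses.R
NULL

.SUPPLEMENT_CAP <- 3    # mmol/gDW/h, standard cap for supplemental nutrients

#' Construct a growth medium
#'
#' @param uptake named non-negative numeric vector: maximum uptake rate
#'   (mmol/gDW/h) per extracellular metabolite id.
#' @param name optional label.
#' @return a [Media-class].
#' @examples
#' Media(c("SUC[e]" = 1.5, "NH4[e]" = 1000), name = "minimal")
#' @export
Media <- function(uptake = numeric(), name = "") {
  obj <- methods::new("Media", name = name, uptake = uptake)
  validObject(obj)
  obj
}

#' @rdname accessors
#' @export
uptakeRates <- function(x) x@uptake

#' Supplement a medium
#'
#' Returns the base medium plus uptake for each supplement metabolite,
#' capped at \code{cap} (3 mmol/gDW/h by default, the standard allowance
#' for supplemental nutrients; primary carbon sources in minimal media are
#' instead capped at 1.5). An empty supplement list returns the base
#' unchanged.
#'
#' @param base a [Media-class].
#' @param supplements character vector of extracellular metabolite ids.
#' @param cap maximum uptake rate for each supplement.
#' @param model optional [MetabolicModel-class]; when given, supplements
#'   are checked to be extracellular metabolites of the model and an error
#'   names any unknown one.
#' @return a [Media-class].
#' @export
buildMedia <- function(base, supplements = character(),
                       cap = .SUPPLEMENT_CAP, model = NULL) {
  if (length(supplements) == 0) return(base)
  if (!is.null(model)) {
    bad <- setdiff(supplements, extracellularMetabolites(model))
    if (length(bad) > 0)
      stop("supplements are not extracellular metabolites of the model: ",
           paste(bad, collapse = ", "))
  }
  up <- base@uptake
  up[supplements] <- pmax(up[supplements], cap, na.rm = TRUE)
  Media(up, name = if (nzchar(base@name))
    paste0(base@name, " + ", paste(supplements, collapse = "+")) else
      paste(supplements, collapse = "+"))
}

#' Apply a medium to a model
#'
#' Sets the uptake bound (negative lower bound) of every exchange reaction
#' of an extracellular metabolite: metabolites named in the medium get
#' \code{lb = -cap}; all other extracellular exchanges get \code{lb = 0}
#' (no uptake). Secretion (the upper bound) is never restricted. Boundary
#' reactions of intracellular metabolites (sinks) are left untouched.
#'
#' @param model a [MetabolicModel-class].
#' @param media a [Media-class].
#' @return the model with media-derived exchange bounds.
#' @export
applyMedia <- function(model, media) {
  ex <- exchangeReactions(model)
  exMet <- vapply(ex, function(r) {
    names(which(model@S[, r] != 0))
  }, character(1))
  extra <- extracellularMetabolites(model)
  isExt <- exMet %in% extra
  exc <- ex[isExt]
  excMet <- exMet[isExt]

  missing <- setdiff(names(media@uptake), excMet)
  if (length(missing) > 0)
    stop("media metabolites without an exchange reaction in the model: ",
         paste(missing, collapse = ", "))

  j <- match(exc, model@reactions$id)
  cap <- media@uptake[excMet]
  cap[is.na(cap)] <- 0
  model@reactions$lb[j] <- -unname(cap)
  model@reactions$ub[j] <- pmax(model@reactions$ub[j], 0)
  model
}

#' Read a media table
#'
#' Reads a tab-separated table with columns \code{metabolite_id} and
#' \code{max_uptake} (mmol/gDW/h).
#'
#' @param path file path.
#' @param name optional label (defaults to the file name).
#' @return a [Media-class].
#' @export
readMedia <- function(path, name = basename(path)) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("metabolite_id", "max_uptake")
  if (!all(need %in% colnames(tab)))
    stop("media table must have columns: ", paste(need, collapse = ", "))
  Media(stats::setNames(as.numeric(tab$max_uptake), tab$metabolite_id),
        name = name)
}
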