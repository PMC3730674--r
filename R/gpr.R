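## Gene-protein-reaction (GPR) logic.
##
## Rules are parenthesised infix boolean expressions over gene ids with
## case-insensitive `and` (enzyme complex: every subunit required) and `or`
## (isozymes: any one suffices), following the COBRA GENE_ASSOCIATION
## convention. `and` binds tighter than `or`. The empty rule is always true
## (orphan or spontaneous reaction).

.gprTokenize <- function(rule) {
  rule <- gsub("([()])", " \\1 ", rule)
  toks <- strsplit(trimws(rule), "\\s+")[[1]]
  toks[nzchar(toks)]
}

#' Parse a gene-protein-reaction rule
#'
#' Parses a COBRA-style boolean gene association such as
#' \code{"g1 and (g2 or g3)"} into an expression tree. \code{and}/\code{or}
#' are case-insensitive; \code{and} has higher precedence. The empty string
#' parses to \code{NULL}, the always-true rule of a reaction that is not
#' gene-dependent.
#'
#' @param rule character(1) rule text.
#' @return \code{NULL}, a gene id (leaf), or a list with elements \code{op}
#'   (\code{"and"}/\code{"or"}) and \code{args} (subtrees).
#' @examples
#' parseGpr("gln-1 and gln-2")
#' parseGpr("")
#' @export
parseGpr <- function(rule) {
  if (is.null(rule) || is.na(rule) || !nzchar(trimws(rule))) return(NULL)
  toks <- .gprTokenize(rule)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  advance <- function() { pos <<- pos + 1L }
  isOp <- function(tok, op) !is.na(tok) && tolower(tok) == op

  parsePrimary <- function() {
    tok <- peek()
    if (is.na(tok)) stop("unexpected end of GPR rule: ", rule)
    if (tok == "(") {
      advance()
      node <- parseOr()
      if (!identical(peek(), ")")) stop("unbalanced parentheses in GPR rule: ", rule)
      advance()
      return(node)
    }
    if (tok == ")" || isOp(tok, "and") || isOp(tok, "or"))
      stop("malformed GPR rule near '", tok, "': ", rule)
    advance()
    tok
  }
  parseAnd <- function() {
    args <- list(parsePrimary())
    while (isOp(peek(), "and")) {
      advance()
      args <- c(args, list(parsePrimary()))
    }
    if (length(args) == 1L) args[[1]] else list(op = "and", args = args)
  }
  parseOr <- function() {
    args <- list(parseAnd())
    while (isOp(peek(), "or")) {
      advance()
      args <- c(args, list(parseAnd()))
    }
    if (length(args) == 1L) args[[1]] else list(op = "or", args = args)
  }

  node <- parseOr()
  if (!is.na(peek())) stop("trailing tokens in GPR rule: ", rule)
  node
}

#' Genes referenced by a GPR rule
#'
#' @param rule rule text or a tree from [parseGpr()].
#' @return character vector of gene ids (possibly empty).
#' @export
gprGenes <- function(rule) {
  if (is.character(rule) && length(rule) == 1L && (is.na(rule) || !nzchar(trimws(rule))))
    return(character())
  tree <- if (is.character(rule) && length(rule) == 1L &&
              grepl("[ ()]", rule)) parseGpr(rule) else rule
  if (is.character(tree) && length(tree) == 1L) return(tree)
  if (is.null(tree)) return(character())
  unique(unlist(lapply(tree$args, gprGenes), use.names = FALSE))
}

#' Evaluate a GPR rule under a gene knockout
#'
#' Knocked-out genes evaluate false, all other genes true; genes absent from
#' the model are treated as present (an unknown leaf cannot block a
#' reaction). Returns whether the reaction retains enzymatic support.
#'
#' @param rule rule text or parsed tree.
#' @param knockedOut character vector of knocked-out gene ids.
#' @return logical(1).
#' @examples
#' evaluateGpr("g1 and g2", "g1")  # complex loses a subunit -> FALSE
#' evaluateGpr("g1 or g2", "g1")   # isozyme survives        -> TRUE
#' evaluateGpr("", "g1")           # orphan reaction         -> TRUE
#' @export
evaluateGpr <- function(rule, knockedOut = character()) {
  tree <- if (is.character(rule) && length(rule) == 1L) parseGpr(rule) else rule
  evalNode <- function(node) {
    if (is.null(node)) return(TRUE)
    if (is.character(node)) return(!(node %in% knockedOut))
    vals <- vapply(node$args, evalNode, logical(1))
    if (node$op == "and") all(vals) else any(vals)
  }
  evalNode(tree)
}

#' Reactions disabled by a gene knockout
#'
#' Evaluates every reaction's GPR with the given genes knocked out and
#' returns the ids of reactions that lose enzymatic support.
#'
#' @param model a [MetabolicModel-class].
#' @param genes character vector of knocked-out gene ids.
#' @return character vector of reaction ids.
#' @export
reactionsDisabledBy <- function(model, genes) {
  rxn <- model@reactions
  if (nrow(rxn) == 0 || length(genes) == 0) return(character())
  ## only rules mentioning a knocked-out gene can change value
  touch <- vapply(rxn$gpr, function(g) any(gprGenes(g) %in% genes), logical(1))
  cand <- which(touch)
  off <- cand[!vapply(rxn$gpr[cand], evaluateGpr, logical(1),
                      knockedOut = genes)]
  rxn$id[off]
}

#' Simulate a gene knockout
#'
#' Returns a copy of the model in which every reaction whose GPR evaluates
#' false under the knockout has both bounds set to zero. Bounds are zeroed
#' rather than rows/columns deleted so that indices stay stable across
#' large screens. Genes not present in the model are reported (message) and
#' ignored: no reaction can depend on them.
#'
#' @param model a [MetabolicModel-class].
#' @param genes character vector of knocked-out gene ids.
#' @return a [MetabolicModel-class] with the affected reactions closed.
#' @export
applyKnockout <- function(model, genes) {
  genes <- unique(genes)
  unknown <- setdiff(genes, model@genes)
  if (length(unknown) > 0)
    message("ignoring genes absent from the model: ",
            paste(unknown, collapse = ", "))
  off <- reactionsDisabledBy(model, genes)
  if (length(off) > 0) {
    j <- match(off, model@reactions$id)
    model@reactions$lb[j] <- 0
    model@reactions$ub[j] <- 0
  }
  model
}
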