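#' @include AllClasses.R
#' @import xml2
NULL

## COBRA-dialect SBML input/output.
##
## Identifiers: SBML SIds admit only letters, digits and underscore, and
## may not start with a digit. Database identifiers such as "CPD[c]" or
## "1diacyl" are made SBML-safe by substituting each disallowed character
## with its ASCII decimal value demarcated by double underscores
## ("[" -> "__91__") and prefixing digit-initial ids with one underscore.
## To keep the codec invertible even for ids that already contain a
## "__<digits>__" substring or start with "_<digit>" (which would collide
## with the substitution tokens), encode() first escapes the underscores of
## such substrings as "__95__".

.SID_OK <- "[A-Za-z0-9_]"

#' Encode an identifier into SBML-safe form
#'
#' @param raw non-empty printable-ASCII identifier.
#' @return SBML-safe identifier; [decodeSbmlId()] inverts it.
#' @examples
#' encodeSbmlId("CPD[c]")   # "CPD__91__c__93__"
#' encodeSbmlId("1diacyl")  # "_1diacyl"
#' encodeSbmlId("abc_def")  # unchanged
#' @export
encodeSbmlId <- function(raw) {
  if (length(raw) != 1L || is.na(raw) || !nzchar(raw))
    stop("identifier must be a non-empty string")
  ## escape pre-existing token look-alikes so decoding stays unambiguous:
  ## single left-to-right pass over the matches of "__<digits>__"
  esc <- function(s) gsub("_", "__95__", s, fixed = TRUE)
  mm <- gregexpr("__[0-9]+__", raw)[[1]]
  if (mm[1] != -1) {
    lens <- attr(mm, "match.length")
    pieces <- character(); last <- 1L
    for (k in seq_along(mm)) {
      pieces <- c(pieces, substr(raw, last, mm[k] - 1),
                  esc(substr(raw, mm[k], mm[k] + lens[k] - 1)))
      last <- mm[k] + lens[k]
    }
    raw <- paste0(paste(pieces, collapse = ""),
                  substr(raw, last, nchar(raw)))
  }
  if (grepl("^_[0-9]", raw))
    raw <- paste0("__95__", substr(raw, 2, nchar(raw)))

  chars <- strsplit(raw, "")[[1]]
  bad <- !grepl(.SID_OK, chars)
  chars[bad] <- vapply(chars[bad], function(ch)
    sprintf("__%d__", utf8ToInt(ch)), character(1))
  out <- paste(chars, collapse = "")
  if (grepl("^[0-9]", out)) out <- paste0("_", out)
  out
}

#' Decode an SBML-safe identifier
#'
#' Inverse of [encodeSbmlId()]. A token of the form
#' \code{__<non-numeric>__} is rejected with an error naming it.
#'
#' @param sid identifier produced by [encodeSbmlId()] (or already legal).
#' @return the original identifier.
#' @examples
#' decodeSbmlId("CPD__91__c__93__")  # "CPD[c]"
#' decodeSbmlId("_1diacyl")          # "1diacyl"
#' @export
decodeSbmlId <- function(sid) {
  if (length(sid) != 1L || is.na(sid) || !nzchar(sid))
    stop("identifier must be a non-empty string")
  if (grepl("^_[0-9]", sid)) sid <- substr(sid, 2, nchar(sid))
  out <- character()
  rest <- sid
  ## left-to-right scan: at each "__", the content up to the closing "__"
  ## is either all digits (a substitution token), digit-free (literal
  ## underscores in a legal id), or a corrupted token -> error naming it
  repeat {
    m <- regexpr("__[^_]+__", rest)
    if (m == -1) { out <- c(out, rest); break }
    len <- attr(m, "match.length")
    tok <- substr(rest, m + 2, m + len - 3)
    if (grepl("^[0-9]+$", tok)) {
      out <- c(out, substr(rest, 1, m - 1), intToUtf8(as.integer(tok)))
      rest <- substr(rest, m + len, nchar(rest))
    } else if (grepl("[0-9]", tok)) {
      stop("malformed substitution token '__", tok, "__' in identifier: ",
           sid)
    } else {
      ## digit-free "__x__" is literal text; emit up to and including the
      ## first "__" and continue scanning after it
      out <- c(out, substr(rest, 1, m + 1))
      rest <- substr(rest, m + 2, nchar(rest))
    }
  }
  paste(out, collapse = "")
}

.noteText <- function(node, key) {
  ps <- xml_find_all(node, ".//*[local-name()='p' or local-name()='html:p']")
  txt <- xml_text(ps)
  hit <- grep(paste0("^\\s*", key, "\\s*:"), txt, value = TRUE)
  if (length(hit) == 0) return(NA_character_)
  trimws(sub(paste0("^\\s*", key, "\\s*:"), "", hit[1]))
}

#' Read a COBRA-dialect SBML model
#'
#' Reads SBML (Level 2 COBRA dialect; SBML 3 \code{fbc} bound and objective
#' attributes are also recognised) into a [MetabolicModel-class]. GPRs come
#' from \code{GENE_ASSOCIATION} notes, pathways from \code{PATHWAYS} (or
#' \code{SUBSYSTEM}) notes, bounds from kinetic-law parameters
#' (\code{LOWER_BOUND}/\code{UPPER_BOUND}) or fbc attributes, and the
#' objective from \code{OBJECTIVE_COEFFICIENT} or the fbc objective list.
#' All identifiers are passed through [decodeSbmlId()]. Exchange reactions
#' are single-metabolite boundary reactions. An unparseable GPR produces a
#' warning and an empty (always-true) rule.
#'
#' @param path SBML file path.
#' @return a [MetabolicModel-class].
#' @export
readCobraSbml <- function(path) {
  doc <- read_xml(path)
  mdl <- xml_find_first(doc, ".//*[local-name()='model']")

  spNodes <- xml_find_all(mdl,
    ".//*[local-name()='listOfSpecies']/*[local-name()='species']")
  sid <- xml_attr(spNodes, "id")
  metIds <- unname(vapply(sid, decodeSbmlId, character(1)))
  boundary <- xml_attr(spNodes, "boundaryCondition")
  keep <- is.na(boundary) | boundary != "true"
  chargeAttr <- suppressWarnings(as.integer(xml_attr(spNodes, "charge")))
  formula <- vapply(spNodes, .noteText, character(1), key = "FORMULA")
  chargeNote <- suppressWarnings(as.integer(
    vapply(spNodes, .noteText, character(1), key = "CHARGE")))
  charge <- ifelse(is.na(chargeAttr), chargeNote, chargeAttr)
  cc <- .metCompartment(metIds)
  met <- DataFrame(id = metIds,
                   name = xml_attr(spNodes, "name"),
                   compartment = xml_attr(spNodes, "compartment"),
                   species = cc$species,
                   formula = formula, charge = charge,
                   row.names = metIds)[keep, ]
  met$name[is.na(met$name)] <- met$species[is.na(met$name)]
  ## trust the compartment tag in the id when present, else the attribute
  tagged <- grepl("\\[[^][]+\\]$", met$id)
  met$compartment[tagged] <- cc$compartment[keep][tagged]

  ## global parameters (used by fbc bound references)
  parNodes <- xml_find_all(mdl,
    ".//*[local-name()='listOfParameters']/*[local-name()='parameter']")
  pars <- stats::setNames(as.numeric(xml_attr(parNodes, "value")),
                          xml_attr(parNodes, "id"))

  rxNodes <- xml_find_all(mdl,
    ".//*[local-name()='listOfReactions']/*[local-name()='reaction']")
  if (length(rxNodes) == 0) stop("SBML model contains no reactions: ", path)
  nrx <- length(rxNodes)
  rid <- unname(vapply(xml_attr(rxNodes, "id"), decodeSbmlId,
                        character(1)))

  trip <- list(); lb <- numeric(nrx); ub <- numeric(nrx)
  objc <- numeric(nrx); gpr <- character(nrx); pw <- character(nrx)
  curated <- logical(nrx); pB <- rep(NA_real_, nrx); pT <- rep(NA_real_, nrx)
  pS <- rep(NA_real_, nrx)
  for (j in seq_len(nrx)) {
    node <- rxNodes[[j]]
    rev <- !identical(xml_attr(node, "reversible"), "false")
    sides <- function(tag, sign) {
      refs <- xml_find_all(node, paste0(
        ".//*[local-name()='", tag, "']/*[local-name()='speciesReference']"))
      if (length(refs) == 0) return(NULL)
      st <- xml_attr(refs, "stoichiometry")
      st <- ifelse(is.na(st), 1, as.numeric(st))
      data.frame(met = unname(vapply(xml_attr(refs, "species"),
                                     decodeSbmlId, character(1))),
                 coef = sign * st)
    }
    df <- rbind(sides("listOfReactants", -1), sides("listOfProducts", +1))
    trip[[j]] <- df

    kl <- xml_find_all(node, paste0(
      ".//*[local-name()='kineticLaw']//*[local-name()='parameter']"))
    kpar <- stats::setNames(as.numeric(xml_attr(kl, "value")),
                            xml_attr(kl, "id"))
    lbRef <- xml_attr(node, "lowerFluxBound")
    ubRef <- xml_attr(node, "upperFluxBound")
    lb[j] <- if ("LOWER_BOUND" %in% names(kpar)) kpar[["LOWER_BOUND"]]
             else if (!is.na(lbRef) && lbRef %in% names(pars)) pars[[lbRef]]
             else if (rev) -.DEFAULT_VMAX else 0
    ub[j] <- if ("UPPER_BOUND" %in% names(kpar)) kpar[["UPPER_BOUND"]]
             else if (!is.na(ubRef) && ubRef %in% names(pars)) pars[[ubRef]]
             else .DEFAULT_VMAX
    objc[j] <- if ("OBJECTIVE_COEFFICIENT" %in% names(kpar))
      kpar[["OBJECTIVE_COEFFICIENT"]] else 0

    ga <- .noteText(node, "GENE_ASSOCIATION")
    if (!is.na(ga)) {
      ok <- tryCatch({ parseGpr(ga); TRUE }, error = function(e) FALSE)
      if (!ok) {
        warning("unparseable GENE_ASSOCIATION for ", rid[j],
                "; treating as orphan: ", ga)
        ga <- ""
      }
      gpr[j] <- ga
    }
    pwx <- .noteText(node, "PATHWAYS")
    if (is.na(pwx)) pwx <- .noteText(node, "SUBSYSTEM")
    pw[j] <- if (is.na(pwx)) "" else gsub("\\s*;\\s*", ";", pwx)
    cu <- .noteText(node, "CURATED")
    curated[j] <- !is.na(cu) && tolower(cu) %in% c("true", "1", "yes")
    num <- function(key) {
      v <- .noteText(node, key)
      if (is.na(v)) NA_real_ else suppressWarnings(as.numeric(v))
    }
    pB[j] <- num("P_BIOCHEM"); pT[j] <- num("P_THERMO")
    pS[j] <- num("PATHWAY_SUPPORT")
  }

  allMet <- met$id
  ii <- integer(); jj <- integer(); xx <- numeric()
  for (j in seq_len(nrx)) {
    df <- trip[[j]]
    if (is.null(df)) next
    df <- df[df$met %in% allMet, , drop = FALSE]  # boundary species removed
    df <- stats::aggregate(coef ~ met, df, sum)
    ii <- c(ii, match(df$met, allMet)); jj <- c(jj, rep(j, nrow(df)))
    xx <- c(xx, df$coef)
  }
  S <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(length(allMet), nrx),
                            dimnames = list(allMet, rid))
  S <- methods::as(methods::as(S, "CsparseMatrix"), "generalMatrix")

  ## objective: OBJECTIVE_COEFFICIENT, else fbc active objective
  objId <- rid[which(objc != 0)]
  if (length(objId) == 0) {
    fo <- xml_find_first(mdl, paste0(
      ".//*[local-name()='listOfFluxObjectives']/*",
      "[local-name()='fluxObjective']"))
    if (!inherits(fo, "xml_missing")) {
      objId <- decodeSbmlId(xml_attr(fo, "reaction"))
    }
  }
  if (length(objId) != 1L)
    stop("model must declare exactly one objective reaction (found ",
         length(objId), "): ", path)

  pwList <- CharacterList(lapply(strsplit(pw, ";"),
                                 function(x) x[nzchar(x)]))
  rxn <- DataFrame(id = rid, name = xml_attr(rxNodes, "name"),
                   lb = lb, ub = ub, gpr = gpr, pathways = pwList,
                   isExchange = Matrix::colSums(S != 0) == 1L,
                   curated = curated, pBiochem = pB, pThermo = pT,
                   pathwaySupport = pS, row.names = rid)
  rxn$name[is.na(rxn$name)] <- rid[is.na(rxn$name)]

  genes <- unique(unlist(lapply(gpr, gprGenes), use.names = FALSE))
  out <- methods::new("MetabolicModel", S = S, metabolites = met,
                      reactions = rxn, objective = objId, genes = genes)
  validObject(out)
  out
}

.xmlEsc <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Write a model as COBRA-dialect SBML
#'
#' Emits SBML Level 2 with COBRA Notes (\code{GENE_ASSOCIATION},
#' \code{PATHWAYS}, formula/charge and evidence fields) and kinetic-law
#' bound parameters; [readCobraSbml()] reads it back losslessly.
#' Identifiers pass through [encodeSbmlId()].
#'
#' @param model a [MetabolicModel-class].
#' @param path output file path.
#' @param id model id attribute.
#' @return invisibly, \code{path}.
#' @export
writeCobraSbml <- function(model, path, id = "model") {
  validObject(model)
  met <- model@metabolites
  rxn <- model@reactions
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write SBML to '", path,
                                           "': ", conditionMessage(e)))
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)

  w('<?xml version="1.0" encoding="UTF-8"?>')
  w('<sbml xmlns="http://www.sbml.org/sbml/level2" level="2" version="1">')
  w('  <model id="', encodeSbmlId(id), '" name="', .xmlEsc(id), '">')
  comps <- unique(met$compartment)
  if (length(comps) == 0) comps <- "c"
  w('    <listOfCompartments>')
  for (cp in comps)
    w('      <compartment id="', encodeSbmlId(cp), '"/>')
  w('    </listOfCompartments>')

  w('    <listOfSpecies>')
  for (i in seq_len(nrow(met))) {
    notes <- character()
    if (!is.na(met$formula[i]))
      notes <- c(notes, paste0("FORMULA: ", met$formula[i]))
    if (!is.na(met$charge[i]))
      notes <- c(notes, paste0("CHARGE: ", met$charge[i]))
    noteXml <- if (length(notes))
      paste0('<notes><body xmlns="http://www.w3.org/1999/xhtml">',
             paste0("<p>", .xmlEsc(notes), "</p>", collapse = ""),
             "</body></notes>") else ""
    w('      <species id="', encodeSbmlId(met$id[i]),
      '" name="', .xmlEsc(met$name[i]),
      '" compartment="', encodeSbmlId(met$compartment[i]), '"',
      if (noteXml == "") "/>" else paste0(">", noteXml, "</species>"))
  }
  w('    </listOfSpecies>')

  w('    <listOfReactions>')
  for (j in seq_len(nrow(rxn))) {
    st <- model@S[, j]
    st <- st[st != 0]
    reac <- st[st < 0]; prod <- st[st > 0]
    notes <- c(paste0("GENE_ASSOCIATION: ", rxn$gpr[j]),
               paste0("PATHWAYS: ", paste(rxn$pathways[[j]], collapse = ";")),
               paste0("CURATED: ", tolower(rxn$curated[j])))
    evFields <- c(P_BIOCHEM = "pBiochem", P_THERMO = "pThermo",
                  PATHWAY_SUPPORT = "pathwaySupport")
    for (k in seq_along(evFields)) {
      val <- rxn[[evFields[[k]]]][j]
      if (!is.na(val))
        notes <- c(notes, paste0(names(evFields)[k], ": ",
                                 format(val, digits = 17)))
    }
    w('      <reaction id="', encodeSbmlId(rxn$id[j]),
      '" name="', .xmlEsc(rxn$name[j]),
      '" reversible="', tolower(rxn$lb[j] < 0), '">')
    w('        <notes><body xmlns="http://www.w3.org/1999/xhtml">',
      paste0("<p>", .xmlEsc(notes), "</p>", collapse = ""),
      '</body></notes>')
    side <- function(tag, v) {
      if (length(v) == 0) return()
      w('        <', tag, '>')
      for (mid in names(v))
        w('          <speciesReference species="', encodeSbmlId(mid),
          '" stoichiometry="', format(abs(v[[mid]]), digits = 17), '"/>')
      w('        </', tag, '>')
    }
    side("listOfReactants", reac)
    side("listOfProducts", prod)
    w('        <kineticLaw>')
    w('          <math xmlns="http://www.w3.org/1998/Math/MathML">',
      '<ci>FLUX_VALUE</ci></math>')
    w('          <listOfParameters>')
    w('            <parameter id="LOWER_BOUND" value="',
      format(rxn$lb[j], digits = 17), '" units="mmol_per_gDW_per_hr"/>')
    w('            <parameter id="UPPER_BOUND" value="',
      format(rxn$ub[j], digits = 17), '" units="mmol_per_gDW_per_hr"/>')
    w('            <parameter id="OBJECTIVE_COEFFICIENT" value="',
      if (rxn$id[j] == model@objective) 1 else 0, '"/>')
    w('          </listOfParameters>')
    w('        </kineticLaw>')
    w('      </reaction>')
  }
  w('    </listOfReactions>')
  w('  </model>')
  w('</sbml>')
  invisible(path)
}
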