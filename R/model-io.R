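## Model import/export: a delimited tabular dialect (reaction + metabolite
## tables with human-readable equation strings) and a compact SBML Level 3
## (fbc v2) reader/writer.  Bound sentinels (+/-1000) survive round trips
## verbatim.

#' Load a metabolic model
#'
#' Dispatches on file type: \code{.xml}/\code{.sbml} sources are parsed as
#' SBML Level 3 with the \code{fbc} package, anything else as the tabular
#' dialect (in which case \code{metabolites} must point to the metabolite
#' table).
#'
#' @param source path to an SBML document or a tabular reaction listing.
#' @param metabolites path to the metabolite table (tabular dialect only).
#' @return a \linkS4class{MetabolicModel}.
#' @export
loadModel <- function(source, metabolites = NULL) {
  if (!file.exists(source)) stop("model source not found: ", source)
  if (grepl("\\.(xml|sbml)$", source, ignore.case = TRUE))
    readSBMLModel(source)
  else
    readModelTable(source, metabolites)
}

#' Read a model from the tabular dialect
#'
#' The reaction table has columns \code{id}, \code{name}, \code{equation}
#' (e.g. \code{"glc + atp -> glyc + adp + pi + h"}; an empty right-hand
#' side denotes a drain), \code{lower}, \code{upper}, \code{gpr},
#' \code{category}, \code{confidence}.  The metabolite table has columns
#' \code{id}, \code{name}, \code{formula}, \code{charge},
#' \code{compartment}.  Files are tab-separated.
#'
#' @param reactionsFile,metabolitesFile file paths.
#' @return a \linkS4class{MetabolicModel}.
#' @export
readModelTable <- function(reactionsFile, metabolitesFile) {
  if (is.null(metabolitesFile))
    stop("the tabular dialect needs both a reaction and a metabolite table")
  rxn <- utils::read.delim(reactionsFile, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  met <- utils::read.delim(metabolitesFile, stringsAsFactors = FALSE,
                           na.strings = "NA")
  if (anyDuplicated(rxn$id))
    stop("duplicate reaction id: ",
         paste(unique(rxn$id[duplicated(rxn$id)]), collapse = ", "))
  if (!is.null(met$formula)) met$formula[is.na(met$formula)] <- NA_character_
  stoich <- lapply(seq_len(nrow(rxn)), function(i) {
    tryCatch(parseEquation(rxn$equation[i]),
             error = function(e) stop("reaction '", rxn$id[i], "': ",
                                      conditionMessage(e), call. = FALSE))
  })
  names(stoich) <- rxn$id
  rxn$equation <- NULL
  MetabolicModel(met, rxn, stoich)
}

#' @rdname readModelTable
#' @param model a \linkS4class{MetabolicModel} to serialize.
#' @export
writeModelTable <- function(model, reactionsFile, metabolitesFile) {
  rxn <- reactions(model)
  S <- stoichiometry(model)
  eqs <- vapply(seq_len(nrow(rxn)), function(j) {
    col <- S[, j]
    formatEquation(col[col != 0], reversible = rxn$lower[j] < 0)
  }, character(1))
  out <- cbind(rxn[, c("id", "name")], equation = eqs,
               rxn[, c("lower", "upper", "gpr", "category", "confidence")])
  utils::write.table(out, reactionsFile, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(metabolites(model), metabolitesFile, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(reactionsFile, metabolitesFile))
}

#' Parse / format reaction equation strings
#'
#' @param equation string like \code{"6 co2 + 12 nadph -> glc + 12 nadp"};
#'   arrows \code{->}, \code{=>}, \code{<=>}, \code{<->} are accepted.
#' @return named numeric stoichiometry (substrates negative).
#' @export
parseEquation <- function(equation) {
  if (is.na(equation) || !nzchar(trimws(equation)))
    stop("empty equation")
  parts <- strsplit(equation, "<=>|<->|=>|->")[[1]]
  if (length(parts) > 2) stop("more than one arrow in equation")
  side <- function(s, sign) {
    s <- trimws(s)
    if (!nzchar(s)) return(stats::setNames(numeric(0), character(0)))
    terms <- trimws(strsplit(s, "\\s\\+\\s|^\\+\\s|\\s\\+$")[[1]])
    terms <- terms[nzchar(terms)]
    out <- numeric(0)
    for (tm in terms) {
      bits <- strsplit(tm, "\\s+")[[1]]
      if (length(bits) == 1) { cf <- 1; id <- bits }
      else if (length(bits) == 2 &&
               grepl("^[0-9.eE+-]+$", bits[1]) &&
               !is.na(suppressWarnings(as.numeric(bits[1])))) {
        cf <- as.numeric(bits[1]); id <- bits[2]
      } else stop("cannot parse term '", tm, "'")
      out[id] <- (out[id] %||% 0) + sign * cf
    }
    out
  }
  lhs <- side(parts[1], -1)
  rhs <- if (length(parts) == 2) side(parts[2], +1)
         else stats::setNames(numeric(0), character(0))
  both <- c(lhs, rhs)
  tapply(both, names(both), sum)[unique(names(both))]
}

`%||%` <- function(a, b) {
  if (is.null(a) || length(a) == 0 || (length(a) == 1 && is.na(a))) b
  else a
}

#' @rdname parseEquation
#' @param stoich named stoichiometry vector.
#' @param reversible use \code{"<=>"} instead of \code{"->"}.
#' @export
formatEquation <- function(stoich, reversible = FALSE) {
  fmt <- function(v) {
    if (!length(v)) return("")
    cf <- abs(v)
    paste(ifelse(abs(cf - 1) < 1e-12, names(v),
                 paste(format(cf, digits = 10, trim = TRUE), names(v))),
          collapse = " + ")
  }
  paste(fmt(stoich[stoich < 0]), if (reversible) "<=>" else "->",
        fmt(stoich[stoich > 0])) |> trimws()
}

## ---- SBML (Level 3, fbc v2 subset) ------------------------------------

#' Read / write a minimal SBML Level 3 (fbc) document
#'
#' Covers the subset needed for constraint-based models: species with
#' formula/charge, reactions with stoichiometry, flux bounds via fbc
#' parameters, gene-product associations (\code{fbc:and}/\code{fbc:or}),
#' and reaction category/confidence carried in the notes body.
#'
#' @param path file path.
#' @return \code{readSBMLModel}: a \linkS4class{MetabolicModel}.
#' @export
readSBMLModel <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  attr1 <- function(node, what) {
    at <- xml2::xml_attrs(node)
    hit <- which(names(at) == what | grepl(paste0(":", what, "$"), names(at)))
    if (length(hit)) at[[hit[1]]] else NA_character_
  }
  params <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  pval <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                          xml2::xml_attr(params, "id"))
  sp <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  met <- data.frame(
    id = xml2::xml_attr(sp, "id"),
    name = ifelse(is.na(xml2::xml_attr(sp, "name")),
                  xml2::xml_attr(sp, "id"), xml2::xml_attr(sp, "name")),
    formula = vapply(sp, attr1, character(1), what = "chemicalFormula"),
    charge = suppressWarnings(as.integer(
      vapply(sp, attr1, character(1), what = "charge"))),
    compartment = xml2::xml_attr(sp, "compartment"),
    stringsAsFactors = FALSE)
  met$charge[is.na(met$charge)] <- 0L
  rx <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  note1 <- function(node, key) {
    ps <- xml2::xml_text(xml2::xml_find_all(node, ".//notes//p"))
    hit <- grep(paste0("^", key, ":"), ps, value = TRUE)
    if (length(hit)) trimws(sub(paste0("^", key, ":"), "", hit[1]))
    else NA_character_
  }
  stoich <- vector("list", length(rx))
  rxn <- data.frame(id = character(0))
  ids <- character(length(rx)); nms <- ids
  lows <- numeric(length(rx)); ups <- lows
  gprs <- character(length(rx)); cats <- gprs
  confs <- integer(length(rx))
  for (k in seq_along(rx)) {
    node <- rx[[k]]
    ids[k] <- xml2::xml_attr(node, "id")
    nm <- xml2::xml_attr(node, "name"); nms[k] <- if (is.na(nm)) ids[k] else nm
    lbid <- attr1(node, "lowerFluxBound"); ubid <- attr1(node, "upperFluxBound")
    lows[k] <- if (!is.na(lbid)) pval[[lbid]] else -1000
    ups[k] <- if (!is.na(ubid)) pval[[ubid]] else 1000
    getside <- function(xp, sign) {
      refs <- xml2::xml_find_all(node, xp)
      if (!length(refs)) return(stats::setNames(numeric(0), character(0)))
      stats::setNames(sign * as.numeric(xml2::xml_attr(refs, "stoichiometry")),
                      xml2::xml_attr(refs, "species"))
    }
    s <- c(getside("./listOfReactants/speciesReference", -1),
           getside("./listOfProducts/speciesReference", +1))
    stoich[[k]] <- tapply(s, names(s), sum)[unique(names(s))]
    gnode <- xml2::xml_find_first(
      node, "./*[local-name()='geneProductAssociation']")
    gprs[k] <- if (inherits(gnode, "xml_missing")) ""
               else .gprFromXml(xml2::xml_child(gnode))
    cats[k] <- note1(node, "category") %||% "metabolic"
    cf <- suppressWarnings(as.integer(note1(node, "confidence")))
    confs[k] <- if (is.na(cf)) NA_integer_ else cf
  }
  names(stoich) <- ids
  MetabolicModel(met,
                 data.frame(id = ids, name = nms, lower = lows, upper = ups,
                            gpr = gprs, category = cats, confidence = confs,
                            stringsAsFactors = FALSE),
                 stoich)
}

.gprFromXml <- function(node) {
  nm <- sub("^.*:", "", xml2::xml_name(node))
  if (nm == "geneProductRef") {
    at <- xml2::xml_attrs(node)
    hit <- grep("(^|:)geneProduct$", names(at))
    return(unname(at[hit[1]]))
  }
  kids <- vapply(xml2::xml_children(node), .gprFromXml, character(1))
  op <- if (nm == "and") " and " else " or "
  paste0("(", paste(kids, collapse = op), ")")
}

#' @rdname readSBMLModel
#' @param model a \linkS4class{MetabolicModel}.
#' @param id SBML model id.
#' @export
writeSBMLModel <- function(model, path, id = "model") {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x); x <- gsub("<", "&lt;", x)
    gsub(">", "&gt;", x)
  }
  met <- metabolites(model); rxn <- reactions(model)
  S <- stoichiometry(model)
  bvals <- sort(unique(c(rxn$lower, rxn$upper)))
  fmt1 <- function(v) format(v, trim = TRUE, digits = 12)
  keys <- vapply(bvals, fmt1, character(1))
  bid <- stats::setNames(
    paste0("fb_", gsub("[^0-9A-Za-z]", "_", keys)), keys)
  bkey <- function(v) bid[[fmt1(v)]]
  L <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
           'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
           'level="3" version="1" fbc:required="false">'),
    sprintf('  <model id="%s" fbc:strict="true">', esc(id)),
    '    <listOfCompartments>',
    sprintf('      <compartment id="%s" constant="true"/>',
            unique(met$compartment)),
    '    </listOfCompartments>',
    '    <listOfSpecies>')
  L <- c(L, vapply(seq_len(nrow(met)), function(i) {
    extra <- ""
    if (!is.na(met$formula[i]))
      extra <- paste0(extra, sprintf(' fbc:chemicalFormula="%s"',
                                     esc(met$formula[i])))
    extra <- paste0(extra, sprintf(' fbc:charge="%d"',
                                   as.integer(met$charge[i])))
    sprintf(paste0('      <species id="%s" name="%s" compartment="%s" ',
                   'hasOnlySubstanceUnits="false" boundaryCondition="false" ',
                   'constant="false"%s/>'),
            esc(met$id[i]), esc(met$name[i]), esc(met$compartment[i]), extra)
  }, character(1)))
  L <- c(L, '    </listOfSpecies>', '    <listOfParameters>',
         vapply(seq_along(bvals), function(i)
           sprintf(paste0('      <parameter id="%s" value="%s" ',
                          'constant="true"/>'),
                   bid[[i]], format(bvals[i], trim = TRUE, digits = 12)),
           character(1)),
         '    </listOfParameters>',
         '    <fbc:listOfGeneProducts>',
         vapply(modelGenes(model), function(g)
           sprintf(paste0('      <fbc:geneProduct fbc:id="%s" ',
                          'fbc:label="%s"/>'), esc(g), esc(g)),
           character(1)),
         '    </fbc:listOfGeneProducts>',
         '    <listOfReactions>')
  for (j in seq_len(nrow(rxn))) {
    col <- S[, j]; col <- col[col != 0]
    refs <- function(v, tag) {
      if (!length(v)) return(character(0))
      c(sprintf('        <listOf%s>', tag),
        vapply(seq_along(v), function(i)
          sprintf(paste0('          <speciesReference species="%s" ',
                         'stoichiometry="%s" constant="true"/>'),
                  esc(names(v)[i]),
                  format(abs(v[i]), trim = TRUE, digits = 12)),
          character(1)),
        sprintf('        </listOf%s>', tag))
    }
    gxml <- if (nzchar(rxn$gpr[j]))
      c('        <fbc:geneProductAssociation>',
        paste0("          ", .gprToXml(.parseGPRAst(rxn$gpr[j]))),
        '        </fbc:geneProductAssociation>')
    else character(0)
    L <- c(L,
      sprintf(paste0('      <reaction id="%s" name="%s" reversible="%s" ',
                     'fast="false" fbc:lowerFluxBound="%s" ',
                     'fbc:upperFluxBound="%s">'),
              esc(rxn$id[j]), esc(rxn$name[j]),
              tolower(rxn$lower[j] < 0), bkey(rxn$lower[j]),
              bkey(rxn$upper[j])),
      '        <notes><body xmlns="http://www.w3.org/1999/xhtml">',
      sprintf('          <p>category: %s</p>', rxn$category[j]),
      if (!is.na(rxn$confidence[j]))
        sprintf('          <p>confidence: %d</p>',
                as.integer(rxn$confidence[j])) else character(0),
      '        </body></notes>',
      refs(col[col < 0], "Reactants"),
      refs(col[col > 0], "Products"),
      gxml,
      '      </reaction>')
  }
  L <- c(L, '    </listOfReactions>', '  </model>', '</sbml>')
  writeLines(L, path)
  invisible(path)
}

## recursive-descent GPR parser -> nested list AST
.parseGPRAst <- function(gpr) {
  toks <- .gprTokens(gpr)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  take <- function() { t <- toks[pos]; pos <<- pos + 1L; t }
  factor <- function() {
    t <- take()
    if (identical(t, "(")) {
      e <- expr()
      if (!identical(take(), ")")) stop("unbalanced GPR parentheses")
      e
    } else list(op = "gene", gene = t)
  }
  term <- function() {
    kids <- list(factor())
    while (!is.na(peek()) && tolower(peek()) == "and") {
      take(); kids <- c(kids, list(factor()))
    }
    if (length(kids) == 1) kids[[1]] else list(op = "and", children = kids)
  }
  expr <- function() {
    kids <- list(term())
    while (!is.na(peek()) && tolower(peek()) == "or") {
      take(); kids <- c(kids, list(term()))
    }
    if (length(kids) == 1) kids[[1]] else list(op = "or", children = kids)
  }
  out <- expr()
  if (pos <= length(toks)) stop("trailing tokens in GPR: ", gpr)
  out
}

.gprToXml <- function(ast) {
  if (ast$op == "gene")
    return(sprintf('<fbc:geneProductRef fbc:geneProduct="%s"/>', ast$gene))
  inner <- paste(vapply(ast$children, .gprToXml, character(1)),
                 collapse = "")
  sprintf('<fbc:%s>%s</fbc:%s>', ast$op, inner, ast$op)
}
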