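## Gene-protein-reaction rules: boolean expressions over gene ids where
## `and` encodes a required complex and `or` encodes isozymes.

.gprTokens <- function(gpr) {
  if (is.na(gpr) || !nzchar(trimws(gpr))) return(character(0))
  x <- gsub("([()])", " \\1 ", gpr)
  strsplit(trimws(x), "\\s+")[[1]]
}

#' Genes referenced by a GPR expression
#'
#' @param gpr a GPR string, e.g. \code{"(g1 and g2) or g3"}.
#' @return character vector of gene ids (empty for a blank rule).
#' @export
gprGenes <- function(gpr) {
  toks <- .gprTokens(gpr)
  setdiff(toks[!tolower(toks) %in% c("and", "or", "(", ")")], character(0))
}

#' Evaluate a GPR expression under gene knockouts
#'
#' AND requires every member of a complex; OR accepts any isozyme.  A
#' blank rule (spontaneous or orphan reaction) always evaluates TRUE.
#'
#' @param gpr a GPR string.
#' @param knockedOut character vector of deleted gene ids.
#' @return logical: is the reaction still catalysable?
#' @export
evalGPR <- function(gpr, knockedOut = character(0)) {
  toks <- .gprTokens(gpr)
  if (!length(toks)) return(TRUE)
  expr <- vapply(toks, function(tk) {
    lt <- tolower(tk)
    if (lt == "and") "&&"
    else if (lt == "or") "||"
    else if (tk %in% c("(", ")")) tk
    else if (tk %in% knockedOut) "FALSE"
    else "TRUE"
  }, character(1))
  out <- tryCatch(eval(parse(text = paste(expr, collapse = " "))),
                  error = function(e)
                    stop("unparseable GPR: '", gpr, "'", call. = FALSE))
  isTRUE(out)
}
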