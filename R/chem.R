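## Elemental bookkeeping for balance checks and molar-mass prediction.

.ATOMIC_MASS <- c(
  C = 12.011, H = 1.008, N = 14.007, O = 15.999, P = 30.974, S = 32.06,
  Mg = 24.305, Fe = 55.845, K = 39.098, Na = 22.99, Ca = 40.078,
  Cl = 35.45, Mn = 54.938, Zn = 65.38, Cu = 63.546, Mo = 95.95,
  Co = 58.933, Se = 78.971
)

#' Parse a chemical formula
#'
#' Parses a Hill-style formula string (e.g. \code{"C6H12O6"}) into a named
#' element-count vector.  An empty string denotes a massless species (such
#' as a photon) with zero atoms of every element; \code{NA} denotes an
#' unknown formula.
#'
#' @param x a single formula string.
#' @return named numeric vector of element counts, or \code{NULL} when the
#'   formula is unknown (\code{NA}).
#' @export
parseFormula <- function(x) {
  if (length(x) != 1L) stop("parseFormula() expects a single string")
  if (is.na(x)) return(NULL)
  x <- trimws(x)
  if (!nzchar(x)) return(stats::setNames(numeric(0), character(0)))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*\\.?[0-9]*)", x)[[1]]
  toks <- regmatches(x, gregexpr("([A-Z][a-z]?)([0-9]*\\.?[0-9]*)", x))[[1]]
  if (sum(nchar(toks)) != nchar(gsub("\\s", "", x)))
    stop("cannot parse formula: ", x)
  el <- sub("[0-9.]*$", "", toks)
  ct <- as.numeric(sub("^[A-Za-z]+", "", toks))
  ct[is.na(ct)] <- 1
  tapply(ct, el, sum)[unique(el)]
}

#' @rdname parseFormula
#' @param counts named element-count vector (as from \code{parseFormula}).
#' @return \code{formulaMass}: molar mass in g/mol.
#' @export
formulaMass <- function(counts) {
  if (is.null(counts)) return(NA_real_)
  if (!length(counts)) return(0)
  unknown <- setdiff(names(counts), names(.ATOMIC_MASS))
  if (length(unknown))
    stop("no atomic mass for element(s): ", paste(unknown, collapse = ", "))
  sum(.ATOMIC_MASS[names(counts)] * counts)
}

## Combine element-count vectors: sum(coef_i * formula_i).
.combineCounts <- function(counts, coefs) {
  all <- unique(unlist(lapply(counts, names)))
  out <- stats::setNames(numeric(length(all)), all)
  for (i in seq_along(counts)) {
    f <- counts[[i]]
    if (length(f)) out[names(f)] <- out[names(f)] + coefs[i] * f
  }
  out[abs(out) > 1e-9]
}

## Format counts back to a Hill-ish string (C, H first, then alphabetical).
.formatFormula <- function(counts) {
  if (is.null(counts)) return(NA_character_)
  if (!length(counts)) return("")
  els <- names(counts)
  ord <- c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  num <- function(v) ifelse(abs(v - 1) < 1e-9, "",
                            ifelse(abs(v - round(v)) < 1e-9,
                                   as.character(round(v)),
                                   format(v, digits = 6)))
  paste0(ord, num(counts[ord]), collapse = "")
}
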