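## Biomass-equation construction from measured macromolecular
## composition: monomer profiles -> condensation reactions and molar
## masses -> mmol/gDW biomass coefficients -> the biomass formation
## reaction with growth-associated maintenance ATP.

.MONOMER_FORMULAS <- c(
  ## free amino acids
  gly = "C2H5NO2", ala = "C3H7NO2", ser = "C3H7NO3", cys = "C3H7NO2S",
  thr = "C4H9NO3", val = "C5H11NO2", leu = "C6H13NO2", ile = "C6H13NO2",
  pro = "C5H9NO2", met = "C5H11NO2S", phe = "C9H11NO2", tyr = "C9H11NO3",
  trp = "C11H12N2O2", asp = "C4H7NO4", glu = "C5H9NO4", asn = "C4H8N2O3",
  gln = "C5H10N2O3", lys = "C6H14N2O2", arg = "C6H14N4O2",
  his = "C6H9N3O2",
  ## nucleoside monophosphates
  amp = "C10H14N5O7P", gmp = "C10H14N5O8P", cmp = "C9H14N3O8P",
  ump = "C9H13N2O9P",
  damp = "C10H14N5O6P", dgmp = "C10H14N5O7P", dcmp = "C9H14N3O7P",
  dtmp = "C10H15N2O8P",
  ## sugars, lipid parts, pigments
  glucose = "C6H12O6", glycerol = "C3H8O3", galactose = "C6H12O6",
  sulfoquinovose = "C6H12O8S", glycerophosphate = "C3H9O6P",
  chlorophyll_a = "C55H72MgN4O5"
)

.WATER_MASS <- 18.015

.monomerMass <- function(id) {
  if (grepl("^fa[0-9]+$", id)) {           # saturated fatty acid CnH2nO2
    nC <- as.integer(sub("^fa", "", id))
    return(nC * 12.011 + 2 * nC * 1.008 + 2 * 15.999)
  }
  f <- .MONOMER_FORMULAS[id]
  if (is.na(f)) stop("unknown monomer mass for '", id, "'")
  formulaMass(parseFormula(unname(f)))
}

#' Read a macromolecular biomass composition
#'
#' The composition table is delimited text with columns
#' \code{macromolecule}, \code{mass_fraction_N2},
#' \code{mass_fraction_KNO3} and \code{subset_of} (blank when the entry
#' is not a subset of another assay: phycoerythrin and cyanophycin are
#' subsets of the protein measurement; phycocyanin and chlorophyll of
#' the lipid measurement).  Monomer profiles are two-column tables
#' (\code{monomer}, \code{mole_fraction}); fatty-acid monomers are named
#' \code{fa<chainlength>} (e.g. \code{fa16}).
#'
#' @param compositionFile path to the composition table.
#' @param aminoAcidFile,fattyAcidFile,lipidSubclassFile optional profile
#'   tables; defaults are the files shipped under
#'   \code{inst/extdata} (the amino-acid and fatty-acid profiles shipped
#'   there are synthetic stand-ins, not measured data).
#' @param molarMassOverrides named numeric (g/mmol) for pool entries with
#'   no polymer structure (e.g. \code{soluble_pool}).
#' @return a list of class \code{"BiomassComposition"}.
#' @export
readBiomassComposition <- function(compositionFile,
                                   aminoAcidFile = NULL,
                                   fattyAcidFile = NULL,
                                   lipidSubclassFile = NULL,
                                   molarMassOverrides = c(
                                     soluble_pool = 0.754)) {
  pick <- function(path, default) {
    if (!is.null(path)) path
    else system.file("extdata", default, package = "TrichoFBA",
                     mustWork = TRUE)
  }
  readProfile <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    stats::setNames(df$mole_fraction, df$monomer)
  }
  comp <- utils::read.delim(compositionFile, stringsAsFactors = FALSE,
                            na.strings = c("NA", ""))
  out <- list(
    massFractions = comp,
    profiles = list(
      aminoAcids = readProfile(pick(aminoAcidFile,
                                    "amino_acid_profile_synthetic.tsv")),
      fattyAcids = readProfile(pick(fattyAcidFile,
                                    "fatty_acid_profile_synthetic.tsv")),
      lipidSubclasses = readProfile(pick(lipidSubclassFile,
                                         "lipid_subclasses_synthetic.tsv"))),
    molarMassOverrides = molarMassOverrides)
  for (pn in names(out$profiles)) {
    s <- sum(out$profiles[[pn]])
    if (abs(s - 1) > 1e-3)
      stop("profile '", pn, "' mole fractions sum to ", s, ", not 1")
    out$profiles[[pn]] <- out$profiles[[pn]] / s
  }
  if (any(comp$mass_fraction_N2 < 0, na.rm = TRUE) ||
      any(comp$mass_fraction_KNO3 < 0, na.rm = TRUE))
    stop("mass fractions must be non-negative")
  class(out) <- "BiomassComposition"
  out
}

#' Build macromolecule condensation reactions and molar masses
#'
#' One condensation reaction per macromolecule: monomers are consumed at
#' their mole fractions and one water is released per condensation bond,
#' so each polymer unit's molar mass is the profile-weighted monomer
#' mass less the condensation water.  Cyanophycin is polymerized
#' arginine and aspartate in a 1:1 ratio.  Lipids combine the four
#' subclasses (SQDG, MGDG, DGDG, PGP) at their mole ratios, each built
#' from glycerol, two profile-averaged fatty-acid chains and the
#' subclass head group, with one water lost per ester/glycosidic bond;
#' the same chain-length distribution is applied to every subclass.
#' Biliproteins (phycoerythrin, phycocyanin) use the protein profile.
#' Entries with a molar-mass override (the soluble pool) get a
#' pass-through reaction.
#'
#' @param composition a [readBiomassComposition()] result.
#' @return list with \code{reactions} (a reaction table in the tabular
#'   dialect, category \code{"macromolecule"}), \code{stoichiometry}
#'   (named list of stoichiometry vectors) and \code{molarMasses} (named,
#'   g/mmol).
#' @export
buildMacromoleculeReactions <- function(composition) {
  stopifnot(inherits(composition, "BiomassComposition"))
  aa <- composition$profiles$aminoAcids
  fa <- composition$profiles$fattyAcids
  sub <- composition$profiles$lipidSubclasses
  macros <- composition$massFractions$macromolecule
  stoich <- list(); mm <- numeric(0)
  profilePolymer <- function(profile) {
    mono <- vapply(names(profile), .monomerMass, numeric(1))
    list(stoich = -profile, mass = sum(profile * mono) - .WATER_MASS,
         water = 1)
  }
  faMass <- sum(fa * vapply(names(fa), .monomerMass, numeric(1)))
  headMass <- c(SQDG = .monomerMass("sulfoquinovose"),
                MGDG = .monomerMass("galactose"),
                DGDG = 2 * .monomerMass("galactose"),
                PGP = .monomerMass("glycerophosphate"))
  headWaters <- c(SQDG = 3, MGDG = 3, DGDG = 4, PGP = 3)
  for (mac in macros) {
    key <- tolower(gsub("[^a-z0-9]+", "_", tolower(mac)))
    res <- switch(key,
      protein = , phycoerythrin = , phycocyanin = profilePolymer(aa),
      cyanophycin = profilePolymer(c(arg = 0.5, asp = 0.5)),
      carbohydrate = profilePolymer(c(glucose = 1)),
      rna = profilePolymer(c(amp = 0.25, gmp = 0.25, cmp = 0.25,
                             ump = 0.25)),
      dna = profilePolymer(c(damp = 0.25, dgmp = 0.25, dcmp = 0.25,
                             dtmp = 0.25)),
      lipids = , lipid = {
        mass <- sum(sub[c("SQDG", "MGDG", "DGDG", "PGP")] *
                    (.monomerMass("glycerol") + 2 * faMass + headMass -
                     headWaters * .WATER_MASS))
        faPer <- 2 * sub / sum(sub)
        st <- c(glycerol = -1,
                stats::setNames(-2 * fa, names(fa)),
                sulfoquinovose = -unname(sub["SQDG"]),
                galactose = -unname(sub["MGDG"] + 2 * sub["DGDG"]),
                glycerophosphate = -unname(sub["PGP"]))
        list(stoich = st, mass = mass,
             water = sum(sub * headWaters))
      },
      chlorophyll = list(stoich = c(chlorophyll_a = -1),
                         mass = .monomerMass("chlorophyll_a"), water = 0),
      {
        ov <- composition$molarMassOverrides[key]
        if (is.na(ov))
          stop("unknown monomer mass for macromolecule '", mac, "'")
        list(stoich = stats::setNames(-1, paste0(key, "_precursor")),
             mass = ov * 1000, water = 0)
      })
    id <- paste0("MACRO_", key)
    s <- res$stoich
    if (res$water > 0) s <- c(s, h2o = res$water)
    s[key] <- 1
    stoich[[id]] <- s
    mm[key] <- res$mass / 1000     # g/mmol
  }
  rxn <- data.frame(id = names(stoich),
                    name = paste("condensation:", macros),
                    lower = 0, upper = 1000, gpr = "",
                    category = "macromolecule",
                    confidence = NA_integer_,
                    stringsAsFactors = FALSE)
  list(reactions = rxn, stoichiometry = stoich, molarMasses = mm)
}

#' Convert mass fractions to biomass coefficients
#'
#' \eqn{coefficient_m = massfraction_m / molarmass_m} (mmol/gDW), after
#' subtracting each subset macromolecule's mass from its parent assay
#' (phycoerythrin and cyanophycin from protein; phycocyanin and
#' chlorophyll from lipid) so nothing is double counted.  By default
#' fractions are used exactly as printed even though they need not total
#' 1 g/g; \code{normalize = TRUE} rescales the (subset-adjusted)
#' fractions to close the mass balance at exactly 1.
#'
#' @param composition a [readBiomassComposition()] result.
#' @param molarMasses named numeric, g/mmol (e.g. from
#'   [buildMacromoleculeReactions()]).
#' @param column \code{"N2"} (default; cells grown on diatomic nitrogen
#'   are the reference composition) or \code{"KNO3"}.
#' @param gam growth-associated maintenance, mmol ATP/gDW (default 544).
#' @param normalize rescale adjusted fractions to sum to 1.
#' @return list of class \code{"BiomassEquation"} with
#'   \code{coefficients} (named, mmol/gDW), \code{adjustedMassFractions}
#'   and \code{gam}.
#' @export
compositionToCoefficients <- function(composition, molarMasses,
                                      column = c("N2", "KNO3"),
                                      gam = 544, normalize = FALSE) {
  column <- match.arg(column)
  df <- composition$massFractions
  key <- tolower(gsub("[^a-z0-9]+", "_", tolower(df$macromolecule)))
  mf <- stats::setNames(df[[paste0("mass_fraction_", column)]], key)
  parent <- stats::setNames(
    tolower(gsub("[^a-z0-9]+", "_", tolower(df$subset_of))), key)
  adj <- mf
  for (k in key[!is.na(parent) & nzchar(parent)]) {
    p <- parent[[k]]
    if (!p %in% names(adj)) next
    adj[p] <- adj[p] - mf[k]
    if (adj[p] < -1e-9)
      stop("subset subtraction drives '", p, "' below zero")
    adj[p] <- max(adj[p], 0)
  }
  if (normalize) adj <- adj / sum(adj)
  miss <- setdiff(names(adj), names(molarMasses))
  if (length(miss))
    stop("no molar mass for: ", paste(miss, collapse = ", "))
  coef <- adj / molarMasses[names(adj)]
  structure(list(coefficients = coef, adjustedMassFractions = adj,
                 gam = gam, column = column),
            class = "BiomassEquation")
}

#' Assemble the biomass formation reaction
#'
#' A single reaction consuming each macromolecule at its biomass
#' coefficient plus growth-associated maintenance ATP hydrolysis
#' (\code{gam} mmol ATP per g DW formed), producing one gram dry weight
#' of biomass per unit flux -- so the flux through this reaction is the
#' specific growth rate in h^-1.
#'
#' @param equation a [compositionToCoefficients()] result.
#' @param energyIds named list of ATP-hydrolysis species ids.
#' @return list with \code{id}, \code{stoichiometry} and a one-row
#'   \code{reaction} table (category \code{"biomass"}).
#' @export
assembleBiomassReaction <- function(equation,
                                    energyIds = list(atp = "atp",
                                                     adp = "adp",
                                                     pi = "pi", h = "h",
                                                     h2o = "h2o")) {
  stopifnot(inherits(equation, "BiomassEquation"))
  coef <- equation$coefficients
  coef <- coef[coef > 0]
  if (!length(coef)) stop("empty biomass equation")
  g <- equation$gam
  e <- energyIds
  s <- c(stats::setNames(-coef, names(coef)),
         stats::setNames(c(-g, -g, g, g, g),
                         c(e$atp, e$h2o, e$adp, e$pi, e$h)))
  list(id = "BIOMASS",
       stoichiometry = s,
       reaction = data.frame(id = "BIOMASS", name = "biomass formation",
                             lower = 0, upper = 1000, gpr = "",
                             category = "biomass",
                             confidence = NA_integer_,
                             stringsAsFactors = FALSE))
}

#' Composition mass totals with and without subset rows
#'
#' The printed column totals of a composition table are ambiguous about
#' whether flagged subset rows are included; both sums are reported and
#' neither is asserted.
#'
#' @param composition a [readBiomassComposition()] result.
#' @param column \code{"N2"} or \code{"KNO3"}.
#' @return list with \code{includingSubsets} and \code{excludingSubsets}
#'   (g/g DW).
#' @export
compositionTotals <- function(composition, column = c("N2", "KNO3")) {
  column <- match.arg(column)
  df <- composition$massFractions
  mf <- df[[paste0("mass_fraction_", column)]]
  isSub <- !is.na(df$subset_of) & nzchar(df$subset_of)
  list(includingSubsets = sum(mf), excludingSubsets = sum(mf[!isSub]))
}
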