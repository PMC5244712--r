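compositionFixture <- function(...) {
  readBiomassComposition(
    system.file("extdata", "biomass_composition.tsv",
                package = "TrichoFBA", mustWork = TRUE), ...)
}

test_that("condensation molar masses follow monomer profiles and water loss", {
  comp <- compositionFixture()
  ## single-monomer protein: molar mass is the glycine residue mass
  aaFile <- tempfile(fileext = ".tsv")
  writeLines(c("monomer\tmole_fraction", "gly\t1"), aaFile)
  glyOnly <- compositionFixture(aminoAcidFile = aaFile)
  mmGly <- buildMacromoleculeReactions(glyOnly)$molarMasses
  expect_equal(mmGly[["protein"]], (75.067 - 18.015) / 1000,
               tolerance = 1e-3)
  ## cyanophycin: 1:1 arginine:aspartate polymer, consumed equimolar
  built <- buildMacromoleculeReactions(comp)
  cphy <- built$stoichiometry$MACRO_cyanophycin
  expect_equal(unname(cphy["arg"]), unname(cphy["asp"]))
  expect_lt(cphy[["arg"]], 0)
  expect_equal(mmGly[["cyanophycin"]],
               (0.5 * 174.2 + 0.5 * 133.1 - 18.015) / 1000,
               tolerance = 1e-3)
  ## every condensation reaction is mass balanced: monomer mass in equals
  ## unit mass plus released water
  mono <- function(id) TrichoFBA:::.monomerMass(id)
  for (id in names(built$stoichiometry)) {
    s <- built$stoichiometry[[id]]
    key <- sub("^MACRO_", "", id)
    if (key == "soluble_pool") next
    consumed <- s[s < 0]
    inMass <- sum(vapply(names(consumed), mono, numeric(1)) *
                  abs(consumed))
    water <- if ("h2o" %in% names(s)) s[["h2o"]] else 0
    expect_equal(inMass, built$molarMasses[[key]] * 1000 +
                 water * 18.015, tolerance = 1e-6)
  }
  ## unknown monomer is reported by name
  badFile <- tempfile(fileext = ".tsv")
  writeLines(c("monomer\tmole_fraction", "unobtainium\t1"), badFile)
  expect_error(
    buildMacromoleculeReactions(compositionFixture(aminoAcidFile = badFile)),
    "unobtainium")
})

test_that("printed mass-fraction/coefficient pairs round-trip through the conversion", {
  comp <- compositionFixture()
  df <- comp$massFractions
  ## implied molar mass from each printed pair (subset-adjusted), then the
  ## conversion must reproduce the printed coefficients exactly
  for (column in c("N2", "KNO3")) {
    mf <- stats::setNames(df[[paste0("mass_fraction_", column)]],
                          df$macromolecule)
    cf <- stats::setNames(df[[paste0("coefficient_", column)]],
                          df$macromolecule)
    adj <- mf
    for (k in df$macromolecule[!is.na(df$subset_of)])
      adj[df$subset_of[df$macromolecule == k]] <-
        adj[df$subset_of[df$macromolecule == k]] - mf[k]
    molar <- adj / cf
    eq <- compositionToCoefficients(comp, molar, column = column)
    expect_equal(unname(eq$coefficients[names(cf)]), unname(cf),
                 tolerance = 1e-12)
  }
  ## the carbohydrate row of the reference composition:
  ## 0.265 g/g at its molar mass gives the printed 4.59e-1 mmol/g
  molarN2 <- stats::setNames(df$mass_fraction_N2 / df$coefficient_N2,
                             df$macromolecule)
  molarN2["protein"] <- (df$mass_fraction_N2[df$macromolecule == "protein"] -
    sum(df$mass_fraction_N2[df$subset_of %in% "protein"], na.rm = TRUE)) /
    df$coefficient_N2[df$macromolecule == "protein"]
  molarN2["lipids"] <- (df$mass_fraction_N2[df$macromolecule == "lipids"] -
    sum(df$mass_fraction_N2[df$subset_of %in% "lipids"], na.rm = TRUE)) /
    df$coefficient_N2[df$macromolecule == "lipids"]
  eq <- compositionToCoefficients(comp, molarN2, column = "N2")
  expect_equal(eq$coefficients[["carbohydrate"]], 4.59e-1,
               tolerance = 1e-9)
  expect_equal(eq$coefficients[["dna"]], 1.39e-3, tolerance = 1e-9)
  ## zero mass fraction maps to zero coefficient
  comp0 <- comp
  comp0$massFractions$mass_fraction_N2[
    comp0$massFractions$macromolecule == "dna"] <- 0
  eq0 <- compositionToCoefficients(comp0, molarN2, column = "N2")
  expect_identical(eq0$coefficients[["dna"]], 0)
})

test_that("subset subtraction, totals and round-trip mass closure behave", {
  comp <- compositionFixture()
  built <- buildMacromoleculeReactions(comp)
  eq <- compositionToCoefficients(comp, built$molarMasses)
  ## coefficients times molar masses recover the adjusted fractions exactly
  expect_equal(unname(eq$coefficients *
                      built$molarMasses[names(eq$coefficients)]),
               unname(eq$adjustedMassFractions), tolerance = 1e-12)
  ## both column totals are reported, differing by the subset rows
  tot <- compositionTotals(comp, "N2")
  subSum <- sum(comp$massFractions$mass_fraction_N2[
    !is.na(comp$massFractions$subset_of)])
  expect_equal(tot$includingSubsets - tot$excludingSubsets, subSum)
  ## over-large subset drives its parent negative -> error
  bad <- comp
  bad$massFractions$mass_fraction_N2[
    bad$massFractions$macromolecule == "cyanophycin"] <- 0.5
  expect_error(compositionToCoefficients(bad, built$molarMasses),
               "below zero")
  ## normalization closes the mass balance at 1 g/g
  eqN <- compositionToCoefficients(comp, built$molarMasses,
                                   normalize = TRUE)
  expect_equal(sum(eqN$adjustedMassFractions), 1, tolerance = 1e-12)
})

test_that("the biomass reaction carries the coefficients and GAM ATP", {
  comp <- compositionFixture()
  built <- buildMacromoleculeReactions(comp)
  eq <- compositionToCoefficients(comp, built$molarMasses)
  rx <- assembleBiomassReaction(eq)
  expect_identical(rx$reaction$category, "biomass")
  expect_equal(rx$stoichiometry[["atp"]], -544)
  expect_equal(rx$stoichiometry[["adp"]], 544)
  expect_equal(rx$stoichiometry[["carbohydrate"]],
               -eq$coefficients[["carbohydrate"]])
  ## empty equation is an error
  eqEmpty <- eq; eqEmpty$coefficients[] <- 0
  expect_error(assembleBiomassReaction(eqEmpty), "empty")
  ## two-macromolecule equation: two substrate terms plus the ATP set
  eq2 <- structure(list(coefficients = c(protein = 0.2, lipid = 0.1),
                        gam = 40), class = "BiomassEquation")
  rx2 <- assembleBiomassReaction(eq2)
  expect_setequal(names(rx2$stoichiometry),
                  c("protein", "lipid", "atp", "h2o", "adp", "pi", "h"))
})

test_that("raising GAM monotonically depresses predicted growth", {
  mus <- vapply(c(30, 60, 120), function(g) {
    toy <- makeToyModel(toyNetworkParams(gamAtp = g))
    pa <- applyCellType(toy$model, unconstrainedVariant(toy$photoautotroph))
    objectiveValue(solveFBA(pa, "BIOMASS"))
  }, numeric(1))
  expect_true(all(diff(mus) < 0))
})
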