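test_that("cell-type overrides pin the defining bounds", {
  toy <- toyFixture()
  dz <- toyStrictDZ(); pa <- toyStrictPA()
  expect_equal(unname(bounds(dz, "PSII")), c(0, 0), ignore_attr = TRUE)
  expect_equal(unname(bounds(dz, "NITROGENASE")), c(0.132, 0.132),
               ignore_attr = TRUE)
  expect_equal(unname(bounds(dz, "EX_glyc")), c(-0.927 / 6, 0),
               ignore_attr = TRUE)
  expect_equal(unname(bounds(pa, "EX_co2")), c(-0.927, -0.927),
               ignore_attr = TRUE)
  expect_equal(unname(bounds(pa, "NITROGENASE")), c(0, 0),
               ignore_attr = TRUE)
  expect_equal(bounds(pa, "EN_ATP")[1, "lower"],
               toy$photoautotroph@maintenanceAtp, ignore_attr = TRUE)
  ## photon budget on the shared exchange
  expect_equal(bounds(dz, "EX_photon")[1, "lower"], -80,
               ignore_attr = TRUE)
  ## idempotent
  again <- applyCellType(dz, toy$diazotroph)
  expect_identical(reactions(again), reactions(dz))
  ## absent reaction id is an error
  badCT <- toy$diazotroph
  badCT@ids$psii <- "NOPE"
  expect_error(applyCellType(toy$model, badCT), "NOPE")
})

test_that("published constraint defaults are carried by the constructor", {
  ids <- toyFixture()$diazotroph@ids
  dz <- cellTypeConstraints("diazotroph", ids = ids)
  pa <- cellTypeConstraints("photoautotroph", ids = ids)
  expect_equal(dz@nitrogenaseFlux, 0.132)
  expect_equal(dz@maintenanceAtp, 67.2)
  expect_equal(pa@maintenanceAtp, 64.3)
  expect_equal(pa@nitrogenaseFlux, 0)
  expect_equal(dz@psiiUpper, 0)
  expect_equal(dz@photonBudget, 80)
  expect_equal(dz@carbonUptake, 0.927)
  ## the alternative printed nitrogenase value is selectable
  dz2 <- cellTypeConstraints("diazotroph", ids = ids,
                             nitrogenaseFlux = 0.206)
  expect_equal(dz2@nitrogenaseFlux, 0.206)
  ## invariant: a strict photoautotroph cannot carry nitrogenase flux
  expect_error(cellTypeConstraints("photoautotroph", ids = ids,
                                   nitrogenaseFlux = 0.1),
               "nitrogenase")
})

test_that("feasible solutions respect the phenotype-defining fluxes", {
  dz <- toyStrictDZ(); pa <- toyStrictPA()
  ## diazotroph: PSII zero and nitrogenase pinned in every solution
  fvaDZ <- runFVA(dz, reactions = c("PSII", "NITROGENASE"),
                  objective = "BIOMASS")
  expect_equal(fvaDZ$min, c(0, 0.132), tolerance = 1e-9)
  expect_equal(fvaDZ$max, c(0, 0.132), tolerance = 1e-9)
  ## photoautotroph: no nitrogen fixation possible
  fvaPA <- runFVA(pa, reactions = "NITROGENASE", objective = "BIOMASS")
  expect_equal(c(fvaPA$min, fvaPA$max), c(0, 0), tolerance = 1e-12)
  ## photon budget: total photon draw can never exceed 80
  for (m in list(dz, pa)) {
    photon <- runFVA(m, reactions = "EX_photon", objective = "BIOMASS",
                     fractionOfOptimum = 0)
    expect_gte(photon$min, -80 - 1e-9)
    expect_lte(photon$max, 0 + 1e-9)
  }
})

test_that("the nutrient-unlimited variant releases the right bounds", {
  toy <- toyFixture()
  paR <- toyRelaxedPA(); dzR <- toyRelaxedDZ()
  expect_equal(unname(bounds(paR, "EX_nh4")), c(-1000, 0),
               ignore_attr = TRUE)
  expect_equal(unname(bounds(paR, "EX_co2")), c(-1000, 0),
               ignore_attr = TRUE)
  expect_equal(unname(bounds(dzR, "EX_glyc")), c(-1000, 0),
               ignore_attr = TRUE)
  expect_equal(unname(bounds(dzR, "NITROGENASE")), c(0, 1000),
               ignore_attr = TRUE)
  ## relaxing an already-relaxed set changes nothing
  ct <- unconstrainedVariant(toy$photoautotroph)
  expect_identical(unconstrainedVariant(ct), ct)
  ## independent optima: both types grow faster than the coupled population
  muPA <- objectiveValue(solveFBA(paR, "BIOMASS"))
  muDZ <- objectiveValue(solveFBA(dzR, "BIOMASS"))
  expect_gt(muPA, 0)
  expect_gt(muDZ, 0)
})
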