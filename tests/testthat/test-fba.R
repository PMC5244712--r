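test_that("FBA honors the steady state and matches the vertex oracle", {
  ## handcrafted 6-reaction energy chain: photons -> ATP -> product drain
  fix <- MetabolicModel(
    data.frame(id = c("hv", "atp", "adp", "p")),
    data.frame(id = c("EX_hv", "PS", "MK", "BIO", "EX_p", "MAINT"),
               lower = c(-10, 0, 0, 0, 0, 2), upper = 1000,
               category = c("exchange", rep("metabolic", 3),
                            "exchange", "metabolic")),
    list(EX_hv = c(hv = -1),
         PS = c(hv = -2, adp = -1, atp = 1),
         MK = c(atp = -3, adp = 3, p = 1),
         BIO = c(p = -1),
         EX_p = c(p = -1),
         MAINT = c(atp = -1, adp = 1)))
  sol <- solveFBA(fix, "BIO")
  expect_identical(solutionStatus(sol), "optimal")
  rxn <- reactions(fix)
  want <- enumerateVertexOptimum(
    as.numeric(rxn$id == "BIO"), as.matrix(stoichiometry(fix)),
    lower = rxn$lower, upper = rxn$upper)
  expect_equal(objectiveValue(sol), want$value, tolerance = 1e-8)
  ## photons are the only energy source: closing them kills the optimum
  dark <- fix; bounds(dark, "EX_hv") <- c(0, 0)
  expect_error(solveFBA(dark, "BIO"), NA)
  expect_identical(solutionStatus(solveFBA(dark, "BIO")), "infeasible")
  ## (maintenance still demands ATP, which nothing can regenerate)
  relaxed <- dark; bounds(relaxed, "MAINT") <- c(0, 1000)
  expect_equal(objectiveValue(solveFBA(relaxed, "BIO")), 0)
})

test_that("toy submodel optima satisfy mass balance to solver tolerance", {
  pa <- toyStrictPA(); dz <- toyStrictDZ()
  for (m in list(pa, dz, toyRelaxedPA(), toyRelaxedDZ())) {
    sol <- solveFBA(m, "BIOMASS")
    expect_identical(solutionStatus(sol), "optimal")
    expect_lte(massBalanceResidual(m, sol), 1e-9)
    ## re-evaluating the objective from the flux vector matches
    expect_equal(fluxes(sol)[["BIOMASS"]], objectiveValue(sol),
                 tolerance = 1e-12)
  }
  ## infeasibility is propagated, never silently zeroed
  pa200 <- pa
  bounds(pa200, "EN_ATP") <- c(200, 1000)
  expect_identical(solutionStatus(solveFBA(pa200, "BIOMASS")),
                   "infeasible")
  ## diazotroph ammonium export is positive at the strict optimum
  expect_gt(fluxes(solveFBA(dz, "BIOMASS"))[["EX_nh4"]], 0)
})

test_that("FVA envelopes bound the FBA solution and pin fixed reactions", {
  dz <- toyStrictDZ()
  sol <- solveFBA(dz, "BIOMASS")
  ids <- c("OPP", "RESP", "GLYDEG", "T_NH4", "NITROGENASE")
  fva <- runFVA(dz, reactions = ids, objective = "BIOMASS")
  expect_true(all(fva$min <= fva$max + 1e-12))
  v <- fluxes(sol)[ids]
  expect_true(all(v >= fva$min - 1e-6 & v <= fva$max + 1e-6))
  ## fixed-bound reaction has a width-zero interval
  nit <- fva[fva$id == "NITROGENASE", ]
  expect_equal(nit$max - nit$min, 0, tolerance = 1e-9)
  ## envelope property: pinning any reaction at its FVA extremes
  ## preserves the optimum at fraction 1.0
  opt <- objectiveValue(sol)
  for (k in seq_along(ids)) {
    for (val in c(fva$min[k], fva$max[k])) {
      pinned <- dz
      bounds(pinned, ids[k]) <- c(val - 1e-8, val + 1e-8)
      solP <- solveFBA(pinned, "BIOMASS")
      expect_equal(objectiveValue(solP), opt, tolerance = 1e-5)
    }
  }
})

test_that("maintenance calibration recovers targets by bisection", {
  pa <- toyRelaxedPA()
  ## photon-limited growth is linear in the maintenance demand: the
  ## analytic intercept from two FBA evaluations is the oracle
  g <- function(m) {
    mod <- pa; bounds(mod, "EN_ATP") <- c(m, 1000)
    objectiveValue(solveFBA(mod, "BIOMASS"))
  }
  m1 <- 10; m2 <- 20
  target <- 0.0146
  slope <- (g(m2) - g(m1)) / (m2 - m1)
  mStar <- m1 + (target - g(m1)) / slope
  cal <- calibrateMaintenance(pa, "BIOMASS", "EN_ATP", target,
                              bracket = c(0, 100))
  expect_lt(abs(cal$growth - target), 1e-6)
  expect_lt(abs(cal$maintenance - mStar), 1e-3)
  ## confirmed by a fresh FBA at the calibrated bound
  expect_lt(abs(g(cal$maintenance) - target), 1e-6)
  ## unreachable target reports the achievable range
  expect_error(calibrateMaintenance(pa, "BIOMASS", "EN_ATP", 10,
                                    bracket = c(0, 100)),
               "achievable range")
})

test_that("gene and reaction knockouts classify essentiality coherently", {
  dz <- toyStrictDZ()
  wt <- objectiveValue(solveFBA(dz, "BIOMASS"))
  ## a gene absent from every GPR leaves growth unchanged
  ghost <- essentiality(dz, "BIOMASS", mode = "gene", targets = "ghost")
  expect_equal(ghost$growth, wt, tolerance = 1e-9)
  expect_identical(ghost$class, "neutral")
  ## nitrogenase loss is lethal for the diazotroph (sole N source);
  ## gene and reaction knockouts agree
  kg <- essentiality(dz, "BIOMASS", mode = "gene", targets = "nifH")
  kr <- essentiality(dz, "BIOMASS", mode = "reaction",
                     targets = "NITROGENASE")
  expect_identical(kg$class, "essential")
  expect_identical(kr$class, "essential")
  ## isozymes: losing one respiratory gene leaves the reaction available
  k1 <- essentiality(dz, "BIOMASS", mode = "gene", targets = "cox1")
  expect_equal(k1$growth, wt, tolerance = 1e-9)
  ## complex subunits are individually lethal where the pathway is
  ## required: PSII and RuBisCO in the photoautotroph
  pa <- toyStrictPA()
  kpa <- essentiality(pa, "BIOMASS", mode = "gene",
                      targets = c("psbA", "rbcL", "glgA"))
  expect_identical(kpa$class, c("essential", "essential", "neutral"))
  ## no deletion can outgrow the wild type
  all <- essentiality(dz, "BIOMASS", mode = "gene")
  expect_true(all(all$growth <= wt + 1e-8))
  ## a reaction whose FVA interval excludes zero cannot be neutral
  fva <- runFVA(dz, reactions = "NITROGENASE", objective = "BIOMASS")
  stopifnot(fva$min > 1e-9 || fva$max < -1e-9)
  expect_true(kr$class %in% c("essential", "growth-reducing"))
})
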