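test_that("supply requirements follow the predictive arithmetic", {
  X <- c(DZ = 0.2, PA = 0.5)
  ## no prior consumption -> nothing forced
  expect_identical(requiredGlycogenSupply(NULL, 0, X), 0)
  expect_identical(requiredGlycogenSupply(0, 0.5, X), 0)
  ## zero growth -> exactly last step's consumption, biomass-ratio scaled
  expect_equal(requiredGlycogenSupply(-0.05, 0, X), 0.05 * 0.2 / 0.5)
  ## hand evaluation of the predictive factor
  expect_equal(requiredGlycogenSupply(-0.05, 0.02, X, dt = 2),
               (0.02 * 2 + 1) * 0.05 * 0.2 / 0.5)
  expect_equal(requiredAmmoniumSupply(-0.1, 0.03, X, dt = 1),
               (0.03 + 1) * 0.1 * 0.5 / 0.2)
  ## six carbons per glycogen unit in the uptake cap
  expect_equal(glycogenUptakeCap(-0.927, 0.5), 0.927 / (6 * 0.5))
  expect_identical(glycogenUptakeCap(0, 0.5), 0)
  expect_identical(glycogenUptakeCap(-1, 0), 0)
})

test_that("step operations couple the two phenotypes as specified", {
  toy <- toyFixture()
  ids <- toy$diazotroph@ids
  X <- c(DZ = 4e-4, PA = 6e-4)
  C <- c(glycogen = 1, nh4 = 1)
  ## photoautotroph covers the forced export when feasible
  pa <- stepPhotoautotroph(toyRelaxedPA(), ids, X, C,
                           prev = list(vGlyDZ = -0.03, muDZ = 0.01))
  expect_true(pa$feasible)
  expect_equal(pa$required, (0.01 + 1) * 0.03 * X[["DZ"]] / X[["PA"]])
  expect_equal(pa$supplied, pa$required, tolerance = 1e-9)
  expect_gte(pa$vGly, pa$required - 1e-9)
  ## no photoautotroph carbon -> diazotroph glycogen cap and growth zero
  dz0 <- stepDiazotroph(toyRelaxedDZ(), ids, X, C,
                        paStep = list(vCO2 = 0, vGly = 0, vNH4 = 0,
                                      nh4Demand = 0, mu = 0,
                                      muDemand = 0),
                        fDZ = 0.4)
  expect_equal(dz0$mu, 0, tolerance = 1e-9)
  expect_equal(dz0$vGly, 0, tolerance = 1e-9)
  ## with carbon available the diazotroph exports ammonium on demand
  dz <- stepDiazotroph(toyRelaxedDZ(), ids, X, C,
                       paStep = c(pa, list()), fDZ = 0.4)
  expect_true(dz$feasible)
  expect_gt(dz$vNH4, 0)
})

test_that("allocation redistributes increments in proportion to shortage", {
  X0 <- c(DZ = 1, PA = 2)
  dX <- c(DZ = 0.1, PA = 0.2)
  XfP <- X0 + dX
  ## production 6, consumption -10 (with Xf'.dt scaling folded in):
  ## alpha = (6 - 10)/(-10) = 0.4, pool = 0.4 x consumer increment
  al <- allocateDifferentiation(
    dX, list(glycogen = c(DZ = -10 / XfP[["DZ"]], PA = 6 / XfP[["PA"]])),
    XfP, X0)
  rec <- al$records
  expect_equal(rec$alpha, 0.4)
  expect_equal(rec$Xdelta, 0.4 * dX[["DZ"]])
  expect_identical(rec$from, "DZ"); expect_identical(rec$to, "PA")
  ## single consumer: sigma = 1
  expect_equal(rec$sigmaFrom, 1)
  ## conservation: allocation neither creates nor destroys biomass
  expect_equal(sum(al$Xf), sum(X0) + sum(dX), tolerance = 1e-15)
  ## surplus-only period: the whole diazotroph increment goes to the
  ## photoautotroph
  alS <- allocateDifferentiation(
    dX, list(glycogen = c(DZ = -1, PA = 2), nh4 = c(DZ = 2, PA = -1)),
    XfP, X0)
  expect_identical(alS$records$metabolite, "surplus")
  expect_equal(alS$Xf[["DZ"]], X0[["DZ"]])
  expect_equal(alS$Xf[["PA"]], X0[["PA"]] + sum(dX))
  ## zero consumption total: no allocation for that metabolite
  alZ <- allocateDifferentiation(
    dX, list(glycogen = c(DZ = 0, PA = 1)), XfP, X0)
  expect_true(!"glycogen" %in% alZ$records$metabolite)
  ## a missing cell type is never bootstrapped from nothing
  alB <- allocateDifferentiation(
    c(DZ = 0, PA = 0.2), list(nh4 = c(DZ = 0, PA = -1)),
    c(DZ = 0, PA = 2.2), c(DZ = 0, PA = 2))
  expect_identical(alB$Xf[["DZ"]], 0)
})

test_that("population bookkeeping is exact along a long run", {
  tr <- toyTrace()
  st <- traceStates(tr)
  expect_identical(traceStatus(tr), "completed")
  ## strictly increasing time
  expect_true(all(diff(st$t) > 0))
  ## biomass conservation: each step's totals equal the batch-reactor
  ## update of the previous step (allocation only redistributes)
  X0dz <- c(tr@params$inoculum[["DZ"]], head(st$X_DZ, -1))
  X0pa <- c(tr@params$inoculum[["PA"]], head(st$X_PA, -1))
  expXf <- X0dz * exp(st$mu_DZ) + X0pa * exp(st$mu_PA)
  expect_equal(st$X_DZ + st$X_PA, expXf, tolerance = 1e-12)
  ## medium mass balance holds exactly, including grace borrowing
  C0g <- c(tr@params$seeds[["glycogen"]], head(st$C_glycogen, -1))
  expect_equal(st$C_glycogen,
               pmax(0, C0g + st$gly_produced - st$gly_consumed),
               tolerance = 1e-12)
  C0n <- c(tr@params$seeds[["nh4"]], head(st$C_NH4, -1))
  expect_equal(st$C_NH4, pmax(0, C0n + st$nh4_produced - st$nh4_consumed),
               tolerance = 1e-12)
  expect_true(all(st$C_glycogen >= 0 & st$C_NH4 >= 0))
  ## fractions partition the population
  expect_true(all(abs(st$f_DZ - st$X_DZ / (st$X_DZ + st$X_PA)) < 1e-12))
  ## sigma normalization on every allocation record
  al <- traceAllocations(tr)
  expect_true(all(abs(al$sigmaFrom - 1) < 1e-12))
  expect_true(all(abs(al$sigmaTo - 1) < 1e-12))
  ## metrics identity: exp(sum mu_t dt) recovers the biomass ratio
  expect_equal(exp(sum(st$mu_t)),
               (st$X_DZ[nrow(st)] + st$X_PA[nrow(st)]) /
                 sum(tr@params$inoculum), tolerance = 1e-9)
})

test_that("single-type and zero-energy populations die right after the grace window", {
  toy <- toyFixture()
  for (inoc in list(c(DZ = 1e-3, PA = 0), c(DZ = 0, PA = 1e-3))) {
    tr <- simulatePopulation(toy, inoc, horizon = 30)
    expect_identical(traceStatus(tr), "died")
    expect_identical(nrow(traceStates(tr)), 4L)   # grace + 1
  }
  dark <- makeToyModel()
  dark$diazotroph@photonBudget <- 0
  dark$photoautotroph@photonBudget <- 0
  tr <- simulatePopulation(dark, c(DZ = 5e-4, PA = 5e-4), horizon = 30)
  expect_identical(traceStatus(tr), "died")
  expect_identical(nrow(traceStates(tr)), 4L)
  ## a different grace length moves the death step accordingly
  tr5 <- simulatePopulation(dark, c(DZ = 5e-4, PA = 5e-4), horizon = 30,
                            grace = 5)
  expect_identical(nrow(traceStates(tr5)), 6L)
})

test_that("metrics identities hold on a hand-checked three-step trace", {
  states <- data.frame(
    t = 1:3,
    X_DZ = c(0.11, 0.121, 0.1331), X_PA = c(0.11, 0.121, 0.1331),
    f_DZ = 0.5,
    C_glycogen = 0, C_NH4 = c(0.02, 0.05, 0.09),
    mu_t = log(1.1), mu_PA = log(1.1), mu_DZ = log(1.1),
    nh4_produced = c(0.1, 0.12, 0.14), nh4_consumed = 0,
    gly_produced = 0, gly_consumed = 0,
    borrowed_gly = 0, borrowed_nh4 = 0, fail = FALSE)
  tr <- new("PopulationTrace", states = states,
            allocations = data.frame(), status = "completed",
            params = list(inoculum = c(DZ = 0.1, PA = 0.1), dt = 1,
                          seeds = c(glycogen = 0, nh4 = 0.01)))
  mt <- computeMetrics(tr)
  ## total growth: ln(0.2662/0.2)/3 h^-1, by hand
  expect_equal(mt$muTotal, log(0.2662 / 0.2) / 3, tolerance = 1e-12)
  ## nitrogen release: (0.09 - 0.01) accumulated over 0.36 produced
  expect_equal(mt$YNEnv, 0.08 / 0.36, tolerance = 1e-12)
  expect_equal(mt$equilibriumFDZ, 0.5)
  ## doubling-time identity at the measured growth rate
  expect_equal(log(2) / 0.0146, 47.5, tolerance = 1e-3)
  tr2 <- tr
  tr2@states$C_NH4 <- c(0.01, 0.01, 0.01)
  expect_equal(computeMetrics(tr2)$YNEnv, 0)
})

test_that("ensembles are seed-deterministic and code death as zero release", {
  toy <- toyFixture()
  e1 <- runEnsemble(toy, n = 2, horizon = 40, seed = 11)
  e2 <- runEnsemble(toy, n = 2, horizon = 40, seed = 11)
  expect_identical(e1, e2)
  expect_identical(nrow(e1), 2L)
  tr <- simulatePopulation(toy, c(DZ = 1e-3, PA = 0), horizon = 40)
  mt <- computeMetrics(tr)
  expect_identical(mt$status, "died")
  expect_identical(mt$YNEnv, 0)
})

test_that("an ammonium-replete medium lifts growth above the baseline", {
  toy <- toyFixture()
  eqF <- 0.17
  inoc <- c(DZ = eqF, PA = 1 - eqF) * 1e-3
  base <- nitrogenSourceScenario(toy, "N2", inoculum = inoc,
                                 horizon = 120)
  rich <- nitrogenSourceScenario(toy, "NH4", inoculum = inoc,
                                 horizon = 120)
  expect_gt(rich$muTotal, base$muTotal)
  ## the baseline scenario is the plain simulation, unchanged
  plain <- simulatePopulation(toy, inoc, horizon = 120)
  expect_equal(traceStates(base$trace), traceStates(plain))
  ## a source the network cannot exchange is an error
  expect_error(nitrogenSourceScenario(toy, "urea"), "arg")
})

test_that("diffusion transporters graft cleanly onto a model", {
  toy <- toyFixture()
  ext <- addDiffusionTransporter(toy$model, "nh4_c")
  st <- modelStatistics(ext)
  expect_identical(st$reactions, modelStatistics(toy$model)$reactions + 2L)
  expect_identical(nrow(checkBalances(ext)), 0L)
  ## active (urea-style) transport consumes ATP
  extA <- addDiffusionTransporter(toy$model, "glc", atpCost = 1)
  s <- stoichiometry(extA)[, "T_glc_diff"]
  expect_equal(s[["atp"]], -1)
  expect_equal(bounds(extA, "T_glc_diff")[1, "lower"], 0,
               ignore_attr = TRUE)
})
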