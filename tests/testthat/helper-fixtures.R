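## Shared fixtures, computed once per test run and cached.

.fixtureCache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixtureCache))
    assign(key, force(expr), envir = .fixtureCache)
  get(key, envir = .fixtureCache)
}

toyFixture <- function() cached("toy", makeToyModel())

## brute-force equilibrium at the full reference resolution
toyEquilibrium <- function()
  cached("oracle", analyticEquilibrium(toyFixture(), step = 1e-4))

## one long reference run from a 50:50 inoculum
toyTrace <- function()
  cached("trace5050",
         simulatePopulation(toyFixture(), c(DZ = 5e-4, PA = 5e-4),
                            horizon = 400))

toyStrictPA <- function()
  cached("strictPA",
         applyCellType(toyFixture()$model, toyFixture()$photoautotroph))

toyStrictDZ <- function()
  cached("strictDZ",
         applyCellType(toyFixture()$model, toyFixture()$diazotroph))

toyRelaxedPA <- function()
  cached("relaxedPA",
         applyCellType(toyFixture()$model,
                       unconstrainedVariant(toyFixture()$photoautotroph)))

toyRelaxedDZ <- function()
  cached("relaxedDZ",
         applyCellType(toyFixture()$model,
                       unconstrainedVariant(toyFixture()$diazotroph)))

## a minimal hand-built model: one exchange feeding a conversion chain
miniModel <- function(formulaB = "H2O") {
  MetabolicModel(
    data.frame(id = c("a", "b"),
               formula = c("H2O", formulaB),
               charge = 0L),
    data.frame(id = c("EX_a", "R1", "EX_b"),
               lower = c(-1000, 0, 0), upper = 1000,
               category = c("exchange", "metabolic", "exchange")),
    list(EX_a = c(a = -1), R1 = c(a = -1, b = 1), EX_b = c(b = -1)))
}
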