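test_that("models are constructed and validated from minimal listings", {
  mod <- miniModel()
  expect_s4_class(mod, "MetabolicModel")
  expect_identical(dim(stoichiometry(mod)), c(2L, 3L))
  ## undeclared metabolite names the offending reaction
  expect_error(
    MetabolicModel(data.frame(id = "a"),
                   data.frame(id = c("EX_a", "R1"), lower = 0, upper = 1,
                              category = c("exchange", "metabolic")),
                   list(EX_a = c(a = -1), R1 = c(a = -1, ghost = 1))),
    "R1.*ghost")
  ## conflicting bounds rejected
  expect_error(
    MetabolicModel(data.frame(id = "a"),
                   data.frame(id = "EX_a", lower = 5, upper = 1,
                              category = "exchange"),
                   list(EX_a = c(a = -1))),
    "lower bound")
  ## exchange reactions must touch exactly one metabolite
  expect_error(
    MetabolicModel(data.frame(id = c("a", "b")),
                   data.frame(id = "EX_bad", lower = -1, upper = 1,
                              category = "exchange"),
                   list(EX_bad = c(a = -1, b = 1))),
    "exchange")
})

test_that("statistics partition reactions by category", {
  toy <- toyFixture()
  st <- modelStatistics(toy$model)
  expect_identical(sum(st$byCategory), st$reactions)
  expect_identical(st$byCategory[names(toy$composition)],
                   toy$composition)
  ## empty model reports zeros
  empty <- MetabolicModel(data.frame(id = character(0)),
                          data.frame(id = character(0),
                                     lower = numeric(0),
                                     upper = numeric(0),
                                     category = character(0)),
                          list())
  stE <- modelStatistics(empty)
  expect_identical(stE$reactions, 0L)
  expect_true(all(stE$byCategory == 0L))
})

test_that("tabular dialect round-trips bit-stably including the 1000 sentinel", {
  toy <- toyFixture()
  rf <- tempfile(fileext = ".tsv"); mf <- tempfile(fileext = ".tsv")
  writeModelTable(toy$model, rf, mf)
  back <- readModelTable(rf, mf)
  expect_identical(reactions(back)$id, reactions(toy$model)$id)
  expect_identical(bounds(back), bounds(toy$model))
  expect_true(all(abs(bounds(back)[, "upper"]) <= 1000))
  expect_equal(as.matrix(stoichiometry(back)),
               as.matrix(stoichiometry(toy$model)))
  expect_identical(modelGenes(back), modelGenes(toy$model))
  ## loadModel dispatches on extension
  expect_identical(reactions(loadModel(rf, mf))$id,
                   reactions(toy$model)$id)
  ## duplicate reaction id rejected at parse time
  tab <- utils::read.delim(rf)
  utils::write.table(rbind(tab, tab[1, ]), rf, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  expect_error(readModelTable(rf, mf), "duplicate")
})

test_that("SBML round-trip preserves structure, bounds and GPR semantics", {
  toy <- toyFixture()
  f <- tempfile(fileext = ".xml")
  writeSBMLModel(toy$model, f)
  back <- readSBMLModel(f)
  expect_identical(reactions(back)$id, reactions(toy$model)$id)
  expect_equal(bounds(back), bounds(toy$model))
  expect_equal(as.matrix(stoichiometry(back)),
               as.matrix(stoichiometry(toy$model)))
  expect_identical(reactions(back)$category, reactions(toy$model)$category)
  expect_identical(sort(modelGenes(back)), sort(modelGenes(toy$model)))
  ## boolean semantics survive the and/or nesting
  for (g in c("psaA", "cox1", "nifD"))
    for (j in seq_len(nrow(reactions(back))))
      expect_identical(evalGPR(reactions(back)$gpr[j], g),
                       evalGPR(reactions(toy$model)$gpr[j], g))
})

test_that("element/charge balance flags exactly the broken reaction", {
  expect_identical(nrow(checkBalances(miniModel())), 0L)
  broken <- miniModel(formulaB = "HO")      # product lost one hydrogen
  bal <- checkBalances(broken)
  expect_identical(bal$id, "R1")
  expect_identical(bal$status, "unbalanced")
  expect_equal(bal$imbalance[[1]][["H"]], -1)
  ## unknown formula -> uncheckable, not unbalanced
  unk <- miniModel(formulaB = NA)
  bal <- checkBalances(unk)
  expect_identical(bal$status, "uncheckable")
  ## the generated toy network is clean by construction
  expect_identical(nrow(checkBalances(toyFixture()$model)), 0L)
})

test_that("directional dead ends and stranded reactions are reported", {
  ## linear chain a -> b -> c with no exit for c
  chain <- MetabolicModel(
    data.frame(id = c("a", "b", "cc")),
    data.frame(id = c("EX_a", "R1", "R2"),
               lower = c(-1000, 0, 0), upper = 1000,
               category = c("exchange", "metabolic", "metabolic")),
    list(EX_a = c(a = -1), R1 = c(a = -1, b = 1), R2 = c(b = -1, cc = 1)))
  de <- findDeadEnds(chain)
  expect_identical(de$metabolites, "cc")
  expect_true("R2" %in% de$reactions)
  ## iterative closure also strands the upstream step
  deIter <- findDeadEnds(chain, iterative = TRUE)
  expect_true(all(c("R1", "R2") %in% deIter$reactions))
  ## fully connected toy network has none
  deToy <- findDeadEnds(toyFixture()$model)
  expect_length(deToy$metabolites, 0)
  expect_length(deToy$reactions, 0)
})

test_that("closed-exchange FVA detects a textbook type-III loop", {
  loop <- MetabolicModel(
    data.frame(id = c("a", "b")),
    data.frame(id = c("EX_a", "F1", "F2"),
               lower = c(-1000, -1000, -1000), upper = 1000,
               category = c("exchange", "metabolic", "metabolic")),
    list(EX_a = c(a = -1), F1 = c(a = -1, b = 1), F2 = c(b = -1, a = 1)))
  expect_setequal(detectFutileCycles(loop), c("F1", "F2"))
  ## the toy network carries no internal loop
  expect_length(detectFutileCycles(toyFixture()$model), 0)
  ## fixed nonzero internal bound: infeasible when closed -> warning
  pinned <- miniModel()
  bounds(pinned, "R1") <- c(1, 1)
  expect_warning(out <- detectFutileCycles(pinned), "infeasible")
  expect_length(out, 0)
})
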