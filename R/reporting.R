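## Run configuration, validation/simulation commands and report writers.
## These functions back the thin command-line front end shipped under
## inst/scripts/trichofba.R.

#' Read and validate a run configuration
#'
#' YAML with blocks \code{model} (either \code{type: toy} with optional
#' \code{params}, or \code{type: tabular} with \code{reactions} and
#' \code{metabolites} paths, or \code{type: sbml} with \code{path}),
#' \code{dfba} (\code{horizon}, \code{dt}, \code{grace}, \code{seed},
#' \code{inoculum: \{DZ, PA\}}, \code{n_ensemble}) and \code{output}
#' (directory).
#'
#' @param path YAML file path.
#' @return validated config list of class \code{"RunConfig"}.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$model$type <- cfg$model$type %||% "toy"
  if (cfg$model$type == "tabular") {
    for (f in c("reactions", "metabolites"))
      if (is.null(cfg$model[[f]]) || !file.exists(cfg$model[[f]]))
        stop("config model$", f, " missing or not found")
  } else if (cfg$model$type == "sbml") {
    if (is.null(cfg$model$path) || !file.exists(cfg$model$path))
      stop("config model$path missing or not found")
  } else if (cfg$model$type != "toy")
    stop("unknown model type: ", cfg$model$type)
  cfg$dfba$horizon <- cfg$dfba$horizon %||% 400
  cfg$dfba$dt <- cfg$dfba$dt %||% 1
  if (cfg$dfba$dt <= 0) stop("dt must be > 0")
  cfg$dfba$grace <- cfg$dfba$grace %||% 3
  cfg$output <- cfg$output %||% "."
  class(cfg) <- c("RunConfig", class(cfg))
  cfg
}

.configModel <- function(cfg) {
  if (cfg$model$type == "toy") {
    p <- do.call(toyNetworkParams, cfg$model$params %||% list())
    makeToyModel(p)
  } else if (cfg$model$type == "tabular") {
    list(model = readModelTable(cfg$model$reactions,
                                cfg$model$metabolites))
  } else list(model = readSBMLModel(cfg$model$path))
}

#' Write a model summary report
#'
#' Structural statistics plus balance, dead-end and futile-cycle screens,
#' as a JSON summary and delimited detail tables.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param dir output directory (created if needed).
#' @return invisibly, the summary list.
#' @export
writeModelReport <- function(model, dir = ".") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  st <- modelStatistics(model)
  bal <- checkBalances(model)
  de <- findDeadEnds(model)
  fc <- detectFutileCycles(model)
  summary <- list(
    reactions = st$reactions, metabolites = st$metabolites,
    genes = st$genes, byCategory = as.list(st$byCategory),
    unbalancedReactions = sum(bal$status == "unbalanced"),
    uncheckableReactions = sum(bal$status == "uncheckable"),
    deadEndMetabolites = length(de$metabolites),
    strandedReactions = length(de$reactions),
    futileCycleReactions = length(fc))
  jsonlite::write_json(summary, file.path(dir, "model_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  if (nrow(bal)) {
    flat <- bal
    flat$imbalance <- vapply(bal$imbalance, function(x)
      paste(names(x), format(x, digits = 4), sep = ":", collapse = ";"),
      character(1))
    utils::write.table(flat, file.path(dir, "balance_violations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  writeLines(de$reactions, file.path(dir, "stranded_reactions.txt"))
  writeLines(fc, file.path(dir, "futile_cycle_reactions.txt"))
  invisible(summary)
}

#' Validate a model per the run configuration
#'
#' Loads the model, writes the [writeModelReport()] outputs and fails
#' (with an error, i.e. nonzero exit under \code{Rscript}) on hard
#' validation problems: unbalanced mechanistic reactions or futile
#' cycles.
#'
#' @param config a [readRunConfig()] result or path to one.
#' @return invisibly, the summary list.
#' @export
cmdValidate <- function(config) {
  if (is.character(config)) config <- readRunConfig(config)
  toy <- .configModel(config)
  out <- file.path(config$output, "validate")
  summary <- writeModelReport(toy$model, out)
  message("model: ", summary$reactions, " reactions, ",
          summary$metabolites, " metabolites, ", summary$genes, " genes")
  if (summary$unbalancedReactions > 0 || summary$futileCycleReactions > 0)
    stop("validation failed: ", summary$unbalancedReactions,
         " unbalanced reaction(s), ", summary$futileCycleReactions,
         " futile-cycle reaction(s); see ", out)
  invisible(summary)
}

#' Run the population simulation per the run configuration
#'
#' Deterministic given the seed.  Writes the tidy trace
#' (\code{trace.tsv}), metrics (\code{metrics.json}, including the total
#' growth rate, equilibrium diazotroph fraction and nitrogen release
#' fraction), an optional ensemble table, and a provenance block (config
#' hash, seed, package version).  A population that dies completes
#' normally with status \code{"died"} recorded.
#'
#' @param config a [readRunConfig()] result or path to one.
#' @param plots also write simple diagnostic plots (PDF).
#' @return invisibly, the metrics list.
#' @export
cmdSimulate <- function(config, plots = FALSE) {
  path <- NULL
  if (is.character(config)) { path <- config; config <- readRunConfig(config) }
  toy <- .configModel(config)
  if (config$model$type != "toy")
    stop("cmdSimulate requires the two-cell-type constraint sets; ",
         "only the toy generator bundles them")
  if (!is.null(config$dfba$seed)) set.seed(config$dfba$seed)
  inoc <- c(DZ = config$dfba$inoculum$DZ %||% 5e-4,
            PA = config$dfba$inoculum$PA %||% 5e-4)
  dir.create(config$output, showWarnings = FALSE, recursive = TRUE)
  tr <- simulatePopulation(toy, inoc, horizon = config$dfba$horizon,
                           dt = config$dfba$dt, grace = config$dfba$grace)
  mt <- computeMetrics(tr)
  utils::write.table(traceStates(tr), file.path(config$output, "trace.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  metrics <- list(status = mt$status, muTotal = mt$muTotal,
                  doublingTime = mt$doublingTime, YNEnv = mt$YNEnv,
                  equilibriumFDZ = mt$equilibriumFDZ)
  if (!is.null(config$dfba$n_ensemble) && config$dfba$n_ensemble > 0) {
    ens <- runEnsemble(toy, n = config$dfba$n_ensemble,
                       horizon = config$dfba$horizon,
                       dt = config$dfba$dt, grace = config$dfba$grace,
                       seed = config$dfba$seed)
    utils::write.table(ens, file.path(config$output, "ensemble.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    metrics$ensembleViableFraction <- mean(ens$status == "completed")
  }
  jsonlite::write_json(metrics, file.path(config$output, "metrics.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  prov <- list(
    configHash = if (!is.null(path)) unname(tools::md5sum(path))
                 else NA_character_,
    seed = config$dfba$seed,
    packageVersion = as.character(utils::packageVersion("TrichoFBA")),
    rVersion = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(prov, file.path(config$output, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  if (plots) {
    grDevices::pdf(file.path(config$output, "trace.pdf"), width = 7,
                   height = 8)
    plotTrace(tr)
    grDevices::dev.off()
  }
  invisible(metrics)
}

#' Diagnostic plots of a population trace
#'
#' Three stacked panels: cell-type fractions, medium concentrations and
#' per-step growth rate over time.
#'
#' @param trace a \linkS4class{PopulationTrace}.
#' @return invisibly \code{NULL}.
#' @export
plotTrace <- function(trace) {
  st <- traceStates(trace)
  op <- graphics::par(mfrow = c(3, 1), mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(op))
  graphics::plot(st$t, st$f_DZ, type = "l", col = "steelblue",
                 xlab = "time (h)", ylab = "fraction", ylim = c(0, 1),
                 main = "trichome composition")
  graphics::lines(st$t, 1 - st$f_DZ, col = "darkgreen")
  graphics::legend("right", c("diazotroph", "photoautotroph"),
                   col = c("steelblue", "darkgreen"), lty = 1, bty = "n")
  graphics::matplot(st$t, cbind(st$C_glycogen, st$C_NH4), type = "l",
                    lty = 1, col = c("darkgreen", "steelblue"),
                    xlab = "time (h)", ylab = "mmol/L",
                    main = "medium concentrations")
  graphics::legend("topleft", c("glycogen", "ammonium"),
                   col = c("darkgreen", "steelblue"), lty = 1, bty = "n")
  graphics::plot(st$t, st$mu_t, type = "l", xlab = "time (h)",
                 ylab = expression(mu[t] ~ (h^-1)),
                 main = "population growth rate")
  invisible(NULL)
}
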