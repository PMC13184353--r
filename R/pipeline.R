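#' @include AllClasses.R simulate.R efa.R cfa.R network.R lifespan.R
NULL

pipelineStages <- c("simulate", "efa", "cfa", "network", "lifespan",
                    "sensitivity")

#' Run the staged analysis pipeline
#'
#' Executes the four-step analysis sequence (plus simulation and the
#' assessment-mode sensitivity split) from a structured YAML configuration:
#' \code{simulate} writes a synthetic cohort file; \code{efa} runs the
#' exploratory factor analysis with KMO/Bartlett and writes the loadings,
#' inter-factor correlations and purity tables; \code{cfa} fits the
#' three-factor AMI model and writes the fit indices; \code{network} builds
#' the absolute-Spearman network, selects the stable partition and writes
#' the module report plus a GraphML export; \code{lifespan} runs the
#' sliding-window scan and the purity ANOVA; \code{sensitivity} re-runs the
#' network per assessment mode.  Every stage derives its own seed from the
#' master seed by stable hashing of the stage name, so adding a stage never
#' perturbs earlier stages' draws, and a re-run with the same configuration
#' reproduces every output file (the manifest records content hashes).
#'
#' @param config path to a YAML config file, or an equivalent nested list.
#'   Top-level keys: \code{seed}, \code{output_dir}, \code{stages}
#'   (ordered subset of simulate/efa/cfa/network/lifespan/sensitivity),
#'   \code{input} (dataset path + \code{scale}, for pipelines starting from
#'   a file) and one optional parameter block per stage.
#' @param outputDir overrides the config's output directory.
#' @return the manifest (also written to \code{manifest.json}): inputs,
#'   parameters, per-stage seeds, package version, output files with MD5
#'   hashes, and a structured log.
#' @export
runPipeline <- function(config, outputDir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (is.null(cfg$stages) || !length(cfg$stages))
    stop("config must list at least one stage")
  bad <- setdiff(cfg$stages, pipelineStages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  outDir <- if (!is.null(outputDir)) outputDir
            else if (!is.null(cfg$output_dir)) cfg$output_dir else "."
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)

  log <- list()
  note <- function(stage, msg) {
    log[[length(log) + 1L]] <<- list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                                     stage = stage, level = "info",
                                     message = msg)
  }
  outputs <- character()
  emit <- function(path) outputs <<- c(outputs, path)
  stageSeeds <- stats::setNames(
    vapply(cfg$stages, function(s) deriveSeed(seed, s), integer(1)),
    cfg$stages)

  ## validate config-referenced columns before any stage runs
  ds <- NULL
  if (!is.null(cfg$input)) {
    scale <- builtinScale(cfg$input$scale %||% "AMI")
    header <- strsplit(readLines(cfg$input$path, n = 1L),
                       "[,\t]")[[1]]
    needed <- c("id", "cohort", "age", scale@items)
    miss <- setdiff(needed, header)
    if (length(miss))
      stop("validation error: input lacks column(s): ",
           paste(miss, collapse = ", "))
    ds <- readCohort(cfg$input$path, scale)
    note("input", sprintf("read %d participants from %s",
                          ncol(ds), cfg$input$path))
  }

  for (stage in cfg$stages) {
    prm <- cfg[[stage]] %||% list()
    sseed <- stageSeeds[[stage]]
    switch(stage,
      simulate = {
        model <- plantedModuleSpec(
          kModules = prm$k_modules %||% 3L,
          itemsPerModule = prm$items_per_module %||% 6L,
          withinLoading = prm$within_loading %||% 0.7,
          betweenCorr = prm$between_corr %||% 0.3,
          itemIds = if (identical(prm$scale, "AMI")) amiBlockItems() else NULL,
          domains = if (identical(prm$scale, "AMI"))
            c("Behavioural", "Social", "Emotional") else NULL)
        spec <- cohortSimSpec(
          n = prm$n %||% 1000L, model = model,
          ageRange = c(prm$age_min %||% 16, prm$age_max %||% 93),
          cohortLabel = prm$cohort %||% "HC",
          mode = prm$mode %||% "unknown", seed = sseed)
        sc <- if (identical(prm$scale, "AMI")) builtinScale("AMI") else NULL
        ds <- simulateCohort(spec, scale = sc)
        f <- file.path(outDir, "simulated_cohort.tsv")
        writeCohort(ds, f)
        emit(f)
        note(stage, sprintf("simulated %d participants (seed %d)",
                            ncol(ds), sseed))
      },
      efa = {
        if (is.null(ds)) stop("efa stage needs a dataset (input or simulate)")
        res <- runEFA(ds, k = prm$k,
                      rotation = prm$rotation %||% "promax",
                      promaxPower = prm$promax_power %||% 4)
        f1 <- file.path(outDir, "efa_loadings.tsv")
        utils::write.table(round(res$solution@pattern, 6), f1, sep = "\t",
                           quote = FALSE, col.names = NA)
        f2 <- file.path(outDir, "efa_factor_corr.tsv")
        utils::write.table(round(res$solution@factorCorr, 6), f2, sep = "\t",
                           quote = FALSE, col.names = NA)
        pur <- factorPurity(res$solution@pattern)
        f3 <- file.path(outDir, "efa_purity.tsv")
        utils::write.table(pur$items, f3, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        f4 <- file.path(outDir, "efa_log.tsv")
        utils::write.table(
          data.frame(kmo = res$kmo, bartlett_chi2 = res$bartlett$chi2,
                     bartlett_df = res$bartlett$df, n_factors = res$nFactors,
                     ml_chi2 = res$solution@fit$chi2,
                     ml_df = res$solution@fit$df, n = res$n),
          f4, sep = "\t", quote = FALSE, row.names = FALSE)
        for (f in c(f1, f2, f3, f4)) emit(f)
        note(stage, sprintf("EFA: %d factors, KMO %.3f", res$nFactors, res$kmo))
      },
      cfa = {
        if (is.null(ds)) stop("cfa stage needs a dataset")
        spec <- cfaModelSpec(
          excludedItems = prm$excluded_items %||% c("AMI-2", "AMI-6", "AMI-8"))
        fit <- cfaFit(ds, spec)
        f <- file.path(outDir, "cfa_fit.tsv")
        utils::write.table(
          data.frame(chi2 = fit@chi2, df = fit@df, p = fit@p,
                     cfi = fit@cfi, tli = fit@tli, rmsea = fit@rmsea,
                     rmsea_lo = fit@rmseaCI[1], rmsea_hi = fit@rmseaCI[2],
                     srmr = fit@srmr, n = fit@n),
          f, sep = "\t", quote = FALSE, row.names = FALSE)
        f2 <- file.path(outDir, "cfa_loadings.tsv")
        utils::write.table(
          data.frame(item = names(fit@loadings),
                     loading = round(fit@loadings, 6),
                     residual = round(fit@residuals, 6)),
          f2, sep = "\t", quote = FALSE, row.names = FALSE)
        emit(f); emit(f2)
        note(stage, sprintf("CFA: chi2(%d) = %.2f, CFI %.3f",
                            fit@df, fit@chi2, fit@cfi))
      },
      network = {
        if (is.null(ds)) stop("network stage needs a dataset")
        net <- spearmanNetwork(ds)
        census <- stablePartition(net, nRestarts = prm$restarts %||% 1000,
                                  seed = sseed)
        summ <- summariseModules(net, modalPartition(census))
        f <- file.path(outDir, "network_modules.tsv")
        utils::write.table(
          data.frame(module = seq_along(summ),
                     modalDomain = vapply(summ, `[[`, character(1), "modalDomain"),
                     purity = vapply(summ, `[[`, numeric(1), "purity"),
                     centralNode = vapply(summ, `[[`, character(1), "centralNode"),
                     members = vapply(summ, function(s)
                       paste(s$members, collapse = ";"), character(1)),
                     modalShare = modalShare(census)),
          f, sep = "\t", quote = FALSE, row.names = FALSE)
        f2 <- file.path(outDir, "network_weights.tsv")
        utils::write.table(round(weightMatrix(net), 6), f2, sep = "\t",
                           quote = FALSE, col.names = NA)
        f3 <- file.path(outDir, "network.graphml")
        exportGraphML(net, f3, partition = modalPartition(census),
                      threshold = prm$threshold %||% 0.1)
        for (ff in c(f, f2, f3)) emit(ff)
        note(stage, sprintf("network: %d modules, modal share %.2f",
                            length(summ), modalShare(census)))
      },
      lifespan = {
        if (is.null(ds)) stop("lifespan stage needs a dataset")
        traj <- lifespanScan(ds,
                             width = prm$width %||% 10,
                             sigma = prm$sigma %||% 5,
                             step = prm$step %||% 1,
                             minEss = prm$min_ess %||% 30,
                             nRestarts = prm$restarts %||% 1000,
                             seed = sseed)
        f <- file.path(outDir, "lifespan_modules.tsv")
        utils::write.table(traj$modules, f, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        emit(f)
        if (nrow(traj$purityRecords) > 1 &&
            length(unique(traj$purityRecords$domain)) > 1) {
          an <- tryCatch(purityAnova(traj$purityRecords),
                         error = function(e) NULL)
          if (!is.null(an)) {
            f2 <- file.path(outDir, "lifespan_anova.tsv")
            utils::write.table(an, f2, sep = "\t", quote = FALSE,
                               row.names = FALSE)
            emit(f2)
          }
        }
        note(stage, sprintf("lifespan: %d included windows",
                            sum(traj$windows$included)))
      },
      sensitivity = {
        if (is.null(ds)) stop("sensitivity stage needs a dataset")
        res <- modeSensitivity(ds, nRestarts = prm$restarts %||% 1000,
                               seed = sseed)
        f <- file.path(outDir, "sensitivity_agreement.tsv")
        utils::write.table(res$agreement$items, f, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        emit(f)
        note(stage, sprintf("sensitivity: adjusted Rand %.3f",
                            res$agreement$adjustedRand))
      }
    )
  }

  manifest <- list(
    package = "apathynet",
    version = as.character(utils::packageVersion("apathynet")),
    masterSeed = seed,
    stageSeeds = as.list(stageSeeds),
    stages = cfg$stages,
    parameters = cfg[intersect(names(cfg), pipelineStages)],
    outputs = lapply(outputs, function(f)
      list(path = f, md5 = unname(tools::md5sum(f)))),
    log = log
  )
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## AMI item ids grouped into their a-priori domain blocks
amiBlockItems <- function() {
  d <- itemDomains(builtinScale("AMI"))
  names(d)[order(match(d, c("Behavioural", "Social", "Emotional")))]
}
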