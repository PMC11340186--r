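#' Extract all four omics feature sets from a cohort bundle
#'
#' Runs the methylation, end-motif and CNV extractors plus the mutation
#' score. When `model` is supplied (a fitted [StackedModel-class]), the
#' training-frozen preprocessing is re-applied instead of re-estimated:
#' methylation imputation medians, the CNV panel of normals and the
#' mutation filter all come from the model, as required for validation
#' cohorts. Without a model, the panel of normals is built from the
#' cohort's control samples and imputation medians from the whole cohort.
#'
#' @param cohort A [simulateCohort()]/[readCohort()] bundle (samples,
#'   methylation, fragments, bins, mutations).
#' @param model Optional fitted model freezing the preprocessing.
#' @param arms Arm table (ignored when `model` carries one).
#' @param minMolecules Methylation coverage floor.
#' @param k Motif length.
#' @param minFragments Per-sample usable-fragment floor.
#' @param minBinsPerArm CNV arm support floor.
#' @param mutConfig Mutation filter (ignored when `model` is given).
#' @return List: features (named list of `SummarizedExperiment`s),
#'   mutScore (named 0/1 vector), pon (the bin reference used).
#' @export
extractFeatures <- function(cohort, model = NULL, arms = armTable(),
                            minMolecules = 10, k = 4,
                            minFragments = 1000, minBinsPerArm = 10,
                            mutConfig = mutationFilterConfig()) {
  si <- cohort$samples
  if (!is.null(model)) {
    arms <- model@armTable
    mutConfig <- model@mutationFilter
  }
  meth <- buildMethylationMatrix(
    cohort$methylation, si, minMolecules = minMolecules,
    imputation = if (is.null(model)) NULL else model@imputation)
  motif <- buildMotifMatrix(cohort$fragments, si, k = k,
                            minFragments = minFragments)
  cnvBits <- cohortArmFeatures(cohort$bins, si,
                               pon = if (is.null(model)) NULL else
                                 model@pon,
                               arms = arms,
                               minBinsPerArm = minBinsPerArm)
  pon <- cnvBits$pon
  cnv <- buildCnvMatrix(cnvBits$armFeatures, si, arms)
  ms <- mutationScores(cohort$mutations, si$sample_id, mutConfig)
  list(features = list(methylation = meth, endmotif = motif, cnv = cnv),
       mutScore = ms, pon = pon)
}

#' Feature-combination ablation of the integrated model
#'
#' Re-fits the logistic combiner on every non-empty subset of the four
#' inputs (training out-of-fold scores) and evaluates each refit on the
#' validation predictions, mirroring feature-combination sweeps used to
#' justify the full four-omics stack.
#'
#' @param oof Training out-of-fold table (from [trainStackedModel()]).
#' @param valPred Validation prediction table (from `predict`).
#' @param valLabels Validation labels aligned to `valPred$sample_id`.
#' @param lambda Ridge strength (`NULL` = `1e-4 * n`).
#' @return data.frame combination / n_inputs / train_cv_auc / val_auc.
#' @export
ablateCombinations <- function(oof, valPred, valLabels, lambda = NULL) {
  inputs <- c("p_methylation", "p_endmotif", "p_cnv", "mutation_score")
  labTr <- oof$label
  combos <- unlist(lapply(seq_along(inputs), function(m)
    utils::combn(inputs, m, simplify = FALSE)), recursive = FALSE)
  rows <- lapply(combos, function(cb) {
    Xtr <- as.matrix(oof[, cb, drop = FALSE])
    fit <- ridgeLogistic(Xtr, as.numeric(canonicalLabels(labTr) == "case"),
                         lambda %||% (1e-4 * nrow(Xtr)))
    pTr <- stats::plogis(fit$coefficients[1] +
                           drop(Xtr %*% fit$coefficients[-1]))
    Xv <- as.matrix(valPred[, cb, drop = FALSE])
    pV <- stats::plogis(fit$coefficients[1] +
                          drop(Xv %*% fit$coefficients[-1]))
    data.frame(combination = paste(sub("^p_", "", cb), collapse = "+"),
               n_inputs = length(cb),
               train_cv_auc = rocAuc(pTr, labTr)$auc,
               val_auc = rocAuc(pV, valLabels)$auc)
  })
  do.call(rbind, rows)
}

#' Run the whole study in memory
#'
#' Simulate a training and a validation cohort, extract features, select
#' markers, train the stacked model, predict the validation cohort and
#' evaluate both cohorts. This is the programmatic core wrapped by
#' [runPipeline()]; it keeps everything in memory.
#'
#' @param trainConfig [SimulationConfig-class] of the training cohort.
#' @param valConfig [SimulationConfig-class] of the validation cohort
#'   (default: training config with a derived seed and the cohort sizes
#'   89/95; the marker panel seed is shared automatically).
#' @param selConfig,mutConfig Selection and mutation-filter configs.
#' @param k Fold count.
#' @param seed Partition seed (default: the training config seed).
#' @param minFragments Per-sample usable-fragment floor.
#' @param minBinsPerArm CNV arm support floor.
#' @param ablate Also run the feature-combination sweep.
#' @param nestedSelection Re-run marker selection inside each CV fold
#'   (see [trainStackedModel()]).
#' @return List: trainCohort, valCohort, trainFeatures, valFeatures,
#'   model, oof, predictions, trainMetrics (on out-of-fold scores),
#'   valMetrics, ablation (optional).
#' @export
runStudy <- function(trainConfig = simulationConfig(),
                     valConfig = NULL,
                     selConfig = selectionConfig(),
                     mutConfig = mutationFilterConfig(),
                     k = 10, seed = NULL, minFragments = 1000,
                     minBinsPerArm = 10, ablate = FALSE,
                     nestedSelection = FALSE) {
  if (is.null(valConfig)) {
    valConfig <- trainConfig
    valConfig@nCases <- 89L
    valConfig@nControls <- 95L
    valConfig@seed <- childSeed(trainConfig@seed, "validation-cohort")
  }
  assertThat(panelSeedOf(trainConfig) == panelSeedOf(valConfig),
             "training and validation cohorts must share the marker panel seed")
  seed <- seed %||% trainConfig@seed
  arms <- armTable()
  trainCohort <- simulateCohort(trainConfig, "train", arms)
  valCohort <- simulateCohort(valConfig, "val", arms)
  overlap <- intersect(trainCohort$samples$sample_id,
                       valCohort$samples$sample_id)
  assertThat(length(overlap) == 0,
             "training and validation cohorts overlap: %s",
             paste(overlap, collapse = ", "))
  trF <- extractFeatures(trainCohort, arms = arms,
                         minFragments = minFragments,
                         minBinsPerArm = minBinsPerArm,
                         mutConfig = mutConfig)
  fit <- trainStackedModel(trF$features, trF$mutScore,
                           selConfig = selConfig, mutConfig = mutConfig,
                           k = k, seed = seed, pon = trF$pon,
                           arms = arms, nestedSelection = nestedSelection)
  vaF <- extractFeatures(valCohort, model = fit$model,
                         minFragments = minFragments,
                         minBinsPerArm = minBinsPerArm)
  pred <- predict(fit$model, vaF$features, vaF$mutScore)
  oofPred <- fit$oof
  oofPred$call <- oofPred$p_integrated >=
    fit$model@cutoffs[["integrated"]]
  trainMetrics <- evaluatePredictions(oofPred, trainCohort$samples)
  valMetrics <- evaluatePredictions(pred, valCohort$samples)
  out <- list(trainCohort = trainCohort, valCohort = valCohort,
              trainFeatures = trF, valFeatures = vaF,
              model = fit$model, oof = fit$oof, predictions = pred,
              trainMetrics = trainMetrics, valMetrics = valMetrics)
  if (ablate)
    out$ablation <- ablateCombinations(
      fit$oof, pred,
      valCohort$samples$label[match(pred$sample_id,
                                    valCohort$samples$sample_id)])
  out
}

#' Read a pipeline run configuration
#'
#' A single YAML document with optional blocks `simulation` (arguments of
#' [simulationConfig()]; `validation` sub-block overrides cohort sizes and
#' seed), `mutation_filter`, `selection`, `model`
#' (k/lambda/cutoff_method), `features` (min_fragments, min_bins_per_arm)
#' and a top-level `seed`.
#'
#' @param path YAML path.
#' @return Config list with defaults filled in.
#' @export
readRunConfig <- function(path) {
  assertThat(file.exists(path), "config file not found: %s", path)
  cfg <- yaml::read_yaml(path) %||% list()
  cfg
}

buildConfigs <- function(cfg, seed = NULL) {
  seed <- seed %||% cfg$seed %||% 1
  simArgs <- cfg$simulation %||% list()
  valOv <- simArgs$validation %||% list()
  simArgs$validation <- NULL
  simArgs$seed <- simArgs$seed %||% seed
  trainConfig <- do.call(simulationConfig, simArgs)
  valConfig <- trainConfig
  valConfig@nCases <- as.integer(valOv$n_cases %||% 89)
  valConfig@nControls <- as.integer(valOv$n_controls %||% 95)
  valConfig@seed <- as.integer(valOv$seed %||%
                                 childSeed(trainConfig@seed,
                                           "validation-cohort"))
  mutConfig <- do.call(mutationFilterConfig, cfg$mutation_filter %||%
                         list())
  selConfig <- do.call(selectionConfig, cfg$selection %||% list())
  list(seed = seed, train = trainConfig, validation = valConfig,
       mutation = mutConfig, selection = selConfig,
       k = cfg$model$k %||% 10,
       cutoffMethod = cfg$model$cutoff_method %||% "youden",
       nestedSelection = isTRUE(cfg$model$nested_selection),
       minFragments = cfg$features$min_fragments %||% 1000,
       minBinsPerArm = cfg$features$min_bins_per_arm %||% 10,
       ablate = isTRUE(cfg$ablate))
}

#' Run the end-to-end pipeline with on-disk artifacts
#'
#' Orchestrates simulate, features, select, train, predict, evaluate and
#' report into a run directory. Every run writes a manifest
#' (`manifest.json`) with the config hash, seeds, package version and md5
#' checksums of the artifacts; re-running with an identical config over an
#' existing completed run is a no-op unless `force = TRUE`. Timing and
#' progress go to `log.txt` (kept out of the deterministic artifacts).
#'
#' @param config Path to a YAML run config, or a config list.
#' @param outputDir Run directory (created).
#' @param seed Optional seed override.
#' @param stages Stages to run, in pipeline order; later stages require
#'   earlier artifacts and error naming the missing stage.
#' @param force Re-run even if the manifest shows a completed identical
#'   run.
#' @return Invisibly, the metrics list (when `evaluate` ran).
#' @export
runPipeline <- function(config = list(), outputDir, seed = NULL,
                        stages = c("simulate", "features", "select",
                                   "train", "predict", "evaluate",
                                   "report"),
                        force = FALSE) {
  allStages <- c("simulate", "features", "select", "train", "predict",
                 "evaluate", "report")
  stages <- match.arg(stages, allStages, several.ok = TRUE)
  if (is.character(config)) config <- readRunConfig(config)
  cc <- buildConfigs(config, seed)
  dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
  manifestPath <- file.path(outputDir, "manifest.json")
  cfgHash <- configHash(list(config = config, seed = cc$seed,
                             stages = stages))
  if (!force && file.exists(manifestPath)) {
    prev <- jsonlite::read_json(manifestPath)
    if (identical(prev$config_hash, cfgHash) &&
        isTRUE(prev$completed)) {
      message("identical completed run found; skipping (use force = TRUE)")
      return(invisible(NULL))
    }
  }
  logPath <- file.path(outputDir, "log.txt")
  logLine <- function(fmt, ...) cat(sprintf("[%s] %s\n",
                                            format(Sys.time(), "%H:%M:%S"),
                                            sprintf(fmt, ...)),
                                    file = logPath, append = TRUE)
  logLine("run start; seed = %d; stages = %s", cc$seed,
          paste(stages, collapse = ","))
  arms <- armTable()
  needs <- function(path, stage) {
    assertThat(file.exists(path),
               "missing artifact %s: run stage '%s' first",
               basename(path), stage)
  }
  paths <- list(
    trainDir = file.path(outputDir, "train"),
    valDir = file.path(outputDir, "validation"),
    model = file.path(outputDir, "model.json"),
    oof = file.path(outputDir, "training_oof.tsv"),
    markers = file.path(outputDir, "selected_markers.tsv"),
    pred = file.path(outputDir, "predictions_validation.tsv"),
    metrics = file.path(outputDir, "metrics.json"),
    report = file.path(outputDir, "report.tsv"))
  metrics <- NULL

  if ("simulate" %in% stages) {
    t0 <- Sys.time()
    trainCohort <- simulateCohort(cc$train, "train", arms)
    valCohort <- simulateCohort(cc$validation, "val", arms)
    overlap <- intersect(trainCohort$samples$sample_id,
                         valCohort$samples$sample_id)
    assertThat(length(overlap) == 0,
               "training and validation cohorts overlap: %s",
               paste(overlap, collapse = ", "))
    writeCohort(trainCohort, paths$trainDir)
    writeCohort(valCohort, paths$valDir)
    logLine("simulate done in %.1fs",
            as.numeric(Sys.time() - t0, units = "secs"))
  }

  runTail <- any(c("features", "select", "train", "predict",
                   "evaluate") %in% stages)
  if (runTail) {
    needs(file.path(paths$trainDir, "samples.tsv"), "simulate")
    needs(file.path(paths$valDir, "samples.tsv"), "simulate")
    trainCohort <- readCohort(paths$trainDir)
    valCohort <- readCohort(paths$valDir)
    overlap <- intersect(trainCohort$samples$sample_id,
                         valCohort$samples$sample_id)
    assertThat(length(overlap) == 0,
               "training and validation cohorts overlap: %s",
               paste(overlap, collapse = ", "))
  }

  if (any(c("features", "select", "train", "predict",
            "evaluate") %in% stages)) {
    t0 <- Sys.time()
    trF <- extractFeatures(trainCohort, arms = arms,
                           minFragments = cc$minFragments,
                           minBinsPerArm = cc$minBinsPerArm,
                           mutConfig = cc$mutation)
    if ("features" %in% stages) {
      for (om in names(trF$features))
        writeFeatureMatrix(trF$features[[om]],
                           file.path(outputDir,
                                     paste0("features_train_", om,
                                            ".tsv")))
      writeTsv(data.frame(sample_id = names(trF$mutScore),
                          mutation_score = unname(trF$mutScore)),
               file.path(outputDir, "mutation_scores_train.tsv"))
      if (nrow(trainCohort$mutations))
        writeEligibilityReport(trainCohort$mutations,
                               file.path(outputDir,
                                         "eligibility_train.tsv"),
                               cc$mutation)
    }
    logLine("features done in %.1fs",
            as.numeric(Sys.time() - t0, units = "secs"))
  }

  if (any(c("select", "train") %in% stages)) {
    t0 <- Sys.time()
    fit <- trainStackedModel(trF$features, trF$mutScore,
                             selConfig = cc$selection,
                             mutConfig = cc$mutation, k = cc$k,
                             seed = cc$seed, pon = trF$pon, arms = arms,
                             cutoffMethod = cc$cutoffMethod,
                             nestedSelection = cc$nestedSelection)
    writeSelectedMarkers(
      lapply(stats::setNames(nm = names(fit$model@selection)),
             function(om) list(selected = fit$model@selection[[om]],
                               filter = univariateFilter(
                                 trF$features[[om]],
                                 alpha = cc$selection@univariateAlpha),
                               importance = NULL)),
      paths$markers)
    writeModel(fit$model, paths$model)
    writeTsv(fit$oof, paths$oof)
    logLine("select+train done in %.1fs",
            as.numeric(Sys.time() - t0, units = "secs"))
  }

  if (any(c("predict", "evaluate") %in% stages)) {
    needs(paths$model, "train")
    model <- readModel(paths$model)
    t0 <- Sys.time()
    vaF <- extractFeatures(valCohort, model = model,
                           minFragments = cc$minFragments,
                           minBinsPerArm = cc$minBinsPerArm)
    pred <- predict(model, vaF$features, vaF$mutScore)
    writeTsv(pred, paths$pred)
    logLine("predict done in %.1fs",
            as.numeric(Sys.time() - t0, units = "secs"))
  }

  if ("evaluate" %in% stages) {
    needs(paths$pred, "predict")
    needs(paths$oof, "train")
    pred <- as.data.frame(readTsv(paths$pred))
    oof <- as.data.frame(readTsv(paths$oof))
    model <- readModel(paths$model)
    oof$call <- oof$p_integrated >= model@cutoffs[["integrated"]]
    metrics <- list(
      training = evaluatePredictions(oof, trainCohort$samples),
      validation = evaluatePredictions(pred, valCohort$samples),
      cutoffs = as.list(model@cutoffs))
    if (cc$ablate) {
      lab <- valCohort$samples$label[match(pred$sample_id,
                                           valCohort$samples$sample_id)]
      metrics$ablation <- ablateCombinations(oof, pred, lab)
    }
    jsonlite::write_json(metrics, paths$metrics, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, force = TRUE)
    labV <- valCohort$samples$label[match(pred$sample_id,
                                          valCohort$samples$sample_id)]
    writeTsv(rocAuc(pred$p_integrated, labV)$curve,
             file.path(outputDir, "roc_validation_integrated.tsv"))
    logLine("evaluate done")
  }

  if ("report" %in% stages) {
    needs(paths$metrics, "evaluate")
    m <- jsonlite::read_json(paths$metrics, simplifyVector = TRUE)
    rows <- data.frame(
      metric = c("validation_auc_integrated",
                 "validation_sensitivity_percent",
                 "validation_specificity_percent",
                 "training_cv_auc_integrated"),
      value = c(m$validation$auc$integrated$auc,
                100 * m$validation$integrated$sensitivity$rate,
                100 * m$validation$integrated$specificity$rate,
                m$training$auc$integrated$auc))
    writeTsv(rows, paths$report)
  }

  arts <- Filter(file.exists,
                 unlist(paths[c("model", "oof", "markers", "pred",
                                "metrics", "report")]))
  manifest <- list(
    config_hash = cfgHash, seed = cc$seed,
    stages = stages, completed = TRUE,
    package_version = as.character(utils::packageVersion("cfdnaStack")),
    checksums = as.list(tools::md5sum(arts)))
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(metrics)
}
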