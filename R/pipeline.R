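#' Default pipeline run configuration
#'
#' A fully serializable configuration from which a run is reproducible
#' given its master seed alone.  Per-stage seeds are derived
#' deterministically from the master seed.
#'
#' @param outDir output directory.
#' @param seed master seed.
#' @param nHgg,nMeta training group sizes.
#' @param nHggValid,nMetaValid held-out validation group sizes.
#' @param snr per-average b=0 SNR of the simulated acquisition.
#' @param gridShape,voxelDims phantom grid geometry.
#' @param smoothingSigma kurtosis-branch smoothing sigma (voxels).
#' @param nFolds LASSO cross-validation folds.
#' @param minsplit,cp CART stopping/pruning parameters.
#' @return named list (a RunConfig).
#' @export
defaultRunConfig <- function(outDir = tempfile("mbglioma_run"), seed = 1,
                             nHgg = 6, nMeta = 4, nHggValid = 2,
                             nMetaValid = 2, snr = 40,
                             gridShape = c(24, 24, 24),
                             voxelDims = c(5, 5, 5), smoothingSigma = 1,
                             nFolds = 5, minsplit = 20, cp = 0.01) {
  list(outDir = outDir, seed = seed,
       scheme = list(bvalues = bValues(paperBScheme()),
                     nAverages = nAverages(paperBScheme())),
       cohort = list(nHgg = nHgg, nMeta = nMeta, nHggValid = nHggValid,
                     nMetaValid = nMetaValid, snr = snr,
                     gridShape = gridShape, voxelDims = voxelDims),
       fit = list(smoothingSigma = smoothingSigma),
       classifier = list(nFolds = nFolds, minsplit = minsplit, cp = cp),
       stages = c("simulate", "fit", "extract", "stats", "train",
                  "validate", "reliability"))
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML path.
#' @export
readRunConfig <- function(path) yaml::read_yaml(path)

#' @rdname readRunConfig
#' @param config a RunConfig list.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

.checksums <- function(paths) {
  paths <- paths[file.exists(paths)]
  as.list(tools::md5sum(paths))
}

.stageManifestPath <- function(outDir, stage)
  file.path(outDir, "manifest", paste0(stage, ".json"))

.stageUpToDate <- function(outDir, stage, inputs) {
  mp <- .stageManifestPath(outDir, stage)
  if (!file.exists(mp)) return(FALSE)
  man <- jsonlite::fromJSON(mp)
  cur <- .checksums(inputs)
  identical(man$inputs[order(names(man$inputs))],
            cur[order(names(cur))]) &&
    all(file.exists(names(unlist(man$outputs))))
}

.writeStageManifest <- function(outDir, stage, inputs, outputs, seed) {
  dir.create(file.path(outDir, "manifest"), showWarnings = FALSE,
             recursive = TRUE)
  man <- list(stage = stage, inputs = .checksums(inputs),
              outputs = .checksums(outputs), seed = seed,
              version = as.character(utils::packageVersion("mbglioma")),
              time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(man, .stageManifestPath(outDir, stage),
                       auto_unbox = TRUE)
  man
}

#' Run the full synthetic analysis pipeline
#'
#' Executes the requested stages in order: \code{simulate} (training and
#' validation cohorts), \code{fit} (voxelwise IVIM + kurtosis maps over the
#' lesion), \code{extract} (135-feature tables), \code{stats} (univariate
#' comparison + ROC tables), \code{train} (zero-imputation, LASSO
#' selection, CART tree), \code{validate} (held-out confusion statistics),
#' \code{reliability} (second-rater mask simulation, Dice/AHD/ICC).  Each
#' stage writes its outputs plus a manifest entry with input/output
#' checksums; a completed stage whose inputs are unchanged is skipped.
#'
#' @param config RunConfig list or path to a YAML config.
#' @return list of stage manifest entries (the run manifest), invisibly
#'   written to \code{run_manifest.json}.
#' @export
runPipeline <- function(config = defaultRunConfig()) {
  if (is.character(config)) config <- readRunConfig(config)
  for (field in c("outDir", "seed", "scheme"))
    if (is.null(config[[field]]))
      stop("config is missing required field '", field, "'")
  if (is.null(config$scheme$bvalues))
    stop("config is missing required field 'scheme'")
  outDir <- config$outDir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  writeRunConfig(config, file.path(outDir, "config.yaml"))
  scheme <- bScheme(config$scheme$bvalues, config$scheme$nAverages)
  ch <- config$cohort
  fitOpt <- fitOptions(smoothingSigma = config$fit$smoothingSigma)
  cl <- config$classifier
  stageSeed <- function(k) (config$seed * 101L + k * 977L) %% (2^31 - 2) + 1
  manifest <- list()
  rds <- function(nm) file.path(outDir, paste0(nm, ".rds"))
  runStage <- function(stage, inputs, outputs, fun) {
    if (.stageUpToDate(outDir, stage, inputs)) {
      man <- jsonlite::fromJSON(.stageManifestPath(outDir, stage))
      man$skipped <- TRUE
      return(man)
    }
    ok <- tryCatch({ fun(); TRUE },
                   error = function(e)
                     stop("stage '", stage, "' failed: ",
                          conditionMessage(e), call. = FALSE))
    .writeStageManifest(outDir, stage, inputs,
                        outputs, stageSeed(match(stage, config$stages)))
  }
  for (stage in config$stages) {
    man <- switch(stage,
      simulate = runStage("simulate", file.path(outDir, "config.yaml"),
                          c(rds("train_cohort"), rds("valid_cohort")), function() {
        train <- generateCohort(ch$nHgg, ch$nMeta, scheme = scheme,
                                snr = ch$snr, masterSeed = stageSeed(1),
                                gridShape = ch$gridShape,
                                voxelDims = ch$voxelDims)
        valid <- generateCohort(ch$nHggValid, ch$nMetaValid,
                                scheme = scheme, snr = ch$snr,
                                masterSeed = stageSeed(2),
                                gridShape = ch$gridShape,
                                voxelDims = ch$voxelDims)
        utils::write.csv(train$manifest,
                         file.path(outDir, "train_manifest.csv"),
                         row.names = FALSE)
        writeBScheme(scheme, file.path(outDir, "btable.txt"))
        saveRDS(train, rds("train_cohort"))
        saveRDS(valid, rds("valid_cohort"))
      }),
      fit = runStage("fit", c(rds("train_cohort"), rds("valid_cohort")),
                     rds("maps"), function() {
        fitCohort <- function(cohort) lapply(cohort$subjects, function(s) {
          lesion <- s$masks@enhancing | s$masks@nonEnhancing |
            s$masks@edema
          fitMaps(s$dwi, lesion, fitOpt)
        })
        maps <- list(train = fitCohort(readRDS(rds("train_cohort"))),
                     valid = fitCohort(readRDS(rds("valid_cohort"))))
        saveRDS(maps, rds("maps"))
      }),
      extract = runStage("extract",
                         c(rds("train_cohort"), rds("valid_cohort"),
                           rds("maps")),
                         c(file.path(outDir, "train_features.csv"),
                           file.path(outDir, "valid_features.csv")),
                         function() {
        maps <- readRDS(rds("maps"))
        mkTable <- function(cohort, mp) buildFeatureTable(
          lapply(seq_along(cohort$subjects), function(i) {
            s <- cohort$subjects[[i]]
            suppressWarnings(
              extractFeatures(mp[[i]], s$masks, s$id, s$label))
          }))
        writeFeatureTable(mkTable(readRDS(rds("train_cohort")),
                                  maps$train),
                          file.path(outDir, "train_features.csv"))
        writeFeatureTable(mkTable(readRDS(rds("valid_cohort")),
                                  maps$valid),
                          file.path(outDir, "valid_features.csv"))
      }),
      stats = runStage("stats", file.path(outDir, "train_features.csv"),
                       c(file.path(outDir, "univariate.csv"),
                         file.path(outDir, "roc.csv")), function() {
        res <- compareGroups(
          readFeatureTable(file.path(outDir, "train_features.csv")))
        utils::write.csv(res$univariate,
                         file.path(outDir, "univariate.csv"),
                         row.names = FALSE)
        utils::write.csv(res$roc, file.path(outDir, "roc.csv"),
                         row.names = FALSE)
      }),
      train = runStage("train", file.path(outDir, "train_features.csv"),
                       file.path(outDir, "model.json"), function() {
        tab <- imputeMissingZero(
          readFeatureTable(file.path(outDir, "train_features.csv")))
        sel <- lassoSelect(tab, nFolds = cl$nFolds, seed = stageSeed(5))
        feats <- if (length(sel$selected)) sel$selected
                 else publishedTreeFeatures()
        model <- fitDecisionTree(tab, features = feats,
                                 minsplit = cl$minsplit, cp = cl$cp)
        writeTreeModel(model, file.path(outDir, "model.json"))
        jsonlite::write_json(sel[c("selected", "lambda")],
                             file.path(outDir, "lasso.json"),
                             auto_unbox = TRUE, digits = NA)
      }),
      validate = runStage("validate",
                          c(file.path(outDir, "model.json"),
                            file.path(outDir, "valid_features.csv")),
                          file.path(outDir, "validation.csv"), function() {
        model <- readTreeModel(file.path(outDir, "model.json"))
        tab <- imputeMissingZero(
          readFeatureTable(file.path(outDir, "valid_features.csv")))
        ev <- evaluateTree(model, tab)
        utils::write.csv(data.frame(
          sensitivity = ev$sensitivity, specificity = ev$specificity,
          accuracy = ev$accuracy, auc = ev$auc, n = ev$n),
          file.path(outDir, "validation.csv"), row.names = FALSE)
      }),
      reliability = runStage("reliability",
                             c(rds("train_cohort"), rds("maps")),
                             file.path(outDir, "reliability.csv"),
                             function() {
        cohort <- readRDS(rds("train_cohort"))
        maps <- readRDS(rds("maps"))
        nRel <- min(4, length(cohort$subjects))
        masksA <- masksB <- list()
        featA <- featB <- list()
        for (i in seq_len(nRel)) {
          s <- cohort$subjects[[i]]
          masksA[[i]] <- s$masks
          # simulated second rater: same subject, fresh boundary draw
          masksB[[i]] <- buildLesionGeometry(
            s$truth, dim(s$masks@enhancing), s$masks@voxelDims,
            seed = s$seed + 11L)
          featA[[i]] <- suppressWarnings(
            extractFeatures(maps$train[[i]], masksA[[i]], s$id, s$label))
          fm <- fitMaps(s$dwi, masksB[[i]]@enhancing |
                          masksB[[i]]@nonEnhancing | masksB[[i]]@edema,
                        fitOpt)
          featB[[i]] <- suppressWarnings(
            extractFeatures(fm, masksB[[i]], s$id, s$label))
        }
        rep <- agreementReport(masksA, masksB,
                               buildFeatureTable(featA),
                               buildFeatureTable(featB))
        utils::write.csv(rep$masks, file.path(outDir, "reliability.csv"),
                         row.names = FALSE)
        utils::write.csv(rep$features,
                         file.path(outDir, "reliability_icc.csv"),
                         row.names = FALSE)
      }),
      stop("unknown stage: ", stage))
    manifest[[stage]] <- man
  }
  jsonlite::write_json(manifest, file.path(outDir, "run_manifest.json"),
                       auto_unbox = TRUE)
  invisible(manifest)
}
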