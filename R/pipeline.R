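# End-to-end orchestration: canonicalize -> extract -> split -> normalize ->
# filter -> SFFS -> final model -> evaluation battery, with stage-tagged
# errors, bookkeeping logs and on-disk artifacts.

#' Pipeline configuration
#'
#' Defaults reproduce the study's stated settings: MI threshold 0.2,
#' t-test alpha 0.05, SFFS cap 30, fivefold CV, 32 gray levels, 70/30
#' stratified split.
#'
#' @param seed integer seed governing every stochastic stage (mandatory).
#' @param simulate NULL, or a list `list(n = ..., cfg = phantomConfig())`
#'   to run on a synthetic cohort.
#' @param imagesDir,annotationsDir,labelsFile input paths (ignored when
#'   simulating). Images are `<eyeId>.png`, annotations `<eyeId>.json`.
#' @param outputDir optional artifact directory.
#' @param miThreshold,alpha,maxK,folds,nLevels,valFrac,tol,patience,
#'   aucFloor,numTreesWrapper,numTreesModel tunables (see the stage
#'   functions).
#' @return a `RunConfig` list.
#' @export
runConfig <- function(seed, simulate = NULL, imagesDir = NULL,
                      annotationsDir = NULL, labelsFile = NULL,
                      outputDir = NULL, miThreshold = 0.2, alpha = 0.05,
                      maxK = 30L, folds = 5L, nLevels = 32L, valFrac = 0.3,
                      tol = 0.005, patience = 6, aucFloor = 0.75,
                      numTreesWrapper = 50L, numTreesModel = 100L) {
  if (missing(seed)) stop("runConfig: a seed is mandatory")
  structure(list(seed = as.integer(seed), simulate = simulate,
                 imagesDir = imagesDir, annotationsDir = annotationsDir,
                 labelsFile = labelsFile, outputDir = outputDir,
                 miThreshold = miThreshold, alpha = alpha, maxK = maxK,
                 folds = folds, nLevels = nLevels, valFrac = valFrac,
                 tol = tol, patience = patience, aucFloor = aucFloor,
                 numTreesWrapper = numTreesWrapper,
                 numTreesModel = numTreesModel),
            class = "RunConfig")
}

withStage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", stage, conditionMessage(e)), call. = FALSE))
}

clinicNames <- c("AreaPPA", "AreaDisc", "Tilt", "Torsion", "Dist_MD",
                 "Angle_MD")

#' Run the full MM radiomics pipeline
#'
#' Executes extraction (322-column table), the stratified 70/30 split,
#' train-fitted z-score normalization, the MI and t-test filters and their
#' intersection, SFFS wrapper selection, the rise-plateau stopping rule,
#' the final random-forest decision model, and the evaluation battery:
#' validation AUC of the new / clinic / union feature sets, the univariate
#' cross-validated AUC table, the Pearson correlation of new versus clinic
#' features, META-PM subclass profiles, and cohort counts. Each stage logs
#' its feature bookkeeping; the summary line
#' `features: total->MI-pass->t-pass->intersection->selected` is emitted at
#' the end.
#'
#' @param config a [runConfig()].
#' @param cohort optional pre-built list(images, roiSets, labels) to bypass
#'   both simulation and disk input.
#' @param featureTable optional pre-extracted [FeatureTable-class]
#'   (skips extraction).
#' @return an [EvalReport-class]; artifacts are written when
#'   `config$outputDir` is set.
#' @export
runPipeline <- function(config, cohort = NULL, featureTable = NULL) {
  seed <- config$seed
  log_ <- function(...) message(sprintf(...))

  if (is.null(featureTable)) {
    if (is.null(cohort)) {
      if (!is.null(config$simulate)) {
        cohort <- withStage("simulate", {
          sim <- config$simulate
          cfg <- sim$cfg
          if (is.null(cfg)) cfg <- phantomConfig()
          generateCohort(cfg, sim$n, seed)
        })
      } else {
        cohort <- withStage("labels", {
          if (is.null(config$labelsFile) || !file.exists(config$labelsFile))
            stop("labels file not found: ",
                 if (is.null(config$labelsFile)) "<unset>"
                 else config$labelsFile)
          labels <- read.csv(config$labelsFile)
          withStage("images", {
            images <- lapply(seq_len(nrow(labels)), function(i)
              readFundus(file.path(config$imagesDir,
                                   paste0(labels$eyeId[i], ".png")),
                         laterality = labels$laterality[i],
                         eyeId = labels$eyeId[i],
                         patientId = labels$patientId[i]))
            roiSets <- lapply(seq_len(nrow(labels)), function(i) {
              img <- images[[i]]
              loadAnnotations(file.path(config$annotationsDir,
                                        paste0(labels$eyeId[i], ".json")),
                              dim(pixels(img))[1:2])
            })
            list(images = images, roiSets = roiSets, labels = labels)
          })
        })
      }
    }
    featureTable <- withStage("extract",
      extractCohortFeatures(cohort$images, cohort$roiSets, cohort$labels,
                            config$nLevels))
    log_("extract: %d features x %d eyes", nrow(featureTable),
         ncol(featureTable))
  }
  labels <- as.data.frame(SummarizedExperiment::colData(featureTable))

  sp <- withStage("split",
    splitTrainValidation(labels, seed, config$valFrac))
  split <- ifelse(labels$eyeId %in% sp$validation, "validation", "train")
  SummarizedExperiment::colData(featureTable)$split <- split
  log_("split: %d train / %d validation", length(sp$train),
       length(sp$validation))

  trainTbl <- splitSubset(featureTable, "train")
  valTbl <- splitSubset(featureTable, "validation")
  nz <- withStage("normalize", zscoreNormalize(trainTbl, val = valTbl))

  miKeep <- withStage("filter",
    mutualInformationFilter(nz$train, config$miThreshold))
  tKeep <- withStage("filter", ttestFilter(nz$train, config$alpha))
  cand <- withStage("filter", filterIntersection(
    rownames(featureTable)[rownames(featureTable) %in% miKeep],
    tKeep))
  log_("filter: MI %d, t-test %d, intersection %d", length(miKeep),
       length(tKeep), length(cand))

  trace <- withStage("sffs",
    sffsSelect(nz$train, cand, maxK = config$maxK, folds = config$folds,
               seed = seed, numTrees = config$numTreesWrapper,
               tol = config$tol, patience = config$patience))
  sel <- withStage("sffs", chooseFinalSet(trace, config$tol))
  trace <- finalizeTrace(trace, sel)
  log_("sffs: chose k = %d", attr(sel, "k"))

  newSet <- setdiff(sel, clinicNames)
  unionSet <- union(sel, clinicNames)
  aucOf <- function(features) {
    m <- fitDecisionModel(nz$train, features, seed, config$numTreesModel)
    rocAuc(predictSeverity(m, nz$val), severeLabels(nz$val))
  }
  setAuc <- withStage("evaluate", c(
    new = aucOf(if (length(newSet)) newSet else sel),
    clinic = aucOf(clinicNames),
    union = aucOf(unionSet)))

  X <- featureMatrix(featureTable)
  y <- severeLabels(featureTable)
  uni <- withStage("evaluate", {
    do.call(rbind, lapply(unionSet, function(f) {
      a <- univariateAucCv(X[, f], y, config$folds, seed)
      data.frame(feature = f,
                 set = if (f %in% clinicNames && f %in% sel) "both"
                 else if (f %in% clinicNames) "clinic" else "new",
                 meanAUC = a[["mean"]], sdAUC = a[["sd"]])
    }))
  })

  corr <- withStage("evaluate", {
    if (length(newSet))
      pearsonCorrelationMatrix(X[, newSet, drop = FALSE],
                               X[, clinicNames, drop = FALSE])
    else list(r = NULL, p = NULL, stars = NULL, flagged = character(0))
  })

  prof <- withStage("evaluate",
    subclassProfileAnalysis(featureTable, unionSet, config$aucFloor,
                            config$folds, seed))
  counts <- withStage("evaluate", groupCounts(labels))

  log_("features: %d->%d->%d->%d->%d", nrow(featureTable), length(miKeep),
       length(tKeep), length(cand), length(sel))

  report <- new("EvalReport", setAuc = setAuc, univariate = uni,
                correlation = corr, profiles = prof, counts = counts,
                meta = list(
                  nFeatures = nrow(featureTable),
                  nMiPass = length(miKeep), nTPass = length(tKeep),
                  nIntersection = length(cand), nSelected = length(sel),
                  chosenK = attr(sel, "k"), finalSet = as.character(sel),
                  newSet = newSet, unionSet = unionSet,
                  nTrain = length(sp$train),
                  nValidation = length(sp$validation),
                  seed = seed, trace = trace))

  if (!is.null(config$outputDir)) {
    withStage("artifacts", {
      dir.create(config$outputDir, recursive = TRUE, showWarnings = FALSE)
      writeFeatureCSV(featureTable,
                      file.path(config$outputDir, "features.csv"))
      write.csv(selectionScores(trace),
                file.path(config$outputDir, "selection_trace.csv"),
                row.names = FALSE)
      writeLines(as.character(sel),
                 file.path(config$outputDir, "chosen_features.txt"))
      write.csv(labels, file.path(config$outputDir, "labels.csv"),
                row.names = FALSE)
      jsonlite::write_json(list(
        setAuc = as.list(setAuc), univariate = uni,
        bookkeeping = report@meta[c("nFeatures", "nMiPass", "nTPass",
                                    "nIntersection", "nSelected")],
        counts = counts$perGroup, seed = seed),
        file.path(config$outputDir, "report.json"), auto_unbox = TRUE,
        digits = NA)
    })
  }
  report
}

#' Plot the SFFS score curve (mean +/- SD per cardinality)
#'
#' @param trace a [SelectionTrace-class].
#' @export
plotSelectionTrace <- function(trace) {
  tr <- selectionScores(trace)
  graphics::plot(tr$k, tr$meanScore, type = "b", pch = 19,
                 ylim = range(c(tr$meanScore - tr$sdScore,
                                tr$meanScore + tr$sdScore), na.rm = TRUE),
                 xlab = "number of selected features",
                 ylab = "mean CV score")
  graphics::arrows(tr$k, tr$meanScore - tr$sdScore, tr$k,
                   tr$meanScore + tr$sdScore, angle = 90, code = 3,
                   length = 0.03)
  if (!is.na(chosenK(trace)))
    graphics::abline(v = chosenK(trace), lty = 2)
  invisible(trace)
}

#' Plot per-grade subclass profiles (mean +/- SD per META-PM grade)
#'
#' @param report an [EvalReport-class] whose profiles slot is populated.
#' @export
plotSubclassProfiles <- function(report) {
  pr <- report@profiles
  if (is.null(pr$profile)) {
    warning("no features above the univariate AUC floor")
    return(invisible(report))
  }
  m <- pr$profile$mean; s <- pr$profile$sd
  old <- graphics::par(mfrow = c(nrow(m), 1), mar = c(2, 4, 1, 1))
  on.exit(graphics::par(old))
  for (f in rownames(m)) {
    graphics::plot(seq_len(ncol(m)), m[f, ], type = "b", pch = 19,
                   xaxt = "n", xlab = "", ylab = f,
                   ylim = range(c(m[f, ] - s[f, ], m[f, ] + s[f, ]),
                                na.rm = TRUE))
    graphics::axis(1, at = seq_len(ncol(m)), labels = colnames(m))
    graphics::arrows(seq_len(ncol(m)), m[f, ] - s[f, ], seq_len(ncol(m)),
                     m[f, ] + s[f, ], angle = 90, code = 3, length = 0.03)
  }
  invisible(report)
}
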