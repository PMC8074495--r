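# FeatureTable construction and serialization.

#' Build a FeatureTable from a feature matrix and study labels
#'
#' @param values eyes x features numeric matrix (row names = eye ids).
#' @param categories named character vector mapping feature name to
#'   category (morphologic/intensity/texture/clinic); defaults to
#'   "morphologic" when unspecified.
#' @param labels data.frame with one row per eye: `eyeId`, optional
#'   `patientId`, `laterality`, `grade`, `plusLesion`, and either `severe`
#'   or the ingredients to derive it via [assignSeverityGroup()].
#' @param split optional character vector (train/validation) per eye.
#' @return a [FeatureTable-class].
#' @export
buildFeatureTable <- function(values, categories = NULL, labels,
                              split = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) rownames(values) <- labels$eyeId
  if (any(!is.finite(values)))
    stop("buildFeatureTable: feature matrix contains non-finite values")
  fn <- colnames(values)
  if (is.null(categories)) categories <- setNames(rep("morphologic",
                                                      length(fn)), fn)
  labels <- as.data.frame(labels)
  if (is.null(labels$severe)) {
    labels$severe <- as.integer(
      assignSeverityGroup(labels$grade, labels$plusLesion) == "severe")
  }
  if (is.null(labels$grade)) labels$grade <- NA_character_
  if (is.null(labels$plusLesion)) labels$plusLesion <- FALSE
  if (is.null(labels$patientId)) labels$patientId <- labels$eyeId
  if (is.null(labels$laterality)) labels$laterality <- NA_character_
  labels$split <- if (is.null(split)) NA_character_ else split
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = t(values)),
    rowData = S4Vectors::DataFrame(category = unname(categories[fn]),
                                   row.names = fn),
    colData = S4Vectors::DataFrame(labels, row.names = labels$eyeId))
  new("FeatureTable", se)
}

#' Extract features for a whole cohort into a FeatureTable
#'
#' Canonicalizes each eye's orientation, extracts the 322-column feature
#' vector and assembles the table.
#'
#' @param images list of [FundusImage-class].
#' @param roiSets list of matching [RoiSet-class].
#' @param labels data.frame of study labels (one row per eye, same order).
#' @param nLevels quantization levels (default 32).
#' @return a [FeatureTable-class] with 322 feature rows.
#' @export
extractCohortFeatures <- function(images, roiSets, labels, nLevels = 32L) {
  stopifnot(length(images) == length(roiSets),
            length(images) == nrow(labels))
  rows <- vector("list", length(images))
  for (i in seq_along(images)) {
    can <- canonicalizeOrientation(images[[i]], roiSets[[i]])
    rows[[i]] <- extractFeatureVector(can$image, can$rois, nLevels)
  }
  cats <- attr(rows[[1]], "categories")
  values <- do.call(rbind, lapply(rows, as.numeric))
  colnames(values) <- names(rows[[1]])
  rownames(values) <- labels$eyeId
  buildFeatureTable(values, cats, labels)
}

#' Write a FeatureTable to CSV (features x metadata + per-eye columns)
#'
#' The CSV carries one row per feature with its category, followed by one
#' column per eye, matching the package's stable feature order.
#'
#' @param x a [FeatureTable-class].
#' @param path output CSV path.
#' @export
writeFeatureCSV <- function(x, path) {
  df <- data.frame(feature = rownames(x),
                   category = SummarizedExperiment::rowData(x)$category,
                   SummarizedExperiment::assay(x, "features"),
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# subset a FeatureTable to the eyes with a given split tag
splitSubset <- function(x, tag) {
  x[, which(splitTag(x) == tag)]
}
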