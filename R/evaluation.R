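# Severity grouping, split, ROC/AUC, univariate CV AUC, correlation,
# subclass profiles, cohort counts.

metaPmGrades <- c("C0", "C1", "PDCA", "MDCA", "C3", "C4")

#' Assign the severe / without-severe MM group
#'
#' An eye is severe when its META-PM grade is MDCA or worse (MDCA, C3, C4)
#' or when plus lesions (lacquer cracks, myopic CNV, Fuchs' spot) are
#' present; eyes graded C0, C1 or PDCA without plus lesions are
#' without-severe.
#'
#' @param grade character vector of grades (C0, C1, PDCA, MDCA, C3, C4).
#' @param plusLesion logical vector (missing/NA treated as FALSE).
#' @return character vector, `"severe"` or `"without"`.
#' @export
assignSeverityGroup <- function(grade, plusLesion = FALSE) {
  grade <- as.character(grade)
  bad <- !grade %in% metaPmGrades
  if (any(bad))
    stop("assignSeverityGroup: unknown grade(s): ",
         paste(unique(grade[bad]), collapse = ", "))
  plusLesion <- as.logical(plusLesion)
  plusLesion[is.na(plusLesion)] <- FALSE
  plusLesion <- rep_len(plusLesion, length(grade))
  ifelse(grade %in% c("MDCA", "C3", "C4") | plusLesion, "severe", "without")
}

#' Stratified 70/30 train/validation split
#'
#' Validation takes ceiling(0.3 n) eyes (so n = 457 gives 319 train / 138
#' validation), stratified by severity via largest-remainder allocation
#' across the two groups; the shuffle is seeded. If either side misses a
#' class the draw is repeated (up to 10 times) before failing.
#'
#' @param labels data.frame with `eyeId` and `severe` (0/1) per eye.
#' @param seed integer seed.
#' @param valFrac validation fraction (default 0.3).
#' @return list with `train` and `validation` eye-id vectors.
#' @export
splitTrainValidation <- function(labels, seed = 1L, valFrac = 0.3) {
  n <- nrow(labels)
  if (n < 10L) stop("splitTrainValidation: need at least 10 eyes")
  if (length(unique(labels$severe)) < 2L)
    stop("splitTrainValidation: both classes required")
  nVal <- ceiling(valFrac * n)
  set.seed(seed)
  for (attempt in 1:10) {
    groups <- split(labels$eyeId, labels$severe)
    quota <- vapply(groups, length, 0L) * valFrac
    take <- floor(quota)
    rem <- quota - take
    short <- nVal - sum(take)
    if (short > 0)
      take[order(rem, decreasing = TRUE)[seq_len(short)]] <-
        take[order(rem, decreasing = TRUE)[seq_len(short)]] + 1L
    val <- unlist(lapply(names(groups), function(g)
      sample(groups[[g]])[seq_len(take[[g]])]), use.names = FALSE)
    tr <- setdiff(labels$eyeId, val)
    sevOf <- setNames(labels$severe, labels$eyeId)
    if (length(unique(sevOf[val])) == 2L && length(unique(sevOf[tr])) == 2L)
      return(list(train = tr, validation = val))
  }
  stop("splitTrainValidation: could not produce a class-complete split")
}

#' ROC AUC (trapezoidal / Mann-Whitney)
#'
#' Trapezoidal area under the ROC curve, equal to the Mann-Whitney U
#' probability that a random severe eye outscores a random non-severe eye,
#' with ties counted one half.
#'
#' @param scores numeric scores (higher = more severe).
#' @param labels binary 0/1 labels.
#' @return AUC in [0, 1].
#' @export
rocAuc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) stop("rocAuc: both classes required")
  aucRank(scores, labels)
}

#' Univariate logistic AUC under stratified k-fold cross-validation
#'
#' Per fold a single-covariate logistic regression is fitted on the
#' remaining folds and its held-out eyes are scored; reported are the mean
#' and SD of the per-fold AUCs.
#'
#' @param feature numeric per-eye values.
#' @param labels binary 0/1 labels.
#' @param folds CV folds (default 5).
#' @param seed integer seed for the fold shuffle.
#' @return named numeric `c(mean, sd)`.
#' @export
univariateAucCv <- function(feature, labels, folds = 5L, seed = 1L) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop("univariateAucCv: both classes required")
  foldId <- stratifiedFolds(labels, folds, seed)
  aucs <- vapply(seq_len(folds), function(f) {
    tr <- foldId != f
    if (length(unique(labels[!tr])) < 2L)
      stop("univariateAucCv: degenerate fold")
    fit <- suppressWarnings(glm(y ~ x,
      data = data.frame(y = labels[tr], x = feature[tr]),
      family = binomial()))
    p <- suppressWarnings(
      predict(fit, newdata = data.frame(x = feature[!tr]), type = "response"))
    aucRank(p, labels[!tr])
  }, 0)
  c(mean = mean(aucs), sd = sd(aucs))
}

#' Pearson correlation matrix with significance stars
#'
#' Pairwise Pearson r between two feature blocks, two-sided p from the
#' t transform with n - 2 degrees of freedom, stars at p < 0.05 (*),
#' p < 0.01 (**) and p < 0.001 (***). Zero-variance columns yield r = 0
#' and are flagged.
#'
#' @param a,b numeric matrices (eyes x features).
#' @return list of matrices `r`, `p`, `stars`, plus `flagged` column names.
#' @export
pearsonCorrelationMatrix <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  n <- nrow(a)
  if (n < 3L) stop("pearsonCorrelationMatrix: need >= 3 eyes")
  zva <- apply(a, 2L, sd) == 0
  zvb <- apply(b, 2L, sd) == 0
  r <- suppressWarnings(cor(a, b))
  r[zva, ] <- 0; r[, zvb] <- 0
  r[!is.finite(r)] <- 0
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p[zva, ] <- 1; p[, zvb] <- 1
  stars <- matrix("", nrow(p), ncol(p), dimnames = dimnames(p))
  stars[p < 0.05] <- "*"
  stars[p < 0.01] <- "**"
  stars[p < 0.001] <- "***"
  list(r = r, p = p, stars = stars,
       flagged = c(colnames(a)[zva], colnames(b)[zvb]))
}

#' Subclass mean/SD profiles with adjacent-grade change flags
#'
#' For every candidate feature whose univariate cross-validated mean AUC
#' exceeds `aucFloor`, the per-grade mean and SD over the whole cohort are
#' tabulated in META-PM order (C0, C1, PDCA, MDCA, C3, C4), and each
#' adjacent-grade transition is tested with Welch's t-test; a transition is
#' flagged "marked" at p < 0.01.
#'
#' @param table a [FeatureTable-class] with grades in `colData`.
#' @param features candidate feature names (default: all rows).
#' @param aucFloor univariate AUC floor (default 0.75).
#' @param folds,seed passed to [univariateAucCv()].
#' @return list with `features` (those above the floor), `auc` (their
#'   univariate mean AUC), `profile` (feature x grade mean and SD tables)
#'   and `transitions` (data.frame of adjacent-grade tests).
#' @export
subclassProfileAnalysis <- function(table, features = rownames(table),
                                    aucFloor = 0.75, folds = 5L, seed = 1L) {
  X <- featureMatrix(table)[, features, drop = FALSE]
  y <- severeLabels(table)
  grade <- as.character(SummarizedExperiment::colData(table)$grade)
  present <- metaPmGrades[metaPmGrades %in% grade]
  if (length(present) < 2L) {
    warning("subclassProfileAnalysis: fewer than two grades present")
    return(list(features = character(0), auc = numeric(0),
                profile = NULL, transitions = NULL))
  }
  auc <- vapply(features, function(f)
    univariateAucCv(X[, f], y, folds, seed)[["mean"]], 0)
  sel <- features[auc > aucFloor]
  if (!length(sel))
    return(list(features = character(0), auc = auc,
                profile = NULL, transitions = NULL))
  mean_ <- sapply(metaPmGrades, function(g)
    colMeans(X[grade == g, sel, drop = FALSE]))
  sd_ <- sapply(metaPmGrades, function(g)
    apply(X[grade == g, sel, drop = FALSE], 2L, sd))
  mean_ <- matrix(mean_, nrow = length(sel),
                  dimnames = list(sel, metaPmGrades))
  sd_ <- matrix(sd_, nrow = length(sel), dimnames = list(sel, metaPmGrades))
  trans <- expand.grid(feature = sel,
                       from = metaPmGrades[-6], stringsAsFactors = FALSE)
  trans$to <- metaPmGrades[match(trans$from, metaPmGrades) + 1L]
  trans$p <- NA_real_
  for (i in seq_len(nrow(trans))) {
    a <- X[grade == trans$from[i], trans$feature[i]]
    b <- X[grade == trans$to[i], trans$feature[i]]
    if (length(a) < 2L || length(b) < 2L) {
      warning(sprintf("subclassProfileAnalysis: %s -> %s skipped (empty)",
                      trans$from[i], trans$to[i]))
      next
    }
    trans$p[i] <- tryCatch(t.test(a, b)$p.value, error = function(e) NA_real_)
  }
  trans$marked <- !is.na(trans$p) & trans$p < 0.01
  list(features = sel, auc = auc, profile = list(mean = mean_, sd = sd_),
       transitions = trans)
}

# half-up rounding to one decimal (matches the cohort table's style)
roundHalfUp1 <- function(x) floor(x * 10 + 0.5) / 10

#' Cohort counts per grade and severity group
#'
#' @param labels data.frame with `grade` and optionally `plusLesion` (an
#'   absent/empty column is treated as all FALSE).
#' @return list with `perGrade` (count and percent per META-PM grade) and
#'   `perGroup` (without/severe totals).
#' @export
groupCounts <- function(labels) {
  if (!nrow(labels)) stop("groupCounts: empty labels")
  grade <- as.character(labels$grade)
  plus <- labels$plusLesion
  if (is.null(plus)) plus <- rep(FALSE, nrow(labels))
  cnt <- vapply(metaPmGrades, function(g) sum(grade == g), 0L)
  pct <- roundHalfUp1(100 * cnt / length(grade))
  grp <- assignSeverityGroup(grade, plus)
  list(perGrade = data.frame(grade = metaPmGrades, n = cnt, pct = pct),
       perGroup = c(without = sum(grp == "without"),
                    severe = sum(grp == "severe"),
                    total = length(grp)))
}
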