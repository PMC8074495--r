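# MM-related feature mining: z-score normalization, mutual-information and
# t-test filters, SFFS wrapper selection scored by random-forest
# cross-validation, the stopping rule, and the final decision model.

#' Z-score normalization fitted on the training split
#'
#' Per feature: subtract the training mean and divide by the training
#' (population) SD. Zero-SD features map to 0 everywhere and are flagged.
#' The same train-fitted scaler is applied to any further tables, so no
#' information leaks from validation into the scaler.
#'
#' @param train a [FeatureTable-class] (the training eyes).
#' @param ... further FeatureTables (e.g. the validation eyes) to transform
#'   with the train-fitted scaler.
#' @return list with `train`, one transformed table per extra argument
#'   (named as passed, or `other1`, ...), and `scaler` (list of `mean`,
#'   `sd`, `zeroSd` feature names).
#' @export
zscoreNormalize <- function(train, ...) {
  if (ncol(train) == 0L) stop("zscoreNormalize: empty training table")
  X <- featureMatrix(train)
  mu <- colMeans(X)
  sdev <- sqrt(colMeans(sweep(X, 2L, mu)^2))  # population SD
  zero <- sdev == 0
  apply1 <- function(tbl) {
    Z <- sweep(featureMatrix(tbl), 2L, mu)
    Z <- sweep(Z, 2L, ifelse(zero, 1, sdev), "/")
    Z[, zero] <- 0
    out <- tbl
    SummarizedExperiment::assay(out, "features") <- t(Z)
    out
  }
  extras <- list(...)
  if (length(extras) && is.null(names(extras)))
    names(extras) <- paste0("other", seq_along(extras))
  out <- c(list(train = apply1(train)), lapply(extras, apply1))
  out$scaler <- list(mean = mu, sd = sdev, zeroSd = names(mu)[zero])
  out
}

# plug-in mutual information (bits) between a discretized feature and a
# binary label, with nBins equal-frequency bins
miBits <- function(x, y, nBins = 10L) {
  br <- unique(quantile(x, probs = seq(0, 1, length.out = nBins + 1L),
                        names = FALSE))
  if (length(br) < 2L) return(0)
  bx <- cut(x, breaks = br, include.lowest = TRUE, labels = FALSE)
  tab <- table(bx, y)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  e <- outer(px, py)
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / e[nz]))
}

#' Mutual-information filter
#'
#' Estimates MI(feature; severe label) in bits by discretizing each feature
#' into 10 equal-frequency bins (plug-in estimator) and retains features
#' with MI strictly above the threshold.
#'
#' @param table a [FeatureTable-class] (typically the normalized training
#'   split); both classes must be present.
#' @param threshold MI threshold in bits (default 0.2).
#' @param nBins discretization bins (default 10).
#' @return character vector of retained feature names, with attribute
#'   `mi` holding all MI values.
#' @export
mutualInformationFilter <- function(table, threshold = 0.2, nBins = 10L) {
  y <- severeLabels(table)
  if (length(unique(y)) < 2L)
    stop("mutualInformationFilter: both classes must be present")
  X <- featureMatrix(table)
  mi <- apply(X, 2L, miBits, y = y, nBins = nBins)
  keep <- colnames(X)[mi > threshold]
  attr(keep, "mi") <- mi
  keep
}

#' Pooled-variance two-sample t-test filter
#'
#' Two-sided Student's t-test per feature between severe and non-severe
#' eyes; features with p below `alpha` are retained. Zero pooled variance
#' is resolved by the group means: equal means give p = 1 (dropped),
#' different means p = 0 (retained).
#'
#' @param table a [FeatureTable-class]; at least two eyes per class.
#' @param alpha significance level (default 0.05).
#' @return character vector of retained feature names, with attribute `p`.
#' @export
ttestFilter <- function(table, alpha = 0.05) {
  y <- severeLabels(table)
  if (min(table(y)) < 2L)
    stop("ttestFilter: need at least 2 eyes per class")
  X <- featureMatrix(table)
  g1 <- y == 1L; g0 <- !g1
  n1 <- sum(g1); n0 <- sum(g0)
  m1 <- colMeans(X[g1, , drop = FALSE]); m0 <- colMeans(X[g0, , drop = FALSE])
  v1 <- apply(X[g1, , drop = FALSE], 2L, var)
  v0 <- apply(X[g0, , drop = FALSE], 2L, var)
  sp2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n0))
  tt <- (m1 - m0) / se
  p <- 2 * pt(abs(tt), df = n1 + n0 - 2, lower.tail = FALSE)
  p[se == 0] <- ifelse(m1[se == 0] == m0[se == 0], 1, 0)
  keep <- colnames(X)[p < alpha]
  attr(keep, "p") <- p
  keep
}

#' Intersection of two filter results
#'
#' Order is preserved by the first argument's (original column) order. An
#' empty intersection triggers a warning since the wrapper stage needs at
#' least one candidate.
#'
#' @param a,b character vectors of feature names.
#' @return character vector.
#' @export
filterIntersection <- function(a, b) {
  out <- a[a %in% b]
  if (!length(out)) warning("filterIntersection: empty intersection")
  attributes(out) <- NULL
  out
}

# rank-based ROC AUC (Mann-Whitney with ties counted 1/2); the hot-loop
# scorer behind the SFFS criterion
aucRank <- function(scores, y) {
  n1 <- sum(y == 1L); n0 <- length(y) - n1
  if (n1 == 0L || n0 == 0L) stop("aucRank: both classes required")
  r <- rank(scores)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n0 * n1)
}

# stratified fold assignment, seeded
stratifiedFolds <- function(y, folds, seed) {
  set.seed(seed)
  f <- integer(length(y))
  for (cls in unique(y)) {
    i <- which(y == cls)
    f[i] <- sample(rep_len(seq_len(folds), length(i)))
  }
  f
}

# mean/sd of the CV criterion for one feature subset
cvCriterion <- function(X, y, foldId, numTrees, seed, criterion = "auc") {
  k <- max(foldId)
  sc <- numeric(k)
  yf <- factor(y, levels = c(0L, 1L))
  for (f in seq_len(k)) {
    tr <- foldId != f
    fit <- ranger::ranger(x = X[tr, , drop = FALSE], y = yf[tr],
                          num.trees = numTrees, probability = TRUE,
                          num.threads = 1L, seed = seed)
    p <- predict(fit, data = X[!tr, , drop = FALSE],
                 num.threads = 1L)$predictions[, "1"]
    sc[f] <- if (criterion == "auc") aucRank(p, y[!tr])
    else mean((p > 0.5) == (y[!tr] == 1L))
  }
  c(mean = mean(sc), sd = sd(sc))
}

#' Sequential floating forward selection with a random-forest criterion
#'
#' Classic SFFS: at each step the candidate whose addition maximizes the
#' criterion joins the subset, then features are conditionally removed while
#' removal strictly improves on the best score previously recorded at the
#' smaller cardinality. The criterion is the mean ROC AUC of a
#' random-forest classifier over stratified k-fold cross-validation on the
#' training eyes (accuracy available via `criterion = "accuracy"`). The
#' forward search stops at `maxK` (clamped to the candidate count with a
#' warning) or earlier when the running best score has not improved by more
#' than `tol` for `patience` consecutive cardinalities; the rise-plateau
#' rule of [chooseFinalSet()] never chooses cardinalities that far past the
#' plateau, so the truncation does not affect the final set. Candidate ties
#' are broken by original column order. All randomness (folds, forests) is
#' governed by `seed`.
#'
#' @param table a [FeatureTable-class] (normalized training eyes).
#' @param candidates character vector of candidate feature names.
#' @param maxK maximal cardinality evaluated (default 30).
#' @param folds CV folds (default 5).
#' @param seed integer seed.
#' @param numTrees trees per scoring forest (default 50).
#' @param criterion `"auc"` (default) or `"accuracy"`.
#' @param tol,patience early-stop rule for the forward search (defaults
#'   0.005 and 6; `patience = Inf` disables it).
#' @return a [SelectionTrace-class].
#' @export
sffsSelect <- function(table, candidates, maxK = 30L, folds = 5L, seed = 1L,
                       numTrees = 50L, criterion = "auc", tol = 0.005,
                       patience = 6) {
  if (!length(candidates)) stop("sffsSelect: no candidates")
  y <- severeLabels(table)
  if (length(unique(y)) < 2L) stop("sffsSelect: both classes required")
  X <- featureMatrix(table)[, candidates, drop = FALSE]
  if (maxK > length(candidates)) {
    warning("sffsSelect: maxK clamped to the number of candidates")
    maxK <- length(candidates)
  }
  foldId <- stratifiedFolds(y, folds, seed)
  evalSet <- function(set) {
    v <- cvCriterion(X[, set, drop = FALSE], y, foldId, numTrees, seed,
                     criterion)
    if (!all(is.finite(v))) stop("sffsSelect: non-finite criterion")
    v
  }
  bestScore <- rep(-Inf, maxK)
  bestSd <- rep(NA_real_, maxK)
  bestSet <- vector("list", maxK)
  cur <- character(0)
  runningBest <- -Inf
  stall <- 0
  while (length(cur) < maxK) {
    rem <- setdiff(candidates, cur)
    sc <- vapply(rem, function(f) evalSet(c(cur, f))[["mean"]], 0)
    pick <- rem[which.max(sc)]          # ties: first in column order
    cur <- c(cur, pick)
    v <- evalSet(cur)
    k <- length(cur)
    if (v[["mean"]] > bestScore[k]) {
      bestScore[k] <- v[["mean"]]; bestSd[k] <- v[["sd"]]
      bestSet[[k]] <- cur
    }
    # conditional exclusion: drop a feature while that strictly improves
    # the record at the smaller cardinality
    while (length(cur) > 2L) {
      drops <- vapply(seq_along(cur), function(i)
        evalSet(cur[-i])[["mean"]], 0)
      i <- which.max(drops)
      if (drops[i] > bestScore[length(cur) - 1L]) {
        cur <- cur[-i]
        k <- length(cur)
        v2 <- evalSet(cur)
        bestScore[k] <- v2[["mean"]]; bestSd[k] <- v2[["sd"]]
        bestSet[[k]] <- cur
      } else break
    }
    if (max(bestScore[seq_len(length(cur))]) > runningBest + tol) {
      runningBest <- max(bestScore[seq_len(length(cur))])
      stall <- 0
    } else {
      stall <- stall + 1
      if (stall >= patience) break
    }
  }
  have <- which(is.finite(bestScore))
  new("SelectionTrace",
      trace = data.frame(k = have, meanScore = bestScore[have],
                         sdScore = bestSd[have]),
      subsets = bestSet[have],
      criterion = criterion, seed = as.integer(seed))
}

#' Choose the final feature set from an SFFS trace (rise-plateau rule)
#'
#' The chosen cardinality is the smallest k such that no larger cardinality
#' improves the mean CV score by more than `tol` over the score at k: the
#' point where the rising phase of the score curve plateaus, trading
#' classification performance against model refinement.
#'
#' @param trace a [SelectionTrace-class].
#' @param tol plateau tolerance on the mean score (default 0.005).
#' @return character vector of the chosen features, with attribute `k`.
#' @export
chooseFinalSet <- function(trace, tol = 0.005) {
  tr <- trace@trace
  if (!nrow(tr)) stop("chooseFinalSet: empty trace")
  m <- tr$meanScore
  chosen <- nrow(tr)
  for (i in seq_len(nrow(tr))) {
    later <- if (i < nrow(tr)) m[(i + 1):nrow(tr)] else numeric(0)
    if (!length(later) || max(later) - m[i] <= tol) { chosen <- i; break }
  }
  out <- trace@subsets[[chosen]]
  attr(out, "k") <- tr$k[chosen]
  out
}

# store the final set back onto a trace
finalizeTrace <- function(trace, finalSet) {
  trace@chosenK <- as.integer(attr(finalSet, "k"))
  trace@finalSet <- as.character(finalSet)
  trace
}

#' Fit the final random-forest decision model
#'
#' A 100-tree probability random forest on the training eyes restricted to
#' the chosen feature subset.
#'
#' @param table a [FeatureTable-class] (normalized training eyes).
#' @param features character vector of feature names.
#' @param seed integer seed.
#' @param numTrees trees (default 100).
#' @return an object of class `mmDecisionModel` with elements `forest` and
#'   `features`; score new tables with [predictSeverity()].
#' @export
fitDecisionModel <- function(table, features, seed = 1L, numTrees = 100L) {
  if (!length(features)) stop("fitDecisionModel: empty feature set")
  X <- featureMatrix(table)
  missing <- setdiff(features, colnames(X))
  if (length(missing))
    stop("fitDecisionModel: unknown features: ",
         paste(missing, collapse = ", "))
  y <- factor(severeLabels(table), levels = c(0L, 1L))
  if (length(unique(y)) < 2L) stop("fitDecisionModel: both classes required")
  forest <- ranger::ranger(x = X[, features, drop = FALSE], y = y,
                           num.trees = numTrees, probability = TRUE,
                           num.threads = 1L, seed = seed)
  structure(list(forest = forest, features = features, seed = seed),
            class = "mmDecisionModel")
}

#' Predict severe-MM probabilities from a decision model
#'
#' @param model an `mmDecisionModel` from [fitDecisionModel()].
#' @param table a [FeatureTable-class] containing the model's features.
#' @return named numeric vector of class-1 (severe) probabilities.
#' @export
predictSeverity <- function(model, table) {
  X <- featureMatrix(table)[, model$features, drop = FALSE]
  p <- predict(model$forest, data = X, num.threads = 1L)$predictions[, "1"]
  setNames(p, rownames(X))
}

#' @export
print.mmDecisionModel <- function(x, ...) {
  cat(sprintf("mmDecisionModel: %d-tree random forest on %d features\n",
              x$forest$num.trees, length(x$features)))
  invisible(x)
}
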