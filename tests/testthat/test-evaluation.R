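# Severity grouping, split arithmetic, ROC/AUC, univariate CV AUC,
# correlation, subclass profiles, cohort counts.

test_that("severity grouping follows the META-PM rule with plus lesions", {
  expect_equal(assignSeverityGroup("MDCA", FALSE), "severe")
  expect_equal(assignSeverityGroup("C3", FALSE), "severe")
  expect_equal(assignSeverityGroup("C4", FALSE), "severe")
  expect_equal(assignSeverityGroup("PDCA", FALSE), "without")
  expect_equal(assignSeverityGroup("C0", FALSE), "without")
  expect_equal(assignSeverityGroup("C1", TRUE), "severe")
  expect_error(assignSeverityGroup("C2", FALSE), "unknown grade")
})

test_that("the 70/30 split gives 319/138 on 457 eyes, is stratified and
           seeded", {
  labels <- data.frame(eyeId = sprintf("e%03d", 1:457),
                       severe = rep(c(0L, 1L), c(278, 179)))
  sp <- splitTrainValidation(labels, seed = 4)
  expect_length(sp$train, 319)
  expect_length(sp$validation, 138)
  sev <- setNames(labels$severe, labels$eyeId)
  # stratification keeps the class share within one eye per stratum
  expect_equal(sum(sev[sp$validation]), round(0.3 * 179), tolerance = 1)

  sp2 <- splitTrainValidation(labels, seed = 4)
  expect_identical(sp, sp2)
  sp3 <- splitTrainValidation(labels, seed = 5)
  expect_false(identical(sp, sp3))

  small <- data.frame(eyeId = letters[1:10], severe = rep(c(0L, 1L), 5))
  spS <- splitTrainValidation(small, seed = 1)
  expect_length(spS$validation, 3)
  expect_length(spS$train, 7)
})

test_that("trapezoidal AUC equals pair counting and honors tie and
           complement identities", {
  expect_equal(rocAuc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1)
  expect_equal(rocAuc(rep(0.5, 8), rep(c(0, 1), 4)), 0.5)
  set.seed(12)
  for (i in 1:5) {
    sc <- round(rnorm(20), 1)   # rounding forces ties
    y <- rbinom(20, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_equal(rocAuc(sc, y), bfAuc(sc, y), tolerance = 1e-12)
    expect_equal(rocAuc(sc, y) + rocAuc(-sc, y), 1, tolerance = 1e-12)
    if (requireNamespace("pROC", quietly = TRUE))
      expect_equal(rocAuc(sc, y),
                   as.numeric(pROC::auc(pROC::roc(y, sc, quiet = TRUE,
                                                  direction = "<"))),
                   tolerance = 1e-12)
  }
  expect_error(rocAuc(1:3, c(1, 1, 1)), "both classes")
})

test_that("univariate logistic CV AUC matches the binormal closed form", {
  # perfectly separating feature
  yS <- rep(c(0L, 1L), each = 50)
  xS <- c(rnorm(50, 0, 0.1), rnorm(50, 10, 0.1))
  uS <- univariateAucCv(xS, yS, seed = 1)
  expect_equal(unname(uS["mean"]), 1)
  expect_equal(unname(uS["sd"]), 0)

  # standardized shift 2: population AUC = Phi(2 / sqrt(2))
  set.seed(21)
  y <- rbinom(2000, 1, 0.5)
  x <- rnorm(2000) + 2 * y
  u <- univariateAucCv(x, y, seed = 21)
  expect_lt(abs(u[["mean"]] - pnorm(2 / sqrt(2))), 0.02)

  # label-independent feature sits at chance
  xN <- rnorm(2000)
  uN <- univariateAucCv(xN, y, seed = 22)
  expect_lt(abs(uN[["mean"]] - 0.5), 0.05)
})

test_that("Pearson correlation matrix matches closed forms, stars and
           permutation invariance", {
  set.seed(5)
  x <- rnorm(30)
  a <- cbind(x = x, z = rnorm(30))
  b <- cbind(lin = -3 * x + 7, cst = rep(2, 30))
  pc <- pearsonCorrelationMatrix(a, b)
  expect_equal(unname(pc$r["x", "lin"]), -1, tolerance = 1e-12)
  expect_equal(unname(pc$r["x", "cst"]), 0)
  expect_true("cst" %in% pc$flagged)

  a5 <- cbind(v = 1:5)
  b5 <- cbind(w = c(2, 1, 4, 3, 5))
  pc5 <- pearsonCorrelationMatrix(a5, b5)
  expect_equal(unname(pc5$r["v", "w"]), 0.8, tolerance = 1e-12)
  expect_equal(unname(pc5$p["v", "w"]),
               cor.test(1:5, c(2, 1, 4, 3, 5))$p.value, tolerance = 1e-9)

  perm <- sample(30)
  pcP <- pearsonCorrelationMatrix(a[perm, ], b[perm, ])
  expect_equal(pc$r, pcP$r, tolerance = 1e-12)

  self <- pearsonCorrelationMatrix(cbind(s = x), cbind(s = x))
  expect_equal(unname(self$r[1, 1]), 1)
  expect_equal(unname(self$stars[1, 1]), "***")
})

test_that("cohort counts reproduce the published grouping arithmetic", {
  counts <- c(C0 = 44, C1 = 112, PDCA = 122, MDCA = 104, C3 = 45, C4 = 30)
  labels <- data.frame(
    grade = rep(names(counts), counts),
    plusLesion = FALSE)
  gc <- groupCounts(labels)
  expect_equal(unname(gc$perGroup["without"]), 278)
  expect_equal(unname(gc$perGroup["severe"]), 179)
  expect_equal(unname(gc$perGroup["total"]), 457)
  expect_equal(gc$perGrade$pct[gc$perGrade$grade == "C0"], 9.6)
  expect_equal(gc$perGrade$n, unname(counts))
  expect_equal(sum(gc$perGroup[c("without", "severe")]),
               unname(gc$perGroup["total"]))

  # absent plus-lesion column treated as all FALSE
  gc2 <- groupCounts(data.frame(grade = rep(names(counts), counts)))
  expect_equal(gc2$perGroup, gc$perGroup)
})

test_that("subclass profiles flag planted adjacent-grade steps and stay
           quiet on nulls", {
  set.seed(31)
  n <- 240
  grades <- sample(c("C0", "C1", "PDCA", "MDCA", "C3", "C4"), n,
                   replace = TRUE)
  step <- ifelse(grades %in% c("MDCA", "C3", "C4"), 3, 0)
  X <- cbind(AreaPPAlike = rnorm(n) + step, inert = rnorm(n))
  labels <- data.frame(eyeId = sprintf("e%03d", 1:n), grade = grades,
                       plusLesion = FALSE)
  ft <- buildFeatureTable(X, setNames(rep("morphologic", 2), colnames(X)),
                          labels)
  pr <- subclassProfileAnalysis(ft, aucFloor = 0.75, seed = 31)
  expect_true("AreaPPAlike" %in% pr$features)
  expect_false("inert" %in% pr$features)
  tr <- pr$transitions
  expect_true(tr$marked[tr$feature == "AreaPPAlike" & tr$from == "PDCA"])
  expect_false(tr$marked[tr$feature == "AreaPPAlike" & tr$from == "C3"])
  expect_false(tr$marked[tr$feature == "AreaPPAlike" & tr$from == "C0"])

  # null cohorts: alpha control across 20 seeds and 5 transitions
  falseFlags <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    g <- sample(c("C0", "C1", "PDCA", "MDCA", "C3", "C4"), 240,
                replace = TRUE)
    sev <- ifelse(g %in% c("MDCA", "C3", "C4"), 1L, 0L)
    # feature separates severity (to pass the AUC floor) but is sampled
    # identically within every grade of the same group
    Xn <- cbind(f = rnorm(240) + 3 * sev)
    lab <- data.frame(eyeId = sprintf("n%03d", 1:240), grade = g,
                      plusLesion = FALSE)
    ftn <- buildFeatureTable(Xn, c(f = "morphologic"), lab)
    prn <- subclassProfileAnalysis(ftn, aucFloor = 0.75, seed = s)
    trn <- prn$transitions
    sum(trn$marked[trn$from %in% c("C0", "C1", "MDCA", "C3")])
  }, 0)
  # 4 null transitions x 20 seeds at p < 0.01: expected ~0.8 false flags
  expect_lte(sum(falseFlags), 4)

  # single grade present: empty profile with a warning
  oneGrade <- buildFeatureTable(
    cbind(f = rnorm(20)), c(f = "morphologic"),
    data.frame(eyeId = sprintf("s%02d", 1:20), grade = "C1",
               plusLesion = FALSE))
  expect_warning(pr1 <- subclassProfileAnalysis(oneGrade, seed = 1),
                 "fewer than two grades")
  expect_length(pr1$features, 0)
})
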