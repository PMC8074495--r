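# First-order, GLCM and NGTDM features: closed forms, brute-force oracle
# equivalence, bank arithmetic.

test_that("quantizeRoi bins full ranges, degenerates gracefully and is
           monotone", {
  ch <- matrix(0:255, 16, 16)
  mask <- matrix(TRUE, 16, 16)
  q <- quantizeRoi(ch, mask, 32)
  expect_equal(sort(unique(as.integer(q$levels))), 1:32)

  const <- quantizeRoi(matrix(7, 4, 4), matrix(TRUE, 4, 4), 32)
  expect_equal(const$ng, 1L)
  expect_true(all(const$levels == 1L))

  # monotone intensity map preserves level ordering
  q2 <- quantizeRoi(ch^2, mask, 32)
  o1 <- order(q$levels[mask]); o2 <- order(q2$levels[mask])
  expect_true(all(diff(q2$levels[mask][o1]) >= 0 |
                  diff(q$levels[mask][o1]) == 0))
})

test_that("first-order statistics match closed forms", {
  const <- matrix(3, 5, 5); mask <- matrix(TRUE, 5, 5)
  f <- firstorderBank(const, mask)
  expect_equal(unname(f["Energy"]), 25 * 9)
  expect_equal(unname(f["Entropy"]), 0)
  expect_equal(unname(f["Variance"]), 0)
  expect_equal(unname(f["Uniformity"]), 1)

  v4 <- matrix(c(1, 2, 3, 4), 2, 2); m4 <- matrix(TRUE, 2, 2)
  f4 <- firstorderBank(v4, m4)
  expect_equal(unname(f4["Mean"]), 2.5)
  expect_equal(unname(f4["Range"]), 3)
  expect_equal(unname(f4["Variance"]), 1.25)

  two <- matrix(rep(c(10, 20), each = 8), 4, 4)
  ft <- firstorderBank(two, matrix(TRUE, 4, 4))
  expect_equal(unname(ft["Entropy"]), 1)
  expect_equal(unname(ft["Uniformity"]), 0.5)
})

test_that("GLCM: constant ROI and checkerboard closed forms", {
  qc <- quantizeRoi(matrix(9, 6, 6), matrix(TRUE, 6, 6), 32)
  g <- glcmFeatures(qc, 0)
  expect_equal(unname(g["contrast"]), 0)
  expect_equal(unname(g["asm"]), 1)
  expect_equal(unname(g["shade"]), 0)
  expect_equal(unname(g["correlation"]), 1)

  # 4x4 checkerboard of two levels: every horizontal pair differs by 1
  cb <- matrix(rep_len(c(1, 2), 16), 4, 4)
  cb[, c(2, 4)] <- 3 - cb[, c(2, 4)]
  qcb <- quantizeRoi(cb, matrix(TRUE, 4, 4), 2)
  gcb <- glcmFeatures(qcb, 0)
  expect_equal(unname(gcb["contrast"]), 1)
  expect_equal(unname(gcb["dissimilarity"]), 1)
  expect_equal(unname(gcb["shade"]), 0)   # symmetric about the center
})

test_that("NGTDM: constant ROI hits the coarseness cap", {
  qc <- quantizeRoi(matrix(5, 6, 6), matrix(TRUE, 6, 6), 32)
  n <- ngtdmFeatures(qc)
  expect_equal(unname(n["Coarseness"]), 1e6)
  expect_equal(unname(n["Contrast"]), 0)
})

test_that("every texture/first-order feature matches its brute-force
           oracle on random small ROIs", {
  angles <- c(0, 45, 90, 135)
  offs <- list(`0` = c(0, 1), `45` = c(-1, 1), `90` = c(-1, 0),
               `135` = c(-1, -1))
  for (s in 1:100) {
    set.seed(s)
    H <- sample(3:8, 1); W <- sample(3:8, 1)
    ch <- matrix(sample(0:40, H * W, replace = TRUE), H, W)
    mask <- matrix(runif(H * W) < 0.85, H, W)
    if (sum(mask) < 4) mask[1:4] <- TRUE
    ng <- sample(3:6, 1)
    q <- quantizeRoi(ch, mask, ng)
    lv <- q$levels

    fo <- firstorderBank(ch, mask, ng)
    bf <- bfFirstorder(ch[mask], ng)
    expect_equal(unname(fo[names(bf)]), unname(bf), tolerance = 1e-9)

    for (a in angles) {
      g <- glcmFeatures(q, a)
      bg <- bfGlcm(lv, offs[[as.character(a)]][1],
                   offs[[as.character(a)]][2])
      if (is.null(bg)) {
        expect_true(attr(g, "flag"))
      } else {
        expect_equal(as.numeric(g), as.numeric(bg), tolerance = 1e-9)
      }
    }
    nt <- ngtdmFeatures(q)
    bn <- bfNgtdm(lv)
    expect_equal(as.numeric(nt), as.numeric(bn), tolerance = 1e-9)
  }
})

test_that("GLCM probabilities are normalized and first-order entropy and
           uniformity respect their bounds", {
  for (s in 1:20) {
    set.seed(100 + s)
    ch <- matrix(rnorm(64, 100, 20), 8, 8)
    mask <- matrix(runif(64) < 0.9, 8, 8)
    if (sum(mask) < 4) mask[1:4] <- TRUE
    q <- quantizeRoi(ch, mask, 8)
    fo <- firstorderBank(ch, mask, 8)
    expect_gte(unname(fo["Entropy"]), 0)
    expect_lte(unname(fo["Entropy"]), log2(8) + 1e-12)
    expect_gte(unname(fo["Uniformity"]), 1 / 8 - 1e-12)
    expect_lte(unname(fo["Uniformity"]), 1)
  }
})

test_that("coarseness increases with the correlation length of the field", {
  set.seed(42)
  base <- matrix(rnorm(60 * 60), 60, 60)
  smooth <- function(z, k) {
    if (k == 0) return(z)
    for (i in 1:k) {
      z <- (z + rbind(z[-1, ], z[nrow(z), ]) + rbind(z[1, ], z[-nrow(z), ]) +
            cbind(z[, -1], z[, ncol(z)]) + cbind(z[, 1], z[, -ncol(z)])) / 5
    }
    z
  }
  mask <- matrix(TRUE, 60, 60)
  co <- vapply(c(0, 4), function(k) {
    f <- smooth(base, k)
    unname(ngtdmFeatures(quantizeRoi(f, mask, 16))["Coarseness"])
  }, 0)
  expect_gt(co[2], co[1])
})

test_that("the banks have the documented sizes and channel symmetry", {
  ph <- generatePhantom(phantomConfig(), "C3", seed = 8)
  ib <- intensityBank(ph$image, ph$rois)
  tb <- textureBank(ph$image, ph$rois)
  expect_length(ib, 54)
  expect_length(tb, 111)

  # permuting channels permutes channel-suffixed features
  img2 <- ph$image
  img2@pixels <- ph$image@pixels[, , c(2, 3, 1)]
  ib2 <- intensityBank(img2, ph$rois)
  expect_equal(unname(ib2[grep("_R$", names(ib2))]),
               unname(ib[grep("_G$", names(ib))]))

  # brightness shift raises first-order energy
  img3 <- ph$image
  px <- ph$image@pixels
  px[, , 1] <- pmin(px[, , 1] + 30L, 255L)
  img3@pixels <- px
  expect_gt(intensityBank(img3, ph$rois)["firstorder_Energy_R"],
            ib["firstorder_Energy_R"])
})

test_that("texture features at the four angles agree on isotropic noise", {
  set.seed(7)
  ch <- matrix(rnorm(80 * 80, 100, 15), 80, 80)
  mask <- matrix(TRUE, 80, 80)
  q <- quantizeRoi(ch, mask, 16)
  g <- sapply(c(0, 45, 90, 135), function(a) glcmFeatures(q, a))
  for (f in c("contrast", "homogeneity", "entropy", "asm"))
    expect_lt(diff(range(g[f, ])) / mean(unlist(g[f, ])), 0.1)
})

test_that("the 322-column vector assembles with correct category counts
           and no missing values", {
  ph <- generatePhantom(phantomConfig(), "C1", seed = 4)
  fv <- extractFeatureVector(ph$image, ph$rois)
  expect_length(fv, 322)
  expect_false(any(is.na(fv)))
  cats <- table(attr(fv, "categories"))
  expect_equal(as.integer(cats[c("morphologic", "intensity", "texture",
                                 "clinic")]), c(151L, 54L, 111L, 6L))

  # clinic columns equal their morphologic-bank ingredients exactly
  expect_equal(unname(fv["AreaPPA"]), unname(fv["shape_AreaPPA"]))
  expect_equal(unname(fv["Tilt"]), unname(fv["shape_Tilt"]))
  expect_equal(unname(fv["Torsion"]), unname(fv["shape_Torsion"]))

  # empty-PPA eye still yields a complete vector
  noPpa <- RoiSet(discContour(ph$rois), NULL, maculaXY(ph$rois),
                  dim(pixels(ph$image))[1:2], smooth = FALSE)
  fv2 <- extractFeatureVector(ph$image, noPpa)
  expect_length(fv2, 322)
  expect_false(any(is.na(fv2)))
})
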