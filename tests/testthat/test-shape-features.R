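# Morphologic descriptors: moment ellipse, clinic features, curvature,
# moments/Hu, Fourier descriptors, ray profiles, the 151-feature bank.

test_that("fitEllipseMoments recovers circles and rotated ellipses", {
  circ <- rasterizeRegion(circlePts(100, 100, 50, 256), c(200, 200))
  e <- fitEllipseMoments(circ)
  expect_lt(abs(e$semiMajor - 50) / 50, 0.02)
  expect_lt(abs(e$semiMinor - 50) / 50, 0.02)

  ell0 <- rasterizeRegion(ellipsePts(100, 100, 80, 40, 0, 256), c(200, 200))
  e0 <- fitEllipseMoments(ell0)
  expect_lt(abs(e0$semiMajor - 80), 1)
  expect_lt(abs(e0$semiMinor - 40), 1)
  expect_lt(abs(e0$orientationDeg), 1)

  ell30 <- rasterizeRegion(ellipsePts(100, 100, 80, 40, 30, 256),
                           c(200, 200))
  expect_lt(abs(fitEllipseMoments(ell30)$orientationDeg - 30), 1)
  expect_error(fitEllipseMoments(matrix(FALSE, 5, 5)), "empty")
})

test_that("clinic features match analytic geometry", {
  rs <- makeRois()   # disc (60,48), ppa outer (100,80), concentric
  cf <- clinicFeatures(rs)
  expect_lt(abs(cf["AreaDisc"] - pi * 60 * 48) / (pi * 60 * 48), 0.01)
  expect_lt(abs(cf["AreaPPA"] - pi * (100 * 80 - 60 * 48)) /
            (pi * (100 * 80 - 60 * 48)), 0.01)

  # circular disc: tilt 1
  circ <- RoiSet(circlePts(100, 100, 50), NULL, c(20, 100), c(200, 200),
                 smooth = FALSE)
  expect_gt(clinicFeatures(circ)["Tilt"], 0.98)

  # vertical disc axis + horizontal macula line: torsion and angle both 0
  vert <- RoiSet(ellipsePts(100, 100, 48, 60, 0), NULL, c(20, 100),
                 c(200, 200), smooth = FALSE)
  cfv <- clinicFeatures(vert)
  expect_lt(abs(cfv["Torsion"]), 1.5)
  expect_lt(abs(cfv["Angle_MD"]), 1e-6)
  expect_lt(abs(cfv["Dist_MD"] - 80), 1)
})

test_that("contour descriptors: Hausdorff and constant curvature", {
  d <- contourDescriptors(circlePts(100, 100, 60, 128),
                          circlePts(100, 100, 60, 128))
  expect_lt(d["ContourHausdorff"], 0.1)

  d2 <- contourDescriptors(circlePts(100, 100, 60, 128),
                           circlePts(100, 100, 100, 128))
  expect_lt(abs(d2["ContourHausdorff"] - 40), 1)
  expect_lt(abs(d2["ContourMinDist"] - 40), 1)

  st <- d2[paste0("DiscCurvature", 1:16)]
  expect_true(all(abs(st - 1 / 60) / (1 / 60) < 0.05))
  st2 <- d2[paste0("PPACurvature", 1:16)]
  expect_true(all(abs(st2 - 1 / 100) / (1 / 100) < 0.05))
})

test_that("central moments are central and Hu invariants are invariant", {
  m <- rasterizeRegion(ellipsePts(60, 60, 35, 20, 25), c(200, 200))
  mm <- regionMoments(m)
  # mu10 = mu01 = 0 by construction: first-order centrals vanish, so the
  # lowest emitted order is mu11; verify centrality via the centroid
  idx <- which(m, arr.ind = TRUE)
  expect_lt(abs(sum(idx[, 2] - 1 - mean(idx[, 2] - 1))), 1e-6)

  shifted <- matrix(FALSE, 200, 200)
  shifted[cbind(idx[, 1] + 30, idx[, 2] + 25)] <- TRUE
  hu1 <- mm[paste0("Hu", 1:7)]
  hu2 <- regionMoments(shifted)[paste0("Hu", 1:7)]
  expect_lt(max(abs(hu1 - hu2) / pmax(abs(hu1), 1e-12)), 1e-6)

  rot <- t(m)[, nrow(m):1]   # 90 degree rotation of the raster
  hu3 <- regionMoments(rot)[paste0("Hu", 1:7)]
  expect_lt(max(abs(hu1 - hu3) / pmax(abs(hu1), 1e-12)), 0.01)
})

test_that("Fourier circularity orders circle > ellipse > star", {
  fc <- fourierShape(circlePts(0, 0, 50, 128))
  expect_gt(fc["FourierCircularity"], 1 - 1e-3)
  fe <- fourierShape(ellipsePts(0, 0, 60, 30, 0, 128))
  expect_lt(fe["FourierCircularity"], 1 - 1e-3)
  th <- seq(0, 2 * pi, length.out = 129)[-129]
  star <- cbind(cos(th), sin(th)) * (50 + 25 * cos(5 * th))
  fs <- fourierShape(star)
  expect_lt(fs["FourierCircularity"], fe["FourierCircularity"])
})

test_that("PPA ray-profile fluctuation behaves like a gradient magnitude", {
  rs <- makeRois(disc = circlePts(100, 100, 40),
                 ppa = circlePts(100, 100, 80))
  flat <- grayImage(matrix(120, 200, 200))
  expect_equal(as.numeric(ppaProfileFeature(flat, rs, 20, "R")), 0)

  # radial two-value alternation at the station spacing: each |step| = a
  u <- 6
  amp <- 40
  stations <- seq(40.5, 80, length.out = u)  # approximate station radii
  bounds <- (stations[-1] + stations[-u]) / 2  # bands centred on stations
  xg <- matrix(rep(0:199, each = 200), 200, 200)
  yg <- matrix(rep(0:199, 200), 200, 200)
  rr <- sqrt((xg - 100)^2 + (yg - 100)^2)
  phase <- matrix(findInterval(rr, bounds), 200, 200)
  altern <- grayImage(120 + amp * (phase %% 2))
  v <- as.numeric(ppaProfileFeature(altern, rs, u, "R"))
  expect_lt(abs(v - amp) / amp, 0.05)
  v2 <- as.numeric(ppaProfileFeature(grayImage(120 + 2 * amp * (phase %% 2)),
                                     rs, u, "R"))
  expect_lt(abs(v2 - 2 * v) / (2 * v), 1e-6)
  expect_error(ppaProfileFeature(flat, rs, 1, "R"), "u must be")
})

test_that("the morphologic bank has 151 stable, deterministic entries", {
  ph <- generatePhantom(phantomConfig(), "MDCA", seed = 3)
  b1 <- morphologicBank(ph$image, ph$rois)
  b2 <- morphologicBank(ph$image, ph$rois)
  expect_length(b1, 151)
  expect_identical(unclass(b1), unclass(b2))
  expect_false(anyDuplicated(names(b1)) > 0)

  # absent PPA: PPA-dependent entries zeroed and flagged
  noPpa <- RoiSet(discContour(ph$rois), NULL, maculaXY(ph$rois),
                  dim(pixels(ph$image))[1:2], smooth = FALSE)
  b3 <- morphologicBank(ph$image, noPpa)
  fl <- attr(b3, "flags")
  expect_length(b3, 151)
  expect_true(all(b3[fl] == 0))
  expect_true(fl[["shape_AreaPPA"]])
  expect_false(fl[["shape_AreaDisc"]])
})

test_that("mirroring flips the sign of Torsion and Angle_MD only", {
  ph <- generatePhantom(phantomConfig(), "C3", seed = 9)
  rs <- ph$rois
  W <- dim(pixels(ph$image))[2]
  mir <- canonicalizeOrientation(
    { img <- ph$image; img@laterality <- "left"; img }, rs)
  cf <- clinicFeatures(rs)
  cfm <- clinicFeatures(mir$rois)
  expect_equal(unname(cfm["Torsion"]), -unname(cf["Torsion"]),
               tolerance = 1e-6)
  expect_equal(unname(cfm["Angle_MD"]), -unname(cf["Angle_MD"]),
               tolerance = 1e-6)
  for (f in c("AreaPPA", "AreaDisc", "Tilt", "Dist_MD"))
    expect_equal(unname(cfm[f]), unname(cf[f]), tolerance = 1e-9)
})

test_that("shape features scale as s^2 (areas) and s (lengths) under
           spatial rescaling", {
  disc <- ellipsePts(60, 60, 30, 22, 20)
  ppa <- ellipsePts(62, 60, 45, 36, 20)
  rs1 <- RoiSet(disc, ppa, c(15, 60), c(120, 120), smooth = FALSE)
  rs2 <- RoiSet(disc * 2, ppa * 2, c(30, 120), c(240, 240), smooth = FALSE)
  cf1 <- clinicFeatures(rs1); cf2 <- clinicFeatures(rs2)
  expect_lt(abs(cf2["AreaDisc"] / cf1["AreaDisc"] - 4) / 4, 0.03)
  expect_lt(abs(cf2["AreaPPA"] / cf1["AreaPPA"] - 4) / 4, 0.03)
  expect_lt(abs(cf2["Dist_MD"] / cf1["Dist_MD"] - 2) / 2, 0.03)
  expect_lt(abs(cf2["Tilt"] - cf1["Tilt"]) / cf1["Tilt"], 0.03)
  d1 <- contourDescriptors(discContour(rs1), ppaContour(rs1))
  d2 <- contourDescriptors(discContour(rs2), ppaContour(rs2))
  expect_lt(abs(d2["DiscPerimeter"] / d1["DiscPerimeter"] - 2) / 2, 0.03)
  expect_lt(abs(d2["ContourHausdorff"] / d1["ContourHausdorff"] - 2) / 2,
            0.03)
})

test_that("Tilt, Hu and Fourier circularity are rotation-invariant within
           2 %", {
  fcs <- sapply(c(0, 30, 75), function(ang) {
    m <- rasterizeRegion(ellipsePts(100, 100, 50, 30, ang, 128),
                         c(200, 200))
    e <- fitEllipseMoments(m)
    expect_lt(abs(e$semiMinor / e$semiMajor - 30 / 50) / (30 / 50), 0.02)
    fourierShape(ellipsePts(100, 100, 50, 30, ang, 128))[["FourierCircularity"]]
  })
  expect_lt(max(abs(fcs - fcs[1]) / fcs[1]), 0.02)
})
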