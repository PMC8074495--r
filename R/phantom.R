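# Synthetic fundus phantoms: elliptical optic disc, crescent/annular PPA
# zone with controllable brightness and texture, macula landmark, and
# class-conditional parameter shifts across META-PM grades.

#' Phantom generator configuration
#'
#' Defaults emulate the structure the analysis assumes: a bright elliptical
#' disc, an enclosing PPA outer ellipse offset toward the macula (a
#' crescent when the offset is large relative to the margin), a dark macula
#' spot, and a tessellated background. Grade-conditional schedules (indexed
#' C0, C1, PDCA, MDCA, C3, C4) shift PPA extent (area), PPA brightness,
#' histogram complexity (bimodal blob fraction) and texture correlation
#' length (NGTDM coarseness); the two largest jumps sit at C0 to C1 and
#' PDCA to MDCA. Disc tilt means follow the per-grade pattern of the
#' clinical cohort (more tilted discs in severe grades).
#'
#' @param height,width frame size in px.
#' @param discSemiMajor mean disc semi-major axis, px.
#' @param discTilt per-grade mean short/long axis ratio.
#' @param ppaWidth per-grade PPA margin beyond the disc, px.
#' @param ppaBrightness per-grade mean PPA red-channel intensity.
#' @param ppaNoiseSd per-grade PPA texture SD.
#' @param ppaCorrLen per-grade texture correlation length, px.
#' @param ppaEntropyMix per-grade Gaussian-to-uniform marginal blend of
#'   the texture field in [0, 1]; raises histogram complexity (entropy)
#'   at fixed variance.
#' @param maculaDist mean disc-centre to macula distance, px.
#' @param gradeProbs grade mix for cohorts (defaults to the published
#'   cohort shares 9.6/24.5/26.7/22.8/9.8/6.6 percent).
#' @param plusRate probability of plus lesions in a non-severe grade.
#' @return a `PhantomConfig` list.
#' @export
phantomConfig <- function(height = 128L, width = 128L,
                          discSemiMajor = 16,
                          discTilt = c(0.78, 0.70, 0.72, 0.65, 0.63, 0.66),
                          ppaWidth = c(3.3, 4.5, 4.8, 6.1, 6.3, 6.5),
                          ppaBrightness = c(124, 131, 133, 142, 143, 145),
                          ppaNoiseSd = c(9, 10, 10.2, 11.5, 11.7, 11.9),
                          ppaCorrLen = c(2.03, 1.9, 1.88, 1.62, 1.6, 1.58),
                          ppaEntropyMix = c(0.15, 0.30, 0.32, 0.55, 0.57, 0.60),
                          maculaDist = 43,
                          gradeProbs = c(44, 112, 122, 104, 45, 30) / 457,
                          plusRate = 0.03) {
  cfg <- list(height = height, width = width, discSemiMajor = discSemiMajor,
              discTilt = discTilt, ppaWidth = ppaWidth,
              ppaBrightness = ppaBrightness, ppaNoiseSd = ppaNoiseSd,
              ppaCorrLen = ppaCorrLen, ppaEntropyMix = ppaEntropyMix,
              maculaDist = maculaDist, gradeProbs = gradeProbs,
              plusRate = plusRate)
  class(cfg) <- "PhantomConfig"
  cfg
}

#' @export
print.PhantomConfig <- function(x, ...) {
  cat(sprintf("PhantomConfig: %d x %d frame, disc a=%g px, grades %s\n",
              x$height, x$width, x$discSemiMajor,
              paste(metaPmGrades, collapse = "/")))
  invisible(x)
}

# Gaussian random field: white noise smoothed by a separable Gaussian
# kernel (correlation length ell), normalized to unit SD
gaussianField <- function(H, W, ell) {
  z <- matrix(rnorm(H * W), H, W)
  if (ell > 0.3) {
    k1 <- gaussBand(H, ell)
    k2 <- gaussBand(W, ell)
    z <- k1 %*% z %*% t(k2)
  }
  z / max(sd(as.numeric(z)), .Machine$double.eps)
}

gaussBand <- function(n, ell) {
  i <- seq_len(n)
  K <- exp(-outer(i, i, "-")^2 / (2 * ell^2))
  K / rowSums(K)
}

# closed ellipse polygon, 0-based coordinates
ellipsePoints <- function(cx, cy, a, b, phiDeg, n = 64L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  phi <- phiDeg * pi / 180
  cbind(x = cx + a * cos(th) * cos(phi) - b * sin(th) * sin(phi),
        y = cy + a * cos(th) * sin(phi) + b * sin(th) * cos(phi))
}

#' Generate one fundus phantom
#'
#' Renders background, disc, PPA zone and macula for the given META-PM
#' grade and returns the image, the ground-truth RoiSet, and a labels row.
#' The same (config, grade, seed) always renders bit-identical output.
#' Eyes with plus lesions in a mild grade receive severe-grade appearance.
#'
#' @param cfg a [phantomConfig()].
#' @param grade one of C0, C1, PDCA, MDCA, C3, C4.
#' @param seed integer seed.
#' @param eyeId identifier (default derived from seed).
#' @param laterality `"right"` (default) or `"left"` (rendered mirrored).
#' @param plusLesion logical (default FALSE).
#' @return list with `image` ([FundusImage-class]), `rois`
#'   ([RoiSet-class]), `label` (one-row data.frame) and `truth` (the
#'   drawn geometry/appearance parameters, for validation).
#' @export
generatePhantom <- function(cfg, grade = "C1", seed = 1L,
                            eyeId = paste0("eye", seed),
                            laterality = "right", plusLesion = FALSE) {
  gi <- match(grade, metaPmGrades)
  if (is.na(gi)) stop("generatePhantom: unknown grade ", grade)
  ai <- if (plusLesion && gi < 4L) 4L else gi  # appearance schedule index
  set.seed(seed)
  H <- cfg$height; W <- cfg$width

  # geometry
  a <- cfg$discSemiMajor + rnorm(1, 0, 1)
  tilt <- min(max(cfg$discTilt[ai] + rnorm(1, 0, 0.12), 0.4), 0.95)
  b <- a * tilt
  phi <- 90 + rnorm(1, 0, 20)
  cx <- 0.62 * W + rnorm(1, 0, 2)
  cy <- 0.50 * H + rnorm(1, 0, 2)
  width <- cfg$ppaWidth[ai] * exp(rnorm(1, 0, 0.28))
  shift <- 0.3 * width
  mAng <- rnorm(1, 0, 6) * pi / 180
  md <- cfg$maculaDist + rnorm(1, 0, 3)
  mac <- c(cx - md * cos(mAng), cy + md * sin(mAng))
  toMac <- (mac - c(cx, cy)) / sqrt(sum((mac - c(cx, cy))^2))
  octr <- c(cx, cy) + shift * toMac
  ao <- a + width + shift + 1
  bo <- b + 0.8 * width + shift + 1
  if (octr[1] - ao < 1 || octr[1] + ao > W - 2 ||
      octr[2] - ao < 1 || octr[2] + ao > H - 2 ||
      mac[1] < 2 || mac[1] > W - 3 || mac[2] < 2 || mac[2] > H - 3)
    stop("generatePhantom: geometry does not fit the frame")

  discPts <- ellipsePoints(cx, cy, a, b, phi)
  ppaPts <- ellipsePoints(octr[1], octr[2], ao, bo, phi)
  rois <- RoiSet(discPts, ppaPts, mac, c(H, W), smooth = FALSE)

  # appearance
  bright <- cfg$ppaBrightness[ai] + rnorm(1, 0, 12)
  nsd <- cfg$ppaNoiseSd[ai] * exp(rnorm(1, 0, 0.30))
  ell <- cfg$ppaCorrLen[ai] * exp(rnorm(1, 0, 0.25))
  lam <- min(max(cfg$ppaEntropyMix[ai] + rnorm(1, 0, 0.10), 0), 1)

  bgBase <- c(150, 78, 46)
  discCol <- c(235, 205, 170)
  chFac <- c(1, 0.8, 0.65)
  bgTess <- gaussianField(H, W, 3)
  tex <- gaussianField(H, W, ell)
  # histogram-complexity control: blend the texture field's marginal from
  # Gaussian (lam = 0) toward uniform (lam = 1) through its copula, at
  # fixed unit variance, so entropy shifts without moving mean/variance
  texShaped <- (1 - lam) * tex + lam * sqrt(12) * (pnorm(tex) - 0.5)
  texShaped <- texShaped / max(sd(as.numeric(texShaped)),
                               .Machine$double.eps)
  pm <- rois@ppaMask; dm <- rois@discMask
  xs <- matrix(rep(0:(W - 1), each = H), H, W)
  ys <- matrix(rep(0:(H - 1), W), H, W)
  dip <- 60 * exp(-((xs - mac[1])^2 + (ys - mac[2])^2) / (2 * 6^2))
  px <- array(0L, c(H, W, 3L))
  for (ci in 1:3) {
    ch <- bgBase[ci] + 6 * bgTess
    ch[dm] <- discCol[ci] + 3 * tex[dm]
    if (sum(pm))
      ch[pm] <- bright * chFac[ci] + nsd * texShaped[pm]
    ch <- ch - dip * chFac[ci]   # dark macula spot
    px[, , ci] <- as.integer(pmin(pmax(round(ch), 0), 255))
  }
  img <- FundusImage(px, laterality = "right", eyeId = eyeId, dpi = 150)
  if (laterality == "left") {
    img <- flipImage(img)
    img@laterality <- "left"
    rois <- flipRois(rois, W)
  }
  label <- data.frame(eyeId = eyeId, patientId = eyeId,
                      laterality = laterality, grade = grade,
                      plusLesion = plusLesion,
                      severe = as.integer(
                        assignSeverityGroup(grade, plusLesion) == "severe"))
  list(image = img, rois = rois, label = label,
       truth = list(discCenter = c(cx, cy), discSemiMajor = a,
                    discSemiMinor = b, discOrientation = phi,
                    ppaCenter = octr, ppaSemiMajor = ao, ppaSemiMinor = bo,
                    macula = mac, width = width, brightness = bright,
                    noiseSd = nsd, corrLen = ell, entropyMix = lam))
}

#' Generate a phantom cohort
#'
#' Draws grades from the configured mix (defaulting to the published
#' cohort's shares), assigns plus lesions at `plusRate` among mild grades,
#' random laterality, and renders each eye from a per-eye seed derived from
#' the master seed.
#'
#' @param cfg a [phantomConfig()].
#' @param n number of eyes (>= 10).
#' @param seed master seed.
#' @return list with `images`, `roiSets`, `labels` (data.frame) and
#'   `truths` (per-eye ground-truth parameter lists).
#' @export
generateCohort <- function(cfg, n, seed = 1L) {
  if (n < 10L) stop("generateCohort: need n >= 10")
  set.seed(seed)
  grades <- sample(metaPmGrades, n, replace = TRUE, prob = cfg$gradeProbs)
  plus <- rbinom(n, 1L, ifelse(grades %in% c("C0", "C1", "PDCA"),
                               cfg$plusRate, 0)) == 1L
  lat <- sample(c("left", "right"), n, replace = TRUE)
  eyeSeeds <- sample.int(99999999L, n)
  images <- vector("list", n); roiSets <- vector("list", n)
  labels <- vector("list", n); truths <- vector("list", n)
  for (i in seq_len(n)) {
    ph <- generatePhantom(cfg, grades[i], eyeSeeds[i],
                          eyeId = sprintf("eye%04d", i),
                          laterality = lat[i], plusLesion = plus[i])
    images[[i]] <- ph$image; roiSets[[i]] <- ph$rois
    labels[[i]] <- ph$label; truths[[i]] <- ph$truth
  }
  list(images = images, roiSets = roiSets,
       labels = do.call(rbind, labels), truths = truths)
}

#' Tabular simulation configuration
#'
#' @param n eyes; @param p features; @param k informative features;
#' @param delta standardized class mean shift of informative features;
#' @param balance class-1 fraction; @param rho equicorrelation among
#'   informative features; @param seed integer seed.
#' @return a `TabularSimConfig` list.
#' @export
tabularSimConfig <- function(n = 300L, p = 50L, k = 3L, delta = 1.5,
                             balance = 0.5, rho = 0, seed = 1L) {
  if (k > p) stop("tabularSimConfig: k must not exceed p")
  if (delta < 0) stop("tabularSimConfig: delta must be >= 0")
  structure(list(n = n, p = p, k = k, delta = delta, balance = balance,
                 rho = rho, seed = seed), class = "TabularSimConfig")
}

#' Simulate a tabular feature set with planted informative features
#'
#' Informative features are Normal(delta, 1) in class 1 and Normal(0, 1) in
#' class 0 (optionally equicorrelated); noise features are Normal(0, 1)
#' independent of the class. The ground-truth informative mask is stored in
#' the table's metadata.
#'
#' @param cfg a [tabularSimConfig()].
#' @return a [FeatureTable-class]; `S4Vectors::metadata(x)$informative`
#'   holds the truth mask.
#' @export
simulateFeatureTable <- function(cfg) {
  set.seed(cfg$seed)
  n <- cfg$n; p <- cfg$p; k <- cfg$k
  y <- rbinom(n, 1L, cfg$balance)
  X <- matrix(rnorm(n * p), n, p)
  if (k > 0 && cfg$rho > 0) {
    fac <- rnorm(n)
    X[, seq_len(k)] <- sqrt(cfg$rho) * fac +
      sqrt(1 - cfg$rho) * X[, seq_len(k)]
  }
  if (k > 0) X[, seq_len(k)] <- X[, seq_len(k)] + cfg$delta * y
  colnames(X) <- c(if (k > 0) paste0("info", seq_len(k)),
                   if (p > k) paste0("noise", seq_len(p - k)))
  rownames(X) <- sprintf("eye%04d", seq_len(n))
  labels <- data.frame(eyeId = rownames(X), severe = y,
                       grade = ifelse(y == 1L, "MDCA", "C1"),
                       plusLesion = FALSE)
  ft <- buildFeatureTable(X, setNames(rep("morphologic", p), colnames(X)),
                          labels)
  S4Vectors::metadata(ft)$informative <-
    setNames(seq_len(p) <= k, colnames(X))
  ft
}
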