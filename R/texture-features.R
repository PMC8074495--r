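# First-order intensity and GLCM/NGTDM texture features of the PPA region,
# computed per color channel, plus assembly of the full 322-column vector.

#' Quantize ROI intensities into gray levels
#'
#' Equal-width binning of in-mask intensities into `nLevels` bins over the
#' in-mask [min, max] range. A constant ROI collapses to a single level.
#'
#' @param channel numeric matrix of intensities.
#' @param mask logical matrix, nonempty.
#' @param nLevels number of gray levels (default 32).
#' @return list with `levels` (integer matrix, NA outside the mask), `ng`
#'   (number of levels actually spanned) and `mask`.
#' @export
quantizeRoi <- function(channel, mask, nLevels = 32L) {
  if (sum(mask) == 0L) stop("quantizeRoi: empty mask")
  v <- channel[mask]
  lv <- matrix(NA_integer_, nrow(channel), ncol(channel))
  rng <- range(v)
  if (rng[1] == rng[2]) {
    lv[mask] <- 1L
    return(list(levels = lv, ng = 1L, mask = mask))
  }
  q <- pmin(floor((v - rng[1]) / (rng[2] - rng[1]) * nLevels) + 1L, nLevels)
  lv[mask] <- as.integer(q)
  list(levels = lv, ng = as.integer(nLevels), mask = mask)
}

#' The 18 first-order intensity statistics of a masked region
#'
#' Energy, total energy (equal to energy under unit pixel spacing), entropy
#' and uniformity of the 32-bin equal-width histogram, minimum, 10th/90th
#' percentiles, maximum, mean, median, interquartile range, range, mean
#' absolute deviation, robust MAD (values within the 10-90 percentile
#' band), root mean square, skewness, kurtosis and population variance.
#'
#' @param channel numeric matrix of intensities.
#' @param mask logical matrix, nonempty.
#' @param nLevels histogram bins for entropy/uniformity (default 32).
#' @return named numeric of length 18.
#' @export
firstorderBank <- function(channel, mask, nLevels = 32L) {
  if (sum(mask) == 0L) stop("firstorderBank: empty mask")
  x <- as.numeric(channel[mask])
  n <- length(x)
  q <- quantizeRoi(channel, mask, nLevels)
  p <- tabulate(q$levels[mask], nbins = q$ng) / n
  p <- p[p > 0]
  mu <- mean(x)
  pop <- function(k) mean((x - mu)^k)
  v <- pop(2)
  q10 <- quantile(x, 0.10, names = FALSE)
  q90 <- quantile(x, 0.90, names = FALSE)
  band <- x[x >= q10 & x <= q90]
  c(Energy = sum(x^2),
    TotalEnergy = sum(x^2),
    Entropy = -sum(p * log2(p)),
    Minimum = min(x),
    Percentile10 = q10,
    Percentile90 = q90,
    Maximum = max(x),
    Mean = mu,
    Median = median(x),
    InterquartileRange = quantile(x, 0.75, names = FALSE) -
      quantile(x, 0.25, names = FALSE),
    Range = max(x) - min(x),
    MeanAbsoluteDeviation = mean(abs(x - mu)),
    RobustMeanAbsoluteDeviation =
      if (length(band)) mean(abs(band - mean(band))) else 0,
    RootMeanSquared = sqrt(mean(x^2)),
    Skewness = if (v > 0) pop(3) / v^1.5 else 0,
    Kurtosis = if (v > 0) pop(4) / v^2 else 0,
    Variance = v,
    Uniformity = sum(p^2))
}

glcmOffsets <- list(`0` = c(0L, 1L), `45` = c(-1L, 1L),
                    `90` = c(-1L, 0L), `135` = c(-1L, -1L))

# crop a channel/mask pair to the mask bounding box (texture and
# first-order statistics are translation-invariant)
cropToMask <- function(channel, mask) {
  idx <- which(mask, arr.ind = TRUE)
  rr <- range(idx[, 1]); cc <- range(idx[, 2])
  list(channel = channel[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE],
       mask = mask[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE])
}

# co-occurrence counts of in-mask level pairs at offset (dr, dc)
glcmMatrix <- function(q, dr, dc) {
  lv <- q$levels
  H <- nrow(lv); W <- ncol(lv)
  r1 <- max(1L, 1L - dr):min(H, H - dr)
  c1 <- max(1L, 1L - dc):min(W, W - dc)
  a <- lv[r1, c1, drop = FALSE]
  b <- lv[r1 + dr, c1 + dc, drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) return(NULL)
  ng <- q$ng
  cnt <- tabulate((a[ok] - 1L) * ng + b[ok], nbins = ng * ng)
  M <- matrix(cnt, ng, ng, byrow = TRUE)
  M <- M + t(M)                       # symmetric
  M / sum(M)
}

#' GLCM texture features at one angle
#'
#' Builds the symmetric, normalized gray-level co-occurrence matrix over
#' in-mask pixel pairs at the given angle and distance and emits contrast,
#' dissimilarity, homogeneity (inverse difference moment), angular second
#' moment, entropy, correlation, cluster shade and cluster prominence.
#' When no valid pair exists all features are 0 with attribute
#' `flag = TRUE`; a constant ROI yields contrast 0, ASM 1, shade 0 and
#' correlation 1 by convention.
#'
#' @param q a quantized ROI from [quantizeRoi()].
#' @param angleDeg one of 0, 45, 90, 135.
#' @param distance pixel offset magnitude (default 1).
#' @return named numeric of length 8.
#' @export
glcmFeatures <- function(q, angleDeg = 0, distance = 1L) {
  off <- glcmOffsets[[as.character(angleDeg)]]
  if (is.null(off)) stop("glcmFeatures: angle must be 0, 45, 90 or 135")
  P <- glcmMatrix(q, off[1] * distance, off[2] * distance)
  nm <- c("contrast", "dissimilarity", "homogeneity", "asm", "entropy",
          "correlation", "shade", "prominence")
  if (is.null(P)) {
    out <- setNames(numeric(8L), nm)
    attr(out, "flag") <- TRUE
    return(out)
  }
  ng <- nrow(P)
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  mux <- sum(i * P); muy <- sum(j * P)
  sx <- sqrt(sum((i - mux)^2 * P)); sy <- sqrt(sum((j - muy)^2 * P))
  corr <- if (sx > 0 && sy > 0) sum((i - mux) * (j - muy) * P) / (sx * sy)
  else 1
  pp <- P[P > 0]
  out <- c(contrast = sum((i - j)^2 * P),
           dissimilarity = sum(abs(i - j) * P),
           homogeneity = sum(P / (1 + (i - j)^2)),
           asm = sum(P^2),
           entropy = -sum(pp * log2(pp)),
           correlation = corr,
           shade = sum((i + j - mux - muy)^3 * P),
           prominence = sum((i + j - mux - muy)^4 * P))
  attr(out, "flag") <- FALSE
  out
}

#' NGTDM texture features
#'
#' Neighborhood gray-tone difference matrix with 8-neighborhood restricted
#' to in-mask neighbors: for each level i, s_i sums |i - mean neighbor
#' level| over in-mask pixels of level i having at least one valid
#' neighbor. Emits coarseness (reciprocal of sum p_i s_i, with epsilon
#' 1e-6 and capped at 1e6 so a constant region is finite), contrast,
#' busyness, complexity and strength.
#'
#' @param q a quantized ROI from [quantizeRoi()].
#' @return named numeric of length 5.
#' @export
ngtdmFeatures <- function(q) {
  lv <- q$levels
  if (all(is.na(lv))) stop("ngtdmFeatures: empty mask")
  H <- nrow(lv); W <- ncol(lv)
  pad <- matrix(NA_integer_, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- lv
  S <- matrix(0, H, W); Cn <- matrix(0L, H, W)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    nb <- pad[(2:(H + 1L)) + dr, (2:(W + 1L)) + dc, drop = FALSE]
    ok <- !is.na(nb)
    S[ok] <- S[ok] + nb[ok]
    Cn <- Cn + ok
  }
  use <- !is.na(lv) & Cn > 0L
  lev <- lv[use]
  abar <- S[use] / Cn[use]
  ng <- q$ng
  ni <- tabulate(lev, nbins = ng)
  si <- vapply(seq_len(ng), function(i)
    sum(abs(i - abar[lev == i])), 0)
  N <- sum(ni)
  pi_ <- ni / N
  act <- which(pi_ > 0)
  ngp <- length(act)
  eps <- 1e-6
  coarse <- min(1 / (eps + sum(pi_ * si)), 1e6)
  if (ngp > 1) {
    ii <- rep(act, each = ngp); jj <- rep(act, ngp)
    pij <- pi_[ii] * pi_[jj]
    contrast <- sum(pij * (ii - jj)^2) / (ngp * (ngp - 1)) * sum(si) / N
    denomB <- sum(abs(ii * pi_[ii] - jj * pi_[jj]))
    busy <- if (denomB > 0) sum(pi_ * si) / denomB else 0
    complexity <- sum(abs(ii - jj) *
      (pi_[ii] * si[ii] + pi_[jj] * si[jj]) / (pi_[ii] + pi_[jj])) / N
    strength <- if (sum(si) > 0)
      sum((pi_[ii] + pi_[jj]) * (ii - jj)^2) / (eps + sum(si)) else 0
  } else {
    contrast <- 0; busy <- 0; complexity <- 0; strength <- 0
  }
  c(Coarseness = coarse, Contrast = contrast, Busyness = busy,
    Complexity = complexity, Strength = strength)
}

#' The 54-feature intensity bank
#'
#' [firstorderBank()] on the PPA region of each color channel:
#' 18 statistics x 3 channels, named `firstorder_<Stat>_<channel>`.
#' All zero with flags when the eye has no PPA.
#'
#' @param img a [FundusImage-class].
#' @param rois the matching [RoiSet-class].
#' @param nLevels histogram bins (default 32).
#' @return named numeric of length 54 with attribute `flags`.
#' @export
intensityBank <- function(img, rois, nLevels = 32L) {
  chs <- c("R", "G", "B")
  statNames <- c("Energy", "TotalEnergy", "Entropy", "Minimum",
                 "Percentile10", "Percentile90", "Maximum", "Mean",
                 "Median", "InterquartileRange", "Range",
                 "MeanAbsoluteDeviation", "RobustMeanAbsoluteDeviation",
                 "RootMeanSquared", "Skewness", "Kurtosis", "Variance",
                 "Uniformity")
  empty <- !hasPPA(rois)
  out <- numeric(0)
  for (ci in 1:3) {
    v <- if (empty) setNames(numeric(18L), statNames)
    else {
      cr <- cropToMask(img@pixels[, , ci], rois@ppaMask)
      firstorderBank(cr$channel, cr$mask, nLevels)
    }
    names(v) <- paste0("firstorder_", names(v), "_", chs[ci])
    out <- c(out, v)
  }
  attr(out, "flags") <- setNames(rep(empty, length(out)), names(out))
  out
}

#' The 111-feature texture bank
#'
#' Per color channel over the PPA region: 8 GLCM features at each of the
#' four angles (0/45/90/135 degrees, distance 1, kept separate rather than
#' averaged) plus 5 NGTDM features: 37 per channel, 111 in total. Names
#' follow `glcm_<feature>_<angle>_<channel>` and `<Feature>_NGTDM_<channel>`.
#' All zero with flags when the eye has no PPA.
#'
#' @param img a [FundusImage-class].
#' @param rois the matching [RoiSet-class].
#' @param nLevels quantization levels (default 32).
#' @return named numeric of length 111 with attribute `flags`.
#' @export
textureBank <- function(img, rois, nLevels = 32L) {
  chs <- c("R", "G", "B")
  angles <- c(0, 45, 90, 135)
  glcmNm <- c("contrast", "dissimilarity", "homogeneity", "asm", "entropy",
              "correlation", "shade", "prominence")
  ngtdmNm <- c("Coarseness", "Contrast", "Busyness", "Complexity", "Strength")
  empty <- !hasPPA(rois)
  out <- numeric(0)
  flags <- logical(0)
  for (ci in 1:3) {
    if (!empty) {
      cr <- cropToMask(img@pixels[, , ci], rois@ppaMask)
      q <- quantizeRoi(cr$channel, cr$mask, nLevels)
    }
    for (a in angles) {
      if (empty) {
        v <- setNames(numeric(8L), glcmNm)
        fl <- TRUE
      } else {
        v <- glcmFeatures(q, a)
        fl <- attr(v, "flag")
      }
      names(v) <- paste0("glcm_", glcmNm, "_", a, "_", chs[ci])
      out <- c(out, v)
      flags <- c(flags, rep(fl, 8L))
    }
    v <- if (empty) setNames(numeric(5L), ngtdmNm)
    else ngtdmFeatures(q)
    names(v) <- paste0(ngtdmNm, "_NGTDM_", chs[ci])
    out <- c(out, v)
    flags <- c(flags, rep(empty, 5L))
  }
  attr(out, "flags") <- setNames(flags, names(out))
  out
}

#' Extract the full 322-column feature vector for one eye
#'
#' Concatenates the 151 morphologic, 54 intensity and 111 texture features
#' (316 automatic features) with the six clinic features re-emitted under
#' their clinic names, and tags each with its category. The image and
#' RoiSet should be in canonical (right-eye) orientation.
#'
#' @param img a [FundusImage-class].
#' @param rois the matching [RoiSet-class].
#' @param nLevels quantization levels for intensity/texture (default 32).
#' @return named numeric of length 322 with attributes `categories`
#'   (named character) and `flags` (named logical).
#' @export
extractFeatureVector <- function(img, rois, nLevels = 32L) {
  m <- morphologicBank(img, rois)
  i <- intensityBank(img, rois, nLevels)
  t_ <- textureBank(img, rois, nLevels)
  clin <- clinicFeatures(rois)
  fl <- c(attr(m, "flags"), attr(i, "flags"), attr(t_, "flags"),
          setNames(c(!hasPPA(rois), rep(FALSE, 5L)), names(clin)))
  out <- c(m, i, t_, clin)
  attributes(out) <- list(names = names(out))
  attr(out, "categories") <- setNames(
    rep(c("morphologic", "intensity", "texture", "clinic"),
        c(length(m), length(i), length(t_), length(clin))), names(out))
  attr(out, "flags") <- fl
  stopifnot(length(out) == 322L, !anyDuplicated(names(out)))
  out
}
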