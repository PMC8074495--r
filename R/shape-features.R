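# Morphologic descriptors of the optic disc and peripapillary atrophy zone.

#' Moment-equivalent ellipse of a binary region
#'
#' Fits the ellipse with the same second central moments as the pixel set:
#' centre = centroid, semi-axes = 2 sqrt(eigenvalues) of the 2 x 2
#' coordinate covariance, orientation = principal eigenvector angle in
#' degrees folded into (-90, 90] (0 when the region is isotropic).
#'
#' @param mask logical matrix, nonempty.
#' @return list with `center` (x, y), `semiMajor`, `semiMinor`,
#'   `orientationDeg`.
#' @export
fitEllipseMoments <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("fitEllipseMoments: empty mask")
  x <- idx[, 2] - 1; y <- idx[, 1] - 1
  cx <- mean(x); cy <- mean(y)
  xc <- x - cx; yc <- y - cy
  cxx <- mean(xc^2); cyy <- mean(yc^2); cxy <- mean(xc * yc)
  e <- eigen(matrix(c(cxx, cxy, cxy, cyy), 2L), symmetric = TRUE)
  semi <- 2 * sqrt(pmax(e$values, 0))
  ori <- if ((e$values[1] - e$values[2]) <= 1e-9 * max(e$values[1], 1e-12)) 0
  else foldAngle(atan2(e$vectors[2, 1], e$vectors[1, 1]) * 180 / pi)
  list(center = c(cx, cy), semiMajor = semi[1],
       semiMinor = max(semi[2], .Machine$double.eps),
       orientationDeg = ori)
}

#' The six clinic features of the optic disc region
#'
#' * `AreaPPA` — pixel count of the PPA zone (between the PPA outer contour
#'   and the disc contour);
#' * `AreaDisc` — pixel count of the disc;
#' * `Tilt` — short axis / long axis of the disc's moment ellipse, in (0, 1];
#' * `Torsion` — signed acute angle (degrees) between the disc long axis and
#'   the perpendicular to the macula-disc-centre line;
#' * `Dist_MD` — Euclidean distance (px) between macula and disc centroid;
#' * `Angle_MD` — signed acute angle (degrees) of the disc-centre-to-macula
#'   line from horizontal, positive when the macula lies below the
#'   horizontal in image coordinates.
#'
#' All quantities are in pixels/degrees; angles are folded into (-90, 90].
#'
#' @param rois an [RoiSet-class] with a nonempty disc mask and macula not at
#'   the disc centroid.
#' @return named numeric of length 6.
#' @export
clinicFeatures <- function(rois) {
  if (sum(rois@discMask) == 0L) stop("clinicFeatures: empty disc mask")
  ell <- fitEllipseMoments(rois@discMask)
  md <- mdLineAngle(rois@macula, ell$center)
  c(AreaPPA = sum(rois@ppaMask),
    AreaDisc = sum(rois@discMask),
    Tilt = ell$semiMinor / ell$semiMajor,
    Torsion = foldAngle(ell$orientationDeg - (md$angle + 90)),
    Dist_MD = md$dist,
    Angle_MD = md$angle)
}

# direction-insensitive angle of the disc-centre -> macula line from
# horizontal, in (-90, 90], positive when the macula lies below the
# horizontal (y-down frame), plus the Euclidean distance
mdLineAngle <- function(macula, center) {
  dx <- macula[1] - center[1]; dy <- macula[2] - center[2]
  d <- sqrt(dx^2 + dy^2)
  if (d == 0) stop("macula coincides with the disc centre")
  if (dx < 0) { dx <- -dx; dy <- -dy }
  ang <- if (dx == 0) 90 else atan2(dy, dx) * 180 / pi
  list(angle = foldAngle(ang), dist = d)
}

# signed curvature of a uniformly resampled closed curve via the Menger
# (circumscribed-circle) construction over a wide stencil; exact for
# circles regardless of the sampling density, positive for convex regions
# in canonical vertex order
curvatureProfile <- function(pts, stencil = max(2L, nrow(pts) %/% 32L)) {
  n <- nrow(pts)
  ip <- ((seq_len(n) - 1L + stencil) %% n) + 1L
  im <- ((seq_len(n) - 1L - stencil) %% n) + 1L
  ax <- pts[im, 1]; ay <- pts[im, 2]
  bx <- pts[, 1]; by <- pts[, 2]
  cx <- pts[ip, 1]; cy <- pts[ip, 2]
  cross <- (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
  ab <- sqrt((bx - ax)^2 + (by - ay)^2)
  bc <- sqrt((cx - bx)^2 + (cy - by)^2)
  ca <- sqrt((ax - cx)^2 + (ay - cy)^2)
  2 * cross / pmax(ab * bc * ca, .Machine$double.eps)
}

# resample a contour for curvature/Fourier work: canonical order, uniform
# arc length, sequence anchored at the +x-extreme (temporal-most) point
canonicalResample <- function(pts, n = 256L) {
  rs <- resampleArc(ensureCanonicalOrder(pts), n)
  i0 <- which.max(rs[, 1])
  if (i0 > 1L) rs <- rs[c(i0:n, 1:(i0 - 1L)), , drop = FALSE]
  rs
}

#' Contour descriptors: perimeter, curvature stations, inter-contour
#' distances
#'
#' Both contours are resampled at 256 points of uniform arc length in
#' canonical order, anchored at their +x-extreme point. Curvature is the
#' finite-difference signed curvature, reported at 16 equally spaced
#' arc-length stations (station 1 at the anchor, ordered along the
#' canonical direction) with mean/SD/max of its magnitude over the full
#' profile. Between the contours the symmetric Hausdorff distance, mean and
#' minimum nearest-point distances and the centroid distance are reported.
#' When the PPA contour is absent all PPA-dependent entries are 0 and
#' flagged.
#'
#' @param disc n x 2 disc contour (n >= 4).
#' @param ppaOuter n x 2 PPA outer contour or NULL.
#' @param nResample resampling density (default 256).
#' @return named numeric (44 values) with attribute `flags`.
#' @export
contourDescriptors <- function(disc, ppaOuter = NULL, nResample = 256L) {
  if (nrow(disc) < 4L) stop("contourDescriptors: disc contour needs >= 4 points")
  oneContour <- function(pts, prefix) {
    rs <- canonicalResample(pts, nResample)
    kap <- curvatureProfile(rs)
    st <- kap[round(seq(0, nResample - 1, length.out = 17L))[1:16] + 1L]
    v <- c(contourPerimeter(rs), st, mean(abs(kap)), sd(abs(kap)), max(abs(kap)))
    names(v) <- c(paste0(prefix, "Perimeter"),
                  paste0(prefix, "Curvature", 1:16),
                  paste0(prefix, "CurvatureMean"),
                  paste0(prefix, "CurvatureSD"),
                  paste0(prefix, "CurvatureMax"))
    list(values = v, pts = rs)
  }
  d <- oneContour(disc, "Disc")
  hasPpa <- !is.null(ppaOuter) && nrow(ppaOuter) >= 4L
  if (hasPpa) {
    p <- oneContour(ppaOuter, "PPA")
    dd <- distMatrix(d$pts, p$pts)
    minA <- apply(dd, 1L, min); minB <- apply(dd, 2L, min)
    between <- c(ContourHausdorff = max(max(minA), max(minB)),
                 ContourMeanDist = mean(c(minA, minB)),
                 ContourMinDist = min(dd),
                 ContourCentroidDist =
                   sqrt(sum((colMeans(d$pts) - colMeans(p$pts))^2)))
    out <- c(d$values, p$values, between)
    flags <- setNames(rep(FALSE, length(out)), names(out))
  } else {
    pv <- setNames(numeric(20L),
                   c("PPAPerimeter", paste0("PPACurvature", 1:16),
                     "PPACurvatureMean", "PPACurvatureSD", "PPACurvatureMax"))
    between <- c(ContourHausdorff = 0, ContourMeanDist = 0,
                 ContourMinDist = 0, ContourCentroidDist = 0)
    out <- c(d$values, pv, between)
    flags <- setNames(c(rep(FALSE, length(d$values)),
                        rep(TRUE, length(pv) + length(between))), names(out))
  }
  attr(out, "flags") <- flags
  out
}

distMatrix <- function(a, b) {
  sqrt(outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2)
}

#' Central moments, normalized moments and Hu invariants of a region
#'
#' Central moments mu_pq for p + q <= 3 (beyond mu00), scale-normalized
#' moments eta_pq, and the seven Hu rotation invariants.
#'
#' @param mask logical matrix, nonempty.
#' @return named numeric of length 21 (mu11..mu03, eta11..eta03, Hu1..Hu7).
#' @export
regionMoments <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("regionMoments: empty mask")
  x <- idx[, 2] - 1; y <- idx[, 1] - 1
  xc <- x - mean(x); yc <- y - mean(y)
  m00 <- length(x)
  mu <- function(p, q) sum(xc^p * yc^q)
  ord <- list(c(1, 1), c(2, 0), c(0, 2), c(3, 0), c(2, 1), c(1, 2), c(0, 3))
  mus <- vapply(ord, function(pq) mu(pq[1], pq[2]), 0)
  etas <- mus / m00^(1 + (vapply(ord, sum, 0)) / 2)
  n <- setNames(etas, c("eta11", "eta20", "eta02", "eta30", "eta21",
                        "eta12", "eta03"))
  hu <- with(as.list(n), {
    a <- eta30 + eta12; b <- eta21 + eta03
    c1 <- eta30 - 3 * eta12; c2 <- 3 * eta21 - eta03
    c(eta20 + eta02,
      (eta20 - eta02)^2 + 4 * eta11^2,
      c1^2 + c2^2,
      a^2 + b^2,
      c1 * a * (a^2 - 3 * b^2) + c2 * b * (3 * a^2 - b^2),
      (eta20 - eta02) * (a^2 - b^2) + 4 * eta11 * a * b,
      c2 * a * (a^2 - 3 * b^2) - c1 * b * (3 * a^2 - b^2))
  })
  c(setNames(mus, c("mu11", "mu20", "mu02", "mu30", "mu21", "mu12", "mu03")),
    n, setNames(hu, paste0("Hu", 1:7)))
}

#' Fourier shape descriptors of a closed contour
#'
#' The contour is resampled uniformly in arc length (canonical order), the
#' centroid is subtracted, and the discrete Fourier transform of the complex
#' boundary x + iy is taken. Emitted are the harmonic magnitudes |c_k| for
#' k = 1..nHarmonics normalized by |c_1|, and the Fourier circularity
#' |c_1| / sum of |c_k| over 1 <= |k| <= nHarmonics, which is 1 for a
#' perfect circle and decreases with boundary complexity.
#'
#' @param contour n x 2 contour points.
#' @param nHarmonics number of harmonics (default 10).
#' @return named numeric: `FourierHarm1..n`, `FourierCircularity`.
#' @export
fourierShape <- function(contour, nHarmonics = 10L) {
  if (NROW(contour) < 4L || abs(polygonArea(as.matrix(contour))) <
        sqrt(.Machine$double.eps))
    stop("fourierShape: degenerate contour")
  N <- max(256L, 4L * nHarmonics)
  rs <- canonicalResample(as.matrix(contour), N)
  z <- complex(real = rs[, 1] - mean(rs[, 1]),
               imaginary = rs[, 2] - mean(rs[, 2]))
  C <- fft(z) / N
  kpos <- Mod(C[1L + seq_len(nHarmonics)])
  kneg <- Mod(C[N + 1L - seq_len(nHarmonics)])
  circ <- kpos[1] / sum(kpos, kneg)
  c(setNames(kpos / kpos[1], paste0("FourierHarm", seq_len(nHarmonics))),
    FourierCircularity = circ)
}

# Cast 72 rays from the disc centroid; along each ray's intersection with
# the PPA mask resample channel intensity at u stations and summarize the
# radial (broadwise) profile. Returns per-ray widths and, per (u, channel),
# the mean absolute successive difference averaged over valid rays.
ppaRayProfiles <- function(img, rois, us = c(10L, 20L, 30L), nRays = 72L) {
  msk <- rois@ppaMask
  H <- nrow(msk); W <- ncol(msk)
  ctr <- fitEllipseMoments(rois@discMask)$center
  idx <- which(msk, arr.ind = TRUE)
  maxR <- if (nrow(idx)) sqrt(max((idx[, 2] - 1 - ctr[1])^2 +
                                  (idx[, 1] - 1 - ctr[2])^2)) + 1 else 1
  ts <- seq(0.5, maxR, by = 0.5)
  ang <- 2 * pi * (seq_len(nRays) - 1L) / nRays
  X <- round(outer(ts, cos(ang)) + ctr[1])
  Y <- round(outer(ts, sin(ang)) + ctr[2])
  valid <- X >= 0 & X < W & Y >= 0 & Y < H
  inp <- matrix(FALSE, length(ts), nRays)
  inp[valid] <- msk[cbind(Y[valid] + 1L, X[valid] + 1L)]
  rayRange <- lapply(seq_len(nRays), function(j) {
    w <- which(inp[, j])
    if (!length(w)) NULL else c(ts[w[1]], ts[w[length(w)]])
  })
  ok <- !vapply(rayRange, is.null, TRUE)
  widths <- vapply(rayRange[ok], function(r) r[2] - r[1], 0)
  weight <- matrix(0, length(us), 3L,
                   dimnames = list(paste0("u", us), c("R", "G", "B")))
  if (any(ok)) {
    jset <- which(ok)
    r1 <- vapply(rayRange[ok], `[`, 0, 1L)
    r2 <- vapply(rayRange[ok], `[`, 0, 2L)
    cosj <- cos(ang[jset]); sinj <- sin(ang[jset])
    for (ui in seq_along(us)) {
      u <- us[ui]
      s <- seq(0, 1, length.out = u)
      tt <- outer(s, r2 - r1) + rep(r1, each = u)      # u x J stations
      xs <- pmin(pmax(round(ctr[1] + tt * rep(cosj, each = u)), 0), W - 1)
      ys <- pmin(pmax(round(ctr[2] + tt * rep(sinj, each = u)), 0), H - 1)
      li <- cbind(as.integer(ys) + 1L, as.integer(xs) + 1L)
      for (ch in 1:3) {
        P <- matrix(img@pixels[, , ch][li], u)
        weight[ui, ch] <- mean(colMeans(abs(diff(P))))
      }
    }
  }
  list(widths = widths, weight = weight, nValid = sum(ok))
}

#' PPA broadwise intensity-fluctuation feature (PPAweight)
#'
#' Operationalizes the "pixel distribution of PPA" profile feature: 72 rays
#' are cast from the disc centroid; along each ray's intersection with the
#' PPA zone the chosen channel is resampled at `u` equally spaced stations,
#' and the feature is the mean (over rays hitting PPA) of the mean absolute
#' successive difference of the station profile. Higher values mean more
#' rapid intensity fluctuation across the PPA's broadwise direction.
#'
#' @param img a [FundusImage-class].
#' @param rois the matching [RoiSet-class].
#' @param u number of radial stations (>= 2).
#' @param channel `"R"`, `"G"` or `"B"`.
#' @return scalar; 0 with attribute `flag = TRUE` when PPA is absent.
#' @export
ppaProfileFeature <- function(img, rois, u = 20L, channel = "R") {
  if (u < 2L) stop("ppaProfileFeature: u must be >= 2")
  if (!hasPPA(rois)) {
    out <- 0
    attr(out, "flag") <- TRUE
    return(out)
  }
  pr <- ppaRayProfiles(img, rois, us = u)
  out <- pr$weight[1L, channel]
  attr(out, "flag") <- FALSE
  out
}

# mask-level region properties; perimeter/hull come from the contour
regionProps <- function(mask, contourPts) {
  A <- sum(mask)
  P <- contourPerimeter(contourPts)
  hull <- contourPts[grDevices::chull(contourPts), , drop = FALSE]
  hullA <- abs(polygonArea(hull))
  idx <- which(mask, arr.ind = TRUE)
  bboxA <- (diff(range(idx[, 1])) + 1) * (diff(range(idx[, 2])) + 1)
  ell <- fitEllipseMoments(mask)
  ecc <- sqrt(max(0, 1 - (ell$semiMinor / ell$semiMajor)^2))
  c(Perimeter = P,
    AreaPerimeterRatio = A / P,
    Circularity = 4 * pi * A / P^2,
    Solidity = A / max(hullA, 1),
    Extent = A / bboxA,
    Eccentricity = ecc,
    ConvexArea = hullA)
}

#' The 151-feature morphologic bank
#'
#' A fixed, documented roster of in-house shape descriptors of the optic
#' disc and PPA zone: the clinic-feature ingredients (10), curvature
#' stations and statistics for both contours (38), mask region properties
#' for both regions (14), central/normalized moments and Hu invariants for
#' both regions (42), Fourier harmonics and circularity for both contours
#' (22), inter-contour distances (4), PPA broadwise width statistics over
#' 72 rays (5), the PPAweight family over u in 10/20/30 and R/G/B (9) and
#' seven derived ratios. PPA-dependent entries are emitted as 0 and flagged
#' when the eye has no PPA.
#'
#' @param img a [FundusImage-class] in canonical orientation.
#' @param rois the matching [RoiSet-class].
#' @return named numeric of length 151 with attribute `flags` (logical).
#' @export
morphologicBank <- function(img, rois) {
  clin <- clinicFeatures(rois)
  ell <- fitEllipseMoments(rois@discMask)
  hasPpa <- hasPPA(rois)
  equivD <- sqrt(4 * sum(rois@discMask) / pi)

  gA <- c(shape_AreaPPA = unname(clin["AreaPPA"]),
          shape_AreaDisc = unname(clin["AreaDisc"]),
          shape_Tilt = unname(clin["Tilt"]),
          shape_Torsion = unname(clin["Torsion"]),
          shape_Dist_MD = unname(clin["Dist_MD"]),
          shape_Angle_MD = unname(clin["Angle_MD"]),
          shape_DiscLongAxis = ell$semiMajor * 2,
          shape_DiscShortAxis = ell$semiMinor * 2,
          shape_DiscOrientation = ell$orientationDeg,
          shape_DiscEquivDiameter = equivD)

  cd <- contourDescriptors(rois@discContour,
                           if (hasPpa) rois@ppaContour else NULL)
  cdFlags <- attr(cd, "flags")

  discProps <- regionProps(rois@discMask, rois@discContour)
  names(discProps) <- paste0("Disc_", names(discProps))
  if (hasPpa) {
    ppaProps <- regionProps(rois@ppaMask, rois@ppaContour)
  } else {
    ppaProps <- setNames(numeric(7L), c("Perimeter", "AreaPerimeterRatio",
      "Circularity", "Solidity", "Extent", "Eccentricity", "ConvexArea"))
  }
  names(ppaProps) <- paste0("PPA_", sub("^PPA_", "", names(ppaProps)))

  discMom <- regionMoments(rois@discMask)
  names(discMom) <- paste0("Disc_", names(discMom))
  if (hasPpa) {
    ppaMom <- regionMoments(rois@ppaMask)
  } else {
    ppaMom <- setNames(numeric(21L), names(regionMoments(rois@discMask)))
  }
  names(ppaMom) <- paste0("PPA_", sub("^PPA_", "", names(ppaMom)))

  fourierNames <- function(region)
    c(paste0("Fourier_Harm", 1:10, "_", region),
      paste0("Fourier_Circularity_", region))
  discF <- setNames(fourierShape(rois@discContour), fourierNames("Disc"))
  ppaF <- if (hasPpa)
    setNames(fourierShape(rois@ppaContour), fourierNames("PPA"))
  else setNames(numeric(11L), fourierNames("PPA"))

  prof <- ppaRayProfiles(img, rois)
  if (hasPpa && length(prof$widths) >= 2L) {
    w <- prof$widths
    m3 <- mean((w - mean(w))^3)
    sk <- if (sd(w) > 0) m3 / (sqrt(mean((w - mean(w))^2)))^3 else 0
    gG <- c(PPAWidthMean = mean(w), PPAWidthSD = sd(w), PPAWidthMax = max(w),
            PPAWidthMin = min(w), PPAWidthSkew = sk)
  } else {
    gG <- c(PPAWidthMean = 0, PPAWidthSD = 0, PPAWidthMax = 0,
            PPAWidthMin = 0, PPAWidthSkew = 0)
  }
  wt <- prof$weight
  gH <- setNames(as.numeric(t(wt)),
                 paste0("PPAweight_", rep(rownames(wt), each = 3L),
                        rep(colnames(wt), 3L)))

  gI <- c(Ratio_AreaPPA_AreaDisc = unname(clin["AreaPPA"] / clin["AreaDisc"]),
          Ratio_AreaPPA_Total =
            unname(clin["AreaPPA"] / (clin["AreaPPA"] + clin["AreaDisc"])),
          Ratio_PPAPerim_DiscPerim =
            unname(cd["PPAPerimeter"] / cd["DiscPerimeter"]),
          Ratio_DistMD_DiscLongAxis =
            unname(clin["Dist_MD"] / (2 * ell$semiMajor)),
          Ratio_PPAWidth_DiscDiameter = unname(gG["PPAWidthMean"] / equivD),
          Ratio_ConvexPPA_ConvexDisc =
            unname(ppaProps["PPA_ConvexArea"] / discProps["Disc_ConvexArea"]),
          Ratio_Hausdorff_DiscDiameter =
            unname(cd["ContourHausdorff"] / equivD))

  # perimeters are reported once, within the region-property block
  cdKeep <- cd[setdiff(names(cd), c("DiscPerimeter", "PPAPerimeter"))]
  out <- c(gA, cdKeep, discProps, ppaProps, discMom, ppaMom, discF, ppaF,
           gG, gH, gI)
  attr(out, "flags") <- NULL
  ppaNames <- c("shape_AreaPPA",
                names(cd)[cdFlags],
                names(ppaProps), names(ppaMom), names(ppaF),
                names(gG), names(gH),
                c("Ratio_AreaPPA_AreaDisc", "Ratio_AreaPPA_Total",
                  "Ratio_PPAPerim_DiscPerim", "Ratio_PPAWidth_DiscDiameter",
                  "Ratio_ConvexPPA_ConvexDisc",
                  "Ratio_Hausdorff_DiscDiameter"))
  flags <- setNames(rep(FALSE, length(out)), names(out))
  if (!hasPpa) flags[names(flags) %in% ppaNames] <- TRUE
  attr(out, "flags") <- flags
  stopifnot(length(out) == 151L)
  out
}
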