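# Independent brute-force oracles and small geometric fixtures, built in
# code at test time. The oracles implement the textbook definitions with
# naive loops and never touch the package's computation paths.

circlePts <- function(cx, cy, r, n = 64L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(x = cx + r * cos(th), y = cy + r * sin(th))
}

ellipsePts <- function(cx, cy, a, b, phiDeg = 0, n = 64L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  phi <- phiDeg * pi / 180
  cbind(x = cx + a * cos(th) * cos(phi) - b * sin(th) * sin(phi),
        y = cy + a * cos(th) * sin(phi) + b * sin(th) * cos(phi))
}

shoelace <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2)
}

# flat gray test image wrapper
grayImage <- function(mat) {
  px <- array(0L, c(nrow(mat), ncol(mat), 3L))
  for (k in 1:3) px[, , k] <- as.integer(round(mat))
  FundusImage(px)
}

# brute-force pair-counting AUC
bfAuc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# brute-force first-order statistics from the raw value vector
bfFirstorder <- function(x, nLevels = 32L) {
  n <- length(x)
  rng <- range(x)
  if (rng[1] == rng[2]) lev <- rep(1L, n)
  else lev <- pmin(floor((x - rng[1]) / (rng[2] - rng[1]) * nLevels) + 1L,
                   nLevels)
  p <- as.numeric(table(lev)) / n
  mu <- sum(x) / n
  v <- sum((x - mu)^2) / n
  q10 <- quantile(x, 0.1, names = FALSE); q90 <- quantile(x, 0.9, names = FALSE)
  band <- x[x >= q10 & x <= q90]
  c(Energy = sum(x^2), TotalEnergy = sum(x^2),
    Entropy = -sum(p * log2(p)), Minimum = min(x), Percentile10 = q10,
    Percentile90 = q90, Maximum = max(x), Mean = mu, Median = median(x),
    InterquartileRange = quantile(x, .75, names = FALSE) -
      quantile(x, .25, names = FALSE),
    Range = max(x) - min(x),
    MeanAbsoluteDeviation = sum(abs(x - mu)) / n,
    RobustMeanAbsoluteDeviation = mean(abs(band - mean(band))),
    RootMeanSquared = sqrt(sum(x^2) / n),
    Skewness = if (v > 0) (sum((x - mu)^3) / n) / v^1.5 else 0,
    Kurtosis = if (v > 0) (sum((x - mu)^4) / n) / v^2 else 0,
    Variance = v, Uniformity = sum(p^2))
}

# brute-force symmetric normalized GLCM and its eight features
bfGlcm <- function(lv, dr, dc) {
  H <- nrow(lv); W <- ncol(lv)
  ng <- max(lv, na.rm = TRUE)
  P <- matrix(0, ng, ng)
  for (r in 1:H) for (c in 1:W) {
    if (is.na(lv[r, c])) next
    r2 <- r + dr; c2 <- c + dc
    if (r2 >= 1 && r2 <= H && c2 >= 1 && c2 <= W && !is.na(lv[r2, c2])) {
      P[lv[r, c], lv[r2, c2]] <- P[lv[r, c], lv[r2, c2]] + 1
      P[lv[r2, c2], lv[r, c]] <- P[lv[r2, c2], lv[r, c]] + 1
    }
  }
  if (sum(P) == 0) return(NULL)
  P <- P / sum(P)
  mux <- 0; muy <- 0
  for (i in 1:ng) for (j in 1:ng) { mux <- mux + i * P[i, j]
                                    muy <- muy + j * P[i, j] }
  sx <- 0; sy <- 0
  for (i in 1:ng) for (j in 1:ng) { sx <- sx + (i - mux)^2 * P[i, j]
                                    sy <- sy + (j - muy)^2 * P[i, j] }
  sx <- sqrt(sx); sy <- sqrt(sy)
  f <- c(contrast = 0, dissimilarity = 0, homogeneity = 0, asm = 0,
         entropy = 0, correlation = 0, shade = 0, prominence = 0)
  for (i in 1:ng) for (j in 1:ng) {
    p <- P[i, j]
    f["contrast"] <- f["contrast"] + (i - j)^2 * p
    f["dissimilarity"] <- f["dissimilarity"] + abs(i - j) * p
    f["homogeneity"] <- f["homogeneity"] + p / (1 + (i - j)^2)
    f["asm"] <- f["asm"] + p^2
    if (p > 0) f["entropy"] <- f["entropy"] - p * log2(p)
    f["shade"] <- f["shade"] + (i + j - mux - muy)^3 * p
    f["prominence"] <- f["prominence"] + (i + j - mux - muy)^4 * p
    if (sx > 0 && sy > 0)
      f["correlation"] <- f["correlation"] +
        (i - mux) * (j - muy) * p / (sx * sy)
  }
  if (sx == 0 || sy == 0) f["correlation"] <- 1
  f
}

# brute-force NGTDM features (8-neighborhood, in-mask neighbors)
bfNgtdm <- function(lv) {
  H <- nrow(lv); W <- ncol(lv)
  ng <- max(lv, na.rm = TRUE)
  si <- numeric(ng); ni <- numeric(ng)
  for (r in 1:H) for (c in 1:W) {
    if (is.na(lv[r, c])) next
    nb <- c()
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- c + dc
      if (r2 >= 1 && r2 <= H && c2 >= 1 && c2 <= W && !is.na(lv[r2, c2]))
        nb <- c(nb, lv[r2, c2])
    }
    if (length(nb)) {
      i <- lv[r, c]
      si[i] <- si[i] + abs(i - mean(nb))
      ni[i] <- ni[i] + 1
    }
  }
  N <- sum(ni); pi_ <- ni / N
  act <- which(pi_ > 0); ngp <- length(act)
  eps <- 1e-6
  coarse <- min(1 / (eps + sum(pi_ * si)), 1e6)
  contrast <- 0; busyD <- 0; complexity <- 0; strengthN <- 0
  if (ngp > 1) {
    for (i in act) for (j in act) {
      contrast <- contrast + pi_[i] * pi_[j] * (i - j)^2
      busyD <- busyD + abs(i * pi_[i] - j * pi_[j])
      complexity <- complexity +
        abs(i - j) * (pi_[i] * si[i] + pi_[j] * si[j]) / (pi_[i] + pi_[j])
      strengthN <- strengthN + (pi_[i] + pi_[j]) * (i - j)^2
    }
    contrast <- contrast / (ngp * (ngp - 1)) * sum(si) / N
    complexity <- complexity / N
  }
  c(Coarseness = coarse,
    Contrast = contrast,
    Busyness = if (busyD > 0) sum(pi_ * si) / busyD else 0,
    Complexity = complexity,
    Strength = if (sum(si) > 0) strengthN / (eps + sum(si)) else 0)
}

# quick RoiSet around concentric ellipses for shape tests
makeRois <- function(H = 220, W = 220, disc = ellipsePts(108, 108, 60, 48),
                     ppa = ellipsePts(108, 108, 100, 80),
                     macula = c(30, 108)) {
  RoiSet(disc, ppa, macula, c(H, W), smooth = FALSE)
}

# Feature-family bucket for the planted-axis recovery check: the four
# planted effects (PPA area, brightness, histogram complexity, texture
# coarseness) map onto the bank's feature families — shape/geometry,
# first-order location, first-order histogram shape, and spatial texture.
bucketOf <- function(n) {
  loc <- "^firstorder_(Energy|TotalEnergy|Mean|Median|Maximum|Minimum|Percentile10|Percentile90|RootMeanSquared)_"
  if (grepl(loc, n)) return("brightness")
  if (grepl("^firstorder_", n)) return("complexity")
  if (grepl("^glcm_", n) || grepl("_NGTDM_", n) || grepl("^PPAweight", n))
    return("texture")
  "area"
}
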