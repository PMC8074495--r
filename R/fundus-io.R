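# Image and annotation I/O, orientation canonicalization.

#' Construct a FundusImage
#'
#' @param pixels H x W x 3 array of intensities in [0, 255] (numeric values
#'   are rounded to integers).
#' @param laterality `"left"` or `"right"`.
#' @param eyeId,patientId identifiers.
#' @param dpi nominal resolution (metadata only).
#' @return a [FundusImage-class] object.
#' @export
FundusImage <- function(pixels, laterality = "right", eyeId = "eye",
                        patientId = eyeId, dpi = 150) {
  storage.mode(pixels) <- "integer"
  new("FundusImage", pixels = pixels, laterality = laterality,
      eyeId = as.character(eyeId), patientId = as.character(patientId),
      dpi = dpi)
}

#' Read a fundus photograph from disk
#'
#' Decodes an 8-bit RGB PNG, TIFF or JPEG into a [FundusImage-class].
#' Grayscale (single-channel) images are rejected; an alpha channel, if
#' present, is dropped.
#'
#' @param path file path; format chosen by extension.
#' @param laterality `"left"` or `"right"` (from the labels table, never
#'   guessed from image content).
#' @param eyeId,patientId identifiers.
#' @param dpi nominal resolution.
#' @return a [FundusImage-class].
#' @export
readFundus <- function(path, laterality, eyeId, patientId = eyeId,
                       dpi = 150) {
  if (!file.exists(path)) stop("readFundus: file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    jpg = ,
    jpeg = jpeg::readJPEG(path),
    stop("readFundus: unsupported image format: ", ext)
  )
  if (length(dim(arr)) != 3L)
    stop("readFundus: single-channel image; an RGB fundus photograph is required")
  if (dim(arr)[3] == 4L) arr <- arr[, , 1:3, drop = FALSE]
  if (dim(arr)[3] != 3L)
    stop("readFundus: expected 3 color channels, found ", dim(arr)[3])
  px <- array(as.integer(round(arr * 255)), dim = dim(arr))
  FundusImage(px, laterality = laterality, eyeId = eyeId,
              patientId = patientId, dpi = dpi)
}

#' Construct an RoiSet from contours and a macula point
#'
#' Contours are smoothed with [smoothContour()] (unless `smooth = FALSE`)
#' and rasterized; the PPA mask is the filled PPA outer contour minus the
#' filled disc, guaranteeing disjointness. The PPA outer contour is required
#' to enclose the disc contour (crescents are expressed by near-coincident
#' boundary stretches).
#'
#' @param disc n x 2 disc contour points.
#' @param ppa n x 2 PPA outer contour points, or NULL when the eye has no
#'   visible PPA.
#' @param macula (x, y) macula centre.
#' @param shape integer (H, W) of the image frame.
#' @param smooth smooth contours before rasterizing (default TRUE).
#' @param nOut points per smoothed contour (default 4x input).
#' @return an [RoiSet-class].
#' @export
RoiSet <- function(disc, ppa = NULL, macula, shape, smooth = TRUE,
                   nOut = NULL) {
  disc <- as.matrix(disc)
  if (smooth)
    disc <- smoothContour(disc, if (is.null(nOut)) 4L * nrow(disc) else nOut)
  discM <- rasterizeRegion(disc, shape)
  if (is.null(ppa) || NROW(ppa) == 0L) {
    ppaC <- matrix(numeric(0), 0L, 2L)
    ppaM <- matrix(FALSE, shape[1], shape[2])
  } else {
    ppaC <- as.matrix(ppa)
    if (smooth)
      ppaC <- smoothContour(ppaC, if (is.null(nOut)) 4L * nrow(ppaC) else nOut)
    ppaM <- rasterizeRegion(ppaC, shape) & !discM
  }
  new("RoiSet", discContour = disc, ppaContour = ppaC,
      macula = as.numeric(macula), discMask = discM, ppaMask = ppaM)
}

#' Load ROI annotations for one eye
#'
#' Accepts one of three on-disk forms:
#' * a JSON file `{"disc": [[x,y],...], "ppa": [[x,y],...], "macula": [x,y]}`
#'   (the `ppa` entry may be absent);
#' * a directory of one-region-per-file CSVs (`disc.csv`, `ppa.csv` with
#'   x,y columns, `macula.csv` with one row) — `ppa.csv` may be absent;
#' * a label-mask PNG (0 = background, 1 = disc, 2 = PPA) from which
#'   contours are traced (requires the EBImage package); the macula must
#'   then be supplied via `macula`.
#'
#' Contours are smoothed and rasterized into masks; coordinates must lie
#' within the image frame.
#'
#' @param path annotation file or directory.
#' @param imageShape integer (H, W) of the image the annotation refers to.
#' @param macula optional (x, y) override, required for the mask-PNG form.
#' @return an [RoiSet-class].
#' @export
loadAnnotations <- function(path, imageShape, macula = NULL) {
  H <- imageShape[1]; W <- imageShape[2]
  if (dir.exists(path)) {
    discF <- file.path(path, "disc.csv")
    if (!file.exists(discF)) stop("loadAnnotations: disc contour missing")
    disc <- as.matrix(read.csv(discF))[, c("x", "y"), drop = FALSE]
    ppaF <- file.path(path, "ppa.csv")
    ppa <- if (file.exists(ppaF))
      as.matrix(read.csv(ppaF))[, c("x", "y"), drop = FALSE] else NULL
    if (is.null(macula)) {
      macF <- file.path(path, "macula.csv")
      if (!file.exists(macF)) stop("loadAnnotations: macula missing")
      m <- read.csv(macF)
      macula <- c(m$x[1], m$y[1])
    }
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    ann <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.null(ann$disc)) stop("loadAnnotations: disc contour missing")
    disc <- matrix(unlist(ann$disc), ncol = 2L, byrow = !is.matrix(ann$disc))
    if (is.matrix(ann$disc)) disc <- ann$disc
    ppa <- if (!is.null(ann$ppa)) {
      if (is.matrix(ann$ppa)) ann$ppa
      else matrix(unlist(ann$ppa), ncol = 2L, byrow = TRUE)
    } else NULL
    if (is.null(macula)) {
      if (is.null(ann$macula)) stop("loadAnnotations: macula missing")
      macula <- as.numeric(unlist(ann$macula))
    }
  } else if (grepl("\\.png$", path, ignore.case = TRUE)) {
    if (!requireNamespace("EBImage", quietly = TRUE))
      stop("loadAnnotations: tracing label-mask PNGs requires EBImage")
    lab <- round(png::readPNG(path) * 255)
    if (length(dim(lab)) == 3L) lab <- lab[, , 1]
    disc <- traceMaskContour(lab == 1)
    ppa <- if (any(lab == 2)) traceMaskContour(lab >= 1) else NULL
    if (is.null(macula))
      stop("loadAnnotations: macula point required with mask annotations")
  } else stop("loadAnnotations: unrecognized annotation format: ", path)

  checkBounds <- function(p, what) {
    if (any(p[, 1] < 0 | p[, 1] > W - 1 | p[, 2] < 0 | p[, 2] > H - 1))
      stop("loadAnnotations: ", what, " coordinates out of image bounds")
  }
  checkBounds(disc, "disc")
  if (!is.null(ppa)) checkBounds(ppa, "ppa")
  checkBounds(matrix(macula, 1L), "macula")
  RoiSet(disc, ppa, macula, imageShape)
}

# trace the outer boundary of a binary mask (Moore tracing via EBImage),
# returning 0-based (x, y) contour points
traceMaskContour <- function(mask) {
  oc <- EBImage::ocontour(EBImage::Image(t(mask) * 1))
  pts <- oc[[which.max(vapply(oc, nrow, 1L))]]
  cbind(x = pts[, 1], y = pts[, 2])
}

# mirror helpers: x -> (W - 1) - x, an exact involution under the
# integer-centre pixel convention
flipImage <- function(img) {
  out <- img
  out@pixels <- img@pixels[, dim(img@pixels)[2]:1, , drop = FALSE]
  out@laterality <- "right"
  out
}

flipRois <- function(rois, W) {
  fx <- function(p) {
    if (nrow(p) == 0L) return(p)
    p[, 1] <- (W - 1) - p[, 1]
    p
  }
  new("RoiSet",
      discContour = fx(rois@discContour),
      ppaContour = fx(rois@ppaContour),
      macula = c((W - 1) - rois@macula[1], rois@macula[2]),
      discMask = rois@discMask[, ncol(rois@discMask):1, drop = FALSE],
      ppaMask = rois@ppaMask[, ncol(rois@ppaMask):1, drop = FALSE])
}

#' Mirror left eyes into the canonical right-eye frame
#'
#' All scans are analysed in a common orientation: right eyes pass through
#' unchanged, left eyes are mirrored horizontally (pixel (x, y) to
#' (W-1-x, y), contour and macula x mapped to (W-1)-x, masks flipped
#' column-wise) and relabelled as right. Mask areas and intensity
#' histograms are preserved exactly.
#'
#' @param img a [FundusImage-class].
#' @param rois the matching [RoiSet-class].
#' @return list with elements `image` and `rois` in canonical orientation.
#' @export
canonicalizeOrientation <- function(img, rois) {
  if (img@laterality == "right") return(list(image = img, rois = rois))
  W <- dim(img@pixels)[2]
  list(image = flipImage(img), rois = flipRois(rois, W))
}
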