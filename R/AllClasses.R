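#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay colData rowData
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom stats approx coef cor fft glm median predict quantile rbinom
#'   rnorm runif sd setNames spline t.test var binomial qt pt
#' @importFrom utils read.csv write.csv head
NULL

#' FundusImage: a color fundus photograph with eye metadata
#'
#' Holds an H x W x 3 integer RGB raster (intensities in 0..255), the eye's
#' laterality, and identifiers. Pixel coordinates throughout the package are
#' 0-based with x = column index, y = row index and y increasing downward;
#' integer coordinates sit at pixel centres.
#'
#' @slot pixels integer array, H x W x 3, values in [0, 255].
#' @slot laterality `"left"` or `"right"`. After
#'   [canonicalizeOrientation()] every eye is `"right"`.
#' @slot eyeId character scalar identifying the eye.
#' @slot patientId character scalar identifying the patient.
#' @slot dpi numeric scalar, nominal scan resolution (metadata only; all
#'   measurements are in pixels).
#'
#' @seealso [readFundus()], [canonicalizeOrientation()]
#' @export
setClass("FundusImage",
  representation(
    pixels = "array",
    laterality = "character",
    eyeId = "character",
    patientId = "character",
    dpi = "numeric"
  ),
  prototype(laterality = "right", eyeId = "eye", patientId = "pt", dpi = 150)
)

setValidity("FundusImage", function(object) {
  d <- dim(object@pixels)
  if (length(d) != 3L || d[3] != 3L)
    return("pixels must be an H x W x 3 array")
  if (d[1] < 1L || d[2] < 1L)
    return("image must have positive height and width")
  rng <- range(object@pixels)
  if (!is.finite(rng[1]) || rng[1] < 0 || rng[2] > 255)
    return("intensities must lie in [0, 255]")
  if (!object@laterality %in% c("left", "right"))
    return("laterality must be 'left' or 'right'")
  if (length(object@dpi) != 1L || object@dpi <= 0)
    return("dpi must be a positive scalar")
  TRUE
})

#' RoiSet: optic-disc / PPA geometry for one eye
#'
#' Bundles the smoothed optic-disc contour, the outer contour of the
#' peripapillary atrophy (PPA) zone, the macula landmark, and the two binary
#' region masks. The PPA mask is the filled outer contour minus the filled
#' disc contour, so the two masks are disjoint by construction; eyes without
#' PPA carry an empty `ppaMask` and a zero-row `ppaContour`.
#'
#' @slot discContour numeric matrix (n x 2) of (x, y) points, closed
#'   implicitly (last point adjacent to first).
#' @slot ppaContour numeric matrix (n x 2); zero rows when PPA is absent.
#' @slot macula numeric length-2 (x, y) of the macula centre.
#' @slot discMask,ppaMask logical H x W matrices.
#'
#' @seealso [loadAnnotations()], [clinicFeatures()]
#' @export
setClass("RoiSet",
  representation(
    discContour = "matrix",
    ppaContour = "matrix",
    macula = "numeric",
    discMask = "matrix",
    ppaMask = "matrix"
  )
)

setValidity("RoiSet", function(object) {
  if (ncol(object@discContour) != 2L || nrow(object@discContour) < 3L)
    return("discContour must be an n x 2 matrix with n >= 3")
  if (ncol(object@ppaContour) != 2L && nrow(object@ppaContour) > 0L)
    return("ppaContour must have 2 columns")
  if (length(object@macula) != 2L || any(!is.finite(object@macula)))
    return("macula must be a finite (x, y) pair")
  if (!identical(dim(object@discMask), dim(object@ppaMask)))
    return("discMask and ppaMask must share their shape")
  if (!is.logical(object@discMask) || !is.logical(object@ppaMask))
    return("masks must be logical matrices")
  if (sum(object@discMask) == 0L)
    return("discMask must be nonempty")
  if (any(object@discMask & object@ppaMask))
    return("discMask and ppaMask must be disjoint")
  TRUE
})

#' FeatureTable: eyes-by-features container with study labels
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding the radiomic
#' feature bank: features as rows (with a `category` column in `rowData`:
#' morphologic, intensity, texture or clinic) and eyes as columns. `colData`
#' carries `eyeId`, `patientId`, `laterality`, `grade` (META-PM:
#' C0/C1/PDCA/MDCA/C3/C4), `plusLesion`, the derived `severe` flag, and a
#' `split` tag (train/validation/NA).
#'
#' @seealso [buildFeatureTable()], [featureMatrix()], [simulateFeatureTable()]
#' @export
setClass("FeatureTable", contains = "SummarizedExperiment")

setValidity("FeatureTable", function(object) {
  if (anyDuplicated(rownames(object)))
    return("feature names must be unique")
  cd <- SummarizedExperiment::colData(object)
  if (!"severe" %in% colnames(cd))
    return("colData must contain a 'severe' column")
  sev <- cd$severe
  if (!all(sev %in% c(0L, 1L, NA)))
    return("severe labels must be 0/1")
  rd <- SummarizedExperiment::rowData(object)
  if (!"category" %in% colnames(rd))
    return("rowData must contain a 'category' column")
  TRUE
})

#' SelectionTrace: SFFS search record
#'
#' Per cardinality k the best feature subset found by sequential floating
#' forward selection together with its mean and SD of the cross-validated
#' criterion; after [chooseFinalSet()] also the chosen cardinality and final
#' set.
#'
#' @slot trace data.frame with columns `k`, `meanScore`, `sdScore`.
#' @slot subsets list of character vectors, the best subset at each k.
#' @slot chosenK integer, NA until a final set is chosen.
#' @slot finalSet character vector of chosen feature names.
#' @slot criterion character, the wrapper criterion (`"auc"` or
#'   `"accuracy"`).
#' @slot seed integer seed that governed folds and forests.
#' @export
setClass("SelectionTrace",
  representation(
    trace = "data.frame",
    subsets = "list",
    chosenK = "integer",
    finalSet = "character",
    criterion = "character",
    seed = "integer"
  ),
  prototype(chosenK = NA_integer_, finalSet = character(0),
            criterion = "auc", seed = NA_integer_)
)

setValidity("SelectionTrace", function(object) {
  tr <- object@trace
  if (!all(c("k", "meanScore", "sdScore") %in% colnames(tr)))
    return("trace needs columns k, meanScore, sdScore")
  if (nrow(tr) != length(object@subsets))
    return("one subset per trace row required")
  if (any(tr$meanScore < 0 | tr$meanScore > 1, na.rm = TRUE))
    return("scores must lie in [0, 1]")
  if (any(tr$sdScore < 0, na.rm = TRUE))
    return("score SDs must be nonnegative")
  TRUE
})

#' EvalReport: evaluation battery output
#'
#' @slot setAuc named numeric: validation AUC of the new, clinic and union
#'   feature sets.
#' @slot univariate data.frame of per-feature cross-validated logistic AUC
#'   (mean, SD) with a set membership column.
#' @slot correlation list with `r`, `p` and `stars` matrices
#'   (new features x clinic features).
#' @slot profiles list with per-grade mean/SD profile table and
#'   adjacent-grade transition tests.
#' @slot counts list of per-grade and per-severity-group counts.
#' @slot meta list of bookkeeping (feature counts through the cascade,
#'   split sizes, seed).
#' @export
setClass("EvalReport",
  representation(
    setAuc = "numeric",
    univariate = "data.frame",
    correlation = "list",
    profiles = "list",
    counts = "list",
    meta = "list"
  )
)
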