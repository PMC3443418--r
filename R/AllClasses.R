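#' @import methods
NULL

#' CTVolume: a 3D CT attenuation volume
#'
#' Container for a single non-contrast CT scan: a 3D grid of attenuation
#' values in Hounsfield units (HU) together with the voxel spacing and the
#' physical position of the first voxel centre. Axis order is (x, y, z)
#' with z the slice axis; the physical centre of voxel `(i, j, k)`
#' (1-based) is `origin + (i-1, j-1, k-1) * spacing`.
#'
#' @slot voxels 3D numeric array of attenuation in HU.
#' @slot spacing Numeric length-3, voxel spacing (dx, dy, dz) in mm; all > 0.
#' @slot origin Numeric length-3, physical position (mm) of the centre of
#'   voxel (1,1,1).
#' @slot scanId Character scalar identifying the scan.
#' @slot participantId Character scalar identifying the participant.
#'
#' @seealso [CTVolume()] for the constructor, [readVolume()], [voxelVolume()]
#' @exportClass CTVolume
setClass("CTVolume",
  representation(
    voxels = "array",
    spacing = "numeric",
    origin = "numeric",
    scanId = "character",
    participantId = "character"
  ),
  prototype(
    origin = c(0, 0, 0),
    scanId = "scan1",
    participantId = "p1"
  )
)

setValidity("CTVolume", function(object) {
  msg <- character(0)
  if (length(dim(object@voxels)) != 3L)
    msg <- c(msg, "voxels must be a 3D array")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 finite positive values (mm)")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be 3 finite values (mm)")
  if (any(!is.finite(object@voxels)))
    msg <- c(msg, "attenuation values must be finite (no NaN/Inf)")
  if (length(object@scanId) != 1L || length(object@participantId) != 1L)
    msg <- c(msg, "scanId and participantId must be single strings")
  if (length(msg)) msg else TRUE
})

#' Construct a CTVolume
#'
#' @param voxels 3D numeric array of attenuation (HU).
#' @param spacing Voxel spacing (dx, dy, dz) in mm.
#' @param origin Physical position (mm) of the centre of voxel (1,1,1).
#' @param scanId,participantId Identifier strings.
#' @return A [CTVolume-class] object.
#' @examples
#' vol <- CTVolume(array(0, c(8, 8, 4)), spacing = c(0.68, 0.68, 3))
#' voxelVolume(vol)
#' @export
CTVolume <- function(voxels, spacing, origin = c(0, 0, 0),
                     scanId = "scan1", participantId = "p1") {
  new("CTVolume", voxels = voxels, spacing = as.numeric(spacing),
      origin = as.numeric(origin), scanId = as.character(scanId),
      participantId = as.character(participantId))
}

#' ArteryTrajectory: a coronary-artery centerline
#'
#' An ordered polyline of physical (mm) coordinates tracing a coronary
#' artery, plus the search radius within which candidate calcium is sought.
#' The default radius of 8 mm reflects the standard reading protocol in
#' which lesion search is restricted to within 8 mm of the reader-traced
#' trajectories.
#'
#' @slot name Artery label (e.g. "LAD", "RCA").
#' @slot points Numeric n x 3 matrix of ordered (x, y, z) mm coordinates.
#' @slot searchRadius Search radius in mm (> 0); default 8.
#'
#' @exportClass ArteryTrajectory
setClass("ArteryTrajectory",
  representation(
    name = "character",
    points = "matrix",
    searchRadius = "numeric"
  ),
  prototype(searchRadius = 8)
)

setValidity("ArteryTrajectory", function(object) {
  msg <- character(0)
  p <- object@points
  if (!is.numeric(p) || ncol(p) != 3L)
    msg <- c(msg, "points must be a numeric n x 3 matrix")
  else {
    if (nrow(p) < 2L)
      msg <- c(msg, "a trajectory needs at least 2 points")
    else if (any(rowSums((p[-1, , drop = FALSE] -
                          p[-nrow(p), , drop = FALSE])^2) == 0))
      msg <- c(msg, "consecutive trajectory points must differ")
    if (any(!is.finite(p)))
      msg <- c(msg, "trajectory coordinates must be finite")
  }
  if (length(object@searchRadius) != 1L || !is.finite(object@searchRadius) ||
      object@searchRadius <= 0)
    msg <- c(msg, "searchRadius must be a single positive number (mm)")
  if (length(msg)) msg else TRUE
})

#' Construct an ArteryTrajectory
#'
#' @param name Artery label.
#' @param points Numeric n x 3 matrix (or coercible) of ordered mm coordinates.
#' @param searchRadius Search radius in mm; default 8.
#' @return An [ArteryTrajectory-class] object.
#' @examples
#' ArteryTrajectory("LAD", rbind(c(0, 0, 0), c(0, 0, 30)))
#' @export
ArteryTrajectory <- function(name, points, searchRadius = 8) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  new("ArteryTrajectory", name = as.character(name), points = points,
      searchRadius = as.numeric(searchRadius))
}

#' PhantomSpec: calibration-phantom insert description
#'
#' Describes the calibration phantom scanned with the participant: a set of
#' inserts of known calcium-hydroxyapatite density. The reference design has
#' four inserts at 0, 50, 100 and 200 mg/mL placed beneath the thorax. Each
#' insert region is either an explicit set of voxel indices (1-based integer
#' n x 3 matrix) or an axis-aligned cylinder given in physical mm as
#' `list(center = c(x, y, z), radius = r, halfLength = h, axis = 1|2|3)`.
#'
#' @slot densities Numeric vector of known densities (mg/mL CaHA), distinct
#'   and non-negative; at least 2 required for calibration.
#' @slot regions List, one region per density (voxel-index matrix or
#'   cylinder description).
#'
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(densities = "numeric", regions = "list")
)

setValidity("PhantomSpec", function(object) {
  msg <- character(0)
  d <- object@densities
  if (length(d) < 2L)
    msg <- c(msg, "at least 2 phantom inserts are required for calibration")
  if (anyDuplicated(d))
    msg <- c(msg, "insert densities must be distinct")
  if (any(!is.finite(d)) || any(d < 0))
    msg <- c(msg, "insert densities must be finite and non-negative (mg/mL)")
  if (length(object@regions) != length(d))
    msg <- c(msg, "need exactly one region per insert density")
  ok <- vapply(object@regions, function(r) {
    (is.matrix(r) && ncol(r) == 3L && nrow(r) >= 1L) ||
      (is.list(r) && all(c("center", "radius", "halfLength", "axis")
                         %in% names(r)))
  }, logical(1))
  if (!all(ok))
    msg <- c(msg, paste("each region must be an n x 3 voxel-index matrix or",
                        "a cylinder list(center, radius, halfLength, axis)"))
  if (length(msg)) msg else TRUE
})

#' Construct a PhantomSpec
#'
#' @param densities Known insert densities (mg/mL calcium hydroxyapatite).
#' @param regions List of insert regions, one per density (see
#'   [PhantomSpec-class]).
#' @return A [PhantomSpec-class] object.
#' @export
PhantomSpec <- function(densities, regions) {
  new("PhantomSpec", densities = as.numeric(densities), regions = regions)
}

#' CalibrationModel: phantom-derived attenuation model
#'
#' Linear fits of insert mean attenuation and attenuation SD against known
#' calcium density, plus the criterion operating point (mu_c, sigma_c) at
#' which the SWCS voxel-weighting function is evaluated:
#' `w(HU) = pnorm((HU - mu_c) / sigma_c)`.
#'
#' @slot meanFit Named numeric (intercept, slope): mean HU vs density (OLS).
#' @slot sdFit Named numeric (intercept, slope): SD of HU vs density (OLS).
#' @slot criterionDensity Criterion calcium density c (mg/mL).
#' @slot sigmaFloor Lower clamp for sigma_c (HU), > 0.
#' @slot muC Fitted mean attenuation at the criterion density (HU).
#' @slot sigmaC Fitted (clamped) attenuation SD at the criterion density (HU).
#' @slot phantomStats The per-insert statistics the fits were computed from
#'   (data.frame: density, meanHU, sdHU, nVoxels).
#'
#' @exportClass CalibrationModel
setClass("CalibrationModel",
  representation(
    meanFit = "numeric",
    sdFit = "numeric",
    criterionDensity = "numeric",
    sigmaFloor = "numeric",
    muC = "numeric",
    sigmaC = "numeric",
    phantomStats = "data.frame"
  )
)

setValidity("CalibrationModel", function(object) {
  msg <- character(0)
  if (length(object@meanFit) != 2L || length(object@sdFit) != 2L)
    msg <- c(msg, "meanFit and sdFit must each be (intercept, slope)")
  else if (!is.finite(object@meanFit[2]) || object@meanFit[2] <= 0)
    msg <- c(msg, "mean-attenuation slope must be > 0 (HU increases with calcium density)")
  if (length(object@sigmaFloor) != 1L || object@sigmaFloor <= 0)
    msg <- c(msg, "sigmaFloor must be a single positive value (HU)")
  if (length(object@sigmaC) != 1L || object@sigmaC < object@sigmaFloor)
    msg <- c(msg, "sigmaC must be >= sigmaFloor")
  if (length(msg)) msg else TRUE
})

#' Lesion: a detected calcified plaque candidate
#'
#' A connected component of supra-threshold voxels inside the coronary
#' search region, meeting the minimum-size criterion (at least 4 contiguous
#' voxels at 130 HU or greater under the default rule). Its Agatston
#' contribution is `volume * coefficient`, with the coefficient determined
#' by the lesion's maximum attenuation.
#'
#' @slot voxelIndices Integer n x 3 matrix of 1-based voxel indices.
#' @slot volume Lesion volume in mm^3 (n voxels times voxel volume).
#' @slot maxHU Maximum attenuation in the lesion (HU).
#' @slot coefficient Integer 1-4 from [agatstonCoefficient()].
#' @slot score `volume * coefficient`.
#'
#' @exportClass Lesion
setClass("Lesion",
  representation(
    voxelIndices = "matrix",
    volume = "numeric",
    maxHU = "numeric",
    coefficient = "integer",
    score = "numeric"
  )
)

setValidity("Lesion", function(object) {
  msg <- character(0)
  if (ncol(object@voxelIndices) != 3L)
    msg <- c(msg, "voxelIndices must be an n x 3 matrix")
  if (object@maxHU < 130)
    msg <- c(msg, "lesion maximum attenuation must be >= 130 HU")
  else if (object@coefficient != agatstonCoefficient(object@maxHU))
    msg <- c(msg, "coefficient inconsistent with maxHU")
  if (abs(object@score - object@volume * object@coefficient) >
      1e-9 * max(1, object@score))
    msg <- c(msg, "score must equal volume * coefficient")
  if (length(msg)) msg else TRUE
})

#' ScoreResult: per-scan (or per-participant) calcium scores
#'
#' Holds the Agatston score and the spatially weighted calcium score (SWCS)
#' for one scan, or their per-participant averages across replicate scans.
#' The Agatston score is 0 exactly when no lesion met the detection
#' criteria; the SWCS is strictly positive whenever the search region is
#' non-empty.
#'
#' @slot scanId,participantId Identifier strings.
#' @slot agatston Agatston score (>= 0).
#' @slot swcs Spatially weighted calcium score (> 0 for non-empty region).
#' @slot nLesions Number of accepted lesions (numeric: may be a mean when
#'   averaged over scans).
#'
#' @exportClass ScoreResult
setClass("ScoreResult",
  representation(
    scanId = "character",
    participantId = "character",
    agatston = "numeric",
    swcs = "numeric",
    nLesions = "numeric"
  )
)

setValidity("ScoreResult", function(object) {
  msg <- character(0)
  if (object@agatston < 0) msg <- c(msg, "agatston must be >= 0")
  if ((object@agatston > 0) != (object@nLesions > 0))
    msg <- c(msg, "agatston must be 0 exactly when no lesions were detected")
  if (!is.finite(object@swcs) || object@swcs < 0)
    msg <- c(msg, "swcs must be finite and non-negative")
  if (length(msg)) msg else TRUE
})

#' ReproSummary: replicate-scan reproducibility comparison
#'
#' Result of [reproducibilityTable()]: per-method percent-difference
#' summaries and intraclass correlations on a common participant subset,
#' together with the paired contrast (Agatston percent difference minus
#' SWCS percent difference) and its bootstrap confidence intervals.
#'
#' @slot subset Label of the subset filter applied.
#' @slot n Number of participants contributing to the paired statistics.
#' @slot nUndefined Participants excluded because a percent difference was
#'   undefined (both replicate scores zero for a method).
#' @slot methods data.frame with one row per method: median and mean percent
#'   difference and ICC.
#' @slot paired data.frame: median and mean of (AS% - SWCS%) with 95%
#'   bootstrap percentile confidence limits.
#'
#' @exportClass ReproSummary
setClass("ReproSummary",
  representation(
    subset = "character",
    n = "integer",
    nUndefined = "integer",
    methods = "data.frame",
    paired = "data.frame"
  )
)
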