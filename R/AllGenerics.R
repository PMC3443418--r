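#' Accessors for cacscore classes
#'
#' Accessor generics for the voxel data, geometry and score slots of the
#' package's S4 classes. Use these rather than `@` access.
#'
#' @param object A cacscore S4 object.
#' @return The slot value; see the class documentation for details.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("voxels", function(object) standardGeneric("voxels"))
#' @rdname accessors
#' @export
setGeneric("spacing", function(object) standardGeneric("spacing"))
#' @rdname accessors
#' @export
setGeneric("voxelOrigin", function(object) standardGeneric("voxelOrigin"))
#' @rdname accessors
#' @export
setGeneric("scanId", function(object) standardGeneric("scanId"))
#' @rdname accessors
#' @export
setGeneric("participantId", function(object) standardGeneric("participantId"))
#' @rdname accessors
#' @export
setGeneric("voxelVolume", function(object) standardGeneric("voxelVolume"))
#' @rdname accessors
#' @export
setGeneric("arteryName", function(object) standardGeneric("arteryName"))
#' @rdname accessors
#' @export
setGeneric("trajectoryPoints",
           function(object) standardGeneric("trajectoryPoints"))
#' @rdname accessors
#' @export
setGeneric("searchRadius", function(object) standardGeneric("searchRadius"))
#' @rdname accessors
#' @export
setGeneric("insertDensities",
           function(object) standardGeneric("insertDensities"))
#' @rdname accessors
#' @export
setGeneric("agatston", function(object) standardGeneric("agatston"))
#' @rdname accessors
#' @export
setGeneric("swcs", function(object) standardGeneric("swcs"))
#' @rdname accessors
#' @export
setGeneric("nLesions", function(object) standardGeneric("nLesions"))
#' @rdname accessors
#' @export
setGeneric("criterionDensity",
           function(object) standardGeneric("criterionDensity"))

#' @rdname accessors
#' @export
setMethod("voxels", "CTVolume", function(object) object@voxels)
#' @rdname accessors
#' @export
setMethod("spacing", "CTVolume", function(object) object@spacing)
#' @rdname accessors
#' @export
setMethod("voxelOrigin", "CTVolume", function(object) object@origin)
#' @rdname accessors
#' @export
setMethod("scanId", "CTVolume", function(object) object@scanId)
#' @rdname accessors
#' @export
setMethod("participantId", "CTVolume", function(object) object@participantId)
#' @rdname accessors
#' @export
setMethod("voxelVolume", "CTVolume", function(object) prod(object@spacing))

#' @rdname accessors
#' @export
setMethod("arteryName", "ArteryTrajectory", function(object) object@name)
#' @rdname accessors
#' @export
setMethod("trajectoryPoints", "ArteryTrajectory",
          function(object) object@points)
#' @rdname accessors
#' @export
setMethod("searchRadius", "ArteryTrajectory",
          function(object) object@searchRadius)

#' @rdname accessors
#' @export
setMethod("insertDensities", "PhantomSpec", function(object) object@densities)

#' @rdname accessors
#' @export
setMethod("scanId", "ScoreResult", function(object) object@scanId)
#' @rdname accessors
#' @export
setMethod("participantId", "ScoreResult",
          function(object) object@participantId)
#' @rdname accessors
#' @export
setMethod("agatston", "ScoreResult", function(object) object@agatston)
#' @rdname accessors
#' @export
setMethod("swcs", "ScoreResult", function(object) object@swcs)
#' @rdname accessors
#' @export
setMethod("nLesions", "ScoreResult", function(object) object@nLesions)

#' @rdname accessors
#' @export
setMethod("criterionDensity", "CalibrationModel",
          function(object) object@criterionDensity)

setMethod("show", "CTVolume", function(object) {
  d <- dim(object@voxels)
  cat(sprintf(
    "CTVolume '%s' (participant '%s')\n  %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm (%.4g mm^3/voxel)\n  HU range [%.1f, %.1f]\n",
    object@scanId, object@participantId, d[1], d[2], d[3],
    object@spacing[1], object@spacing[2], object@spacing[3],
    prod(object@spacing), min(object@voxels), max(object@voxels)))
})

setMethod("show", "ArteryTrajectory", function(object) {
  cat(sprintf("ArteryTrajectory '%s': %d points, search radius %.3g mm\n",
              object@name, nrow(object@points), object@searchRadius))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: %d inserts at %s mg/mL\n",
              length(object@densities),
              paste(object@densities, collapse = "/")))
})

setMethod("show", "CalibrationModel", function(object) {
  cat(sprintf(
    paste0("CalibrationModel\n",
           "  mean HU = %.4g + %.4g * density;  sd HU = %.4g + %.4g * density\n",
           "  criterion density %.4g mg/mL -> mu_c = %.4g HU, sigma_c = %.4g HU\n"),
    object@meanFit[1], object@meanFit[2], object@sdFit[1], object@sdFit[2],
    object@criterionDensity, object@muC, object@sigmaC))
})

setMethod("show", "Lesion", function(object) {
  cat(sprintf(
    "Lesion: %d voxels, %.4g mm^3, max %.1f HU, coefficient %d, score %.4g\n",
    nrow(object@voxelIndices), object@volume, object@maxHU,
    object@coefficient, object@score))
})

setMethod("show", "ScoreResult", function(object) {
  cat(sprintf(
    "ScoreResult scan '%s' participant '%s': Agatston %.4g (%g lesions), SWCS %.6g\n",
    object@scanId, object@participantId, object@agatston, object@nLesions,
    object@swcs))
})

setMethod("show", "ReproSummary", function(object) {
  cat(sprintf("ReproSummary (subset: %s, n = %d, %d undefined excluded)\n",
              object@subset, object@n, object@nUndefined))
  print(object@methods, row.names = FALSE)
  cat("Paired AS% - SWCS%:\n")
  print(object@paired, row.names = FALSE)
})
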