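#' Agatston attenuation coefficient
#'
#' Maps a lesion's maximum attenuation to the Agatston coefficient:
#' 1 for 130-199 HU, 2 for 200-299, 3 for 300-399, 4 for 400 HU and above.
#'
#' @param maxHU Maximum attenuation (HU) of a lesion; must be >= 130.
#'   Vectorized.
#' @return Integer coefficient(s) in 1..4.
#' @examples
#' agatstonCoefficient(c(150, 199, 200, 350, 450))
#' @export
agatstonCoefficient <- function(maxHU) {
  if (any(maxHU < 130))
    stop("agatstonCoefficient is defined only for maxHU >= 130")
  as.integer(pmin(findInterval(maxHU, c(130, 200, 300, 400)), 4L))
}

#' Detect calcified lesions
#'
#' Finds connected components of supra-threshold voxels inside the coronary
#' search region and keeps those meeting the minimum-size criterion. Under
#' the standard rule a lesion is at least 4 contiguous voxels at 130 HU or
#' greater. Contiguity uses 26-connectivity (full 3x3x3 shell) by default;
#' 6-connectivity (faces only) is available. Candidate voxels flagged in
#' `excludeMask` are removed before labelling (replacing interactive
#' analyst review of candidate plaques).
#'
#' @param volume A [CTVolume-class].
#' @param roi Integer n x 3 matrix of search-region voxel indices, from
#'   [regionOfInterest()].
#' @param threshold Attenuation threshold (HU); default 130.
#' @param minVoxels Minimum lesion size in voxels; default 4.
#' @param connectivity 26 (default) or 6.
#' @param excludeMask Optional logical array (volume-shaped) of voxels to
#'   exclude.
#' @return List of [Lesion-class], sorted by first (smallest linear) voxel
#'   index; empty list when nothing qualifies.
#' @export
findLesions <- function(volume, roi, threshold = 130, minVoxels = 4,
                        connectivity = 26, excludeMask = NULL) {
  stopifnot(is(volume, "CTVolume"))
  dims <- dim(volume@voxels)
  if (nrow(roi) > 0 &&
      (any(roi < 1L) || any(roi[, 1] > dims[1]) ||
       any(roi[, 2] > dims[2]) || any(roi[, 3] > dims[3])))
    stop("roi indices fall outside the volume")
  mask <- .roiMask(dims, roi) & (volume@voxels >= threshold)
  if (!is.null(excludeMask)) mask <- mask & !excludeMask
  comps <- .connectedComponents(mask, connectivity)
  comps <- comps[vapply(comps, nrow, integer(1)) >= minVoxels]
  vv <- prod(volume@spacing)
  lapply(comps, function(idx) {
    mx <- max(volume@voxels[idx])
    co <- agatstonCoefficient(mx)
    vol <- nrow(idx) * vv
    new("Lesion", voxelIndices = idx, volume = vol, maxHU = mx,
        coefficient = co, score = vol * co)
  })
}

#' Agatston score of a lesion set
#'
#' Sum over accepted lesions of lesion volume (mm^3) times the
#' attenuation coefficient; 0 for an empty lesion list. Note this scores
#' lesion volume, not the classic per-slice area.
#'
#' @param lesions List of [Lesion-class] from [findLesions()].
#' @return Numeric score (>= 0).
#' @examples
#' agatstonScore(list())  # 0
#' @export
agatstonScore <- function(lesions) {
  if (length(lesions) == 0) return(0)
  sum(vapply(lesions, function(l) l@score, numeric(1)))
}

#' SWCS per-voxel weight field
#'
#' Step 1 of the spatially weighted calcium score: every voxel in the
#' search region receives the phantom-calibrated weight
#' [voxelWeight()]; voxels outside the region are exactly 0.
#'
#' @param volume A [CTVolume-class].
#' @param roi Integer n x 3 matrix of search-region voxel indices.
#' @param model A [CalibrationModel-class].
#' @return 3D array of weights aligned to the volume.
#' @export
weightField <- function(volume, roi, model) {
  w <- array(0, dim(volume@voxels))
  if (nrow(roi) > 0)
    w[roi] <- voxelWeight(volume@voxels[roi], model)
  w
}

#' SWCS neighbour-adjusted score field
#'
#' Step 2: each voxel's score is its own weight multiplied by the mean
#' weight over its neighbourhood (including itself; truncated at volume
#' borders), up-weighting voxels whose neighbours also show high
#' attenuation and suppressing isolated noise.
#'
#' @inheritParams weightField
#' @param neighborhood 26 (3x3x3 box, default) or 6 (centre + faces).
#' @return 3D array of adjusted scores `s = w * mean(w over neighbourhood)`.
#' @export
adjustedScoreField <- function(volume, roi, model, neighborhood = 26) {
  w <- weightField(volume, roi, model)
  w * .neighborhoodMean(w, neighborhood)
}

#' Spatially weighted calcium score (SWCS)
#'
#' The threshold-free calcium score: the sum over the search region of the
#' neighbour-adjusted voxel scores times the voxel volume, scaled by
#' `kappa`:
#' `SWCS = kappa * sum_v s[v] * voxelVolume`, with
#' `s[v] = w[v] * mean(w over the neighbourhood of v)`.
#' Strictly positive for any non-empty region and strictly increasing when
#' any region voxel's attenuation increases.
#'
#' @inheritParams adjustedScoreField
#' @param kappa Global scale constant; default 1 (see [calibrateKappa()]).
#' @return Numeric score > 0.
#' @export
swcsScore <- function(volume, roi, model, neighborhood = 26, kappa = 1) {
  if (nrow(roi) == 0)
    stop("empty search region: SWCS is undefined (this is not a zero score)")
  s <- adjustedScoreField(volume, roi, model, neighborhood)
  kappa * sum(s[roi]) * prod(volume@spacing)
}

#' Score one scan end to end
#'
#' Composes the pipeline: phantom statistics -> calibration fit -> search
#' region -> lesion detection / Agatston score and SWCS, returning one
#' [ScoreResult-class]. Component failures are re-raised with the pipeline
#' stage named.
#'
#' @param volume A [CTVolume-class].
#' @param trajectories List of [ArteryTrajectory-class].
#' @param phantom A [PhantomSpec-class].
#' @param connectivity Lesion contiguity: 26 (default) or 6.
#' @param neighborhood SWCS neighbourhood: 26 (default) or 6.
#' @param criterionDensity `"auto"` or mg/mL (see [fitCalibration()]).
#' @param kappa SWCS scale constant; default 1.
#' @param sigmaFloor Sigma clamp in HU; default 1.
#' @param roiMode `"3d"` or `"2d"` (see [regionOfInterest()]).
#' @param recalibrate If `TRUE`, apply [recalibrateHU()] before the
#'   threshold test and weighting; default `FALSE`.
#' @param reference Reference line for `recalibrate = TRUE`.
#' @param excludeMask Optional logical exclusion array for candidate review.
#' @return A [ScoreResult-class].
#' @examples
#' cfg <- syntheticCohortConfig(nParticipants = 1, seed = 7)
#' scan <- generateScan(cfg, participantIndex = 1, scanIndex = 1)
#' scoreScan(scan$volume, scan$trajectories, scan$phantom)
#' @export
scoreScan <- function(volume, trajectories, phantom,
                      connectivity = 26, neighborhood = 26,
                      criterionDensity = "auto", kappa = 1, sigmaFloor = 1,
                      roiMode = "3d", recalibrate = FALSE,
                      reference = c(intercept = 30, slope = 1),
                      excludeMask = NULL) {
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop("scoreScan [", what, "]: ", conditionMessage(e), call. = FALSE))
  }
  pstats <- stage("phantom", extractPhantomStats(volume, phantom))
  model <- stage("calibration",
                 fitCalibration(pstats, criterionDensity = criterionDensity,
                                sigmaFloor = sigmaFloor))
  if (recalibrate) {
    volume <- stage("recalibration",
                    recalibrateHU(volume, model, reference))
    pstats <- stage("phantom", extractPhantomStats(volume, phantom))
    model <- stage("calibration",
                   fitCalibration(pstats, criterionDensity = criterionDensity,
                                  sigmaFloor = sigmaFloor))
  }
  roi <- stage("roi", regionOfInterest(volume, trajectories, mode = roiMode))
  if (nrow(roi) == 0)
    stop("scoreScan [roi]: trajectories give no coverage of the volume",
         call. = FALSE)
  lesions <- stage("lesions",
                   findLesions(volume, roi, connectivity = connectivity,
                               excludeMask = excludeMask))
  as <- agatstonScore(lesions)
  sw <- stage("swcs",
              swcsScore(volume, roi, model, neighborhood = neighborhood,
                        kappa = kappa))
  new("ScoreResult", scanId = volume@scanId,
      participantId = volume@participantId,
      agatston = as, swcs = sw, nLesions = as.numeric(length(lesions)))
}

#' Per-participant score across replicate scans
#'
#' Averages the Agatston score and the SWCS arithmetically over a
#' participant's available scans (one or two), following the convention of
#' using the average of the two replicate scores per participant.
#'
#' @param results List of [ScoreResult-class] for one participant.
#' @return A [ScoreResult-class] with `scanId = "mean"`.
#' @export
participantScore <- function(results) {
  if (length(results) < 1)
    stop("no scores supplied")
  pid <- unique(vapply(results, participantId, character(1)))
  if (length(pid) != 1)
    stop("scores belong to different participants: ",
         paste(pid, collapse = ", "))
  new("ScoreResult", scanId = "mean", participantId = pid,
      agatston = mean(vapply(results, agatston, numeric(1))),
      swcs = mean(vapply(results, swcs, numeric(1))),
      nLesions = mean(vapply(results, nLesions, numeric(1))))
}

#' Log transform of a calcium score
#'
#' `log_base(score + 1)`, the transform used for score comparisons and
#' regression modelling (base 2 for doubling interpretation, base e
#' otherwise).
#'
#' @param score Numeric score(s), >= 0.
#' @param base 2 (default) or `exp(1)`.
#' @return Transformed score(s).
#' @examples
#' logTransform(7)          # 3
#' logTransform(7, exp(1))  # log(8)
#' @export
logTransform <- function(score, base = 2) {
  if (any(score < 0))
    stop("scores must be non-negative")
  log(score + 1, base = base)
}

#' Fit the SWCS global scale constant
#'
#' Regresses Agatston scores on SWCS (through the origin, log-free) over a
#' supra-threshold cohort to obtain a scale `kappa` making the two scores
#' numerically comparable where both are defined. Purely a convenience:
#' `kappa` rescales the SWCS without changing any ordering.
#'
#' @param agatstonScores,swcsScores Numeric vectors of per-scan scores with
#'   `agatstonScores > 0` rows used.
#' @return Fitted scale (numeric).
#' @export
calibrateKappa <- function(agatstonScores, swcsScores) {
  keep <- agatstonScores > 0 & swcsScores > 0
  if (sum(keep) < 3)
    stop("need at least 3 supra-threshold score pairs")
  unname(stats::coef(stats::lm(agatstonScores[keep] ~ 0 + swcsScores[keep])))
}
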