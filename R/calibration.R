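#' Per-insert attenuation statistics from the calibration phantom
#'
#' Computes the sample mean and sample standard deviation (n - 1
#' denominator) of attenuation over each phantom insert's voxels. These
#' statistics parameterize the SWCS voxel-weighting function via
#' [fitCalibration()].
#'
#' @param volume A [CTVolume-class].
#' @param phantom A [PhantomSpec-class]; each resolved region must lie
#'   inside the volume and contain at least 8 voxels.
#' @return data.frame with columns `density` (mg/mL), `meanHU`, `sdHU`,
#'   `nVoxels`, one row per insert, ordered by density.
#' @export
extractPhantomStats <- function(volume, phantom) {
  stopifnot(is(volume, "CTVolume"), is(phantom, "PhantomSpec"))
  dims <- dim(volume@voxels)
  rows <- lapply(seq_along(phantom@densities), function(i) {
    idx <- .resolveRegion(volume, phantom@regions[[i]])
    if (nrow(idx) < 8)
      stop("phantom insert at ", phantom@densities[i],
           " mg/mL has fewer than 8 voxels (", nrow(idx), ")")
    if (any(idx < 1L) || any(idx[, 1] > dims[1]) || any(idx[, 2] > dims[2]) ||
        any(idx[, 3] > dims[3]))
      stop("phantom insert at ", phantom@densities[i],
           " mg/mL extends outside the volume")
    v <- volume@voxels[idx]
    data.frame(density = phantom@densities[i], meanHU = mean(v),
               sdHU = stats::sd(v), nVoxels = nrow(idx))
  })
  df <- do.call(rbind, rows)
  df[order(df$density), , drop = FALSE]
}

#' Fit the phantom calibration model
#'
#' Fits two ordinary-least-squares lines through the per-insert statistics:
#' mean attenuation vs known density and attenuation SD vs known density.
#' The weighting function's operating point is the fitted mean `mu_c` and
#' fitted SD `sigma_c` evaluated at the criterion density `c`, with
#' `sigma_c` clamped below at `sigmaFloor` (a fitted SD can be non-positive
#' on noise-free data).
#'
#' The default criterion density (`criterionDensity = "auto"`) is the
#' density whose fitted mean attenuation equals 130 HU, i.e.
#' `c = (130 - intercept) / slope`, clipped to the phantom's density range.
#' This anchors the threshold-free score to the conventional 130 HU
#' operating point so supra-threshold scores are comparable to the Agatston
#' score.
#'
#' @param stats data.frame from [extractPhantomStats()] (columns density,
#'   meanHU, sdHU, nVoxels), at least 2 distinct densities.
#' @param criterionDensity `"auto"` (default) or a density in mg/mL within
#'   `[0, max(density)]`.
#' @param sigmaFloor Lower clamp for sigma_c, in HU; default 1.
#' @param anchorHU Attenuation anchor used by `"auto"`; default 130.
#' @return A [CalibrationModel-class].
#' @examples
#' st <- data.frame(density = c(0, 50, 100, 200),
#'                  meanHU = 10 + 1.1 * c(0, 50, 100, 200),
#'                  sdHU = 15, nVoxels = 100)
#' fitCalibration(st)
#' @export
fitCalibration <- function(stats, criterionDensity = "auto", sigmaFloor = 1,
                           anchorHU = 130) {
  need <- c("density", "meanHU", "sdHU")
  if (!all(need %in% names(stats)))
    stop("stats must have columns density, meanHU, sdHU")
  d <- stats$density
  if (length(unique(d)) < 2)
    stop("calibration needs at least 2 distinct phantom densities")
  mfit <- stats::lm(meanHU ~ density, data = stats)
  sfit <- stats::lm(sdHU ~ density, data = stats)
  meanFit <- c(intercept = unname(stats::coef(mfit)[1]),
               slope = unname(stats::coef(mfit)[2]))
  sdFit <- c(intercept = unname(stats::coef(sfit)[1]),
             slope = unname(stats::coef(sfit)[2]))
  if (!is.finite(meanFit[2]) || meanFit[2] <= 0)
    stop("fitted mean-attenuation slope is not positive; ",
         "check phantom insert statistics")
  if (identical(criterionDensity, "auto")) {
    cdens <- (anchorHU - meanFit[1]) / meanFit[2]
    cdens <- min(max(cdens, 0), max(d))
  } else {
    cdens <- as.numeric(criterionDensity)
    if (cdens < 0 || cdens > max(d))
      stop("criterionDensity must lie in [0, ", max(d), "] mg/mL")
  }
  muC <- unname(meanFit[1] + meanFit[2] * cdens)
  sigmaRaw <- unname(sdFit[1] + sdFit[2] * cdens)
  sigmaC <- max(sigmaRaw, sigmaFloor)
  if (sigmaRaw < sigmaFloor)
    warning(sprintf("fitted sigma at criterion density (%.3g HU) below floor; clamped to %.3g HU",
                    sigmaRaw, sigmaFloor))
  new("CalibrationModel", meanFit = meanFit, sdFit = sdFit,
      criterionDensity = unname(cdens), sigmaFloor = sigmaFloor,
      muC = muC, sigmaC = sigmaC,
      phantomStats = as.data.frame(stats))
}

#' SWCS voxel weight
#'
#' The probability-scale weight assigned to a voxel with attenuation `hu`:
#' `w = pnorm((hu - mu_c) / sigma_c)`, the probability that a voxel drawn
#' from the phantom-implied attenuation distribution at the criterion
#' calcium density would show at most the observed attenuation. Strictly
#' increasing in HU; 0.5 exactly at `mu_c`. To preserve strict positivity
#' for physically extreme attenuation (air at -1000 HU underflows the
#' normal CDF), weights are floored at `1e-12`.
#'
#' @param hu Attenuation value(s) in HU (vectorized).
#' @param model A [CalibrationModel-class].
#' @return Weight(s) in `[1e-12, 1]`.
#' @examples
#' m <- fitCalibration(data.frame(density = c(0, 50, 100, 200),
#'                                meanHU = 30 + c(0, 50, 100, 200),
#'                                sdHU = 10, nVoxels = 100))
#' voxelWeight(m@muC, m)  # 0.5
#' @export
voxelWeight <- function(hu, model) {
  stopifnot(is(model, "CalibrationModel"))
  pmax(stats::pnorm((hu - model@muC) / model@sigmaC), 1e-12)
}

#' Serialize a calibration model to/from JSON
#'
#' @param model A [CalibrationModel-class].
#' @param path Output `.json` path.
#' @return `path` invisibly (write); a [CalibrationModel-class] (read).
#' @export
writeCalibration <- function(model, path) {
  out <- list(
    mean_fit = as.list(model@meanFit),
    sd_fit = as.list(model@sdFit),
    criterion_density = model@criterionDensity,
    sigma_floor = model@sigmaFloor,
    mu_c = model@muC,
    sigma_c = model@sigmaC,
    phantom_stats = model@phantomStats)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeCalibration
#' @export
readCalibration <- function(path) {
  raw <- jsonlite::fromJSON(path)
  new("CalibrationModel",
      meanFit = c(intercept = raw$mean_fit$intercept,
                  slope = raw$mean_fit$slope),
      sdFit = c(intercept = raw$sd_fit$intercept, slope = raw$sd_fit$slope),
      criterionDensity = raw$criterion_density,
      sigmaFloor = raw$sigma_floor, muC = raw$mu_c, sigmaC = raw$sigma_c,
      phantomStats = as.data.frame(raw$phantom_stats))
}

#' Recalibrate attenuation values to a reference density line
#'
#' Optional affine recalibration mapping the scan's fitted phantom line
#' onto a reference density-to-HU line, so a fixed 130 HU threshold means
#' the same calcium density on every scanner. Off by default in
#' [scoreScan()].
#'
#' @param volume A [CTVolume-class].
#' @param model A [CalibrationModel-class] fitted on this scan's phantom.
#' @param reference Named numeric `c(intercept, slope)` of the reference
#'   line (HU at density 0 and HU per mg/mL).
#' @return A [CTVolume-class] with adjusted attenuation.
#' @export
recalibrateHU <- function(volume, model,
                          reference = c(intercept = 30, slope = 1)) {
  stopifnot(is(volume, "CTVolume"), is(model, "CalibrationModel"))
  # implied density of each voxel under the scan's line, re-expressed on
  # the reference line
  dens <- (volume@voxels - model@meanFit[1]) / model@meanFit[2]
  adj <- reference[["intercept"]] + reference[["slope"]] * dens
  initialize(volume, voxels = adj)
}
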