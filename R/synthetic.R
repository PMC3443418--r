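#' Configuration for the synthetic cardiac-CT cohort generator
#'
#' Defines a cohort of simulated participants, each receiving one or two
#' consecutive non-contrast chest CT scans with a calibration phantom of
#' known calcium-hydroxyapatite densities beneath the thorax. Defaults
#' emulate the reference acquisition: 3 mm slices with sub-millimetre
#' in-plane spacing, phantom inserts at 0/50/100/200 mg/mL, and a cohort in
#' which roughly half of participants carry only sub-threshold
#' calcification (Agatston score 0) while the rest carry supra-threshold
#' plaques of graded severity.
#'
#' Disease severity is modelled by a participant-level latent `u ~ U(0,1)`
#' that jointly grades plaque count, radius and calcium density (extent and
#' density of calcification co-vary, as in real atherosclerotic burden),
#' with independent per-plaque jitter. Replicate scans share the
#' participant's plaque ground truth but receive independent scanner noise
#' and a small rigid trajectory/plaque repositioning jitter.
#'
#' @param nParticipants Number of participants.
#' @param shape Volume dimensions (voxels), default `c(48, 48, 20)`.
#' @param spacing Voxel spacing mm, default `c(0.68, 0.68, 3)`.
#' @param phantomDensities Insert densities mg/mL, default 0/50/100/200.
#' @param densityToHU Simulated scanner line `c(intercept, slope)`: mean HU
#'   at density 0 and HU per mg/mL. The default (30, 1) puts 130 HU at
#'   100 mg/mL, inside the phantom range.
#' @param noiseSD Additive Gaussian scanner noise SD in HU; default 10.
#' @param backgroundHU Soft-tissue background attenuation; default 30.
#' @param fractionZeroAS Target fraction of participants whose plaques are
#'   all sub-threshold; default 0.5.
#' @param nScansPerParticipant 1 or 2 (default 2).
#' @param jitterSD SD (mm) of the rigid per-scan repositioning jitter and
#'   of per-plaque placement jitter between replicate scans; default 0.3.
#' @param supraRadiusRange,supraDensityRange Plaque radius (mm) and density
#'   (mg/mL) spans graded by severity for supra-threshold participants.
#' @param subRadiusRange,subDensityRange The same for sub-threshold
#'   participants; the density span stays safely below the attenuation
#'   threshold so these participants score Agatston 0.
#' @param plaqueLambda Poisson rate scale for extra plaques (count is
#'   `1 + rpois(plaqueLambda * u)`).
#' @param seed Integer master seed; every drawn quantity derives from it.
#' @return A list of class `SyntheticCohortConfig`.
#' @seealso [generateScan()], [generateCohort()]
#' @export
syntheticCohortConfig <- function(nParticipants = 200,
                                  shape = c(48, 48, 20),
                                  spacing = c(0.68, 0.68, 3),
                                  phantomDensities = c(0, 50, 100, 200),
                                  densityToHU = c(intercept = 30, slope = 1),
                                  noiseSD = 10,
                                  backgroundHU = 30,
                                  fractionZeroAS = 0.5,
                                  nScansPerParticipant = 2,
                                  jitterSD = 0.3,
                                  supraRadiusRange = c(1.6, 3.4),
                                  supraDensityRange = c(120, 380),
                                  subRadiusRange = c(1.0, 3.0),
                                  subDensityRange = c(35, 75),
                                  plaqueLambda = 1.2,
                                  seed = 1) {
  stopifnot(nParticipants >= 1, length(shape) == 3, all(shape >= 16),
            length(spacing) == 3, all(spacing > 0), noiseSD >= 0,
            fractionZeroAS >= 0, fractionZeroAS <= 1,
            nScansPerParticipant %in% 1:2, jitterSD >= 0,
            length(phantomDensities) >= 2)
  cfg <- list(nParticipants = as.integer(nParticipants), shape = as.integer(shape),
              spacing = as.numeric(spacing),
              phantomDensities = as.numeric(phantomDensities),
              densityToHU = c(intercept = unname(densityToHU[1]),
                              slope = unname(densityToHU[2])),
              noiseSD = noiseSD, backgroundHU = backgroundHU,
              fractionZeroAS = fractionZeroAS,
              nScansPerParticipant = as.integer(nScansPerParticipant),
              jitterSD = jitterSD,
              supraRadiusRange = supraRadiusRange,
              supraDensityRange = supraDensityRange,
              subRadiusRange = subRadiusRange,
              subDensityRange = subDensityRange,
              plaqueLambda = plaqueLambda, seed = as.integer(seed))
  class(cfg) <- c("SyntheticCohortConfig", "list")
  cfg
}

#' @export
print.SyntheticCohortConfig <- function(x, ...) {
  cat(sprintf(
    "SyntheticCohortConfig: %d participants x %d scan(s), %dx%dx%d voxels\n  noise %.3g HU, target zero-AS fraction %.2f, seed %d\n",
    x$nParticipants, x$nScansPerParticipant, x$shape[1], x$shape[2],
    x$shape[3], x$noiseSD, x$fractionZeroAS, x$seed))
  invisible(x)
}

# phantom geometry: a row of z-aligned cylinders near the posterior (high-y)
# edge, clear of the artery region
.phantomGeometry <- function(cfg) {
  ext <- (cfg$shape - 1) * cfg$spacing
  y <- ext[2] - 3.5
  zmid <- ext[3] / 2
  xs <- seq(4, ext[1] - 4, length.out = length(cfg$phantomDensities))
  regions <- lapply(xs, function(x)
    list(center = c(x, y, zmid), radius = 2.2,
         halfLength = ext[3] / 2 - 4, axis = 3L))
  PhantomSpec(cfg$phantomDensities, regions)
}

# participant ground truth: severity latent, plaques, unjittered trajectory
.participantTruth <- function(cfg, pIndex) {
  withr::with_seed(.subSeed(cfg$seed, 101, pIndex), {
    ext <- (cfg$shape - 1) * cfg$spacing
    supra <- stats::runif(1) >= cfg$fractionZeroAS
    u <- stats::runif(1)
    rr <- if (supra) cfg$supraRadiusRange else cfg$subRadiusRange
    dr <- if (supra) cfg$supraDensityRange else cfg$subDensityRange
    nPlaques <- 1L + stats::rpois(1, cfg$plaqueLambda * u)
    nPlaques <- min(nPlaques, 5L)
    # trajectory: gentle xy wander along z through the anterior half
    nPts <- 5L
    tz <- seq(6, ext[3] - 6, length.out = nPts)
    tx <- pmin(pmax(ext[1] / 2 + cumsum(stats::runif(nPts, -2.5, 2.5)),
                    8), ext[1] - 8)
    ty <- pmin(pmax(ext[2] * 0.35 + cumsum(stats::runif(nPts, -2, 2)),
                    6), ext[2] * 0.55)
    traj <- cbind(tx, ty, tz)
    plaques <- do.call(rbind, lapply(seq_len(nPlaques), function(q) {
      radius <- stats::runif(1, -0.2, 0.2) +
        rr[1] + u * (rr[2] - rr[1])
      radius <- min(max(radius, rr[1] * 0.8), rr[2] * 1.05)
      density <- stats::runif(1, -1, 1) * diff(dr) * 0.12 +
        dr[1] + u * (dr[2] - dr[1])
      density <- min(max(density, dr[1] * 0.95), dr[2] * 1.05)
      # place near a random point along the polyline, within 4 mm of it
      for (try in 1:20) {
        t <- stats::runif(1, 0, 1) * (nPts - 1)
        s <- min(floor(t) + 1, nPts - 1)
        frac <- t - (s - 1)
        base <- traj[s, ] + frac * (traj[s + 1, ] - traj[s, ])
        dirv <- stats::rnorm(3)
        dirv <- dirv / sqrt(sum(dirv^2))
        ctr <- base + dirv * stats::runif(1, 0, 4)
        if (all(ctr - radius >= 1) && all(ctr + radius <= ext - 1) &&
            ctr[2] + radius <= ext[2] * 0.62) break
        if (try == 20) stop("plaque placement failed after 20 retries")
      }
      data.frame(cx = ctr[1], cy = ctr[2], cz = ctr[3],
                 radius = radius, density = density)
    }))
    list(participantId = sprintf("p%04d", pIndex), supra = supra,
         severity = u, trajectory = traj, plaques = plaques,
         trueVolume = sum(4 / 3 * pi * plaques$radius^3))
  })
}

# render one scan: jittered geometry + phantom + noise
.renderScan <- function(cfg, truth, pIndex, scanIndex) {
  withr::with_seed(.subSeed(cfg$seed, 202, pIndex, scanIndex), {
    dims <- cfg$shape
    sp <- cfg$spacing
    arr <- array(cfg$backgroundHU, dims)
    d2h <- function(d) cfg$densityToHU[["intercept"]] +
      cfg$densityToHU[["slope"]] * d
    shift <- stats::rnorm(3, sd = cfg$jitterSD)
    phantom <- .phantomGeometry(cfg)
    vol0 <- CTVolume(arr, sp)   # geometry holder for index maths
    for (i in seq_along(phantom@densities)) {
      idx <- .resolveRegion(vol0, phantom@regions[[i]])
      arr[idx] <- d2h(phantom@densities[i])
    }
    ax <- lapply(1:3, function(d) (seq_len(dims[d]) - 1) * sp[d])
    for (q in seq_len(nrow(truth$plaques))) {
      p <- truth$plaques[q, ]
      ctr <- c(p$cx, p$cy, p$cz) + shift + stats::rnorm(3, sd = cfg$jitterSD)
      sub <- lapply(1:3, function(d)
        which(ax[[d]] >= ctr[d] - p$radius & ax[[d]] <= ctr[d] + p$radius))
      if (any(lengths(sub) == 0)) next
      g <- as.matrix(expand.grid(i = sub[[1]], j = sub[[2]], k = sub[[3]]))
      cc <- cbind(ax[[1]][g[, 1]], ax[[2]][g[, 2]], ax[[3]][g[, 3]])
      inside <- rowSums(sweep(cc, 2, ctr)^2) <= p$radius^2
      if (any(inside)) {
        gi <- g[inside, , drop = FALSE]
        arr[gi] <- pmax(arr[gi], d2h(p$density))
      }
    }
    if (cfg$noiseSD > 0)
      arr <- arr + stats::rnorm(length(arr), sd = cfg$noiseSD)
    traj <- sweep(truth$trajectory, 2, -shift)
    volume <- CTVolume(arr, sp, origin = c(0, 0, 0),
                       scanId = sprintf("%s_s%d", truth$participantId,
                                        scanIndex),
                       participantId = truth$participantId)
    list(volume = volume, phantom = phantom,
         trajectories = list(ArteryTrajectory("coronary", traj)),
         groundTruth = truth)
  })
}

#' Generate one synthetic scan
#'
#' Renders one scan of one participant: soft-tissue background, cylindrical
#' phantom inserts mapped through the simulated scanner's density-to-HU
#' line, spherical plaques placed within 4 mm of a generated centerline
#' (partial volume arises from voxel-centre sampling), plus additive
#' Gaussian noise. Replicate scans (`scanIndex` 1 vs 2) share the
#' participant's ground truth but have independent noise and repositioning
#' jitter. Fully deterministic given `(config$seed, participantIndex,
#' scanIndex)`.
#'
#' @param config A [syntheticCohortConfig()].
#' @param participantIndex Integer participant number (1-based).
#' @param scanIndex Scan number (1 or 2).
#' @return List with elements `volume` ([CTVolume-class]), `phantom`
#'   ([PhantomSpec-class]), `trajectories` (list of
#'   [ArteryTrajectory-class]) and `groundTruth` (plaque table, severity,
#'   true calcified volume, supra-threshold flag).
#' @export
generateScan <- function(config, participantIndex, scanIndex = 1) {
  stopifnot(inherits(config, "SyntheticCohortConfig"),
            participantIndex >= 1, scanIndex %in% 1:2)
  truth <- .participantTruth(config, participantIndex)
  .renderScan(config, truth, participantIndex, scanIndex)
}

#' Generate a synthetic cohort
#'
#' Generates `nParticipants x nScansPerParticipant` scans with
#' per-participant RNG substreams (cohorts are reproducible and extensible:
#' participant i's ground truth does not depend on how many other
#' participants are generated). Optionally writes each scan to disk as
#' NIfTI plus trajectory/phantom JSON, together with `ground_truth.csv` and
#' the resolved configuration.
#'
#' @param config A [syntheticCohortConfig()].
#' @param outDir Optional output directory; created if missing.
#' @return List with `scans` (list of [generateScan()] results, ordered by
#'   participant then scan) and `groundTruth` (one row per participant:
#'   participant_id, supra, severity, n_plaques, true_volume, max_density).
#' @export
generateCohort <- function(config, outDir = NULL) {
  stopifnot(inherits(config, "SyntheticCohortConfig"))
  scans <- list()
  gt <- vector("list", config$nParticipants)
  for (p in seq_len(config$nParticipants)) {
    truth <- .participantTruth(config, p)
    gt[[p]] <- data.frame(
      participant_id = truth$participantId, supra = truth$supra,
      severity = truth$severity, n_plaques = nrow(truth$plaques),
      true_volume = truth$trueVolume,
      max_density = max(truth$plaques$density))
    for (s in seq_len(config$nScansPerParticipant)) {
      scans[[length(scans) + 1L]] <- .renderScan(config, truth, p, s)
    }
  }
  gtab <- do.call(rbind, gt)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    for (sc in scans) {
      id <- sc$volume@scanId
      writeVolume(sc$volume, file.path(outDir, paste0(id, ".nii.gz")))
      writeTrajectories(sc$trajectories,
                        file.path(outDir, paste0(id, "_traj.json")))
      writePhantom(sc$phantom, file.path(outDir, paste0(id, "_phantom.json")))
    }
    utils::write.csv(gtab, file.path(outDir, "ground_truth.csv"),
                     row.names = FALSE)
    jsonlite::write_json(unclass(config), file.path(outDir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(scans = scans, groundTruth = gtab)
}
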