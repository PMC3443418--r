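test_that("attenuation coefficient reproduces the printed bins", {
  expect_equal(agatstonCoefficient(c(150, 250, 350, 450)), c(1L, 2L, 3L, 4L))
  expect_equal(agatstonCoefficient(c(130, 199, 200, 299, 300, 399, 400, 2000)),
               c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L))
  expect_error(agatstonCoefficient(129), ">= 130")
})

test_that("lesion detection applies the 4-voxel / 130 HU criteria", {
  # 3-voxel cluster at 200 HU: below the minimum size -> nothing
  vol <- toyVolume(blocks = list(list(i = 2:4, j = 2, k = 2, hu = 200)))
  expect_length(findLesions(vol, fullROI(vol)), 0)
  # 5-voxel face-connected cluster, max 320 HU, unit voxels
  vol2 <- toyVolume(blocks = list(list(i = 2:6, j = 3, k = 3, hu = 310)))
  v <- voxels(vol2); v[4, 3, 3] <- 320
  vol2 <- CTVolume(v, spacing(vol2))
  les <- findLesions(vol2, fullROI(vol2))
  expect_length(les, 1)
  expect_equal(les[[1]]@volume, 5)
  expect_equal(les[[1]]@maxHU, 320)
  expect_equal(les[[1]]@coefficient, 3L)
  expect_equal(les[[1]]@score, 15)
})

test_that("a sub-threshold gap splits lesions; bridging it merges them", {
  mkvol <- function(gapHU) {
    toyVolume(dims = c(14, 8, 6), background = 50,
              blocks = list(list(i = 2:4, j = 2:3, k = 2, hu = 250),
                            list(i = 5, j = 2, k = 2, hu = gapHU),
                            list(i = 6:8, j = 2:3, k = 2, hu = 250)))
  }
  split2 <- findLesions(mkvol(100), fullROI(mkvol(100)))
  expect_length(split2, 2)
  merged <- findLesions(mkvol(180), fullROI(mkvol(180)))
  expect_length(merged, 1)
  expect_equal(nrow(merged[[1]]@voxelIndices), 13)
})

test_that("lesion labelling matches the propagation oracle on random grids", {
  withr::with_seed(99, {
    for (trial in 1:12) {
      d <- sample(6:12, 3, replace = TRUE)
      arr <- array(ifelse(runif(prod(d)) < 0.25, 300, 50), d)
      vol <- CTVolume(arr, c(1, 1, 1))
      roi <- fullROI(vol)
      for (conn in c(6, 26)) {
        les <- findLesions(vol, roi, minVoxels = 1, connectivity = conn)
        oc <- oracleComponents(arr >= 130, conn)
        expect_equal(length(les), length(oc))
        key <- function(m) paste(sort(paste(m[, 1], m[, 2], m[, 3])),
                                 collapse = ";")
        expect_setequal(vapply(les, function(l) key(l@voxelIndices),
                               character(1)),
                        vapply(oc, key, character(1)))
      }
    }
  })
})

test_that("Agatston score sums volume times coefficient over lesions", {
  expect_equal(agatstonScore(list()), 0)
  vol <- toyVolume(dims = c(16, 10, 6), background = 40,
                   blocks = list(list(i = 2:5, j = 2, k = 2, hu = 150),
                                 list(i = 8:12, j = 2:3, k = 2:3, hu = 450)))
  les <- findLesions(vol, fullROI(vol))
  # 4 voxels @150 HU -> 4*1; 20 voxels @450 HU -> 20*4
  expect_equal(agatstonScore(les), 4 * 1 + 20 * 4)
})

test_that("SWCS equals the naive double-loop reference", {
  withr::with_seed(7, {
    arr <- array(rnorm(12^3, 100, 60), c(12, 12, 12))
  })
  vol <- CTVolume(arr, c(0.7, 0.7, 2.5))
  m <- directModel(130, 15)
  # full region and a ragged sub-region, both neighbourhood modes
  roiFull <- fullROI(vol)
  roiSub <- roiFull[(roiFull[, 1] + roiFull[, 2] * 2 + roiFull[, 3]) %% 3
                    != 0, ]
  for (roi in list(roiFull, roiSub)) {
    for (nb in c(26, 6)) {
      expect_equal(swcsScore(vol, roi, m, neighborhood = nb),
                   naiveSWCS(vol, roi, m, neighborhood = nb),
                   tolerance = 1e-9)
    }
  }
})

test_that("SWCS positivity and monotonicity", {
  air <- CTVolume(array(-1000, c(8, 8, 4)), c(1, 1, 1))
  m <- directModel(130, 10)
  roi <- fullROI(air)
  expect_gt(swcsScore(air, roi, m), 0)        # all-air region stays positive
  expect_error(swcsScore(air, matrix(integer(0), ncol = 3), m), "empty")
  # raising any single voxel strictly increases the score
  vol <- toyVolume(dims = c(8, 8, 4), background = 70)
  base <- swcsScore(vol, roi, m)
  withr::with_seed(31, {
    for (r in 1:10) {
      v <- voxels(vol)
      tgt <- c(sample(8, 1), sample(8, 1), sample(4, 1))
      v[tgt[1], tgt[2], tgt[3]] <- v[tgt[1], tgt[2], tgt[3]] + runif(1, 5, 300)
      expect_gt(swcsScore(CTVolume(v, spacing(vol)), roi, m), base)
    }
  })
})

test_that("scores are invariant under axis permutation", {
  withr::with_seed(12, {
    arr <- array(rnorm(10 * 12 * 8, 80, 70), c(10, 12, 8))
  })
  sp <- c(0.7, 0.8, 2.0)
  vol <- CTVolume(arr, sp)
  tr <- list(ArteryTrajectory("a", rbind(c(3, 4, 2), c(5, 6, 12)),
                              searchRadius = 5))
  m <- directModel(130, 15)
  roi <- regionOfInterest(vol, tr)
  as0 <- agatstonScore(findLesions(vol, roi))
  sw0 <- swcsScore(vol, roi, m)
  perm <- c(3, 1, 2)
  volP <- CTVolume(aperm(arr, perm), sp[perm])
  trP <- list(ArteryTrajectory("a", trajectoryPoints(tr[[1]])[, perm],
                               searchRadius = 5))
  roiP <- regionOfInterest(volP, trP)
  expect_equal(nrow(roiP), nrow(roi))
  expect_equal(agatstonScore(findLesions(volP, roiP)), as0)
  expect_equal(swcsScore(volP, roiP, m), sw0, tolerance = 1e-12)
})

test_that("sub-threshold perturbations leave AS fixed and raise SWCS", {
  vol <- toyVolume(dims = c(12, 12, 6), background = 60,
                   blocks = list(list(i = 4:7, j = 4:7, k = 3:4, hu = 300)))
  roi <- fullROI(vol)
  m <- directModel(130, 15)
  as0 <- agatstonScore(findLesions(vol, roi))
  sw0 <- swcsScore(vol, roi, m)
  expect_gt(as0, 0)
  withr::with_seed(55, {
    for (r in 1:25) {
      v <- voxels(vol)
      repeat {
        tgt <- c(sample(12, 1), sample(12, 1), sample(6, 1))
        if (v[tgt[1], tgt[2], tgt[3]] < 129) break
      }
      v[tgt[1], tgt[2], tgt[3]] <- runif(1, v[tgt[1], tgt[2], tgt[3]], 129.9)
      volp <- CTVolume(v, spacing(vol))
      expect_equal(agatstonScore(findLesions(volp, roi)), as0)
      expect_gt(swcsScore(volp, roi, m), sw0)
    }
  })
})

test_that("scoreScan composes the pipeline and reports stage errors", {
  cfg <- syntheticCohortConfig(nParticipants = 2, seed = 41)
  sc <- generateScan(cfg, participantIndex = 2, scanIndex = 1)
  res <- scoreScan(sc$volume, sc$trajectories, sc$phantom)
  expect_s4_class(res, "ScoreResult")
  expect_gt(swcs(res), 0)
  expect_equal(participantId(res), "p0002")
  # no trajectory coverage -> staged error
  off <- list(ArteryTrajectory("far", rbind(c(500, 500, 0), c(500, 500, 50))))
  expect_error(scoreScan(sc$volume, off, sc$phantom), "roi")
})

test_that("sub-threshold plaque raises SWCS above background while AS stays 0", {
  cfg <- syntheticCohortConfig(nParticipants = 1, noiseSD = 0,
                               fractionZeroAS = 1, seed = 9)
  sc <- generateScan(cfg, 1, 1)
  roi <- regionOfInterest(sc$volume, sc$trajectories)
  # same scan with the search region wiped to pure background: the noise-free
  # difference is exactly the sub-threshold plaque signal
  flat <- voxels(sc$volume)
  flat[roi] <- cfg$backgroundHU
  st <- extractPhantomStats(sc$volume, sc$phantom)
  # noise-free inserts have sd 0: keep a realistic sigma via the floor
  m <- suppressWarnings(fitCalibration(st, sigmaFloor = 10))
  withPlaque <- swcsScore(sc$volume, roi, m)
  noPlaque <- swcsScore(CTVolume(flat, spacing(sc$volume)), roi, m)
  expect_equal(agatstonScore(findLesions(sc$volume, roi)), 0)
  expect_gt(withPlaque, noPlaque)
})

test_that("participant scores average the available scans", {
  r <- function(s, p, a, w, n) new("ScoreResult", scanId = s,
                                   participantId = p, agatston = a,
                                   swcs = w, nLesions = n)
  two <- list(r("s1", "p1", 10, 8, 1), r("s2", "p1", 20, 12, 2))
  avg <- participantScore(two)
  expect_equal(agatston(avg), 15)
  expect_equal(swcs(avg), 10)
  one <- participantScore(list(r("s1", "p9", 7, 3, 1)))
  expect_equal(agatston(one), 7)
  dup <- participantScore(list(two[[1]], two[[1]]))
  expect_equal(agatston(dup), 10)
  expect_error(participantScore(list(r("s1", "p1", 1, 1, 1),
                                     r("s1", "p2", 1, 1, 1))),
               "different participants")
})

test_that("log transform matches its closed forms", {
  expect_equal(logTransform(0), 0)
  expect_equal(logTransform(0, exp(1)), 0)
  expect_equal(logTransform(1), 1)
  expect_equal(logTransform(7), 3)
  expect_equal(logTransform(7, exp(1)), log(8))
  expect_error(logTransform(-1), "non-negative")
})

test_that("fraction_zero_as = 1 yields AS = 0 with SWCS still positive", {
  cfg <- syntheticCohortConfig(nParticipants = 6, fractionZeroAS = 1,
                               nScansPerParticipant = 1, seed = 13)
  coh <- generateCohort(cfg)
  sc <- scoreCohort(coh)
  expect_true(all(sc$table$agatston == 0))
  expect_true(all(sc$table$swcs > 0))
})
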