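test_that("CTVolume enforces its geometric invariants", {
  expect_error(CTVolume(array(0, c(4, 4)), c(1, 1, 1)), "3D")
  expect_error(CTVolume(array(0, c(4, 4, 4)), c(1, -1, 1)), "spacing")
  expect_error(CTVolume(array(c(NA, rep(0, 63)), c(4, 4, 4)), c(1, 1, 1)),
               "finite")
  vol <- CTVolume(array(0, c(20, 20, 10)), spacing = c(0.68, 0.68, 3.0))
  expect_equal(voxelVolume(vol), 1.3872)  # 0.68 * 0.68 * 3.0
})

test_that("ArteryTrajectory enforces point and radius invariants", {
  expect_error(ArteryTrajectory("a", matrix(c(0, 0, 0), nrow = 1)),
               "at least 2")
  expect_error(ArteryTrajectory("a", rbind(c(0, 0, 0), c(0, 0, 0))),
               "must differ")
  expect_error(ArteryTrajectory("a", rbind(c(0, 0, 0), c(1, 0, 0)),
                                searchRadius = 0), "positive")
  tr <- ArteryTrajectory("LAD", rbind(c(0, 0, 0), c(0, 0, 30)))
  expect_equal(searchRadius(tr), 8)
})

test_that("volume round-trips through NIfTI preserving data and geometry", {
  withr::with_seed(42, {
    arr <- array(round(rnorm(20 * 20 * 10, 50, 30), 3), c(20, 20, 10))
  })
  vol <- CTVolume(arr, spacing = c(0.68, 0.68, 3.0), origin = c(5, -3, 12),
                  scanId = "rt", participantId = "pX")
  f <- withr::local_tempfile(fileext = ".nii.gz")
  writeVolume(vol, f)
  back <- readVolume(f, scanId = "rt", participantId = "pX")
  expect_equal(voxels(back), voxels(vol), tolerance = 1e-9)
  # NIfTI-1 stores header geometry as 32-bit floats, so spacing and origin
  # round-trip to single precision only
  expect_equal(spacing(back), spacing(vol), tolerance = 1e-6)
  expect_equal(voxelOrigin(back), voxelOrigin(vol), tolerance = 1e-6)
})

test_that("readVolume rejects missing files, NRRD and non-3D data", {
  expect_error(readVolume(file.path(tempdir(), "nope.nii")), "not found")
  f4 <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(0, c(4, 4, 4, 3))), f4)
  expect_error(readVolume(f4), "3D")
  fn <- withr::local_tempfile(fileext = ".nrrd")
  writeLines("NRRD0004", fn)
  expect_error(readVolume(fn), "NRRD")
})

test_that("trajectories round-trip through JSON and read from TSV", {
  trs <- list(ArteryTrajectory("LAD", rbind(c(1, 2, 3), c(4, 5, 6),
                                            c(4, 5, 9)), searchRadius = 6),
              ArteryTrajectory("RCA", rbind(c(0, 0, 0), c(10, 0, 0))))
  f <- withr::local_tempfile(fileext = ".json")
  writeTrajectories(trs, f)
  back <- readTrajectories(f)
  expect_length(back, 2)
  expect_equal(trajectoryPoints(back[[1]]), trajectoryPoints(trs[[1]]))
  expect_equal(searchRadius(back[[1]]), 6)
  expect_equal(searchRadius(back[[2]]), 8)  # default applied on write side

  ftsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("name\tx\ty\tz", "LAD\t0\t0\t0", "LAD\t0\t0\t30"), ftsv)
  tt <- readTrajectories(ftsv)
  expect_equal(searchRadius(tt[[1]]), 8)  # absent radius -> 8 mm default
  expect_equal(nrow(trajectoryPoints(tt[[1]])), 2)

  fbad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("name\tx\ty\tz", "LAD\t0\t0\t0"), fbad)
  expect_error(readTrajectories(fbad), "at least 2")
})

test_that("phantom specs round-trip and label masks resolve", {
  ph <- PhantomSpec(c(0, 50, 100, 200), lapply(1:4, function(i)
    list(center = c(5 * i, 20, 15), radius = 2, halfLength = 10, axis = 3L)))
  f <- withr::local_tempfile(fileext = ".json")
  writePhantom(ph, f)
  back <- readPhantom(f)
  expect_equal(insertDensities(back), c(0, 50, 100, 200))
  expect_equal(back@regions[[2]]$center, c(10, 20, 15))

  lab <- array(0L, c(6, 6, 4))
  lab[1:2, 1:2, 1:2] <- 1L
  lab[4:5, 4:5, 1:2] <- 2L
  phm <- phantomFromLabels(lab, c("1" = 0, "2" = 200))
  expect_equal(nrow(phm@regions[[1]]), 8)
  expect_error(PhantomSpec(c(100), list(list(center = 0, radius = 1,
                                             halfLength = 1, axis = 1))),
               "at least 2")
  expect_error(PhantomSpec(c(100, 100), list(1, 2)), "distinct")
})

test_that("score tables write deterministically and round-trip", {
  r <- function(s, p, a, w, n) new("ScoreResult", scanId = s,
                                   participantId = p, agatston = a,
                                   swcs = w, nLesions = n)
  res <- list(r("s2", "p2", 10.5, 12.25, 2), r("s1", "p1", 0, 1e-8, 0))
  f <- withr::local_tempfile(fileext = ".csv")
  writeScores(res, f)
  expect_length(readLines(f), 3)
  back <- readScores(f)
  expect_equal(back$participant_id, c("p1", "p2"))  # sorted on write
  expect_equal(back$swcs, c(1e-8, 12.25), tolerance = 1e-9)
  expect_error(writeScores(list(), f), "no score")
})

test_that("region of interest matches the brute-force all-voxel oracle", {
  vol <- CTVolume(array(0, c(14, 14, 8)), spacing = c(1, 1, 2),
                  origin = c(0, 0, 0))
  trs <- list(ArteryTrajectory("a", rbind(c(3, 3, 0), c(10, 8, 14)),
                               searchRadius = 4),
              ArteryTrajectory("b", rbind(c(12, 2, 2), c(12, 12, 10)),
                               searchRadius = 3))
  roi <- regionOfInterest(vol, trs)
  oracle <- bruteROI(vol, trs)
  o1 <- roi[order(roi[, 1], roi[, 2], roi[, 3]), ]
  o2 <- oracle[order(oracle[, 1], oracle[, 2], oracle[, 3]), ]
  expect_equal(unname(o1), unname(o2))
  expect_gt(nrow(roi), 0)
})

test_that("ROI geometry: forced cases and monotonicity in radius", {
  vol <- CTVolume(array(0, c(16, 16, 10)), spacing = c(1, 1, 1))
  # radius 0.4 with the line through voxel centres -> exactly on-line voxels
  tr <- axialTrajectory(7, 7, 0, 9, radius = 0.4)
  roi <- regionOfInterest(vol, list(tr))
  expect_equal(nrow(roi), 10)
  expect_true(all(roi[, 1] == 8 & roi[, 2] == 8))
  # trajectory entirely outside the volume -> empty set, not an error
  far <- axialTrajectory(200, 200, 0, 9, radius = 2)
  expect_equal(nrow(regionOfInterest(vol, list(far))), 0)
  # nested radii give nested regions
  radii <- c(1, 2.5, 4, 6)
  rois <- lapply(radii, function(r)
    regionOfInterest(vol, list(axialTrajectory(7.3, 6.1, 1, 8, radius = r))))
  keys <- lapply(rois, function(m) paste(m[, 1], m[, 2], m[, 3]))
  for (i in 1:3)
    expect_true(all(keys[[i]] %in% keys[[i + 1]]))
})
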