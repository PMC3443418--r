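# Fixture builders and independent brute-force oracles. The oracles are
# deliberately written with different algorithms from the package
# implementations (per-voxel scans, label propagation, explicit loops,
# stats::aov) so they can stand as references.

# -- fixtures -----------------------------------------------------------

# uniform-background volume with optional rectangular blocks of given HU
toyVolume <- function(dims = c(12, 12, 8), spacing = c(1, 1, 1),
                      background = 60, blocks = list()) {
  arr <- array(background, dims)
  for (b in blocks) {
    arr[b$i, b$j, b$k] <- b$hu
  }
  CTVolume(arr, spacing)
}

fullROI <- function(volume) {
  d <- dim(voxels(volume))
  idx <- as.matrix(expand.grid(i = seq_len(d[1]), j = seq_len(d[2]),
                               k = seq_len(d[3])))
  storage.mode(idx) <- "integer"
  unname(idx)
}

# straight-line trajectory along the z axis through physical (x, y)
axialTrajectory <- function(x, y, z0, z1, radius = 8) {
  ArteryTrajectory("toy", rbind(c(x, y, z0), c(x, y, z1)),
                   searchRadius = radius)
}

# a calibration model with known operating point, bypassing phantom fits
directModel <- function(muC = 130, sigmaC = 15) {
  fitCalibration(
    data.frame(density = c(0, 100), meanHU = c(muC - 100, muC),
               sdHU = c(sigmaC, sigmaC), nVoxels = c(100, 100)),
    criterionDensity = 100, sigmaFloor = 1e-6)
}

# -- oracles ------------------------------------------------------------

# brute-force ROI: loop every voxel, min distance over all segments
bruteROI <- function(volume, trajectories) {
  d <- dim(voxels(volume))
  sp <- spacing(volume)
  o <- voxelOrigin(volume)
  hits <- matrix(integer(0), ncol = 3)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    ctr <- o + (c(i, j, k) - 1) * sp
    inside <- FALSE
    for (tr in trajectories) {
      p <- trajectoryPoints(tr)
      r <- searchRadius(tr)
      for (s in seq_len(nrow(p) - 1)) {
        a <- p[s, ]; b <- p[s + 1, ]
        ab <- b - a
        t <- sum((ctr - a) * ab) / sum(ab^2)
        t <- min(max(t, 0), 1)
        if (sum((ctr - (a + t * ab))^2) <= r^2) { inside <- TRUE; break }
      }
      if (inside) break
    }
    if (inside) hits <- rbind(hits, c(i, j, k))
  }
  storage.mode(hits) <- "integer"
  hits
}

# connected components by iterative min-label propagation (not BFS)
oracleComponents <- function(mask, connectivity) {
  d <- dim(mask)
  lab <- array(NA_real_, d)
  lab[mask] <- which(mask)
  offs <- expand.grid(a = -1:1, b = -1:1, c = -1:1)
  offs <- offs[rowSums(abs(offs)) > 0, ]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, ]
  repeat {
    old <- lab
    for (r in seq_len(nrow(offs))) {
      sh <- array(NA_real_, d)
      i1 <- max(1, 1 + offs$a[r]):min(d[1], d[1] + offs$a[r])
      j1 <- max(1, 1 + offs$b[r]):min(d[2], d[2] + offs$b[r])
      k1 <- max(1, 1 + offs$c[r]):min(d[3], d[3] + offs$c[r])
      sh[i1 - offs$a[r], j1 - offs$b[r], k1 - offs$c[r]] <- lab[i1, j1, k1]
      upd <- !is.na(lab) & !is.na(sh) & sh < lab
      lab[upd] <- sh[upd]
    }
    if (identical(old, lab)) break
  }
  labs <- sort(unique(lab[!is.na(lab)]))
  lapply(labs, function(l) which(!is.na(lab) & lab == l, arr.ind = TRUE))
}

# naive SWCS: explicit double loop over region voxels and neighbourhoods
naiveSWCS <- function(volume, roi, model, neighborhood = 26, kappa = 1) {
  d <- dim(voxels(volume))
  w <- array(0, d)
  for (r in seq_len(nrow(roi)))
    w[roi[r, 1], roi[r, 2], roi[r, 3]] <-
      voxelWeight(voxels(volume)[roi[r, 1], roi[r, 2], roi[r, 3]], model)
  total <- 0
  for (r in seq_len(nrow(roi))) {
    i <- roi[r, 1]; j <- roi[r, 2]; k <- roi[r, 3]
    acc <- 0; cnt <- 0
    for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
      if (neighborhood == 6 && sum(abs(c(di, dj, dk))) > 1) next
      ii <- i + di; jj <- j + dj; kk <- k + dk
      if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] ||
          kk < 1 || kk > d[3]) next
      acc <- acc + w[ii, jj, kk]; cnt <- cnt + 1
    }
    total <- total + w[i, j, k] * (acc / cnt)
  }
  kappa * total * prod(spacing(volume))
}

# ICC(1,1) straight from the stats::aov ANOVA table
aovICC <- function(x1, x2) {
  d <- data.frame(value = c(x1, x2),
                  pid = factor(rep(seq_along(x1), 2)))
  tab <- summary(stats::aov(value ~ pid, data = d))[[1]]
  msb <- tab["pid", "Mean Sq"]
  msw <- tab["Residuals", "Mean Sq"]
  (msb - msw) / (msb + msw)
}
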