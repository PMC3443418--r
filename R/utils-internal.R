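# Internal geometry and labelling helpers. All voxel indices are 1-based
# (i, j, k); the physical centre of voxel (i,j,k) is
# origin + (i-1, j-1, k-1) * spacing.

# physical centre coordinates of a set of voxel indices (n x 3 matrix)
.voxelCenters <- function(volume, idx) {
  sp <- volume@spacing
  o <- volume@origin
  cbind(o[1] + (idx[, 1] - 1) * sp[1],
        o[2] + (idx[, 2] - 1) * sp[2],
        o[3] + (idx[, 3] - 1) * sp[3])
}

.linearIndex <- function(idx, dims) {
  as.integer(idx[, 1] + (idx[, 2] - 1L) * dims[1] +
             (idx[, 3] - 1L) * dims[1] * dims[2])
}

.arrayIndex <- function(lin, dims) {
  lin0 <- lin - 1L
  i <- lin0 %% dims[1]
  j <- (lin0 %/% dims[1]) %% dims[2]
  k <- lin0 %/% (dims[1] * dims[2])
  cbind(i + 1L, j + 1L, k + 1L)
}

# logical mask from an n x 3 voxel-index matrix
.roiMask <- function(dims, roi) {
  m <- array(FALSE, dims)
  if (nrow(roi) > 0) m[roi] <- TRUE
  m
}

# neighbour offsets for 6- (faces) or 26- (full 3x3x3 shell) connectivity
.neighborOffsets <- function(connectivity) {
  if (connectivity == 6) {
    rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
          c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  } else if (connectivity == 26) {
    g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
    g[rowSums(abs(g)) > 0, , drop = FALSE]
  } else {
    stop("connectivity must be 6 or 26")
  }
}

# connected components over the TRUE voxels of `mask`; returns a list of
# n x 3 index matrices, one per component, ordered by smallest linear index.
# BFS over an explicit candidate list: candidate sets are small (lesions),
# so plain R is fast enough.
.connectedComponents <- function(mask, connectivity = 26) {
  dims <- dim(mask)
  cand <- which(mask)
  if (length(cand) == 0) return(list())
  offs <- .neighborOffsets(connectivity)
  offLin <- as.integer(offs[, 1] + offs[, 2] * dims[1] +
                       offs[, 3] * dims[1] * dims[2])
  inMask <- mask
  visited <- array(FALSE, dims)
  comps <- list()
  for (seed in cand) {
    if (visited[seed]) next
    queue <- seed
    visited[seed] <- TRUE
    members <- integer(0)
    while (length(queue)) {
      cur <- queue
      queue <- integer(0)
      members <- c(members, cur)
      curIdx <- .arrayIndex(cur, dims)
      for (a in seq_len(nrow(offs))) {
        ni <- curIdx[, 1] + offs[a, 1]
        nj <- curIdx[, 2] + offs[a, 2]
        nk <- curIdx[, 3] + offs[a, 3]
        ok <- ni >= 1L & ni <= dims[1] & nj >= 1L & nj <= dims[2] &
              nk >= 1L & nk <= dims[3]
        if (!any(ok)) next
        nlin <- cur[ok] + offLin[a]
        nlin <- nlin[inMask[nlin] & !visited[nlin]]
        if (length(nlin)) {
          visited[nlin] <- TRUE
          queue <- c(queue, unique(nlin))
        }
      }
    }
    comps[[length(comps) + 1L]] <- sort(members)
  }
  ord <- order(vapply(comps, `[`, integer(1), 1L))
  lapply(comps[ord], function(m) .arrayIndex(m, dims))
}

# truncated-box neighbourhood mean of a 3D array: for mode 26 the 3x3x3 box
# including the centre, for mode 6 the centre plus its 6 face neighbours;
# at volume borders the neighbourhood is clipped (no padding values enter
# the mean).
.neighborhoodMean <- function(arr, mode = 26) {
  dims <- dim(arr)
  offs <- rbind(c(0, 0, 0), .neighborOffsets(mode))
  pad <- array(0, dims + 2L)
  pad[2:(dims[1] + 1L), 2:(dims[2] + 1L), 2:(dims[3] + 1L)] <- arr
  cnt <- array(0, dims + 2L)
  cnt[2:(dims[1] + 1L), 2:(dims[2] + 1L), 2:(dims[3] + 1L)] <- 1
  num <- array(0, dims)
  den <- array(0, dims)
  for (a in seq_len(nrow(offs))) {
    i <- (2:(dims[1] + 1L)) + offs[a, 1]
    j <- (2:(dims[2] + 1L)) + offs[a, 2]
    k <- (2:(dims[3] + 1L)) + offs[a, 3]
    num <- num + pad[i, j, k]
    den <- den + cnt[i, j, k]
  }
  num / den
}

# voxel indices inside an axis-aligned cylinder (physical mm)
.cylinderIndices <- function(volume, center, radius, halfLength, axis) {
  dims <- dim(volume@voxels)
  all <- as.matrix(expand.grid(i = seq_len(dims[1]), j = seq_len(dims[2]),
                               k = seq_len(dims[3])))
  ctr <- .voxelCenters(volume, all)
  ax <- as.integer(axis)
  perp <- setdiff(1:3, ax)
  inside <- abs(ctr[, ax] - center[ax]) <= halfLength &
    (ctr[, perp[1]] - center[perp[1]])^2 +
    (ctr[, perp[2]] - center[perp[2]])^2 <= radius^2
  all[inside, , drop = FALSE]
}

# resolve a PhantomSpec region (index matrix or cylinder list) to indices
.resolveRegion <- function(volume, region) {
  if (is.matrix(region)) {
    storage.mode(region) <- "integer"
    region
  } else {
    .cylinderIndices(volume, region$center, region$radius,
                     region$halfLength, region$axis)
  }
}

# deterministic sub-seed derivation (kept below 2^31)
.subSeed <- function(seed, ...) {
  parts <- c(seed, ...)
  s <- 0
  for (p in parts) s <- (s * 69069 + p + 1) %% 2147483647
  as.integer(s)
}
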