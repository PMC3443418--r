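#' Coronary search region around artery trajectories
#'
#' Returns the set of voxels whose centres lie within each trajectory's
#' search radius (default 8 mm) of the trajectory polyline, united over all
#' arteries. Distance is Euclidean point-to-segment distance to the
#' polyline's segments (not just its vertices), so sparsely sampled
#' centerlines do not create gaps. Anisotropic spacing is respected: no
#' resampling is performed.
#'
#' @param volume A [CTVolume-class].
#' @param trajectories Non-empty list of [ArteryTrajectory-class] objects
#'   (a single trajectory is also accepted).
#' @param mode `"3d"` (default) computes full 3D Euclidean distance;
#'   `"2d"` computes in-plane (x, y) distance to the segment's xy
#'   projection, restricted to slices overlapping the segment's z extent —
#'   emulating per-slice reading software.
#' @return Integer n x 3 matrix of 1-based voxel indices (possibly 0 rows:
#'   an empty region is not an error, but scoring functions reject it).
#' @examples
#' vol <- CTVolume(array(0, c(20, 20, 10)), spacing = c(1, 1, 1))
#' tr <- ArteryTrajectory("LAD", rbind(c(10, 10, 0), c(10, 10, 9)),
#'                        searchRadius = 3)
#' nrow(regionOfInterest(vol, list(tr)))
#' @export
regionOfInterest <- function(volume, trajectories, mode = c("3d", "2d")) {
  mode <- match.arg(mode)
  stopifnot(is(volume, "CTVolume"))
  if (is(trajectories, "ArteryTrajectory"))
    trajectories <- list(trajectories)
  if (length(trajectories) == 0)
    stop("at least one artery trajectory is required")
  dims <- dim(volume@voxels)
  sp <- volume@spacing
  o <- volume@origin
  inROI <- array(FALSE, dims)
  ax <- list(o[1] + (seq_len(dims[1]) - 1) * sp[1],
             o[2] + (seq_len(dims[2]) - 1) * sp[2],
             o[3] + (seq_len(dims[3]) - 1) * sp[3])
  for (tr in trajectories) {
    p <- tr@points
    r <- tr@searchRadius
    for (s in seq_len(nrow(p) - 1L)) {
      a <- p[s, ]
      b <- p[s + 1L, ]
      # candidate sub-grid: bounding box of the segment, padded by r
      lo <- pmin(a, b) - r
      hi <- pmax(a, b) + r
      sub <- lapply(1:3, function(d) which(ax[[d]] >= lo[d] & ax[[d]] <= hi[d]))
      if (any(lengths(sub) == 0)) next
      g <- as.matrix(expand.grid(i = sub[[1]], j = sub[[2]], k = sub[[3]]))
      ctr <- cbind(ax[[1]][g[, 1]], ax[[2]][g[, 2]], ax[[3]][g[, 3]])
      if (mode == "3d") {
        d2 <- .segmentDist2(ctr, a, b)
      } else {
        inZ <- ctr[, 3] >= min(a[3], b[3]) - sp[3] / 2 &
               ctr[, 3] <= max(a[3], b[3]) + sp[3] / 2
        d2 <- rep(Inf, nrow(ctr))
        if (any(inZ))
          d2[inZ] <- .segmentDist2(cbind(ctr[inZ, 1:2, drop = FALSE], 0),
                                   c(a[1:2], 0), c(b[1:2], 0))
      }
      hit <- d2 <= r^2
      if (any(hit))
        inROI[g[hit, , drop = FALSE]] <- TRUE
    }
  }
  idx <- which(inROI, arr.ind = TRUE)
  storage.mode(idx) <- "integer"
  unname(idx)
}

# squared distance from points (n x 3) to segment a-b
.segmentDist2 <- function(pts, a, b) {
  d <- b - a
  len2 <- sum(d^2)
  rel <- sweep(pts, 2, a)
  t <- pmin(pmax(as.numeric(rel %*% d) / len2, 0), 1)
  proj <- outer(t, d)
  rowSums((rel - proj)^2)
}
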