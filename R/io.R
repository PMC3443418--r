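#' Read a CT volume from a NIfTI-1 file
#'
#' Reads a 3D scalar NIfTI-1 volume (`.nii` / `.nii.gz`) into a
#' [CTVolume-class]. Voxel spacing is taken from the pixdim field and the
#' origin (physical centre of voxel (1,1,1)) from the qform/sform
#' translation. Axis order is (x, y, z) with z the slice axis.
#'
#' @param path Path to a NIfTI-1 file.
#' @param scanId,participantId Identifiers to attach; default to the file
#'   base name and `"unknown"`.
#' @return A [CTVolume-class].
#' @seealso [writeVolume()]
#' @export
readVolume <- function(path, scanId = NULL, participantId = "unknown") {
  if (!file.exists(path))
    stop("volume file not found: ", path)
  if (grepl("\\.nrrd$|\\.nhdr$", path, ignore.case = TRUE))
    stop("NRRD input is not supported; convert to NIfTI-1 (.nii/.nii.gz)")
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected 3D scalar volume, got ", length(d), "D data in ", path)
  sp <- RNifti::pixdim(img)
  if (length(sp) < 3L || any(sp[1:3] <= 0))
    stop("non-positive voxel spacing (pixdim) in ", path)
  xf <- RNifti::xform(img)
  orig <- as.numeric(xf[1:3, 4])
  if (is.null(scanId))
    scanId <- sub("\\.nii(\\.gz)?$", "", basename(path))
  vox <- array(as.numeric(img), dim = d)   # strip niftiImage attributes
  CTVolume(vox, spacing = as.numeric(sp[1:3]), origin = orig,
           scanId = scanId, participantId = participantId)
}

#' Write a CT volume to a NIfTI-1 file
#'
#' @param volume A [CTVolume-class].
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
writeVolume <- function(volume, path) {
  stopifnot(is(volume, "CTVolume"))
  img <- RNifti::asNifti(volume@voxels)
  RNifti::pixdim(img) <- volume@spacing
  m <- diag(c(volume@spacing, 1))
  m[1:3, 4] <- volume@origin
  img <- RNifti::`qform<-`(img, structure(m, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read artery trajectories from JSON or TSV
#'
#' JSON input is a list of objects `{name, points: [[x,y,z], ...], radius}`;
#' TSV input has columns `name`, `x`, `y`, `z` and optionally `radius`
#' (constant per artery), one row per centerline point, in mm. When no
#' radius is given the standard 8 mm search radius is used.
#'
#' @param path Path to a `.json` or `.tsv`/`.txt` file.
#' @return A list of [ArteryTrajectory-class] objects.
#' @seealso [writeTrajectories()], [regionOfInterest()]
#' @export
readTrajectories <- function(path) {
  if (!file.exists(path))
    stop("trajectory file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                              simplifyMatrix = FALSE)
    trajs <- lapply(raw, function(tr) {
      pts <- do.call(rbind, lapply(tr$points, as.numeric))
      if (is.null(pts) || nrow(pts) < 2L)
        stop("trajectory '", tr$name, "' needs at least 2 points")
      r <- if (is.null(tr$radius)) 8 else as.numeric(tr$radius)
      ArteryTrajectory(tr$name, pts, searchRadius = r)
    })
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("name", "x", "y", "z")
    if (!all(need %in% names(tab)))
      stop("trajectory TSV must have columns name, x, y, z")
    if (!all(vapply(tab[c("x", "y", "z")], is.numeric, logical(1))))
      stop("trajectory coordinates must be numeric")
    trajs <- lapply(split(tab, factor(tab$name, levels = unique(tab$name))),
      function(g) {
        if (nrow(g) < 2L)
          stop("trajectory '", g$name[1], "' needs at least 2 points")
        r <- if ("radius" %in% names(g)) g$radius[1] else 8
        ArteryTrajectory(g$name[1], as.matrix(g[, c("x", "y", "z")]),
                         searchRadius = r)
      })
    names(trajs) <- NULL
  }
  trajs
}

#' Write artery trajectories to JSON
#'
#' @param trajectories List of [ArteryTrajectory-class] objects.
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
writeTrajectories <- function(trajectories, path) {
  out <- lapply(trajectories, function(tr) {
    list(name = tr@name,
         points = lapply(seq_len(nrow(tr@points)),
                         function(i) as.numeric(tr@points[i, ])),
         radius = tr@searchRadius)
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read or write a phantom specification (JSON)
#'
#' The geometric JSON form is a list of inserts
#' `{density, center:[x,y,z], radius, halfLength, axis}` (mm; axis 1/2/3).
#' For label-mask phantoms use [phantomFromLabels()].
#'
#' @param path Path to a `.json` phantom specification.
#' @return A [PhantomSpec-class].
#' @export
readPhantom <- function(path) {
  if (!file.exists(path))
    stop("phantom file not found: ", path)
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  densities <- vapply(raw, function(x) as.numeric(x$density), numeric(1))
  regions <- lapply(raw, function(x) {
    list(center = as.numeric(x$center), radius = as.numeric(x$radius),
         halfLength = as.numeric(x$halfLength), axis = as.integer(x$axis))
  })
  PhantomSpec(densities, regions)
}

#' @rdname readPhantom
#' @param phantom A [PhantomSpec-class] with cylinder-geometry regions.
#' @export
writePhantom <- function(phantom, path) {
  if (any(vapply(phantom@regions, is.matrix, logical(1))))
    stop("only cylinder-geometry phantom specs can be written to JSON; ",
         "voxel-index regions are volume-specific")
  out <- lapply(seq_along(phantom@densities), function(i) {
    r <- phantom@regions[[i]]
    list(density = phantom@densities[i], center = as.numeric(r$center),
         radius = r$radius, halfLength = r$halfLength, axis = r$axis)
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Build a PhantomSpec from an integer label mask
#'
#' @param labelVolume A [CTVolume-class]-shaped integer array (or CTVolume)
#'   whose non-zero values label phantom inserts.
#' @param densityMap Named numeric vector mapping label value (as name) to
#'   known insert density in mg/mL, e.g. `c("1" = 0, "2" = 50)`.
#' @return A [PhantomSpec-class] with voxel-index regions.
#' @export
phantomFromLabels <- function(labelVolume, densityMap) {
  arr <- if (is(labelVolume, "CTVolume")) labelVolume@voxels else labelVolume
  labs <- as.integer(names(densityMap))
  regions <- lapply(labs, function(l) {
    idx <- which(arr == l, arr.ind = TRUE)
    if (nrow(idx) == 0) stop("label ", l, " not present in mask")
    storage.mode(idx) <- "integer"
    unname(idx)
  })
  PhantomSpec(as.numeric(densityMap), regions)
}

#' Write and read score tables (CSV)
#'
#' Writes a CSV with header `scan_id,participant_id,agatston,swcs,n_lesions`
#' in deterministic order (participant_id, then scan_id).
#'
#' @param results Non-empty list of [ScoreResult-class] objects.
#' @param path Output `.csv` path.
#' @return `path` invisibly (write); a data.frame (read).
#' @export
writeScores <- function(results, path) {
  if (length(results) == 0)
    stop("no score results to write")
  df <- scoreTable(results)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeScores
#' @export
readScores <- function(path) {
  if (!file.exists(path))
    stop("score file not found: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(scan_id = "character",
                                 participant_id = "character"))
}

#' Tabulate score results
#'
#' @param results List of [ScoreResult-class] objects.
#' @return data.frame with columns scan_id, participant_id, agatston, swcs,
#'   n_lesions, ordered by (participant_id, scan_id).
#' @export
scoreTable <- function(results) {
  df <- data.frame(
    scan_id = vapply(results, scanId, character(1)),
    participant_id = vapply(results, participantId, character(1)),
    agatston = vapply(results, agatston, numeric(1)),
    swcs = vapply(results, swcs, numeric(1)),
    n_lesions = vapply(results, nLesions, numeric(1)),
    stringsAsFactors = FALSE)
  df[order(df$participant_id, df$scan_id), , drop = FALSE]
}
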