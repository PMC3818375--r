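#' Read a voxel volume from a multi-page TIFF stack
#'
#' Slices are stored one TIFF page per z-plane. The isotropic voxel spacing is
#' never guessed from the file: it must either be present in the plain-text
#' sidecar written by [write_stack()] (`<path>.meta.txt`) or be passed
#' explicitly.
#'
#' @param path path to a multi-page TIFF file.
#' @param spacing_um voxel spacing in micrometres; overrides the sidecar.
#' @return A [voxel_volume()].
#' @export
read_stack <- function(path, spacing_um = NULL) {
  pages <- read_tiff_pages(path)
  if (!length(pages)) stop("empty TIFF stack: ", path)
  d1 <- dim(pages[[1]])
  ragged <- vapply(pages, function(p) any(dim(p) != d1), logical(1))
  if (any(ragged))
    stop("ragged stack: slice dimensions differ at page ", which(ragged)[1])
  meta <- read_meta_sidecar(paste0(path, ".meta.txt"))
  if (is.null(spacing_um)) spacing_um <- meta$spacing_um
  if (is.null(spacing_um))
    stop("voxel spacing missing: pass `spacing_um` or provide a sidecar file")
  vox <- array(unlist(pages), dim = c(d1[1], d1[2], length(pages)))
  binary <- isTRUE(meta$binary) || all(vox %in% c(0L, 255L))
  meta$spacing_um <- NULL; meta$binary <- NULL
  voxel_volume(vox, as.numeric(spacing_um), binary = binary, meta = meta)
}

#' Write a voxel volume as a multi-page TIFF stack
#'
#' Binary volumes are written 8-bit with bone = 255 and background = 0; gray
#' volumes are written 16-bit (values must fit the 16-bit range). A plain-text
#' key/value sidecar `<path>.meta.txt` records the spacing and scalar metadata
#' so that [read_stack()] round-trips losslessly.
#'
#' @param volume a [voxel_volume()].
#' @param path output TIFF path.
#' @export
write_stack <- function(volume, path) {
  stopifnot(inherits(volume, "voxel_volume"))
  vox <- volume$voxels
  bits <- if (volume$binary) 8L else 16L
  pages <- lapply(seq_len(dim(vox)[3]), function(k) {
    m <- vox[, , k, drop = TRUE]
    storage.mode(m) <- "integer"
    m
  })
  write_tiff_pages(pages, path, bits = bits)
  meta <- volume$meta[vapply(volume$meta, function(x)
    is.atomic(x) && length(x) <= 16, logical(1))]
  write_meta_sidecar(c(list(spacing_um = volume$spacing_um,
                            binary = volume$binary), meta),
                     paste0(path, ".meta.txt"))
  invisible(path)
}

write_meta_sidecar <- function(meta, path) {
  lines <- vapply(names(meta), function(k)
    paste0(k, " = ", paste(format(meta[[k]], digits = 17), collapse = " ")),
    character(1))
  writeLines(lines, path)
}

read_meta_sidecar <- function(path) {
  if (!file.exists(path)) return(list())
  lines <- readLines(path, warn = FALSE)
  out <- list()
  for (ln in lines) {
    kv <- regmatches(ln, regexec("^\\s*([^=]+?)\\s*=\\s*(.*)$", ln))[[1]]
    if (length(kv) != 3) next
    vals <- strsplit(kv[3], "\\s+")[[1]]
    num <- suppressWarnings(as.numeric(vals))
    out[[kv[2]]] <- if (!anyNA(num)) num else
      if (all(vals %in% c("TRUE", "FALSE"))) as.logical(vals) else kv[3]
  }
  out
}

#' Estimate the bone long axis from a binary volume
#'
#' Principal inertia axis of the bone-voxel point cloud, canonicalized to a
#' positive z-component. When the two largest inertia moments are nearly equal
#' the direction is ill-defined; the result then carries
#' `attr(, "degenerate") = TRUE` and a warning is raised rather than failing
#' silently.
#'
#' @param volume binary [voxel_volume()].
#' @param tol relative eigenvalue gap under which the axis is flagged
#'   degenerate.
#' @return Unit 3-vector with attribute `degenerate`.
#' @export
estimate_long_axis <- function(volume, tol = 0.05) {
  b <- bone_logical(volume)
  if (!any(b)) stop("empty volume: no bone voxels")
  co <- which(b, arr.ind = TRUE) - 1 # 0-based voxel coordinates
  co <- sweep(co, 2, colMeans(co))
  cv <- crossprod(co) / nrow(co)
  eg <- eigen(cv, symmetric = TRUE)
  axis <- eg$vectors[, 1]
  if (axis[3] < 0) axis <- -axis
  degenerate <- (eg$values[1] - eg$values[2]) < tol * max(eg$values[1], 1e-12)
  if (degenerate)
    warning("long axis is degenerate: leading inertia moments nearly equal")
  structure(unit3(axis), degenerate = degenerate)
}

#' Reorient a volume so a given axis maps to +z
#'
#' Rotates about the volume centre with trilinear interpolation. Binary input
#' is interpolated on a 0/1 field and re-thresholded at 0.5 (values >= 0.5
#' become bone), which preserves thin struts better than nearest-neighbour
#' resampling at the modest angles that occur in practice.
#'
#' @param volume a [voxel_volume()].
#' @param target_axis unit 3-vector to be mapped onto +z.
#' @param out_dim optional output dimensions (defaults to the input's).
#' @return A [voxel_volume()] of the same kind.
#' @export
reorient <- function(volume, target_axis, out_dim = NULL) {
  stopifnot(inherits(volume, "voxel_volume"))
  target_axis <- unit3(target_axis, "target_axis")
  R <- rotation_between(target_axis, c(0, 0, 1))
  d_in <- dim(volume$voxels)
  if (is.null(out_dim)) out_dim <- d_in
  if (max(abs(R - diag(3))) < 1e-12 && all(out_dim == d_in)) return(volume)
  src <- if (volume$binary) bone_logical(volume) * 1.0 else volume$voxels * 1.0
  res <- cpp_affine_resample(as.vector(src), as.integer(d_in),
                             as.integer(out_dim), t(R),
                             (d_in - 1) / 2, (out_dim - 1) / 2, 0)
  arr <- array(res, dim = out_dim)
  if (volume$binary) arr <- (arr >= 0.5) * 255L
  voxel_volume(arr, volume$spacing_um, binary = volume$binary,
               meta = volume$meta)
}

#' Gradient-based half-maximum binarization
#'
#' A simplified edge-detection ray-casting segmentation: along axis-aligned
#' rays, edges are located where the gray-level gradient exceeds
#' `min_contrast`; each edge contributes a local half-maximum threshold (the
#' midpoint of the median gray levels of the plateaus on either side) and ray
#' segments are classified against the mean of their ray's local thresholds.
#' Rays that cross no edge fall back to the volume-wide mean threshold.
#' Because only gray-level differences enter, the segmentation is invariant to
#' global additive brightness shifts.
#'
#' @param gray gray-valued [voxel_volume()].
#' @param ray_step unused spacing hook kept for interface stability; rays are
#'   cast along every x-row.
#' @param min_contrast minimum absolute voxel-to-voxel gray step treated as an
#'   edge.
#' @return Binary [voxel_volume()] with bone = 255.
#' @export
binarize_gradient <- function(gray, ray_step = 1L, min_contrast = 50) {
  stopifnot(inherits(gray, "voxel_volume"))
  vox <- gray$voxels
  d <- dim(vox)
  out <- array(FALSE, d)
  thresholds <- c()
  ray_thr <- array(NA_real_, d[2:3])
  seg_info <- vector("list", d[2] * d[3])
  ii <- 0L
  for (z in seq_len(d[3])) {
    for (y in seq_len(d[2])) {
      ii <- ii + 1L
      g <- vox[, y, z]
      dg <- diff(g)
      edge <- which(abs(dg) >= min_contrast)
      if (!length(edge)) { seg_info[ii] <- list(NULL); next }
      # collapse runs of consecutive edge positions to their strongest step
      runs <- split(edge, cumsum(c(1, diff(edge) > 1)))
      edge <- vapply(runs, function(r) r[which.max(abs(dg[r]))], numeric(1))
      bounds <- c(0, edge, length(g))
      meds <- vapply(seq_len(length(bounds) - 1), function(j)
        stats::median(g[(bounds[j] + 1):(bounds[j + 1])]), numeric(1))
      thr <- (meds[-length(meds)] + meds[-1]) / 2
      ray_thr[y, z] <- mean(thr)
      thresholds <- c(thresholds, thr)
      seg_info[[ii]] <- list(bounds = bounds, meds = meds)
    }
  }
  if (!length(thresholds)) stop("no edges: volume has no contrast")
  global_thr <- mean(thresholds)
  ii <- 0L
  for (z in seq_len(d[3])) {
    for (y in seq_len(d[2])) {
      ii <- ii + 1L
      si <- seg_info[[ii]]
      if (is.null(si)) {
        out[, y, z] <- vox[, y, z] > global_thr
      } else {
        thr <- ray_thr[y, z]
        for (j in seq_len(length(si$bounds) - 1)) {
          rng <- (si$bounds[j] + 1):(si$bounds[j + 1])
          out[rng, y, z] <- si$meds[j] > thr
        }
      }
    }
  }
  voxel_volume(out * 255L, gray$spacing_um, binary = TRUE, meta = gray$meta)
}

#' Spherical volume of interest
#'
#' @param center 0-based voxel coordinates of the sphere centre (3-vector).
#' @param diameter sphere diameter in voxels (>= 10); voxels whose centres lie
#'   within `diameter / 2` of `center` belong to the VOI.
#' @param role `"orientation"` (the 200-pixel class of the protocol) or
#'   `"morphometry"` (the 400-pixel class).
#' @param side `"medial"` or `"lateral"`.
#' @export
spherical_voi <- function(center, diameter, role = c("orientation", "morphometry"),
                          side = c("medial", "lateral")) {
  role <- match.arg(role); side <- match.arg(side)
  center <- as.numeric(center)
  if (length(center) != 3L) stop("`center` must be a 3-vector")
  if (diameter < 10) stop("VOI diameter must be >= 10 voxels")
  structure(list(center = center, diameter = diameter, role = role, side = side),
            class = "spherical_voi")
}

#' Extract a spherical VOI
#'
#' Crops the bounding cube of the sphere and returns it together with the
#' boolean sphere mask; all downstream measurements are restricted to the
#' mask. The closed sphere must lie fully inside the volume.
#'
#' @param volume a [voxel_volume()].
#' @param voi a [spherical_voi()].
#' @return List with elements `volume` (cropped [voxel_volume()]) and `mask`
#'   (logical array of the same dimensions).
#' @export
extract_voi <- function(volume, voi) {
  stopifnot(inherits(volume, "voxel_volume"), inherits(voi, "spherical_voi"))
  d <- dim(volume$voxels)
  r <- voi$diameter / 2
  c0 <- voi$center
  if (any(c0 - r < 0) || any(c0 + r > d - 1))
    stop("VOI sphere extends beyond (or touches) the volume bounds")
  lo <- ceiling(c0 - r); hi <- floor(c0 + r) # 0-based
  cube <- volume$voxels[(lo[1] + 1):(hi[1] + 1),
                        (lo[2] + 1):(hi[2] + 1),
                        (lo[3] + 1):(hi[3] + 1), drop = FALSE]
  dd <- dim(cube)
  cx <- (lo[1]:hi[1]) - c0[1]
  cy <- (lo[2]:hi[2]) - c0[2]
  cz <- (lo[3]:hi[3]) - c0[3]
  d2 <- outer(outer(cx^2, cy^2, "+"), cz^2, "+")
  mask <- d2 <= r^2 + 1e-9
  list(volume = voxel_volume(cube, volume$spacing_um, binary = volume$binary,
                             meta = c(volume$meta,
                                      list(voi_role = voi$role, voi_side = voi$side))),
       mask = mask)
}

#' Middle sagittal slices of a VOI cube
#'
#' Returns the `n` x-z slices centred on the VOI midplane along y (the
#' mediolateral axis). For a y-extent m the 0-based slice indices are
#' `floor((m - n)/2) .. floor((m - n)/2) + n - 1`.
#'
#' @param voi_volume a [voxel_volume()] or 3D array (e.g. a VOI mask).
#' @param n number of slices (default 10).
#' @return List of `n` 2D matrices (x-z images; anterior left, proximal up).
#' @export
middle_sagittal_slices <- function(voi_volume, n = 10L) {
  arr <- as_volume_array(voi_volume)
  m <- dim(arr)[2]
  if (m < n) stop(sprintf("y-extent %d is smaller than n = %d", m, n))
  start0 <- floor((m - n) / 2)
  lapply(seq_len(n), function(k) arr[, start0 + k, , drop = TRUE])
}
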