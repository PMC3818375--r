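#' Voxel volume container
#'
#' A `voxel_volume` is the carrier of all image computation in fabricgait: a
#' 3D scalar (gray) or binary grid with isotropic spacing. Binary volumes use
#' the 8-bit microCT convention: bone voxels are 255, background voxels 0.
#' After reorientation the axis convention is z = proximodistal long axis,
#' x = anteroposterior (anterior towards -x), y = mediolateral.
#'
#' @param voxels 3D numeric/integer array.
#' @param spacing_um isotropic voxel edge length in micrometres (> 0).
#' @param binary logical; if `TRUE`, voxels must be in {0, 255}.
#' @param meta named list of free-form metadata (ground-truth axis, side
#'   labels, generator parameters, ...).
#' @return An object of class `voxel_volume`.
#' @export
voxel_volume <- function(voxels, spacing_um, binary = FALSE, meta = list()) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array")
  if (any(dim(voxels) < 1L)) stop("all three axis extents must be >= 1")
  if (!is.numeric(spacing_um) || length(spacing_um) != 1L || spacing_um <= 0)
    stop("`spacing_um` must be a single positive number")
  if (binary && !all(voxels %in% c(0, 255)))
    stop("binary volumes must contain only 0 and 255")
  structure(
    list(voxels = voxels, spacing_um = spacing_um, binary = binary, meta = meta),
    class = "voxel_volume"
  )
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<voxel_volume> %d x %d x %d, spacing %.3g um, %s\n",
              d[1], d[2], d[3], x$spacing_um,
              if (x$binary) sprintf("binary (BV/TV %.1f%%)", bone_fraction(x) * 100)
              else "gray"))
  if (length(x$meta)) cat("  meta:", paste(names(x$meta), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.voxel_volume <- function(x) dim(x$voxels)

# logical bone array of a binary volume; accepts the 0/255 convention, 0/1
# integer labels or logical arrays interchangeably (DA and friends must be
# invariant to that relabeling)
bone_logical <- function(volume) {
  v <- if (inherits(volume, "voxel_volume")) volume$voxels else volume
  v > 0.5
}

# bone voxel fraction (0..1)
bone_fraction <- function(volume) {
  b <- bone_logical(volume)
  sum(b) / length(b)
}

as_volume_array <- function(volume) {
  if (inherits(volume, "voxel_volume")) volume$voxels else volume
}

# normalize a 3-vector to unit norm, erroring on (near-)zero input
unit3 <- function(v, what = "axis") {
  v <- as.numeric(v)
  if (length(v) != 3L) stop(sprintf("`%s` must be a 3-vector", what))
  n <- sqrt(sum(v^2))
  if (!is.finite(n) || n < 1e-12) stop(sprintf("`%s` must be non-zero", what))
  v / n
}

# rotation matrix mapping unit vector `from` onto unit vector `to`
rotation_between <- function(from, to) {
  from <- unit3(from); to <- unit3(to)
  c0 <- sum(from * to)
  ax <- c(from[2]*to[3] - from[3]*to[2],
          from[3]*to[1] - from[1]*to[3],
          from[1]*to[2] - from[2]*to[1])
  s <- sqrt(sum(ax^2))
  if (s < 1e-12) {
    if (c0 > 0) return(diag(3))
    # antiparallel: rotate 180 deg about any perpendicular axis
    p <- if (abs(from[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- p - sum(p * from) * from
    ax <- ax / sqrt(sum(ax^2))
    K <- skew3(ax)
    return(diag(3) + 2 * K %*% K)
  }
  ax <- ax / s
  K <- skew3(ax)
  diag(3) + s * K + (1 - c0) * (K %*% K)
}

skew3 <- function(a) {
  matrix(c(0, a[3], -a[2],
           -a[3], 0, a[1],
           a[2], -a[1], 0), 3, 3)
}
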