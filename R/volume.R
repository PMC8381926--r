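#' CT volume container
#'
#' A `ct_volume` is a 3-d grid of HU-calibrated intensities together with its
#' world-frame geometry: voxel spacing (mm), world origin (mm) and a 3x3
#' orthonormal direction matrix. The internal world frame is the scanner /
#' DICOM patient frame (LPS); NIfTI's RAS convention is converted on read.
#' Voxel `(i, j, k)` (0-based) maps to world position
#' `origin + direction %*% (spacing * c(i, j, k))`; this mapping is used
#' everywhere downstream.
#'
#' @param hu 3-d numeric array of intensities in Hounsfield units; the first
#'   array index runs along x, the second along y, the third along z.
#' @param spacing_mm strictly positive length-3 voxel spacing in mm.
#' @param origin_mm world position of voxel (0, 0, 0) in mm.
#' @param direction 3x3 orthonormal direction matrix (columns are the world
#'   directions of the voxel axes); `|det|` must be 1.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(hu, spacing_mm = c(1, 1, 1), origin_mm = c(0, 0, 0),
                      direction = diag(3)) {
  if (length(dim(hu)) != 3L)
    stop("hu must be a 3-d array", call. = FALSE)
  spacing_mm <- as.numeric(spacing_mm)
  origin_mm <- as.numeric(origin_mm)
  direction <- as.matrix(direction)
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop("spacing_mm must be 3 strictly positive values", call. = FALSE)
  if (length(origin_mm) != 3L || anyNA(origin_mm))
    stop("origin_mm must be a finite length-3 vector", call. = FALSE)
  if (!all(dim(direction) == c(3L, 3L)) ||
      max(abs(crossprod(direction) - diag(3))) > 1e-6)
    stop("direction must be a 3x3 orthonormal matrix", call. = FALSE)
  structure(list(hu = hu, spacing_mm = spacing_mm, origin_mm = origin_mm,
                 direction = direction),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$hu)
  cat(sprintf("<ct_volume> %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3],
              paste(sprintf("%.3f", x$spacing_mm), collapse = " x ")))
  cat(sprintf("  origin (mm): %s\n",
              paste(sprintf("%.2f", x$origin_mm), collapse = ", ")))
  cat(sprintf("  HU range: [%.0f, %.0f]\n", min(x$hu), max(x$hu)))
  invisible(x)
}

#' Volume geometry
#'
#' Extracts the grid geometry (dimensions, spacing, origin, direction) of a
#' `ct_volume` so that masks — plain logical arrays — can be mapped back to
#' world coordinates.
#'
#' @param volume a `ct_volume`, or an object that already is a
#'   `ct_geometry`.
#' @return An object of class `ct_geometry`.
#' @export
volume_geometry <- function(volume) {
  if (inherits(volume, "ct_geometry")) return(volume)
  stopifnot(inherits(volume, "ct_volume"))
  structure(list(dim = dim(volume$hu), spacing_mm = volume$spacing_mm,
                 origin_mm = volume$origin_mm, direction = volume$direction),
            class = "ct_geometry")
}

#' Convert voxel indices to world coordinates
#'
#' @param geometry a `ct_geometry` (or `ct_volume`).
#' @param ijk n x 3 matrix (or length-3 vector) of 0-based voxel indices;
#'   fractional indices are allowed (sub-voxel positions).
#' @return n x 3 matrix of world coordinates in mm.
#' @export
voxel_to_world <- function(geometry, ijk) {
  g <- volume_geometry(geometry)
  if (is.null(dim(ijk))) ijk <- matrix(as.numeric(ijk), 1L)
  ijk <- as.matrix(ijk)
  phys <- sweep(ijk, 2L, g$spacing_mm, "*")
  sweep(phys %*% t(g$direction), 2L, g$origin_mm, "+")
}

#' @rdname voxel_to_world
#' @param xyz n x 3 matrix (or length-3 vector) of world coordinates in mm.
#' @return `world_to_voxel()`: n x 3 matrix of fractional 0-based voxel
#'   indices.
#' @export
world_to_voxel <- function(geometry, xyz) {
  g <- volume_geometry(geometry)
  if (is.null(dim(xyz))) xyz <- matrix(as.numeric(xyz), 1L)
  xyz <- as.matrix(xyz)
  phys <- sweep(xyz, 2L, g$origin_mm, "-") %*% g$direction
  sweep(phys, 2L, g$spacing_mm, "/")
}

# world coordinates of every voxel, as an (nx*ny*nz) x 3 matrix in array
# (column-major) order. Memory-heavy but vectorised; used by the phantom
# renderer and center-of-mass computations.
all_voxel_world_coords <- function(geometry) {
  g <- volume_geometry(geometry)
  d <- g$dim
  i <- rep.int(seq_len(d[1]) - 1L, d[2] * d[3])
  j <- rep.int(rep(seq_len(d[2]) - 1L, each = d[1]), d[3])
  k <- rep(seq_len(d[3]) - 1L, each = d[1] * d[2])
  voxel_to_world(g, cbind(i, j, k))
}

# world coordinates of the voxels where mask is TRUE
mask_world_coords <- function(mask, geometry) {
  g <- volume_geometry(geometry)
  idx <- which(mask)
  if (length(idx) == 0L) return(matrix(numeric(0), 0L, 3L))
  d <- g$dim
  idx0 <- idx - 1L
  i <- idx0 %% d[1]
  j <- (idx0 %/% d[1]) %% d[2]
  k <- idx0 %/% (d[1] * d[2])
  voxel_to_world(g, cbind(i, j, k))
}

voxel_volume_mm3 <- function(geometry) {
  g <- volume_geometry(geometry)
  prod(g$spacing_mm)
}
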