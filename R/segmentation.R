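#' Threshold segmentation
#'
#' Returns the binary mask of voxels whose intensity is at or above the
#' threshold; the standard first step of the analysis (2200 HU for beads and
#' metal, 600 HU for bone).
#'
#' @param volume a [ct_volume()].
#' @param threshold_hu scalar threshold in HU.
#' @return A logical 3-d array on the same grid as `volume`. An empty mask
#'   is allowed; downstream operations decide how to handle it.
#' @export
threshold_segment <- function(volume, threshold_hu) {
  stopifnot(inherits(volume, "ct_volume"), is.numeric(threshold_hu),
            length(threshold_hu) == 1L)
  volume$hu >= threshold_hu
}

#' Bead set
#'
#' A labelled set of fiducial bead centroids in world millimetres, with the
#' segmented voxel volume of each bead. At least 3 non-collinear beads are
#' required for any rigid fit downstream.
#'
#' @param points n x 3 matrix of world coordinates (mm).
#' @param labels unique integer labels.
#' @param volumes_mm3 segmented voxel volume of each bead.
#' @return An object of class `bead_set`.
#' @export
bead_set <- function(points, labels = seq_len(nrow(points)),
                     volumes_mm3 = rep(NA_real_, nrow(points))) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3L)
  labels <- as.integer(labels)
  if (anyDuplicated(labels))
    stop("bead labels must be unique", call. = FALSE)
  structure(list(points = points, labels = labels,
                 volumes_mm3 = as.numeric(volumes_mm3)),
            class = "bead_set")
}

#' @export
print.bead_set <- function(x, ...) {
  cat(sprintf("<bead_set> %d beads\n", nrow(x$points)))
  df <- data.frame(label = x$labels, round(x$points, 4),
                   volume_mm3 = round(x$volumes_mm3, 3))
  names(df)[2:4] <- c("x_mm", "y_mm", "z_mm")
  print(df, row.names = FALSE)
  invisible(x)
}

n_beads <- function(beads) nrow(beads$points)

#' Extract bead centroids from a CT volume
#'
#' Thresholds the volume, labels 26-connected components, keeps components
#' whose voxel volume lies inside `[min_volume_mm3, max_volume_mm3]` (the
#' window that accepts 1-mm tantalum beads and rejects the much larger
#' implant metal), and returns the intensity-weighted centroid of each kept
#' component. The weight of a voxel is `max(HU - threshold, 0)`, which
#' approximates partial-volume sub-voxel localisation; if a component's
#' weights are all zero its unweighted centroid is used. Labels are assigned
#' in deterministic order, sorted by centroid (x, y, z).
#'
#' @param volume a [ct_volume()].
#' @param threshold_hu segmentation threshold (default 2200 HU).
#' @param min_volume_mm3,max_volume_mm3 accepted component volume window
#'   (defaults 0.1 and 2.0 mm^3).
#' @return A [bead_set()].
#' @export
extract_beads <- function(volume, threshold_hu = 2200,
                          min_volume_mm3 = 0.1, max_volume_mm3 = 2.0) {
  stopifnot(inherits(volume, "ct_volume"))
  g <- volume_geometry(volume)
  mask <- threshold_segment(volume, threshold_hu)
  vox_vol <- voxel_volume_mm3(g)
  labels <- .cc_label26(as.vector(mask), as.integer(g$dim))
  n_comp <- attr(labels, "n_components")
  if (n_comp == 0L)
    stop("fewer than 3 beads found (no voxels above threshold); review the ",
         "threshold and bead volume window", call. = FALSE)
  sizes <- tabulate(labels, nbins = n_comp)
  keep <- which(sizes * vox_vol >= min_volume_mm3 &
                  sizes * vox_vol <= max_volume_mm3)
  if (length(keep) < 3L)
    stop(sprintf(
      "fewer than 3 beads found (%d component(s) in the volume window); review the threshold and bead volume window",
      length(keep)), call. = FALSE)

  idx <- which(labels > 0L & labels %in% keep)
  comp <- labels[idx]
  d <- g$dim
  idx0 <- idx - 1L
  ijk <- cbind(idx0 %% d[1], (idx0 %/% d[1]) %% d[2],
               idx0 %/% (d[1] * d[2]))
  xyz <- voxel_to_world(g, ijk)
  w <- pmax(volume$hu[idx] - threshold_hu, 0)

  centroids <- t(vapply(keep, function(k) {
    sel <- comp == k
    wk <- w[sel]
    if (sum(wk) <= 0) wk <- rep(1, sum(sel))
    colSums(xyz[sel, , drop = FALSE] * wk) / sum(wk)
  }, numeric(3)))
  vols <- sizes[keep] * vox_vol
  ord <- order(centroids[, 1], centroids[, 2], centroids[, 3])
  bead_set(centroids[ord, , drop = FALSE],
           labels = seq_along(keep),
           volumes_mm3 = vols[ord])
}

#' Extract surface points from a binary mask
#'
#' Returns the world coordinates of boundary voxels: mask voxels with at
#' least one face-adjacent (6-neighbour) background or out-of-grid
#' neighbour. Optionally subsamples the cloud uniformly with a fixed seed.
#'
#' @param mask logical 3-d array.
#' @param geometry the grid geometry ([volume_geometry()] of the source
#'   volume).
#' @param subsample_fraction keep this fraction of boundary points
#'   (default 1 = all).
#' @param seed seed for the subsampling draw.
#' @return An n x 3 matrix of world coordinates (mm).
#' @export
extract_surface_points <- function(mask, geometry, subsample_fraction = 1,
                                   seed = 1L) {
  if (!any(mask))
    stop("cannot extract surface points from an empty mask", call. = FALSE)
  g <- volume_geometry(geometry)
  d <- dim(mask)
  interior <- array(FALSE, dim = d)
  if (all(d > 2L)) {
    core <- mask[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)] &
      mask[1:(d[1] - 2), 2:(d[2] - 1), 2:(d[3] - 1)] &
      mask[3:d[1], 2:(d[2] - 1), 2:(d[3] - 1)] &
      mask[2:(d[1] - 1), 1:(d[2] - 2), 2:(d[3] - 1)] &
      mask[2:(d[1] - 1), 3:d[2], 2:(d[3] - 1)] &
      mask[2:(d[1] - 1), 2:(d[2] - 1), 1:(d[3] - 2)] &
      mask[2:(d[1] - 1), 2:(d[2] - 1), 3:d[3]]
    interior[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)] <- core
  }
  boundary <- mask & !interior
  pts <- mask_world_coords(boundary, g)
  if (subsample_fraction < 1) {
    n_keep <- max(1L, floor(subsample_fraction * nrow(pts)))
    withr::with_seed(as.integer(seed), {
      pts <- pts[sort(sample.int(nrow(pts), n_keep)), , drop = FALSE]
    })
  }
  pts
}

#' Sub-voxel iso-surface points
#'
#' Like [extract_surface_points()], but each boundary voxel centre is moved
#' onto the HU iso-surface of the threshold by one Newton step along the
#' local intensity gradient (central differences). Boundary-voxel centres
#' are quantised to the grid, and two examinations of the same anatomy on
#' differently-posed grids produce staircase patterns that point-to-point
#' registration can lock onto; iso-surface points remove that quantisation
#' and carry the partial-volume sub-voxel information instead.
#'
#' @param volume a [ct_volume()].
#' @param threshold_hu iso-surface level.
#' @param mask optional logical array restricting the segmentation (defaults
#'   to `hu >= threshold_hu`).
#' @param with_normals if `TRUE`, the unit intensity-gradient directions are
#'   attached as attribute `"normals"` (an n x 3 matrix); surface normals
#'   up to sign.
#' @return An n x 3 matrix of world coordinates (mm).
#' @export
subvoxel_surface_points <- function(volume, threshold_hu, mask = NULL,
                                    with_normals = FALSE) {
  stopifnot(inherits(volume, "ct_volume"))
  g <- volume_geometry(volume)
  if (is.null(mask)) mask <- threshold_segment(volume, threshold_hu)
  if (!any(mask))
    stop("cannot extract surface points from an empty mask", call. = FALSE)
  d <- g$dim
  interior <- array(FALSE, dim = d)
  if (all(d > 2L)) {
    core <- mask[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)] &
      mask[1:(d[1] - 2), 2:(d[2] - 1), 2:(d[3] - 1)] &
      mask[3:d[1], 2:(d[2] - 1), 2:(d[3] - 1)] &
      mask[2:(d[1] - 1), 1:(d[2] - 2), 2:(d[3] - 1)] &
      mask[2:(d[1] - 1), 3:d[2], 2:(d[3] - 1)] &
      mask[2:(d[1] - 1), 2:(d[2] - 1), 1:(d[3] - 2)] &
      mask[2:(d[1] - 1), 2:(d[2] - 1), 3:d[3]]
    interior[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)] <- core
  }
  idx <- which(mask & !interior)
  idx0 <- idx - 1L
  i <- idx0 %% d[1]
  j <- (idx0 %/% d[1]) %% d[2]
  k <- idx0 %/% (d[1] * d[2])
  hu <- volume$hu
  at <- function(ii, jj, kk) hu[1L + ii + d[1] * (jj + d[2] * kk)]
  grad_axis <- function(p, dmax, sp, ii, jj, kk, axis) {
    hi <- pmin(p + 1L, dmax - 1L)
    lo <- pmax(p - 1L, 0L)
    num <- switch(axis,
                  x = at(hi, jj, kk) - at(lo, jj, kk),
                  y = at(ii, hi, kk) - at(ii, lo, kk),
                  z = at(ii, jj, hi) - at(ii, jj, lo))
    num / ((hi - lo) * sp)
  }
  gx <- grad_axis(i, d[1], g$spacing_mm[1], i, j, k, "x")
  gy <- grad_axis(j, d[2], g$spacing_mm[2], i, j, k, "y")
  gz <- grad_axis(k, d[3], g$spacing_mm[3], i, j, k, "z")
  g2 <- gx^2 + gy^2 + gz^2
  hu0 <- hu[idx]
  scale <- ifelse(g2 > 1e-8, (threshold_hu - hu0) / g2, 0)
  shift <- cbind(scale * gx, scale * gy, scale * gz)
  # clamp the Newton step to stay within the voxel neighbourhood
  n_shift <- sqrt(rowSums(shift^2))
  cap <- 0.9 * max(g$spacing_mm)
  too_far <- n_shift > cap
  if (any(too_far))
    shift[too_far, ] <- shift[too_far, , drop = FALSE] *
      (cap / n_shift[too_far])
  centers <- voxel_to_world(g, cbind(i, j, k))
  pts <- centers + shift %*% t(g$direction)
  if (with_normals) {
    gn <- sqrt(pmax(g2, 1e-12))
    normals <- cbind(gx / gn, gy / gn, gz / gn) %*% t(g$direction)
    attr(pts, "normals") <- normals
  }
  pts
}

#' Split beads into bone and implant sets
#'
#' Assigns each bead to the implant if it lies within `clearance_mm` of the
#' implant metal (the largest 26-connected component of `implant_mask`,
#' i.e. the cup), otherwise to the bone. Both sides must end up with at
#' least 3 beads.
#'
#' @param beads a [bead_set()].
#' @param implant_mask logical 3-d array from the metal threshold.
#' @param geometry grid geometry of the mask.
#' @param clearance_mm assignment distance (default 3 mm).
#' @param volume optional source [ct_volume()]; when given together with
#'   `threshold_hu`, bead-to-cup distances are measured against the
#'   sub-voxel iso-surface of the cup instead of boundary-voxel centres,
#'   which removes the grid-quantisation jitter from the clearance
#'   decision.
#' @param threshold_hu metal threshold used for the sub-voxel cup surface.
#' @return A list with elements `bone` and `implant`, both [bead_set()]s
#'   retaining the original labels.
#' @export
split_bone_and_implant <- function(beads, implant_mask, geometry,
                                   clearance_mm = 3.0, volume = NULL,
                                   threshold_hu = NULL) {
  stopifnot(inherits(beads, "bead_set"))
  g <- volume_geometry(geometry)
  if (!any(implant_mask))
    stop("implant mask is empty; cannot locate the cup", call. = FALSE)
  labels <- .cc_label26(as.vector(implant_mask), as.integer(g$dim))
  n_comp <- attr(labels, "n_components")
  sizes <- tabulate(labels, nbins = n_comp)
  cup_label <- which.max(sizes)
  cup_mask <- array(labels == cup_label, dim = g$dim)
  cup_pts <- if (!is.null(volume) && !is.null(threshold_hu)) {
    subvoxel_surface_points(volume, threshold_hu, mask = cup_mask)
  } else {
    extract_surface_points(cup_mask, g)
  }
  nn <- .nn_index(cup_pts, beads$points)
  # a bead centroid sitting inside the cup component is distance zero
  vox <- round(world_to_voxel(g, beads$points))
  inside <- vapply(seq_len(nrow(vox)), function(i) {
    v <- vox[i, ] + 1
    all(v >= 1) && all(v <= g$dim) && cup_mask[v[1], v[2], v[3]]
  }, TRUE)
  dist <- ifelse(inside, 0, nn$dist)
  to_implant <- dist <= clearance_mm
  subset_beads <- function(sel) {
    bead_set(beads$points[sel, , drop = FALSE], beads$labels[sel],
             beads$volumes_mm3[sel])
  }
  bone <- subset_beads(!to_implant)
  implant <- subset_beads(to_implant)
  if (n_beads(bone) < 3L)
    stop(sprintf("only %d bone bead(s) after the split (need >= 3)",
                 n_beads(bone)), call. = FALSE)
  if (n_beads(implant) < 3L)
    stop(sprintf("only %d implant bead(s) after the split (need >= 3)",
                 n_beads(implant)), call. = FALSE)
  list(bone = bone, implant = implant)
}
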