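#' Migration result
#'
#' Six degree-of-freedom implant-versus-bone motion: translations of the
#' implant center of mass (mm) and Cardan rotations (degrees) about axes
#' through the center of mass, together with the registration quality of
#' both bodies and the reporting frame.
#'
#' @param translations_mm length-3 (tx, ty, tz) in mm.
#' @param rotations_deg length-3 (rx, ry, rz) in degrees, each in
#'   (-180, 180\].
#' @param center_of_mass_mm implant center of mass in the reporting frame.
#' @param frame `"dicom"` or `"anatomical"`.
#' @param mode `"beads"`, `"surface"` or `NA` when not produced by the
#'   pipeline.
#' @param quality list with `registration_quality` entries `bone` and
#'   `implant` (either may be `NULL`).
#' @param motion the underlying `rigid_transform` (optional; kept so the
#'   result can be re-expressed in another frame without loss).
#' @param euler_order Cardan sequence used for `rotations_deg`.
#' @param gimbal `TRUE` when the decomposition was near gimbal lock; then
#'   `rotations_alt_deg` carries the alternate-sequence angles.
#' @param rotations_alt_deg alternate-sequence angles (or `NULL`).
#' @param gate quality-gate outcome from [quality_gate()] (or `NULL`).
#' @param id identifier used in result tables.
#' @return An object of class `migration_result`.
#' @export
migration_result <- function(translations_mm, rotations_deg,
                             center_of_mass_mm,
                             frame = c("dicom", "anatomical"),
                             mode = NA_character_,
                             quality = list(bone = NULL, implant = NULL),
                             motion = NULL, euler_order = "xyz",
                             gimbal = FALSE, rotations_alt_deg = NULL,
                             gate = NULL, id = NULL) {
  frame <- match.arg(frame)
  translations_mm <- as.numeric(translations_mm)
  rotations_deg <- as.numeric(rotations_deg)
  stopifnot(length(translations_mm) == 3L, length(rotations_deg) == 3L,
            length(center_of_mass_mm) == 3L)
  if (any(rotations_deg <= -180 | rotations_deg > 180))
    stop("rotations must lie in (-180, 180] degrees", call. = FALSE)
  structure(list(translations_mm = translations_mm,
                 rotations_deg = rotations_deg,
                 center_of_mass_mm = as.numeric(center_of_mass_mm),
                 frame = frame, mode = mode, quality = quality,
                 motion = motion, euler_order = euler_order,
                 gimbal = isTRUE(gimbal),
                 rotations_alt_deg = rotations_alt_deg,
                 gate = gate, id = id),
            class = "migration_result")
}

#' @export
print.migration_result <- function(x, ...) {
  cat(sprintf("<migration_result> frame = %s, mode = %s\n", x$frame,
              x$mode))
  cat(sprintf("  translation (mm):  tx = %+.4f  ty = %+.4f  tz = %+.4f\n",
              x$translations_mm[1], x$translations_mm[2],
              x$translations_mm[3]))
  cat(sprintf("  rotation (deg):    rx = %+.4f  ry = %+.4f  rz = %+.4f\n",
              x$rotations_deg[1], x$rotations_deg[2], x$rotations_deg[3]))
  if (!is.null(x$gate))
    cat(sprintf("  quality gate: %s%s\n",
                if (x$gate$pass) "pass" else "FAIL",
                if (length(x$gate$reasons))
                  paste0(" (", paste(x$gate$reasons, collapse = "; "), ")")
                else ""))
  if (x$gimbal) cat("  NOTE: near gimbal lock; see rotations_alt_deg\n")
  invisible(x)
}

#' Implant motion relative to bone
#'
#' Both inputs map exam-1 world coordinates to exam-2 world coordinates for
#' their body. The relative motion `bone^-1 o implant` expresses the
#' implant's motion in the bone-anchored frame; it is the identity when the
#' two bodies moved together (pure patient repositioning).
#'
#' @param bone,implant `rigid_transform`s of the two bodies.
#' @return The migration `rigid_transform`.
#' @export
relative_motion <- function(bone, implant) {
  rt_compose(rt_inverse(bone), implant)
}

#' Decompose a rigid motion into six degrees of freedom
#'
#' Translations are reported as the displacement of the implant center of
#' mass under the motion; rotations are fixed-frame Cardan angles
#' (x, then y, then z by default) of the rotation part, i.e. rotation about
#' axes through the center of mass. [recompose_6dof()] inverts the
#' decomposition exactly. Decompositions within 0.1 degrees of gimbal lock
#' (|ry| near 90 degrees) are flagged and the alternate sequence is
#' provided.
#'
#' @param motion a `rigid_transform`.
#' @param com center of mass (mm) about which the rotation is reported.
#' @param euler_order `"xyz"` (default) or `"zyx"`.
#' @return A [migration_result()] in the DICOM frame.
#' @export
decompose_6dof <- function(motion, com, euler_order = c("xyz", "zyx")) {
  stopifnot(inherits(motion, "rigid_transform"))
  euler_order <- match.arg(euler_order)
  com <- as.numeric(com)
  stopifnot(length(com) == 3L, all(is.finite(com)))
  translations <- rt_apply(motion, com) - com
  ang <- euler_angles(motion$R, order = euler_order)
  gimbal <- isTRUE(attr(ang, "gimbal"))
  alt <- NULL
  if (gimbal) {
    alt_order <- if (euler_order == "xyz") "zyx" else "xyz"
    alt <- as.numeric(euler_angles(motion$R, order = alt_order))
  }
  migration_result(translations, as.numeric(ang), com, frame = "dicom",
                   motion = motion, euler_order = euler_order,
                   gimbal = gimbal, rotations_alt_deg = alt)
}

#' @rdname decompose_6dof
#' @param result a [migration_result()].
#' @return `recompose_6dof()`: the `rigid_transform` whose decomposition at
#'   the result's center of mass reproduces the result.
#' @export
recompose_6dof <- function(result) {
  stopifnot(inherits(result, "migration_result"))
  if (!is.null(result$motion)) return(result$motion)
  R <- rt_from_euler(result$rotations_deg, order = result$euler_order)$R
  com <- result$center_of_mass_mm
  tr <- com + result$translations_mm - drop(R %*% com)
  rigid_transform(R, tr)
}

#' Center of mass of a binary mask
#'
#' Unweighted mean of the world positions of the mask voxels; used as the
#' reference point about which implant migration is reported.
#'
#' @param mask logical 3-d array (e.g. the implant metal mask).
#' @param geometry grid geometry of the mask.
#' @return Length-3 world coordinates in mm.
#' @export
center_of_mass <- function(mask, geometry) {
  if (!any(mask))
    stop("cannot compute the center of mass of an empty mask",
         call. = FALSE)
  colMeans(mask_world_coords(mask, volume_geometry(geometry)))
}

#' Re-orient a migration result into an anatomical frame
#'
#' Conjugates the motion into a new orthonormal basis (columns of `basis`
#' are the anatomical axes expressed in the DICOM frame) and re-decomposes
#' it, then applies a per-axis sign convention to the reported rotations.
#' This mirrors the clinical step of re-slicing the CT (multi-planar
#' reconstruction) so that the reported axes match the anatomical
#' (radiostereometry-style) frame. With the identity basis and all-positive
#' signs the numeric result is unchanged.
#'
#' @param result a [migration_result()].
#' @param basis 3x3 orthonormal matrix with det +1.
#' @param rotation_signs length-3 vector of +1/-1 applied to the reported
#'   rotations.
#' @return A [migration_result()] in the anatomical frame.
#' @export
reorient <- function(result, basis, rotation_signs = c(1, 1, 1)) {
  stopifnot(inherits(result, "migration_result"))
  basis <- as.matrix(basis)
  if (max(abs(crossprod(basis) - diag(3))) > 1e-9 ||
      abs(det(basis) - 1) > 1e-9)
    stop("basis must be orthonormal with det = +1", call. = FALSE)
  if (!all(rotation_signs %in% c(-1, 1)))
    stop("rotation_signs must be +1 or -1 per axis", call. = FALSE)
  motion <- recompose_6dof(result)
  Q <- basis
  R2 <- t(Q) %*% motion$R %*% Q
  t2 <- drop(t(Q) %*% motion$t)
  com2 <- drop(t(Q) %*% result$center_of_mass_mm)
  dec <- decompose_6dof(rigid_transform(R2, t2), com2,
                        euler_order = result$euler_order)
  migration_result(dec$translations_mm,
                   rotation_signs * dec$rotations_deg,
                   com2, frame = "anatomical", mode = result$mode,
                   quality = result$quality, motion = dec$motion,
                   euler_order = result$euler_order, gimbal = dec$gimbal,
                   rotations_alt_deg =
                     if (is.null(dec$rotations_alt_deg)) NULL
                     else rotation_signs * dec$rotations_alt_deg,
                   gate = result$gate, id = result$id)
}

# drop points whose voxel lies within `margin_voxels` of the grid boundary:
# structures cut by the field of view produce flat patches there that have
# no counterpart in the other exam
trim_boundary_points <- function(pts, geometry, margin_voxels = 2) {
  g <- volume_geometry(geometry)
  idx <- world_to_voxel(g, pts)
  keep <- rowSums(idx < margin_voxels |
                    idx > matrix(g$dim - 1 - margin_voxels, nrow(idx), 3,
                                 byrow = TRUE)) == 0
  subset_cloud(pts, keep)
}

# subset a point cloud, carrying the "normals" attribute along
subset_cloud <- function(pts, keep) {
  normals <- attr(pts, "normals")
  out <- pts[keep, , drop = FALSE]
  if (!is.null(normals))
    attr(out, "normals") <- normals[keep, , drop = FALSE]
  out
}

# surface cloud of the bone, with points near metal removed so that the
# partial-volume halo around the implant (which moves with the implant)
# cannot bias the bone registration
bone_surface_cloud <- function(volume, bone_thr, metal_thr,
                               exclusion_mm = 3) {
  g <- volume_geometry(volume)
  metal <- threshold_segment(volume, metal_thr)
  bone <- volume$hu >= bone_thr & !metal
  if (!any(bone))
    stop("bone mask is empty; check bone_threshold_hu", call. = FALSE)
  pts <- subvoxel_surface_points(volume, bone_thr, mask = bone,
                                 with_normals = TRUE)
  pts <- trim_boundary_points(pts, g)
  if (any(metal)) {
    metal_surf <- extract_surface_points(metal, g)
    nn <- .nn_index(metal_surf, pts)
    pts <- subset_cloud(pts, nn$dist > exclusion_mm)
  }
  if (nrow(pts) < 100L)
    stop("fewer than 100 bone surface points; check bone_threshold_hu",
         call. = FALSE)
  pts
}

largest_component_mask <- function(mask, geometry) {
  g <- volume_geometry(geometry)
  labels <- .cc_label26(as.vector(mask), as.integer(g$dim))
  n_comp <- attr(labels, "n_components")
  if (n_comp == 0L) stop("mask is empty", call. = FALSE)
  sizes <- tabulate(labels, nbins = n_comp)
  array(labels == which.max(sizes), dim = g$dim)
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s': %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full migration analysis on one examination pair
#'
#' Executes the pipeline: threshold segmentation, bead extraction and
#' bone/implant attribution, bone registration (matched beads or bone
#' surface ICP depending on `registration_mode`), implant registration
#' (matched implant beads, falling back to ICP on the cup metal surface
#' when fewer than 3 implant beads survive), relative motion, 6-DOF
#' decomposition about the implant center of mass, and optional
#' re-orientation into the anatomical frame. A quality-gate failure is
#' reported on the result but the result is still returned, matching the
#' report-and-judge clinical workflow; hard errors carry the failing stage
#' name.
#'
#' @param exam1,exam2 [ct_volume()]s of the two examinations.
#' @param config an [analysis_config()].
#' @param id identifier attached to the result.
#' @return A [migration_result()] with `quality`, `gate` and a `log`
#'   attribute describing the stages.
#' @export
run_ctma <- function(exam1, exam2, config = analysis_config(), id = NULL) {
  stopifnot(inherits(exam1, "ct_volume"), inherits(exam2, "ct_volume"),
            inherits(config, "analysis_config"))
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))

  bthr <- config$bone_threshold_hu
  b1 <- bthr[1]
  b2 <- bthr[length(bthr)]
  mthr <- config$metal_threshold_hu
  g1 <- volume_geometry(exam1)
  g2 <- volume_geometry(exam2)

  metal1 <- with_stage("segmentation", threshold_segment(exam1, mthr))
  metal2 <- with_stage("segmentation", threshold_segment(exam2, mthr))
  cup1 <- with_stage("segmentation", largest_component_mask(metal1, g1))
  cup2 <- with_stage("segmentation", largest_component_mask(metal2, g2))

  surf1 <- with_stage("segmentation",
                      bone_surface_cloud(exam1, b1, mthr))
  surf2 <- with_stage("segmentation",
                      bone_surface_cloud(exam2, b2, mthr))
  note("bone surface: %d / %d points", nrow(surf1), nrow(surf2))

  beads_ok <- TRUE
  split1 <- split2 <- NULL
  bead_err <- NULL
  beads_try <- tryCatch({
    beads1 <- extract_beads(exam1, mthr, config$bead_volume_range_mm3[1],
                            config$bead_volume_range_mm3[2])
    beads2 <- extract_beads(exam2, mthr, config$bead_volume_range_mm3[1],
                            config$bead_volume_range_mm3[2])
    split1 <- split_bone_and_implant(beads1, metal1, g1,
                                     config$bead_clearance_mm,
                                     volume = exam1, threshold_hu = mthr)
    split2 <- split_bone_and_implant(beads2, metal2, g2,
                                     config$bead_clearance_mm,
                                     volume = exam2, threshold_hu = mthr)
    TRUE
  }, error = function(e) e)
  if (inherits(beads_try, "error")) {
    beads_ok <- FALSE
    bead_err <- conditionMessage(beads_try)
    note("bead extraction failed: %s", bead_err)
  } else {
    note("beads: %d bone + %d implant (exam 1), %d + %d (exam 2)",
         n_beads(split1$bone), n_beads(split1$implant),
         n_beads(split2$bone), n_beads(split2$implant))
  }

  coarse <- with_stage("coarse alignment", coarse_align(surf1, surf2))

  # the bone surface ICP serves both modes: in surface mode it IS the bone
  # registration; in beads mode it provides a reliable initial alignment
  # for the mutual-nearest-neighbour bead matching
  surf_fit <- with_stage("bone registration (surface)",
    icp_register_plane(surf1, surf2, init = coarse,
                       max_iter = config$icp_max_iter,
                       tol_mm = config$icp_tol_mm,
                       max_target_points = config$icp_max_points,
                       seed = config$seed))
  note("bone surface ICP: RMS %.4f mm, %d iterations",
       surf_fit$quality$mean_error_mm, surf_fit$quality$iterations)

  if (config$registration_mode == "beads") {
    if (!beads_ok)
      stop(sprintf("stage 'bone registration (beads)': %s", bead_err),
           call. = FALSE)
    bone_fit <- with_stage("bone registration (beads)", {
      pairs <- match_beads(split1$bone, split2$bone,
                           init = surf_fit$transform,
                           max_pair_distance_mm =
                             config$match_max_distance_mm)
      ia <- match(pairs$label_a, split1$bone$labels)
      ib <- match(pairs$label_b, split2$bone$labels)
      kabsch_fit(split1$bone$points[ia, , drop = FALSE],
                 split2$bone$points[ib, , drop = FALSE])
    })
    note("bone registration (beads): ME %.4f mm, CN %.1f",
         bone_fit$quality$mean_error_mm, bone_fit$quality$condition_number)
  } else {
    bone_fit <- surf_fit
  }
  T_bone <- bone_fit$transform

  # implant registration follows the "thread and beads" recipe: matched
  # liner beads give the initial rigid fit and the marker-style quality
  # metrics, then point-to-plane ICP on the threaded cup metal surface
  # refines the registration with the cup's much larger lever arm. With
  # fewer than 3 surviving implant beads, the surface ICP alone carries
  # the registration, initialised from the bone transform (migration
  # between double examinations is small).
  implant_beads_usable <- beads_ok &&
    n_beads(split1$implant) >= 3L && n_beads(split2$implant) >= 3L
  bead_pair <- NULL
  if (implant_beads_usable) {
    bead_fit <- with_stage("implant registration (beads)", {
      pairs <- match_beads(split1$implant, split2$implant, init = T_bone,
                           max_pair_distance_mm =
                             config$match_max_distance_mm)
      ia <- match(pairs$label_a, split1$implant$labels)
      ib <- match(pairs$label_b, split2$implant$labels)
      bead_pair <- list(a = split1$implant$points[ia, , drop = FALSE],
                        b = split2$implant$points[ib, , drop = FALSE])
      c(kabsch_fit(bead_pair$a, bead_pair$b), list(pair = bead_pair))
    })
    bead_pair <- bead_fit$pair
    init_implant <- bead_fit$transform
    note("implant bead fit: ME %.4f mm, CN %.1f",
         bead_fit$quality$mean_error_mm, bead_fit$quality$condition_number)
  } else {
    init_implant <- T_bone
    note("implant registration without beads (cup surface only)")
  }
  implant_fit <- with_stage("implant registration (thread surface)", {
    p1 <- subvoxel_surface_points(exam1, mthr, mask = cup1)
    p2 <- subvoxel_surface_points(exam2, mthr, mask = cup2,
                                  with_normals = TRUE)
    icp_register_plane(p1, p2, init = init_implant,
                       max_iter = config$icp_max_iter,
                       tol_mm = config$icp_tol_mm,
                       max_target_points = config$icp_max_points,
                       seed = config$seed, anchors = bead_pair)
  })
  note("implant registration (thread surface ICP): RMS %.4f mm, %d iterations",
       implant_fit$quality$mean_error_mm, implant_fit$quality$iterations)
  if (implant_beads_usable) {
    # marker-style quality at the final pose: bead residuals under the
    # refined transform, spread of the bead configuration
    resid <- rt_apply(implant_fit$transform, bead_pair$a) - bead_pair$b
    implant_fit$quality <- registration_quality(
      sqrt(mean(rowSums(resid^2))), condition_number(bead_pair$a),
      nrow(bead_pair$a), implant_fit$quality$converged,
      implant_fit$quality$iterations)
  }
  T_implant <- implant_fit$transform

  motion <- relative_motion(T_bone, T_implant)
  com <- with_stage("center of mass", center_of_mass(cup1, g1))
  result <- decompose_6dof(motion, com, euler_order = config$euler_order)

  gate_b <- quality_gate(bone_fit$quality, config$cn_max,
                         config$mean_error_max_mm)
  gate_i <- quality_gate(implant_fit$quality, config$cn_max,
                         config$mean_error_max_mm)
  reasons <- c(if (length(gate_b$reasons))
                 paste0("bone: ", gate_b$reasons),
               if (length(gate_i$reasons))
                 paste0("implant: ", gate_i$reasons))
  gate <- list(pass = gate_b$pass && gate_i$pass, reasons = reasons)
  if (!gate$pass)
    note("quality gate FAILED: %s", paste(reasons, collapse = "; "))

  result <- migration_result(result$translations_mm, result$rotations_deg,
                             result$center_of_mass_mm, frame = "dicom",
                             mode = config$registration_mode,
                             quality = list(bone = bone_fit$quality,
                                            implant = implant_fit$quality),
                             motion = motion,
                             euler_order = config$euler_order,
                             gimbal = result$gimbal,
                             rotations_alt_deg = result$rotations_alt_deg,
                             gate = gate, id = id)
  if (config$frame == "anatomical")
    result <- reorient(result, config$anatomical_basis,
                       config$rotation_signs)
  attr(result, "log") <- log
  result
}
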