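#' Digital phantom specification
#'
#' Describes a hip-like digital phantom: a hollow hemispherical "pelvic"
#' bone shell with irregular bumps (so that surface registration has
#' non-degenerate geometry), a threaded metal acetabular cup seated inside
#' it, 1-mm tantalum beads in the bone and in the cup liner, and CT-like
#' noise and streak artefacts. Defaults emulate a clinical micromotion CT
#' protocol: isotropic 0.6-mm voxels, cortical-bone intensities around
#' 900 HU, implant metal around 3000 HU and tantalum beads well above the
#' 2200 HU segmentation threshold.
#'
#' Beads are rasterised as anti-aliased spheres (partial-volume weighting at
#' the surface) so that sub-voxel centroid recovery is meaningfully
#' exercised. Tantalum is far denser than the implant alloy, so beads get
#' their own peak intensity `bead_hu` (default 8000 on an extended HU
#' scale); with a 1-mm bead sampled at 0.6-mm voxels this keeps every bead
#' above the 2200 HU threshold for any sub-voxel placement, which mirrors
#' clinical experience that 1-mm tantalum beads are always visible.
#'
#' @param volume_shape voxels per axis (default 184^3, a ~110-mm field of
#'   view around the acetabulum).
#' @param voxel_spacing_mm voxel spacing, default 0.6 mm isotropic.
#' @param bone_hu,soft_tissue_hu,metal_hu,bead_hu tissue peak intensities.
#' @param bead_diameter_mm tantalum bead diameter (default 1.0).
#' @param n_bone_beads,n_implant_beads bead counts (>= 3 each; defaults 9
#'   and 5, typical marker counts for the pelvis and a cup liner).
#' @param cup_outer_radius_mm outer radius of the metal cup (default 24).
#' @param cup_thread_pitch_mm pitch of the circumferential thread ridges on
#'   the cup (default 2).
#' @param cup_thread_amplitude_mm radial amplitude of the thread ridges.
#' @param noise_sd_hu additive Gaussian noise SD (default 20).
#' @param streak_amplitude_hu amplitude of the radial sinusoidal streak
#'   pattern centred on the cup (default 50).
#' @param seed integer seed; required — the whole phantom is a deterministic
#'   function of (spec, transforms, seed).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(volume_shape = c(184L, 184L, 184L),
                         voxel_spacing_mm = c(0.6, 0.6, 0.6),
                         bone_hu = 900,
                         soft_tissue_hu = 40,
                         metal_hu = 3000,
                         bead_hu = 8000,
                         bead_diameter_mm = 1.0,
                         n_bone_beads = 9L,
                         n_implant_beads = 5L,
                         cup_outer_radius_mm = 24,
                         cup_thread_pitch_mm = 2,
                         cup_thread_amplitude_mm = 0.5,
                         noise_sd_hu = 20,
                         streak_amplitude_hu = 50,
                         seed) {
  if (missing(seed) || !is.numeric(seed))
    stop("seed is required", call. = FALSE)
  volume_shape <- as.integer(volume_shape)
  if (length(volume_shape) != 3L || any(volume_shape < 16L))
    stop("volume_shape must be 3 integers >= 16", call. = FALSE)
  if (any(voxel_spacing_mm <= 0))
    stop("voxel_spacing_mm must be positive", call. = FALSE)
  if (!(metal_hu > 2200 && bead_hu > 2200))
    stop("metal_hu and bead_hu must exceed 2200 HU so the metal threshold ",
         "separates them by construction", call. = FALSE)
  if (!(bone_hu >= 600 && bone_hu < 2200))
    stop("bone_hu must lie in [600, 2200) HU", call. = FALSE)
  if (soft_tissue_hu >= 600)
    stop("soft_tissue_hu must be below 600 HU", call. = FALSE)
  if (n_bone_beads < 3L || n_implant_beads < 3L)
    stop("at least 3 beads are required on each body (rigid fit)",
         call. = FALSE)
  if (noise_sd_hu < 0 || streak_amplitude_hu < 0)
    stop("noise_sd_hu and streak_amplitude_hu must be >= 0", call. = FALSE)
  if (cup_outer_radius_mm < 8)
    stop("cup_outer_radius_mm must be >= 8 mm", call. = FALSE)
  structure(list(
    volume_shape = volume_shape,
    voxel_spacing_mm = as.numeric(voxel_spacing_mm),
    bone_hu = bone_hu, soft_tissue_hu = soft_tissue_hu,
    metal_hu = metal_hu, bead_hu = bead_hu,
    bead_diameter_mm = bead_diameter_mm,
    n_bone_beads = as.integer(n_bone_beads),
    n_implant_beads = as.integer(n_implant_beads),
    cup_outer_radius_mm = cup_outer_radius_mm,
    cup_thread_pitch_mm = cup_thread_pitch_mm,
    cup_thread_amplitude_mm = cup_thread_amplitude_mm,
    noise_sd_hu = noise_sd_hu,
    streak_amplitude_hu = streak_amplitude_hu,
    seed = as.integer(seed)), class = "phantom_spec")
}

# geometry derived from the spec; all radii in mm, scene centred at the
# world origin with the cup/bone hemisphere opening towards -z
phantom_geometry <- function(spec) {
  cup_outer <- spec$cup_outer_radius_mm
  cup_inner <- cup_outer - 2.5
  bone_inner <- cup_outer + 2
  bone_outer <- bone_inner + 7
  bump_radius <- 0.22 * bone_outer
  # a few large protrusions at fixed asymmetric directions plus many small
  # seeded bumps: real pelvic bone is highly irregular (ridges, spines,
  # foramina), and a smooth hemisphere would leave surface registration
  # rotationally under-constrained
  bump_dirs <- rbind(c(0.80, 0.15, 0.58), c(-0.45, 0.70, 0.55),
                     c(-0.30, -0.85, 0.43), c(0.20, -0.30, 0.93))
  bump_dirs <- bump_dirs / sqrt(rowSums(bump_dirs^2))
  bump_center_r <- bone_outer - 0.5 * bump_radius
  small_seed <- as.integer((as.double(spec$seed) * 2654435 + 11) %%
                             2147483647)
  withr::with_seed(small_seed, {
    n_small <- 30L
    sd_ <- matrix(stats::rnorm(3L * n_small), n_small, 3L)
    sd_[, 3] <- abs(sd_[, 3]) + 0.05
    sd_ <- sd_ / sqrt(rowSums(sd_^2))
    small_radius <- stats::runif(n_small, 1.5, 4)
  })
  small_center_r <- bone_outer - 0.4 * small_radius
  bumps <- list(
    centers = rbind(bump_dirs * bump_center_r, sd_ * small_center_r),
    radii = c(rep(bump_radius, nrow(bump_dirs)), small_radius))
  hole_dirs <- rbind(c(0.55, 0.25, 0.80), c(-0.60, 0.45, 0.66),
                     c(0.05, -0.70, 0.71))
  hole_dirs <- hole_dirs / sqrt(rowSums(hole_dirs^2))
  list(cup_outer = cup_outer, cup_inner = cup_inner,
       hole_centers = hole_dirs * (cup_inner + cup_outer) / 2,
       hole_radius = 0.16 * cup_outer,
       bone_inner = bone_inner, bone_outer = bone_outer,
       bump_centers = bumps$centers,
       bump_radii = bumps$radii,
       scene_extent = max(sqrt(rowSums(bumps$centers^2)) + bumps$radii),
       bone_bead_r = c(bone_inner + 2.5, bone_outer - 1),
       implant_bead_r = cup_inner - 2.5)
}

# quasi-uniform directions on the upper hemisphere with minimum angular
# separation (greedy rejection under the current RNG stream); directions
# within `avoid_angle_deg` of any `avoid` direction are rejected too
sample_directions <- function(n, min_z, min_angle_deg, avoid = NULL,
                              avoid_angle_deg = 0) {
  dirs <- matrix(numeric(0), 0L, 3L)
  cos_min <- cos(min_angle_deg * pi / 180)
  cos_avoid <- cos(avoid_angle_deg * pi / 180)
  tries <- 0L
  while (nrow(dirs) < n) {
    tries <- tries + 1L
    if (tries > 20000L)
      stop("could not place beads with the requested separation",
           call. = FALSE)
    v <- random_unit_vector()
    if (v[3] < min_z) next
    if (!is.null(avoid) && any(avoid %*% v > cos_avoid)) next
    if (nrow(dirs) > 0L && any(dirs %*% v > cos_min)) next
    dirs <- rbind(dirs, v)
  }
  dirs
}

# bead centres in the canonical (exam-1) scene frame
phantom_bead_layout <- function(spec) {
  geo <- phantom_geometry(spec)
  withr::with_seed(spec$seed, {
    bone_dirs <- sample_directions(spec$n_bone_beads, 0.12, 18)
    bone_r <- stats::runif(spec$n_bone_beads, geo$bone_bead_r[1],
                           geo$bone_bead_r[2])
    bone <- bone_dirs * bone_r
    # liner beads stay clear of the shell screw holes: a bead under a hole
    # has no metal directly above it, which would confuse the
    # clearance-based bone/implant attribution downstream
    hole_dirs <- geo$hole_centers /
      sqrt(rowSums(geo$hole_centers^2))
    hole_half_angle <- asin(min(1, geo$hole_radius /
                                  sqrt(sum(geo$hole_centers[1, ]^2)))) *
      180 / pi
    imp_dirs <- sample_directions(spec$n_implant_beads, 0.25, 28,
                                  avoid = hole_dirs,
                                  avoid_angle_deg = hole_half_angle + 7)
    implant <- imp_dirs * geo$implant_bead_r
  })
  list(bone = bone, implant = implant)
}

# anti-aliased coverage from a signed distance (negative = inside)
aa_coverage <- function(d, h) pmin(1, pmax(0, 0.5 - d / h))

# signed distance helpers; X is an n x 3 coordinate matrix
dist_shell_hemisphere <- function(X, r_inner, r_outer) {
  r <- sqrt(rowSums(X^2))
  rc <- (r_inner + r_outer) / 2
  pmax(abs(r - rc) - (r_outer - r_inner) / 2, -X[, 3])
}

dist_sphere <- function(X, center, radius) {
  dx <- X[, 1] - center[1]
  dy <- X[, 2] - center[2]
  dz <- X[, 3] - center[3]
  sqrt(dx * dx + dy * dy + dz * dz) - radius
}

# voxels within the axis-aligned bounding box of a sphere (plus the
# anti-aliasing margin); restricting the per-sphere work to this subset
# keeps rendering cost linear in structure size, not volume size
sphere_bbox_sel <- function(X, center, radius, h) {
  m <- radius + 2 * h
  which(abs(X[, 1] - center[1]) < m & abs(X[, 2] - center[2]) < m &
          abs(X[, 3] - center[3]) < m)
}

local_min_sphere <- function(d, X, center, radius, h) {
  sel <- sphere_bbox_sel(X, center, radius, h)
  if (length(sel))
    d[sel] <- pmin(d[sel],
                   dist_sphere(X[sel, , drop = FALSE], center, radius))
  d
}

local_blend_sphere <- function(hu, X, center, radius, value, h) {
  sel <- sphere_bbox_sel(X, center, radius, h)
  if (length(sel)) {
    f <- aa_coverage(dist_sphere(X[sel, , drop = FALSE], center, radius), h)
    hu[sel] <- hu[sel] * (1 - f) + value * f
  }
  hu
}

dist_cup <- function(X, geo, pitch, amp) {
  r <- sqrt(rowSums(X^2))
  # helical thread, advancing with azimuth like a real screw thread
  phase <- 2 * pi * X[, 3] / pitch - atan2(X[, 2], X[, 1])
  outer_eff <- geo$cup_outer + amp * sin(phase)
  d <- pmax(pmax(geo$cup_inner - r, r - outer_eff), -X[, 3])
  # screw holes through the shell at asymmetric positions: like a clinical
  # shell they break the (near-)screw symmetry of the threaded hemisphere,
  # so that surface-only implant registration can resolve all 6 DOF
  for (j in seq_len(nrow(geo$hole_centers)))
    d <- pmax(d, -dist_sphere(X, geo$hole_centers[j, ], geo$hole_radius))
  d
}

# composite one exam; Tb / Ti transform the bone / implant body from the
# canonical scene frame into this exam's world frame
render_phantom_exam <- function(spec, geom, world, beads, Tb, Ti,
                                exam_index) {
  geo <- phantom_geometry(spec)
  h <- mean(spec$voxel_spacing_mm)
  n <- nrow(world)
  hu <- rep(spec$soft_tissue_hu, n)

  blend <- function(hu, f, value) hu * (1 - f) + value * f

  # bone body, evaluated in canonical coordinates
  Xb <- rt_apply(rt_inverse(Tb), world)
  d_bone <- dist_shell_hemisphere(Xb, geo$bone_inner, geo$bone_outer)
  for (b in seq_along(geo$bump_radii))
    d_bone <- local_min_sphere(d_bone, Xb, geo$bump_centers[b, ],
                               geo$bump_radii[b], h)
  hu <- blend(hu, aa_coverage(d_bone, h), spec$bone_hu)

  # implant body (metal cup with thread)
  Xi <- rt_apply(rt_inverse(Ti), world)
  d_cup <- dist_cup(Xi, geo, spec$cup_thread_pitch_mm,
                    spec$cup_thread_amplitude_mm)
  hu <- blend(hu, aa_coverage(d_cup, h), spec$metal_hu)

  # beads last so they are never overwritten
  bead_r <- spec$bead_diameter_mm / 2
  for (i in seq_len(nrow(beads$bone)))
    hu <- local_blend_sphere(hu, Xb, beads$bone[i, ], bead_r,
                             spec$bead_hu, h)
  for (i in seq_len(nrow(beads$implant)))
    hu <- local_blend_sphere(hu, Xi, beads$implant[i, ], bead_r,
                             spec$bead_hu, h)

  n_metal <- sum(hu >= 2200)
  n_bone_or_metal <- sum(hu >= 600)

  # streak artefacts: a radial sinusoid in azimuth about the cup, fixed to
  # the scanner frame (like real metal streaks, the pattern does not move
  # with the patient). The amplitude decays quickly beyond the cup radius:
  # streaks are a local phenomenon around the metal, and a coherent
  # corrugation across the whole bone would be both unphysical and a
  # systematic trap for surface registration.
  if (spec$streak_amplitude_hu > 0) {
    cc <- rt_apply(Ti, c(0, 0, 0))
    dx <- world[, 1] - cc[1]
    dy <- world[, 2] - cc[2]
    rho <- sqrt(dx * dx + dy * dy + (world[, 3] - cc[3])^2)
    phi <- atan2(dy, dx)
    decay <- exp(-pmax(rho - geo$cup_outer, 0) / (0.25 * geo$cup_outer))
    hu <- hu + spec$streak_amplitude_hu * sin(8 * phi) * decay
  }

  if (spec$noise_sd_hu > 0) {
    noise_seed <- as.integer((as.double(spec$seed) * 7919 +
                                exam_index * 104729) %% 2147483647)
    withr::with_seed(noise_seed, {
      hu <- hu + stats::rnorm(n, sd = spec$noise_sd_hu)
    })
  }

  list(hu = hu, n_metal = n_metal, n_bone_or_metal = n_bone_or_metal)
}

#' Generate a double-examination phantom pair
#'
#' Renders two CT volumes of the same scene. In exam 1 both bodies are in
#' the canonical pose. In exam 2 the whole scene is moved by `repositioning`
#' (the patient lying differently in the scanner) and the implant is
#' additionally moved by `migration` relative to the bone, i.e. the implant
#' body is at `repositioning o migration`. The returned ground truth records
#' the exact bead coordinates of both exams, so
#' `implant beads (exam 2) = repositioning(migration(implant beads (exam 1)))`
#' holds to numerical precision.
#'
#' Identical `(spec, migration, repositioning)` always yield bit-identical
#' volumes. Exam 2 is rendered analytically at the transformed poses rather
#' than by resampling exam 1, so the two exams have independent
#' partial-volume sampling — the property that makes double examinations
#' informative.
#'
#' @param spec a [phantom_spec()].
#' @param migration implant-versus-bone migration, a `rigid_transform`
#'   (identity by default).
#' @param repositioning whole-scene transform between the exams (identity by
#'   default); see [sample_repositioning()].
#' @return A list with elements `exam1`, `exam2` (both [ct_volume()]) and
#'   `truth` (class `ctma_ground_truth`).
#' @export
generate_phantom_pair <- function(spec, migration = rt_identity(),
                                  repositioning = rt_identity()) {
  stopifnot(inherits(spec, "phantom_spec"),
            inherits(migration, "rigid_transform"),
            inherits(repositioning, "rigid_transform"))
  geo <- phantom_geometry(spec)
  beads <- phantom_bead_layout(spec)
  d <- spec$volume_shape
  sp <- spec$voxel_spacing_mm
  origin <- -(d - 1) * sp / 2
  geom <- structure(list(dim = d, spacing_mm = sp, origin_mm = origin,
                         direction = diag(3)), class = "ct_geometry")

  Ti2 <- rt_compose(repositioning, migration)

  # field-of-view check: every bead and the whole cup must stay inside the
  # grid with a small margin in both exams
  bead_r <- spec$bead_diameter_mm / 2
  margin <- bead_r + max(sp)
  lo <- origin - sp / 2 + margin
  hi <- origin + (d - 1) * sp + sp / 2 - margin
  check_inside <- function(pts, what) {
    bad <- sweep(pts, 2, lo, "<") | sweep(pts, 2, hi, ">")
    if (any(bad)) {
      ax <- c("x", "y", "z")[which(bad, arr.ind = TRUE)[1, 2]]
      stop(sprintf(
        "%s leaves the field of view along %s (allowed [%.1f, %.1f] mm); reduce the migration/repositioning or enlarge volume_shape",
        what, ax, lo[which(ax == c("x", "y", "z"))],
        hi[which(ax == c("x", "y", "z"))]), call. = FALSE)
    }
  }
  cup_extent <- geo$cup_outer + spec$cup_thread_amplitude_mm
  ball_probe <- function(extent) {
    rbind(c(extent, 0, 0), c(-extent, 0, 0), c(0, extent, 0),
          c(0, -extent, 0), c(0, 0, extent), c(0, 0, -extent))
  }
  # the whole bone (shell + bumps) must stay inside the grid: a clipped
  # bone surface would leave spurious flat patches that bias surface
  # registration, and clipping differs between the two exams
  check_inside(beads$bone, "bone bead set (exam 1)")
  check_inside(beads$implant, "implant bead set (exam 1)")
  check_inside(ball_probe(cup_extent), "implant cup (exam 1)")
  check_inside(ball_probe(geo$scene_extent), "bone surface (exam 1)")
  check_inside(rt_apply(repositioning, beads$bone),
               "bone bead set (exam 2)")
  check_inside(rt_apply(Ti2, beads$implant), "implant bead set (exam 2)")
  check_inside(rt_apply(Ti2, ball_probe(cup_extent)),
               "implant cup (exam 2)")
  check_inside(rt_apply(repositioning, ball_probe(geo$scene_extent)),
               "bone surface (exam 2)")

  world <- all_voxel_world_coords(geom)
  e1 <- render_phantom_exam(spec, geom, world, beads, rt_identity(),
                            rt_identity(), 1L)
  e2 <- render_phantom_exam(spec, geom, world, beads, repositioning, Ti2,
                            2L)

  vol1 <- ct_volume(array(e1$hu, dim = d), sp, origin)
  vol2 <- ct_volume(array(e2$hu, dim = d), sp, origin)

  truth <- structure(list(
    migration = migration,
    repositioning = repositioning,
    bone_beads = list(exam1 = beads$bone,
                      exam2 = rt_apply(repositioning, beads$bone)),
    implant_beads = list(exam1 = beads$implant,
                         exam2 = rt_apply(Ti2, beads$implant)),
    bead_radius_mm = bead_r,
    clean_voxel_counts = list(
      exam1 = list(metal = e1$n_metal, bone_or_metal = e1$n_bone_or_metal),
      exam2 = list(metal = e2$n_metal, bone_or_metal = e2$n_bone_or_metal)),
    spec = spec), class = "ctma_ground_truth")

  list(exam1 = vol1, exam2 = vol2, truth = truth)
}

#' Export phantom ground truth
#'
#' `write_ground_truth()` stores the transforms as JSON (rotation row-major
#' plus translation in mm); `write_bead_csv()` stores the analytic bead
#' coordinates with columns `exam, structure, label, x_mm, y_mm, z_mm`.
#'
#' @param truth a `ctma_ground_truth` from [generate_phantom_pair()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ctma_ground_truth"))
  jsonlite::write_json(list(
    migration = rt_to_list(truth$migration),
    repositioning = rt_to_list(truth$repositioning),
    bead_radius_mm = truth$bead_radius_mm,
    clean_voxel_counts = truth$clean_voxel_counts),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
write_bead_csv <- function(truth, path) {
  stopifnot(inherits(truth, "ctma_ground_truth"))
  one <- function(mat, exam, structure_) {
    if (nrow(mat) == 0L) return(NULL)
    data.frame(exam = exam, structure = structure_,
               label = seq_len(nrow(mat)),
               x_mm = mat[, 1], y_mm = mat[, 2], z_mm = mat[, 3])
  }
  df <- rbind(one(truth$bone_beads$exam1, 1L, "bone"),
              one(truth$implant_beads$exam1, 1L, "implant"),
              one(truth$bone_beads$exam2, 2L, "bone"),
              one(truth$implant_beads$exam2, 2L, "implant"))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @return `read_bead_csv()`: a data.frame with the bead table.
#' @export
read_bead_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("exam", "structure", "label", "x_mm", "y_mm", "z_mm")
  if (!all(needed %in% names(df)))
    stop(sprintf("bead CSV %s lacks columns: %s", path,
                 paste(setdiff(needed, names(df)), collapse = ", ")),
         call. = FALSE)
  df
}
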