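make_volume <- function(hu_fun, dims = c(40L, 40L, 40L), sp = 0.6,
                        origin = NULL) {
  sp <- rep(sp, 3)
  if (is.null(origin)) origin <- -(dims - 1) * sp / 2
  g <- structure(list(dim = dims, spacing_mm = sp, origin_mm = origin,
                      direction = diag(3)), class = "ct_geometry")
  xyz <- ctmotion:::all_voxel_world_coords(g)
  ct_volume(array(hu_fun(xyz), dims), sp, origin)
}

aa_sphere_hu <- function(centers, radius = 0.5, peak = 8000, bg = 40,
                         h = 0.6) {
  function(xyz) {
    hu <- rep(bg, nrow(xyz))
    for (i in seq_len(nrow(centers))) {
      d <- sqrt(rowSums(sweep(xyz, 2, centers[i, ])^2)) - radius
      f <- pmin(1, pmax(0, 0.5 - d / h))
      hu <- hu * (1 - f) + peak * f
    }
    hu
  }
}

test_that("threshold_segment matches the definition", {
  v <- make_volume(function(xyz) rep(700, nrow(xyz)), dims = c(8L, 8L, 8L))
  expect_true(all(threshold_segment(v, 600)))
  expect_false(any(threshold_segment(v, 2200)))
})

test_that("bead centroids are recovered to sub-voxel accuracy", {
  centers <- rbind(c(10.3, 20.7, 30.1), c(4.1, 25.3, 27.9),
                   c(15.8, 18.2, 34.4))
  v <- make_volume(aa_sphere_hu(centers), dims = c(80L, 80L, 96L),
                   origin = c(0, 0, 0))
  beads <- extract_beads(v)
  expect_identical(nrow(beads$points), 3L)
  # labels are sorted by centroid, so match by nearest truth
  for (i in seq_len(3)) {
    errs <- sqrt(rowSums(sweep(centers, 2, beads$points[i, ])^2))
    expect_lt(min(errs), 0.1)
  }
  expect_true(all(beads$volumes_mm3 > 0.1 & beads$volumes_mm3 < 2))
})

test_that("bead extraction errors and the size window behave as specified", {
  v <- make_volume(function(xyz) rep(40, nrow(xyz)), dims = c(8L, 8L, 8L))
  expect_error(extract_beads(v), "fewer than 3 beads")

  # two small spheres plus one large metal blob: the size window keeps
  # exactly the 2 beads
  centers <- rbind(c(-8, -8, -8), c(8, 8, 8))
  big <- function(xyz) {
    hu <- aa_sphere_hu(centers)(xyz)
    d <- sqrt(rowSums(xyz^2)) - 5     # 5-mm metal blob, ~520 mm^3
    f <- pmin(1, pmax(0, 0.5 - d / 0.6))
    hu * (1 - f) + 3000 * f
  }
  v2 <- make_volume(big)
  mask <- threshold_segment(v2, 2200)
  labels <- ctmotion:::.cc_label26(as.vector(mask), dim(mask))
  expect_identical(attr(labels, "n_components"), 3L)
  expect_error(extract_beads(v2), "fewer than 3")  # only 2 pass the window
})

test_that("centroid extraction is translation-equivariant", {
  centers <- rbind(c(-6, -5, -4), c(5, 6, 4), c(0, 2, 6))
  v1 <- make_volume(aa_sphere_hu(centers))
  delta <- c(10.25, -3.5, 7.125)
  v2 <- ct_volume(v1$hu, v1$spacing_mm, v1$origin_mm + delta)
  b1 <- extract_beads(v1)
  b2 <- extract_beads(v2)
  expect_lt(max(abs(sweep(b2$points - b1$points, 2, delta))), 1e-9)
})

test_that("surface extraction matches the closed-form cube count", {
  mask <- array(FALSE, c(14L, 14L, 14L))
  mask[3:12, 3:12, 3:12] <- TRUE  # solid 10^3 cube
  g <- structure(list(dim = c(14L, 14L, 14L), spacing_mm = c(1, 1, 1),
                      origin_mm = c(0, 0, 0), direction = diag(3)),
                 class = "ct_geometry")
  pts <- extract_surface_points(mask, g)
  expect_identical(nrow(pts), 6L * 100L - 12L * 10L + 8L)  # 488

  single <- array(FALSE, c(3L, 3L, 3L))
  single[2, 2, 2] <- TRUE
  expect_identical(nrow(extract_surface_points(single, g = structure(
    list(dim = c(3L, 3L, 3L), spacing_mm = c(1, 1, 1),
         origin_mm = c(0, 0, 0), direction = diag(3)),
    class = "ct_geometry"))), 1L)

  expect_identical(nrow(extract_surface_points(mask, g,
                                               subsample_fraction = 1)),
                   488L)
  expect_identical(nrow(extract_surface_points(mask, g,
                                               subsample_fraction = 0.5,
                                               seed = 1)), 244L)
  expect_error(extract_surface_points(array(FALSE, c(3, 3, 3)), g),
               "empty mask")
})

test_that("sub-voxel iso-surface points sit on the true sphere surface", {
  center <- c(0.2, -0.35, 0.15)
  v <- make_volume(aa_sphere_hu(matrix(center, 1), radius = 10,
                                peak = 900), dims = c(48L, 48L, 48L))
  pts <- subvoxel_surface_points(v, 600, with_normals = TRUE)
  r <- sqrt(rowSums(sweep(pts, 2, center)^2))
  dev <- abs(r - mean(r))
  rms_iso <- sqrt(mean(dev^2))
  # reference: the voxel-centre boundary cloud of the same mask
  ctr <- extract_surface_points(threshold_segment(v, 600),
                                volume_geometry(v))
  rc <- sqrt(rowSums(sweep(ctr, 2, center)^2))
  rms_ctr <- sqrt(mean((rc - mean(rc))^2))
  # the Newton step cannot beat the 0.6-mm ramp sampling entirely, but it
  # must reconstruct the sphere markedly more tightly than the
  # grid-quantised cloud and stay well under a quarter voxel; its real
  # value for registration is that the residual is incoherent with the
  # grid phase rather than a staircase pattern
  expect_lt(rms_iso, 0.75 * rms_ctr)
  expect_lt(rms_iso, 0.15)
  expect_lt(max(dev), 0.3)
  normals <- attr(pts, "normals")
  expect_equal(dim(normals), dim(pts))
  expect_lt(max(abs(sqrt(rowSums(normals^2)) - 1)), 1e-9)
})

test_that("bone/implant split matches ground truth on the phantom", {
  spec <- small_spec(21)
  pair <- generate_phantom_pair(spec)
  v <- pair$exam1
  g <- volume_geometry(v)
  metal <- threshold_segment(v, 2200)
  beads <- extract_beads(v)
  split <- split_bone_and_implant(beads, metal, g, 3,
                                  volume = v, threshold_hu = 2200)
  expect_identical(nrow(split$bone$points), spec$n_bone_beads)
  expect_identical(nrow(split$implant$points), spec$n_implant_beads)
  # every recovered implant bead is within 0.1 mm of a true implant bead
  for (i in seq_len(nrow(split$implant$points))) {
    d <- sqrt(rowSums(sweep(pair$truth$implant_beads$exam1, 2,
                            split$implant$points[i, ])^2))
    expect_lt(min(d), 0.1)
  }
  # a clearance that swallows every bead leaves the bone side empty
  expect_error(split_bone_and_implant(beads, metal, g, 1e4),
               "bone bead")
  # clearance 0 leaves the implant side empty (disjoint geometry)
  expect_error(split_bone_and_implant(beads, metal, g, 0),
               "implant bead")
})
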