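test_that("relative_motion composes as specified", {
  G <- random_rigid(41)
  expect_lt(max(rt_discrepancy(relative_motion(G, G), rt_identity())),
            1e-12)

  tr <- rigid_transform(diag(3), c(0.2, 0, 0))
  expect_lt(max(rt_discrepancy(relative_motion(rt_identity(), tr), tr)),
            1e-12)

  # point-wise oracle: bone^-1(implant(x)) on 100 random points
  bone <- random_rigid(42)
  implant <- random_rigid(43)
  withr::with_seed(44, pts <- matrix(stats::rnorm(300, sd = 30), 100, 3))
  rel <- relative_motion(bone, implant)
  direct <- rt_apply(rel, pts)
  oracle <- rt_apply(rt_inverse(bone), rt_apply(implant, pts))
  expect_lt(max(abs(direct - oracle)), 1e-9)
})

test_that("decompose_6dof handles axis-aligned cases and round-trips", {
  z <- decompose_6dof(rt_identity(), c(5, 5, 5))
  expect_identical(max(abs(c(z$translations_mm, z$rotations_deg))), 0)

  rot5 <- decompose_6dof(rt_from_euler(c(0, 0, 5)), c(0, 0, 0))
  expect_lt(max(abs(rot5$translations_mm)), 1e-12)
  expect_equal(rot5$rotations_deg, c(0, 0, 5), tolerance = 1e-9)

  # 500 random transforms: decompose -> recompose discrepancy < 1e-9
  withr::with_seed(45, {
    for (i in 1:500) {
      T1 <- rigid_transform(
        ctmotion:::rotation_about_axis(stats::rnorm(3), stats::runif(1, -170, 170)),
        stats::rnorm(3, sd = 5))
      com <- stats::rnorm(3, sd = 20)
      dec <- decompose_6dof(T1, com)
      rebuilt <- rigid_transform(
        rt_from_euler(dec$rotations_deg, order = dec$euler_order)$R,
        com + dec$translations_mm -
          drop(rt_from_euler(dec$rotations_deg,
                             order = dec$euler_order)$R %*% com))
      if (!dec$gimbal)
        expect_lt(max(rt_discrepancy(rebuilt, T1)), 1e-9)
    }
  })

  near_gimbal <- decompose_6dof(rt_from_euler(c(10, 89.95, 20)), c(0, 0, 0))
  expect_true(near_gimbal$gimbal)
  expect_identical(length(near_gimbal$rotations_alt_deg), 3L)
})

test_that("center_of_mass matches single-voxel, symmetry and linearity", {
  g <- structure(list(dim = c(9L, 9L, 9L), spacing_mm = c(1, 1, 1),
                      origin_mm = c(0, 0, 0), direction = diag(3)),
                 class = "ct_geometry")
  single <- array(FALSE, c(9L, 9L, 9L))
  single[2, 3, 4] <- TRUE
  expect_equal(center_of_mass(single, g), c(1, 2, 3), tolerance = 1e-12)

  two <- single
  two[8, 7, 6] <- TRUE
  expect_equal(center_of_mass(two, g), c(4, 4, 4), tolerance = 1e-12)

  # hemispherical shell: center of mass on the symmetry axis
  gs <- structure(list(dim = c(41L, 41L, 41L), spacing_mm = c(1, 1, 1),
                       origin_mm = c(-20, -20, -20), direction = diag(3)),
                  class = "ct_geometry")
  xyz <- ctmotion:::all_voxel_world_coords(gs)
  r <- sqrt(rowSums(xyz^2))
  shell <- array(r >= 12 & r <= 16 & xyz[, 3] >= 0, c(41L, 41L, 41L))
  com <- center_of_mass(shell, gs)
  expect_lt(max(abs(com[1:2])), 1e-6)

  expect_error(center_of_mass(array(FALSE, c(3, 3, 3)), g), "empty")
})

test_that("reorient conjugates the motion and respects sign conventions", {
  motion <- rt_from_euler(c(0.8, -0.4, 1.2), c(0.5, -0.3, 0.2))
  com <- c(10, -5, 20)
  res <- decompose_6dof(motion, com)

  same <- reorient(res, diag(3), c(1, 1, 1))
  expect_equal(same$translations_mm, res$translations_mm,
               tolerance = 1e-12)
  expect_equal(same$rotations_deg, res$rotations_deg, tolerance = 1e-12)
  expect_identical(same$frame, "anatomical")

  # a swap of x and y axes permutes the reported translation
  swap <- matrix(c(0, 1, 0, 1, 0, 0, 0, 0, -1), 3, 3)
  expect_equal(det(swap), 1, tolerance = 1e-12)
  pure_t <- decompose_6dof(rigid_transform(diag(3), c(1, 0, 0)),
                           c(0, 0, 0))
  swapped <- reorient(pure_t, swap)
  expect_equal(swapped$translations_mm, c(0, 1, 0), tolerance = 1e-12)

  # commuting-diagram oracle: transforming raw points into the new basis
  # first yields the identical 6-DOF output
  Q <- ctmotion:::rotation_about_axis(c(1, 2, 0.5), 33)
  re <- reorient(res, Q)
  motion_prime <- rigid_transform(t(Q) %*% motion$R %*% Q,
                                  drop(t(Q) %*% motion$t))
  res_prime <- decompose_6dof(motion_prime, drop(t(Q) %*% com))
  expect_lt(max(abs(re$translations_mm - res_prime$translations_mm)), 1e-9)
  expect_lt(max(abs(re$rotations_deg - res_prime$rotations_deg)), 1e-9)

  # sign flips apply to the reported rotations
  fl <- reorient(res, diag(3), c(-1, 1, -1))
  expect_equal(fl$rotations_deg, res$rotations_deg * c(-1, 1, -1),
               tolerance = 1e-12)

  expect_error(reorient(res, diag(c(-1, 1, 1))), "det")
})

test_that("run_ctma on one phantom pair recovers the migration (both modes)", {
  spec <- small_spec(46)
  mig <- rt_from_euler(c(0, 0, 1), c(0.5, 0, 0))
  repo <- sample_repositioning(3, 2, seed = 47)
  pair <- generate_phantom_pair(spec, mig, repo)

  # tolerances scaled to the reduced unit-test phantom: its 14-mm cup has
  # roughly half the clinical bead lever arm, so rotation noise is about
  # twice that of the clinical-scale acceptance phantom (which is held to
  # 0.1 mm / 0.3 deg in test-acceptance.R)
  for (mode in c("beads", "surface")) {
    res <- run_ctma(pair$exam1, pair$exam2,
                    analysis_config(registration_mode = mode), id = mode)
    err <- max_abs_6dof_error(res, mig)
    expect_lt(err["t"], 0.15)
    expect_lt(err["r"], 0.6)
    expect_identical(res$mode, mode)
    expect_identical(res$frame, "dicom")
    expect_s3_class(res$quality$bone, "registration_quality")
    expect_s3_class(res$quality$implant, "registration_quality")
  }

  # identical volume twice: exactly zero in all six degrees of freedom
  res0 <- run_ctma(pair$exam1, pair$exam1, analysis_config())
  expect_lt(max(abs(c(res0$translations_mm, res0$rotations_deg))), 1e-9)

  # anatomical frame request is honoured
  basis <- ctmotion:::rotation_about_axis(c(0, 0, 1), 90)
  resa <- run_ctma(pair$exam1, pair$exam2,
                   analysis_config(frame = "anatomical",
                                   anatomical_basis = basis,
                                   rotation_signs = c(1, -1, 1)))
  expect_identical(resa$frame, "anatomical")

  # stage names propagate in errors
  empty <- ct_volume(array(0, dim(pair$exam1$hu)), pair$exam1$spacing_mm,
                     pair$exam1$origin_mm)
  expect_error(run_ctma(empty, pair$exam2, analysis_config()), "stage")
})
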