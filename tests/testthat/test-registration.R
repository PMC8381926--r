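test_that("kabsch_fit recovers exact transforms on matched points", {
  axes <- diag(3)
  id <- kabsch_fit(axes, axes)
  expect_lt(max(rt_discrepancy(id$transform, rt_identity())), 1e-12)
  expect_lt(id$quality$mean_error_mm, 1e-12)

  rz90 <- rt_from_euler(c(0, 0, 90))
  fit <- kabsch_fit(axes, rt_apply(rz90, axes))
  expect_lt(max(rt_discrepancy(fit$transform, rz90)), 1e-12)
  expect_lt(fit$quality$mean_error_mm, 1e-12)

  tr <- rigid_transform(diag(3), c(1, 2, 3))
  fit2 <- kabsch_fit(axes, sweep(axes, 2, c(1, 2, 3), "+"))
  expect_lt(max(abs(fit2$transform$R - diag(3))), 1e-12)
  expect_equal(fit2$transform$t, c(1, 2, 3), tolerance = 1e-12)

  collinear <- cbind(1:4, 2 * (1:4), -(1:4))
  expect_error(kabsch_fit(collinear, collinear), "rank")
  expect_error(kabsch_fit(axes, axes[1:2, ]), "same number")
})

test_that("kabsch_fit agrees with a brute-force rotation-grid oracle", {
  withr::with_seed(31, {
    src <- matrix(stats::rnorm(15, sd = 10), 5, 3)
    true_ang <- c(2.3, -3.1, 1.7)
    true_t <- c(0.4, -0.8, 1.1)
    T_true <- rt_from_euler(true_ang, true_t)
    tgt <- rt_apply(T_true, src)
  })
  # independent oracle: exhaustive grid over Euler angles at 0.5-degree
  # resolution; translation eliminated via centroids
  cs <- colMeans(src)
  ct <- colMeans(tgt)
  sc <- sweep(src, 2, cs)
  tc <- sweep(tgt, 2, ct)
  grid <- seq(-5, 5, by = 0.5)
  best <- list(rms = Inf)
  for (ax in grid) for (ay in grid) for (az in grid) {
    R <- rt_from_euler(c(ax, ay, az))$R
    rms <- sqrt(mean(rowSums((sc %*% t(R) - tc)^2)))
    if (rms < best$rms) best <- list(rms = rms, ang = c(ax, ay, az))
  }
  fit <- kabsch_fit(src, tgt)
  fitted_ang <- euler_angles(fit$transform$R)
  # grid oracle agrees within its own resolution
  expect_lt(max(abs(best$ang - as.numeric(fitted_ang))), 0.5)
  expect_lt(max(rt_discrepancy(fit$transform, T_true)), 1e-9)
})

test_that("condition_number matches its definition and invariances", {
  tetra <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  expect_equal(condition_number(tetra), 1, tolerance = 1e-9)
  expect_identical(condition_number(cbind(1:5, 1:5, 1:5)), Inf)
  pts <- matrix(stats::rnorm(30), 10, 3)
  expect_equal(condition_number(pts * 10), condition_number(pts),
               tolerance = 1e-9)
  G <- random_rigid(4)
  expect_equal(condition_number(rt_apply(G, pts)), condition_number(pts),
               tolerance = 1e-6)
  expect_error(condition_number(pts[1:2, ]), "at least 3")

  # anisotropic stretch: scaling one axis by c gives condition number c
  stretched <- rbind(diag(c(1, 1, 1)), -diag(c(1, 1, 1)))
  stretched[, 3] <- stretched[, 3] / 99.5
  expect_equal(condition_number(stretched), 99.5, tolerance = 1e-6)
})

test_that("quality_gate applies the clinical limits with reasons", {
  q <- function(me, cn) registration_quality(me, cn, 8L)
  expect_true(quality_gate(q(0.1, 50))$pass)
  g1 <- quality_gate(q(0.1, 150))
  expect_false(g1$pass)
  expect_match(g1$reasons, "condition number", all = FALSE)
  g2 <- quality_gate(q(0.35, 50))
  expect_false(g2$pass)
  expect_match(g2$reasons, "mean error", all = FALSE)
  # boundary: the gate fails at the limit itself
  expect_false(quality_gate(q(0.30, 50))$pass)
  expect_false(quality_gate(q(0.1, 100))$pass)
  expect_false(quality_gate(q(0.1, Inf))$pass)
})

test_that("match_beads pairs mutually, reports dropout, breaks ties by label", {
  withr::with_seed(8, pts <- matrix(stats::rnorm(24, sd = 20), 8, 3))
  a <- bead_set(pts)
  b <- bead_set(pts)
  m <- match_beads(a, b)
  expect_identical(m$label_a, m$label_b)
  expect_identical(nrow(m), 8L)

  # drop one bead on one side: n-1 pairs, dropout reported
  b2 <- bead_set(pts[-3, ], labels = (1:8)[-3])
  m2 <- match_beads(a, b2)
  expect_identical(nrow(m2), 7L)
  expect_identical(attr(m2, "unmatched_a"), 3L)

  # rigidly moved set with the true init pairs perfectly
  G <- random_rigid(9, max_t = 15, max_r = 30)
  b3 <- bead_set(rt_apply(G, pts))
  m3 <- match_beads(a, b3, init = G)
  expect_identical(m3$label_a, m3$label_b)
  expect_lt(max(m3$distance_mm), 1e-9)

  expect_error(match_beads(bead_set(pts[1:2, ]), b), "at least 3")
})

test_that("icp_register satisfies its contract on exact clouds", {
  withr::with_seed(12, cloud <- matrix(stats::rnorm(900, sd = 15), 300, 3))
  same <- icp_register(cloud, cloud)
  expect_lt(max(rt_discrepancy(same$transform, rt_identity())), 1e-12)
  expect_lt(same$quality$mean_error_mm, 1e-12)

  G <- rt_from_euler(c(1, -2, 3), c(2, -1, 1.5))
  moved <- icp_register(cloud, rt_apply(G, cloud))
  expect_lt(max(rt_discrepancy(moved$transform, G)), 1e-6)

  # matched noise-free clouds: ICP equals the closed-form Kabsch fit
  kb <- kabsch_fit(cloud, rt_apply(G, cloud))
  expect_lt(max(rt_discrepancy(moved$transform, kb$transform)), 1e-6)

  # final RMS never exceeds the RMS of the initial alignment
  init_nn <- ctmotion:::.nn_index(rt_apply(G, cloud), cloud)
  expect_lte(moved$quality$mean_error_mm, sqrt(mean(init_nn$dist^2)))
})

test_that("icp_register_plane recovers transforms and needs normals", {
  # ellipsoid with exact analytic normals
  withr::with_seed(13, {
    u <- matrix(stats::rnorm(6000), 2000, 3)
    u <- u / sqrt(rowSums(u^2))
  })
  semi <- c(20, 15, 10)
  cloud <- sweep(u, 2, semi, "*")
  normals <- sweep(u, 2, semi, "/")
  normals <- normals / sqrt(rowSums(normals^2))
  expect_error(icp_register_plane(cloud, cloud), "normals")
  G <- rt_from_euler(c(1.5, -1, 2), c(1, 2, -1))
  tgt <- rt_apply(G, cloud)
  tgt_n <- normals %*% t(G$R)
  fit <- icp_register_plane(cloud, tgt, target_normals = tgt_n)
  expect_lt(rt_discrepancy(fit$transform, G)["r"], 0.2)
  expect_lt(fit$quality$mean_error_mm, 0.1)
})

test_that("registration is left-invariant under a global rigid motion", {
  withr::with_seed(14, {
    src <- matrix(stats::rnorm(30, sd = 10), 10, 3)
    T0 <- random_rigid(15)
    tgt <- rt_apply(T0, src)
    G <- random_rigid(16)
  })
  base <- kabsch_fit(src, tgt)$transform
  conj <- kabsch_fit(rt_apply(G, src), rt_apply(G, tgt))$transform
  expected <- rt_compose(G, rt_compose(base, rt_inverse(G)))
  expect_lt(max(rt_discrepancy(conj, expected)), 1e-9)
})

test_that("coarse_align handles the specified cases", {
  withr::with_seed(17, {
    cloud <- matrix(stats::rnorm(1500, sd = 8), 500, 3)
    cloud[, 1] <- cloud[, 1] * 3    # distinct principal axes
    cloud[, 2] <- cloud[, 2] * 1.7
  })
  same <- coarse_align(cloud, cloud)
  expect_lt(max(rt_discrepancy(same, rt_identity())), 0.5)

  shifted <- sweep(cloud, 2, c(5, -3, 2), "+")
  tr <- coarse_align(cloud, shifted)
  expect_lt(rt_discrepancy(tr, rigid_transform(diag(3), c(5, -3, 2)))["t"],
            0.5)

  iso <- rbind(diag(3), -diag(3))  # exactly isotropic: centroid fallback
  expect_warning(coarse_align(iso, iso), "near-isotropic")
})

test_that("coarse_align captures the phantom repositioning well enough for ICP", {
  spec <- small_spec(22)
  repo <- sample_repositioning(3, 2, seed = 44)
  pair <- generate_phantom_pair(spec, repositioning = repo)
  s1 <- ctmotion:::bone_surface_cloud(pair$exam1, 600, 2200)
  s2 <- ctmotion:::bone_surface_cloud(pair$exam2, 600, 2200)
  co <- coarse_align(s1, s2)
  resid <- ctmotion:::.nn_index(s2, rt_apply(co, s1))
  expect_lt(sqrt(mean(resid$dist^2)), 2)
})
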