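# a tiny volume with three bright beads for cross-format checks
bead_test_volume <- function() {
  dims <- c(24L, 20L, 16L)
  sp <- c(0.6, 0.6, 0.6)
  origin <- c(-7, -6, -4.5)
  g <- structure(list(dim = dims, spacing_mm = sp, origin_mm = origin,
                      direction = diag(3)), class = "ct_geometry")
  xyz <- ctmotion:::all_voxel_world_coords(g)
  centers <- rbind(c(0.13, 0.42, -0.31), c(-3.2, 2.1, 1.4),
                   c(3.9, -2.7, -1.2))
  hu <- rep(40, nrow(xyz))
  for (i in seq_len(nrow(centers))) {
    d <- sqrt(rowSums(sweep(xyz, 2, centers[i, ])^2)) - 0.5
    f <- pmin(1, pmax(0, 0.5 - d / 0.6))
    hu <- hu * (1 - f) + 8000 * f
  }
  list(volume = ct_volume(array(hu, dims), sp, origin), centers = centers)
}

test_that("MetaImage and NIfTI volumes round-trip exactly", {
  v <- bead_test_volume()$volume
  for (ext in c(".mha", ".nii", ".nii.gz")) {
    path <- withr::local_tempfile(fileext = ext)
    write_volume(v, path)
    back <- read_volume(path)
    expect_equal(back$hu, v$hu, tolerance = 1e-12)
    expect_lt(max(abs(back$spacing_mm - v$spacing_mm)), 1e-6)
    expect_lt(max(abs(back$origin_mm - v$origin_mm)), 1e-4)
    expect_lt(max(abs(back$direction - v$direction)), 1e-6)
  }
})

test_that("DICOM series round-trips and applies the rescale to HU", {
  v <- bead_test_volume()$volume
  dir <- withr::local_tempdir()
  write_dicom_series(v, dir, rescale_slope = 1, rescale_intercept = -1024)
  back <- read_volume(dir)
  # stored values are integers, so HU round-trip is exact to the rounding
  expect_lt(max(abs(back$hu - round(v$hu))), 0.51)
  expect_lt(max(abs(back$spacing_mm - v$spacing_mm)), 1e-6)
  expect_lt(max(abs(back$origin_mm - v$origin_mm)), 1e-6)

  # linear rescale example: stored 1624 with intercept -1024 reads as 600 HU
  u <- ct_volume(array(600, c(4, 4, 4)), c(1, 1, 1), c(0, 0, 0))
  d2 <- withr::local_tempdir()
  write_dicom_series(u, d2, rescale_slope = 1, rescale_intercept = -1024)
  raw1 <- readBin(list.files(d2, full.names = TRUE)[1], "raw",
                  file.size(list.files(d2, full.names = TRUE)[1]))
  # last 32 bytes are the 16 stored pixels of the slice
  stored <- readBin(raw1[(length(raw1) - 31L):length(raw1)], "integer",
                    n = 16L, size = 2L, endian = "little")
  expect_true(all(stored == 1624L))
  expect_true(all(read_volume(d2)$hu == 600))
})

test_that("mixed DICOM series and non-uniform spacing raise distinct errors", {
  v <- ct_volume(array(0, c(6, 6, 4)), c(1, 1, 1), c(0, 0, 0))
  dir <- withr::local_tempdir()
  write_dicom_series(v, file.path(dir), series_uid = "1.2.3.4")
  # drop a second series into the same directory
  v2 <- ct_volume(array(0, c(6, 6, 2)), c(1, 1, 1), c(0, 0, 20))
  tmp2 <- withr::local_tempdir()
  write_dicom_series(v2, tmp2, series_uid = "1.2.3.5")
  file.copy(list.files(tmp2, full.names = TRUE)[1],
            file.path(dir, "other_series.dcm"))
  expect_error(read_volume(dir), "1.2.3.4.*1.2.3.5")

  # non-uniform slice spacing: delete a middle slice
  dir3 <- withr::local_tempdir()
  write_dicom_series(v, dir3)
  file.remove(list.files(dir3, full.names = TRUE)[2])
  expect_error(read_volume(dir3), "non-uniform slice spacing")
})

test_that("the same bead yields the same world centroid in every format", {
  bt <- bead_test_volume()
  centroids <- lapply(c("mha", "nii", "dcm"), function(fmt) {
    path <- if (fmt == "dcm") withr::local_tempdir()
            else withr::local_tempfile(fileext = paste0(".", fmt))
    if (fmt == "dcm") write_dicom_series(bt$volume, path)
    else write_volume(bt$volume, path)
    extract_beads(read_volume(path))$points
  })
  for (i in 2:3)
    expect_lt(max(abs(centroids[[i]] - centroids[[1]])), 0.01)
})

test_that("analysis config validates and round-trips as JSON", {
  expect_error(analysis_config(bone_threshold_hu = 2500), "metal > bone")
  expect_error(analysis_config(anatomical_basis = diag(c(-1, 1, 1))),
               "det")
  cfg <- analysis_config(bone_threshold_hu = c(400, 550),
                         registration_mode = "surface",
                         dose_factor_msv_per_mgy_cm = 0.015)
  path <- withr::local_tempfile(fileext = ".json")
  write_config(cfg, path)
  back <- read_config(path)
  expect_identical(back$bone_threshold_hu, c(400, 550))
  expect_identical(back$registration_mode, "surface")
  expect_identical(back$dose_factor_msv_per_mgy_cm, 0.015)
})

test_that("migration tables round-trip at 6 decimals and enforce one frame", {
  mk <- function(id, frame = "dicom", tx = 0.123456) {
    migration_result(c(tx, -0.2, 0.3), c(0.5, -1, 2), c(1, 2, 3),
                     frame = frame, mode = "beads",
                     quality = list(
                       bone = registration_quality(0.05, 2.3, 9L),
                       implant = registration_quality(0.04, 3.1, 5L)),
                     gate = list(pass = TRUE, reasons = character(0)),
                     id = id)
  }
  path <- withr::local_tempfile(fileext = ".csv")
  write_migration_table(list(mk("a"), mk("b", tx = -1.654321)), path)
  back <- read_migration_table(path)
  expect_identical(length(back), 2L)
  expect_equal(back[[1]]$translations_mm[1], 0.123456, tolerance = 1e-9)
  expect_equal(back[[2]]$translations_mm[1], -1.654321, tolerance = 1e-9)
  expect_equal(back[[1]]$quality$bone$mean_error_mm, 0.05,
               tolerance = 1e-9)

  # zero migration writes a row of zeros
  z <- migration_result(c(0, 0, 0), c(0, 0, 0), c(0, 0, 0), id = "z")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_migration_table(list(z), p2)
  row <- utils::read.csv(p2)
  expect_true(all(row[c("tx_mm", "ty_mm", "tz_mm",
                        "rx_deg", "ry_deg", "rz_deg")] == 0))

  # empty list: header-only file plus a warning
  p3 <- withr::local_tempfile(fileext = ".csv")
  expect_warning(write_migration_table(list(), p3), "header-only")
  expect_identical(nrow(utils::read.csv(p3)), 0L)

  # mixed frames are rejected
  expect_error(
    write_migration_table(list(mk("a"), mk("b", frame = "anatomical")),
                          withr::local_tempfile(fileext = ".csv")),
    "frames")
})
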