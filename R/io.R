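#' Read a CT volume
#'
#' Reads a DICOM series directory, a NIfTI-1 file (`.nii` / `.nii.gz`) or a
#' MetaImage file (`.mha`) into a [ct_volume()]. Intensities are returned in
#' Hounsfield units (the DICOM rescale slope/intercept is applied on read);
#' world coordinates are LPS millimetres for all formats.
#'
#' @param path a DICOM series directory or a `.nii`, `.nii.gz` or `.mha`
#'   file.
#' @return A `ct_volume`.
#' @export
read_volume <- function(path) {
  if (dir.exists(path)) return(read_dicom_series(path))
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE))
    return(read_nifti_volume(path))
  if (grepl("\\.mha$", path, ignore.case = TRUE))
    return(read_mha_volume(path))
  stop(sprintf(
    "unrecognised volume format: %s (expected DICOM directory, .nii, .nii.gz or .mha)",
    path), call. = FALSE)
}

#' Write a CT volume
#'
#' Dispatches on the path: a `.nii` / `.nii.gz` or `.mha` extension writes a
#' single file; any other path is treated as a directory and a DICOM series
#' is written into it.
#'
#' @param volume a `ct_volume`.
#' @param path output file or directory.
#' @param ... passed to [write_dicom_series()] when writing DICOM.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, ...) {
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE))
    return(write_nifti_volume(volume, path))
  if (grepl("\\.mha$", path, ignore.case = TRUE))
    return(write_mha_volume(volume, path))
  write_dicom_series(volume, path, ...)
}

#' Analysis configuration
#'
#' Collects the tunable parameters of the migration analysis. The defaults
#' are the clinical operating point: beads and metal are segmented at
#' 2200 HU, bone at 600 HU, and the effective-dose conversion factor is the
#' pelvic DLP coefficient 0.0129 mSv/(mGy cm). `bone_threshold_hu` may be a
#' length-2 vector giving a per-exam override (scanners occasionally need a
#' lower bone threshold, e.g. 400 or 550 HU, when reconstruction settings
#' deviate).
#'
#' @param bone_threshold_hu bone segmentation threshold (HU); scalar or one
#'   value per exam.
#' @param metal_threshold_hu metal/bead segmentation threshold (HU).
#' @param registration_mode `"beads"` (fiducial beads in the pelvic bone) or
#'   `"surface"` (markerless bone-surface registration).
#' @param euler_order Cardan sequence for the 6-DOF report, `"xyz"` fixed
#'   frame by default.
#' @param frame `"dicom"` to report in the scanner frame, `"anatomical"` to
#'   re-orient with `anatomical_basis` / `rotation_signs`.
#' @param anatomical_basis 3x3 orthonormal basis (columns = anatomical axes
#'   expressed in the DICOM frame, det +1).
#' @param rotation_signs per-axis sign convention (+1/-1) applied to the
#'   reported rotations in the anatomical frame.
#' @param bead_volume_range_mm3 connected-component volume window accepted
#'   as a bead (default 0.1-2.0 mm^3, matching 1-mm tantalum beads).
#' @param bead_clearance_mm beads closer than this to the implant metal are
#'   attributed to the implant.
#' @param icp_max_iter,icp_tol_mm,icp_max_points ICP controls.
#' @param match_max_distance_mm bead pairs farther apart than this after
#'   the initial alignment are rejected as mismatches.
#' @param cn_max,mean_error_max_mm marker quality gate: maximum condition
#'   number and maximum mean error of rigid-body fitting.
#' @param dose_factor_msv_per_mgy_cm DLP-to-effective-dose conversion.
#' @param seed seed for the deterministic subsampling inside ICP.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(bone_threshold_hu = 600,
                            metal_threshold_hu = 2200,
                            registration_mode = c("beads", "surface"),
                            euler_order = c("xyz", "zyx"),
                            frame = c("dicom", "anatomical"),
                            anatomical_basis = diag(3),
                            rotation_signs = c(1, 1, 1),
                            bead_volume_range_mm3 = c(0.1, 2.0),
                            bead_clearance_mm = 3.0,
                            icp_max_iter = 100L,
                            icp_tol_mm = 1e-4,
                            icp_max_points = 50000L,
                            match_max_distance_mm = 5,
                            cn_max = 100,
                            mean_error_max_mm = 0.30,
                            dose_factor_msv_per_mgy_cm = 0.0129,
                            seed = 1L) {
  registration_mode <- match.arg(registration_mode)
  euler_order <- match.arg(euler_order)
  frame <- match.arg(frame)
  bone_threshold_hu <- as.numeric(bone_threshold_hu)
  metal_threshold_hu <- as.numeric(metal_threshold_hu)
  bead_volume_range_mm3 <- as.numeric(bead_volume_range_mm3)
  rotation_signs <- as.numeric(rotation_signs)
  if (!length(bone_threshold_hu) %in% c(1L, 2L))
    stop("bone_threshold_hu must have length 1 or 2", call. = FALSE)
  if (any(metal_threshold_hu <= bone_threshold_hu))
    stop("thresholds must satisfy metal > bone", call. = FALSE)
  if (any(bone_threshold_hu <= -1000))
    stop("thresholds must satisfy bone > air", call. = FALSE)
  anatomical_basis <- as.matrix(anatomical_basis)
  if (max(abs(crossprod(anatomical_basis) - diag(3))) > 1e-9 ||
      abs(det(anatomical_basis) - 1) > 1e-9)
    stop("anatomical_basis must be orthonormal with det = +1",
         call. = FALSE)
  if (!all(rotation_signs %in% c(-1, 1)))
    stop("rotation_signs must be +1 or -1 per axis", call. = FALSE)
  structure(list(
    bone_threshold_hu = bone_threshold_hu,
    metal_threshold_hu = metal_threshold_hu,
    registration_mode = registration_mode,
    euler_order = euler_order,
    frame = frame,
    anatomical_basis = anatomical_basis,
    rotation_signs = rotation_signs,
    bead_volume_range_mm3 = bead_volume_range_mm3,
    bead_clearance_mm = bead_clearance_mm,
    icp_max_iter = as.integer(icp_max_iter),
    icp_tol_mm = icp_tol_mm,
    icp_max_points = as.integer(icp_max_points),
    match_max_distance_mm = match_max_distance_mm,
    cn_max = cn_max,
    mean_error_max_mm = mean_error_max_mm,
    dose_factor_msv_per_mgy_cm = dose_factor_msv_per_mgy_cm,
    seed = as.integer(seed)), class = "analysis_config")
}

#' Read / write an analysis configuration
#'
#' The configuration round-trips through a flat JSON file whose keys are the
#' [analysis_config()] argument names.
#'
#' @param config an `analysis_config`.
#' @param path JSON file path.
#' @return `write_config()`: `path` invisibly; `read_config()`: an
#'   `analysis_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "analysis_config"))
  x <- unclass(config)
  x$anatomical_basis <- as.numeric(t(x$anatomical_basis))  # row-major
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(x$anatomical_basis))
    x$anatomical_basis <- matrix(as.numeric(x$anatomical_basis), 3, 3,
                                 byrow = TRUE)
  do.call(analysis_config, x)
}

migration_table_columns <- c(
  "id", "mode", "frame",
  "tx_mm", "ty_mm", "tz_mm", "rx_deg", "ry_deg", "rz_deg",
  "com_x_mm", "com_y_mm", "com_z_mm",
  "bone_condition_number", "bone_mean_error_mm",
  "implant_condition_number", "implant_mean_error_mm",
  "gate_pass")

#' Write migration results as a CSV table
#'
#' One row per examination pair with the six degrees of freedom, the implant
#' center of mass, and the registration quality metrics. Values round-trip
#' losslessly at 6 decimals through [read_migration_table()]. All results in
#' one table must share the same reporting frame.
#'
#' @param results a list of `migration_result` objects (or a single one).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_migration_table <- function(results, path) {
  if (inherits(results, "migration_result")) results <- list(results)
  if (length(results) == 0L) {
    warning("writing a header-only migration table (no results)")
    df <- as.data.frame(stats::setNames(
      rep(list(character(0)), length(migration_table_columns)),
      migration_table_columns))
    utils::write.csv(df, path, row.names = FALSE)
    return(invisible(path))
  }
  frames <- vapply(results, `[[`, "", "frame")
  if (length(unique(frames)) > 1L)
    stop(sprintf("cannot mix reporting frames in one table: %s",
                 paste(unique(frames), collapse = ", ")), call. = FALSE)
  rows <- lapply(seq_along(results), function(i) {
    r <- results[[i]]
    qb <- r$quality$bone
    qi <- r$quality$implant
    data.frame(
      id = if (!is.null(r$id)) r$id else sprintf("pair_%03d", i),
      mode = r$mode, frame = r$frame,
      tx_mm = r$translations_mm[1], ty_mm = r$translations_mm[2],
      tz_mm = r$translations_mm[3],
      rx_deg = r$rotations_deg[1], ry_deg = r$rotations_deg[2],
      rz_deg = r$rotations_deg[3],
      com_x_mm = r$center_of_mass_mm[1], com_y_mm = r$center_of_mass_mm[2],
      com_z_mm = r$center_of_mass_mm[3],
      bone_condition_number = if (!is.null(qb)) qb$condition_number else NA,
      bone_mean_error_mm = if (!is.null(qb)) qb$mean_error_mm else NA,
      implant_condition_number =
        if (!is.null(qi)) qi$condition_number else NA,
      implant_mean_error_mm = if (!is.null(qi)) qi$mean_error_mm else NA,
      gate_pass = isTRUE(r$gate$pass))
  })
  df <- do.call(rbind, rows)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) round(x, 6))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_migration_table
#' @return `read_migration_table()`: a list of `migration_result` objects.
#' @export
read_migration_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(migration_table_columns, names(df))
  if (length(missing_cols) > 0L)
    stop(sprintf("migration table %s lacks columns: %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    quality <- list(
      bone = if (!is.na(r$bone_mean_error_mm))
        registration_quality(r$bone_mean_error_mm, r$bone_condition_number,
                             NA_integer_, TRUE, 0L) else NULL,
      implant = if (!is.na(r$implant_mean_error_mm))
        registration_quality(r$implant_mean_error_mm,
                             r$implant_condition_number,
                             NA_integer_, TRUE, 0L) else NULL)
    migration_result(
      translations_mm = c(r$tx_mm, r$ty_mm, r$tz_mm),
      rotations_deg = c(r$rx_deg, r$ry_deg, r$rz_deg),
      center_of_mass_mm = c(r$com_x_mm, r$com_y_mm, r$com_z_mm),
      frame = r$frame, mode = r$mode, quality = quality,
      id = r$id)
  })
}
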