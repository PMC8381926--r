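# NIfTI-1 reading/writing. Implemented directly against the NIfTI-1 header
# layout (348-byte header, single-file .nii / .nii.gz). NIfTI stores the
# voxel-to-world affine in RAS; the package world frame is LPS, so the first
# two affine rows are negated on read and write.

nifti_datatypes <- list(
  `2` = list(what = "integer", size = 1L, signed = FALSE),
  `4` = list(what = "integer", size = 2L, signed = TRUE),
  `8` = list(what = "integer", size = 4L, signed = TRUE),
  `16` = list(what = "numeric", size = 4L, signed = TRUE),
  `64` = list(what = "numeric", size = 8L, signed = TRUE),
  `512` = list(what = "integer", size = 2L, signed = FALSE)
)

read_nifti_volume <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", 348L)
  if (length(hdr_raw) < 348L)
    stop(sprintf("unreadable NIfTI file (truncated header): %s", path),
         call. = FALSE)
  rb <- function(off, what, n, size, signed = TRUE, endian = "little") {
    readBin(hdr_raw[(off + 1L):(off + n * size)], what, n = n, size = size,
            signed = signed, endian = endian)
  }
  endian <- "little"
  sizeof_hdr <- rb(0L, "integer", 1L, 4L)
  if (sizeof_hdr != 348L) {
    sizeof_hdr_be <- readBin(hdr_raw[1:4], "integer", 1L, 4L,
                             endian = "big")
    if (sizeof_hdr_be == 348L) endian <- "big"
    else stop(sprintf("unreadable NIfTI file (bad sizeof_hdr): %s", path),
              call. = FALSE)
  }
  rb <- function(off, what, n, size, signed = TRUE) {
    readBin(hdr_raw[(off + 1L):(off + n * size)], what, n = n, size = size,
            signed = signed, endian = endian)
  }
  magic <- rawToChar(hdr_raw[345:347])
  if (!magic %in% c("n+1", "ni1"))
    stop(sprintf("unreadable NIfTI file (bad magic '%s'): %s", magic, path),
         call. = FALSE)
  dims <- rb(40L, "integer", 8L, 2L)
  if (dims[1] < 3L)
    stop("NIfTI volume must be 3-dimensional", call. = FALSE)
  nd <- dims[2:4]
  datatype <- rb(70L, "integer", 1L, 2L)
  pixdim <- rb(76L, "numeric", 8L, 4L)
  vox_offset <- rb(108L, "numeric", 1L, 4L)
  scl_slope <- rb(112L, "numeric", 1L, 4L)
  scl_inter <- rb(116L, "numeric", 1L, 4L)
  qform_code <- rb(252L, "integer", 1L, 2L)
  sform_code <- rb(254L, "integer", 1L, 2L)

  if (sform_code > 0L) {
    srow <- rbind(rb(280L, "numeric", 4L, 4L),
                  rb(296L, "numeric", 4L, 4L),
                  rb(312L, "numeric", 4L, 4L))
    A <- srow[, 1:3]
    offset <- srow[, 4]
  } else if (qform_code > 0L) {
    b <- rb(256L, "numeric", 1L, 4L)
    c_ <- rb(260L, "numeric", 1L, 4L)
    d <- rb(264L, "numeric", 1L, 4L)
    a2 <- 1 - b^2 - c_^2 - d^2
    a <- sqrt(max(0, a2))
    Rq <- matrix(c(a^2 + b^2 - c_^2 - d^2, 2 * (b * c_ + a * d),
                   2 * (b * d - a * c_),
                   2 * (b * c_ - a * d), a^2 + c_^2 - b^2 - d^2,
                   2 * (c_ * d + a * b),
                   2 * (b * d + a * c_), 2 * (c_ * d - a * b),
                   a^2 + d^2 - b^2 - c_^2), 3, 3)
    qfac <- if (pixdim[1] < 0) -1 else 1
    A <- Rq %*% diag(c(pixdim[2], pixdim[3], qfac * pixdim[4]))
    offset <- c(rb(268L, "numeric", 1L, 4L), rb(272L, "numeric", 1L, 4L),
                rb(276L, "numeric", 1L, 4L))
  } else {
    A <- diag(pixdim[2:4])
    offset <- c(0, 0, 0)
  }
  # RAS -> LPS
  A[1:2, ] <- -A[1:2, ]
  offset[1:2] <- -offset[1:2]
  spacing <- sqrt(colSums(A^2))
  direction <- sweep(A, 2L, spacing, "/")

  dt <- nifti_datatypes[[as.character(datatype)]]
  if (is.null(dt))
    stop(sprintf("unsupported NIfTI datatype code %d", datatype),
         call. = FALSE)
  # skip from end of header to vox_offset
  skip <- as.integer(round(vox_offset)) - 348L
  if (skip > 0L) readBin(con, "raw", skip)
  n_vox <- prod(nd)
  vals <- readBin(con, dt$what, n = n_vox, size = dt$size,
                  signed = dt$signed, endian = endian)
  if (length(vals) < n_vox)
    stop(sprintf("unreadable NIfTI file (truncated data): %s", path),
         call. = FALSE)
  vals <- as.numeric(vals)
  if (!is.na(scl_slope) && scl_slope != 0)
    vals <- vals * scl_slope + scl_inter
  ct_volume(array(vals, dim = nd), spacing_mm = spacing,
            origin_mm = offset, direction = direction)
}

write_nifti_volume <- function(volume, path) {
  stopifnot(inherits(volume, "ct_volume"))
  g <- volume_geometry(volume)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wb <- function(x, size) writeBin(x, con, size = size, endian = "little")

  A <- g$direction %*% diag(g$spacing_mm)
  offset <- g$origin_mm
  # LPS -> RAS
  A[1:2, ] <- -A[1:2, ]
  offset[1:2] <- -offset[1:2]

  wb(348L, 4L)                                   # sizeof_hdr
  writeBin(raw(36L), con)                        # data_type..dim_info
  wb(as.integer(c(3L, g$dim, 1L, 1L, 1L, 1L)), 2L)  # dim[8]
  writeBin(raw(14L), con)                        # intent_p1..intent_code
  wb(64L, 2L)                                    # datatype: float64
  wb(64L, 2L)                                    # bitpix
  wb(0L, 2L)                                     # slice_start
  wb(c(1, g$spacing_mm, 0, 0, 0, 0), 4L)         # pixdim[8]
  wb(352, 4L)                                    # vox_offset
  wb(c(1, 0), 4L)                                # scl_slope, scl_inter
  writeBin(raw(2L + 1L + 1L), con)               # slice_end, slice_code, xyzt
  wb(c(0, 0), 4L)                                # cal_max, cal_min
  wb(c(0, 0), 4L)                                # slice_duration, toffset
  wb(c(0L, 0L), 4L)                              # glmax, glmin
  writeBin(raw(80L + 24L), con)                  # descrip, aux_file
  wb(c(0L, 1L), 2L)                              # qform_code, sform_code
  wb(rep(0, 6), 4L)                              # quatern b,c,d + qoffset
  wb(c(A[1, ], offset[1]), 4L)                   # srow_x
  wb(c(A[2, ], offset[2]), 4L)                   # srow_y
  wb(c(A[3, ], offset[3]), 4L)                   # srow_z
  writeBin(raw(16L), con)                        # intent_name
  writeBin(charToRaw("n+1"), con)
  writeBin(raw(1L), con)                         # magic NUL
  writeBin(raw(4L), con)                         # extension flag
  wb(as.numeric(volume$hu), 8L)
  invisible(path)
}
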