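# Minimal DICOM series support: explicit-VR little-endian, single-frame CT
# slices, one series per directory. Enough to round-trip the package's own
# exports and to read standard uncompressed scanner output; compressed
# transfer syntaxes are rejected with a clear error.

TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"

dcm_tag <- function(group, element) {
  sprintf("%04X,%04X", group, element)
}

# VRs with the 4-byte length layout (2 reserved bytes + uint32 length)
long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

dcm_encode_element <- function(group, element, vr, value_raw) {
  if (length(value_raw) %% 2L == 1L) {
    pad <- if (vr %in% c("UI")) as.raw(0L) else charToRaw(" ")
    value_raw <- c(value_raw, pad)
  }
  head <- c(writeBin(as.integer(group), raw(), size = 2L,
                     endian = "little"),
            writeBin(as.integer(element), raw(), size = 2L,
                     endian = "little"),
            charToRaw(vr))
  if (vr %in% long_vrs) {
    head <- c(head, raw(2L),
              writeBin(length(value_raw), raw(), size = 4L,
                       endian = "little"))
  } else {
    head <- c(head, writeBin(as.integer(length(value_raw)), raw(),
                             size = 2L, endian = "little"))
  }
  c(head, value_raw)
}

dcm_str <- function(x) charToRaw(paste(x, collapse = "\\"))
dcm_ds <- function(x) charToRaw(paste(formatC(x, format = "g", digits = 12),
                                      collapse = "\\"))
dcm_us <- function(x) writeBin(as.integer(x), raw(), size = 2L,
                               endian = "little")

#' Write a CT volume as a DICOM series
#'
#' Writes one explicit-VR little-endian single-frame CT file per axial slice.
#' Stored pixel values are signed 16-bit; HU are recovered on read through
#' the rescale slope/intercept.
#'
#' @param volume a `ct_volume`.
#' @param dir output directory (created if missing).
#' @param series_uid SeriesInstanceUID; a deterministic UID derived from the
#'   volume dimensions by default.
#' @param rescale_slope,rescale_intercept linear HU calibration stored in the
#'   files: `HU = slope * stored + intercept`.
#' @return The output directory, invisibly.
#' @export
write_dicom_series <- function(volume, dir,
                               series_uid = NULL,
                               rescale_slope = 1,
                               rescale_intercept = -1024) {
  stopifnot(inherits(volume, "ct_volume"))
  g <- volume_geometry(volume)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (is.null(series_uid))
    series_uid <- paste0("1.2.826.0.1.3680043.9999.1.",
                         paste(g$dim, collapse = "."))
  study_uid <- paste0(series_uid, ".0")
  nx <- g$dim[1]; ny <- g$dim[2]; nz <- g$dim[3]
  iop <- c(g$direction[, 1], g$direction[, 2])
  for (k in seq_len(nz)) {
    ipp <- drop(voxel_to_world(g, c(0, 0, k - 1)))
    stored <- round((volume$hu[, , k] - rescale_intercept) / rescale_slope)
    if (any(stored < -32768 | stored > 32767))
      stop("stored pixel values exceed the signed 16-bit range; adjust ",
           "rescale_slope/rescale_intercept", call. = FALSE)
    sop_uid <- sprintf("%s.%d", series_uid, k)
    # pixel data: rows (y) outer, columns (x) inner == column-major slice
    pix <- writeBin(as.integer(stored), raw(), size = 2L, endian = "little")
    body <- c(
      dcm_encode_element(0x0008, 0x0016, "UI",
                         charToRaw("1.2.840.10008.5.1.4.1.1.2")),
      dcm_encode_element(0x0008, 0x0018, "UI", charToRaw(sop_uid)),
      dcm_encode_element(0x0008, 0x0060, "CS", charToRaw("CT")),
      dcm_encode_element(0x0020, 0x000D, "UI", charToRaw(study_uid)),
      dcm_encode_element(0x0020, 0x000E, "UI", charToRaw(series_uid)),
      dcm_encode_element(0x0020, 0x0013, "IS", charToRaw(as.character(k))),
      dcm_encode_element(0x0020, 0x0032, "DS", dcm_ds(ipp)),
      dcm_encode_element(0x0020, 0x0037, "DS", dcm_ds(iop)),
      dcm_encode_element(0x0028, 0x0002, "US", dcm_us(1L)),
      dcm_encode_element(0x0028, 0x0004, "CS", charToRaw("MONOCHROME2")),
      dcm_encode_element(0x0028, 0x0010, "US", dcm_us(ny)),
      dcm_encode_element(0x0028, 0x0011, "US", dcm_us(nx)),
      dcm_encode_element(0x0028, 0x0030, "DS",
                         dcm_ds(c(g$spacing_mm[2], g$spacing_mm[1]))),
      dcm_encode_element(0x0028, 0x0100, "US", dcm_us(16L)),
      dcm_encode_element(0x0028, 0x0101, "US", dcm_us(16L)),
      dcm_encode_element(0x0028, 0x0102, "US", dcm_us(15L)),
      dcm_encode_element(0x0028, 0x0103, "US", dcm_us(1L)),
      dcm_encode_element(0x0028, 0x1052, "DS", dcm_ds(rescale_intercept)),
      dcm_encode_element(0x0028, 0x1053, "DS", dcm_ds(rescale_slope)),
      dcm_encode_element(0x7FE0, 0x0010, "OW", pix))
    meta_body <- c(
      dcm_encode_element(0x0002, 0x0002, "UI",
                         charToRaw("1.2.840.10008.5.1.4.1.1.2")),
      dcm_encode_element(0x0002, 0x0003, "UI", charToRaw(sop_uid)),
      dcm_encode_element(0x0002, 0x0010, "UI", charToRaw(TS_EXPLICIT_LE)))
    meta <- c(dcm_encode_element(0x0002, 0x0000, "UL",
                                 writeBin(length(meta_body), raw(),
                                          size = 4L, endian = "little")),
              meta_body)
    path <- file.path(dir, sprintf("slice_%04d.dcm", k))
    con <- file(path, "wb")
    writeBin(raw(128L), con)
    writeBin(charToRaw("DICM"), con)
    writeBin(c(meta, body), con)
    close(con)
  }
  invisible(dir)
}

# DICOM strings may be padded with trailing spaces or NULs
raw_to_string <- function(r) trimws(rawToChar(r[r != as.raw(0L)]))

# parse one explicit-VR little-endian DICOM file; returns the tags needed to
# assemble a series
dcm_parse_file <- function(path) {
  raw_all <- readBin(path, "raw", file.size(path))
  if (length(raw_all) < 200L ||
      rawToChar(raw_all[129:132]) != "DICM")
    stop(sprintf("unreadable DICOM file (missing DICM marker): %s", path),
         call. = FALSE)
  pos <- 132L  # bytes consumed
  u16 <- function(off) readBin(raw_all[(off + 1L):(off + 2L)], "integer",
                               size = 2L, signed = FALSE, endian = "little")
  u32 <- function(off) readBin(raw_all[(off + 1L):(off + 4L)], "integer",
                               size = 4L, endian = "little")
  wanted <- c("0008,0018", "0020,000D", "0020,000E", "0020,0032",
              "0020,0037", "0028,0010", "0028,0011", "0028,0030",
              "0028,1052", "0028,1053", "0028,0103", "7FE0,0010",
              "0002,0010")
  out <- list()
  n <- length(raw_all)
  while (pos + 8L <= n) {
    group <- u16(pos); element <- u16(pos + 2L)
    vr <- rawToChar(raw_all[(pos + 5L):(pos + 6L)])
    if (grepl("^[A-Z]{2}$", vr)) {
      if (vr %in% long_vrs) {
        len <- u32(pos + 8L)
        hdr <- 12L
      } else {
        len <- u16(pos + 6L)
        hdr <- 8L
      }
    } else {
      # implicit VR fallback (not produced by this package)
      stop(sprintf("unsupported DICOM encoding (implicit VR?) in %s", path),
           call. = FALSE)
    }
    tag <- dcm_tag(group, element)
    if (tag %in% wanted) {
      val <- raw_all[(pos + hdr + 1L):(pos + hdr + len)]
      out[[tag]] <- list(vr = vr, raw = val)
    }
    pos <- pos + hdr + len
    if (tag == "7FE0,0010") break
  }
  ts <- raw_to_string(out[["0002,0010"]]$raw)
  if (!identical(ts, TS_EXPLICIT_LE))
    stop(sprintf(
      "unsupported DICOM transfer syntax '%s' in %s (only %s is supported)",
      ts, path, TS_EXPLICIT_LE), call. = FALSE)
  getstr <- function(tag) {
    v <- out[[tag]]
    if (is.null(v)) return(NULL)
    raw_to_string(v$raw)
  }
  getnum <- function(tag) {
    s <- getstr(tag)
    if (is.null(s)) return(NULL)
    as.numeric(strsplit(s, "\\\\")[[1]])
  }
  getu16 <- function(tag) {
    v <- out[[tag]]
    if (is.null(v)) return(NULL)
    readBin(v$raw, "integer", size = 2L, signed = FALSE, endian = "little")
  }
  pixrep <- getu16("0028,0103")
  rows <- getu16("0028,0010")
  cols <- getu16("0028,0011")
  pix_raw <- out[["7FE0,0010"]]$raw
  stored <- readBin(pix_raw, "integer", n = rows * cols, size = 2L,
                    signed = isTRUE(pixrep == 1L), endian = "little")
  slope <- getnum("0028,1053"); if (is.null(slope)) slope <- 1
  inter <- getnum("0028,1052"); if (is.null(inter)) inter <- 0
  list(series_uid = getstr("0020,000E"),
       ipp = getnum("0020,0032"),
       iop = getnum("0020,0037"),
       pixel_spacing = getnum("0028,0030"),
       rows = rows, cols = cols,
       hu = slope * stored + inter)
}

read_dicom_series <- function(dir, slice_spacing_tol = 1e-3) {
  files <- list.files(dir, pattern = "\\.dcm$", full.names = TRUE,
                      ignore.case = TRUE)
  if (length(files) == 0L)
    files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0L)
    stop(sprintf("no DICOM files found in %s", dir), call. = FALSE)
  slices <- lapply(files, dcm_parse_file)
  uids <- vapply(slices, `[[`, "", "series_uid")
  if (length(unique(uids)) > 1L)
    stop(sprintf("directory %s mixes multiple DICOM series: %s", dir,
                 paste(sort(unique(uids)), collapse = ", ")),
         call. = FALSE)
  s1 <- slices[[1]]
  rowdir <- s1$iop[1:3]; coldir <- s1$iop[4:6]
  normal <- c(rowdir[2] * coldir[3] - rowdir[3] * coldir[2],
              rowdir[3] * coldir[1] - rowdir[1] * coldir[3],
              rowdir[1] * coldir[2] - rowdir[2] * coldir[1])
  zpos <- vapply(slices, function(s) sum(s$ipp * normal), 0)
  ord <- order(zpos)
  slices <- slices[ord]
  zpos <- zpos[ord]
  nz <- length(slices)
  if (nz > 1L) {
    dz <- diff(zpos)
    if (any(dz <= 0))
      stop(sprintf("duplicate slice positions in %s", dir), call. = FALSE)
    if ((max(dz) - min(dz)) > slice_spacing_tol)
      stop(sprintf(
        "non-uniform slice spacing in %s (range %.6f-%.6f mm exceeds %g mm)",
        dir, min(dz), max(dz), slice_spacing_tol), call. = FALSE)
    slice_spacing <- mean(dz)
  } else {
    slice_spacing <- 1
  }
  nx <- s1$cols; ny <- s1$rows
  hu <- array(0, dim = c(nx, ny, nz))
  for (k in seq_len(nz)) {
    sk <- slices[[k]]
    if (sk$cols != nx || sk$rows != ny)
      stop(sprintf("inconsistent slice dimensions in %s", dir),
           call. = FALSE)
    hu[, , k] <- sk$hu  # pixel order: columns (x) fastest
  }
  spacing <- c(s1$pixel_spacing[2], s1$pixel_spacing[1], slice_spacing)
  direction <- cbind(rowdir, coldir, normal)
  dimnames(direction) <- NULL
  ct_volume(hu, spacing_mm = spacing, origin_mm = slices[[1]]$ipp,
            direction = direction)
}
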