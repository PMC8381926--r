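# MetaImage (.mha, local uncompressed data) reading/writing. The header is
# plain "Key = value" ASCII terminated by "ElementDataFile = LOCAL", followed
# by the raw voxel block. MetaImage world coordinates are already LPS (ITK
# convention), so no axis flip is needed.

mha_element_types <- list(
  MET_UCHAR = list(what = "integer", size = 1L, signed = FALSE),
  MET_SHORT = list(what = "integer", size = 2L, signed = TRUE),
  MET_USHORT = list(what = "integer", size = 2L, signed = FALSE),
  MET_INT = list(what = "integer", size = 4L, signed = TRUE),
  MET_FLOAT = list(what = "numeric", size = 4L, signed = TRUE),
  MET_DOUBLE = list(what = "numeric", size = 8L, signed = TRUE)
)

read_mha_volume <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  keys <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L)
      stop(sprintf("unreadable MetaImage file (no ElementDataFile): %s",
                   path), call. = FALSE)
    m <- regmatches(line, regexec("^\\s*([A-Za-z0-9_]+)\\s*=\\s*(.*?)\\s*$",
                                  line))[[1]]
    if (length(m) != 3L)
      stop(sprintf("unreadable MetaImage header line: '%s'", line),
           call. = FALSE)
    keys[[m[2]]] <- m[3]
    if (m[2] == "ElementDataFile") break
  }
  if (!identical(keys$ElementDataFile, "LOCAL"))
    stop("only MetaImage files with ElementDataFile = LOCAL are supported",
         call. = FALSE)
  if (!is.null(keys$NDims) && as.integer(keys$NDims) != 3L)
    stop("MetaImage volume must be 3-dimensional", call. = FALSE)
  if (!is.null(keys$CompressedData) &&
      tolower(keys$CompressedData) == "true")
    stop("compressed MetaImage data is not supported", call. = FALSE)
  num <- function(key, default = NULL) {
    if (is.null(keys[[key]])) return(default)
    as.numeric(strsplit(trimws(keys[[key]]), "\\s+")[[1]])
  }
  dims <- as.integer(num("DimSize"))
  spacing <- num("ElementSpacing", c(1, 1, 1))
  origin <- num("Offset", c(0, 0, 0))
  tm <- num("TransformMatrix", c(1, 0, 0, 0, 1, 0, 0, 0, 1))
  # TransformMatrix rows are the axis direction cosines -> our columns
  direction <- matrix(tm, 3, 3)
  etype <- keys$ElementType
  dt <- mha_element_types[[etype]]
  if (is.null(dt))
    stop(sprintf("unsupported MetaImage ElementType '%s'", etype),
         call. = FALSE)
  msb <- !is.null(keys$BinaryDataByteOrderMSB) &&
    tolower(keys$BinaryDataByteOrderMSB) == "true"
  endian <- if (msb) "big" else "little"
  n_vox <- prod(dims)
  vals <- readBin(con, dt$what, n = n_vox, size = dt$size,
                  signed = dt$signed, endian = endian)
  if (length(vals) < n_vox)
    stop(sprintf("unreadable MetaImage file (truncated data): %s", path),
         call. = FALSE)
  ct_volume(array(as.numeric(vals), dim = dims), spacing_mm = spacing,
            origin_mm = origin, direction = direction)
}

write_mha_volume <- function(volume, path) {
  stopifnot(inherits(volume, "ct_volume"))
  g <- volume_geometry(volume)
  con <- file(path, "wb")
  on.exit(close(con))
  fmt <- function(x) paste(formatC(x, format = "g", digits = 17),
                           collapse = " ")
  header <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    paste("TransformMatrix =", fmt(as.numeric(g$direction))),
    paste("Offset =", fmt(g$origin_mm)),
    paste("ElementSpacing =", fmt(g$spacing_mm)),
    paste("DimSize =", paste(g$dim, collapse = " ")),
    "ElementType = MET_DOUBLE",
    "ElementDataFile = LOCAL")
  writeChar(paste0(paste(header, collapse = "\n"), "\n"), con,
            eos = NULL)
  writeBin(as.numeric(volume$hu), con, size = 8L, endian = "little")
  invisible(path)
}
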