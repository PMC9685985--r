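# MetaImage (.mha / .mhd + .raw) reader and writer. Text header followed by
# (or pointing at) little-endian raw voxel data. Volumes are written as
# MET_DOUBLE so the round trip is bit-exact; masks as MET_UCHAR. The custom
# header key `CalibratedBoneFraction` records the 0-1064 calibration flag.

.met_types <- list(
  MET_UCHAR  = list(what = "integer", size = 1L, signed = FALSE),
  MET_CHAR   = list(what = "integer", size = 1L, signed = TRUE),
  MET_USHORT = list(what = "integer", size = 2L, signed = FALSE),
  MET_SHORT  = list(what = "integer", size = 2L, signed = TRUE),
  MET_UINT   = list(what = "integer", size = 4L, signed = TRUE),
  MET_INT    = list(what = "integer", size = 4L, signed = TRUE),
  MET_FLOAT  = list(what = "double",  size = 4L, signed = TRUE),
  MET_DOUBLE = list(what = "double",  size = 8L, signed = TRUE)
)

write_metaimage <- function(voxels, spacing, origin, path, element_type,
                            calibrated = FALSE) {
  d <- dim(voxels)
  ext <- tolower(tools::file_ext(path))
  local_data <- ext == "mha"
  if (!ext %in% c("mha", "mhd"))
    stop("MetaImage path must end in .mha or .mhd", call. = FALSE)
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    paste("DimSize =", paste(d, collapse = " ")),
    paste("ElementSpacing =", paste(format(spacing, digits = 17), collapse = " ")),
    paste("Offset =", paste(format(origin, digits = 17), collapse = " ")),
    paste("CalibratedBoneFraction =", if (calibrated) "True" else "False"),
    paste("ElementType =", element_type),
    paste("ElementDataFile =",
          if (local_data) "LOCAL" else paste0(basename(tools::file_path_sans_ext(path)), ".raw"))
  )
  tinfo <- .met_types[[element_type]]
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeLines(hdr, con)
  vals <- as.vector(voxels)
  write_raw <- function(cn) {
    if (tinfo$what == "integer")
      writeBin(as.integer(vals), cn, size = tinfo$size, endian = "little")
    else
      writeBin(as.double(vals), cn, size = tinfo$size, endian = "little")
  }
  if (local_data) {
    write_raw(con)
  } else {
    rawpath <- file.path(dirname(path),
                         paste0(basename(tools::file_path_sans_ext(path)), ".raw"))
    con2 <- file(rawpath, "wb")
    on.exit(close(con2), add = TRUE)
    write_raw(con2)
  }
  invisible(path)
}

read_metaimage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L)
      stop("MetaImage header ended before ElementDataFile: ", path, call. = FALSE)
    kv <- regmatches(line, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*)$", line))[[1L]]
    if (length(kv) != 3L)
      stop("malformed MetaImage header line: ", line, call. = FALSE)
    fields[[kv[2L]]] <- trimws(kv[3L])
    if (kv[2L] == "ElementDataFile") break
  }
  need <- c("DimSize", "ElementType", "ElementDataFile")
  miss <- setdiff(need, names(fields))
  if (length(miss))
    stop("MetaImage header missing field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  d <- as.integer(strsplit(fields$DimSize, "\\s+")[[1L]])
  if (length(d) != 3L || any(is.na(d)) || any(d < 1L))
    stop("MetaImage DimSize must give three positive integers", call. = FALSE)
  spacing <- if (!is.null(fields$ElementSpacing))
    as.numeric(strsplit(fields$ElementSpacing, "\\s+")[[1L]]) else c(1, 1, 1)
  origin <- if (!is.null(fields$Offset))
    as.numeric(strsplit(fields$Offset, "\\s+")[[1L]]) else c(0, 0, 0)
  if (identical(fields$BinaryDataByteOrderMSB, "True") ||
      identical(fields$ElementByteOrderMSB, "True"))
    stop("big-endian MetaImage data is not supported", call. = FALSE)
  tinfo <- .met_types[[fields$ElementType]]
  if (is.null(tinfo))
    stop("unsupported MetaImage ElementType: ", fields$ElementType, call. = FALSE)
  n <- prod(d)
  if (identical(fields$ElementDataFile, "LOCAL")) {
    vals <- readBin(con, tinfo$what, n = n, size = tinfo$size,
                    signed = tinfo$signed, endian = "little")
  } else {
    rawpath <- file.path(dirname(path), fields$ElementDataFile)
    if (!file.exists(rawpath))
      stop("MetaImage data file not found: ", rawpath, call. = FALSE)
    vals <- readBin(rawpath, tinfo$what, n = n, size = tinfo$size,
                    signed = tinfo$signed, endian = "little")
  }
  if (length(vals) != n)
    stop("MetaImage data truncated: expected ", n, " voxels, got ",
         length(vals), call. = FALSE)
  calibrated_volume(array(as.double(vals), d), spacing = spacing,
                    origin = origin,
                    calibrated = identical(fields$CalibratedBoneFraction, "True"))
}
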