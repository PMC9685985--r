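# Minimal DICOM series support: explicit-VR little-endian, uncompressed,
# single-sample monochrome, 16-bit pixels -- the subset needed to round-trip
# reconstructed CT slices. One file per axial slice (fixed z); slices are
# ordered by ImagePositionPatient z and must share Rows/Columns/PixelSpacing.

.dcm_uid_explicit_le <- "1.2.840.10008.1.2.1"
.dcm_calibrated_desc <- "BONE_FRACTION_0_1064"

.dcm_elem <- function(group, elem, vr, value_raw) {
  # explicit VR little endian encoding of one data element
  len <- length(value_raw)
  head <- writeBin(c(group, elem), raw(), size = 2L, endian = "little")
  if (vr %in% c("OB", "OW", "SQ", "UN", "UT")) {
    c(head, charToRaw(vr), as.raw(c(0, 0)),
      writeBin(as.integer(len), raw(), size = 4L, endian = "little"), value_raw)
  } else {
    c(head, charToRaw(vr),
      writeBin(as.integer(len), raw(), size = 2L, endian = "little"), value_raw)
  }
}

.dcm_str <- function(s) {
  r <- charToRaw(s)
  if (length(r) %% 2L == 1L) r <- c(r, charToRaw(" "))
  r
}

.dcm_us <- function(x) writeBin(as.integer(x), raw(), size = 2L, endian = "little")

write_dicom_series <- function(voxels, spacing, origin, dir_path,
                               calibrated = FALSE) {
  d <- dim(voxels)
  if (min(voxels) < 0 || max(voxels) > 65535 ||
      any(voxels != round(voxels)))
    stop("DICOM output stores 16-bit unsigned integers; voxel values must be ",
         "integers in [0, 65535] (use MetaImage for fractional grey values)",
         call. = FALSE)
  if (!dir.exists(dir_path)) dir.create(dir_path, recursive = TRUE)
  ndig <- max(4L, nchar(as.character(d[3])))
  for (k in seq_len(d[3])) {
    z <- origin[3] + (k - 1L) * spacing[3]
    # pixel data row-major by DICOM convention (rows = y, columns = x, x
    # fastest) which is R's column-major order of the nx x ny slice
    px <- as.integer(voxels[, , k])
    px[px > 32767L] <- px[px > 32767L] - 65536L  # reinterpret for 16-bit write
    meta <- c(
      .dcm_elem(0x0002L, 0x0010L, "UI", .dcm_str(.dcm_uid_explicit_le))
    )
    body <- c(
      .dcm_elem(0x0008L, 0x103EL, "LO",
                .dcm_str(if (calibrated) .dcm_calibrated_desc else "RAW")),
      .dcm_elem(0x0020L, 0x0013L, "IS", .dcm_str(as.character(k))),
      .dcm_elem(0x0020L, 0x0032L, "DS",
                .dcm_str(paste(format(c(origin[1], origin[2], z), digits = 17),
                               collapse = "\\"))),
      .dcm_elem(0x0028L, 0x0002L, "US", .dcm_us(1L)),
      .dcm_elem(0x0028L, 0x0004L, "CS", .dcm_str("MONOCHROME2")),
      .dcm_elem(0x0028L, 0x0010L, "US", .dcm_us(d[2])),   # Rows (y)
      .dcm_elem(0x0028L, 0x0011L, "US", .dcm_us(d[1])),   # Columns (x)
      .dcm_elem(0x0028L, 0x0030L, "DS",
                .dcm_str(paste(format(c(spacing[2], spacing[1]), digits = 17),
                               collapse = "\\"))),         # row spacing \ col spacing
      .dcm_elem(0x0028L, 0x0100L, "US", .dcm_us(16L)),
      .dcm_elem(0x0028L, 0x0101L, "US", .dcm_us(16L)),
      .dcm_elem(0x0028L, 0x0102L, "US", .dcm_us(15L)),
      .dcm_elem(0x0028L, 0x0103L, "US", .dcm_us(0L)),
      .dcm_elem(0x7FE0L, 0x0010L, "OW",
                writeBin(px, raw(), size = 2L, endian = "little"))
    )
    path <- file.path(dir_path, sprintf(paste0("slice%0", ndig, "d.dcm"), k))
    con <- file(path, "wb")
    writeBin(raw(128L), con)
    writeBin(charToRaw("DICM"), con)
    writeBin(meta, con)
    writeBin(body, con)
    close(con)
  }
  invisible(dir_path)
}

.dcm_read_file <- function(path) {
  rawv <- readBin(path, "raw", n = file.info(path)$size)
  if (length(rawv) < 200L || rawToChar(rawv[129:132]) != "DICM")
    stop("not a DICOM file (missing DICM magic): ", path, call. = FALSE)
  pos <- 133L
  u16 <- function(at) sum(as.integer(rawv[at + 0:1]) * c(1, 256))
  u32 <- function(at) sum(as.integer(rawv[at + 0:3]) * c(1, 256, 65536, 16777216))
  tags <- list()
  while (pos + 8L <= length(rawv)) {
    group <- u16(pos); elem <- u16(pos + 2L)
    vr <- rawToChar(rawv[pos + 4:5])
    if (vr %in% c("OB", "OW", "SQ", "UN", "UT")) {
      len <- u32(pos + 8L); data_at <- pos + 12L
    } else if (grepl("^[A-Z]{2}$", vr)) {
      len <- u16(pos + 6L); data_at <- pos + 8L
    } else {
      stop("unsupported DICOM encoding (implicit VR?) in ", path, call. = FALSE)
    }
    if (data_at + len - 1L > length(rawv))
      stop("truncated DICOM element in ", path, call. = FALSE)
    key <- sprintf("%04X,%04X", group, elem)
    tags[[key]] <- list(vr = vr, data = rawv[seq.int(data_at, length.out = len)])
    pos <- data_at + len
  }
  getstr <- function(key) {
    t <- tags[[key]]
    if (is.null(t)) return(NULL)
    trimws(rawToChar(t$data))
  }
  getus <- function(key) {
    t <- tags[[key]]
    if (is.null(t)) return(NULL)
    readBin(t$data, "integer", size = 2L, signed = FALSE, endian = "little")
  }
  ts <- getstr("0002,0010")
  if (!is.null(ts) && ts != .dcm_uid_explicit_le)
    stop("unsupported DICOM transfer syntax ", ts, " in ", path, call. = FALSE)
  rows <- getus("0028,0010"); cols <- getus("0028,0011")
  bits <- getus("0028,0100")
  if (is.null(rows) || is.null(cols))
    stop("DICOM file lacks Rows/Columns: ", path, call. = FALSE)
  if (!identical(bits, 16L))
    stop("only 16-bit DICOM pixel data is supported: ", path, call. = FALSE)
  ps <- getstr("0028,0030")
  spacing_rc <- if (is.null(ps)) c(1, 1) else as.numeric(strsplit(ps, "\\\\")[[1L]])
  ipp <- getstr("0020,0032")
  pos3 <- if (is.null(ipp)) c(0, 0, NA_real_) else as.numeric(strsplit(ipp, "\\\\")[[1L]])
  pdat <- tags[["7FE0,0010"]]
  if (is.null(pdat)) stop("DICOM file lacks PixelData: ", path, call. = FALSE)
  px <- readBin(pdat$data, "integer", n = rows * cols, size = 2L,
                signed = FALSE, endian = "little")
  if (length(px) != rows * cols)
    stop("DICOM pixel data truncated: ", path, call. = FALSE)
  list(pixels = matrix(px, nrow = cols, ncol = rows)[, , drop = FALSE],
       # matrix(px, cols, rows): px is row-major (x fastest) -> [x, y]
       rows = rows, cols = cols,
       spacing_xy = c(spacing_rc[2], spacing_rc[1]),
       position = pos3,
       series_desc = getstr("0008,103E"))
}

read_dicom_series <- function(dir_path) {
  files <- sort(list.files(dir_path, pattern = "\\.dcm$", full.names = TRUE,
                           ignore.case = TRUE))
  if (length(files) == 0L)
    files <- sort(list.files(dir_path, full.names = TRUE))
  files <- files[!dir.exists(files)]
  if (length(files) == 0L)
    stop("no DICOM slice files found in ", dir_path, call. = FALSE)
  slices <- lapply(files, .dcm_read_file)
  dims <- vapply(slices, function(s) c(s$cols, s$rows), numeric(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("DICOM slices have inconsistent Rows/Columns: cannot form a single grid",
         call. = FALSE)
  sp <- vapply(slices, function(s) s$spacing_xy, numeric(2))
  if (max(abs(sp - sp[, 1])) > 1e-9)
    stop("DICOM slices have conflicting PixelSpacing: cannot form a single grid",
         call. = FALSE)
  zs <- vapply(slices, function(s) s$position[3], numeric(1))
  ord <- if (all(is.finite(zs))) order(zs) else seq_along(slices)
  slices <- slices[ord]; zs <- zs[ord]
  dz <- 1
  if (length(zs) > 1L && all(is.finite(zs))) {
    dzs <- diff(zs)
    if (max(dzs) - min(dzs) > 1e-6 * max(abs(dzs), 1))
      stop("DICOM slice positions are not equally spaced", call. = FALSE)
    dz <- dzs[1L]
    if (dz <= 0) stop("DICOM slice positions are not strictly increasing",
                      call. = FALSE)
  }
  nx <- slices[[1L]]$cols; ny <- slices[[1L]]$rows
  vox <- array(0, c(nx, ny, length(slices)))
  for (k in seq_along(slices)) vox[, , k] <- slices[[k]]$pixels
  orig <- slices[[1L]]$position
  if (!all(is.finite(orig))) orig <- c(0, 0, 0)
  calibrated <- identical(slices[[1L]]$series_desc, .dcm_calibrated_desc)
  calibrated_volume(vox, spacing = c(sp[1, 1], sp[2, 1], dz), origin = orig,
                    calibrated = calibrated)
}
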