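# Minimal single-frame CT DICOM I/O, explicit VR little endian only.
# Covers exactly what the phantom/annotation pipeline needs: geometry,
# rescale, patient/series identity, signed 16-bit pixel data.

DICOM_TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
DICOM_SOP_CT <- "1.2.840.10008.5.1.4.1.1.2"
# long-form VRs carry a 2-byte reserved field and a 4-byte length
.dicom_long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

.u16le <- function(x) as.raw(c(x %% 256, x %/% 256))
.u32le <- function(x) as.raw(c(x %% 256, (x %/% 256) %% 256,
                               (x %/% 65536) %% 256, (x %/% 16777216) %% 256))

.dicom_pad <- function(value, vr) {
  if (length(value) %% 2L == 1L) {
    pad <- if (vr == "UI") as.raw(0L) else charToRaw(" ")
    value <- c(value, pad)
  }
  value
}

.dicom_element <- function(group, elem, vr, value_raw) {
  value_raw <- .dicom_pad(value_raw, vr)
  hdr <- c(.u16le(group), .u16le(elem), charToRaw(vr))
  if (vr %in% .dicom_long_vrs) {
    c(hdr, as.raw(c(0, 0)), .u32le(length(value_raw)), value_raw)
  } else {
    if (length(value_raw) > 65534) stop("value too long for short-form VR")
    c(hdr, .u16le(length(value_raw)), value_raw)
  }
}

.dicom_str <- function(group, elem, vr, s) {
  .dicom_element(group, elem, vr, charToRaw(paste(s, collapse = "\\")))
}

.dicom_us <- function(group, elem, x) {
  .dicom_element(group, elem, "US", .u16le(as.integer(x)))
}

.dicom_ds <- function(group, elem, x) {
  .dicom_str(group, elem, "DS", sprintf("%.10g", as.numeric(x)))
}

# deterministic short UID derived from a string seed
.dicom_uid <- function(seed_string) {
  codes <- utf8ToInt(seed_string)
  h <- 0
  for (c in codes) h <- (h * 131 + c) %% 999999937
  sprintf("1.2.826.0.1.3680043.9.7431.%d", h)
}

#' Write a CT volume as a single-frame DICOM series
#'
#' Emits one explicit-VR little-endian file per axial slice with signed
#' 16-bit pixel data, rescale slope/intercept, pixel spacing, slice
#' thickness and per-slice image position, suitable for round-tripping
#' through [read_dicom_series()] (and readable by standard DICOM tooling).
#'
#' @param volume a [ct_volume()].
#' @param dir output directory; created if missing.
#' @return invisibly, the vector of file paths written (one per slice).
#' @export
write_dicom_series <- function(volume, dir) {
  stopifnot(inherits(volume, "ct_volume"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  series_uid <- .dicom_uid(paste0("series:", volume$patient_id))
  study_uid <- .dicom_uid(paste0("study:", volume$patient_id))
  d <- dim(volume$slices[[1]])
  paths <- character(n_slices(volume))
  for (i in seq_len(n_slices(volume))) {
    sop_uid <- paste0(series_uid, ".", i)
    meta <- c(
      .dicom_str(0x0002, 0x0002, "UI", DICOM_SOP_CT),
      .dicom_str(0x0002, 0x0003, "UI", sop_uid),
      .dicom_str(0x0002, 0x0010, "UI", DICOM_TS_EXPLICIT_LE)
    )
    meta <- c(.dicom_element(0x0002, 0x0000, "UL", .u32le(length(meta))), meta)
    stored <- volume$slices[[i]]
    # DICOM pixel data is row-major from the top-left corner
    px <- writeBin(as.integer(t(stored)), raw(), size = 2, endian = "little")
    body <- c(
      .dicom_str(0x0008, 0x0016, "UI", DICOM_SOP_CT),
      .dicom_str(0x0008, 0x0018, "UI", sop_uid),
      .dicom_str(0x0008, 0x0060, "CS", "CT"),
      .dicom_str(0x0010, 0x0020, "LO", volume$patient_id),
      .dicom_ds(0x0018, 0x0050, volume$slice_thickness),
      .dicom_str(0x0020, 0x000D, "UI", study_uid),
      .dicom_str(0x0020, 0x000E, "UI", series_uid),
      .dicom_str(0x0020, 0x0013, "IS", sprintf("%d", i)),
      .dicom_ds(0x0020, 0x0032, c(0, 0, volume$slice_positions[i])),
      .dicom_ds(0x0020, 0x0037, c(1, 0, 0, 0, 1, 0)),
      .dicom_us(0x0028, 0x0002, 1),
      .dicom_str(0x0028, 0x0004, "CS", "MONOCHROME2"),
      .dicom_us(0x0028, 0x0010, d[1]),
      .dicom_us(0x0028, 0x0011, d[2]),
      .dicom_ds(0x0028, 0x0030, volume$pixel_spacing),
      .dicom_us(0x0028, 0x0100, 16),
      .dicom_us(0x0028, 0x0101, 16),
      .dicom_us(0x0028, 0x0102, 15),
      .dicom_us(0x0028, 0x0103, 1),
      .dicom_ds(0x0028, 0x1052, volume$rescale_intercept),
      .dicom_ds(0x0028, 0x1053, volume$rescale_slope),
      .dicom_element(0x7FE0, 0x0010, "OW", px)
    )
    path <- file.path(dir, sprintf("slice_%04d.dcm", i))
    con <- file(path, "wb")
    writeBin(c(raw(128), charToRaw("DICM"), meta, body), con)
    close(con)
    paths[i] <- path
  }
  invisible(paths)
}

.parse_dicom_file <- function(path) {
  r <- readBin(path, "raw", n = file.size(path))
  if (length(r) < 140 || rawToChar(r[129:132]) != "DICM")
    stop("not a DICOM part-10 file: ", path)
  pos <- 133L
  u16 <- function(i) as.integer(r[i]) + 256L * as.integer(r[i + 1L])
  u32 <- function(i) u16(i) + 65536 * u16(i + 2L)
  els <- list()
  while (pos + 7L <= length(r)) {
    group <- u16(pos); elem <- u16(pos + 2L)
    vr <- rawToChar(r[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr))
      stop("only explicit-VR little-endian DICOM is supported: ", path)
    if (vr %in% .dicom_long_vrs) {
      len <- u32(pos + 8L); vstart <- pos + 12L
    } else {
      len <- u16(pos + 6L); vstart <- pos + 8L
    }
    value <- if (len > 0) r[vstart:(vstart + len - 1L)] else raw(0)
    els[[sprintf("%04X,%04X", group, elem)]] <- list(vr = vr, value = value)
    pos <- vstart + len
  }
  els
}

.el_str <- function(els, key) {
  e <- els[[key]]
  if (is.null(e)) return(NULL)
  v <- e$value
  while (length(v) && v[length(v)] %in% as.raw(c(0x00, 0x20)))
    v <- v[-length(v)]
  if (!length(v)) return("")
  trimws(rawToChar(v))
}

.el_num <- function(els, key) {
  s <- .el_str(els, key)
  if (is.null(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}

.el_us <- function(els, key) {
  e <- els[[key]]
  if (is.null(e)) return(NULL)
  readBin(e$value, "integer", n = 1, size = 2, signed = FALSE,
          endian = "little")
}

#' Read a single-frame CT DICOM series into a CT volume
#'
#' Reads every DICOM file in `directory`, checks that they belong to one
#' series with consistent slice shapes, and returns the slices sorted
#' ascending by position along the scan axis (the third component of Image
#' Position Patient), falling back to Instance Number when positions are
#' absent. Duplicated slice positions and mixed series are rejected.
#'
#' @param directory path containing the `.dcm` files of one series.
#' @return a [ct_volume()]; rescale slope/intercept default to 1/0 when the
#'   file omits them.
#' @export
read_dicom_series <- function(directory) {
  files <- list.files(directory, pattern = "\\.dcm$", full.names = TRUE,
                      ignore.case = TRUE)
  if (length(files) == 0)
    files <- list.files(directory, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0) stop("no DICOM files in ", directory)
  parsed <- lapply(files, function(f) {
    els <- .parse_dicom_file(f)
    rows <- .el_us(els, "0028,0010"); cols <- .el_us(els, "0028,0011")
    if (is.null(rows) || is.null(cols)) stop("missing Rows/Columns in ", f)
    pe <- els[["7FE0,0010"]]
    if (is.null(pe)) stop("missing pixel data in ", f)
    signed <- isTRUE(.el_us(els, "0028,0103") == 1L)
    vals <- readBin(pe$value, "integer", n = rows * cols, size = 2,
                    signed = signed, endian = "little")
    ipp <- .el_num(els, "0020,0032")
    list(patient_id = .el_str(els, "0010,0020"),
         series_uid = .el_str(els, "0020,000E"),
         instance = .el_num(els, "0020,0013"),
         position = if (!is.null(ipp)) ipp[3] else NA_real_,
         thickness = .el_num(els, "0018,0050"),
         spacing = .el_num(els, "0028,0030"),
         slope = .el_num(els, "0028,1053"),
         intercept = .el_num(els, "0028,1052"),
         stored = t(matrix(vals, nrow = cols, ncol = rows)))
  })
  uids <- vapply(parsed, function(p) p$series_uid %||% "", "")
  if (length(unique(uids)) > 1L)
    stop("directory mixes multiple DICOM series")
  shapes <- vapply(parsed, function(p) dim(p$stored), integer(2))
  if (any(shapes != shapes[, 1]))
    stop("inconsistent slice shapes within the series")
  pos <- vapply(parsed, function(p) p$position, 0)
  if (anyNA(pos)) {
    inst <- vapply(parsed, function(p) p$instance %||% NA_real_, 0)
    if (anyNA(inst)) stop("neither slice positions nor instance numbers present")
    if (anyDuplicated(inst)) stop("duplicated instance numbers in series")
    pos <- inst
  } else if (anyDuplicated(pos)) {
    stop("duplicated slice positions in series")
  }
  p1 <- parsed[[1]]
  ct_volume(patient_id = p1$patient_id %||% "unknown",
            slices = lapply(parsed, function(p) p$stored),
            rescale_slope = (p1$slope %||% 1),
            rescale_intercept = (p1$intercept %||% 0),
            pixel_spacing = p1$spacing %||% c(1, 1),
            slice_positions = pos,
            slice_thickness = p1$thickness %||% 1)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a
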