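# Minimal DICOM codec for single-frame CT series, Explicit VR Little Endian
# (transfer syntax 1.2.840.10008.1.2.1).  Covers exactly what the pipeline
# needs: uncompressed 16-bit monochrome slices with geometry and modality
# rescale tags.  Compressed transfer syntaxes, sequences with undefined
# length and multi-frame objects are rejected.

TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
SOP_CT <- "1.2.840.10008.5.1.4.1.1.2"

u16raw <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
u32raw <- function(x) {
  # writeBin size 4 is signed; split to avoid overflow beyond 2^31-1
  x <- as.numeric(x)
  lo <- x %% 65536
  hi <- x %/% 65536
  c(u16raw(lo), u16raw(hi))
}

# one UID from the current RNG stream: reproducible under set.seed()
dcm_uid <- function() {
  paste0("2.25.", sample(1:9, 1),
         paste(sample(0:9, 24, replace = TRUE), collapse = ""))
}

pad_even <- function(r, pad = as.raw(0x20)) {
  if (length(r) %% 2L == 1L) c(r, pad) else r
}

dcm_element <- function(group, elem, vr, value_raw) {
  head <- c(u16raw(group), u16raw(elem), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN"))
    c(head, raw(2), u32raw(length(value_raw)), value_raw)
  else
    c(head, u16raw(length(value_raw)), value_raw)
}

dcm_str_element <- function(group, elem, vr, value) {
  pad <- if (vr == "UI") as.raw(0) else as.raw(0x20)
  dcm_element(group, elem, vr, pad_even(charToRaw(value), pad))
}

dcm_us_element <- function(group, elem, value)
  dcm_element(group, elem, "US", u16raw(value))

# numbers in DICOM decimal strings: up to 16 bytes
ds_format <- function(x) paste(vapply(x, function(v)
  formatC(v, digits = 10, format = "g"), ""), collapse = "\\")

encode_pixels_int16 <- function(values, signed) {
  v <- as.integer(round(values))
  if (signed) {
    if (min(v) < -32768L || max(v) > 32767L)
      stop(sprintf("pixel value extremum %d outside signed 16-bit range",
                   if (min(v) < -32768L) min(v) else max(v)), call. = FALSE)
  } else {
    if (min(v) < 0L || max(v) > 65535L)
      stop(sprintf("pixel value extremum %d outside unsigned 16-bit range",
                   if (min(v) < 0L) min(v) else max(v)), call. = FALSE)
    v <- ifelse(v > 32767L, v - 65536L, v)  # two's complement for writeBin
  }
  writeBin(v, raw(), size = 2, endian = "little")
}

#' Write a CT volume as a DICOM series
#'
#' Writes one uncompressed single-frame Explicit-VR-little-endian CT file per
#' slice, with geometry tags (ImagePositionPatient, ImageOrientationPatient,
#' PixelSpacing, SliceThickness) derived from the volume geometry and the
#' modality rescale stored under tags (0028,1052)/(0028,1053).
#'
#' UIDs are drawn from the R random stream, so series written under
#' `set.seed()` are byte-reproducible.
#'
#' @param v a [ct_volume()]; stored values must fit 16-bit storage.
#' @param directory output directory (created if needed).
#' @param signed store pixels as signed (`PixelRepresentation=1`, default) or
#'   unsigned 16-bit integers.
#' @return invisibly, the vector of files written (in slice order).
#' @export
write_dicom_series <- function(v, directory, signed = TRUE) {
  validate_ct_volume(v)
  if (!nzchar(directory)) stop("empty output path", call. = FALSE)
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  d <- dim(v$voxels)
  study_uid <- dcm_uid(); series_uid <- dcm_uid()
  iop <- c(v$direction[, 3], v$direction[, 2])  # row dir, then column dir
  files <- character(d[1])
  for (k in seq_len(d[1])) {
    sop_uid <- dcm_uid()
    ipp <- index_to_world(v, c(k - 1, 0, 0))[1, ]
    px <- encode_pixels_int16(as.vector(t(v$voxels[k, , , drop = TRUE])),
                              signed)
    ds <- c(
      dcm_str_element(0x0008, 0x0016, "UI", SOP_CT),
      dcm_str_element(0x0008, 0x0018, "UI", sop_uid),
      dcm_str_element(0x0008, 0x0060, "CS", "CT"),
      dcm_str_element(0x0018, 0x0050, "DS", ds_format(v$spacing[1])),
      dcm_str_element(0x0020, 0x000D, "UI", study_uid),
      dcm_str_element(0x0020, 0x000E, "UI", series_uid),
      dcm_str_element(0x0020, 0x0013, "IS", as.character(k)),
      dcm_str_element(0x0020, 0x0032, "DS", ds_format(ipp)),
      dcm_str_element(0x0020, 0x0037, "DS", ds_format(iop)),
      dcm_us_element(0x0028, 0x0002, 1),
      dcm_str_element(0x0028, 0x0004, "CS", "MONOCHROME2"),
      dcm_us_element(0x0028, 0x0010, d[2]),
      dcm_us_element(0x0028, 0x0011, d[3]),
      dcm_str_element(0x0028, 0x0030, "DS",
                      ds_format(c(v$spacing[2], v$spacing[3]))),
      dcm_us_element(0x0028, 0x0100, 16),
      dcm_us_element(0x0028, 0x0101, 16),
      dcm_us_element(0x0028, 0x0102, 15),
      dcm_us_element(0x0028, 0x0103, if (signed) 1 else 0),
      dcm_str_element(0x0028, 0x1052, "DS", ds_format(v$rescale_intercept)),
      dcm_str_element(0x0028, 0x1053, "DS", ds_format(v$rescale_slope)),
      dcm_element(0x7FE0, 0x0010, "OW", px)
    )
    meta_body <- c(
      dcm_element(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
      dcm_str_element(0x0002, 0x0002, "UI", SOP_CT),
      dcm_str_element(0x0002, 0x0003, "UI", sop_uid),
      dcm_str_element(0x0002, 0x0010, "UI", TS_EXPLICIT_LE),
      dcm_str_element(0x0002, 0x0012, "UI", "2.25.73123721569321515")
    )
    meta <- c(dcm_element(0x0002, 0x0000, "UL", u32raw(length(meta_body))),
              meta_body)
    files[k] <- file.path(directory, sprintf("slice_%04d.dcm", k))
    con <- file(files[k], "wb")
    writeBin(c(raw(128), charToRaw("DICM"), meta, ds), con)
    close(con)
  }
  invisible(files)
}

# --- reading ----------------------------------------------------------------

rd_u16 <- function(r, pos) sum(as.integer(r[pos + 0:1]) * c(1L, 256L))
rd_u32 <- function(r, pos) sum(as.numeric(r[pos + 0:3]) * 256^(0:3))

# parse one Explicit VR LE dataset into a list keyed "GGGG,EEEE"
parse_dicom_elements <- function(r, pos, end) {
  out <- list()
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (pos + 7 <= end) {
    group <- rd_u16(r, pos); elem <- rd_u16(r, pos + 2)
    vr <- rawToChar(r[pos + 4:5])
    if (vr %in% long_vrs) {
      len <- rd_u32(r, pos + 8); body <- pos + 12
    } else {
      len <- rd_u16(r, pos + 6); body <- pos + 8
    }
    if (len == 4294967295)
      stop("undefined-length element not supported", call. = FALSE)
    key <- sprintf("%04X,%04X", group, elem)
    val_raw <- if (len > 0) r[body + seq_len(len) - 1] else raw(0)
    out[[key]] <- decode_dicom_value(vr, val_raw)
    pos <- body + len
  }
  out
}

raw_to_string <- function(val_raw) {
  # strip padding (trailing NUL or space) at the byte level: string literals
  # and regexes cannot carry NUL in R
  while (length(val_raw) > 0 &&
         val_raw[length(val_raw)] %in% as.raw(c(0x00, 0x20)))
    val_raw <- val_raw[-length(val_raw)]
  rawToChar(val_raw)
}

decode_dicom_value <- function(vr, val_raw) {
  if (vr %in% c("DS", "IS")) {
    as.numeric(strsplit(raw_to_string(val_raw), "\\\\")[[1]])
  } else if (vr %in% c("UI", "CS", "LO", "SH", "PN", "AE", "LT", "ST", "DA",
                       "TM", "AS", "UT")) {
    raw_to_string(val_raw)
  } else if (vr == "US") {
    vapply(seq_len(length(val_raw) / 2),
           function(i) rd_u16(val_raw, 2 * i - 1), 0)
  } else if (vr == "UL") {
    vapply(seq_len(length(val_raw) / 4),
           function(i) rd_u32(val_raw, 4 * i - 3), 0)
  } else {
    val_raw
  }
}

# read one DICOM file into a tag list (meta group + dataset merged)
parse_dicom_file <- function(path) {
  r <- readBin(path, raw(), n = file.size(path))
  if (length(r) < 200 || rawToChar(r[129:132]) != "DICM")
    stop(sprintf("%s: not a DICOM part-10 file", path), call. = FALSE)
  pos <- 133
  # file meta group is always Explicit VR LE; its group length bounds it
  if (rd_u16(r, pos) != 2L)
    stop(sprintf("%s: missing file meta group", path), call. = FALSE)
  meta_len <- rd_u32(r, pos + 8)
  meta <- parse_dicom_elements(r, pos, pos + 11 + meta_len)
  ts <- meta[["0002,0010"]]
  if (!identical(ts, TS_EXPLICIT_LE))
    stop(sprintf("%s: unsupported transfer syntax '%s'", path, ts),
         call. = FALSE)
  ds <- parse_dicom_elements(r, pos + 12 + meta_len, length(r))
  c(meta, ds)
}

decode_pixels_int16 <- function(val_raw, n, signed) {
  readBin(val_raw, "integer", n = n, size = 2, signed = signed,
          endian = "little")
}

#' Read a DICOM CT series from a directory
#'
#' Reads all DICOM files in `directory`, verifies they belong to a single
#' series with consistent in-plane geometry, sorts slices by the projection of
#' ImagePositionPatient onto the slice normal (filenames are ignored for
#' ordering), and assembles a [ct_volume()] of *stored* values.  The rescale
#' slope/intercept are taken from tags (0028,1053)/(0028,1052); when absent
#' they default to 1 and 0 with a warning, since downstream calibration
#' depends on stored-value consistency.
#'
#' @param directory path containing one DICOM series.
#' @return a [ct_volume()].
#' @export
read_dicom_series <- function(directory) {
  files <- list.files(directory, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0)
    stop(sprintf("no files found in '%s'", directory), call. = FALSE)
  tags <- lapply(files, parse_dicom_file)

  series <- unique(vapply(tags, function(t) t[["0020,000E"]] %||% "", ""))
  if (length(series) != 1)
    stop(sprintf("directory mixes %d series UIDs; refusing to assemble",
                 length(series)), call. = FALSE)
  for (i in seq_along(tags))
    if (is.null(tags[[i]][["7FE0,0010"]]))
      stop(sprintf("%s: missing pixel data", files[i]), call. = FALSE)

  rows <- unique(vapply(tags, function(t) t[["0028,0010"]][1], 0))
  cols <- unique(vapply(tags, function(t) t[["0028,0011"]][1], 0))
  ps <- unique(vapply(tags, function(t)
    paste(signif(t[["0028,0030"]], 12), collapse = ","), ""))
  iop_s <- unique(vapply(tags, function(t)
    paste(signif(t[["0020,0037"]], 12), collapse = ","), ""))
  if (length(rows) != 1 || length(cols) != 1 || length(ps) != 1 ||
      length(iop_s) != 1)
    stop("inconsistent in-plane geometry across slices", call. = FALSE)

  iop <- tags[[1]][["0020,0037"]]
  if (is.null(iop)) iop <- c(1, 0, 0, 0, 1, 0)
  rowdir <- iop[1:3]; coldir <- iop[4:6]
  normal <- c(rowdir[2] * coldir[3] - rowdir[3] * coldir[2],
              rowdir[3] * coldir[1] - rowdir[1] * coldir[3],
              rowdir[1] * coldir[2] - rowdir[2] * coldir[1])

  ipp <- t(vapply(tags, function(t) t[["0020,0032"]] %||% c(0, 0, 0),
                  numeric(3)))
  proj <- as.vector(ipp %*% normal)
  ord <- order(proj)
  tags <- tags[ord]; ipp <- ipp[ord, , drop = FALSE]; proj <- proj[ord]

  n <- length(tags)
  slice_sp <- if (n > 1) {
    dif <- diff(proj)
    if (any(dif <= 0)) stop("duplicate slice positions in series", call. = FALSE)
    if (diff(range(dif)) > 1e-3 * mean(dif))
      warning("non-uniform slice spacing; using the mean", call. = FALSE)
    mean(dif)
  } else {
    st <- tags[[1]][["0018,0050"]]
    if (is.null(st) || !is.finite(st[1]) || st[1] <= 0) 1 else st[1]
  }

  slope <- tags[[1]][["0028,1053"]]
  intercept <- tags[[1]][["0028,1052"]]
  if (is.null(slope) || is.null(intercept)) {
    warning(paste("rescale tags (0028,1052)/(0028,1053) absent;",
                  "defaulting to slope 1, intercept 0"), call. = FALSE)
    if (is.null(slope)) slope <- 1
    if (is.null(intercept)) intercept <- 0
  }

  pixel_rep <- tags[[1]][["0028,0103"]] %||% 1
  pxsp <- tags[[1]][["0028,0030"]]  # (row spacing, column spacing)
  vox <- array(0L, c(n, rows, cols))
  for (k in seq_len(n)) {
    v <- decode_pixels_int16(tags[[k]][["7FE0,0010"]], rows * cols,
                             signed = pixel_rep == 1)
    vox[k, , ] <- t(matrix(v, nrow = cols, ncol = rows))
  }

  ct_volume(vox,
            spacing = c(slice_sp, pxsp[1], pxsp[2]),
            origin = ipp[1, ],
            direction = cbind(normal, coldir, rowdir),
            rescale_slope = slope[1], rescale_intercept = intercept[1],
            source_id = directory)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
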