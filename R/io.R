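# Volume readers/writers: NIfTI-1 (via RNifti), MetaImage (.mhd/.raw, own
# codec) and DICOM series (own codec, see dicom.R).  Internal world
# coordinates are LPS (the DICOM patient system); NIfTI stores RAS, so the
# first two affine rows are negated on the way out and back.

# LPS 4x4 affine mapping (col,row,slice) 0-based indices to world mm
lps_affine <- function(g) {
  A <- cbind(g$direction[, 3] * g$spacing[3],
             g$direction[, 2] * g$spacing[2],
             g$direction[, 1] * g$spacing[1],
             g$origin)
  rbind(A, c(0, 0, 0, 1))
}

affine_to_geometry <- function(A) {
  M <- A[1:3, 1:3]
  sp_xyz <- sqrt(colSums(M^2))
  D <- sweep(M, 2, sp_xyz, "/")
  list(spacing = rev(sp_xyz),                        # (slice,row,col)
       origin = A[1:3, 4],
       direction = D[, 3:1])                         # columns slice,row,col
}

write_nifti_volume <- function(values, g, path) {
  img <- RNifti::asNifti(aperm(values, c(3, 2, 1)))
  A <- lps_affine(g)
  A[1:2, ] <- -A[1:2, ]  # LPS -> RAS
  RNifti::`sform<-`(img, structure(A, code = 2L)) -> img
  RNifti::`qform<-`(img, structure(A, code = 2L)) -> img
  RNifti::writeNifti(img, path)
  invisible(path)
}

read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  A <- RNifti::xform(img, useQuaternionFirst = FALSE)
  A[1:2, ] <- -A[1:2, ]  # RAS -> LPS
  vals <- aperm(array(as.numeric(img), dim(img)), c(3, 2, 1))
  list(values = vals, geometry = affine_to_geometry(unclass(A)))
}

# --- MetaImage --------------------------------------------------------------

write_metaimage_volume <- function(values, g, path, element_type) {
  if (!grepl("\\.mhd$", path)) path <- paste0(path, ".mhd")
  raw_name <- sub("\\.mhd$", ".raw", basename(path))
  d <- dim(values)                     # (slice,row,col)
  M <- cbind(g$direction[, 3], g$direction[, 2], g$direction[, 1])
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    paste("TransformMatrix =", paste(formatC(as.vector(M), digits = 17,
                                             format = "g"), collapse = " ")),
    paste("Offset =", paste(formatC(g$origin, digits = 17, format = "g"),
                            collapse = " ")),
    "CenterOfRotation = 0 0 0",
    paste("ElementSpacing =", paste(formatC(c(g$spacing[3], g$spacing[2],
                                              g$spacing[1]), digits = 17,
                                            format = "g"), collapse = " ")),
    paste("DimSize =", paste(c(d[3], d[2], d[1]), collapse = " ")),
    paste("ElementType =", element_type),
    paste("ElementDataFile =", raw_name)
  )
  writeLines(hdr, path)
  v <- as.vector(aperm(values, c(3, 2, 1)))  # x (column) fastest
  con <- file(file.path(dirname(path), raw_name), "wb")
  on.exit(close(con))
  if (element_type == "MET_SHORT") {
    writeBin(as.integer(round(v)), con, size = 2, endian = "little")
  } else if (element_type == "MET_DOUBLE") {
    writeBin(as.numeric(v), con, size = 8, endian = "little")
  } else stop("unsupported ElementType ", element_type, call. = FALSE)
  invisible(path)
}

read_metaimage_volume <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, "", 1)
  val <- function(k) {
    i <- match(k, keys)
    if (is.na(i)) NULL else kv[[i]][2]
  }
  numv <- function(k) as.numeric(strsplit(val(k), "\\s+")[[1]])
  if (!identical(val("BinaryDataByteOrderMSB"), "False"))
    stop("big-endian MetaImage not supported", call. = FALSE)
  if (identical(val("CompressedData"), "True"))
    stop("compressed MetaImage not supported", call. = FALSE)
  d_xyz <- numv("DimSize")
  sp_xyz <- numv("ElementSpacing")
  off <- numv("Offset")
  M <- matrix(numv("TransformMatrix"), 3, 3)
  et <- val("ElementType")
  raw_path <- file.path(dirname(path), val("ElementDataFile"))
  n <- prod(d_xyz)
  v <- if (et == "MET_SHORT") {
    readBin(raw_path, "integer", n = n, size = 2, signed = TRUE,
            endian = "little")
  } else if (et == "MET_DOUBLE") {
    readBin(raw_path, "double", n = n, size = 8, endian = "little")
  } else stop("unsupported ElementType ", et, call. = FALSE)
  vals <- aperm(array(v, d_xyz), c(3, 2, 1))
  list(values = vals,
       geometry = list(spacing = rev(sp_xyz), origin = off,
                       direction = M[, 3:1]))
}

# --- dispatcher -------------------------------------------------------------

#' Write a volume to NIfTI, MetaImage or a DICOM series
#'
#' NIfTI and MetaImage store floating-point values losslessly (float64).
#' DICOM output of a floating-point [scalar_volume()] is re-encoded to
#' unsigned 16-bit with intercept 0 and slope `max(values) / (2^16 - 1)`
#' recorded in tags (0028,1053)/(0028,1052), preserving relative precision
#' across the value range; values are recovered within half an encoding step.
#'
#' @param v a [ct_volume()] or [scalar_volume()].
#' @param path output file (`.nii`/`.mhd`) or directory (DICOM).
#' @param format one of `"nifti"`, `"metaimage"`, `"dicom"`.
#' @return invisibly, the path written.
#' @seealso [read_volume()]
#' @export
write_volume <- function(v, path, format = c("nifti", "metaimage", "dicom")) {
  format <- match.arg(format)
  if (is.null(path) || !nzchar(path)) stop("empty output path", call. = FALSE)
  g <- volume_geometry(v)
  if (inherits(v, "ct_volume")) {
    switch(format,
      nifti = write_nifti_volume(v$voxels, g, path),
      metaimage = write_metaimage_volume(v$voxels, g, path, "MET_SHORT"),
      dicom = write_dicom_series(v, path))
  } else if (inherits(v, "scalar_volume")) {
    switch(format,
      nifti = write_nifti_volume(v$values, g, path),
      metaimage = write_metaimage_volume(v$values, g, path, "MET_DOUBLE"),
      dicom = {
        mx <- max(v$values)
        if (min(v$values) < 0)
          stop("DICOM re-encoding requires non-negative values; found ",
               min(v$values), call. = FALSE)
        slope <- if (mx > 0) mx / 65535 else 1
        ct <- ct_volume(round(v$values / slope), spacing = g$spacing,
                        origin = g$origin, direction = g$direction,
                        rescale_slope = slope, rescale_intercept = 0,
                        source_id = "scalar re-encoding")
        write_dicom_series(ct, path, signed = FALSE)
      })
  } else stop("not a volume object", call. = FALSE)
  invisible(path)
}

#' Read a volume written by [write_volume()]
#'
#' For DICOM input the stored values are mapped back through the recorded
#' rescale slope/intercept so that floating-point round trips recover values
#' within the declared encoding tolerance.  Units are not carried by the
#' on-disk formats and must be supplied.
#'
#' @param path file or DICOM directory.
#' @param format one of `"nifti"`, `"metaimage"`, `"dicom"`.
#' @param units units tag for the returned [scalar_volume()].
#' @return a [scalar_volume()].
#' @export
read_volume <- function(path, format = c("nifti", "metaimage", "dicom"),
                        units = "HU") {
  format <- match.arg(format)
  if (format == "dicom") {
    ct <- read_dicom_series(path)
    return(scalar_volume(ct$rescale_slope * ct$voxels + ct$rescale_intercept,
                         units = units, geometry = volume_geometry(ct)))
  }
  r <- switch(format, nifti = read_nifti_volume(path),
              metaimage = read_metaimage_volume(path))
  scalar_volume(r$values, units = units, geometry = r$geometry)
}
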