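# Stored value <-> Hounsfield unit rescale contract.  DICOM stores only
# non-negative (or small signed) integers; the modality rescale tags
# (0028,1052) intercept and (0028,1053) slope define HU = m * stored + b.

#' Convert stored values to Hounsfield units
#'
#' Applies the DICOM modality rescale `HU = m * stored + b` voxel-wise, using
#' the slope and intercept carried by the volume.
#'
#' @param v a [ct_volume()].
#' @return a [scalar_volume()] in HU with the geometry of `v`.
#' @examples
#' v <- ct_volume(array(1024L, c(1, 2, 2)), rescale_slope = 1,
#'                rescale_intercept = -1024)
#' stored_to_hu(v)$values[1]  # 0 HU: water
#' @export
stored_to_hu <- function(v) {
  validate_ct_volume(v)
  scalar_volume(v$rescale_slope * v$voxels + v$rescale_intercept,
                units = "HU", geometry = volume_geometry(v))
}

#' Convert a Hounsfield-unit volume back to stored values
#'
#' Inverse of [stored_to_hu()]: `stored = round((HU - b) / m)`.  Composing
#' with [stored_to_hu()] reproduces HU to within `|m| / 2`.
#'
#' @param hu a [scalar_volume()] with units `"HU"`.
#' @param m rescale slope (nonzero).
#' @param b rescale intercept in HU.
#' @param storage_range allowed stored-value range, default signed 16-bit.
#' @return a [ct_volume()] carrying `m` and `b`.
#' @export
hu_to_stored <- function(hu, m = 1, b = 0,
                         storage_range = c(-32768, 32767)) {
  stopifnot(inherits(hu, "scalar_volume"), hu$units == "HU")
  if (!is.finite(m) || m == 0) stop("rescale slope m must be nonzero", call. = FALSE)
  stored <- round((hu$values - b) / m)
  if (min(stored) < storage_range[1] || max(stored) > storage_range[2])
    stop(sprintf(
      "stored values [%g, %g] leave the representable range [%g, %g]",
      min(stored), max(stored), storage_range[1], storage_range[2]),
      call. = FALSE)
  g <- hu$geometry
  ct_volume(stored, spacing = g$spacing, origin = g$origin,
            direction = g$direction, rescale_slope = m,
            rescale_intercept = b, source_id = "hu_to_stored")
}
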