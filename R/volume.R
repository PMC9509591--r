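#' @keywords internal
"_PACKAGE"

# Internal array order is (slice, row, column); voxel indices are 0-based in
# the index<->world mapping.  World coordinates follow the scanner's patient
# coordinate system (LPS) as given by the direction cosines.

#' CT volume of stored integer values
#'
#' A `ct_volume` is the raw representation of a CT series: a 3D array of
#' *stored* integer pixel values (not Hounsfield units) together with the
#' geometry and the rescale metadata needed to recover HU via
#' `HU = m * stored + b`.
#'
#' @param voxels 3D integer-valued array, dimension order (slice, row, column).
#' @param spacing numeric length-3, voxel size in mm per (slice, row, column)
#'   axis; all components must be > 0.
#' @param origin numeric length-3, world position (mm, patient coordinates) of
#'   the centre of voxel (0,0,0).
#' @param direction 3x3 matrix whose columns are the unit world-direction
#'   vectors of increasing slice, row and column index.  The default is the
#'   standard axial orientation: slices advance along +z, rows along +y,
#'   columns along +x, so world (x, y, z) = spacing * (col, row, slice)
#'   index.
#' @param rescale_slope rescale slope `m` (unitless, nonzero).
#' @param rescale_intercept rescale intercept `b` in HU.
#' @param source_id free-text provenance string.
#'
#' @return An object of class `ct_volume`.
#' @examples
#' v <- ct_volume(array(0L, c(2, 4, 4)), spacing = c(1, 0.5, 0.5))
#' dim(v$voxels)
#' @export
ct_volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                      direction = axial_direction(), rescale_slope = 1,
                      rescale_intercept = 0, source_id = "") {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) == 2L) dim(voxels) <- c(1L, dim(voxels))
  obj <- structure(list(
    voxels = voxels,
    spacing = as.numeric(spacing),
    origin = as.numeric(origin),
    direction = matrix(as.numeric(direction), 3, 3),
    rescale_slope = as.numeric(rescale_slope),
    rescale_intercept = as.numeric(rescale_intercept),
    source_id = as.character(source_id)
  ), class = "ct_volume")
  validate_ct_volume(obj)
}

validate_ct_volume <- function(x) {
  stopifnot(inherits(x, "ct_volume"))
  if (length(dim(x$voxels)) != 3L || length(x$voxels) == 0L)
    stop("voxels must be a non-empty 3D array", call. = FALSE)
  if (length(x$spacing) != 3L || any(!is.finite(x$spacing)) ||
      any(x$spacing <= 0))
    stop("all spacing components must be finite and > 0", call. = FALSE)
  if (length(x$origin) != 3L || any(!is.finite(x$origin)))
    stop("origin must be a finite length-3 vector", call. = FALSE)
  if (!is.finite(x$rescale_slope) || x$rescale_slope == 0)
    stop("rescale slope m must be nonzero", call. = FALSE)
  if (!is.finite(x$rescale_intercept))
    stop("rescale intercept b must be finite", call. = FALSE)
  if (any(abs(crossprod(x$direction) - diag(3)) > 1e-6))
    stop("direction matrix must have orthonormal columns", call. = FALSE)
  x
}

#' Scalar volume with physical units
#'
#' A `scalar_volume` is a 3D floating-point field derived from a
#' [ct_volume()] — Hounsfield units, QCT density, wet apparent density or
#' Young's modulus — carrying its units tag and the geometry of the volume it
#' was derived from.
#'
#' @param values 3D numeric array (slice, row, column).
#' @param units one of `"HU"`, `"mg/cm3"`, `"g/cm3"`, `"MPa"`.
#' @param geometry list with `spacing`, `origin`, `direction` (as in
#'   [ct_volume()]), usually obtained via [volume_geometry()].
#' @return An object of class `scalar_volume`.
#' @seealso [volume_geometry()], [stored_to_hu()]
#' @export
scalar_volume <- function(values, units, geometry = NULL) {
  units <- match.arg(units, c("HU", "mg/cm3", "g/cm3", "MPa"))
  values <- as.array(values)
  if (length(dim(values)) == 2L) dim(values) <- c(1L, dim(values))
  if (is.null(geometry))
    geometry <- list(spacing = c(1, 1, 1), origin = c(0, 0, 0),
                     direction = axial_direction())
  obj <- structure(list(values = values, units = units, geometry = geometry),
                   class = "scalar_volume")
  if (length(dim(obj$values)) != 3L || length(obj$values) == 0L)
    stop("values must be a non-empty 3D array", call. = FALSE)
  obj
}

#' Standard axial direction matrix
#'
#' Columns are the world directions of increasing (slice, row, column)
#' index: +z, +y, +x.  This is the right-handed orientation of an ordinary
#' axial CT series (ImageOrientationPatient 1\\0\\0\\0\\1\\0).
#'
#' @return a 3x3 direction matrix.
#' @export
axial_direction <- function()
  cbind(c(0, 0, 1), c(0, 1, 0), c(1, 0, 0))

#' Extract the geometry of a volume
#'
#' @param v a `ct_volume` or `scalar_volume`.
#' @return list with components `spacing`, `origin`, `direction`.
#' @export
volume_geometry <- function(v) {
  if (inherits(v, "ct_volume"))
    list(spacing = v$spacing, origin = v$origin, direction = v$direction)
  else if (inherits(v, "scalar_volume"))
    v$geometry
  else stop("not a volume object", call. = FALSE)
}

volume_values <- function(v) {
  if (inherits(v, "ct_volume")) v$voxels else v$values
}

#' Map 0-based voxel indices to world coordinates
#'
#' `world = origin + direction %*% (spacing * index)`, with `index` 0-based in
#' (slice, row, column) order.
#'
#' @param v a volume object.
#' @param idx numeric matrix (n x 3) of 0-based (slice, row, column) indices,
#'   or a length-3 vector.
#' @return n x 3 matrix of world coordinates in mm.
#' @export
index_to_world <- function(v, idx) {
  g <- volume_geometry(v)
  idx <- rbind_coerce(idx)
  sweep(idx %*% diag(g$spacing) %*% t(g$direction), 2, g$origin, "+")
}

#' Map world coordinates to continuous 0-based voxel indices
#'
#' Inverse of [index_to_world()]; returns fractional indices suitable for
#' interpolation.
#'
#' @inheritParams index_to_world
#' @param xyz numeric matrix (n x 3) of world points in mm, or length-3 vector.
#' @return n x 3 matrix of continuous (slice, row, column) indices.
#' @export
world_to_index <- function(v, xyz) {
  g <- volume_geometry(v)
  xyz <- rbind_coerce(xyz)
  sweep(xyz, 2, g$origin, "-") %*% g$direction %*% diag(1 / g$spacing)
}

rbind_coerce <- function(x) {
  if (is.null(dim(x))) matrix(as.numeric(x), ncol = 3) else
    matrix(as.numeric(x), ncol = 3)
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("CT volume: %d slices x %d rows x %d cols\n", d[1], d[2], d[3]))
  cat(sprintf("  spacing (mm): %s\n", paste(signif(x$spacing, 6), collapse = " x ")))
  cat(sprintf("  rescale: HU = %g * stored + %g\n",
              x$rescale_slope, x$rescale_intercept))
  cat(sprintf("  stored range: [%g, %g]\n", min(x$voxels), max(x$voxels)))
  if (nzchar(x$source_id)) cat("  source:", x$source_id, "\n")
  invisible(x)
}

#' @export
print.scalar_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("Scalar volume [%s]: %d x %d x %d, range [%g, %g]\n",
              x$units, d[1], d[2], d[3], min(x$values), max(x$values)))
  invisible(x)
}

# shared check that two volumes have identical geometry
same_geometry <- function(a, b, tol = 0) {
  ga <- volume_geometry(a); gb <- volume_geometry(b)
  all(abs(ga$spacing - gb$spacing) <= tol) &&
    all(abs(ga$origin - gb$origin) <= tol) &&
    all(abs(ga$direction - gb$direction) <= tol)
}
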