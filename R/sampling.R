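# Phantom-insert sampling: profile lines (the workflow's "draw a line
# through a sample and average its grayscale") and cylindrical ROIs (volume
# averaging, which suppresses noise by 1/sqrt(n)).

#' Calibration sample from one phantom insert
#'
#' Pairs a manufacturer-defined QCT density with the measured mean stored
#' grayscale of the insert.
#'
#' @param label insert label.
#' @param qct_density known QCT density in mg/cm3 (>= 0).
#' @param mean_grayscale mean stored value measured over the insert.
#' @param sd_grayscale standard deviation of the sampled stored values.
#' @param n number of voxels or sample points (>= 1).
#' @return an object of class `phantom_sample`.
#' @export
phantom_sample <- function(label, qct_density, mean_grayscale,
                           sd_grayscale = 0, n = 1) {
  stopifnot(is.finite(qct_density), qct_density >= 0,
            is.finite(mean_grayscale), n >= 1, sd_grayscale >= 0)
  structure(list(label = as.character(label),
                 qct_density = as.numeric(qct_density),
                 mean_grayscale = as.numeric(mean_grayscale),
                 sd_grayscale = as.numeric(sd_grayscale),
                 n = as.integer(n)),
            class = "phantom_sample")
}

#' @export
print.phantom_sample <- function(x, ...) {
  cat(sprintf("%s: %.1f mg/cm3 <-> grayscale %.2f (sd %.2f, n=%d)\n",
              x$label, x$qct_density, x$mean_grayscale, x$sd_grayscale, x$n))
  invisible(x)
}

#' Profile line through a phantom insert
#'
#' @param start,end world coordinates (mm) of the line endpoints.
#' @param step sampling interval along the line in mm (> 0).
#' @return an object of class `profile_line`.
#' @export
profile_line <- function(start, end, step) {
  start <- as.numeric(start); end <- as.numeric(end)
  stopifnot(length(start) == 3, length(end) == 3)
  if (all(start == end)) stop("profile line has zero length", call. = FALSE)
  if (!is.finite(step) || step <= 0)
    stop("profile line step must be > 0", call. = FALSE)
  structure(list(start = start, end = end, step = as.numeric(step)),
            class = "profile_line")
}

#' Cylindrical region of interest
#'
#' @param center world coordinates (mm) of the cylinder centre.
#' @param axis cylinder axis direction; must have unit norm (tolerance 1e-9)
#'   or be normalisable via `normalize = TRUE`.
#' @param radius cylinder radius in mm (> 0).
#' @param half_height half the cylinder height in mm (> 0).
#' @param normalize if `TRUE`, normalise `axis` to unit length.
#' @return an object of class `cylinder_roi`.
#' @export
cylinder_roi <- function(center, axis = c(1, 0, 0), radius, half_height,
                         normalize = FALSE) {
  axis <- as.numeric(axis)
  if (normalize) axis <- axis / sqrt(sum(axis^2))
  if (abs(sqrt(sum(axis^2)) - 1) > 1e-9)
    stop("cylinder axis must be a unit vector", call. = FALSE)
  if (!is.finite(radius) || radius <= 0) stop("radius must be > 0", call. = FALSE)
  if (!is.finite(half_height) || half_height <= 0)
    stop("half_height must be > 0", call. = FALSE)
  structure(list(center = as.numeric(center), axis = axis,
                 radius = as.numeric(radius),
                 half_height = as.numeric(half_height)),
            class = "cylinder_roi")
}

# trilinear interpolation of a (slice,row,col) array at fractional 0-based
# indices (n x 3 matrix); points must lie inside [0, dim-1] per axis
trilinear <- function(arr, idx) {
  d <- dim(arr)
  i0 <- pmin(floor(idx[, 1]), d[1] - 2); i0 <- pmax(i0, 0)
  j0 <- pmin(floor(idx[, 2]), d[2] - 2); j0 <- pmax(j0, 0)
  k0 <- pmin(floor(idx[, 3]), d[3] - 2); k0 <- pmax(k0, 0)
  # degenerate single-voxel axes: clamp base to 0 and weight to 0
  if (d[1] == 1) i0 <- rep(0, nrow(idx))
  if (d[2] == 1) j0 <- rep(0, nrow(idx))
  if (d[3] == 1) k0 <- rep(0, nrow(idx))
  fi <- idx[, 1] - i0; fj <- idx[, 2] - j0; fk <- idx[, 3] - k0
  if (d[1] == 1) fi <- 0
  if (d[2] == 1) fj <- 0
  if (d[3] == 1) fk <- 0
  g <- function(di, dj, dk)
    arr[cbind(pmin(i0 + di, d[1] - 1) + 1,
              pmin(j0 + dj, d[2] - 1) + 1,
              pmin(k0 + dk, d[3] - 1) + 1)]
  (1 - fi) * (1 - fj) * (1 - fk) * g(0, 0, 0) +
    fi * (1 - fj) * (1 - fk) * g(1, 0, 0) +
    (1 - fi) * fj * (1 - fk) * g(0, 1, 0) +
    fi * fj * (1 - fk) * g(1, 1, 0) +
    (1 - fi) * (1 - fj) * fk * g(0, 0, 1) +
    fi * (1 - fj) * fk * g(1, 0, 1) +
    (1 - fi) * fj * fk * g(0, 1, 1) +
    fi * fj * fk * g(1, 1, 1)
}

#' Sample stored values along a profile line
#'
#' Samples the stored values of a CT volume at uniform steps along a line in
#' world coordinates, with trilinear interpolation, and summarises them into a
#' [phantom_sample()] (without a density; see `qct_density`).
#'
#' @param v a [ct_volume()].
#' @param line a [profile_line()].
#' @param qct_density known insert density in mg/cm3 to attach to the sample.
#' @param label sample label.
#' @return a [phantom_sample()].
#' @export
sample_profile_line <- function(v, line, qct_density = 0, label = "line") {
  validate_ct_volume(v)
  stopifnot(inherits(line, "profile_line"))
  len <- sqrt(sum((line$end - line$start)^2))
  tt <- seq(0, len, by = line$step) / len
  if (tt[length(tt)] < 1) tt <- c(tt, 1)
  pts <- outer(tt, line$end - line$start) +
    matrix(line$start, length(tt), 3, byrow = TRUE)
  idx <- world_to_index(v, pts)
  d <- dim(v$voxels)
  bad <- which(idx[, 1] < 0 | idx[, 1] > d[1] - 1 |
               idx[, 2] < 0 | idx[, 2] > d[2] - 1 |
               idx[, 3] < 0 | idx[, 3] > d[3] - 1)
  if (length(bad) > 0)
    stop(sprintf("profile line leaves the volume at t = %.4f (point %d of %d)",
                 tt[bad[1]], bad[1], length(tt)), call. = FALSE)
  vals <- trilinear(v$voxels, idx)
  phantom_sample(label, qct_density, mean(vals), stats::sd(vals),
                 length(vals))
}

#' Sample stored values over a cylindrical ROI
#'
#' Averages the stored values of all voxels whose centres fall inside the
#' cylinder; no interpolation is involved, so the count equals the number of
#' included voxels.
#'
#' @param v a [ct_volume()].
#' @param roi a [cylinder_roi()].
#' @inheritParams sample_profile_line
#' @return a [phantom_sample()].
#' @export
sample_cylinder_roi <- function(v, roi, qct_density = 0, label = "roi") {
  validate_ct_volume(v)
  stopifnot(inherits(roi, "cylinder_roi"))
  sel <- cylinder_mask(v, roi)
  vals <- v$voxels[sel]
  if (length(vals) == 0)
    stop("cylinder ROI contains no voxel centres", call. = FALSE)
  phantom_sample(label, qct_density, mean(vals),
                 if (length(vals) > 1) stats::sd(vals) else 0, length(vals))
}

# logical mask of voxel centres inside a cylinder ROI
cylinder_mask <- function(v, roi) {
  d <- dim(volume_values(v))
  idx <- as.matrix(expand.grid(i = 0:(d[1] - 1), j = 0:(d[2] - 1),
                               k = 0:(d[3] - 1)))
  w <- index_to_world(v, idx)
  rel <- sweep(w, 2, roi$center, "-")
  ax <- as.vector(rel %*% roi$axis)
  rad2 <- rowSums(rel^2) - ax^2
  m <- abs(ax) <= roi$half_height & rad2 <= roi$radius^2
  array(m, d)  # expand.grid varies i fastest: already column-major (i,j,k)
}
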