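# Synthetic CT phantoms and bone-like volumes with closed-form ground truth.
# The generators emulate a calibration acquisition: stored values are the
# known density line inverted and rounded to integers, plus additive
# Gaussian noise on the stored scale (no spatial correlation, no scanner
# artifacts).  All randomness comes from R's Mersenne-Twister with inversion
# sampling, seeded per design, so volumes are bit-reproducible.

#' Design of a synthetic calibration phantom
#'
#' The default design emulates a five-insert QCT phantom on a 1 mm grid:
#' insert densities 0-800 mg/cm3 (a typical solid-phantom range), a
#' water-equivalent background, a grayscale-density line with slope 0.8
#' mg/cm3 per stored unit (chosen so every insert density sits on an exact
#' integer stored value, making the noise-free design invertible to machine
#' precision), and additive stored-value noise of SD 20.  Each insert
#' cylinder covers about 400 voxel centres.
#'
#' @param insert_densities QCT densities of the inserts in mg/cm3.
#' @param insert_centers n x 3 matrix of cylinder centres in world mm
#'   (x, y, z); with the default axial orientation and unit spacing, x runs
#'   along columns, y along rows and z across slices.
#' @param insert_radius,insert_half_height cylinder geometry in mm (shared).
#' @param background_density background QCT density in mg/cm3.
#' @param true_slope,true_intercept the density = slope * grayscale +
#'   intercept line used to synthesise stored values.
#' @param noise_sd additive Gaussian noise SD on the stored-value scale.
#' @param dim volume dimensions (slice, row, column).
#' @param spacing voxel spacing in mm.
#' @param rng_seed integer seed recorded in the output metadata.
#' @return an object of class `phantom_design`.
#' @export
phantom_design <- function(insert_densities = c(0, 100, 200, 400, 800),
                           insert_centers = rbind(
                             c(10, 10, 3.5), c(10, 30, 3.5), c(20, 20, 3.5),
                             c(30, 10, 3.5), c(30, 30, 3.5)),
                           insert_radius = 4, insert_half_height = 3.5,
                           background_density = 0,
                           true_slope = 0.8, true_intercept = -780,
                           noise_sd = 20,
                           dim = c(8, 40, 40), spacing = c(1, 1, 1),
                           rng_seed = 1L) {
  insert_centers <- matrix(insert_centers, ncol = 3)
  stopifnot(length(insert_densities) == nrow(insert_centers),
            all(insert_densities >= 0), noise_sd >= 0,
            insert_radius > 0, insert_half_height > 0, true_slope != 0)
  structure(list(insert_densities = insert_densities,
                 insert_centers = insert_centers,
                 insert_radius = insert_radius,
                 insert_half_height = insert_half_height,
                 background_density = background_density,
                 true_slope = true_slope, true_intercept = true_intercept,
                 noise_sd = noise_sd, dim = as.integer(dim),
                 spacing = spacing, rng_seed = as.integer(rng_seed)),
            class = "phantom_design")
}

density_to_stored <- function(rho, slope, intercept)
  round((rho - intercept) / slope)

#' Generate a synthetic phantom scan with ground truth
#'
#' Builds a [ct_volume()] whose insert cylinders carry stored values on the
#' design's grayscale-density line (rounded to integers before noise), plus
#' seeded Gaussian noise; stored values are clipped to signed 16-bit and
#' clipping events are counted.  The ground truth carries the exact noiseless
#' density field and per-insert true means.
#'
#' @param design a [phantom_design()].
#' @return list with `volume` (a [ct_volume()]), `truth` (noiseless density
#'   [scalar_volume()], per-insert table, the true line), `rois` (one
#'   [cylinder_roi()] per insert), `n_clipped`, and `design`.
#' @export
make_phantom_volume <- function(design) {
  stopifnot(inherits(design, "phantom_design"))
  d <- design$dim
  geom_v <- ct_volume(array(0L, d), spacing = design$spacing)
  n_ins <- length(design$insert_densities)
  axis <- c(0, 0, 1)  # cylinders run across the slices
  rois <- lapply(seq_len(n_ins), function(i)
    cylinder_roi(design$insert_centers[i, ], axis = axis,
                 radius = design$insert_radius,
                 half_height = design$insert_half_height))
  masks <- lapply(rois, function(r) cylinder_mask(geom_v, r))
  overlap <- Reduce(`+`, lapply(masks, as.integer))
  if (any(overlap > 1))
    stop("insert cylinders overlap; phantom design rejected", call. = FALSE)
  lower <- index_to_world(geom_v, c(0, 0, 0))[1, ]
  upper <- index_to_world(geom_v, d - 1)[1, ]
  # world-axis extent of a cylinder: |a_i|*hh + r*sqrt(1 - a_i^2) per axis
  ext <- abs(axis) * design$insert_half_height +
    design$insert_radius * sqrt(pmax(1 - axis^2, 0))
  for (i in seq_len(n_ins)) {
    ctr <- design$insert_centers[i, ]
    if (any(ctr - ext < pmin(lower, upper)) ||
        any(ctr + ext > pmax(lower, upper)))
      stop(sprintf("insert %d extends outside the volume", i), call. = FALSE)
    if (sum(masks[[i]]) == 0)
      stop(sprintf("insert %d contains no voxel centres", i), call. = FALSE)
  }

  rho <- array(design$background_density, d)
  for (i in seq_len(n_ins)) rho[masks[[i]]] <- design$insert_densities[i]
  base <- density_to_stored(rho, design$true_slope, design$true_intercept)

  old_kind <- RNGkind("Mersenne-Twister", "Inversion")
  on.exit(RNGkind(old_kind[1], old_kind[2]), add = TRUE)
  set.seed(design$rng_seed)
  stored <- round(base + stats::rnorm(length(base), 0, design$noise_sd))
  n_clipped <- sum(stored < -32768 | stored > 32767)
  stored <- pmin(pmax(stored, -32768), 32767)
  dim(stored) <- d

  vol <- ct_volume(stored, spacing = design$spacing,
                   rescale_slope = 1, rescale_intercept = -1024,
                   source_id = sprintf("synthetic phantom (seed %d)",
                                       design$rng_seed))
  insert_table <- data.frame(
    label = paste0("insert", seq_len(n_ins)),
    qct_density_mg_cm3 = design$insert_densities,
    true_grayscale = density_to_stored(design$insert_densities,
                                       design$true_slope,
                                       design$true_intercept),
    n_voxels = vapply(masks, sum, 0L)
  )
  truth <- list(
    density = scalar_volume(rho, "mg/cm3", volume_geometry(vol)),
    inserts = insert_table,
    true_slope = design$true_slope,
    true_intercept = design$true_intercept
  )
  list(volume = vol, truth = truth, rois = rois, n_clipped = n_clipped,
       design = design)
}

#' Generate a synthetic bone-like volume with ground truth
#'
#' A simple long-bone cross-section: a dense cortical shell (annular
#' cylinder), a lower-density trabecular interior with voxel-wise integer
#' densities drawn uniformly from `interior_density_range`, and optionally an
#' internal air pocket.  Stored values equal the QCT densities (identity
#' calibration), so the conversion pipeline can be checked bit-for-bit
#' against the carried ground-truth modulus volume.
#'
#' @param shell_density cortical shell QCT density in mg/cm3; must map above
#'   the cutoff.
#' @param interior_density_range length-2 range (mg/cm3) for the trabecular
#'   interior; must map inside (0, cutoff].
#' @param pocket_density QCT density of the air pocket (mg/cm3, mapping to
#'   apparent density <= 0), or `NULL` to omit the pocket.
#' @param law the [material_law()] used both to validate the densities and to
#'   compute the ground-truth modulus volume.
#' @param dim volume dimensions (slice, row, column).
#' @param inner_radius in-plane radius (voxels) of the trabecular interior;
#'   everything outside it is cortical shell, so a pocket-free volume
#'   contains no air voxels and `inner_radius = 0` gives a shell-only
#'   (all-cortical) volume.
#' @param pocket_radius air-pocket radius in voxels.
#' @param rng_seed integer seed for the interior density draw.
#' @return list with `volume` (a [ct_volume()], identity calibration),
#'   `truth` (density/apparent/modulus [scalar_volume()]s plus branch
#'   counts), and `calibration` (the identity model to feed the pipeline).
#' @export
make_bone_volume <- function(shell_density = 1100,
                             interior_density_range = c(100, 500),
                             pocket_density = -300,
                             law = material_law(),
                             dim = c(12, 32, 32), inner_radius = 9,
                             pocket_radius = 3, rng_seed = 1L) {
  app <- function(rho) law$lotz_slope * rho + law$lotz_intercept
  if (app(shell_density) <= law$cutoff_density)
    stop("shell_density must map above the cortical cutoff", call. = FALSE)
  if (app(interior_density_range[1]) <= 0 ||
      app(interior_density_range[2]) > law$cutoff_density)
    stop("interior_density_range must map inside (0, cutoff]", call. = FALSE)
  if (!is.null(pocket_density) && app(pocket_density) > 0)
    stop("pocket_density must map to apparent density <= 0", call. = FALSE)

  d <- as.integer(dim)
  ctr <- c(d[2] + 1, d[3] + 1) / 2
  g <- expand.grid(i = seq_len(d[1]), j = seq_len(d[2]), k = seq_len(d[3]))
  r2 <- (g$j - ctr[1])^2 + (g$k - ctr[2])^2

  old_kind <- RNGkind("Mersenne-Twister", "Inversion")
  on.exit(RNGkind(old_kind[1], old_kind[2]), add = TRUE)
  set.seed(rng_seed)

  rho <- array(shell_density, d)
  interior <- r2 <= inner_radius^2
  pocket <- if (is.null(pocket_density)) rep(FALSE, nrow(g)) else
    interior & (g$j - ctr[1] - 3)^2 + (g$k - ctr[2])^2 <= pocket_radius^2
  interior_only <- interior & !pocket
  if (any(interior_only))
    rho[interior_only] <- sample(seq(interior_density_range[1],
                                     interior_density_range[2]),
                                 sum(interior_only), replace = TRUE)
  if (any(pocket)) rho[pocket] <- pocket_density

  vol <- ct_volume(rho, rescale_slope = 1, rescale_intercept = -1024,
                   source_id = sprintf("synthetic bone (seed %d)", rng_seed))
  geom <- volume_geometry(vol)
  density <- scalar_volume(rho, "mg/cm3", geom)
  apparent <- qct_to_apparent(density, law)
  modulus <- apparent_to_modulus(apparent, law)
  br <- classify_branch(apparent, law)
  truth <- list(density = density, apparent = apparent, modulus = modulus,
                branch_counts = c(air = sum(br == 0L),
                                  trabecular = sum(br == 1L),
                                  cortical = sum(br == 2L)),
                rng_seed = rng_seed)
  identity_model <- list(slope = 1, intercept = 0)
  list(volume = vol, truth = truth, calibration = identity_model)
}
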