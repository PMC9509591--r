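# Density -> Young's modulus material law.  QCT density is first converted to
# wet apparent density by the Lotz linear relation
#   rho_app (g/cm3) = 0.0012 * rho_CT (mg/cm3) + 0.17,
# then mapped through three branches: air pockets get a constant low modulus,
# trabecular bone a density power law (Morgan-type coefficient pre-adjusted
# by a 1.28 transverse-stiffness factor), cortical bone a constant modulus.
# The inequalities leave rho = 0 and rho = cutoff formally unassigned; here
# rho <= 0 is air and 0 < rho <= cutoff is trabecular, so the upward jump to
# the cortical constant is not applied one ULP early.

#' Construct a material law
#'
#' Holds every constant of the piecewise density-to-modulus mapping.  The
#' defaults are the published constants: Lotz conversion 0.0012 / 0.17,
#' air modulus 1 MPa, trabecular law `11417.6 * rho^1.89` MPa (the 1.28
#' transverse-stiffness factor already folded into the coefficient),
#' cortical modulus 17,000 MPa, cortical cutoff density 1 g/cm3.
#'
#' @param lotz_slope g/cm3 per mg/cm3 (default 0.0012).
#' @param lotz_intercept g/cm3 (default 0.17).
#' @param air_modulus MPa assigned where apparent density <= 0 (default 1).
#' @param trab_coefficient MPa per (g/cm3)^exponent (default 11417.6, which
#'   is the base trabecular coefficient times `transverse_factor`).
#' @param trab_exponent unitless power (default 1.89).
#' @param cortical_modulus MPa above the cutoff (default 17000).
#' @param cutoff_density trabecular/cortical cutoff in g/cm3 (default 1.0);
#'   user-settable, as operators may prefer a site-specific threshold.
#' @param modulus_floor MPa floor applied to the trabecular branch (default
#'   1, i.e. the air modulus) so that vanishing positive densities cannot
#'   yield sub-air stiffness, which would ill-condition FE solves.  Set 0 to
#'   disable.
#' @param transverse_factor the transverse-stiffness adjustment (default
#'   1.28).  Informational unless `base_trab_coefficient` is supplied, in
#'   which case `trab_coefficient` is computed as
#'   `base_trab_coefficient * transverse_factor`.
#' @param base_trab_coefficient optional unadjusted trabecular coefficient.
#' @return an object of class `material_law`.
#' @examples
#' law <- material_law()
#' apparent_to_modulus(c(-0.1, 0.5, 1.0, 1.5), law)
#' @export
material_law <- function(lotz_slope = 0.0012, lotz_intercept = 0.17,
                         air_modulus = 1, trab_coefficient = 11417.6,
                         trab_exponent = 1.89, cortical_modulus = 17000,
                         cutoff_density = 1.0, modulus_floor = 1,
                         transverse_factor = 1.28,
                         base_trab_coefficient = NULL) {
  if (!is.null(base_trab_coefficient))
    trab_coefficient <- base_trab_coefficient * transverse_factor
  law <- structure(list(
    lotz_slope = lotz_slope, lotz_intercept = lotz_intercept,
    air_modulus = air_modulus, trab_coefficient = trab_coefficient,
    trab_exponent = trab_exponent, cortical_modulus = cortical_modulus,
    cutoff_density = cutoff_density, modulus_floor = modulus_floor,
    transverse_factor = transverse_factor
  ), class = "material_law")
  validate_material_law(law)
}

validate_material_law <- function(law) {
  with(law, {
    if (air_modulus <= 0 || trab_coefficient <= 0 || cortical_modulus <= 0)
      stop("all moduli must be > 0", call. = FALSE)
    if (cutoff_density <= 0) stop("cutoff_density must be > 0", call. = FALSE)
    if (trab_exponent <= 0) stop("trab_exponent must be > 0", call. = FALSE)
    if (modulus_floor < 0) stop("modulus_floor must be >= 0", call. = FALSE)
    trab_at_cut <- trab_coefficient * cutoff_density^trab_exponent
    if (trab_at_cut > cortical_modulus)
      warning(sprintf(paste("trabecular law at the cutoff (%.1f MPa) exceeds",
                            "the cortical modulus (%.1f MPa): the mapping is",
                            "non-monotone"),
                      trab_at_cut, cortical_modulus), call. = FALSE)
  })
  law
}

#' @export
print.material_law <- function(x, ...) {
  cat("Piecewise density -> modulus law:\n")
  cat(sprintf("  rho_app = %g * rho_CT + %g   [g/cm3 from mg/cm3]\n",
              x$lotz_slope, x$lotz_intercept))
  cat(sprintf("  rho <= 0            : E = %g MPa (air)\n", x$air_modulus))
  cat(sprintf("  0 < rho <= %g       : E = max(%g * rho^%g, %g) MPa\n",
              x$cutoff_density, x$trab_coefficient, x$trab_exponent,
              x$modulus_floor))
  cat(sprintf("  rho > %g            : E = %g MPa (cortical)\n",
              x$cutoff_density, x$cortical_modulus))
  invisible(x)
}

#' Read or write a material law as YAML
#'
#' All constants live in one config file; nothing is hard-coded in the
#' conversion routines.
#'
#' @param path YAML file.
#' @return for `read_material_law`, a [material_law()].
#' @examples
#' read_material_law(system.file("extdata", "material_law.yaml",
#'                               package = "qct2e"))
#' @export
read_material_law <- function(path) {
  if (!file.exists(path))
    stop(sprintf("material-law file '%s' not found", path), call. = FALSE)
  cfg <- yaml::read_yaml(path)
  known <- names(formals(material_law))
  bad <- setdiff(names(cfg), known)
  if (length(bad) > 0)
    stop("unknown material-law fields: ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(material_law, cfg)
}

#' @rdname read_material_law
#' @param law a [material_law()] to serialise.
#' @export
write_material_law <- function(law, path) {
  yaml::write_yaml(unclass(law), path)
  invisible(path)
}

#' Convert QCT density to wet apparent density
#'
#' The Lotz linear relation `rho_app = 0.0012 * rho_CT + 0.17` (defaults),
#' element-wise.  Negative inputs are allowed — scanners report sub-water
#' densities — and negative outputs are meaningful (air branch).
#'
#' @param rho_ct numeric vector/array of QCT densities (mg/cm3), or a
#'   [scalar_volume()] with units `"mg/cm3"`.
#' @param law a [material_law()] supplying the Lotz constants.
#' @return same shape as the input, in g/cm3 (a [scalar_volume()] in, a
#'   [scalar_volume()] out).
#' @export
qct_to_apparent <- function(rho_ct, law = material_law()) {
  if (inherits(rho_ct, "scalar_volume")) {
    stopifnot(rho_ct$units == "mg/cm3")
    return(scalar_volume(law$lotz_slope * rho_ct$values + law$lotz_intercept,
                         units = "g/cm3", geometry = rho_ct$geometry))
  }
  law$lotz_slope * rho_ct + law$lotz_intercept
}

#' Convert wet apparent density to Young's modulus
#'
#' The three-branch law: `rho <= 0` is air (`air_modulus`);
#' `0 < rho <= cutoff_density` is trabecular,
#' `max(trab_coefficient * rho^trab_exponent, modulus_floor)`;
#' `rho > cutoff_density` is cortical (`cortical_modulus`).
#'
#' @param rho_app numeric vector/array of wet apparent densities (g/cm3), or
#'   a [scalar_volume()] with units `"g/cm3"`.
#' @param law a [material_law()].
#' @return Young's moduli in MPa, same shape as the input.
#' @export
apparent_to_modulus <- function(rho_app, law = material_law()) {
  if (inherits(rho_app, "scalar_volume")) {
    stopifnot(rho_app$units == "g/cm3")
    return(scalar_volume(apparent_to_modulus(rho_app$values, law),
                         units = "MPa", geometry = rho_app$geometry))
  }
  validate_material_law(law)
  e <- array(law$air_modulus, dim = dim(rho_app) %||% length(rho_app))
  trab <- rho_app > 0 & rho_app <= law$cutoff_density
  e[trab] <- pmax(law$trab_coefficient * rho_app[trab]^law$trab_exponent,
                  law$modulus_floor)
  e[rho_app > law$cutoff_density] <- law$cortical_modulus
  if (is.null(dim(rho_app))) as.vector(e) else e
}

#' Classify apparent densities into material branches
#'
#' @inheritParams apparent_to_modulus
#' @return integer codes: 0 air, 1 trabecular, 2 cortical.
#' @export
classify_branch <- function(rho_app, law = material_law()) {
  if (inherits(rho_app, "scalar_volume")) rho_app <- rho_app$values
  b <- array(0L, dim = dim(rho_app) %||% length(rho_app))
  b[rho_app > 0 & rho_app <= law$cutoff_density] <- 1L
  b[rho_app > law$cutoff_density] <- 2L
  if (is.null(dim(rho_app))) as.vector(b) else b
}

#' Run the full grayscale-to-modulus conversion on a volume
#'
#' Chains [apply_calibration()], [qct_to_apparent()] and
#' [apparent_to_modulus()] voxel-for-voxel and summarises the result:
#' per-branch voxel counts, modulus range, and the magnitude of the
#' discontinuity the law has at the cutoff (with defaults, E jumps from
#' 11,417.6 to 17,000 MPa there).
#'
#' @param v a [ct_volume()].
#' @param model a `calibration_model` (or list with `slope`/`intercept`).
#' @param law a [material_law()].
#' @param keep_intermediates return the QCT-density and apparent-density
#'   volumes alongside the modulus volume.
#' @return list with `modulus` ([scalar_volume()] in MPa), `branch_counts`
#'   (named vector: air/trabecular/cortical), `summary` (list), and — when
#'   requested — `qct_density` and `apparent_density`.
#' @export
convert_volume <- function(v, model, law = material_law(),
                           keep_intermediates = FALSE) {
  validate_material_law(law)
  rho_ct <- apply_calibration(v, model)
  rho_app <- qct_to_apparent(rho_ct, law)
  e <- apparent_to_modulus(rho_app, law)
  br <- classify_branch(rho_app, law)
  counts <- c(air = sum(br == 0L), trabecular = sum(br == 1L),
              cortical = sum(br == 2L))
  jump <- law$cortical_modulus -
    max(law$trab_coefficient * law$cutoff_density^law$trab_exponent,
        law$modulus_floor)
  out <- list(
    modulus = e,
    branch_counts = counts,
    summary = list(
      n_voxels = length(e$values),
      branch_counts = as.list(counts),
      modulus_MPa = list(min = min(e$values),
                         median = stats::median(e$values),
                         max = max(e$values)),
      cutoff_density_g_cm3 = law$cutoff_density,
      cutoff_jump_MPa = jump,
      calibration = list(slope = model$slope, intercept = model$intercept)
    )
  )
  if (keep_intermediates) {
    out$qct_density <- rho_ct
    out$apparent_density <- rho_app
  }
  out
}
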