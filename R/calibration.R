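# Grayscale -> QCT density calibration.  The regression operates on STORED
# grayscale values (not HU): scanner software measures in HU but results are
# converted back to stored values before the fit, and only internal
# consistency of the scale matters.  Density is the response, grayscale the
# predictor; ordinary least squares.

#' Fit the linear grayscale-to-density calibration
#'
#' Ordinary least squares of manufacturer QCT density (mg/cm3, response) on
#' measured mean stored grayscale (predictor) over the phantom inserts.
#' Phantom density scales are near-linear by construction, so a low R-squared
#' almost always indicates a setup error; a warning is emitted below
#' `r2_warn`.
#'
#' @param samples list of [phantom_sample()] objects (>= 2, with at least two
#'   distinct mean grayscales).
#' @param r2_warn warn when R-squared falls below this threshold.
#' @return an object of class `calibration_model` with elements `slope`
#'   ((mg/cm3) per stored unit), `intercept` (mg/cm3), `r_squared`,
#'   `residual_se` (mg/cm3), `slope_se`, `intercept_se`, `n_samples` and the
#'   input `samples`.
#' @examples
#' s <- lapply(1:3, function(i)
#'   phantom_sample(paste0("s", i), qct_density = 2 * (100 * i) - 100,
#'                  mean_grayscale = 100 * i))
#' fit_calibration(s)
#' @export
fit_calibration <- function(samples, r2_warn = 0.99) {
  if (inherits(samples, "phantom_sample")) samples <- list(samples)
  stopifnot(all(vapply(samples, inherits, TRUE, "phantom_sample")))
  if (length(samples) < 2)
    stop("calibration needs at least 2 phantom samples", call. = FALSE)
  g <- vapply(samples, function(s) s$mean_grayscale, 0)
  rho <- vapply(samples, function(s) s$qct_density, 0)
  if (length(unique(g)) < 2)
    stop("all sample grayscales are identical; cannot fit a line",
         call. = FALSE)
  fit <- stats::lm(rho ~ g)
  sm <- suppressWarnings(summary(fit))  # lm warns on noiseless fits
  r2 <- if (stats::var(rho) == 0) 1 else sm$r.squared
  if (is.finite(r2) && r2 < r2_warn)
    warning(sprintf("calibration R-squared %.4f below %.2f: check phantom %s",
                    r2, r2_warn, "measurements"), call. = FALSE)
  co <- sm$coefficients
  structure(list(
    slope = unname(co["g", "Estimate"]),
    intercept = unname(co["(Intercept)", "Estimate"]),
    r_squared = r2,
    residual_se = sm$sigma,
    slope_se = unname(co["g", "Std. Error"]),
    intercept_se = unname(co["(Intercept)", "Std. Error"]),
    n_samples = length(samples),
    samples = samples
  ), class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("Calibration: rho_CT = %.6g * grayscale + %.6g  [mg/cm3]\n",
              x$slope, x$intercept))
  cat(sprintf("  n = %d inserts, R^2 = %.5f, residual SE = %.4g mg/cm3\n",
              x$n_samples, x$r_squared, x$residual_se))
  invisible(x)
}

#' Apply a calibration model to a CT volume
#'
#' Maps every stored voxel value through the fitted line
#' `rho_CT = slope * stored + intercept`.  Negative calibrated densities are
#' retained: they drive the air branch of the material law downstream.
#'
#' @param v a [ct_volume()].
#' @param model a `calibration_model` from [fit_calibration()], or any list
#'   with numeric `slope` and `intercept`.
#' @return a [scalar_volume()] in mg/cm3.
#' @export
apply_calibration <- function(v, model) {
  validate_ct_volume(v)
  stopifnot(is.finite(model$slope), is.finite(model$intercept))
  scalar_volume(model$slope * v$voxels + model$intercept,
                units = "mg/cm3", geometry = volume_geometry(v))
}

#' Read a phantom specification file
#'
#' A phantom specification (YAML or JSON) lists the calibration inserts:
#' each entry has a `label`, a `qct_density_mg_cm3`, and either a
#' pre-measured `mean_grayscale` (typed in, as an operator would) or an ROI
#' to measure from the series — a cylinder
#' (`roi: {type: cylinder, center, axis, radius, half_height}`) or a line
#' (`roi: {type: line, start, end, step}`).
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @return list of insert specifications.
#' @examples
#' spec <- read_phantom_spec(system.file("extdata",
#'   "example_phantom_spec.yaml", package = "qct2e"))
#' fit_calibration(measure_phantom_samples(spec))
#' @export
read_phantom_spec <- function(path) {
  if (!file.exists(path))
    stop(sprintf("phantom specification '%s' not found", path), call. = FALSE)
  spec <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE) else
    yaml::read_yaml(path)
  inserts <- spec$inserts %||% spec
  for (ins in inserts) {
    if (is.null(ins$label) || is.null(ins$qct_density_mg_cm3))
      stop("each insert needs 'label' and 'qct_density_mg_cm3'", call. = FALSE)
    if (is.null(ins$mean_grayscale) && is.null(ins$roi))
      stop(sprintf("insert '%s' has neither mean_grayscale nor roi",
                   ins$label), call. = FALSE)
  }
  inserts
}

#' Measure phantom samples defined by a specification
#'
#' Turns each insert of a phantom specification into a [phantom_sample()]:
#' typed-in `mean_grayscale` entries are taken as-is; ROI entries are measured
#' from the volume with [sample_cylinder_roi()] or [sample_profile_line()].
#'
#' @param inserts list from [read_phantom_spec()].
#' @param v a [ct_volume()]; may be `NULL` if all inserts are pre-measured.
#' @return list of [phantom_sample()] objects.
#' @export
measure_phantom_samples <- function(inserts, v = NULL) {
  lapply(inserts, function(ins) {
    if (!is.null(ins$mean_grayscale)) {
      phantom_sample(ins$label, ins$qct_density_mg_cm3, ins$mean_grayscale,
                     ins$sd_grayscale %||% 0, ins$n %||% 1)
    } else {
      if (is.null(v))
        stop(sprintf("insert '%s' needs a volume to measure its ROI",
                     ins$label), call. = FALSE)
      roi <- ins$roi
      if (identical(roi$type, "cylinder")) {
        sample_cylinder_roi(v, cylinder_roi(unlist(roi$center),
                                            unlist(roi$axis %||% c(1, 0, 0)),
                                            roi$radius, roi$half_height),
                            qct_density = ins$qct_density_mg_cm3,
                            label = ins$label)
      } else if (identical(roi$type, "line")) {
        sample_profile_line(v, profile_line(unlist(roi$start),
                                            unlist(roi$end),
                                            roi$step %||%
                                              (min(v$spacing) / 2)),
                            qct_density = ins$qct_density_mg_cm3,
                            label = ins$label)
      } else stop(sprintf("insert '%s': unknown roi type '%s'",
                          ins$label, roi$type), call. = FALSE)
    }
  })
}

#' Write a calibration report
#'
#' Writes a CSV of the per-insert samples with the fitted coefficients, and
#' optionally a density-versus-grayscale scatter plot with the fitted line.
#'
#' @param model a `calibration_model`.
#' @param csv_path output CSV path.
#' @param plot_path optional PNG path for the scatter plot.
#' @return invisibly, the report data frame.
#' @export
write_calibration_report <- function(model, csv_path, plot_path = NULL) {
  df <- data.frame(
    label = vapply(model$samples, function(s) s$label, ""),
    qct_density_mg_cm3 = vapply(model$samples, function(s) s$qct_density, 0),
    mean_grayscale = vapply(model$samples, function(s) s$mean_grayscale, 0),
    sd_grayscale = vapply(model$samples, function(s) s$sd_grayscale, 0),
    n = vapply(model$samples, function(s) s$n, 1L),
    fitted_density = vapply(model$samples, function(s)
      model$slope * s$mean_grayscale + model$intercept, 0)
  )
  df$slope <- model$slope
  df$intercept <- model$intercept
  df$r_squared <- model$r_squared
  utils::write.csv(df, csv_path, row.names = FALSE)
  if (!is.null(plot_path)) {
    grDevices::png(plot_path, width = 640, height = 480)
    on.exit(grDevices::dev.off())
    graphics::plot(df$mean_grayscale, df$qct_density_mg_cm3,
                   xlab = "stored grayscale value",
                   ylab = "QCT density (mg/cm3)",
                   main = "Phantom calibration", pch = 19)
    graphics::abline(model$intercept, model$slope, col = "steelblue")
  }
  invisible(df)
}
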