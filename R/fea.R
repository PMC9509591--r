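# Material binning for finite-element export.  Voxel moduli are grouped into
# a small set of isotropic materials: air keeps a reserved bin 0, the
# cortical constant keeps its own top bin, and the trabecular range in
# between is partitioned equal-width in modulus or in apparent density.

#' Bin a modulus volume into FE materials
#'
#' @param e a [scalar_volume()] in MPa (output of [convert_volume()]).
#' @param n_bins number of trabecular bins (>= 1); collapsed with a warning
#'   when it exceeds the number of distinct trabecular values.
#' @param strategy `"equal-E"` (equal-width in modulus, default) or
#'   `"equal-rho"` (equal-width in apparent density, i.e. edges placed on the
#'   power-law image of an even density grid).
#' @param law the [material_law()] that produced `e`; identifies the air and
#'   cortical constants and supplies the power law for `"equal-rho"` edges.
#' @return an object of class `material_binning`: `labels` (integer volume;
#'   0 air, 1..n trabecular, n+1 cortical), `table` (data frame of bin id,
#'   representative modulus = within-bin mean, voxel count, and edges).
#' @export
bin_materials <- function(e, n_bins = 10,
                          strategy = c("equal-E", "equal-rho"),
                          law = material_law()) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(e, "scalar_volume"), e$units == "MPa", n_bins >= 1)
  v <- e$values
  is_air <- v == law$air_modulus
  is_cort <- v == law$cortical_modulus
  is_trab <- !is_air & !is_cort
  tv <- v[is_trab]

  n_distinct <- length(unique(tv))
  if (length(tv) > 0 && n_bins > n_distinct) {
    warning(sprintf("n_bins = %d exceeds %d distinct trabecular values; %s",
                    n_bins, n_distinct, "collapsing"), call. = FALSE)
    n_bins <- n_distinct
  }

  labels <- array(0L, dim(v))
  labels[is_cort] <- n_bins + 1L
  edges <- numeric(0)
  if (length(tv) > 0) {
    if (strategy == "equal-E") {
      edges <- seq(min(tv), max(tv), length.out = n_bins + 1)
    } else {
      # invert the power law at the trabecular extremes, grid in density
      rho_rng <- (range(tv) / law$trab_coefficient)^(1 / law$trab_exponent)
      rho_edges <- seq(rho_rng[1], rho_rng[2], length.out = n_bins + 1)
      edges <- law$trab_coefficient * rho_edges^law$trab_exponent
    }
    if (edges[1] == edges[n_bins + 1]) {  # constant trabecular field
      labels[is_trab] <- 1L
      edges <- c(edges[1], edges[1])
      n_bins <- 1L
    } else {
      bin <- findInterval(tv, edges, rightmost.closed = TRUE,
                          all.inside = TRUE)
      labels[is_trab] <- as.integer(bin)
    }
  }

  ids <- 0:(n_bins + 1L)
  counts <- vapply(ids, function(b) sum(labels == b), 0L)
  rep_mod <- vapply(ids, function(b) {
    if (b == 0L) law$air_modulus
    else if (b == n_bins + 1L) law$cortical_modulus
    else if (counts[b + 1L] > 0) mean(v[labels == b]) else NA_real_
  }, 0)
  tab <- data.frame(
    bin_id = ids,
    kind = c("air", rep("trabecular", n_bins), "cortical"),
    E_MPa = rep_mod,
    voxel_count = counts,
    edge_lo = c(NA, edges[seq_len(n_bins)], NA),
    edge_hi = c(NA, edges[seq_len(n_bins) + 1], NA)
  )
  structure(list(labels = labels, table = tab, n_bins = n_bins,
                 strategy = strategy, geometry = e$geometry),
            class = "material_binning")
}

#' @export
print.material_binning <- function(x, ...) {
  cat(sprintf("Material binning (%s): %d trabecular bins + air + cortical\n",
              x$strategy, x$n_bins))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Write a material table for an FE solver
#'
#' `dialect = "csv"` writes one row per occupied bin (bin_id, E_MPa,
#' voxel_count).  `dialect = "abaqus"` writes one isotropic elastic material
#' block per occupied bin.  The Poisson ratio is not part of the density
#' conversion at all — it is a configuration constant, flagged as such in the
#' output header.
#'
#' @param b a `material_binning`.
#' @param path output file.
#' @param dialect `"csv"` or `"abaqus"`.
#' @param poisson_ratio Poisson ratio emitted alongside each modulus in the
#'   solver dialect (default 0.3; configuration-supplied, not derived).
#' @return invisibly, the path written.
#' @export
write_material_table <- function(b, path, dialect = c("csv", "abaqus"),
                                 poisson_ratio = 0.3) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(b, "material_binning"))
  occ <- b$table[b$table$voxel_count > 0, , drop = FALSE]
  if (dialect == "csv") {
    utils::write.csv(occ[, c("bin_id", "E_MPa", "voxel_count")], path,
                     row.names = FALSE)
  } else {
    lines <- c("** Voxel material bins (isotropic elastic)",
               sprintf("** Poisson ratio %.3f is a configuration constant,",
                       poisson_ratio),
               "** not derived from the density-modulus conversion.")
    for (i in seq_len(nrow(occ))) {
      lines <- c(lines,
                 sprintf("*Material, name=BIN_%d_%s", occ$bin_id[i],
                         toupper(occ$kind[i])),
                 "*Elastic",
                 sprintf("%.6g, %.3f", occ$E_MPa[i], poisson_ratio))
    }
    writeLines(lines, path)
  }
  invisible(path)
}

#' Write the bin-label volume as integer NIfTI
#'
#' @param b a `material_binning`.
#' @param path output `.nii` path.
#' @return invisibly, the path written.
#' @export
write_label_volume <- function(b, path) {
  write_nifti_volume(b$labels, b$geometry, path)
  invisible(path)
}
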