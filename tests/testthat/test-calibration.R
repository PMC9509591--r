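test_that("a noiseless line is recovered to machine precision with R^2 = 1", {
  s <- lapply(c(150, 400, 650, 900), function(g)
    phantom_sample(paste0("g", g), qct_density = 2 * g - 100,
                   mean_grayscale = g))
  m <- fit_calibration(s)
  expect_equal(m$slope, 2, tolerance = 1e-12)
  expect_equal(m$intercept, -100, tolerance = 1e-12)
  expect_equal(m$r_squared, 1)
  expect_equal(m$n_samples, 4)
})

test_that("degenerate sample sets are rejected and poor fits warned about", {
  one <- phantom_sample("a", 100, 500)
  expect_error(fit_calibration(list(one)), "at least 2")
  same <- list(phantom_sample("a", 100, 500), phantom_sample("b", 300, 500))
  expect_error(fit_calibration(same), "identical")
  noisy <- list(phantom_sample("a", 0, 100), phantom_sample("b", 500, 200),
                phantom_sample("c", 100, 300))
  expect_warning(fit_calibration(noisy), "R-squared")
})

test_that("apply_calibration is the affine map slope*stored + intercept", {
  v <- uniform_ct(0, dim = c(2, 4, 4))
  out <- apply_calibration(v, list(slope = 2, intercept = -100))
  expect_true(all(out$values == -100))
  expect_equal(out$units, "mg/cm3")

  # identity model reinterprets stored values as densities
  set.seed(41)
  v2 <- random_ct(dim = c(2, 4, 4))
  idm <- apply_calibration(v2, list(slope = 1, intercept = 0))
  expect_equal(as.vector(idm$values), as.numeric(v2$voxels))

  # shifting the stored values by k shifts every output by slope*k
  v3 <- ct_volume(v2$voxels + 37L, spacing = v2$spacing)
  m <- list(slope = 1.7, intercept = 12)
  expect_equal(apply_calibration(v3, m)$values,
               apply_calibration(v2, m)$values + 1.7 * 37,
               tolerance = 1e-12)
})

test_that("a volume held at a sample's mean grayscale calibrates to that
          sample's fitted density within the residual SE", {
  set.seed(42)
  g <- c(100, 300, 500, 700, 900)
  rho <- 1.5 * g - 50 + stats::rnorm(5, 0, 5)
  s <- mapply(function(gi, ri) phantom_sample("s", max(ri, 0), gi),
              g, rho, SIMPLIFY = FALSE)
  m <- fit_calibration(s, r2_warn = 0)
  v <- uniform_ct(g[3], dim = c(2, 4, 4))
  out <- apply_calibration(v, m)
  expect_lt(abs(out$values[1] - s[[3]]$qct_density), m$residual_se * 3)
})

test_that("typed-in phantom specs and measured ROIs produce the same model", {
  des <- phantom_design(noise_sd = 0)
  sim <- make_phantom_volume(des)
  measured <- measure_phantom_samples(lapply(seq_len(5), function(i) list(
    label = paste0("i", i),
    qct_density_mg_cm3 = des$insert_densities[i],
    roi = list(type = "cylinder",
               center = as.numeric(des$insert_centers[i, ]),
               axis = c(0, 0, 1), radius = des$insert_radius,
               half_height = des$insert_half_height))), sim$volume)
  typed <- measure_phantom_samples(lapply(seq_len(5), function(i) list(
    label = paste0("i", i),
    qct_density_mg_cm3 = des$insert_densities[i],
    mean_grayscale = sim$truth$inserts$true_grayscale[i])))
  m1 <- fit_calibration(measured)
  m2 <- fit_calibration(typed)
  expect_equal(m1$slope, m2$slope, tolerance = 1e-12)
  expect_equal(m1$intercept, m2$intercept, tolerance = 1e-12)
})

test_that("phantom spec files round-trip through YAML and JSON", {
  inserts <- list(
    list(label = "a", qct_density_mg_cm3 = 0, mean_grayscale = 975),
    list(label = "b", qct_density_mg_cm3 = 800, mean_grayscale = 1975))
  fy <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(inserts = inserts), fy)
  fj <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(inserts = inserts), fj, auto_unbox = TRUE)
  sy <- measure_phantom_samples(read_phantom_spec(fy))
  sj <- measure_phantom_samples(read_phantom_spec(fj))
  expect_equal(vapply(sy, function(s) s$mean_grayscale, 0),
               vapply(sj, function(s) s$mean_grayscale, 0))
  bad <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(inserts = list(list(label = "x"))), bad)
  expect_error(read_phantom_spec(bad), "qct_density")
})

test_that("calibration report CSV carries samples and coefficients", {
  s <- lapply(c(100, 500, 900), function(g)
    phantom_sample(paste0("g", g), 0.8 * g, g))
  m <- fit_calibration(s)
  f <- withr::local_tempfile(fileext = ".csv")
  df <- write_calibration_report(m, f)
  back <- utils::read.csv(f)
  expect_equal(nrow(back), 3)
  expect_equal(back$slope[1], m$slope)
  expect_equal(back$mean_grayscale, df$mean_grayscale)
})
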