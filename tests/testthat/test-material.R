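test_that("the three branches reproduce the published constants", {
  law <- material_law()
  expect_identical(apparent_to_modulus(1.5, law), 17000)
  expect_identical(apparent_to_modulus(-0.1, law), 1)
  # the cutoff itself belongs to the trabecular branch
  expect_equal(apparent_to_modulus(1.0, law), 11417.6)
  expect_equal(apparent_to_modulus(0.5, law), 11417.6 * 0.5^1.89)
  # rho = 0 belongs to the air branch
  expect_identical(apparent_to_modulus(0, law), 1)
})

test_that("the Lotz conversion is the affine map 0.0012*rho + 0.17", {
  law <- material_law()
  expect_equal(qct_to_apparent(0, law), 0.17)
  expect_equal(qct_to_apparent(1000, law), 1.37)
  expect_equal(qct_to_apparent(-0.17 / 0.0012, law), 0, tolerance = 1e-12)
})

test_that("default material law carries the documented constants and they
          survive a YAML round trip", {
  law <- material_law()
  expect_equal(law$cutoff_density, 1.0)
  expect_equal(law$trab_exponent, 1.89)
  expect_equal(law$transverse_factor, 1.28)
  expect_equal(law$trab_coefficient, 11417.6)
  expect_equal(law$cortical_modulus, 17000)
  expect_equal(law$air_modulus, 1)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_material_law(law, f)
  law2 <- read_material_law(f)
  expect_equal(unclass(law2), unclass(law))
  # supplying a base coefficient applies the transverse factor explicitly
  law3 <- material_law(base_trab_coefficient = 11417.6 / 1.28)
  expect_equal(law3$trab_coefficient, 11417.6)
})

test_that("invalid or non-monotone laws are rejected or flagged", {
  expect_error(material_law(cortical_modulus = -1), "moduli")
  expect_error(material_law(cutoff_density = 0), "cutoff")
  expect_warning(material_law(cutoff_density = 1.5), "non-monotone")
  f <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(bogus_field = 1), f)
  expect_error(read_material_law(f), "unknown material-law fields")
})

test_that("the modulus floor prevents sub-air trabecular stiffness and can
          be disabled", {
  law <- material_law()
  tiny <- 1e-6
  expect_equal(apparent_to_modulus(tiny, law), 1)
  nofloor <- material_law(modulus_floor = 0)
  expect_lt(apparent_to_modulus(tiny, nofloor), 1)
})

test_that("apparent_to_modulus is non-decreasing over a dense density grid
          with the default constants", {
  rho <- seq(-1, 3, length.out = 1e5)
  e <- apparent_to_modulus(rho, material_law())
  expect_true(all(diff(e) >= 0))
  expect_equal(range(e), c(1, 17000))
})

test_that("vectorized conversion equals a literal per-voxel scalar loop", {
  law <- material_law()
  model <- list(slope = 1.3, intercept = -200)
  set.seed(51)
  for (rep in 1:3) {
    v <- random_ct(dim = c(16, 16, 16), lo = -200, hi = 1500,
                   spacing = c(1, 1, 1))
    res <- convert_volume(v, model, law)
    oracle <- array(NA_real_, dim(v$voxels))
    for (i in seq_len(dim(v$voxels)[1]))
      for (j in seq_len(dim(v$voxels)[2]))
        for (k in seq_len(dim(v$voxels)[3])) {
          rho_ct <- model$slope * v$voxels[i, j, k] + model$intercept
          rho <- law$lotz_slope * rho_ct + law$lotz_intercept
          oracle[i, j, k] <-
            if (rho <= 0) law$air_modulus
            else if (rho <= law$cutoff_density)
              max(law$trab_coefficient * rho^law$trab_exponent,
                  law$modulus_floor)
            else law$cortical_modulus
        }
    expect_identical(res$modulus$values, oracle)
  }
})

test_that("branch counts partition the volume and the summary reports the
          cutoff discontinuity", {
  # constructed half-air / half-cortical volume
  vals <- array(0L, c(2, 4, 4))
  vals[1, , ] <- -500L   # maps below 0 g/cm3 under identity calibration
  vals[2, , ] <- 1000L   # maps above the cutoff
  v <- ct_volume(vals)
  res <- convert_volume(v, list(slope = 1, intercept = 0))
  expect_equal(unname(res$branch_counts),
               c(16, 0, 16))
  expect_equal(sum(res$branch_counts), length(vals))
  expect_equal(res$summary$cutoff_jump_MPa, 17000 - 11417.6)
  expect_true(all(res$modulus$values[1, , ] == 1))
  expect_true(all(res$modulus$values[2, , ] == 17000))
})

test_that("units tags flow mg/cm3 -> g/cm3 -> MPa through the pipeline", {
  v <- uniform_ct(500)
  res <- convert_volume(v, list(slope = 1, intercept = 0),
                        keep_intermediates = TRUE)
  expect_equal(res$qct_density$units, "mg/cm3")
  expect_equal(res$apparent_density$units, "g/cm3")
  expect_equal(res$modulus$units, "MPa")
})
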