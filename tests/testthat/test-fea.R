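make_modulus_fixture <- function(seed = 61, dim = c(4, 16, 16)) {
  set.seed(seed)
  bone <- make_bone_volume(rng_seed = seed, dim = dim)
  convert_volume(bone$volume, bone$calibration)$modulus
}

test_that("bin counts conserve the voxel total and representatives lie
          within their edges", {
  e <- make_modulus_fixture()
  b <- bin_materials(e, n_bins = 8)
  expect_equal(sum(b$table$voxel_count), length(e$values))
  trab <- b$table[b$table$kind == "trabecular" & b$table$voxel_count > 0, ]
  expect_true(all(trab$E_MPa >= trab$edge_lo - 1e-9 &
                    trab$E_MPa <= trab$edge_hi + 1e-9))
  # brute-force histogram oracle over the trabecular voxels
  law <- material_law()
  tv <- e$values[e$values != law$air_modulus &
                   e$values != law$cortical_modulus]
  edges <- seq(min(tv), max(tv), length.out = 9)
  # half-open bins [e_i, e_{i+1}) with the top edge closed
  oracle <- graphics::hist(tv, breaks = edges, right = FALSE,
                           include.lowest = TRUE, plot = FALSE)$counts
  expect_equal(b$table$voxel_count[b$table$kind == "trabecular"], oracle)
})

test_that("bin labels are monotone in representative modulus and air and
          cortical bins are isolated", {
  e <- make_modulus_fixture()
  b <- bin_materials(e, n_bins = 6)
  occ <- b$table[b$table$voxel_count > 0, ]
  expect_true(all(diff(occ$E_MPa) > 0))
  expect_equal(occ$kind[1], "air")
  expect_equal(occ$kind[nrow(occ)], "cortical")
  expect_equal(b$table$E_MPa[1], 1)
  expect_equal(b$table$E_MPa[nrow(b$table)], 17000)
})

test_that("degenerate binnings collapse sensibly", {
  # uniform cortical volume: a single occupied bin at 17000
  v <- uniform_ct(1000)
  e <- convert_volume(v, list(slope = 1, intercept = 0))$modulus
  b <- bin_materials(e, n_bins = 5)
  occ <- b$table[b$table$voxel_count > 0, ]
  expect_equal(nrow(occ), 1)
  expect_equal(occ$E_MPa, 17000)

  # n_bins = 1 pools all trabecular voxels into one bin at their mean
  e2 <- make_modulus_fixture()
  b1 <- bin_materials(e2, n_bins = 1)
  law <- material_law()
  tv <- e2$values[e2$values != law$air_modulus &
                    e2$values != law$cortical_modulus]
  expect_equal(b1$table$E_MPa[b1$table$kind == "trabecular"], mean(tv))

  # more bins than distinct values collapses with a warning
  vals <- array(c(rep(1, 10), rep(5000, 10), rep(17000, 12)), c(2, 4, 4))
  e3 <- scalar_volume(vals, "MPa")
  expect_warning(b3 <- bin_materials(e3, n_bins = 4), "collapsing")
  expect_equal(sum(b3$table$voxel_count), 32)
})

test_that("material tables round-trip through CSV and the solver snippet has
          one block per occupied bin", {
  e <- make_modulus_fixture()
  b <- bin_materials(e, n_bins = 3)
  f <- withr::local_tempfile(fileext = ".csv")
  write_material_table(b, f, "csv")
  back <- utils::read.csv(f)
  occ <- b$table[b$table$voxel_count > 0, ]
  expect_equal(back$bin_id, occ$bin_id)
  expect_equal(back$E_MPa, occ$E_MPa)
  expect_equal(back$voxel_count, occ$voxel_count)

  fs <- withr::local_tempfile(fileext = ".inp")
  write_material_table(b, fs, "abaqus")
  lines <- readLines(fs)
  expect_equal(sum(grepl("^\\*Material", lines)), nrow(occ))
  expect_equal(length(lines), 3 + 3 * nrow(occ))  # header + 3 per material
  expect_true(any(grepl("configuration constant", lines)))
})

test_that("the label volume writes and reads as integers with geometry", {
  e <- make_modulus_fixture()
  b <- bin_materials(e, n_bins = 4)
  f <- withr::local_tempfile(fileext = ".nii")
  write_label_volume(b, f)
  back <- read_volume(f, "nifti", units = "MPa")
  expect_equal(back$values, array(as.numeric(b$labels), dim(b$labels)))
})
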