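test_that("a written DICOM series round-trips voxels, geometry and rescale
          tags exactly", {
  set.seed(11)
  v <- random_ct(dim = c(3, 6, 5), m = 1, b = -1024)
  d <- withr::local_tempdir()
  write_dicom_series(v, d)
  v2 <- read_dicom_series(d)
  expect_identical(as.vector(v2$voxels), as.vector(v$voxels))
  expect_equal(v2$spacing, v$spacing)
  expect_equal(v2$origin, v$origin)
  expect_equal(v2$direction, v$direction)
  expect_equal(v2$rescale_slope, 1)
  expect_equal(v2$rescale_intercept, -1024)
})

test_that("slices are ordered by spatial position, not filename", {
  set.seed(12)
  v <- random_ct(dim = c(4, 4, 4))
  d <- withr::local_tempdir()
  files <- write_dicom_series(v, d)
  # shuffle the names so lexicographic order disagrees with position
  shuffled <- file.path(d, sprintf("zz_%d.dcm", c(3, 1, 4, 2)))
  file.rename(files, shuffled)
  v2 <- read_dicom_series(d)
  expect_identical(as.vector(v2$voxels), as.vector(v$voxels))

  # oracle: assemble manually from single-slice reads at known positions
  one <- withr::local_tempdir()
  for (k in 1:4) {
    file.copy(shuffled[k], file.path(one, "s.dcm"))
    slice <- read_dicom_series(one)
    expect_identical(slice$voxels[1, , ], v$voxels[k, , ])
    file.remove(file.path(one, "s.dcm"))
  }
})

test_that("missing rescale tags default to m=1, b=0 with a warning", {
  set.seed(13)
  v <- random_ct(dim = c(2, 4, 4), lo = 0, hi = 500)
  d <- withr::local_tempdir()
  files <- write_dicom_series(v, d)
  # strip the rescale elements by walking the element structure
  u16 <- function(r, p) as.integer(r[p]) + 256L * as.integer(r[p + 1])
  u32 <- function(r, p) sum(as.numeric(r[p + 0:3]) * 256^(0:3))
  strip_elements <- function(f, kill) {
    r <- readBin(f, raw(), file.size(f))
    pos <- 133
    drop <- integer(0)
    long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
    while (pos + 7 <= length(r)) {
      tag <- sprintf("%04X,%04X", u16(r, pos), u16(r, pos + 2))
      vr <- rawToChar(r[pos + 4:5])
      if (vr %in% long_vrs) {
        len <- u32(r, pos + 8); body <- pos + 12
      } else {
        len <- u16(r, pos + 6); body <- pos + 8
      }
      if (tag %in% kill) drop <- c(drop, pos:(body + len - 1))
      pos <- body + len
    }
    writeBin(r[-drop], f)
  }
  for (f in files) strip_elements(f, c("0028,1052", "0028,1053"))
  expect_warning(v2 <- read_dicom_series(d), "defaulting to slope 1")
  expect_equal(v2$rescale_slope, 1)
  expect_equal(v2$rescale_intercept, 0)
  expect_identical(as.vector(v2$voxels), as.vector(v$voxels))
})

test_that("mixed series UIDs and missing pixel data are rejected", {
  set.seed(14)
  d <- withr::local_tempdir()
  write_dicom_series(random_ct(dim = c(2, 4, 4)), d)
  d2 <- withr::local_tempdir()
  write_dicom_series(random_ct(dim = c(2, 4, 4)), d2)
  file.copy(list.files(d2, full.names = TRUE)[1],
            file.path(d, "foreign.dcm"))
  expect_error(read_dicom_series(d), "series UIDs")

  expect_error(read_dicom_series(withr::local_tempdir()), "no files")
})

test_that("inconsistent in-plane geometry within one series is rejected", {
  set.seed(15)
  d <- withr::local_tempdir()
  write_dicom_series(random_ct(dim = c(2, 4, 4), spacing = c(1, 1, 1)), d)
  d2 <- withr::local_tempdir()
  write_dicom_series(random_ct(dim = c(2, 6, 6), spacing = c(1, 2, 2),
                               origin = c(0, 0, 10)), d2)
  # transplant the first series' UID into a slice of the second (the random
  # UIDs have equal byte length, so an in-place substitution is valid DICOM)
  uid_a <- qct2e:::parse_dicom_file(
    list.files(d, full.names = TRUE)[1])[["0020,000E"]]
  f_b <- list.files(d2, full.names = TRUE)[1]
  uid_b <- qct2e:::parse_dicom_file(f_b)[["0020,000E"]]
  expect_equal(nchar(uid_a), nchar(uid_b))
  r <- readBin(f_b, raw(), file.size(f_b))
  pat <- charToRaw(uid_b)
  hit <- which(vapply(seq_len(length(r) - length(pat) + 1), function(i)
    all(r[i + seq_along(pat) - 1] == pat), TRUE))
  for (h in hit) r[h + seq_along(pat) - 1] <- charToRaw(uid_a)
  writeBin(r, file.path(d, "intruder.dcm"))
  expect_error(read_dicom_series(d), "in-plane geometry")
})

test_that("pydicom reads series written by this package identically", {
  set.seed(16)
  v <- random_ct(dim = c(2, 6, 5), m = 1, b = -1024)
  d <- withr::local_tempdir()
  write_dicom_series(v, d)
  out <- python_lines(paste0(
    "import pydicom, glob\n",
    "import numpy as np\n",
    "fs = sorted(glob.glob('", d, "/*.dcm'))\n",
    "ds = [pydicom.dcmread(f) for f in fs]\n",
    "ds.sort(key=lambda x: float(x.ImagePositionPatient[2]))\n",
    "a = np.stack([x.pixel_array for x in ds])\n",
    "print(int(a.sum()))\n",
    "print(float(ds[0].RescaleSlope), float(ds[0].RescaleIntercept))\n",
    "print(a.shape[0], a.shape[1], a.shape[2])\n"))
  expect_equal(as.numeric(out[1]), sum(v$voxels))
  expect_equal(scan(text = out[2], quiet = TRUE), c(1, -1024))
  expect_equal(scan(text = out[3], quiet = TRUE), dim(v$voxels))
})
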