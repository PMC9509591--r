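# shared fixtures: small volumes built in code

random_ct <- function(dim = c(2, 6, 5), lo = -1000, hi = 3000,
                      spacing = c(2.5, 0.7, 0.8), origin = c(10, -5, 3),
                      m = 1, b = -1024) {
  ct_volume(array(sample(lo:hi, prod(dim), replace = TRUE), dim),
            spacing = spacing, origin = origin,
            rescale_slope = m, rescale_intercept = b)
}

uniform_ct <- function(value, dim = c(4, 8, 8), spacing = c(1, 1, 1)) {
  ct_volume(array(as.integer(value), dim), spacing = spacing)
}

# an affine (hence trilinear-exact) stored-value field over the index grid
affine_field_ct <- function(dim = c(6, 10, 10), coef = c(7, 3, 2),
                            offset = 100) {
  g <- expand.grid(i = 0:(dim[1] - 1), j = 0:(dim[2] - 1),
                   k = 0:(dim[3] - 1))
  v <- offset + coef[1] * g$i + coef[2] * g$j + coef[3] * g$k
  ct_volume(array(v, dim))
}

expect_same_geometry <- function(a, b, tol = 0) {
  ga <- volume_geometry(a)
  gb <- volume_geometry(b)
  if (tol == 0) {
    expect_identical(ga$spacing, gb$spacing)
    expect_identical(ga$origin, gb$origin)
    expect_identical(ga$direction, gb$direction)
  } else {
    expect_equal(ga$spacing, gb$spacing, tolerance = tol)
    expect_equal(ga$origin, gb$origin, tolerance = tol)
    expect_equal(ga$direction, gb$direction, tolerance = tol)
  }
}

# run a python one-liner against the interpreter on PATH; used to cross-check
# the image writers against reference readers
python_lines <- function(code) {
  system2("python", c("-c", shQuote(code)), stdout = TRUE, stderr = FALSE)
}
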