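test_that("counts-per-g normalization matches hand-computed values and is linear", {
  expect_equal(normalize_counts_per_g(2048, 2048), 1.0)
  expect_equal(normalize_counts_per_g(0, 2048), 0.0)
  expect_equal(normalize_counts_per_g(-1024, 2048), -0.5)
  # linearity to machine precision
  set.seed(1)
  x <- rnorm(100, sd = 500)
  for (a in c(-3, 0.5, 7)) {
    expect_equal(normalize_counts_per_g(a * x, 2048),
                 a * normalize_counts_per_g(x, 2048))
  }
  expect_error(normalize_counts_per_g(1, 0), "positive")
  expect_error(normalize_counts_per_g(1, -5), "positive")
})

test_that("offset-code decode maps code endpoints onto the +/- half-span", {
  expect_equal(normalize_offset_code(0, 63, 1.5), -1.5)
  expect_equal(normalize_offset_code(63, 63, 1.5), 1.5)
  expect_equal(normalize_offset_code(31.5, 63, 1.5), 0)
  # linear in between
  expect_equal(normalize_offset_code(c(21, 42), 63, 1.5),
               c(-0.5, 0.5))
  expect_error(normalize_offset_code(64, 63, 1.5), "outside")
  expect_equal(normalize_offset_code(64, 63, 1.5, clip = TRUE), 1.5)
  expect_error(normalize_offset_code(1, -1, 1.5), "positive")
})

test_that("min-max normalization covers [0,1] in both orientations", {
  expect_equal(normalize_minmax(c(0, 5, 10)), c(1, 0.5, 0))
  expect_equal(normalize_minmax(c(0, 5, 10), inverted = FALSE),
               c(0, 0.5, 1))
  set.seed(2)
  x <- rnorm(200)
  y <- normalize_minmax(x)
  expect_true(all(y >= 0 & y <= 1))
  expect_equal(range(y), c(0, 1))
  expect_equal(y[which.max(x)], 0)  # max maps to 0 in inverted orientation
  expect_equal(y[which.min(x)], 1)
  expect_error(normalize_minmax(rep(3, 5)), "constant")
})

test_that("vector magnitude is the Euclidean norm and rotation-invariant", {
  expect_equal(vector_magnitude(3, 4, 0), 5)
  expect_equal(vector_magnitude(0, 0, 0), 0)
  expect_equal(vector_magnitude(1, 1, 1), sqrt(3))
  expect_error(vector_magnitude(1:3, 1:2, 1:3), "equal lengths")
  set.seed(3)
  xyz <- matrix(rnorm(3 * 1000), ncol = 3)
  v0 <- vector_magnitude(xyz[, 1], xyz[, 2], xyz[, 3])
  for (i in 1:20) {
    r <- xyz %*% random_rotation()
    expect_lt(max(abs(vector_magnitude(r[, 1], r[, 2], r[, 3]) - v0)), 1e-9)
  }
})

test_that("preprocess normalizes per axis, compounds tri-axial data, keeps length", {
  p <- device_profile("sleep")
  raw <- act_raw(matrix(rep(c(2048, 0, 0), each = 5), 5, 3), p)
  out <- preprocess(raw)
  expect_s3_class(out, "act_norm")
  expect_equal(out$values, rep(1, 5))    # 2048 counts on one axis = 1 g
  expect_equal(out$fs, 25)

  # single-axial min-max profile: identical to normalize_minmax
  pv <- device_profile("vag")
  x <- c(0, 2, 4, 8, 3)
  expect_equal(preprocess(act_raw(x, pv))$values, normalize_minmax(x))

  # length preserved for every preset
  for (nm in c("sleep", "adl", "vag")) {
    pr <- device_profile(nm)
    set.seed(4)
    m <- if (pr$norm_scheme == "offset_code")
      matrix(sample(0:63, 40 * pr$n_axes, replace = TRUE), 40)
    else matrix(rnorm(40 * pr$n_axes, sd = 100), 40)
    expect_length(preprocess(act_raw(m, pr))$values, 40)
  }
})

test_that("profile constructor validates fields and presets carry device constants", {
  sleep <- device_profile("sleep")
  expect_equal(sleep$fs, 25)
  expect_equal(sleep$resolution_bits, 16L)
  expect_equal(sleep$norm_constants$counts_per_g, 2048)
  adl <- device_profile("adl")
  expect_equal(adl$norm_constants$code_max, 63)
  expect_equal(adl$norm_constants$half_span_g, 1.5)
  vag <- device_profile("vag")
  expect_equal(vag$fs, 2000)
  expect_equal(vag$n_axes, 1L)
  expect_error(device_profile("x", fs = -1, resolution_bits = 8, n_axes = 1,
                              norm_scheme = "minmax"), "fs")
  expect_error(device_profile("x", fs = 10, resolution_bits = 40, n_axes = 1,
                              norm_scheme = "minmax"), "resolution_bits")
  expect_error(device_profile("x", fs = 10, resolution_bits = 8, n_axes = 2,
                              norm_scheme = "minmax"), "n_axes")
})

test_that("signal CSV reader detects headers and timestamp columns", {
  p <- device_profile("sleep")
  m <- matrix(round(rnorm(30, sd = 100)), 10, 3)
  f1 <- tempfile(fileext = ".csv")
  write.csv(as.data.frame(m), f1, row.names = FALSE)     # header
  got <- read_signal_csv(f1, p)
  expect_equal(unname(got$samples), unname(m))

  f2 <- tempfile(fileext = ".csv")
  write.table(m, f2, sep = ",", row.names = FALSE, col.names = FALSE)
  expect_equal(unname(read_signal_csv(f2, p)$samples), unname(m))

  f3 <- tempfile(fileext = ".csv")  # leading timestamp column
  write.table(cbind(seq(0, by = 0.04, length.out = 10), m), f3, sep = ",",
              row.names = FALSE, col.names = FALSE)
  expect_equal(unname(read_signal_csv(f3, p)$samples), unname(m))

  f4 <- tempfile(fileext = ".csv")  # axis mismatch
  write.table(m[, 1], f4, sep = ",", row.names = FALSE, col.names = FALSE)
  expect_error(read_signal_csv(f4, p), "expects 3 axes")
})

test_that("custom profiles load from key-value config text", {
  f <- tempfile(fileext = ".dcf")
  writeLines(c("name: mydev", "fs: 100", "resolution_bits: 10",
               "n_axes: 3", "norm_scheme: counts_per_g",
               "counts_per_g: 512"), f)
  p <- read_profile(f)
  expect_equal(p$fs, 100)
  expect_equal(p$norm_constants$counts_per_g, 512)
  expect_error(read_profile(tempfile()), "not found")
})
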