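test_that("quantization factor is (2^b - 1)/2", {
  expect_equal(quantization_factor(3), 3.5)
  expect_equal(quantization_factor(1), 0.5)
  expect_equal(quantization_factor(16), 32767.5)
  expect_error(quantization_factor(0), "integer >= 1")
  expect_error(quantization_factor(2.5), "integer >= 1")
})

test_that("floor encoding maps the [-1,1] range onto integer code levels", {
  enc <- encode_floor(c(1, -1, 0, 0.4), bits = 3)
  expect_equal(enc$codes, c(7L, 0L, 3L, 4L))
  expect_equal(enc$qf, 3.5)
  expect_error(encode_floor(numeric(0), 3), "empty")
  # overshoot clips by default, raises in strict mode
  expect_equal(encode_floor(c(1.7, -2), bits = 3)$codes, c(7L, 0L))
  expect_error(encode_floor(1.7, bits = 3, strict = TRUE), "strict")
  # exact integer boundaries map to themselves, floor is toward -Inf
  expect_equal(encode_floor(c(-5/7, -3/7), bits = 3)$codes, c(1L, 2L))
})

test_that("dequantization inverts the code mapping onto [-1, 1]", {
  e <- function(codes) structure(list(codes = codes, bits = 3L, qf = 3.5,
                                      fs = 1, n = length(codes),
                                      source = NULL), class = "act_encoded")
  expect_equal(dequantize(e(7L)), 1)
  expect_equal(dequantize(e(0L)), -1)
  expect_equal(dequantize(e(3L)), -1/7)
})

test_that("quantization error vanishes on representable values and is bounded", {
  s <- c(-1, -1/7, 1)
  expect_equal(quantization_error(s, encode_floor(s, 3)), rep(0, 3))
  expect_equal(quantization_error(0, encode_floor(0, 3)), 1/7)
  # literal mode subtracts raw codes
  expect_equal(quantization_error(0, encode_floor(0, 3), mode = "literal"),
               0 - 3)
  expect_error(quantization_error(1:3 / 3, encode_floor(0.1, 3)), "lengths")
  # |Qe| <= 1/Qf on a dense grid, for several bit depths
  grid <- seq(-1, 1, length.out = 4001)
  for (b in c(1, 3, 5, 8)) {
    qe <- quantization_error(grid, encode_floor(grid, b))
    expect_lte(max(abs(qe)), 1 / quantization_factor(b) + 1e-12)
  }
})

test_that("floor encoder agrees with the brute-force level-lookup oracle", {
  # a dense grid of generic points: exact code-boundary values are excluded
  # since double rounding makes either adjacent code defensible there
  set.seed(6)
  grid <- sort(runif(2000, -1, 1))
  for (b in 1:8) {
    expect_equal(encode_floor(grid, b)$codes, oracle_encode(grid, b),
                 info = paste("bits =", b))
  }
  # exact integer boundaries map to themselves (no epsilon nudging)
  for (b in c(1, 2, 4, 8, 16)) {
    expect_equal(encode_floor(c(-1, 1), b)$codes, c(0L, 2L^b - 1L))
  }
})

test_that("codes stay in range and reconstruction error is bounded for random input", {
  set.seed(7)
  for (b in c(1, 2, 4, 8, 12, 16)) {
    s <- runif(500, -1, 1)
    enc <- encode_floor(s, b)
    expect_true(all(enc$codes >= 0 & enc$codes <= 2^b - 1))
    expect_lte(max(abs(s - dequantize(enc))), 2 / (2^b - 1) + 1e-12)
  }
})

test_that("SNR increases with bit depth and is infinite for exact signals", {
  expect_equal(snr_db(c(-1, 1, -1/7), encode_floor(c(-1, 1, -1/7), 3)), Inf)
  expect_error(snr_db(rep(0, 5), encode_floor(rep(0, 5), 3)), "all-zero")
  s <- fullscale_fixture()$values
  expect_gt(snr_db(s, encode_floor(s, 8)), snr_db(s, encode_floor(s, 3)))
  # RMS of the quantization error is non-increasing in b on a fixed signal
  rmse <- vapply(1:12, function(b)
    sqrt(mean(quantization_error(s, encode_floor(s, b))^2)), numeric(1))
  expect_true(all(diff(rmse) <= 1e-12))
})

test_that("bit rate is bits per sample times sampling frequency", {
  expect_equal(bit_rate(16, 25), 400)
  expect_equal(bit_rate(3, 25), 75)
  expect_equal(bit_rate(6, 32), 192)
  expect_equal(bit_rate(3, 2000), 6000)
  expect_error(bit_rate(0, 25), "positive")
  expect_error(bit_rate(3, -1), "positive")
})

test_that("space savings counts payload bits of the compounded channel", {
  expect_equal(space_savings(16, 3), 81.25)
  expect_equal(space_savings(48, 48), 0)
  expect_equal(space_savings(3 * 16, 3), 93.75)
  expect_error(space_savings(0, 3), "positive")
})

test_that("encoding report assembles SNR, bit rates and savings for a device", {
  norm <- preprocess(sleep_fixture())
  rep3 <- encode_report(norm, bits = 3)
  expect_equal(rep3$bit_rate_raw, 400)
  expect_equal(rep3$bit_rate_encoded, 75)
  expect_equal(rep3$n_samples, 200)
  # encoded-stream SNR far exceeds the raw-stream (scale-mismatch) figure
  expect_gt(rep3$snr_encoded_db, rep3$snr_raw_db + 20)

  # bits = device resolution on a single-axis device: no savings
  pv <- device_profile("vag")
  set.seed(8)
  nv <- preprocess(act_raw(round(runif(100, 0, 4095)), pv))
  rv <- encode_report(nv, bits = 12)
  expect_equal(rv$space_savings_pct, 0)

  # more bits, less quantization error
  r4 <- encode_report(norm, bits = 4)
  s <- norm$values
  rms_qe <- function(b) sqrt(mean(quantization_error(s, encode_floor(s, b))^2))
  expect_lte(rms_qe(4), rms_qe(3))
})
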