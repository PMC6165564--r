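# reference statistics frozen from an independent implementation
# (statsmodels: kpss(regression="c") and adfuller(regression="ct") with the
# same lag rules) on the exact series generated below
test_that("KPSS and ADF statistics match the frozen independent oracle", {
  set.seed(42)
  wn <- rnorm(500)
  rw <- cumsum(rnorm(500))
  ar <- as.numeric(arima.sim(list(ar = 0.7), 500))
  tr <- 0.01 * (1:500) + rnorm(500)
  expect_equal(kpss_stationarity(wn)$statistic, 0.036275, tolerance = 1e-4)
  expect_equal(kpss_stationarity(rw)$statistic, 6.630706, tolerance = 1e-4)
  expect_equal(kpss_stationarity(ar)$statistic, 0.132834, tolerance = 1e-4)
  expect_equal(kpss_stationarity(tr)$statistic, 7.616458, tolerance = 1e-4)
  expect_equal(adf_unit_root(wn)$statistic, -8.056964, tolerance = 1e-4)
  expect_equal(adf_unit_root(rw)$statistic, -0.551992, tolerance = 1e-4)
  expect_equal(adf_unit_root(ar)$statistic, -7.183712, tolerance = 1e-4)
  expect_equal(adf_unit_root(tr)$statistic, -6.459430, tolerance = 1e-4)
})

test_that("KPSS separates white noise from random walks across seeds", {
  dec <- vapply(1:40, function(s) {
    set.seed(s)
    c(wn = kpss_stationarity(rnorm(2000))$decision,
      rw = kpss_stationarity(cumsum(rnorm(2000)))$decision)
  }, character(2))
  expect_gte(mean(dec["wn", ] == "stationary"), 0.9)       # ~1 - alpha
  expect_gte(mean(dec["rw", ] == "non-stationary"), 0.95)
  # degenerate constant input: stationary with zero statistic
  k <- kpss_stationarity(rep(2, 50))
  expect_equal(k$statistic, 0)
  expect_equal(k$decision, "stationary")
  expect_error(kpss_stationarity(rnorm(10)), "at least 20")
})

test_that("ADF rejects a unit root for stationary series and keeps it for walks", {
  dec <- vapply(1:40, function(s) {
    set.seed(s)
    c(wn = adf_unit_root(rnorm(2000))$decision,
      rw = adf_unit_root(cumsum(rnorm(2000)))$decision,
      ramp = adf_unit_root(0.05 * (1:2000) + rnorm(2000))$decision)
  }, character(3))
  expect_gte(mean(dec["wn", ] == "no unit root"), 0.95)
  expect_gte(mean(dec["rw", ] == "unit-root (non-stationary)"), 0.9)
  # trend term in the regression: a linear ramp is trend-stationary
  expect_gte(mean(dec["ramp", ] == "no unit root"), 0.95)
  expect_error(adf_unit_root(rep(1, 50)), "constant")
})

test_that("KS test separates Gaussian from uniform and spiky samples", {
  dec <- vapply(1:40, function(s) {
    set.seed(s)
    spiky <- rnorm(5000, sd = 0.05)
    spiky[sample(5000, 50)] <- spiky[sample(5000, 50)] + rexp(50, 1 / 0.5)
    c(g = ks_gaussianity(rnorm(5000))$decision,
      u = ks_gaussianity(runif(5000))$decision,
      s = ks_gaussianity(spiky)$decision)
  }, character(3))
  expect_gte(mean(dec["g", ] == "Gaussian"), 0.9)
  expect_gte(mean(dec["u", ] == "non-Gaussian"), 0.95)
  expect_gte(mean(dec["s", ] == "non-Gaussian"), 0.95)
  expect_error(ks_gaussianity(rep(1, 30)), "zero variance")
})

test_that("Gini sparsity index matches closed-form values and invariances", {
  expect_equal(gini_sparsity(c(0, 0, 0, 1)), 0.75)
  expect_equal(gini_sparsity(rep(3, 4)), 0)
  expect_equal(gini_sparsity(rep(-2, 7)), 0)
  # 1-sparse vector of length n has Gini exactly 1 - 1/n
  for (n in c(10, 100, 1000))
    expect_equal(gini_sparsity(c(rep(0, n - 1), 5)), 1 - 1 / n)
  expect_error(gini_sparsity(rep(0, 4)), "all-zero")
  set.seed(5)
  x <- rnorm(300)
  g <- gini_sparsity(x)
  for (a in c(-2, 0.1, 10))
    expect_equal(gini_sparsity(a * x), g)          # scale invariance
  expect_equal(gini_sparsity(sample(x)), g)        # permutation invariance
})

test_that("characterization battery collects decisions for a whole signal", {
  set.seed(6)
  ch_noise <- characterize(rnorm(2000), fs = 25)
  d <- decisions(ch_noise)
  expect_equal(unname(d["kpss"]), "stationary")
  expect_equal(unname(d["ks"]), "Gaussian")
  expect_true(all(vapply(ch_noise, function(r)
    is.na(r$p_value) || (r$p_value >= 0 && r$p_value <= 1), logical(1))))

  # a quiet-baseline spiky record: non-Gaussian and sparse in windows.
  # noise below half an ADC count quantizes to true zeros at rest, the
  # regime in which counts-type actigraphy is sparse
  cfg <- synthetic_config("sleep-plm", seed = 9, noise_sd = 5e-5,
                          drift_sd = 0, bout_s = 60)
  m <- simulate_movement(cfg, "Mild")
  norm <- preprocess(emulate_device(m, cfg$profile))
  d2 <- decisions(characterize(norm))
  expect_equal(unname(d2["ks"]), "non-Gaussian")
  expect_equal(unname(d2["gini"]), "sparse-in-windows")

  expect_error(characterize(numeric(0)), "empty")
  # deterministic: same input, same decisions
  expect_identical(decisions(characterize(norm)), d2)
})
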