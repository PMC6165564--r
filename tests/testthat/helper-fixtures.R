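# shared fixtures, all generated in code

`%||%` <- function(a, b) if (is.null(a)) b else a

# a short deterministic tri-axial counts signal for the sleep profile
sleep_fixture <- function(n = 200, seed = 1) {
  set.seed(seed)
  p <- device_profile("sleep")
  counts <- matrix(round(rnorm(n * 3, sd = 300)), n, 3)
  act_raw(counts, p)
}

# a normalized signal spanning [-1, 1] for encoder tests
fullscale_fixture <- function(n = 1000, seed = 2) {
  set.seed(seed)
  act_norm(runif(n, -1, 1), fs = 25, profile = device_profile("sleep"))
}

# brute-force reference encoder: greatest level (code) whose dequantized
# value does not exceed the sample; independent of encode_floor's arithmetic
oracle_encode <- function(s, bits) {
  qf <- (2^bits - 1) / 2
  levels <- ((0:(2^bits - 1)) - qf) / qf
  vapply(s, function(v) {
    ok <- which(levels <= v)
    if (!length(ok)) 0L else as.integer(max(ok) - 1L)
  }, integer(1L))
}

# random 3-D rotation matrix via QR of a Gaussian matrix
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
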