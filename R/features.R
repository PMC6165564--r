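#' @title Time, frequency and signal-specific features for actigraphy
#' @description [extract_features()] computes the 13-feature vector used to
#'   compare raw and encoded actigraphy: six time-domain statistics, three
#'   Hjorth parameters, two spectral features and two signal-specific
#'   features (spiky index and rapid change factor).
#' @name features
NULL

act_feature_names <- c("rms", "maxima", "peak_to_peak", "peak_to_rms",
                       "peak_to_avg_power", "sndr_db", "hjorth_mobility_1",
                       "hjorth_mobility_2", "hjorth_complexity",
                       "median_frequency_hz", "band_power", "spiky_index",
                       "rapid_change_factor")

#' Time-domain features
#'
#' RMS, maximum peak, peak-to-peak span, peak-to-RMS ratio, peak to average
#' power ratio, and the signal-to-noise-and-distortion ratio (SNDR).  SNDR
#' is taken from the periodogram as \code{10 log10} of the dominant non-DC
#' spectral component's power over the power of everything else.
#'
#' @param s numeric series, n >= 2.
#' @return named numeric vector with entries \code{rms}, \code{maxima},
#'   \code{peak_to_peak}, \code{peak_to_rms}, \code{peak_to_avg_power},
#'   \code{sndr_db}.
#' @export
time_features <- function(s) {
  s <- as.numeric(s)
  if (length(s) < 2L) stop("need at least 2 samples", call. = FALSE)
  r <- rms(s)
  if (r == 0) stop("ratio features undefined for an all-zero signal",
                   call. = FALSE)
  c(rms = r, maxima = max(s), peak_to_peak = max(s) - min(s),
    peak_to_rms = max(s) / r, peak_to_avg_power = max(s) / mean(s^2),
    sndr_db = sndr_periodogram(s))
}

# dominant-component power over residual power, periodogram based, in dB
sndr_periodogram <- function(s) {
  s <- s - mean(s)
  if (all(s == 0)) return(NA_real_)
  n <- length(s)
  pw <- Mod(stats::fft(s))^2 / n
  half <- pw[2:(floor(n / 2) + 1L)]  # positive frequencies, DC removed
  tot <- sum(half)
  dom <- max(half)
  rest <- tot - dom
  if (rest <= 0) return(Inf)
  10 * log10(dom / rest)
}

#' Hjorth parameters
#'
#' With \eqn{\sigma_x}, \eqn{\sigma_f}, \eqn{\sigma_s} the standard
#' deviations of the signal, its first difference and its second difference:
#' first-order mobility \eqn{M_f = \sigma_f/\sigma_x}, second-order mobility
#' \eqn{M_s = \sigma_s/\sigma_x}, and complexity
#' \eqn{C_x = (\sigma_s/\sigma_f) / (\sigma_f/\sigma_x)} -- the mobility of
#' the first difference over the mobility of the signal, the standard Hjorth
#' complexity.  Differences are unscaled (the sampling period cancels in
#' \eqn{M_f}); for a slow sinusoid at \eqn{f_0}, \eqn{M_f \approx 2\pi
#' f_0/f_s} and \eqn{C_x \approx 1}.
#'
#' @param s numeric series, n >= 3 with positive variance.
#' @return named numeric vector \code{hjorth_mobility_1},
#'   \code{hjorth_mobility_2}, \code{hjorth_complexity}.
#' @export
hjorth_parameters <- function(s) {
  s <- as.numeric(s)
  if (length(s) < 3L) stop("need at least 3 samples", call. = FALSE)
  sx <- stats::sd(s)
  if (sx == 0) stop("Hjorth parameters undefined for a constant signal",
                    call. = FALSE)
  sf <- stats::sd(diff(s))
  ss <- stats::sd(diff(s, differences = 2L))
  if (sf == 0) stop("Hjorth complexity undefined: constant first difference",
                    call. = FALSE)
  mf <- sf / sx
  c(hjorth_mobility_1 = mf, hjorth_mobility_2 = ss / sx,
    hjorth_complexity = (ss / sf) / mf)
}

#' Frequency-domain features
#'
#' Median frequency -- the frequency at which the cumulative periodogram
#' (DC excluded) reaches half the total power -- and band power, the average
#' signal power \code{mean(s^2)}.
#'
#' @param s numeric series, n >= 8.
#' @param fs sampling frequency, Hz.
#' @return named numeric vector \code{median_frequency_hz},
#'   \code{band_power}.
#' @export
frequency_features <- function(s, fs) {
  s <- as.numeric(s)
  if (length(s) < 8L) stop("need at least 8 samples", call. = FALSE)
  if (all(s == 0)) stop("frequency features undefined for all-zero input",
                        call. = FALSE)
  bp <- mean(s^2)
  sc <- s - mean(s)
  n <- length(sc)
  nb <- floor(n / 2)
  if (all(sc == 0)) {
    mf <- 0
  } else {
    pw <- Mod(stats::fft(sc))^2 / n
    half <- pw[2:(nb + 1L)]
    freqs <- (1:nb) * fs / n
    cum <- cumsum(half) / sum(half)
    mf <- freqs[which(cum >= 0.5)[1L]]
  }
  c(median_frequency_hz = mf, band_power = bp)
}

# local maxima with topographic prominence; returns indices and prominences
find_peaks <- function(s) {
  n <- length(s)
  if (n < 3L) return(list(idx = integer(0), prominence = numeric(0)))
  ge_l <- s[2:(n - 1L)] > s[1:(n - 2L)]
  ge_r <- s[2:(n - 1L)] >= s[3:n]
  idx <- which(ge_l & ge_r) + 1L
  if (!length(idx)) return(list(idx = integer(0), prominence = numeric(0)))
  prom <- vapply(idx, function(i) {
    h <- s[i]
    # walk left until a higher sample; lowest valley on the way bounds left
    left_min <- h
    j <- i - 1L
    while (j >= 1L && s[j] <= h) { left_min <- min(left_min, s[j]); j <- j - 1L }
    right_min <- h
    j <- i + 1L
    while (j <= n && s[j] <= h) { right_min <- min(right_min, s[j]); j <- j + 1L }
    h - max(left_min, right_min)
  }, numeric(1L))
  list(idx = idx, prominence = prom)
}

#' Spiky index: prominent movement events per second
#'
#' Counts local maxima whose topographic prominence reaches
#' \code{prominence_frac} of the signal's dynamic range (max - min) and
#' divides by the total record duration in seconds.  Invariant to baseline
#' shifts.
#'
#' @param s numeric series.
#' @param fs sampling frequency, Hz.
#' @param prominence_frac fraction of dynamic range a peak must rise above
#'   its surroundings to count as an event; default 0.25.
#' @return events per second (scalar >= 0).
#' @export
spiky_index <- function(s, fs, prominence_frac = 0.25) {
  s <- as.numeric(s)
  if (!is.numeric(fs) || fs <= 0) stop("fs must be positive", call. = FALSE)
  if (length(s) < 2L) stop("need at least 2 samples", call. = FALSE)
  duration <- length(s) / fs
  rng <- max(s) - min(s)
  if (rng == 0) return(0)
  pk <- find_peaks(s)
  sum(pk$prominence >= prominence_frac * rng) / duration
}

#' Rapid change factor
#'
#' Resolution-dependent feature combining the quantization step, the bit
#' depth and the sampling period: \code{(2 / (2^bits - 1)) / (bits / fs)} --
#' the amplitude step a b-bit code can represent, per bit-sampling-period.
#' Strictly decreasing in \code{bits} at fixed \code{fs}: coarse encodings
#' change rapidly per retained bit.
#'
#' @param bits encoding (or device) bits per sample.
#' @param fs sampling frequency, Hz.
#' @return scalar.
#' @examples
#' rapid_change_factor(3, 25)  # (2/7) / (3 * 0.04) = 2.381
#' @export
rapid_change_factor <- function(bits, fs) {
  if (!is.numeric(bits) || bits < 1 || bits != floor(bits))
    stop("bits must be an integer >= 1", call. = FALSE)
  if (!is.numeric(fs) || fs <= 0) stop("fs must be positive", call. = FALSE)
  step <- 2 / (2^bits - 1)
  step / (bits * (1 / fs))
}

#' Extract the full 13-feature vector
#'
#' Assembles the six time-domain features, the three Hjorth parameters, the
#' two frequency features, the spiky index and the rapid change factor into
#' one named vector.  Deterministic given input and configuration; a feature
#' whose preconditions fail (e.g. zero variance) is recorded as \code{NA}.
#'
#' @param s numeric series, an \code{"act_norm"}, or an
#'   \code{"act_encoded"} (dequantized to the signal scale first).
#' @param fs sampling frequency, Hz (taken from the object when available).
#' @param bits bits per sample used for the rapid change factor; defaults to
#'   the encoding bits for encoded input, otherwise the device resolution
#'   bits, otherwise 16.
#' @param prominence_frac passed to [spiky_index()].
#' @return named numeric vector of length 13.
#' @export
extract_features <- function(s, fs = NULL, bits = NULL,
                             prominence_frac = 0.25) {
  if (inherits(s, "act_encoded")) {
    if (is.null(fs)) fs <- s$fs
    if (is.null(bits)) bits <- s$bits
    s <- dequantize(s)
  } else if (inherits(s, "act_norm")) {
    if (is.null(fs)) fs <- s$fs
    if (is.null(bits) && !is.null(s$profile)) bits <- s$profile$resolution_bits
    s <- s$values
  }
  if (is.null(fs) || is.na(fs)) stop("fs required", call. = FALSE)
  if (is.null(bits)) bits <- 16L
  grab <- function(expr) tryCatch(expr, error = function(e) NULL)
  out <- rep(NA_real_, 13L)
  names(out) <- act_feature_names
  tf <- grab(time_features(s))
  if (!is.null(tf)) out[names(tf)] <- tf
  hj <- grab(hjorth_parameters(s))
  if (!is.null(hj)) out[names(hj)] <- hj
  ff <- grab(frequency_features(s, fs))
  if (!is.null(ff)) out[names(ff)] <- ff
  si <- grab(spiky_index(s, fs, prominence_frac))
  if (!is.null(si)) out["spiky_index"] <- si
  out["rapid_change_factor"] <- rapid_change_factor(bits, fs)
  out
}

#' Build a labeled feature set from a list of signals
#'
#' Applies [extract_features()] to each signal and stacks the vectors into a
#' data frame with a class label per row and a group tag (\code{"raw"} or
#' \code{"encoded"}) for the whole set.
#'
#' @param signals list of series / \code{"act_norm"} / \code{"act_encoded"}.
#' @param labels class label per signal.
#' @param group \code{"raw"} or \code{"encoded"}.
#' @param fs,bits,prominence_frac passed to [extract_features()].
#' @return An \code{"act_features"} data frame: 13 feature columns plus
#'   \code{label}, with the group stored as an attribute.
#' @export
feature_set <- function(signals, labels, group = c("raw", "encoded"),
                        fs = NULL, bits = NULL, prominence_frac = 0.25) {
  group <- match.arg(group)
  if (length(signals) != length(labels))
    stop("signals and labels lengths differ", call. = FALSE)
  m <- t(vapply(signals, extract_features, numeric(13L), fs = fs,
                bits = bits, prominence_frac = prominence_frac))
  df <- as.data.frame(m)
  df$label <- as.character(labels)
  structure(df, class = c("act_features", "data.frame"), group = group)
}
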