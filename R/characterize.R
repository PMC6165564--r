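#' @title Signal-characterization battery for actigraphy
#' @description Actigraphy traces are typically non-stationary, non-Gaussian
#'   and sparse in short windows; the battery in [characterize()] quantifies
#'   those properties so that processing choices (low-bit encoding, sparsity
#'   aware features) can be justified per recording.
#' @name characterization
NULL

new_char_result <- function(test_name, statistic, p_value, decision, params) {
  if (!is.na(p_value) && (p_value < 0 || p_value > 1))
    stop("internal: p-value outside [0,1]")
  structure(list(test_name = test_name, statistic = statistic,
                 p_value = p_value, decision = decision, params = params),
            class = "act_chartest")
}

#' @export
print.act_chartest <- function(x, ...) {
  cat(sprintf("%-28s stat = %10.4g  p = %-8s -> %s\n", x$test_name,
              x$statistic,
              if (is.na(x$p_value)) "NA" else format.pval(x$p_value),
              x$decision))
  invisible(x)
}

# Bartlett-window long-run variance of a demeaned series
lrvar_bartlett <- function(e, lag) {
  n <- length(e)
  s2 <- sum(e^2) / n
  if (lag > 0) {
    for (i in seq_len(lag)) {
      w <- 1 - i / (lag + 1)
      s2 <- s2 + 2 * w * sum(e[(i + 1):n] * e[1:(n - i)]) / n
    }
  }
  s2
}

# interpolate a p-value from a one-row table of critical values
interp_pval <- function(stat, cvals, probs) {
  if (stat <= min(cvals)) return(max(probs))
  if (stat >= max(cvals)) return(min(probs))
  stats::approx(cvals, probs, xout = stat, rule = 2)$y
}

#' KPSS test for level stationarity
#'
#' Tests the null of level stationarity against a unit-root alternative.
#' The statistic is \eqn{\sum_t S_t^2 / (n^2 \hat\sigma^2)} where \eqn{S_t}
#' are partial sums of the demeaned series and \eqn{\hat\sigma^2} is a
#' Bartlett-window long-run variance with lag truncation
#' \code{trunc(4 * (n/100)^0.25)}.  The p-value is interpolated from the
#' standard critical-value table and clipped to [0.01, 0.10].
#'
#' A large statistic (small p) rejects stationarity; actigraphy with activity
#' bouts typically rejects.
#'
#' @param s numeric series (or \code{"act_norm"}); n >= 20.
#' @param alpha significance level; default 0.05.
#' @param lag Bartlett lag truncation; NULL = automatic rule above.
#' @return An \code{"act_chartest"} with decision \code{"stationary"} or
#'   \code{"non-stationary"}.
#' @export
kpss_stationarity <- function(s, alpha = 0.05, lag = NULL) {
  if (inherits(s, "act_norm")) s <- s$values
  s <- as.numeric(s)
  n <- length(s)
  if (n < 20L) stop("KPSS needs at least 20 samples", call. = FALSE)
  if (is.null(lag)) lag <- trunc(4 * (n / 100)^0.25)
  if (stats::sd(s) == 0) {  # constant series: trivially level-stationary
    return(new_char_result("Stationarity (KPSS, level)", 0, NA_real_,
                           "stationary", list(alpha = alpha, lag = lag)))
  }
  e <- s - mean(s)
  stat <- sum(cumsum(e)^2) / (n^2 * lrvar_bartlett(e, lag))
  # level-stationarity critical values at 10/5/2.5/1%
  p <- interp_pval(stat, c(0.347, 0.463, 0.574, 0.739),
                   c(0.10, 0.05, 0.025, 0.01))
  new_char_result("Stationarity (KPSS, level)", stat, p,
                  if (p >= alpha) "stationary" else "non-stationary",
                  list(alpha = alpha, lag = lag))
}

#' Augmented Dickey-Fuller unit-root test
#'
#' Field convention sometimes files this under "linearity"; what is computed
#' is the standard ADF unit-root test with constant and linear trend: the
#' regression \eqn{\Delta y_t = a + b t + \rho y_{t-1} + \sum \gamma_i
#' \Delta y_{t-i} + e_t} with lag order \code{trunc((n-1)^(1/3))} by
#' default, and the t-statistic of \eqn{\rho} referred to the
#' Dickey-Fuller distribution (tabulated critical values, interpolated in
#' both sample size and probability; p clipped to [0.01, 0.99]).
#'
#' The null is a unit root; failing to reject labels the series
#' \code{"unit-root (non-stationary)"}.
#'
#' @inheritParams kpss_stationarity
#' @param lag number of lagged differences; NULL = automatic rule above.
#' @return An \code{"act_chartest"} with decision
#'   \code{"unit-root (non-stationary)"} or \code{"no unit root"}.
#' @export
adf_unit_root <- function(s, alpha = 0.05, lag = NULL) {
  if (inherits(s, "act_norm")) s <- s$values
  s <- as.numeric(s)
  n <- length(s)
  if (n < 20L) stop("ADF needs at least 20 samples", call. = FALSE)
  if (stats::sd(s) == 0)
    stop("ADF undefined for a constant series", call. = FALSE)
  if (is.null(lag)) lag <- trunc((n - 1)^(1/3))
  k <- lag + 1L
  y <- diff(s)
  m <- length(y)
  # design: y_{t-1}, trend, lagged differences
  z <- stats::embed(y, k)
  yt <- z[, 1L]
  xt1 <- s[k:(n - 1L)]
  tt <- k:m
  X <- cbind(xt1, 1, tt)
  if (k > 1L) X <- cbind(X, z[, 2:k, drop = FALSE])
  fit <- stats::lm.fit(X, yt)
  res <- fit$residuals
  df <- length(yt) - ncol(X)
  sigma2 <- sum(res^2) / df
  XtXinv <- chol2inv(chol(crossprod(X)))
  stat <- fit$coefficients[1L] / sqrt(sigma2 * XtXinv[1L, 1L])
  # Dickey-Fuller critical values, constant + trend, by sample size
  tbl <- -rbind(
    c(4.38, 3.95, 3.60, 3.24, 1.14, 0.80, 0.50, 0.15),
    c(4.15, 3.80, 3.50, 3.18, 1.19, 0.87, 0.58, 0.24),
    c(4.04, 3.73, 3.45, 3.15, 1.22, 0.90, 0.62, 0.28),
    c(3.99, 3.69, 3.43, 3.13, 1.23, 0.92, 0.64, 0.31),
    c(3.98, 3.68, 3.42, 3.13, 1.24, 0.93, 0.65, 0.32),
    c(3.96, 3.66, 3.41, 3.12, 1.25, 0.94, 0.66, 0.33))
  tbl_n <- c(25, 50, 100, 250, 500, 1e5)
  tbl_p <- c(0.01, 0.025, 0.05, 0.10, 0.90, 0.95, 0.975, 0.99)
  cvals <- vapply(seq_along(tbl_p), function(j)
    stats::approx(tbl_n, tbl[, j], xout = min(n, 1e5), rule = 2)$y,
    numeric(1L))
  p <- min(max(stats::approx(cvals, tbl_p, xout = stat, rule = 2)$y,
               0.01), 0.99)
  new_char_result("Unit root (augmented Dickey-Fuller)", unname(stat), p,
                  if (p > alpha) "unit-root (non-stationary)"
                  else "no unit root",
                  list(alpha = alpha, lag = lag))
}

#' Kolmogorov-Smirnov test of Gaussianity
#'
#' One-sample KS test of the series against a Gaussian with the sample mean
#' and standard deviation.  Rejection labels the series non-Gaussian; random
#' human motion with rare high-amplitude events typically rejects.
#'
#' @inheritParams kpss_stationarity
#' @return An \code{"act_chartest"} with decision \code{"Gaussian"} or
#'   \code{"non-Gaussian"}.
#' @export
ks_gaussianity <- function(s, alpha = 0.05) {
  if (inherits(s, "act_norm")) s <- s$values
  s <- as.numeric(s)
  if (length(s) < 20L) stop("KS needs at least 20 samples", call. = FALSE)
  sdv <- stats::sd(s)
  if (sdv == 0) stop("KS Gaussianity undefined for zero variance",
                     call. = FALSE)
  ht <- suppressWarnings(stats::ks.test(s, "pnorm", mean(s), sdv))
  new_char_result("Gaussianity (Kolmogorov-Smirnov)",
                  unname(ht$statistic), ht$p.value,
                  if (ht$p.value > alpha) "Gaussian" else "non-Gaussian",
                  list(alpha = alpha))
}

#' Gini sparsity index
#'
#' Sparsity measure on absolute values: sort \eqn{|s|} ascending and compute
#' \deqn{G = 1 - 2 \sum_k \frac{|s|_{(k)}}{\|s\|_1}\,\frac{n - k + 1/2}{n}.}
#' 0 for a perfectly uniform magnitude profile, approaching 1 for a
#' maximally sparse (single-spike) one.  Scale- and permutation-invariant.
#'
#' @param s numeric series (or \code{"act_norm"}); not all zero.
#' @return scalar in [0, 1].
#' @examples
#' gini_sparsity(c(0, 0, 0, 1))  # 0.75
#' gini_sparsity(rep(3, 4))      # 0
#' @export
gini_sparsity <- function(s) {
  if (inherits(s, "act_norm")) s <- s$values
  a <- sort(abs(as.numeric(s)))
  l1 <- sum(a)
  if (l1 == 0) stop("Gini sparsity undefined for an all-zero series",
                    call. = FALSE)
  n <- length(a)
  k <- seq_len(n)
  1 - 2 * sum((a / l1) * ((n - k + 0.5) / n))
}

#' Windowed Gini sparsity
#'
#' Gini sparsity of the baseline-removed signal over consecutive fixed-length
#' windows; actigraphy is typically sparse at this short-window scale even
#' when a gravity baseline makes the whole record look dense.  The per-window
#' baseline is the window median; all-zero windows (no movement) are skipped.
#'
#' @param s numeric series or \code{"act_norm"}.
#' @param fs sampling frequency in Hz (taken from \code{s} if available).
#' @param window_s window length in seconds; default 10.
#' @return list with \code{per_window} Gini values and their \code{median}.
#' @export
gini_windowed <- function(s, fs = NULL, window_s = 10) {
  if (inherits(s, "act_norm")) { if (is.null(fs)) fs <- s$fs; s <- s$values }
  if (is.null(fs) || fs <= 0) stop("fs required", call. = FALSE)
  w <- max(4L, floor(window_s * fs))
  n <- length(s)
  starts <- seq(1L, n, by = w)
  g <- vapply(starts, function(i) {
    seg <- s[i:min(i + w - 1L, n)]
    d <- seg - stats::median(seg)
    if (sum(abs(d)) == 0 || length(d) < 4L) NA_real_ else gini_sparsity(d)
  }, numeric(1L))
  g <- g[!is.na(g)]
  list(per_window = g,
       median = if (length(g)) stats::median(g) else NA_real_)
}

#' Run the full characterization battery
#'
#' Applies the KPSS stationarity test, the augmented Dickey-Fuller unit-root
#' test, the Kolmogorov-Smirnov Gaussianity test and the (whole-signal and
#' windowed) Gini sparsity index to one series and collects decisions.
#' The sparsity decision is \code{"sparse-in-windows"} when the median
#' windowed Gini reaches 0.6 (Gaussian noise sits near 0.41, isolated-spike
#' trains near 1).
#'
#' @param s numeric series or \code{"act_norm"}.
#' @param alpha significance level shared by the hypothesis tests.
#' @param fs sampling frequency (needed for windowed sparsity when \code{s}
#'   is a bare vector).
#' @param window_s sparsity window length in seconds.
#' @return An object of class \code{"act_characterization"}: a list of
#'   \code{"act_chartest"} results, with \code{as.data.frame} support.
#' @export
characterize <- function(s, alpha = 0.05, fs = NULL, window_s = 10) {
  if (inherits(s, "act_norm")) { if (is.null(fs)) fs <- s$fs; v <- s$values }
  else v <- as.numeric(s)
  if (length(v) == 0L) stop("empty input", call. = FALSE)
  res <- list(
    kpss = kpss_stationarity(v, alpha = alpha),
    adf = adf_unit_root(v, alpha = alpha),
    ks = ks_gaussianity(v, alpha = alpha)
  )
  g_full <- gini_sparsity(v)
  gw <- if (!is.null(fs)) gini_windowed(v, fs = fs, window_s = window_s)
        else list(median = NA_real_)
  sparse_dec <- if (is.na(gw$median)) "sparsity-undetermined"
                else if (gw$median >= 0.6) "sparse-in-windows"
                else "non-sparse"
  res$gini <- new_char_result("Sparsity (Gini index)",
                              if (is.na(gw$median)) g_full else gw$median,
                              NA_real_, sparse_dec,
                              list(window_s = window_s, whole_signal = g_full))
  structure(res, class = "act_characterization", alpha = alpha)
}

#' @export
print.act_characterization <- function(x, ...) {
  cat(sprintf("<act_characterization> alpha = %g\n", attr(x, "alpha")))
  for (r in x) print(r)
  invisible(x)
}

#' @export
as.data.frame.act_characterization <- function(x, ...) {
  do.call(rbind, lapply(unname(x), function(r)
    data.frame(test = r$test_name, statistic = r$statistic,
               p_value = r$p_value, decision = r$decision,
               stringsAsFactors = FALSE)))
}

#' Decisions from a characterization battery
#' @param x an \code{"act_characterization"}.
#' @return character vector of decision labels.
#' @export
decisions <- function(x) {
  stopifnot(inherits(x, "act_characterization"))
  vapply(x, function(r) r$decision, character(1L))
}
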