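#' Normalize raw accelerometer counts by a counts-per-g scale
#'
#' Divides raw device counts by the manufacturer counts-per-g constant so the
#' output is in units of g (9.8 m/s^2).  Applied independently per axis.
#'
#' @param raw numeric vector or matrix of device counts.
#' @param counts_per_g positive scale, counts per g (e.g. 2048).
#' @return normalized values in g, same shape as \code{raw}.
#' @examples
#' normalize_counts_per_g(c(2048, 0, -1024), 2048)
#' @export
normalize_counts_per_g <- function(raw, counts_per_g) {
  if (!is.numeric(counts_per_g) || length(counts_per_g) != 1L ||
      counts_per_g <= 0)
    stop("counts_per_g must be a positive scalar", call. = FALSE)
  raw / counts_per_g
}

#' Decode offset-binary A-to-D codes onto a symmetric g span
#'
#' Affine decode of integer codes 0..code_max onto -half_span_g..+half_span_g:
#' \code{s = -half_span_g + (code / code_max) * 2 * half_span_g}.  The default
#' constants (code_max 63, half-span 1.5 g) decode a 6-bit wrist actigraph.
#'
#' @param raw_code numeric vector or matrix of codes in [0, code_max].
#' @param code_max largest code (2^bits - 1).
#' @param half_span_g physical half-span in g mapped to the code extremes.
#' @param clip if TRUE, out-of-range codes are clipped into [0, code_max]
#'   instead of raising an error.
#' @return values in g, same shape as \code{raw_code}.
#' @examples
#' normalize_offset_code(c(0, 31.5, 63), 63, 1.5)
#' @export
normalize_offset_code <- function(raw_code, code_max, half_span_g,
                                  clip = FALSE) {
  if (!is.numeric(code_max) || code_max <= 0)
    stop("code_max must be positive", call. = FALSE)
  if (!is.numeric(half_span_g) || half_span_g <= 0)
    stop("half_span_g must be positive", call. = FALSE)
  out_of_range <- raw_code < 0 | raw_code > code_max
  if (any(out_of_range)) {
    if (clip) {
      raw_code <- pmin(pmax(raw_code, 0), code_max)
    } else {
      stop(sprintf("%d code(s) outside [0, %g]; use clip = TRUE to tolerate",
                   sum(out_of_range), code_max), call. = FALSE)
    }
  }
  -half_span_g + (raw_code / code_max) * 2 * half_span_g
}

#' Min-max normalization onto [0, 1]
#'
#' Scales a series onto the unit interval using its own extremes.  The
#' default orientation is \emph{inverted}: \code{(max - s) / (max - min)},
#' which maps the sample maximum to 0 and the minimum to 1.  Set
#' \code{inverted = FALSE} for the conventional \code{(s - min)/(max - min)}.
#'
#' @param raw numeric vector or matrix.
#' @param inverted orientation flag; default TRUE (inverted).
#' @return values in [0, 1], same shape as \code{raw}; both endpoints are
#'   attained.
#' @examples
#' normalize_minmax(c(0, 5, 10))            # 1.0 0.5 0.0
#' normalize_minmax(c(0, 5, 10), FALSE)     # 0.0 0.5 1.0
#' @export
normalize_minmax <- function(raw, inverted = TRUE) {
  scale1 <- function(v) {
    hi <- max(v); lo <- min(v)
    if (hi == lo)
      stop("constant input: min-max normalization undefined", call. = FALSE)
    if (inverted) (hi - v) / (hi - lo) else (v - lo) / (hi - lo)
  }
  if (is.matrix(raw)) apply(raw, 2L, scale1) else scale1(raw)
}

#' Tri-axial vector magnitude (vector compounding)
#'
#' Collapses per-axis samples to a single magnitude series
#' \code{sqrt(x^2 + y^2 + z^2)}, so that vibration captured along any axis
#' contributes to one channel.  Invariant under rotation of the device frame.
#'
#' @param x,y,z equal-length numeric vectors.
#' @return nonnegative magnitude series of the same length.
#' @examples
#' vector_magnitude(3, 4, 0)  # 5
#' @export
vector_magnitude <- function(x, y, z) {
  if (length(y) != length(x) || length(z) != length(x))
    stop("axis series must have equal lengths", call. = FALSE)
  sqrt(x^2 + y^2 + z^2)
}

#' Preprocess a raw actigraphy signal into a normalized magnitude series
#'
#' Applies the profile's normalization scheme per axis, then collapses
#' tri-axial data to a single magnitude channel via [vector_magnitude()].
#' Single-axial signals skip compounding.  The output keeps the input length;
#' no resampling takes place.
#'
#' @param raw an \code{"act_raw"} signal (see [act_raw()]).
#' @param minmax_inverted orientation passed to [normalize_minmax()] for
#'   profiles using that scheme.
#' @param clip passed to [normalize_offset_code()] for offset-code profiles.
#' @return An object of class \code{"act_norm"}: list with \code{values}
#'   (numeric vector), \code{fs}, \code{profile}.
#' @export
preprocess <- function(raw, minmax_inverted = TRUE, clip = FALSE) {
  stopifnot(inherits(raw, "act_raw"))
  p <- raw$profile
  norm <- switch(p$norm_scheme,
    counts_per_g = normalize_counts_per_g(raw$samples,
                                          p$norm_constants$counts_per_g),
    offset_code  = normalize_offset_code(raw$samples,
                                         p$norm_constants$code_max,
                                         p$norm_constants$half_span_g,
                                         clip = clip),
    minmax       = normalize_minmax(raw$samples, inverted = minmax_inverted)
  )
  norm <- as.matrix(norm)
  values <- if (p$n_axes == 3L)
    vector_magnitude(norm[, 1L], norm[, 2L], norm[, 3L])
  else
    norm[, 1L]
  if (!all(is.finite(values)))
    stop("preprocessing produced non-finite values", call. = FALSE)
  act_norm(values, p$fs, p)
}

#' Construct a normalized signal container
#'
#' @param values numeric vector, unit g or dimensionless [0, 1].
#' @param fs sampling frequency in Hz.
#' @param profile source device profile, or NULL.
#' @return An \code{"act_norm"} object.
#' @export
act_norm <- function(values, fs, profile = NULL) {
  values <- as.numeric(values)
  if (!all(is.finite(values)))
    stop("normalized signal must be finite", call. = FALSE)
  if (!is.numeric(fs) || fs <= 0) stop("fs must be positive", call. = FALSE)
  structure(list(values = values, fs = as.numeric(fs), profile = profile),
            class = "act_norm")
}

#' @export
print.act_norm <- function(x, ...) {
  cat(sprintf("<act_norm> %d samples @ %g Hz, range [%.4g, %.4g]\n",
              length(x$values), x$fs, min(x$values), max(x$values)))
  invisible(x)
}

#' Read an actigraphy signal from delimited text
#'
#' Accepts CSV/TSV with one sample per row and 1 or 3 numeric columns; an
#' optional leading timestamp column and a header row are auto-detected (a
#' non-numeric first row is treated as a header; a first column that is
#' strictly increasing and distinct from the axis count expectation is
#' treated as timestamps).
#'
#' @param path file path.
#' @param profile device profile the data was recorded with.
#' @param sep field separator; guessed from the first line when NULL.
#' @return An \code{"act_raw"} signal.
#' @export
read_signal_csv <- function(path, profile, sep = NULL) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  if (is.null(sep)) sep <- if (grepl("\t", first)) "\t" else ","
  fields <- strsplit(first, sep, fixed = TRUE)[[1L]]
  header <- anyNA(suppressWarnings(as.numeric(fields)))
  df <- utils::read.table(path, header = header, sep = sep,
                          strip.white = TRUE)
  bad <- !vapply(df, is.numeric, logical(1L))
  if (any(bad))
    stop("non-numeric data column(s): ", paste(which(bad), collapse = ", "),
         call. = FALSE)
  nc <- ncol(df)
  want <- profile$n_axes
  if (nc == want + 1L) df <- df[, -1L, drop = FALSE]  # leading timestamp
  else if (nc != want)
    stop(sprintf("profile '%s' expects %d axes but file has %d data columns",
                 profile$name, want, nc), call. = FALSE)
  act_raw(as.matrix(df), profile)
}
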