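#' Device profiles for actigraph classes
#'
#' An actigraph is described by its sampling frequency, A-to-D resolution,
#' axis count and the amplitude-normalization scheme that maps raw device
#' output back onto physical units.  Three presets cover the device classes
#' the package targets:
#'
#' \describe{
#'   \item{\code{"sleep"}}{tri-axial ankle actigraph, 16 bits/sample, 25 Hz,
#'     counts-per-g normalization (2048 counts/g).}
#'   \item{\code{"adl"}}{tri-axial wrist actigraph for activities of daily
#'     living, 6 bits/sample, 32 Hz, offset-code normalization mapping codes
#'     0..63 linearly onto -1.5 g .. +1.5 g.}
#'   \item{\code{"vag"}}{single-axial vibroarthrography sensor, 12
#'     bits/sample, 2 kHz, min-max normalization onto [0, 1].}
#' }
#'
#' @param name preset name (\code{"sleep"}, \code{"adl"}, \code{"vag"}) or a
#'   label for a custom profile.
#' @param fs sampling frequency in Hz; required for custom profiles.
#' @param resolution_bits A-to-D resolution in bits/sample, in 1..32.
#' @param n_axes number of recording axes, 1 or 3.
#' @param norm_scheme one of \code{"counts_per_g"}, \code{"offset_code"},
#'   \code{"minmax"}.
#' @param norm_constants named list of scheme constants:
#'   \code{counts_per_g} needs \code{counts_per_g}; \code{offset_code} needs
#'   \code{code_max} and \code{half_span_g}; \code{minmax} takes none.
#'
#' @return An object of class \code{"act_profile"}.
#' @examples
#' device_profile("sleep")
#' device_profile("custom", fs = 100, resolution_bits = 10, n_axes = 3,
#'                norm_scheme = "counts_per_g",
#'                norm_constants = list(counts_per_g = 512))
#' @export
device_profile <- function(name, fs = NULL, resolution_bits = NULL,
                           n_axes = NULL, norm_scheme = NULL,
                           norm_constants = NULL) {
  presets <- list(
    sleep = list(fs = 25, resolution_bits = 16L, n_axes = 3L,
                 norm_scheme = "counts_per_g",
                 norm_constants = list(counts_per_g = 2048)),
    adl   = list(fs = 32, resolution_bits = 6L, n_axes = 3L,
                 norm_scheme = "offset_code",
                 norm_constants = list(code_max = 63, half_span_g = 1.5)),
    vag   = list(fs = 2000, resolution_bits = 12L, n_axes = 1L,
                 norm_scheme = "minmax",
                 norm_constants = list())
  )
  if (name %in% names(presets)) {
    p <- presets[[name]]
    if (is.null(fs)) fs <- p$fs
    if (is.null(resolution_bits)) resolution_bits <- p$resolution_bits
    if (is.null(n_axes)) n_axes <- p$n_axes
    if (is.null(norm_scheme)) norm_scheme <- p$norm_scheme
    if (is.null(norm_constants)) norm_constants <- p$norm_constants
  }
  if (is.null(fs) || is.null(resolution_bits) || is.null(n_axes) ||
      is.null(norm_scheme)) {
    stop("custom profiles need fs, resolution_bits, n_axes and norm_scheme",
         call. = FALSE)
  }
  norm_scheme <- match.arg(norm_scheme,
                           c("counts_per_g", "offset_code", "minmax"))
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a positive scalar (Hz)", call. = FALSE)
  resolution_bits <- as.integer(resolution_bits)
  if (is.na(resolution_bits) || resolution_bits < 1L || resolution_bits > 32L)
    stop("resolution_bits must lie in [1, 32]", call. = FALSE)
  n_axes <- as.integer(n_axes)
  if (!n_axes %in% c(1L, 3L))
    stop("n_axes must be 1 or 3", call. = FALSE)
  if (is.null(norm_constants)) norm_constants <- list()
  if (norm_scheme == "counts_per_g") {
    cpg <- norm_constants$counts_per_g
    if (is.null(cpg) || !is.numeric(cpg) || cpg <= 0)
      stop("counts_per_g scheme needs a positive counts_per_g constant",
           call. = FALSE)
  }
  if (norm_scheme == "offset_code") {
    cm <- norm_constants$code_max
    hs <- norm_constants$half_span_g
    if (is.null(cm) || cm <= 0 || is.null(hs) || hs <= 0)
      stop("offset_code scheme needs positive code_max and half_span_g",
           call. = FALSE)
  }
  structure(
    list(name = as.character(name), fs = as.numeric(fs),
         resolution_bits = resolution_bits, n_axes = n_axes,
         norm_scheme = norm_scheme, norm_constants = norm_constants),
    class = "act_profile"
  )
}

#' Read a device profile from a key-value config file
#'
#' The config is plain Debian-control-format text (\code{key: value} lines),
#' e.g.
#' \preformatted{
#' name: mydev
#' fs: 100
#' resolution_bits: 10
#' n_axes: 3
#' norm_scheme: counts_per_g
#' counts_per_g: 512
#' }
#'
#' @param path path to the config file.
#' @return An \code{"act_profile"}.
#' @export
read_profile <- function(path) {
  if (!file.exists(path)) stop("profile config not found: ", path,
                               call. = FALSE)
  d <- as.list(read.dcf(path)[1L, ])
  num <- function(x) if (is.null(x)) NULL else as.numeric(x)
  consts <- list()
  if (!is.null(d$counts_per_g)) consts$counts_per_g <- num(d$counts_per_g)
  if (!is.null(d$code_max)) consts$code_max <- num(d$code_max)
  if (!is.null(d$half_span_g)) consts$half_span_g <- num(d$half_span_g)
  device_profile(name = if (is.null(d$name)) "custom" else d$name,
                 fs = num(d$fs), resolution_bits = num(d$resolution_bits),
                 n_axes = num(d$n_axes), norm_scheme = d$norm_scheme,
                 norm_constants = consts)
}

#' @export
print.act_profile <- function(x, ...) {
  cat(sprintf("<act_profile> %s: %d-axis, %d bits/sample @ %g Hz, %s normalization\n",
              x$name, x$n_axes, x$resolution_bits, x$fs, x$norm_scheme))
  if (length(x$norm_constants))
    cat("  constants:",
        paste(names(x$norm_constants), unlist(x$norm_constants),
              sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' Construct a raw actigraphy signal
#'
#' Bundles per-axis device output (counts, codes or volts) with the profile
#' of the device that produced it.
#'
#' @param samples numeric vector (single-axial) or matrix/data frame with one
#'   column per axis.
#' @param profile an \code{"act_profile"}.
#' @return An object of class \code{"act_raw"} with fields \code{samples}
#'   (matrix, one column per axis), \code{profile} and \code{n}.
#' @export
act_raw <- function(samples, profile) {
  stopifnot(inherits(profile, "act_profile"))
  m <- as.matrix(samples)
  storage.mode(m) <- "double"
  if (nrow(m) < 1L) stop("signal must contain at least one sample",
                         call. = FALSE)
  if (anyNA(m)) stop("signal contains missing values", call. = FALSE)
  if (ncol(m) != profile$n_axes)
    stop(sprintf("profile '%s' expects %d axes but data has %d columns",
                 profile$name, profile$n_axes, ncol(m)), call. = FALSE)
  structure(list(samples = m, profile = profile, n = nrow(m)),
            class = "act_raw")
}

#' @export
print.act_raw <- function(x, ...) {
  cat(sprintf("<act_raw> %d samples x %d axes (%s, %g Hz)\n",
              x$n, ncol(x$samples), x$profile$name, x$profile$fs))
  invisible(x)
}
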