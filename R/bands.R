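#' Frequency-band definition
#'
#' A band is a named frequency window used to cut spectra and to drive the
#' band-pass filter. Two slightly different band tables are in circulation
#' for scalp EEG work and both are provided by [band_table()].
#'
#' @param name band label, one of `"theta"`, `"alpha"`, `"beta"`, `"gamma"`.
#' @param low,high band edges in Hz, `0 < low < high`.
#' @return An object of class `band_definition`.
#' @examples
#' band_definition("alpha", 8, 13)
#' @export
band_definition <- function(name, low, high) {
  stopifnot(is.character(name), length(name) == 1)
  if (!is.finite(low) || !is.finite(high) || low <= 0 || high <= low) {
    stopf("invalid band [%s, %s] Hz: need 0 < low < high", low, high)
  }
  structure(list(name = name, low = low, high = high),
            class = "band_definition")
}

#' @export
print.band_definition <- function(x, ...) {
  cat(sprintf("<band %s: %g-%g Hz>\n", x$name, x$low, x$high))
  invisible(x)
}

#' Canonical band tables
#'
#' Two named band tables are kept because the hand-crafted feature path and
#' the topographic EEG-image path conventionally use slightly different
#' windows:
#' \describe{
#'   \item{`"handcrafted"`}{theta 5-7, alpha 8-13, beta 14-30, gamma 31-60 Hz
#'     (used by the FFT, differential-entropy and wavelet encoders).}
#'   \item{`"image"`}{theta 4-7, alpha 8-13, beta 13-30 Hz (used by the
#'     topographic EEG-image encoder; no gamma plane).}
#' }
#'
#' @param which `"handcrafted"` or `"image"`.
#' @return A named list of [band_definition] objects.
#' @examples
#' band_table("handcrafted")$gamma
#' @export
band_table <- function(which = c("handcrafted", "image")) {
  which <- match.arg(which)
  if (which == "handcrafted") {
    list(
      theta = band_definition("theta", 5, 7),
      alpha = band_definition("alpha", 8, 13),
      beta  = band_definition("beta", 14, 30),
      gamma = band_definition("gamma", 31, 60)
    )
  } else {
    list(
      theta = band_definition("theta", 4, 7),
      alpha = band_definition("alpha", 8, 13),
      beta  = band_definition("beta", 13, 30)
    )
  }
}

check_band_nyquist <- function(band, sampling_rate) {
  if (band$high > sampling_rate / 2) {
    stopf("band %s [%g, %g] Hz exceeds Nyquist frequency %g Hz",
          band$name, band$low, band$high, sampling_rate / 2)
  }
  invisible(band)
}
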