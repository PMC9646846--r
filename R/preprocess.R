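#' Per-channel range normalisation to [-1, 1]
#'
#' Linearly rescales each channel of an epoch so its minimum maps to -1 and
#' its maximum to +1. A constant channel has no range to rescale and is
#' mapped to all zeros.
#'
#' @param epoch an [eeg_epoch()] or a channels x samples matrix.
#' @return Same type as the input, normalised per channel.
#' @export
normalize_channels <- function(epoch) {
  sig <- if (inherits(epoch, "eeg_epoch")) epoch$signal else epoch
  stopifnot(is.matrix(sig))
  rows <- seq_len(nrow(sig))
  neg <- -sig
  hi <- sig[cbind(rows, max.col(sig, ties.method = "first"))]
  lo <- -neg[cbind(rows, max.col(neg, ties.method = "first"))]
  rng <- hi - lo
  out <- sig
  flat <- rng == 0
  if (any(!flat)) {
    idx <- which(!flat)
    out[idx, ] <- 2 * (sig[idx, , drop = FALSE] - lo[idx]) / rng[idx] - 1
  }
  out[flat, ] <- 0
  if (inherits(epoch, "eeg_epoch")) {
    epoch$signal <- out
    epoch
  } else {
    out
  }
}

#' Cut the stimulus-on analysis window out of an epoch
#'
#' Drops the pre-stimulus baseline from the epoch's signal and returns an
#' epoch whose `signal` is the stimulus-on window only; the baseline segment
#' is kept in the `baseline` element for encoders that need it (the wavelet
#' path baselines on the pre-stimulus second).
#'
#' @param epoch an [eeg_epoch()].
#' @param n_samples expected analysis-window length (default: everything
#'   after the pre-stimulus segment).
#' @return An [eeg_epoch()] with `pre_stimulus_samples = 0` and a `baseline`
#'   matrix element (possibly 0 columns).
#' @export
extract_analysis_window <- function(epoch, n_samples = NULL) {
  stopifnot(inherits(epoch, "eeg_epoch"))
  pre <- epoch$pre_stimulus_samples
  avail <- ncol(epoch$signal) - pre
  if (is.null(n_samples)) n_samples <- avail
  if (avail < n_samples) {
    stopf("epoch too short: need %d post-stimulus samples, have %d",
          n_samples, avail)
  }
  baseline <- epoch$signal[, seq_len(pre), drop = FALSE]
  win <- epoch$signal[, pre + seq_len(n_samples), drop = FALSE]
  out <- eeg_epoch(win, epoch$subject_id, epoch$stimulus_id,
                   epoch$class_label, epoch$sampling_rate, 0L)
  out$baseline <- baseline
  out
}

#' Zero-phase band-pass filter
#'
#' Restricts a multi-channel signal to a frequency band. The default
#' realisation masks the discrete Fourier transform (keeping bins whose
#' frequency lies in `[low, high]` inclusive, for both spectral halves) and
#' inverts it: exactly zero-phase, with complete rejection outside the
#' passband, and vectorised over channels. `method = "iir"` instead applies
#' a forward-backward Butterworth filter of the given order.
#'
#' @param x channels x samples matrix (or a numeric vector, treated as one
#'   channel).
#' @param band a [band_definition()].
#' @param sampling_rate Hz.
#' @param method `"fft"` (default) or `"iir"`.
#' @param order Butterworth order for `method = "iir"`.
#' @return Filtered signal, same shape as `x`.
#' @export
bandpass <- function(x, band, sampling_rate, method = c("fft", "iir"),
                     order = 4) {
  method <- match.arg(method)
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1)
  check_band_nyquist(band, sampling_rate)
  out <- if (method == "fft") {
    n <- ncol(x)
    freqs <- dft_bin_frequencies(n, sampling_rate)
    keep <- freqs >= band$low & freqs <= band$high
    Z <- stats::mvfft(t(x))
    Z[!keep, ] <- 0
    Re(t(stats::mvfft(Z, inverse = TRUE))) / n
  } else {
    wlo <- band$low / (sampling_rate / 2)
    whi <- band$high / (sampling_rate / 2)
    bf <- signal::butter(order, c(wlo, whi), type = "pass")
    t(apply(x, 1, function(ch) signal::filtfilt(bf, ch)))
  }
  if (vec) as.numeric(out) else out
}

## Frequencies of the n DFT bins, folding the upper half to its (negative)
## mirror magnitude so a symmetric band mask selects both spectral halves.
dft_bin_frequencies <- function(n, sampling_rate) {
  k <- 0:(n - 1)
  f <- k * sampling_rate / n
  pmin(f, sampling_rate - f)
}

#' Recording-chain conditioning for externally acquired epochs
#'
#' The simulator emits clean epochs at the target rate, but real recordings
#' typically need the conventional chain first: downsampling, broad-band
#' filtering, mains notch and baseline correction. These thin wrappers carry
#' the conventional defaults (250 Hz, 0.5-100 Hz, 50 Hz notch, first-second
#' baseline).
#'
#' @param epoch an [eeg_epoch()].
#' @param target_rate target sampling rate in Hz (must divide the epoch's
#'   rate).
#' @param low,high broad-band filter edges in Hz.
#' @param notch_freq mains frequency in Hz; a 2 Hz-wide band-stop is applied.
#' @param baseline_ms duration (ms) of the leading segment whose mean is
#'   subtracted per channel.
#' @return The conditioned [eeg_epoch()].
#' @name recording_chain
NULL

#' @rdname recording_chain
#' @export
downsample_epoch <- function(epoch, target_rate = 250) {
  stopifnot(inherits(epoch, "eeg_epoch"))
  factor <- epoch$sampling_rate / target_rate
  if (factor != round(factor) || factor < 1) {
    stopf("sampling rate %g is not an integer multiple of target %g",
          epoch$sampling_rate, target_rate)
  }
  factor <- as.integer(factor)
  if (factor == 1L) return(epoch)
  sig <- t(apply(epoch$signal, 1,
                 function(ch) signal::decimate(ch, factor)))
  eeg_epoch(sig, epoch$subject_id, epoch$stimulus_id, epoch$class_label,
            target_rate, as.integer(epoch$pre_stimulus_samples / factor))
}

#' @rdname recording_chain
#' @export
broadband_filter_epoch <- function(epoch, low = 0.5, high = 100) {
  stopifnot(inherits(epoch, "eeg_epoch"))
  epoch$signal <- bandpass(epoch$signal,
                           band_definition("broadband", low, high),
                           epoch$sampling_rate, method = "iir", order = 2)
  epoch
}

#' @rdname recording_chain
#' @export
notch_filter_epoch <- function(epoch, notch_freq = 50) {
  stopifnot(inherits(epoch, "eeg_epoch"))
  nyq <- epoch$sampling_rate / 2
  bf <- signal::butter(2, c(notch_freq - 1, notch_freq + 1) / nyq,
                       type = "stop")
  epoch$signal <- t(apply(epoch$signal, 1,
                          function(ch) signal::filtfilt(bf, ch)))
  epoch
}

#' @rdname recording_chain
#' @export
baseline_correct_epoch <- function(epoch, baseline_ms = 1000) {
  stopifnot(inherits(epoch, "eeg_epoch"))
  n <- min(ncol(epoch$signal),
           max(1L, round(baseline_ms / 1000 * epoch$sampling_rate)))
  mu <- rowMeans(epoch$signal[, seq_len(n), drop = FALSE])
  epoch$signal <- epoch$signal - mu
  epoch
}
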