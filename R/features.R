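#' Per-channel discrete Fourier spectrum of an analysis window
#'
#' @param x channels x samples matrix.
#' @param sampling_rate Hz.
#' @return List of class `spectrum_record`: `coefficients` (complex
#'   channels x bins), `bin_frequencies` (Hz, folded so bin k and its mirror
#'   share the same magnitude frequency).
#' @export
epoch_spectrum <- function(x, sampling_rate) {
  stopifnot(is.matrix(x))
  Z <- t(stats::mvfft(t(x)))
  structure(list(coefficients = Z,
                 bin_frequencies = dft_bin_frequencies(ncol(x), sampling_rate),
                 sampling_rate = sampling_rate),
            class = "spectrum_record")
}

band_bins <- function(bin_frequencies, band, positive_only = TRUE, n = NULL) {
  keep <- bin_frequencies >= band$low & bin_frequencies <= band$high
  if (positive_only && !is.null(n)) {
    ## restrict to the non-negative-frequency half (bins 0 .. floor(n/2))
    keep[seq_len(length(keep)) > floor(n / 2) + 1L] <- FALSE
  }
  which(keep)
}

#' FFT band-magnitude features
#'
#' Computes the per-channel discrete Fourier transform of the 3 s analysis
#' window, keeps the bins whose frequency lies inside the requested band
#' (positive-frequency half), and concatenates the coefficient magnitudes
#' across channels into one fixed-length vector of length
#' `n_channels * n_bins`.
#'
#' @param epoch an [eeg_epoch()] (analysis window only) or a channels x
#'   samples matrix.
#' @param band a [band_definition()].
#' @param sampling_rate Hz; taken from the epoch when omitted.
#' @return Named numeric feature vector (channel-major).
#' @export
fft_features <- function(epoch, band, sampling_rate = NULL) {
  x <- if (inherits(epoch, "eeg_epoch")) epoch$signal else epoch
  if (is.null(sampling_rate)) {
    if (!inherits(epoch, "eeg_epoch")) stopf("sampling_rate required")
    sampling_rate <- epoch$sampling_rate
  }
  check_band_nyquist(band, sampling_rate)
  spec <- epoch_spectrum(x, sampling_rate)
  bins <- band_bins(spec$bin_frequencies, band, n = ncol(x))
  if (length(bins) == 0) {
    stopf("band %s [%g, %g] Hz contains no DFT bins at n = %d, fs = %g",
          band$name, band$low, band$high, ncol(x), sampling_rate)
  }
  mags <- abs(spec$coefficients[, bins, drop = FALSE])
  out <- as.vector(t(mags))      # channel-major: channel 1's bins first
  names(out) <- as.vector(vapply(
    seq_len(nrow(x)),
    function(ch) sprintf("ch%02d_bin%03d", ch, bins - 1L),
    character(length(bins))))
  out
}

#' Band power of a band-passed window
#'
#' `P = sum_t |x_t|^2` over the analysis window, per channel.
#'
#' @param x_filtered band-passed channels x samples matrix.
#' @return Numeric vector, one power per channel.
#' @export
band_power <- function(x_filtered) {
  stopifnot(is.matrix(x_filtered))
  rowSums(x_filtered^2)
}

#' Differential-entropy features
#'
#' For a band-passed channel with power `P = sum_t x_t^2` over an N-sample
#' window, the Gaussian closed form of differential entropy gives
#' `h = 1/2 log(P) + 1/2 log(2*pi*e / N)` nats: the per-sample variance
#' estimate `P/N` plugged into `1/2 log(2*pi*e*sigma^2)`. For the canonical
#' 3 s window, N = 750.
#'
#' @param epoch an [eeg_epoch()] (analysis window) or channels x samples
#'   matrix of the *raw* window; the band-pass is applied internally.
#' @param band a [band_definition()].
#' @param sampling_rate Hz; taken from the epoch when omitted.
#' @return Numeric vector, one DE value (nats) per channel.
#' @export
de_features <- function(epoch, band, sampling_rate = NULL) {
  x <- if (inherits(epoch, "eeg_epoch")) epoch$signal else epoch
  if (is.null(sampling_rate)) {
    if (!inherits(epoch, "eeg_epoch")) stopf("sampling_rate required")
    sampling_rate <- epoch$sampling_rate
  }
  xf <- bandpass(x, band, sampling_rate)
  de_from_bandpassed(xf)
}

#' @rdname de_features
#' @param x_filtered an already band-passed channels x samples matrix.
#' @export
de_from_bandpassed <- function(x_filtered) {
  P <- band_power(x_filtered)
  n <- ncol(x_filtered)
  if (any(P == 0)) {
    stopf("differential entropy undefined: zero band power in channel(s) %s",
          paste(which(P == 0), collapse = ", "))
  }
  0.5 * log(P) + 0.5 * log(2 * pi * exp(1) / n)
}

## All-band DE in one pass: single FFT per epoch, Parseval for band power.
## Equivalent to de_features() with the default (spectral-mask) band-pass.
de_feature_matrix <- function(x, bands, sampling_rate) {
  stopifnot(is.matrix(x))
  n <- ncol(x)
  Z <- stats::mvfft(t(x))                       # bins x channels
  freqs <- dft_bin_frequencies(n, sampling_rate)
  out <- matrix(NA_real_, nrow = nrow(x), ncol = length(bands))
  colnames(out) <- names(bands)
  for (b in seq_along(bands)) {
    keep <- freqs >= bands[[b]]$low & freqs <= bands[[b]]$high
    ## Parseval: sum_t x~_t^2 = (1/n) sum_{k in band} |Z_k|^2
    P <- colSums(abs(Z[keep, , drop = FALSE])^2) / n
    if (any(P == 0)) {
      stopf("differential entropy undefined: zero %s-band power",
            names(bands)[b])
    }
    out[, b] <- 0.5 * log(P) + 0.5 * log(2 * pi * exp(1) / n)
  }
  out
}

## ---- Morlet wavelet path ------------------------------------------------

#' Adaptive Morlet cycle count
#'
#' Number of cycles grows linearly with frequency between the two anchor
#' points (3.5 cycles at 2 Hz, 18 cycles at 60 Hz by default), trading
#' temporal for spectral resolution as frequency increases.
#'
#' @param freq frequency (Hz), vectorised.
#' @param anchors list with `f` (two frequencies) and `cycles` (two counts).
#' @return Cycle count(s).
#' @export
morlet_cycles <- function(freq, anchors = list(f = c(2, 60),
                                               cycles = c(3.5, 18))) {
  anchors$cycles[1] + (anchors$cycles[2] - anchors$cycles[1]) *
    (freq - anchors$f[1]) / (anchors$f[2] - anchors$f[1])
}

## Complex Morlet wavelet power of one channel at one frequency, evaluated
## at the requested sample indices (1-based, into the padded signal).
morlet_power_channel <- function(x, freq, sampling_rate, cycles, at) {
  sd_t <- cycles / (2 * pi * freq)
  half <- ceiling(3 * sd_t * sampling_rate)
  tt <- (-half:half) / sampling_rate
  ## L2-normalised complex Morlet kernel
  kern <- exp(2i * pi * freq * tt) * exp(-tt^2 / (2 * sd_t^2))
  kern <- kern / sqrt(sum(abs(kern)^2))
  nconv <- length(x) + length(kern) - 1L
  X <- stats::fft(c(x, rep(0, nconv - length(x))))
  K <- stats::fft(c(kern, rep(0, nconv - length(kern))))
  conv <- stats::fft(X * K, inverse = TRUE) / nconv
  conv <- conv[half + at]                      # centre-aligned
  abs(conv)^2
}

#' Morlet-wavelet band-power features
#'
#' Time-frequency power via complex Morlet wavelets with the adaptive cycle
#' count of [morlet_cycles()]. The signal (baseline + stimulus window) is
#' zero-padded by `pad_s` seconds on both sides, power is evaluated on a
#' time grid downsampled by `time_decim`, and an absolute baseline — mean
#' power over `baseline_window_ms` relative to stimulus onset — is
#' subtracted per channel and frequency. Powers at the frequencies falling
#' inside each requested band are averaged over time and concatenated
#' across channels.
#'
#' @param epoch an [eeg_epoch()] that still contains its pre-stimulus
#'   segment (needed for the baseline).
#' @param bands list of [band_definition()]s.
#' @param freqs analysis frequencies in Hz (default 2-60 Hz in 2 Hz steps).
#' @param time_decim temporal decimation factor of the output grid.
#' @param pad_s zero padding, seconds per side.
#' @param baseline_window_ms two numbers, window relative to stimulus onset
#'   (ms) over which mean power is taken as the absolute baseline.
#' @return Named feature vector: channel x band mean baseline-corrected
#'   power (band-major).
#' @export
wavelet_features <- function(epoch, bands = band_table("handcrafted"),
                             freqs = seq(2, 60, by = 2),
                             time_decim = 3L, pad_s = 0.2,
                             baseline_window_ms = c(-900, -300)) {
  stopifnot(inherits(epoch, "eeg_epoch"))
  fs <- epoch$sampling_rate
  pre <- epoch$pre_stimulus_samples
  need_pre <- ceiling(-baseline_window_ms[1] / 1000 * fs)
  if (pre < need_pre) {
    stopf("baseline window [%g, %g] ms needs %d pre-stimulus samples, have %d",
          baseline_window_ms[1], baseline_window_ms[2], need_pre, pre)
  }
  npad <- round(pad_s * fs)
  nch <- nrow(epoch$signal)
  ntot <- ncol(epoch$signal)
  ## sample grid (in original samples, 1-based) at reduced temporal resolution
  grid <- seq(1L, ntot, by = as.integer(time_decim))
  base_idx <- which(grid >= pre + 1 + baseline_window_ms[1] / 1000 * fs &
                    grid <= pre + 1 + baseline_window_ms[2] / 1000 * fs)
  stim_idx <- which(grid > pre)
  power <- array(0, dim = c(nch, length(freqs), length(grid)))
  for (ch in seq_len(nch)) {
    xp <- c(rep(0, npad), epoch$signal[ch, ], rep(0, npad))
    for (fi in seq_along(freqs)) {
      p <- morlet_power_channel(xp, freqs[fi], fs,
                                morlet_cycles(freqs[fi]), npad + grid)
      power[ch, fi, ] <- p
    }
  }
  ## absolute baseline removal per channel x frequency
  base <- apply(power[, , base_idx, drop = FALSE], c(1, 2), mean)
  corrected <- sweep(power, c(1, 2), base, "-")
  out <- numeric(0)
  for (b in seq_along(bands)) {
    fsel <- freqs >= bands[[b]]$low & freqs <= bands[[b]]$high
    if (!any(fsel)) {
      stopf("no analysis frequencies inside band %s", names(bands)[b])
    }
    v <- apply(corrected[, fsel, stim_idx, drop = FALSE], 1, mean)
    names(v) <- sprintf("wav_%s_ch%02d", names(bands)[b], seq_len(nch))
    out <- c(out, v)
  }
  out
}

## ---- topographic EEG images ---------------------------------------------

#' Azimuthal-equidistant ("polar") projection of electrode positions
#'
#' Projects unit-sphere electrode coordinates to the plane about the vertex:
#' a point at polar angle theta (from +z) and azimuth phi maps to the planar
#' point at radius theta and angle phi. The vertex maps to the origin; an
#' equatorial electrode to radius pi/2.
#'
#' @param positions_3d n x 3 matrix (columns x, y, z); normalised to the
#'   unit sphere internally.
#' @return n x 2 matrix of planar coordinates.
#' @export
project_montage <- function(positions_3d) {
  stopifnot(is.matrix(positions_3d), ncol(positions_3d) == 3)
  nrm <- sqrt(rowSums(positions_3d^2))
  if (any(nrm == 0)) stopf("zero-norm electrode position")
  p <- positions_3d / nrm
  theta <- acos(pmin(pmax(p[, 3], -1), 1))
  phi <- atan2(p[, 2], p[, 1])
  cbind(x = theta * cos(phi), y = theta * sin(phi))
}

#' Synthetic spherical-cap montage
#'
#' Builds a deterministic n-channel layout on the upper unit hemisphere
#' (sunflower/Fibonacci arrangement) standing in for a recording cap; this
#' is a synthetic layout, not a standard 10-10 montage.
#'
#' @param n_channels number of electrodes.
#' @return A `montage_layout` list: `channel_names`, `positions_3d`,
#'   `positions_2d` (via [project_montage()]).
#' @export
make_montage <- function(n_channels = 62) {
  i <- seq_len(n_channels)
  z <- 1 - (i - 0.5) / n_channels * 0.95     # cap: z in (0.05, 1)
  golden <- pi * (3 - sqrt(5))
  phi <- (i - 1) * golden
  r <- sqrt(1 - z^2)
  p3 <- cbind(x = r * cos(phi), y = r * sin(phi), z = z)
  structure(list(channel_names = sprintf("E%02d", i),
                 positions_3d = p3,
                 positions_2d = project_montage(p3)),
            class = "montage_layout")
}

#' Read / write a montage as plain CSV
#'
#' Columns: channel_name, x, y, z (3D unit-sphere coordinates); the 2D
#' projection is recomputed on read.
#'
#' @param layout a `montage_layout`.
#' @param path CSV file path.
#' @return `read_montage_csv` returns a `montage_layout`.
#' @export
write_montage_csv <- function(layout, path) {
  df <- data.frame(channel_name = layout$channel_names,
                   x = layout$positions_3d[, 1],
                   y = layout$positions_3d[, 2],
                   z = layout$positions_3d[, 3])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_montage_csv
#' @export
read_montage_csv <- function(path) {
  df <- utils::read.csv(path)
  p3 <- as.matrix(df[, c("x", "y", "z")])
  rownames(p3) <- NULL
  structure(list(channel_names = as.character(df$channel_name),
                 positions_3d = p3,
                 positions_2d = project_montage(p3)),
            class = "montage_layout")
}

## Thin-plate spline scattered interpolation in the plane: exact at the
## data sites, smooth in between. Kernel U(r) = r^2 log r (U(0) = 0).
tps_interpolate <- function(xy, values, grid_xy) {
  n <- nrow(xy)
  rad <- function(r) ifelse(r == 0, 0, r^2 * log(r))
  D <- as.matrix(stats::dist(xy))
  K <- rad(D)
  P <- cbind(1, xy)
  A <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  rhs <- c(values, rep(0, 3))
  coef <- solve(A + diag(1e-10, n + 3), rhs)
  Dg <- sqrt(outer(grid_xy[, 1], xy[, 1], "-")^2 +
             outer(grid_xy[, 2], xy[, 2], "-")^2)
  as.numeric(rad(Dg) %*% coef[1:n] +
             cbind(1, grid_xy) %*% coef[(n + 1):(n + 3)])
}

#' Topographic EEG image
#'
#' Encodes one epoch as a 32 x 32 x 3 "image": per band of the image band
#' table (theta, alpha, beta), per channel, spectral power is the sum of
#' squared FFT coefficient magnitudes over the band's bins; the 62 scattered
#' per-channel powers are interpolated (thin-plate spline) onto a square
#' mesh over the projected montage, one band per colour plane
#' (red = theta, green = alpha, blue = beta). Pixels outside the scalp disc
#' take `fill`.
#'
#' @param epoch an [eeg_epoch()] analysis window or channels x samples
#'   matrix.
#' @param layout a `montage_layout` with one row per channel.
#' @param bands band table for the three planes (default
#'   `band_table("image")`).
#' @param grid_size mesh resolution per side.
#' @param sampling_rate Hz; taken from the epoch when omitted.
#' @param fill value outside the electrode disc.
#' @return An `eeg_image`: list with `pixels` (grid x grid x bands array),
#'   `band_order`, `grid_x`, `grid_y`.
#' @export
make_eeg_image <- function(epoch, layout, bands = band_table("image"),
                           grid_size = 32L, sampling_rate = NULL,
                           fill = 0) {
  x <- if (inherits(epoch, "eeg_epoch")) epoch$signal else epoch
  if (is.null(sampling_rate)) {
    if (!inherits(epoch, "eeg_epoch")) stopf("sampling_rate required")
    sampling_rate <- epoch$sampling_rate
  }
  if (nrow(x) != length(layout$channel_names)) {
    stopf("layout has %d channels but epoch has %d",
          length(layout$channel_names), nrow(x))
  }
  spec <- epoch_spectrum(x, sampling_rate)
  xy <- layout$positions_2d
  rmax <- max(sqrt(rowSums(xy^2))) * 1.02
  ax <- seq(-rmax, rmax, length.out = grid_size)
  grid <- as.matrix(expand.grid(x = ax, y = ax))
  inside <- sqrt(rowSums(grid^2)) <= rmax
  pixels <- array(fill, dim = c(grid_size, grid_size, length(bands)),
                  dimnames = list(NULL, NULL, names(bands)))
  for (b in seq_along(bands)) {
    bins <- band_bins(spec$bin_frequencies, bands[[b]], n = ncol(x))
    pow <- rowSums(abs(spec$coefficients[, bins, drop = FALSE])^2)
    vals <- rep(fill, nrow(grid))
    vals[inside] <- tps_interpolate(xy, pow, grid[inside, , drop = FALSE])
    pixels[, , b] <- matrix(vals, nrow = grid_size)
  }
  structure(list(pixels = pixels, band_order = names(bands),
                 grid_x = ax, grid_y = ax),
            class = "eeg_image")
}

#' Flatten an EEG image into a feature vector
#'
#' @param image an `eeg_image`.
#' @return Numeric vector of length grid^2 * bands.
#' @export
eeg_image_features <- function(image) {
  stopifnot(inherits(image, "eeg_image"))
  as.numeric(image$pixels)
}
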