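fs <- 250
tt750 <- (0:749) / fs

test_that("FFT features agree with the brute-force DFT oracle", {
  set.seed(4)
  x <- matrix(rnorm(8 * 120), nrow = 8)
  spec <- epoch_spectrum(x, fs)
  for (ch in c(1, 5, 8)) {
    oracle <- dft_bruteforce(x[ch, ])
    expect_lt(max(abs(spec$coefficients[ch, ] - oracle)) /
                max(abs(oracle)), 1e-10)
  }
})

test_that("a pure 10 Hz sinusoid concentrates in bin 3f with magnitude N/2", {
  x <- matrix(sin(2 * pi * 10 * tt750), nrow = 1)
  alpha <- band_table("handcrafted")$alpha
  f <- fft_features(x, alpha, fs)
  # 750 samples at 250 Hz: frequency f sits in bin 3f (0-based)
  expect_equal(names(which.max(f)), "ch01_bin030")
  expect_equal(max(f), 375, tolerance = 1e-6)
  other <- f[names(f) != "ch01_bin030"]
  expect_lt(max(other), 1e-6)
})

test_that("constant signals have no in-band energy", {
  x <- matrix(3, nrow = 2, ncol = 750)
  f <- fft_features(x, band_table("handcrafted")$theta, fs)
  expect_lt(max(f), 1e-8)
  expect_equal(length(f), 2 * length(seq(5 * 3, 7 * 3)))
  expect_error(fft_features(x, band_definition("narrow", 10.1, 10.2), fs),
               "no DFT bins")
})

test_that("differential entropy matches its closed form", {
  # P = 750 (unit per-sample power) gives h = 1/2 log(2 pi e) nats
  x <- matrix(rep(c(1, -1), 375), nrow = 1)
  expect_equal(de_from_bandpassed(x), 0.5 * log(2 * pi * exp(1)),
               tolerance = 1e-12)
  expect_equal(de_from_bandpassed(x), 1.41894, tolerance = 1e-5)
  set.seed(5)
  y <- matrix(rnorm(3 * 750), nrow = 3)
  # doubling the amplitude adds exactly log 2
  expect_equal(de_from_bandpassed(2 * y) - de_from_bandpassed(y),
               rep(log(2), 3), tolerance = 1e-12)
  # sign invariance
  expect_equal(de_from_bandpassed(-y), de_from_bandpassed(y))
  expect_error(de_from_bandpassed(matrix(0, 1, 750)), "zero band power")
})

test_that("the one-pass band DE matrix equals the per-band filter route", {
  set.seed(6)
  x <- matrix(rnorm(4 * 750), nrow = 4)
  bands <- band_table("handcrafted")
  M <- de_feature_matrix(x, bands, fs)
  for (b in names(bands)) {
    expect_equal(M[, b], unname(de_features(x, bands[[b]], fs)),
                 tolerance = 1e-10)
  }
})

test_that("wide-band DE of Gaussian noise approaches the Gaussian entropy", {
  sigma <- 1.7
  wide <- band_definition("wide", 0.1, 124.9)
  set.seed(7)
  # trials as rows: one mvfft computes all trials at once
  h <- de_feature_matrix(matrix(rnorm(400 * 750, sd = sigma), nrow = 400),
                         list(wide = wide), fs)
  expect_equal(mean(h), 0.5 * log(2 * pi * exp(1) * sigma^2),
               tolerance = 3 * sd(h) / sqrt(length(h)) +
                 0.5 * log(750 / 749))
})

test_that("Morlet cycle counts interpolate linearly between the anchors", {
  expect_equal(morlet_cycles(2), 3.5)
  expect_equal(morlet_cycles(60), 18)
  expect_equal(morlet_cycles(31), 10.75)
})

test_that("wavelet features vanish for silent and stationary signals", {
  nch <- 2
  zero_ep <- eeg_epoch(matrix(0, nch, 1000), "s", "v", 0L, fs, 250L)
  f0 <- wavelet_features(zero_ep, bands = band_table("handcrafted")["alpha"])
  expect_equal(unname(f0), rep(0, nch))

  carrier <- sin(2 * pi * 10 * (0:999) / fs)
  stationary <- eeg_epoch(rbind(carrier, carrier), "s", "v", 0L, fs, 250L)
  onset <- rbind(carrier, carrier)
  onset[, 1:250] <- 0
  onset_ep <- eeg_epoch(onset, "s", "v", 0L, fs, 250L)
  fst <- wavelet_features(stationary, bands = band_table("handcrafted")["alpha"])
  fon <- wavelet_features(onset_ep, bands = band_table("handcrafted")["alpha"])
  # a rhythm present in the baseline too is removed by the absolute baseline
  expect_lt(max(abs(fst)), 0.15 * max(abs(fon)))
  expect_error(wavelet_features(eeg_epoch(onset, "s", "v", 0L, fs, 0L)),
               "baseline")
})

test_that("polar projection sends vertex to origin and equator to radius pi/2", {
  p <- rbind(c(0, 0, 1), c(1, 0, 0), c(0.3, 0.4, 0.866), c(-0.3, 0.4, 0.866))
  q <- project_montage(p)
  expect_equal(unname(q[1, ]), c(0, 0), tolerance = 1e-12)
  expect_equal(sqrt(sum(q[2, ]^2)), pi / 2, tolerance = 1e-12)
  # electrodes mirrored about the midline project to mirrored points
  expect_equal(q[3, "y"], q[4, "y"], tolerance = 1e-12)
  expect_equal(q[3, "x"], -q[4, "x"], tolerance = 1e-12)
  expect_error(project_montage(rbind(c(0, 0, 0))), "zero-norm")
})

test_that("montage construction and CSV round trip preserve the layout", {
  m <- make_montage(62)
  expect_equal(length(m$channel_names), 62)
  expect_equal(dim(m$positions_2d), c(62, 2))
  expect_true(all(abs(sqrt(rowSums(m$positions_3d^2)) - 1) < 1e-12))
  path <- tempfile(fileext = ".csv")
  write_montage_csv(m, path)
  m2 <- read_montage_csv(path)
  expect_equal(m2$positions_3d, m$positions_3d, tolerance = 1e-12)
  expect_equal(m2$positions_2d, m$positions_2d, tolerance = 1e-12)
})

test_that("EEG images interpolate channel powers onto the mesh", {
  m <- make_montage(16)
  # constant per-channel signal power -> constant image inside the disc
  x <- matrix(rep(sin(2 * pi * 10 * tt750), 16), nrow = 16, byrow = TRUE)
  img <- make_eeg_image(x, m, sampling_rate = fs)
  expect_equal(dim(img$pixels), c(32, 32, 3))
  alpha_plane <- img$pixels[, , "alpha"]
  inside <- sqrt(outer(img$grid_x^2, img$grid_y^2, "+")) <=
    max(sqrt(rowSums(m$positions_2d^2)))
  vals <- alpha_plane[inside]
  expect_lt(diff(range(vals)) / max(vals), 0.05)
  # silent epoch -> all-zero image
  img0 <- make_eeg_image(matrix(0, 16, 750), m, sampling_rate = fs)
  expect_true(all(img0$pixels == 0))
  expect_error(make_eeg_image(x[1:8, ], m, sampling_rate = fs), "channels")
})

test_that("image values at electrode sites recover the electrode powers", {
  m <- make_montage(16)
  set.seed(8)
  amps <- runif(16, 0.5, 2)
  x <- amps * matrix(rep(sin(2 * pi * 10 * tt750), 16), nrow = 16,
                     byrow = TRUE)
  img <- make_eeg_image(x, m, sampling_rate = fs)
  pow <- amps^2 * 375^2     # one positive-half bin of magnitude A * N / 2
  # snap each electrode to its nearest grid node inside the scalp disc
  # (outside the disc pixels carry the fill value by construction)
  rmax <- max(sqrt(rowSums(m$positions_2d^2))) * 1.02
  grid <- expand.grid(i = seq_along(img$grid_x), j = seq_along(img$grid_y))
  gx <- img$grid_x[grid$i]; gy <- img$grid_y[grid$j]
  inside <- sqrt(gx^2 + gy^2) <= rmax
  at_site <- vapply(seq_len(16), function(ch) {
    d2 <- (gx - m$positions_2d[ch, 1])^2 + (gy - m$positions_2d[ch, 2])^2
    d2[!inside] <- Inf
    k <- which.min(d2)
    img$pixels[grid$i[k], grid$j[k], "alpha"]
  }, numeric(1))
  # grid-snapped lookup: exact at the node, smooth in between
  expect_gt(cor(at_site, pow), 0.95)
  expect_lt(median(abs(at_site - pow) / pow), 0.15)
})

test_that("permuting channels together with the layout leaves the image unchanged", {
  m <- make_montage(12)
  set.seed(9)
  x <- matrix(rnorm(12 * 750), nrow = 12)
  img1 <- make_eeg_image(x, m, sampling_rate = fs)
  perm <- sample(12)
  m2 <- m
  m2$channel_names <- m$channel_names[perm]
  m2$positions_3d <- m$positions_3d[perm, ]
  m2$positions_2d <- m$positions_2d[perm, ]
  img2 <- make_eeg_image(x[perm, ], m2, sampling_rate = fs)
  expect_equal(img2$pixels, img1$pixels, tolerance = 1e-8)
  expect_equal(length(eeg_image_features(img1)), 32 * 32 * 3)
})
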