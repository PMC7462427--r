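test_that("window centers sit on the sample grid, symmetric about the pulse", {
  expect_equal(nrow(window_centers(window_spec(retain_span = c(0, 0)))), 1L)

  # brute-force enumeration of multiples of 0.1 s inside [-0.5, 0.5]
  spec <- window_spec(fs = 100, center_spacing = 10, retain_span = c(-0.5, 0.5),
                      freq_grid = seq(2, 25, 0.5), window_length = 0.5)
  oracle <- sum(abs((-100:100) * 10 / 100) <= 0.5 + 1e-12)
  wc <- window_centers(spec)
  expect_equal(nrow(wc), oracle)
  expect_equal(nrow(wc), 11L)
  expect_equal(wc$center_s, sort(wc$center_s))
  expect_equal(wc$center_s, -rev(wc$center_s))
  expect_identical(wc$tag[wc$center_s == 0], "pulse")

  expect_error(window_spec(fs = 128, epoch_span = c(-1, 1),
                           retain_span = c(-1, 1)),
               "exceeds the epoch")
})

test_that("cross-spectra match a textbook DFT oracle and are Hermitian", {
  set.seed(21)
  n_samples <- 5 * 128 + 1
  data <- array(stats::rnorm(2 * n_samples * 3), c(2, n_samples, 3))
  data[2, , 2] <- data[1, , 2]   # identical channels in trial 2
  trials <- list(data = data, fs = 128, pulse_index = 321L,
                 times = (seq_len(n_samples) - 321L) / 128)
  spec <- window_spec()
  cs <- cross_spectra(trials, spec)

  # direct oracle: demean, taper, zero-pad, naive DFT, cross-product
  w <- 26L; j <- 1L; f <- 10
  wl <- spec$wl_samples
  idx <- 321L + cs$manifest$offset_samples[w] + seq(-wl %/% 2, length.out = wl)
  taper <- 0.5 - 0.5 * cos(2 * pi * seq(0, wl - 1) / (wl - 1))
  seg <- data[, idx, j]
  seg <- seg - rowMeans(seg)
  padded <- cbind(seg * rep(taper, each = 2), matrix(0, 2, spec$nfft - wl))
  k <- f / spec$freq_step
  fa <- naive_dft_bin(padded[1, ], k)
  fb <- naive_dft_bin(padded[2, ], k)
  X <- cs_matrix(cs, window = w, freq = f, trial = j)
  expect_equal(X[1, 2], fa * Conj(fb), tolerance = 1e-10)
  expect_equal(X[2, 1], Conj(X[1, 2]))
  expect_true(all(Im(diag(X)) == 0) || max(abs(Im(diag(X)))) < 1e-12)
  expect_true(all(Re(diag(X)) >= 0))

  # identical channels: cross-spectrum real and equal to the auto-spectrum
  X2 <- cs_matrix(cs, window = w, freq = f, trial = 2L)
  expect_equal(Im(X2[1, 2]), 0, tolerance = 1e-10)
  expect_equal(X2[1, 2], X2[1, 1], tolerance = 1e-10)
})

test_that("a pure sinusoid concentrates diagonal power at its frequency", {
  n_samples <- 5 * 128 + 1
  t <- (seq_len(n_samples) - 321L) / 128
  data <- array(0, c(2, n_samples, 2))
  for (j in 1:2) {
    data[1, , j] <- sin(2 * pi * 10 * t + j)
    data[2, , j] <- stats::rnorm(n_samples, sd = 0.1)
  }
  cs <- cross_spectra(list(data = data, fs = 128, pulse_index = 321L), window_spec())
  pow <- vapply(cs$freq, function(f)
    Re(cs_matrix(cs, window = 26L, freq = f, trial = 1L)[1, 1]), numeric(1))
  expect_equal(cs$freq[which.max(pow)], 10)
  near <- abs(cs$freq - 10) <= 2
  expect_gt(sum(pow[near]) / sum(pow), 0.95)
})

test_that("the window extraction refuses to run past the epoch", {
  data <- array(stats::rnorm(2 * 100 * 2), c(2, 100, 2))
  trials <- list(data = data, fs = 128, pulse_index = 50L)
  expect_error(cross_spectra(trials, window_spec()), "past the epoch")
})

test_that("scalar dwPLI matches brute-force ordered-pair summation", {
  expect_equal(as.numeric(dwpli_pairs(c(1, 1, -1))), -1 / 3)
  expect_equal(as.numeric(dwpli_pairs(c(1, 1, -1))), brute_dwpli(c(1, 1, -1)))
  expect_equal(as.numeric(dwpli_pairs(c(2, 3, 5))), 1)   # common sign
  z <- dwpli_pairs(c(0, 0, 0))
  expect_equal(as.numeric(z), 0)
  expect_true(attr(z, "degenerate"))
  set.seed(4)
  for (n in 2:6) {
    I <- stats::rnorm(n)
    expect_equal(as.numeric(dwpli_pairs(I)), brute_dwpli(I), tolerance = 1e-12)
  }
})

test_that("array dwPLI equals the ordered-pair oracle computed from cs_matrix", {
  cfg <- sim_config(n_regions = 3, n_trials = 5,
                    bands = list(band_plan(c(8, 12), c(1L, 1L, 2L),
                                           lag_cycles = c(0, 0.25, 0))),
                    noise_sd = 0.3, seed = 17)
  ens <- generate_trials(cfg)
  spec <- window_spec(freq_grid = seq(8, 12, 0.5))
  cs <- cross_spectra(ens, spec)
  dw <- dwpli(cs)
  for (w in c(1L, 26L, 51L)) {
    for (f in c(8, 10, 12)) {
      I12 <- vapply(1:5, function(j)
        Im(cs_matrix(cs, window = w, freq = f, trial = j)[1, 2]), numeric(1))
      fi <- which(dw$freq == f)
      expect_equal(dw$values[1, 2, fi, w], brute_dwpli(I12), tolerance = 1e-12)
      expect_equal(dw$values[2, 1, fi, w], dw$values[1, 2, fi, w])
    }
  }
  expect_true(all(dw$values >= -1 & dw$values <= 1))
})

test_that("dwPLI is invariant to channel scaling and trial order", {
  cfg <- sim_config(n_regions = 2, n_trials = 8,
                    bands = list(band_plan(c(8, 12), c(1L, 1L),
                                           lag_cycles = c(0, 0.25))),
                    noise_sd = 0.2, seed = 23)
  ens <- generate_trials(cfg)
  spec <- window_spec(freq_grid = seq(8, 12, 1))
  base <- dwpli(cross_spectra(ens, spec))

  scaled <- ens
  scaled$data[1, , ] <- 3.7 * scaled$data[1, , ]
  expect_equal(dwpli(cross_spectra(scaled, spec))$values, base$values,
               tolerance = 1e-10)

  permuted <- ens
  permuted$data <- permuted$data[, , c(5, 2, 8, 1, 7, 3, 6, 4)]
  expect_equal(dwpli(cross_spectra(permuted, spec))$values, base$values,
               tolerance = 1e-10)
})

test_that("band averaging is the arithmetic mean over the closed band", {
  dm <- c(2, 2, 3, 3)   # 2 nodes, 3 freqs, 3 windows
  vals <- array(0, dm)
  vals[1, 2, , ] <- c(0.2, 0.4, 0.6)   # recycled per window
  vals[2, 1, , ] <- c(0.2, 0.4, 0.6)
  dw <- structure(list(values = vals, degenerate = array(FALSE, dm),
                       freq = c(8, 8.5, 9), manifest = toy_manifest(1, 1),
                       n_trials = 5),
                  class = "dwpli_spectrum")
  conn <- band_average(dw, c(8, 9))
  expect_equal(conn$layers[1, 2, 1], 0.4)
  single <- band_average(dw, c(8.5, 8.5))
  expect_equal(single$layers[1, 2, 1], 0.4)
  expect_error(band_average(dw, c(15, 20)), "no frequency bins")

  # default alpha band covers the 9 bins 8.0 ... 12.0
  freqs <- seq(2, 25, 0.5)
  expect_equal(sum(freqs >= 8 & freqs <= 12), 9L)
})

test_that("edge change differences post minus pre means, excluding the pulse", {
  set.seed(31)
  layers <- array(stats::runif(4 * 4 * 11), c(4, 4, 11))
  for (l in 1:11) {
    layers[, , l] <- (layers[, , l] + t(layers[, , l])) / 2
    diag(layers[, , l]) <- 0
  }
  conn <- toy_conn(layers, n_pre = 5, n_post = 5)
  ec <- edge_change(conn)

  # explicit per-layer loop oracle
  for (r in seq_len(nrow(ec))) {
    a <- ec$node_a[r]; b <- ec$node_b[r]
    pre_vals <- vapply(1:5, function(l) layers[a, b, l], numeric(1))
    post_vals <- vapply(7:11, function(l) layers[a, b, l], numeric(1))
    expect_equal(ec$change[r], mean(post_vals) - mean(pre_vals))
  }

  # post identical to pre -> zero change
  sym <- layers
  sym[, , 7:11] <- sym[, , 1:5]
  expect_true(all(edge_change(toy_conn(sym, 5, 5))$change == 0))

  # constant offset on every post layer -> that offset on every edge
  off <- layers
  for (l in 7:11) {
    shifted <- layers[, , l - 6] + 0.17
    diag(shifted) <- 0
    off[, , l] <- shifted
  }
  off[, , 1:5] <- layers[, , 1:5]
  ec_off <- edge_change(toy_conn(off, 5, 5))
  expect_equal(ec_off$change, rep(0.17, nrow(ec_off)), tolerance = 1e-12)

  expect_error(edge_change(conn_interval(conn, "pre"),
                           conn_interval(conn, c("post", "pulse"))),
               "layer counts differ")
})
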