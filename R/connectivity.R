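#' Sliding-window spectral estimation settings
#'
#' Defines the tapered sliding windows and frequency grid used for
#' trial-consistency connectivity. Defaults reproduce the analysis scale
#' of a 128 Hz peri-stimulus recording: 0.5-s Hanning-tapered windows
#' whose centers are 5 samples (about 39 ms) apart, a 2-25 Hz grid in
#' 0.5 Hz steps, and a retained analysis span of +/- 1 s around the pulse
#' (51 windows: 25 pre, the pulse window, 25 post).
#'
#' @param fs Sampling rate in Hz.
#' @param epoch_span Epoch limits in seconds relative to the pulse.
#' @param center_spacing Spacing between window centers, in samples.
#' @param window_length Taper length in seconds.
#' @param freq_grid Frequencies in Hz at which cross-spectra are evaluated;
#'   must be uniformly spaced and lie on the zero-padded DFT grid.
#' @param retain_span Seconds around the pulse within which window centers
#'   are retained for analysis.
#' @param taper `"hanning"` (single-taper Hanning, the default) or
#'   `"dpss"` (multitaper with Slepian sequences).
#' @param n_tapers Number of DPSS tapers when `taper = "dpss"`.
#' @return A `window_spec` list.
#' @export
window_spec <- function(fs = 128, epoch_span = c(-2.5, 2.5),
                        center_spacing = 5L, window_length = 0.5,
                        freq_grid = seq(2, 25, by = 0.5),
                        retain_span = c(-1, 1),
                        taper = c("hanning", "dpss"), n_tapers = 3L) {
  taper <- match.arg(taper)
  stopifnot(fs > 0, length(epoch_span) == 2L, length(retain_span) == 2L,
            is_count(center_spacing), center_spacing >= 1)
  wl_samples <- round(window_length * fs)
  if (wl_samples < 2) stopf("window_length x fs must be >= 2 samples")
  if (any(freq_grid <= 0) || any(freq_grid >= fs / 2)) {
    stopf("freq_grid must lie within (0, fs/2)")
  }
  steps <- diff(freq_grid)
  if (length(freq_grid) > 1 &&
      any(abs(steps - steps[1]) > 1e-9)) {
    stopf("freq_grid must be uniformly spaced")
  }
  step <- if (length(freq_grid) > 1) steps[1] else 0.5
  nfft <- round(fs / step)
  if (abs(nfft - fs / step) > 1e-9 ||
      any(abs(freq_grid / step - round(freq_grid / step)) > 1e-9)) {
    stopf("freq_grid must lie on a DFT grid of step fs/nfft")
  }
  if (retain_span[2] + window_length / 2 > epoch_span[2] + 1e-9 ||
      retain_span[1] - window_length / 2 < epoch_span[1] - 1e-9) {
    stopf("retain_span plus half a window exceeds the epoch")
  }
  structure(
    list(fs = fs, epoch_span = as.numeric(epoch_span),
         center_spacing = as.integer(center_spacing),
         window_length = window_length, wl_samples = wl_samples,
         freq_grid = as.numeric(freq_grid), freq_step = step, nfft = nfft,
         retain_span = as.numeric(retain_span), taper = taper,
         n_tapers = as.integer(n_tapers)),
    class = "window_spec"
  )
}

#' Retained window centers around the pulse
#'
#' Window centers sit at integer multiples of `center_spacing` samples
#' from the pulse sample, symmetric about 0 and including 0, restricted to
#' `retain_span`.
#'
#' @param spec A [window_spec()].
#' @return A tibble with `index`, `offset_samples`, `center_s` and `tag`
#'   (`"pre"`, `"pulse"`, `"post"`), ordered by time.
#' @examples
#' nrow(window_centers(window_spec())) # 51
#' @export
window_centers <- function(spec) {
  stopifnot(inherits(spec, "window_spec"))
  kmax <- floor(spec$retain_span[2] * spec$fs / spec$center_spacing + 1e-9)
  kmin <- -floor(-spec$retain_span[1] * spec$fs / spec$center_spacing + 1e-9)
  k <- kmin:kmax
  offset <- k * spec$center_spacing
  center_s <- offset / spec$fs
  tibble::tibble(
    index = seq_along(k),
    offset_samples = as.integer(offset),
    center_s = center_s,
    tag = dplyr::case_when(center_s < 0 ~ "pre",
                           center_s == 0 ~ "pulse",
                           TRUE ~ "post")
  )
}

hanning_taper <- function(n) {
  0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
}

# Tapers as a wl_samples x n_tapers matrix (one column for Hanning).
taper_matrix <- function(spec) {
  if (spec$taper == "hanning") {
    matrix(hanning_taper(spec$wl_samples), ncol = 1)
  } else {
    nw <- 2
    t(pracma_dpss(spec$wl_samples, nw, spec$n_tapers))
  }
}

# Slepian (DPSS) tapers via the symmetric tridiagonal formulation.
pracma_dpss <- function(n, nw, k) {
  w <- nw / n
  d <- ((n - 1 - 2 * seq(0, n - 1)) / 2)^2 * cos(2 * pi * w)
  e <- seq_len(n - 1) * (n - seq_len(n - 1)) / 2
  tri <- diag(d)
  tri[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- e
  tri[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- e
  dec <- eigen(tri, symmetric = TRUE)
  v <- dec$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    if (sum(v[, j]) < 0) v[, j] <- -v[, j]
  }
  t(v)
}

#' Tapered windowed Fourier coefficients for all trials
#'
#' For every retained window and trial, the segment of each region's trace
#' is demeaned, tapered, zero-padded to the spectral grid and Fourier
#' transformed. The cross-spectrum between two regions at a window,
#' frequency and trial is the product of one region's coefficient with the
#' conjugate of the other's; [cs_matrix()] materializes that Hermitian
#' matrix on demand, while the coefficients themselves are stored to keep
#' memory linear in the number of regions.
#'
#' @param trials A `trial_ensemble` (or any list with `data`, `fs`,
#'   `pulse_index`).
#' @param spec A [window_spec()]; its `fs` and `epoch_span` must match the
#'   ensemble.
#' @return A `cross_spectra` object: complex coefficient array
#'   `n_regions x n_freq x n_trials x n_windows x n_tapers`, the window
#'   manifest, and the spec.
#' @export
cross_spectra <- function(trials, spec = window_spec(fs = trials$fs)) {
  stopifnot(inherits(spec, "window_spec"))
  x <- trials$data
  n <- dim(x)[1]; n_samples <- dim(x)[2]; n_trials <- dim(x)[3]
  if (n_trials < 2) stopf("at least 2 trials are required")
  if (abs(spec$fs - trials$fs) > 1e-9) stopf("spec fs does not match data fs")
  manifest <- window_centers(spec)
  wl <- spec$wl_samples
  half <- wl %/% 2
  offsets <- seq(-half, length.out = wl)
  tap <- taper_matrix(spec)
  n_tap <- ncol(tap)
  bins <- round(spec$freq_grid / spec$freq_step) + 1L
  nf <- length(bins)
  coef <- array(complex(real = 0), c(n, nf, n_trials, nrow(manifest), n_tap))
  for (w in seq_len(nrow(manifest))) {
    idx <- trials$pulse_index + manifest$offset_samples[w] + offsets
    if (any(idx < 1) || any(idx > n_samples)) {
      stopf("window %d extends past the epoch; data are never zero-filled", w)
    }
    for (j in seq_len(n_trials)) {
      seg <- x[, idx, j, drop = FALSE]
      dim(seg) <- c(n, wl)
      seg <- seg - rowMeans(seg)
      for (tp in seq_len(n_tap)) {
        padded <- matrix(0, n, spec$nfft)
        padded[, seq_len(wl)] <- seg * rep(tap[, tp], each = n)
        ft <- t(stats::mvfft(t(padded)))
        coef[, , j, w, tp] <- ft[, bins, drop = FALSE]
      }
    }
  }
  structure(
    list(coef = coef, freq = spec$freq_grid, manifest = manifest,
         spec = spec),
    class = "cross_spectra"
  )
}

#' Materialize one Hermitian cross-spectral matrix
#'
#' @param cs A [cross_spectra()] result.
#' @param window,trial Window and trial indices.
#' @param freq Frequency in Hz (must be on the grid).
#' @return Complex `n x n` Hermitian matrix, averaged over tapers.
#' @export
cs_matrix <- function(cs, window, freq, trial) {
  stopifnot(inherits(cs, "cross_spectra"))
  fi <- which(abs(cs$freq - freq) < 1e-9)
  if (length(fi) != 1L) stopf("frequency %g Hz is not on the grid", freq)
  n_tap <- dim(cs$coef)[5]
  n <- dim(cs$coef)[1]
  acc <- matrix(complex(real = 0), n, n)
  for (tp in seq_len(n_tap)) {
    f <- cs$coef[, fi, trial, window, tp]
    acc <- acc + outer(f, Conj(f))
  }
  acc / n_tap
}

#' Debiased weighted phase lag index across trials
#'
#' For each region pair, window and frequency, with `I_j` the imaginary
#' part of the trial-`j` cross-spectrum, the estimator is
#' `sum_{j != k} I_j I_k / sum_{j != k} |I_j I_k|`, i.e. the debiased
#' square-root weighted phase lag index. Values lie in `[-1, 1]`; a pair
#' whose imaginary cross-spectra vanish in all trials has denominator 0
#' and is defined as 0 with a degeneracy flag. The estimator is blind to
#' zero-lag (volume-conduction-like) coupling and unbiased for
#' independent signals at any trial count.
#'
#' @param cs A [cross_spectra()] result (at least 2 trials).
#' @return A `dwpli_spectrum`: array `n x n x n_freq x n_windows` of dwPLI
#'   values, a logical `degenerate` array of the same shape, frequencies
#'   and the window manifest.
#' @export
dwpli <- function(cs) {
  stopifnot(inherits(cs, "cross_spectra"))
  dm <- dim(cs$coef)
  n <- dm[1]; nf <- dm[2]; n_trials <- dm[3]; nw <- dm[4]; n_tap <- dm[5]
  if (n_trials < 2) stopf("dwPLI undefined for fewer than 2 trials")
  ia <- rep(seq_len(n), times = n)
  ib <- rep(seq_len(n), each = n)
  vals <- array(0, c(n, n, nf, nw))
  degen <- array(FALSE, c(n, n, nf, nw))
  for (w in seq_len(nw)) {
    for (fi in seq_len(nf)) {
      # imaginary cross-spectra for all ordered pairs x trials, pooled
      # over tapers before the imaginary-part products
      imat <- matrix(0, n * n, n_trials)
      for (tp in seq_len(n_tap)) {
        f <- cs$coef[, fi, , w, tp]
        dim(f) <- c(n, n_trials)
        re <- Re(f); im <- Im(f)
        imat <- imat + (im[ia, , drop = FALSE] * re[ib, , drop = FALSE] -
                          re[ia, , drop = FALSE] * im[ib, , drop = FALSE])
      }
      imat <- imat / n_tap
      s <- rowSums(imat)
      s2 <- rowSums(imat^2)
      sa <- rowSums(abs(imat))
      num <- s^2 - s2
      den <- sa^2 - s2
      bad <- den <= .Machine$double.eps * pmax(1, sa^2)
      v <- ifelse(bad, 0, num / den)
      vals[, , fi, w] <- matrix(v, n, n)
      degen[, , fi, w] <- matrix(bad, n, n)
    }
  }
  for (fi in seq_len(nf)) for (w in seq_len(nw)) {
    diag(vals[, , fi, w]) <- 0
  }
  structure(
    list(values = vals, degenerate = degen, freq = cs$freq,
         manifest = cs$manifest, n_trials = n_trials),
    class = "dwpli_spectrum"
  )
}

#' dwPLI from one pair's per-trial imaginary cross-spectra
#'
#' The scalar form of the estimator behind [dwpli()], exposed for
#' inspection and small exact computations:
#' `sum_{j != k} I_j I_k / sum_{j != k} |I_j I_k|` over ordered trial
#' pairs, computed via the equivalent running-sum identity. Returns 0
#' (flagged) when the denominator vanishes.
#'
#' @param imag_xspec Numeric vector of per-trial imaginary cross-spectra.
#' @return Scalar in `[-1, 1]` with logical attribute `"degenerate"`.
#' @examples
#' dwpli_pairs(c(1, 1, -1)) # -1/3
#' @export
dwpli_pairs <- function(imag_xspec) {
  if (length(imag_xspec) < 2) stopf("dwPLI undefined for fewer than 2 trials")
  s <- sum(imag_xspec)
  s2 <- sum(imag_xspec^2)
  sa <- sum(abs(imag_xspec))
  den <- sa^2 - s2
  if (den <= .Machine$double.eps * max(1, sa^2)) {
    return(structure(0, degenerate = TRUE))
  }
  structure((s^2 - s2) / den, degenerate = FALSE)
}

#' Average dwPLI over a frequency band
#'
#' Arithmetic mean over the frequency bins inside the closed band, per
#' window and region pair, yielding one connectivity matrix per window
#' (a layer sequence ready for multilayer community detection).
#'
#' @param dw A [dwpli()] result.
#' @param band Numeric length-2 band edges in Hz (closed interval).
#' @param label Optional band label (e.g. `"alpha"`).
#' @return A `connectivity_series`: `layers` array `n x n x L`, window
#'   manifest, band, label.
#' @export
band_average <- function(dw, band, label = NULL) {
  stopifnot(inherits(dw, "dwpli_spectrum"), length(band) == 2L)
  sel <- which(dw$freq >= band[1] - 1e-9 & dw$freq <= band[2] + 1e-9)
  if (length(sel) == 0L) stopf("band [%g, %g] contains no frequency bins",
                               band[1], band[2])
  dm <- dim(dw$values)
  layers <- array(0, c(dm[1], dm[2], dm[4]))
  for (w in seq_len(dm[4])) {
    sl <- dw$values[, , sel, w, drop = FALSE]
    dim(sl) <- c(dm[1] * dm[2], length(sel))
    layers[, , w] <- matrix(rowMeans(sl), dm[1], dm[2])
  }
  new_connectivity_series(layers, band = band, manifest = dw$manifest,
                          label = label %||% sprintf("%g-%g Hz", band[1], band[2]))
}

new_connectivity_series <- function(layers, band, manifest, label = NULL) {
  stopifnot(length(dim(layers)) == 3L, dim(layers)[1] == dim(layers)[2],
            dim(layers)[3] == nrow(manifest))
  if (sum(manifest$tag == "pulse") != 1L) {
    stopf("a connectivity series must contain exactly one pulse-centered layer")
  }
  structure(
    list(layers = layers, band = as.numeric(band), manifest = manifest,
         label = label),
    class = "connectivity_series"
  )
}

#' @export
print.connectivity_series <- function(x, ...) {
  cat(sprintf("<connectivity_series> %s: %d nodes x %d layers (%d pre / %d pulse / %d post)\n",
              x$label, dim(x$layers)[1], dim(x$layers)[3],
              sum(x$manifest$tag == "pre"), sum(x$manifest$tag == "pulse"),
              sum(x$manifest$tag == "post")))
  invisible(x)
}

#' Subset a connectivity series by peri-stimulus interval
#'
#' @param conn A `connectivity_series`.
#' @param interval One or more of `"pre"`, `"pulse"`, `"post"`.
#' @return A `connectivity_series` restricted to those layers (the pulse
#'   layer is retained in the manifest only when requested; subsetting to
#'   an interval without the pulse returns a plain layer stack).
#' @export
conn_interval <- function(conn, interval) {
  stopifnot(inherits(conn, "connectivity_series"))
  keep <- conn$manifest$tag %in% interval
  if (!any(keep)) stopf("no layers tagged %s", paste(interval, collapse = "/"))
  out <- list(layers = conn$layers[, , keep, drop = FALSE],
              band = conn$band,
              manifest = conn$manifest[keep, , drop = FALSE],
              label = conn$label)
  class(out) <- "connectivity_series"
  out
}

#' Per-edge pre-to-post connectivity change
#'
#' Mean dwPLI over the post-pulse layers minus mean over the pre-pulse
#' layers, per edge; the pulse-centered layer is excluded. With a single
#' series the split follows the window manifest tags; alternatively two
#' series (pre and post) may be given.
#'
#' @param pre A `connectivity_series` covering the whole epoch (then
#'   `post` is `NULL`), or the pre-interval series.
#' @param post Optional post-interval series.
#' @return Tibble with `node_a`, `node_b` (a < b), `pre`, `post`, `change`.
#' @export
edge_change <- function(pre, post = NULL) {
  if (is.null(post)) {
    stopifnot(inherits(pre, "connectivity_series"))
    pre_l <- pre$layers[, , pre$manifest$tag == "pre", drop = FALSE]
    post_l <- pre$layers[, , pre$manifest$tag == "post", drop = FALSE]
  } else {
    pre_l <- pre$layers; post_l <- post$layers
    if (dim(pre_l)[1] != dim(post_l)[1]) stopf("mismatched node counts")
    if (dim(pre_l)[3] != dim(post_l)[3]) {
      stopf("pre and post layer counts differ (%d vs %d)",
            dim(pre_l)[3], dim(post_l)[3])
    }
  }
  n <- dim(pre_l)[1]
  mean_layers <- function(a) {
    dim(a) <- c(n * n, dim(a)[3])
    matrix(rowMeans(a), n, n)
  }
  pm <- mean_layers(pre_l)
  qm <- mean_layers(post_l)
  pairs <- upper_pairs(n)
  tibble::tibble(
    node_a = pairs[, 1L], node_b = pairs[, 2L],
    pre = pm[pairs], post = qm[pairs],
    change = qm[pairs] - pm[pairs]
  )
}
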