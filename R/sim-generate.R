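#' Generate a peri-stimulus trial ensemble of regional oscillations
#'
#' Simulates region-by-sample-by-trial source time series with the
#' community structure planted in the configuration. In each band and
#' trial, every community shares one band-limited source (band-pass
#' filtered white noise, a fresh realization per trial); each member
#' receives that source delayed by its `lag_cycles` at the band center
#' frequency and scaled by `coupling`, plus independent Gaussian noise.
#' At the pulse (time 0) the coupling structure switches instantaneously
#' from the pre- to the post-partition: pre-pulse samples mix pre-community
#' sources, post-pulse samples mix an independent set of post-community
#' sources. No stimulation artifact waveform is modeled.
#'
#' The shared sources are filtered with a zero-phase Butterworth band-pass
#' (second-order sections applied forward and backward, fourth-order
#' magnitude response); one second of padding on each side absorbs filter
#' transients and the circular wrap of the fractional-sample delays.
#'
#' @param config A [sim_config()].
#' @return A `trial_ensemble`: list with `data` (array
#'   `n_regions x n_samples x n_trials`), `fs`, `times` (seconds relative
#'   to the pulse), `pulse_index` (sample at time 0), and the config.
#' @examples
#' cfg <- sim_config(n_regions = 2, n_trials = 10,
#'                   bands = list(band_plan(c(8, 12), c(1, 1),
#'                                          lag_cycles = c(0, 0.25))),
#'                   noise_sd = 0.05, seed = 42)
#' ens <- generate_trials(cfg)
#' dim(ens$data)
#' @export
generate_trials <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  fs <- config$fs
  for (b in config$bands) {
    if (any(b$band >= fs / 2) || any(b$band <= 0)) {
      stopf("band outside (0, fs/2)")
    }
  }
  if (config$n_trials < 2) stopf("`n_trials` must be >= 2")

  n_samples <- round(diff(config$epoch_span) * fs) + 1L
  pulse_index <- round(-config$epoch_span[1] * fs) + 1L
  times <- (seq_len(n_samples) - pulse_index) / fs
  n <- config$n_regions
  pad <- round(fs)                      # 1 s transient padding each side
  n_pad <- n_samples + 2L * pad

  # Per-band filter and per-node delay operators, reused across trials.
  band_ops <- lapply(config$bands, function(b) {
    wn <- b$band / (fs / 2)
    bf <- signal::butter(2, wn, type = "pass")
    f_center <- mean(b$band)
    tau <- b$lag_cycles / f_center      # seconds
    freqs <- c(0:(n_pad %/% 2), -((n_pad - n_pad %/% 2 - 1):1)) * fs / n_pad
    shift <- exp(-2i * pi * outer(freqs, tau))   # n_pad x n
    list(plan = b, filt = bf, shift = shift)
  })

  pre_idx <- which(times < 0)
  post_idx <- which(times >= 0)         # switch takes effect at the pulse
  keep <- pad + seq_len(n_samples)

  data <- with_seed(config$seed, {
    out <- array(0, dim = c(n, n_samples, config$n_trials))
    for (j in seq_len(config$n_trials)) {
      x <- matrix(0, n, n_samples)
      for (op in band_ops) {
        b <- op$plan
        if (b$coupling == 0) next
        mix <- matrix(0, n, n_samples)
        for (phase in c("pre", "post")) {
          part <- if (phase == "pre") b$pre_partition else b$post_partition
          cols <- if (phase == "pre") pre_idx else post_idx
          for (comm in unique(part)) {
            members <- which(part == comm)
            src <- signal::filtfilt(op$filt, stats::rnorm(n_pad))
            src <- src / stats::sd(src[keep])
            sf <- stats::fft(src)
            for (i in members) {
              delayed <- Re(stats::fft(sf * op$shift[, i], inverse = TRUE)) / n_pad
              mix[i, cols] <- delayed[keep][cols]
            }
          }
        }
        x <- x + b$coupling * mix
      }
      x <- x + matrix(stats::rnorm(n * n_samples, sd = config$noise_sd),
                      n, n_samples)
      out[, , j] <- x
    }
    out
  })

  structure(
    list(data = data, fs = fs, times = times, pulse_index = pulse_index,
         config = config),
    class = "trial_ensemble"
  )
}

#' @export
print.trial_ensemble <- function(x, ...) {
  cat(sprintf("<trial_ensemble> %d regions x %d samples x %d trials, %g Hz, pulse at sample %d\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$fs,
              x$pulse_index))
  invisible(x)
}

#' Generate (or wrap) node coordinates with a stimulation site
#'
#' By default places regions uniformly at random inside a sphere of radius
#' 0.15 m (head scale), reproducibly from the config seed. A user-supplied
#' coordinate table is returned unchanged apart from validation.
#'
#' @param config A [sim_config()].
#' @param coordinates Optional `n_regions x 3` numeric matrix of positions
#'   in meters; overrides the random placement.
#' @param radius Sphere radius in meters for random placement.
#' @return A `geometry`: list with `coordinates` (n x 3, meters) and
#'   `stim_node`.
#' @export
generate_geometry <- function(config, coordinates = NULL, radius = 0.15) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_regions
  if (is.null(coordinates)) {
    coordinates <- with_seed(config$seed + 104729L, {
      pts <- matrix(NA_real_, 0, 3)
      while (nrow(pts) < n) {
        cand <- matrix(stats::runif(3 * n, -radius, radius), ncol = 3)
        cand <- cand[rowSums(cand^2) <= radius^2, , drop = FALSE]
        pts <- rbind(pts, cand)
      }
      pts[seq_len(n), , drop = FALSE]
    })
  } else {
    coordinates <- as.matrix(coordinates)
    if (nrow(coordinates) != n || ncol(coordinates) != 3 ||
        !all(is.finite(coordinates))) {
      stopf("`coordinates` must be a finite n_regions x 3 matrix")
    }
  }
  dimnames(coordinates) <- list(NULL, c("x", "y", "z"))
  structure(list(coordinates = coordinates, stim_node = config$stim_node),
            class = "geometry")
}

#' @export
print.geometry <- function(x, ...) {
  cat(sprintf("<geometry> %d nodes, stim node %d\n",
              nrow(x$coordinates), x$stim_node))
  invisible(x)
}

#' Pairwise Euclidean node distances
#'
#' @param geom A [generate_geometry()] result.
#' @return Symmetric n x n matrix of distances in meters.
#' @export
node_distances <- function(geom) {
  stopifnot(inherits(geom, "geometry"))
  as.matrix(stats::dist(geom$coordinates))
}
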