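#' Describe one frequency band's planted community structure
#'
#' A band plan specifies, for a single narrow frequency band, which
#' communities of regions share an oscillatory source before and after the
#' stimulation pulse, how strongly each member is driven by its community
#' source, and the per-node phase lag at which the shared source arrives.
#'
#' Phase-lag-based connectivity (the debiased weighted phase lag index,
#' dwPLI) is blind to zero-lag coupling by construction: if two members
#' receive the shared source at identical lags, the imaginary part of their
#' cross-spectrum is zero in expectation. At least one node per
#' multi-member community should therefore carry a lag distinct from its
#' community peers; a warning is emitted otherwise.
#'
#' @param band Numeric length-2, band edges in Hz (e.g. `c(8, 12)` for
#'   alpha, `c(13, 20)` for beta).
#' @param pre_partition,post_partition Integer community label per region
#'   in effect before / after the pulse.
#' @param coupling Amplitude share of the shared community source in
#'   `[0, 1]`. 0 disconnects all regions in this band.
#' @param lag_cycles Per-node phase lag of the shared source, in cycles of
#'   the band's center frequency. Recycled to the number of regions.
#' @return A `band_plan` list.
#' @seealso [sim_config()], [generate_trials()]
#' @export
band_plan <- function(band, pre_partition, post_partition = pre_partition,
                      coupling = 0.9, lag_cycles = 0.25) {
  stopifnot(is.numeric(band), length(band) == 2L, band[1] < band[2],
            all(band > 0))
  if (!is.numeric(coupling) || length(coupling) != 1L ||
      coupling < 0 || coupling > 1) {
    stopf("`coupling` must be a single value in [0, 1]")
  }
  pre_partition <- as.integer(pre_partition)
  post_partition <- as.integer(post_partition)
  if (length(pre_partition) != length(post_partition)) {
    stopf("pre and post partitions must have equal length")
  }
  structure(
    list(band = as.numeric(band),
         pre_partition = pre_partition,
         post_partition = post_partition,
         coupling = coupling,
         lag_cycles = as.numeric(lag_cycles)),
    class = "band_plan"
  )
}

#' Configure a synthetic peri-stimulus trial ensemble
#'
#' Collects every parameter of the coupled-oscillator generator: geometry
#' of the recording (regions, sampling rate, epoch), the planted
#' band-specific community structure, noise level, stimulation site and
#' seeds. Defaults mirror a source-localized single-pulse TMS-EEG
#' recording: 68 cortical regions sampled at 128 Hz over a 5-s epoch
#' centered on the pulse.
#'
#' @param n_regions Number of regions (nodes). Default 68.
#' @param fs Sampling rate in Hz. Default 128. Must exceed twice the
#'   highest band edge.
#' @param epoch_span Numeric length-2, epoch limits in seconds relative to
#'   the pulse at time 0. Default `c(-2.5, 2.5)`.
#' @param n_trials Trials per ensemble; at least 2 (trial-consistency
#'   dwPLI is undefined for fewer).
#' @param bands List of [band_plan()] objects.
#' @param noise_sd Standard deviation of the independent additive noise on
#'   every channel (shared sources have unit standard deviation, so
#'   `noise_sd` is also the noise-to-source amplitude ratio).
#' @param stim_node Index of the region taken as the stimulation site.
#' @param seed Base RNG seed; identical configs generate identical data.
#' @param n_subjects Number of independent replicate ensembles ("subjects")
#'   an experiment will draw; replicate `s` uses seed `seed + s - 1`.
#' @return A validated `sim_config` list.
#' @examples
#' cfg <- sim_config(
#'   n_regions = 4, n_trials = 20,
#'   bands = list(band_plan(c(8, 12), pre_partition = c(1, 1, 2, 2),
#'                          lag_cycles = c(0, 0.25, 0, 0.25))),
#'   seed = 1
#' )
#' @export
sim_config <- function(n_regions = 68L, fs = 128, epoch_span = c(-2.5, 2.5),
                       n_trials = 60L, bands = list(), noise_sd = 0.3,
                       stim_node = 1L, seed = 1L, n_subjects = 10L) {
  if (!is_count(n_regions) || n_regions < 2) {
    stopf("`n_regions` must be an integer >= 2")
  }
  if (!is.numeric(fs) || fs <= 0) stopf("`fs` must be positive")
  stopifnot(is.numeric(epoch_span), length(epoch_span) == 2L)
  if (!(epoch_span[1] <= 0 && epoch_span[2] >= 0)) {
    stopf("`epoch_span` must contain time 0 (the pulse)")
  }
  if (!is_count(n_trials) || n_trials < 2) {
    stopf("dwPLI is a cross-trial estimator: `n_trials` must be >= 2")
  }
  if (!is_count(stim_node) || stim_node < 1 || stim_node > n_regions) {
    stopf("`stim_node` must index a region")
  }
  bands <- lapply(bands, function(b) {
    if (!inherits(b, "band_plan")) stopf("`bands` must be band_plan objects")
    if (any(b$band >= fs / 2) || any(b$band <= 0)) {
      stopf("band [%g, %g] Hz outside (0, fs/2) = (0, %g)",
            b$band[1], b$band[2], fs / 2)
    }
    if (length(b$pre_partition) != n_regions) {
      stopf("band partitions must have length n_regions = %d", n_regions)
    }
    b$lag_cycles <- rep_len(b$lag_cycles, n_regions)
    flat <- unique(unlist(lapply(
      list(b$pre_partition, b$post_partition), function(part) {
        Filter(function(comm) {
          members <- which(part == comm)
          length(members) > 1 &&
            length(unique(b$lag_cycles[members])) == 1L
        }, unique(part))
      })))
    if (length(flat) > 0) {
      warning(sprintf(
        "band [%g, %g]: community %s has identical lags on all members; its coupling is invisible to dwPLI",
        b$band[1], b$band[2], paste(flat, collapse = ", ")), call. = FALSE)
    }
    b
  })
  structure(
    list(n_regions = as.integer(n_regions), fs = fs,
         epoch_span = as.numeric(epoch_span),
         n_trials = as.integer(n_trials), bands = bands,
         noise_sd = noise_sd, stim_node = as.integer(stim_node),
         seed = as.integer(seed), n_subjects = as.integer(n_subjects)),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> %d regions, %g Hz, epoch [%g, %g] s, %d trials, %d subject(s)\n",
              x$n_regions, x$fs, x$epoch_span[1], x$epoch_span[2],
              x$n_trials, x$n_subjects))
  for (b in x$bands) {
    cat(sprintf("  band [%g, %g] Hz: %d pre / %d post communities, coupling %g\n",
                b$band[1], b$band[2], length(unique(b$pre_partition)),
                length(unique(b$post_partition)), b$coupling))
  }
  invisible(x)
}

#' Retrieve a planted community partition
#'
#' Returns the exact ground-truth label vector the generator uses for a
#' given band and peri-stimulus interval, for parameter-recovery tests.
#'
#' @param config A [sim_config()].
#' @param band Numeric length-2 band edges matching a configured band.
#' @param interval `"pre"` or `"post"`.
#' @return Integer label vector of length `n_regions`.
#' @export
planted_partition <- function(config, band, interval = c("pre", "post")) {
  stopifnot(inherits(config, "sim_config"))
  interval <- match.arg(interval)
  for (b in config$bands) {
    if (isTRUE(all.equal(b$band, as.numeric(band)))) {
      return(if (interval == "pre") b$pre_partition else b$post_partition)
    }
  }
  stopf("no configured band matches [%g, %g] Hz", band[1], band[2])
}
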