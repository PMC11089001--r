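#' Episode detection configuration
#'
#' Band-limited oscillation episodes are detected in the amplitude envelope
#' of the band-pass-filtered LFP (magnitude of the analytic signal, i.e. the
#' full-wave-rectified amplitude, then smoothed): an episode starts where
#' the smoothed envelope exceeds `mean + enter_sd * sd` for at least
#' `min_duration`, with its boundaries extended outward to the
#' `mean + exit_sd * sd` crossings of the raw envelope. The baseline mean
#' and s.d. are estimated over the whole-session unsmoothed envelope.
#' Defaults follow the beta-band settings (15-30 Hz, 2 s.d. / 1 s.d.,
#' 80 ms); `band = c(30, 60)` with `min_duration = 0.025` gives the gamma
#' settings.
#'
#' @param band numeric length-2, band edges in Hz.
#' @param enter_sd,exit_sd detection and boundary thresholds in s.d. units of
#'   the envelope amplitude (exit_sd < enter_sd).
#' @param min_duration minimum time above the enter threshold, seconds.
#' @param smooth_window smoothing window for the rectified signal, seconds;
#'   default 3 cycles of the band center frequency.
#' @param filter_order Butterworth order for the zero-phase band-pass.
#' @return object of class `detection_config`.
#' @export
detection_config <- function(band = c(15, 30), enter_sd = 2, exit_sd = 1,
                             min_duration = 0.080, smooth_window = NULL,
                             filter_order = 4) {
  stopifnot(length(band) == 2, band[1] > 0, band[2] > band[1],
            exit_sd < enter_sd, min_duration > 0)
  if (is.null(smooth_window)) smooth_window <- 3 / mean(band)
  structure(list(band = band, enter_sd = enter_sd, exit_sd = exit_sd,
                 min_duration = min_duration, smooth_window = smooth_window,
                 filter_order = filter_order),
            class = "detection_config")
}

# Zero-phase (forward-backward) Butterworth band-pass.
bandpass_filter <- function(x, fs, band, order = 4) {
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  signal::filtfilt(bf, x)
}

moving_average <- function(x, w) {
  w <- max(1, as.integer(w))
  stats::filter(c(rep(x[1], w), x, rep(x[length(x)], w)),
                rep(1 / w, w), sides = 2)[(w + 1):(w + length(x))] |>
    as.numeric()
}

# Amplitude envelope of the band-passed signal (magnitude of the analytic
# signal), raw and smoothed. Detection thresholds are computed from the raw
# envelope's whole-session mean and s.d.; the threshold test runs on the
# smoothed envelope so ripple does not split events.
detection_envelopes <- function(values, fs, cfg) {
  bp <- bandpass_filter(values, fs, cfg$band, cfg$filter_order)
  raw <- Mod(analytic_signal(bp))
  list(raw = raw, smooth = moving_average(raw, round(cfg$smooth_window * fs)))
}

# Smoothed detection envelope (for plotting).
detection_envelope <- function(values, fs, cfg) {
  detection_envelopes(values, fs, cfg)$smooth
}

#' Detect band-limited oscillation episodes
#'
#' @param lfp an [lfp_signal()] tibble.
#' @param cfg a [detection_config()].
#' @return a tibble of episodes: `band`, `start_s`, `end_s`, `peak_envelope`
#'   (envelope maximum, signal units), `envelope_argmax_s` (its time).
#'   Episodes are time-ordered, non-overlapping, each at least
#'   `min_duration` above the enter threshold; episodes whose extended
#'   boundaries touch are merged. A constant or all-zero signal yields an
#'   empty table.
#' @export
detect_episodes <- function(lfp, cfg = detection_config()) {
  stopifnot(inherits(cfg, "detection_config"))
  fs <- lfp_sampling_rate(lfp)
  if (nrow(lfp) < 10 * fs / cfg$band[1]) {
    abort("signal too short for episode detection in this band")
  }
  band_label <- paste0(cfg$band[1], "-", cfg$band[2], "Hz")
  empty <- tibble(band = character(0), start_s = numeric(0),
                  end_s = numeric(0), peak_envelope = numeric(0),
                  envelope_argmax_s = numeric(0))
  if (sd(lfp$value) == 0) return(empty)
  envs <- detection_envelopes(lfp$value, fs, cfg)
  env <- envs$smooth
  m <- mean(envs$raw); s <- sd(envs$raw)
  if (s == 0) return(empty)
  enter <- m + cfg$enter_sd * s
  exit <- m + cfg$exit_sd * s
  min_n <- ceiling(cfg$min_duration * fs)
  core <- logical_runs(env > enter)
  core <- core[(core$end - core$start + 1) >= min_n, , drop = FALSE]
  if (nrow(core) == 0) return(empty)
  # extend each core run outward to the exit-threshold crossings of the raw
  # envelope (boundary resolution is not limited by the smoother)
  below <- envs$raw <= exit
  starts <- integer(nrow(core)); ends <- integer(nrow(core))
  for (k in seq_len(nrow(core))) {
    i <- core$start[k]
    prev_below <- which(below[seq_len(i - 1)])
    starts[k] <- if (length(prev_below)) max(prev_below) + 1 else 1
    j <- core$end[k]
    if (j >= length(env)) {
      ends[k] <- length(env)
    } else {
      nxt_below <- which(below[seq(j + 1, length(env))]) + j
      ends[k] <- if (length(nxt_below)) min(nxt_below) - 1 else length(env)
    }
  }
  # merge touching/overlapping extended episodes
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  ms <- starts[1]; me <- ends[1]
  out_s <- integer(0); out_e <- integer(0)
  for (k in seq_along(starts)[-1]) {
    if (starts[k] <= me + 1) {
      me <- max(me, ends[k])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- starts[k]; me <- ends[k]
    }
  }
  out_s <- c(out_s, ms); out_e <- c(out_e, me)
  peak_i <- vapply(seq_along(out_s), function(k) {
    seg <- seq(out_s[k], out_e[k])
    seg[which.max(env[seg])]
  }, integer(1))
  tibble(band = band_label,
         start_s = (out_s - 1) / fs,
         end_s = (out_e - 1) / fs,
         peak_envelope = env[peak_i],
         envelope_argmax_s = (peak_i - 1) / fs)
}

#' Instantaneous phase of the band-passed LFP
#'
#' Computes the Hilbert (analytic-signal) phase of the band-pass-filtered
#' signal. Convention: 0 degrees at the band-passed signal peak, +/-180 at
#' the trough.
#'
#' @param lfp an [lfp_signal()] tibble.
#' @param band band edges in Hz (default beta, 15-30).
#' @param filter_order Butterworth order.
#' @return a tibble `time_s`, `phase_deg` on the LFP time base, with the
#'   sampling rate attribute preserved.
#' @export
lfp_phase <- function(lfp, band = c(15, 30), filter_order = 4) {
  fs <- lfp_sampling_rate(lfp)
  bp <- bandpass_filter(lfp$value, fs, band, filter_order)
  ph <- Arg(analytic_signal(bp)) * 180 / pi
  out <- tibble(time_s = lfp$time_s, phase_deg = wrap_deg(ph))
  attr(out, "lfp_rate") <- fs
  out
}

#' Assign oscillation phases to spikes fired during episodes
#'
#' Only spikes inside detected episodes receive a phase (outside episodes no
#' phase is defined); the phase is that of the nearest LFP sample.
#'
#' @param spikes tibble with `unit_id`, `time_s`.
#' @param phase tibble from [lfp_phase()].
#' @param episodes episode tibble from [detect_episodes()] (or ground truth
#'   with `start_s`/`end_s`).
#' @return tibble `unit_id`, `time_s`, `phase_deg`, restricted to in-episode
#'   spikes.
#' @export
assign_spike_phases <- function(spikes, phase, episodes) {
  fs <- attr(phase, "lfp_rate")
  if (is.null(fs)) abort("phase series carries no sampling rate")
  keep <- in_intervals(spikes$time_s, episodes$start_s, episodes$end_s)
  sp <- spikes[keep, , drop = FALSE]
  idx <- pmin(pmax(round(sp$time_s * fs) + 1, 1), nrow(phase))
  tibble(unit_id = sp$unit_id, time_s = sp$time_s,
         phase_deg = phase$phase_deg[idx])
}

phase_bin_centers <- function(n_bins) -180 + (seq_len(n_bins) - 0.5) * 360 / n_bins

# Bin index in 1..n_bins for phases in (-180, 180].
phase_bin_index <- function(phase_deg, n_bins) {
  i <- ceiling((wrap_deg(phase_deg) + 180) / (360 / n_bins))
  pmin(pmax(i, 1L), n_bins)
}

#' Smoothed circular phase histogram
#'
#' Spike counts in `n_bins` phase bins, circularly convolved with a Gaussian
#' kernel (sigma = `kernel_sd_bins` bins) and normalized to sum to 1.
#'
#' @param phases_deg spike phases in degrees.
#' @param n_bins number of bins (default 20, i.e. 18-degree bins).
#' @param kernel_sd_bins Gaussian kernel standard deviation in bin units
#'   (default 0.65); 0 disables smoothing.
#' @return tibble `bin`, `bin_center_deg`, `prob` summing to 1.
#' @export
phase_histogram <- function(phases_deg, n_bins = 20, kernel_sd_bins = 0.65) {
  if (length(phases_deg) < 1) abort("phase_histogram() needs at least 1 phase")
  counts <- tabulate(phase_bin_index(phases_deg, n_bins), nbins = n_bins)
  if (kernel_sd_bins > 0) {
    d <- seq_len(n_bins) - 1
    d <- pmin(d, n_bins - d)                       # circular lag
    kern <- exp(-d^2 / (2 * kernel_sd_bins^2))
    kern <- kern / sum(kern)
    counts <- vapply(seq_len(n_bins), function(i) {
      sum(counts * kern[((seq_len(n_bins) - i) %% n_bins) + 1])
    }, numeric(1))
  }
  tibble(bin = seq_len(n_bins), bin_center_deg = phase_bin_centers(n_bins),
         prob = counts / sum(counts))
}

#' Firing probability aligned to the episode envelope maximum
#'
#' Histogram of spike lags relative to each episode's envelope maximum,
#' min-max scaled to [0, 1].
#'
#' @param spikes tibble with `time_s` (optionally `unit_id`).
#' @param episodes episode tibble with `envelope_argmax_s` (as from
#'   [detect_episodes()]); ground-truth tables use `center_s`.
#' @param window half-width of the lag window, seconds.
#' @param bin_width lag bin width, seconds.
#' @return tibble `lag_s` (bin center), `prob` (scaled 0-1).
#' @export
envelope_aligned_probability <- function(spikes, episodes, window = 0.5,
                                         bin_width = 0.025) {
  stopifnot(nrow(episodes) >= 1)
  ref <- if ("envelope_argmax_s" %in% names(episodes)) {
    episodes$envelope_argmax_s
  } else {
    episodes$center_s
  }
  lags <- as.vector(outer(spikes$time_s, ref, "-"))
  lags <- lags[abs(lags) <= window]
  breaks <- seq(-window, window, by = bin_width)
  counts <- tabulate(findInterval(lags, breaks, rightmost.closed = TRUE),
                     nbins = length(breaks) - 1)
  p <- counts
  rng <- range(p)
  scaled <- if (diff(rng) == 0) rep(0, length(p)) else (p - rng[1]) / diff(rng)
  tibble(lag_s = breaks[-length(breaks)] + bin_width / 2, prob = scaled)
}
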