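#' Configuration for the synthetic session generator
#'
#' Bundles every parameter of the synthetic recording session: a 1/f-background
#' LFP with injected beta bursts, a Markov-chain ethogram of innate behaviors
#' (feeding F, social contact S, new-object exploration E) interleaved with
#' unscored gaps, and inhomogeneous-Poisson spike trains whose rate follows
#' behavior-specific gains and whose phases are von Mises-coupled to the
#' injected oscillation.
#'
#' The default population mirrors the structure the downstream analysis is
#' designed to detect. Cells are interleaved over four classes: 20%
#' multimodal "transition cells" (rate gain for every behavior, hence
#' recruited - shifted to the oscillation peak - in every pre-onset window),
#' 15% per behavior of behavior-specific cells (gain for one behavior,
#' recruited only before that behavior), and 35% untuned, non-entrained
#' cells. Entrained cells (kappa = 2) lock to the oscillation trough
#' (180 degrees, where most hypothalamic cells fire) except when recruited,
#' when they lock to the peak (0 degrees). The transition state is therefore
#' a selective phase shift with no accompanying rate change, carried
#' predominantly by the multimodal ensemble, as a population of order one
#' hundred simultaneously recorded cells.
#'
#' @param session_length session duration, seconds.
#' @param lfp_rate LFP sampling rate, samples/s.
#' @param n_cells number of units.
#' @param behaviors behavior label set.
#' @param base_rate baseline firing rate, spikes/s per cell.
#' @param behavior_gain `n_cells x length(behaviors)` matrix of dimensionless
#'   rate multipliers (default: tuned-cell structure described above).
#' @param tuned_gain rate multiplier used when building the default gain
#'   matrix.
#' @param burst_rate injected oscillation bursts per minute.
#' @param burst_duration_mean mean burst duration, seconds.
#' @param burst_freq burst carrier frequency, Hz (within 15-30 for beta).
#' @param burst_snr ratio of burst envelope peak to the background standard
#'   deviation in the burst band.
#' @param kappa per-cell von Mises concentration (scalar recycled).
#' @param mu_transition,mu_control per-cell preferred phase, degrees, inside
#'   2-s pre-onset transition windows vs. elsewhere during oscillation
#'   episodes.
#' @param markov_matrix behavior-to-behavior transition probability matrix,
#'   rows summing to 1 (default uniform).
#' @param bout_duration_mean mean scored-behavior bout duration, seconds.
#' @param gap_range range (seconds) of the unscored gap between bouts; the
#'   minimum must be >= `transition_window` so transition epochs never overlap
#'   the preceding scored behavior.
#' @param transition_window anticipation window before each behavior onset,
#'   seconds.
#' @param seed integer seed; all generator randomness derives from it.
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(session_length = 600,
                             lfp_rate = 1250,
                             n_cells = 120,
                             behaviors = c("F", "S", "E"),
                             base_rate = 8,
                             behavior_gain = NULL,
                             tuned_gain = 3,
                             burst_rate = 75,
                             burst_duration_mean = 0.202,
                             burst_freq = 20,
                             burst_snr = 6,
                             kappa = NULL,
                             mu_transition = NULL,
                             mu_control = NULL,
                             markov_matrix = NULL,
                             bout_duration_mean = 8,
                             gap_range = c(3, 8),
                             transition_window = 2,
                             seed = 1) {
  stopifnot(session_length > 0, lfp_rate > 2 * burst_freq, n_cells >= 1,
            length(behaviors) >= 1, base_rate >= 0, burst_rate >= 0,
            burst_snr > 0, burst_duration_mean > 0,
            gap_range[1] >= transition_window)
  nb <- length(behaviors)
  if (is.null(markov_matrix)) {
    markov_matrix <- matrix(1 / nb, nb, nb, dimnames = list(behaviors, behaviors))
  }
  if (!isTRUE(all.equal(unname(rowSums(markov_matrix)), rep(1, nb),
                        tolerance = 1e-9))) {
    abort("markov_matrix rows must each sum to 1")
  }
  # Interleaved tuning classes per 20 cells: 4 multimodal (M), 3 each
  # behavior-specific, 7 untuned (U); generalized to any behavior set.
  base_pattern <- c("M", behaviors[1], "U",
                    if (nb >= 2) behaviors[2] else "U",
                    if (nb >= 3) behaviors[3] else "U", "U",
                    "M", behaviors[1], "U",
                    if (nb >= 2) behaviors[2] else "U",
                    if (nb >= 3) behaviors[3] else "U", "U",
                    "M", "U", behaviors[1],
                    if (nb >= 2) behaviors[2] else "U", "U",
                    if (nb >= 3) behaviors[3] else "U",
                    "M", "U")
  tuning <- rep(base_pattern, length.out = n_cells)
  if (is.null(behavior_gain)) {
    behavior_gain <- matrix(1, n_cells, nb, dimnames = list(NULL, behaviors))
    for (i in seq_len(n_cells)) {
      if (tuning[i] == "M") {
        behavior_gain[i, ] <- tuned_gain
      } else if (tuning[i] %in% behaviors) {
        behavior_gain[i, tuning[i]] <- tuned_gain
      }
    }
  }
  stopifnot(nrow(behavior_gain) == n_cells, ncol(behavior_gain) == nb,
            all(behavior_gain >= 0))
  colnames(behavior_gain) <- behaviors
  if (is.null(kappa)) kappa <- ifelse(tuning == "U", 0, 2)
  kappa <- rep_len(kappa, n_cells)
  if (any(kappa < 0)) abort("kappa must be >= 0")
  if (is.null(mu_transition)) mu_transition <- ifelse(tuning == "U", 180, 0)
  if (is.null(mu_control)) mu_control <- rep(180, n_cells)
  mu_transition <- rep_len(mu_transition, n_cells)
  mu_control <- rep_len(mu_control, n_cells)
  structure(
    list(session_length = session_length, lfp_rate = lfp_rate,
         n_cells = n_cells, behaviors = behaviors, base_rate = base_rate,
         behavior_gain = behavior_gain, burst_rate = burst_rate,
         burst_duration_mean = burst_duration_mean, burst_freq = burst_freq,
         burst_snr = burst_snr, kappa = kappa,
         mu_transition = mu_transition, mu_control = mu_control,
         markov_matrix = markov_matrix,
         bout_duration_mean = bout_duration_mean, gap_range = gap_range,
         transition_window = transition_window, seed = seed),
    class = "generator_config")
}

#' Draw a state sequence from a first-order Markov chain
#'
#' @param markov_matrix row-stochastic transition matrix with state names as
#'   dimnames.
#' @param n sequence length.
#' @param seed integer seed.
#' @return character vector of states.
#' @export
markov_sequence <- function(markov_matrix, n, seed = 1) {
  states <- rownames(markov_matrix)
  stopifnot(!is.null(states), n >= 1)
  withr::with_seed(seed, {
    out <- character(n)
    out[1] <- sample(states, 1)
    for (i in seq_len(n - 1)) {
      out[i + 1] <- sample(states, 1, prob = markov_matrix[out[i], ])
    }
    out
  })
}

#' Generate a Markov-chain ethogram
#'
#' Produces time-ordered, non-overlapping scored behavior bouts separated by
#' unscored gaps of at least `gap_range[1]` seconds, with the bout label
#' sequence drawn from `markov_matrix`. Gaps guarantee that the 2-s transition
#' epoch preceding each onset lies in unscored time.
#'
#' @param cfg a [generator_config()].
#' @return a tibble with columns `behavior`, `start_s`, `end_s`.
#' @export
generate_ethogram <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  with_stream_seed(cfg$seed, "ethogram", {
    states <- cfg$behaviors
    t <- runif(1, cfg$gap_range[1], cfg$gap_range[2])
    rows <- list()
    cur <- sample(states, 1)
    repeat {
      dur <- max(2, rexp(1, 1 / cfg$bout_duration_mean))
      if (t + dur > cfg$session_length) break
      rows[[length(rows) + 1]] <- tibble(behavior = cur, start_s = t,
                                         end_s = t + dur)
      t <- t + dur + runif(1, cfg$gap_range[1], cfg$gap_range[2])
      cur <- sample(states, 1, prob = cfg$markov_matrix[cur, ])
    }
    if (length(rows) == 0) {
      abort("session too short to place any behavior episode")
    }
    bind_rows(rows)
  })
}

# Constructor for the package's LFP container: a tibble (time_s, value) with
# the sampling rate carried as an attribute.
#' Build an LFP tibble
#'
#' @param values sampled signal.
#' @param rate sampling rate, samples/s.
#' @return tibble with columns `time_s`, `value` and attribute `lfp_rate`.
#' @export
lfp_signal <- function(values, rate) {
  out <- tibble(time_s = (seq_along(values) - 1) / rate, value = values)
  attr(out, "lfp_rate") <- rate
  class(out) <- c("lfp_tbl", class(out))
  out
}

#' Sampling rate of an LFP tibble
#' @param lfp an object returned by [lfp_signal()] or [read_lfp()].
#' @return samples/s.
#' @export
lfp_sampling_rate <- function(lfp) {
  r <- attr(lfp, "lfp_rate")
  if (is.null(r)) abort("LFP object carries no sampling rate")
  r
}

#' Generate a synthetic LFP with injected oscillation bursts
#'
#' Background is 1/f-shaped noise rescaled so its 15-30 Hz band-passed
#' component has unit standard deviation. Each burst is a Hann-windowed
#' cosine at `burst_freq` whose envelope peak equals `burst_snr` times the
#' background band standard deviation; burst phase is 0 degrees (cosine peak)
#' at the burst center. The configured burst duration is the full width at
#' half maximum (FWHM) of the envelope, so the Hann support spans twice the
#' duration; the ground-truth episode interval is the FWHM region
#' (center +/- duration/2), which is also what an amplitude-threshold
#' detector reports for such a burst. Overlapping requested bursts are merged
#' and reported merged in the ground truth.
#'
#' @param cfg a [generator_config()].
#' @return a list with `lfp` (an [lfp_signal()] tibble) and `episodes`, a
#'   tibble of ground-truth bursts (`start_s`, `end_s`, `center_s`,
#'   `freq_hz`, `amplitude`).
#' @export
generate_lfp <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  fs <- cfg$lfp_rate
  n <- round(cfg$session_length * fs)
  with_stream_seed(cfg$seed, "lfp", {
    # 1/f background: shape white noise in the frequency domain.
    white <- rnorm(n)
    fr <- fft(white)
    freqs <- seq(0, fs - fs / n, length.out = n)
    freqs <- pmin(freqs, fs - freqs)        # two-sided frequency axis
    amp <- 1 / sqrt(pmax(freqs, 1))         # power ~ 1/f above 1 Hz
    amp[1] <- 0
    bg <- Re(fft(fr * amp, inverse = TRUE) / n)
    bp <- bandpass_filter(bg, fs, c(15, 30))
    bg <- bg / sd(bp)                       # unit s.d. in the beta band

    n_bursts <- round(cfg$burst_rate / 60 * cfg$session_length)
    x <- bg
    episodes <- tibble(start_s = numeric(0), end_s = numeric(0),
                       center_s = numeric(0), freq_hz = numeric(0),
                       amplitude = numeric(0))
    if (n_bursts > 0) {
      durs <- cfg$burst_duration_mean * runif(n_bursts, 0.9, 1.1)
      sup <- 2 * durs                       # Hann support = 2 x FWHM
      ctrs <- runif(n_bursts, max(sup), cfg$session_length - max(sup))
      o <- order(ctrs)
      ctrs <- ctrs[o]; durs <- durs[o]; sup <- sup[o]
      starts <- ctrs - durs / 2             # ground-truth (FWHM) interval
      ends <- ctrs + durs / 2
      for (k in seq_len(n_bursts)) {
        i0 <- max(1, floor((ctrs[k] - sup[k] / 2) * fs) + 1)
        i1 <- min(n, ceiling((ctrs[k] + sup[k] / 2) * fs))
        tt <- (seq(i0, i1) - 1) / fs
        env <- cos(pi * (tt - ctrs[k]) / sup[k])^2   # Hann, peak at center
        x[i0:i1] <- x[i0:i1] +
          cfg$burst_snr * env * cos(2 * pi * cfg$burst_freq * (tt - ctrs[k]))
      }
      # merge overlapping requested bursts in the ground truth
      merged <- list(c(starts[1], ends[1]))
      for (k in seq_len(n_bursts)[-1]) {
        last <- merged[[length(merged)]]
        if (starts[k] <= last[2]) {
          merged[[length(merged)]] <- c(last[1], max(last[2], ends[k]))
        } else {
          merged[[length(merged) + 1]] <- c(starts[k], ends[k])
        }
      }
      ms <- vapply(merged, `[`, numeric(1), 1)
      me <- vapply(merged, `[`, numeric(1), 2)
      episodes <- tibble(start_s = ms, end_s = me, center_s = (ms + me) / 2,
                         freq_hz = cfg$burst_freq, amplitude = cfg$burst_snr)
    }
    components <- tibble(center_s = if (n_bursts > 0) ctrs else numeric(0),
                         support_s = if (n_bursts > 0) sup else numeric(0),
                         freq_hz = cfg$burst_freq,
                         amplitude = cfg$burst_snr)
    list(lfp = lfp_signal(x, fs), episodes = episodes,
         components = components)
  })
}

# Rate-gain lookup intervals: the scored bouts (rate gain applies only
# while the behavior is expressed; pre-onset windows stay at base rate).
gain_intervals <- function(eth) {
  eth <- arrange(eth, .data$start_s)
  tibble(start_s = eth$start_s, end_s = eth$end_s, behavior = eth$behavior)
}

# Per-time rate gain for one cell (vector of times -> multiplier).
eval_gain <- function(times, gains_row, intervals) {
  g <- rep(1, length(times))
  if (nrow(intervals) == 0) return(g)
  idx <- findInterval(times, intervals$start_s)
  hit <- idx >= 1 & idx <= nrow(intervals)
  hit[hit] <- times[hit] < intervals$end_s[idx[hit]]
  g[hit] <- gains_row[intervals$behavior[idx[hit]]]
  g
}

# TRUE for times inside any (start, end) interval pair.
in_intervals <- function(times, starts, ends) {
  if (length(starts) == 0) return(rep(FALSE, length(times)))
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  idx <- findInterval(times, starts)
  hit <- idx >= 1
  hit[hit] <- times[hit] < ends[idx[hit]]
  hit
}

#' Generate phase-coupled, behavior-modulated spike trains
#'
#' Each cell is an inhomogeneous Poisson process with rate
#' `base_rate * behavior_gain(behavior at t)`. Inside ground-truth
#' oscillation episodes, spikes are additionally von Mises phase-coupled
#' (concentration `kappa`): during the 2-s pre-onset transition window of a
#' behavior, cells activated by that upcoming behavior (gain > 1) lock to
#' `mu_transition`, while all other cells - and all cells outside transition
#' windows - lock to `mu_control`. The transition state is thus carried
#' purely by a selective phase shift, not by a firing-rate change, so
#' phase shuffling destroys it. The candidate rate inside episodes is
#' tilted by exp(kappa)/I0(kappa) so thinning leaves the mean rate
#' unchanged. Outside episodes no phase is defined and no coupling is
#' applied.
#'
#' @param cfg a [generator_config()].
#' @param ethogram tibble from [generate_ethogram()].
#' @param episodes ground-truth burst table from [generate_lfp()]
#'   (merged episode intervals).
#' @param components un-merged burst component table from [generate_lfp()];
#'   used to evaluate the exact injected-carrier phase (overlapping bursts
#'   interfere, so the phase inside a merged episode is the argument of the
#'   summed analytic carriers, not a single burst's phase). When `NULL`,
#'   each episode is treated as a single component.
#' @return tibble with columns `unit_id` (integer) and `time_s`, sorted and
#'   strictly increasing within each unit.
#' @export
generate_spikes <- function(cfg, ethogram, episodes, components = NULL) {
  stopifnot(inherits(cfg, "generator_config"))
  assert_ethogram(ethogram)
  ivals <- gain_intervals(ethogram)
  eth_o <- arrange(ethogram, .data$start_s)
  trans <- tibble(start_s = pmax(eth_o$start_s - cfg$transition_window, 0),
                  end_s = eth_o$start_s, upcoming = eth_o$behavior)
  ep_dur <- episodes$end_s - episodes$start_s
  t_ep <- sum(ep_dur)
  cum_ep <- cumsum(c(0, ep_dur))
  if (is.null(components)) {
    components <- tibble(center_s = episodes$center_s,
                         support_s = 2 * ep_dur,
                         freq_hz = episodes$freq_hz,
                         amplitude = episodes$amplitude)
  }
  # exact injected-carrier phase on the LFP grid: the argument of the sum
  # of the analytic burst carriers (handles interference of merged bursts)
  fs <- cfg$lfp_rate
  n_grid <- round(cfg$session_length * fs)
  zre <- numeric(n_grid); zim <- numeric(n_grid)
  for (k in seq_len(nrow(components))) {
    ctr <- components$center_s[k]; sup <- components$support_s[k]
    i0 <- max(1, floor((ctr - sup / 2) * fs) + 1)
    i1 <- min(n_grid, ceiling((ctr + sup / 2) * fs))
    if (i1 < i0) next
    tt <- (seq(i0, i1) - 1) / fs
    env <- components$amplitude[k] * cos(pi * (tt - ctr) / sup)^2
    arg <- 2 * pi * components$freq_hz[k] * (tt - ctr)
    zre[i0:i1] <- zre[i0:i1] + env * cos(arg)
    zim[i0:i1] <- zim[i0:i1] + env * sin(arg)
  }
  grid_phase <- atan2(zim, zre) * 180 / pi
  out <- vector("list", cfg$n_cells)
  for (i in seq_len(cfg$n_cells)) {
    out[[i]] <- with_stream_seed(cfg$seed, paste0("spikes", i), {
      gains_row <- cfg$behavior_gain[i, ]
      gmax <- max(1, gains_row)
      k <- cfg$kappa[i]
      tilt <- if (k > 0) exp(k) / besselI(k, 0) else 1

      # stream 1: whole session at the gain ceiling, thin by gain, drop
      # in-episode candidates (handled by stream 2)
      n1 <- rpois(1, cfg$base_rate * gmax * cfg$session_length)
      t1 <- runif(n1, 0, cfg$session_length)
      keep1 <- runif(n1) < eval_gain(t1, gains_row, ivals) / gmax
      t1 <- t1[keep1]
      t1 <- t1[!in_intervals(t1, episodes$start_s, episodes$end_s)]

      # stream 2: inside episodes at the tilted rate, thin by gain and by
      # the von Mises density around the window-dependent preferred phase
      t2 <- numeric(0)
      if (t_ep > 0) {
        n2 <- rpois(1, cfg$base_rate * gmax * tilt * t_ep)
        u <- runif(n2, 0, t_ep)
        ep_idx <- findInterval(u, cum_ep, rightmost.closed = TRUE)
        ep_idx <- pmin(ep_idx, nrow(episodes))
        t2 <- episodes$start_s[ep_idx] + (u - cum_ep[ep_idx])
        phase <- grid_phase[pmin(pmax(round(t2 * fs) + 1, 1), n_grid)]
        # selective recruitment: shift to mu_transition only when the cell
        # is activated (gain > 1) by the behavior this window precedes
        w_idx <- findInterval(t2, trans$start_s)
        in_win <- w_idx >= 1
        in_win[in_win] <- t2[in_win] < trans$end_s[w_idx[in_win]]
        recruited <- in_win
        recruited[in_win] <-
          gains_row[trans$upcoming[w_idx[in_win]]] > 1
        mu <- ifelse(recruited, cfg$mu_transition[i], cfg$mu_control[i])
        p_acc <- eval_gain(t2, gains_row, ivals) / gmax
        if (k > 0) {
          p_acc <- p_acc * exp(k * (cos((phase - mu) * pi / 180) - 1))
        }
        t2 <- t2[runif(n2) < p_acc]
      }
      tt <- sort(unique(c(t1, t2)))
      tibble(unit_id = i, time_s = tt)
    })
  }
  bind_rows(out)
}

#' Simulate a complete synthetic session
#'
#' Chains [generate_ethogram()], [generate_lfp()] and [generate_spikes()] and
#' packages the result with its ground truth.
#'
#' @param cfg a [generator_config()].
#' @return a list of class `phasesig_session` with elements `lfp`, `spikes`,
#'   `ethogram`, `ground_truth` (episodes, per-cell preferred phases and
#'   kappa, behavior gains, bout label sequence) and `config`.
#' @export
simulate_session <- function(cfg = generator_config()) {
  eth <- generate_ethogram(cfg)
  l <- generate_lfp(cfg)
  spikes <- generate_spikes(cfg, eth, l$episodes, l$components)
  gt <- list(
    episodes = l$episodes,
    pref_phase = tibble(unit_id = seq_len(cfg$n_cells),
                        mu_transition = cfg$mu_transition,
                        mu_control = cfg$mu_control, kappa = cfg$kappa),
    gains = as_tibble(cfg$behavior_gain) |>
      mutate(unit_id = dplyr::row_number()) |>
      tidyr::pivot_longer(-"unit_id", names_to = "behavior",
                          values_to = "gain"),
    behavior_sequence = eth$behavior
  )
  structure(list(lfp = l$lfp, spikes = spikes, ethogram = eth,
                 ground_truth = gt, config = cfg),
            class = "phasesig_session")
}

#' @export
print.phasesig_session <- function(x, ...) {
  cat("<phasesig_session>\n")
  cat("  duration:", x$config$session_length, "s at",
      x$config$lfp_rate, "Hz\n")
  cat("  units:", x$config$n_cells, " spikes:", nrow(x$spikes), "\n")
  cat("  behavior bouts:", nrow(x$ethogram),
      " ground-truth bursts:", nrow(x$ground_truth$episodes), "\n")
  invisible(x)
}
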