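#' Match-score configuration
#'
#' @param n_surrogates number of time-shift surrogates (default 1000).
#' @param offset_range range of the circular surrogate shift, seconds
#'   (default 120-240 s, applied with random sign).
#' @param min_spikes minimum session spike count for a unit to be scored
#'   (default 20; 10 is used for putative dopamine cells).
#' @param seed integer seed.
#' @return object of class `match_score_config`.
#' @export
match_score_config <- function(n_surrogates = 1000,
                               offset_range = c(120, 240),
                               min_spikes = 20, seed = 1) {
  stopifnot(n_surrogates >= 100, offset_range[1] > 0,
            offset_range[2] > offset_range[1], min_spikes >= 1)
  structure(list(n_surrogates = n_surrogates, offset_range = offset_range,
                 min_spikes = min_spikes, seed = seed),
            class = "match_score_config")
}

# Spike count of one unit inside a set of intervals.
count_in_intervals <- function(times, starts, ends) {
  if (length(starts) == 0) return(0L)
  o <- order(starts)
  sum(findInterval(times, starts[o]) - findInterval(times, ends[o]))
}

#' Firing rate of one unit during one behavior
#'
#' Spike count inside the behavior's intervals divided by the total behavior
#' duration.
#'
#' @param times spike times of one unit, seconds.
#' @param eth ethogram tibble.
#' @param behavior behavior label.
#' @return rate in spikes/s.
#' @export
behavior_rate <- function(times, eth, behavior) {
  iv <- eth[eth$behavior == behavior, , drop = FALSE]
  tot <- sum(iv$end_s - iv$start_s)
  if (tot <= 0) abort(sprintf("behavior '%s' has zero scored time", behavior))
  count_in_intervals(times, iv$start_s, iv$end_s) / tot
}

#' Match score of one unit for one behavior
#'
#' The match score is the percentile of the unit's within-behavior firing
#' rate in a surrogate distribution of rates obtained by circularly shifting
#' the behavior time stamps by `n_surrogates` uniform draws from
#' `offset_range` seconds (random sign, wrap-around at the session edge).
#' Ties with surrogate rates count one half (mid-rank percentile). Scores
#' near 1 mark behavior-activated units, near 0 behavior-suppressed ones.
#'
#' @param times spike times of one unit.
#' @param eth ethogram tibble.
#' @param behavior behavior label.
#' @param session_span session length, seconds.
#' @param cfg a [match_score_config()].
#' @param stream suffix for the seed substream (so different units use
#'   independent surrogate offsets).
#' @return score in \[0, 1\], or `NA` if the behavior is absent from the
#'   ethogram.
#' @export
match_score <- function(times, eth, behavior, session_span,
                        cfg = match_score_config(), stream = "") {
  iv <- eth[eth$behavior == behavior, , drop = FALSE]
  if (nrow(iv) == 0) return(NA_real_)
  tot <- sum(iv$end_s - iv$start_s)
  observed <- count_in_intervals(times, iv$start_s, iv$end_s) / tot
  offs <- with_stream_seed(cfg$seed, paste0("match-", behavior, "-", stream), {
    runif(cfg$n_surrogates, cfg$offset_range[1], cfg$offset_range[2]) *
      sample(c(-1, 1), cfg$n_surrogates, replace = TRUE)
  })
  # shifting the behavior stamps by +off equals shifting spikes by -off;
  # wrap spike times circularly over the session
  sur <- vapply(offs, function(off) {
    ts <- (times - off) %% session_span
    count_in_intervals(ts, iv$start_s, iv$end_s) / tot
  }, numeric(1))
  (sum(sur < observed) + 0.5 * sum(sur == observed)) / length(sur)
}

#' Match scores for all units and behaviors
#'
#' Applies [match_score()] to every unit with at least `min_spikes` spikes in
#' the session, for every listed behavior.
#'
#' @param spikes tibble `unit_id`, `time_s`.
#' @param eth ethogram tibble.
#' @param behaviors behavior labels to score (default all in the ethogram).
#' @param session_span session length, seconds (default: last spike or
#'   ethogram end).
#' @param cfg a [match_score_config()].
#' @return tibble `unit_id`, `behavior`, `score`, `n_spikes`.
#' @export
match_score_table <- function(spikes, eth, behaviors = NULL,
                              session_span = NULL,
                              cfg = match_score_config()) {
  assert_ethogram(eth)
  if (is.null(behaviors)) behaviors <- sort(unique(eth$behavior))
  if (is.null(session_span)) {
    session_span <- max(max(spikes$time_s), max(eth$end_s))
  }
  by_unit <- split(spikes$time_s, spikes$unit_id)
  rows <- purrr::imap(by_unit, function(ts, uid) {
    if (length(ts) < cfg$min_spikes) return(NULL)
    tibble(unit_id = as.integer(uid), behavior = behaviors,
           score = vapply(behaviors, function(b) {
             match_score(ts, eth, b, session_span, cfg, stream = uid)
           }, numeric(1)),
           n_spikes = length(ts))
  })
  bind_rows(rows)
}

#' Classify multimodal units from a match-score table
#'
#' A unit is multimodal when its match score for every listed behavior lies
#' in that behavior's upper population quartile (scores compared across all
#' scored units).
#'
#' @param table tibble from [match_score_table()].
#' @param behaviors the behaviors that must all be preferred (default all in
#'   the table).
#' @param quartile population quantile defining "upper quartile"
#'   (default 0.75).
#' @return tibble `unit_id`, `multimodal` (logical).
#' @export
classify_multimodal <- function(table, behaviors = NULL, quartile = 0.75) {
  if (is.null(behaviors)) behaviors <- sort(unique(table$behavior))
  tab <- table[table$behavior %in% behaviors, , drop = FALSE]
  if (length(unique(tab$unit_id)) < 4) {
    abort("need at least 4 units to define population quartiles")
  }
  tab |>
    group_by(.data$behavior) |>
    mutate(top = .data$score > quantile(.data$score, quartile)) |>
    group_by(.data$unit_id) |>
    summarise(multimodal = all(.data$top) & n() == length(behaviors),
              .groups = "drop")
}

#' Burst/tonic interspike-interval configuration
#'
#' @param burst_max_isi ISI below which a spike belongs to a burst, seconds
#'   (default 0.080).
#' @param tonic_min_isi ISI above which firing is tonic, seconds
#'   (default 0.170).
#' @param dopamine_max_rate session firing-rate ceiling for putative dopamine
#'   cells, Hz (default 10, strict).
#' @return object of class `burst_config`.
#' @export
burst_config <- function(burst_max_isi = 0.080, tonic_min_isi = 0.170,
                         dopamine_max_rate = 10) {
  stopifnot(burst_max_isi < tonic_min_isi)
  structure(list(burst_max_isi = burst_max_isi, tonic_min_isi = tonic_min_isi,
                 dopamine_max_rate = dopamine_max_rate),
            class = "burst_config")
}

#' Label spikes as burst, tonic or neither by adjacent interspike intervals
#'
#' A spike is `burst` if its interval to either neighbor is shorter than
#' `burst_max_isi`, `tonic` if every adjacent interval exceeds
#' `tonic_min_isi`, otherwise `neither`. Terminal spikes are judged on their
#' single adjacent interval.
#'
#' @param times sorted spike times of one unit (>= 2 spikes).
#' @param cfg a [burst_config()].
#' @return character vector, one label per spike.
#' @export
classify_isi <- function(times, cfg = burst_config()) {
  n <- length(times)
  if (n < 2) abort("classify_isi() needs at least 2 spikes")
  isi <- diff(times)
  prev <- c(Inf, isi)
  nxt <- c(isi, Inf)
  ifelse(pmin(prev, nxt) < cfg$burst_max_isi, "burst",
         ifelse(pmin(prev, nxt) > cfg$tonic_min_isi, "tonic", "neither"))
}

#' Putative dopamine cell mask by firing rate
#'
#' Keeps units with a whole-session firing rate strictly below
#' `dopamine_max_rate`. (The spike-width criterion needs waveforms and is out
#' of scope here.)
#'
#' @param rates named numeric vector or tibble (`unit_id`, `rate`) of
#'   session firing rates, Hz.
#' @param cfg a [burst_config()].
#' @return logical mask (same order as input).
#' @export
select_putative_dopamine <- function(rates, cfg = burst_config()) {
  r <- if (is.data.frame(rates)) rates$rate else rates
  r < cfg$dopamine_max_rate
}
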