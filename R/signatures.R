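#' Phase-signature configuration
#'
#' @param n_bins number of phase bins per oscillation cycle (default 20).
#' @param peak_halfwidth_bins half-width of the peak neighborhood in bins
#'   (default 4; with 20 bins that is +/-72 degrees around the peak).
#' @param active_quartile population quantile defining "highly active" cells
#'   per bin (default 0.75 -> upper quartile).
#' @param n_bootstrap bootstrap replicates per bin (default 1000).
#' @param min_spikes minimum in-epoch spike count per unit (default 20; 10
#'   for putative dopamine cells).
#' @param kernel_sd_bins Gaussian smoothing of the per-unit phase histograms,
#'   in bins (default 0.65).
#' @param high_specificity when TRUE, only match scores above 0.9 or below
#'   0.1 enter the signature (robustness variant).
#' @param seed integer seed for the bootstrap.
#' @return object of class `signature_config`.
#' @export
signature_config <- function(n_bins = 20, peak_halfwidth_bins = 4,
                             active_quartile = 0.75, n_bootstrap = 1000,
                             min_spikes = 20, kernel_sd_bins = 0.65,
                             high_specificity = FALSE, seed = 1) {
  stopifnot(n_bins >= 4, peak_halfwidth_bins >= 1,
            peak_halfwidth_bins * 2 < n_bins, n_bootstrap >= 1,
            min_spikes >= 1)
  structure(list(n_bins = n_bins, peak_halfwidth_bins = peak_halfwidth_bins,
                 active_quartile = active_quartile, n_bootstrap = n_bootstrap,
                 min_spikes = min_spikes, kernel_sd_bins = kernel_sd_bins,
                 high_specificity = high_specificity, seed = seed),
            class = "signature_config")
}

# Peak-neighborhood bin indices: bins whose centers lie within
# peak_halfwidth_bins * bin_width of phase 0 (the oscillation peak).
peak_bins <- function(cfg) {
  ctr <- phase_bin_centers(cfg$n_bins)
  which(abs(ctr) <= cfg$peak_halfwidth_bins * 360 / cfg$n_bins)
}

# Antipodal trough bins (centers within the same width of +/-180).
trough_bins <- function(cfg) {
  ctr <- phase_bin_centers(cfg$n_bins)
  which(circ_diff_deg(ctr, 180) <= cfg$peak_halfwidth_bins * 360 / cfg$n_bins)
}

#' Smoothed phase histograms for every unit
#'
#' @param spike_phases tibble `unit_id`, `phase_deg` (e.g. from
#'   [assign_spike_phases()], optionally pre-filtered to a set of epochs).
#' @param cfg a [signature_config()].
#' @return tibble `unit_id`, `bin`, `bin_center_deg`, `prob`, `n_spikes`;
#'   units with fewer than `min_spikes` phases are dropped.
#' @export
unit_phase_histograms <- function(spike_phases, cfg = signature_config()) {
  by_unit <- split(spike_phases$phase_deg, spike_phases$unit_id)
  rows <- purrr::imap(by_unit, function(ph, uid) {
    if (length(ph) < cfg$min_spikes) return(NULL)
    h <- phase_histogram(ph, cfg$n_bins, cfg$kernel_sd_bins)
    h$unit_id <- as.integer(uid)
    h$n_spikes <- length(ph)
    h
  })
  bind_rows(rows) |> select("unit_id", "bin", "bin_center_deg", "prob",
                            "n_spikes")
}

#' Highly active cells per phase bin
#'
#' For each phase bin, selects the units whose firing probability in that bin
#' lies in the population upper quartile: the top `ceiling(n_units / 4)`
#' units by bin probability, ties broken deterministically by unit id (a
#' warning is emitted when a bin is entirely tied).
#'
#' @param histograms tibble from [unit_phase_histograms()].
#' @param cfg a [signature_config()].
#' @return tibble `bin`, `unit_id`.
#' @export
highly_active_cells <- function(histograms, cfg = signature_config()) {
  units <- unique(histograms$unit_id)
  if (length(units) < 4) abort("need at least 4 units with enough spikes")
  n_take <- ceiling(length(units) * (1 - cfg$active_quartile))
  tied <- integer(0)
  out <- lapply(seq_len(cfg$n_bins), function(b) {
    h <- histograms[histograms$bin == b, , drop = FALSE]
    if (length(unique(h$prob)) == 1) tied <<- c(tied, b)
    o <- order(-h$prob, h$unit_id)
    tibble(bin = b, unit_id = h$unit_id[o][seq_len(min(n_take, nrow(h)))])
  })
  if (length(tied) > 0) {
    warn(sprintf(
      "all firing probabilities equal in bin(s) %s; using unit-id order",
      paste(tied, collapse = ", ")))
  }
  bind_rows(out)
}

# phi = c/(N - c) with the half-count clamp keeping degenerate bins finite.
phi_of <- function(m_values) {
  n <- length(m_values)
  c_raw <- sum(m_values > 0.5)
  c_cl <- min(max(c_raw, 0.5), n - 0.5)
  c_cl / (n - c_cl)
}

filter_specificity <- function(m, cfg) {
  if (!cfg$high_specificity) return(m)
  m[m > 0.9 | m < 0.1]
}

#' Population phase signature for one behavior
#'
#' For each phase bin, takes the match scores of the bin's highly active
#' cells, counts the behavior-activated ones (c = number with m > 0.5) and
#' forms the odds phi = c / (N - c). Degenerate bins (c = 0 or c = N) are
#' clamped by half a count so phi stays finite; bins with an empty active
#' set yield NA.
#'
#' @param active tibble from [highly_active_cells()].
#' @param match_table tibble from [match_score_table()].
#' @param behavior behavior whose match scores define the signature.
#' @param cfg a [signature_config()].
#' @return tibble of class `phase_signature`: `behavior`, `bin`,
#'   `bin_center_deg`, `n_active`, `c`, `phi`.
#' @export
phase_signature <- function(active, match_table, behavior,
                            cfg = signature_config()) {
  mt <- match_table[match_table$behavior == behavior, , drop = FALSE]
  rows <- lapply(seq_len(cfg$n_bins), function(b) {
    ids <- active$unit_id[active$bin == b]
    m <- mt$score[match(ids, mt$unit_id)]
    m <- filter_specificity(m[!is.na(m)], cfg)
    if (length(m) == 0) {
      return(tibble(behavior = behavior, bin = b,
                    bin_center_deg = phase_bin_centers(cfg$n_bins)[b],
                    n_active = 0L, c = NA_integer_, phi = NA_real_))
    }
    tibble(behavior = behavior, bin = b,
           bin_center_deg = phase_bin_centers(cfg$n_bins)[b],
           n_active = length(m), c = sum(m > 0.5), phi = phi_of(m))
  })
  structure(bind_rows(rows),
            class = c("phase_signature", "tbl_df", "tbl", "data.frame"))
}

#' Bootstrap replicates of a phase signature
#'
#' Resamples each bin's active-cell match-score multiset with replacement
#' `n_bootstrap` times and maps each resample through phi = c/(N - c).
#'
#' @inheritParams phase_signature
#' @return tibble `behavior`, `bin`, `replicate`, `phi`.
#' @export
bootstrap_signatures <- function(active, match_table, behavior,
                                 cfg = signature_config()) {
  mt <- match_table[match_table$behavior == behavior, , drop = FALSE]
  with_stream_seed(cfg$seed, paste0("bootstrap-", behavior), {
    rows <- lapply(seq_len(cfg$n_bins), function(b) {
      ids <- active$unit_id[active$bin == b]
      m <- mt$score[match(ids, mt$unit_id)]
      m <- filter_specificity(m[!is.na(m)], cfg)
      if (length(m) < 2) return(NULL)
      phis <- vapply(seq_len(cfg$n_bootstrap), function(r) {
        phi_of(sample(m, length(m), replace = TRUE))
      }, numeric(1))
      tibble(behavior = behavior, bin = b,
             replicate = seq_len(cfg$n_bootstrap), phi = phis)
    })
    bind_rows(rows)
  })
}

#' Peak-to-trough preference of a phase signature
#'
#' Ratio of the mean phi over the peak-neighborhood bins to the mean phi over
#' the antipodal trough bins; intermediate bins are excluded. Ratios above 1
#' indicate peak-concentrated behavior signaling (the transition regime),
#' below 1 trough-concentrated signaling.
#'
#' @param signature tibble from [phase_signature()] (or any tibble with
#'   `bin` and `phi`).
#' @param cfg a [signature_config()].
#' @return tibble of class `peak_trough_stat`: `ratio`, `peak_mean`,
#'   `trough_mean`, `n_peak_bins`, `n_trough_bins`.
#' @export
peak_trough_preference <- function(signature, cfg = signature_config()) {
  pk <- peak_bins(cfg); tr <- trough_bins(cfg)
  pv <- signature$phi[signature$bin %in% pk]
  tv <- signature$phi[signature$bin %in% tr]
  if (anyNA(pv) || anyNA(tv)) abort("phi undefined on peak or trough bins")
  tm <- mean(tv)
  if (tm == 0) abort("trough mean is zero; peak:trough ratio undefined")
  structure(tibble(ratio = mean(pv) / tm, peak_mean = mean(pv),
                   trough_mean = tm, n_peak_bins = length(pv),
                   n_trough_bins = length(tv)),
            class = c("peak_trough_stat", "tbl_df", "tbl", "data.frame"))
}

#' Signature replicates for a labeled set of epochs
#'
#' The workhorse connecting spikes to the decoders: restricts spike phases to
#' the given epochs, builds per-unit histograms (min-spike filtered), selects
#' highly active cells per bin, and returns bootstrap phi replicates for each
#' requested behavior's match scores, plus the point signatures.
#'
#' @param spike_phases tibble `unit_id`, `time_s`, `phase_deg` from
#'   [assign_spike_phases()].
#' @param epochs tibble with `start_s`, `end_s` defining the epoch set.
#' @param match_table tibble from [match_score_table()].
#' @param behaviors behaviors whose match scores to evaluate.
#' @param cfg a [signature_config()].
#' @param n_bootstrap overrides `cfg$n_bootstrap` when given.
#' @param active optional pre-computed active-cell table (fixes the same
#'   subset of cells across epoch sets, the robustness variant).
#' @return list with `replicates` (tibble `behavior`, `bin`, `replicate`,
#'   `phi`), `signature` (point estimates), `active`, `histograms`.
#' @export
epoch_signatures <- function(spike_phases, epochs, match_table, behaviors,
                             cfg = signature_config(), n_bootstrap = NULL,
                             active = NULL) {
  if (!is.null(n_bootstrap)) cfg$n_bootstrap <- n_bootstrap
  sp <- spike_phases[in_intervals(spike_phases$time_s, epochs$start_s,
                                  epochs$end_s), , drop = FALSE]
  hist <- unit_phase_histograms(sp, cfg)
  if (nrow(hist) == 0) abort("no unit reaches min_spikes inside these epochs")
  if (is.null(active)) active <- highly_active_cells(hist, cfg)
  sig <- bind_rows(lapply(behaviors, function(b) {
    phase_signature(active, match_table, b, cfg)
  }))
  reps <- bind_rows(lapply(behaviors, function(b) {
    bootstrap_signatures(active, match_table, b, cfg)
  }))
  list(replicates = reps, signature = sig, active = active,
       histograms = hist)
}

#' Epoch-level bootstrap of a phase signature
#'
#' Case bootstrap over epochs: each replicate resamples the epoch set with
#' replacement, recomputes every unit's (multiplicity-weighted) phase
#' histogram, reselects the highly active cells per bin, and maps the
#' resulting match-score multisets through phi. Unlike the match-score
#' bootstrap ([bootstrap_signatures()]), replicates carry the epoch-sampling
#' and cell-selection variability, which makes them structurally comparable
#' to signatures computed across independently placed control epoch sets -
#' the row construction used for the decoding datasets.
#'
#' @inheritParams epoch_signatures
#' @param n_replicates number of epoch resamples.
#' @param seed integer seed.
#' @param equalize_counts when TRUE (default), each unit's resampled spikes
#'   are subsampled to exactly `min_spikes` per replicate before the
#'   histogram is formed. Histogram sampling noise then has the same
#'   variance for every unit, so upper-quartile selection cannot favor
#'   low-count units - a bias that would otherwise couple the active-cell
#'   composition to each epoch pool's incidental rate profile.
#' @return tibble `behavior`, `bin`, `replicate`, `phi`.
#' @export
epoch_bootstrap_signatures <- function(spike_phases, epochs, match_table,
                                       behaviors, cfg = signature_config(),
                                       n_replicates = 1000, seed = 1,
                                       equalize_counts = TRUE) {
  n_ep <- nrow(epochs)
  stopifnot(n_ep >= 2)
  sp <- spike_phases
  ep_idx <- rep(NA_integer_, nrow(sp))
  for (e in seq_len(n_ep)) {
    sel <- sp$time_s >= epochs$start_s[e] & sp$time_s < epochs$end_s[e]
    ep_idx[sel & is.na(ep_idx)] <- e
  }
  keep <- !is.na(ep_idx)
  sp <- sp[keep, , drop = FALSE]
  ep_idx <- ep_idx[keep]
  units <- sort(unique(sp$unit_id))
  nb <- cfg$n_bins
  # per-epoch raw bin counts, one column per epoch: rows = unit x bin
  u_i <- match(sp$unit_id, units)
  b_i <- phase_bin_index(sp$phase_deg, nb)
  cnt <- matrix(0L, length(units) * nb, n_ep)
  idx3 <- cbind((u_i - 1) * nb + b_i, ep_idx)
  for (r in seq_len(nrow(idx3))) {
    cnt[idx3[r, 1], idx3[r, 2]] <- cnt[idx3[r, 1], idx3[r, 2]] + 1L
  }
  # circular Gaussian smoother as a matrix
  d <- seq_len(nb) - 1
  d <- pmin(d, nb - d)
  kern <- exp(-d^2 / (2 * cfg$kernel_sd_bins^2))
  kern <- kern / sum(kern)
  K <- matrix(0, nb, nb)
  for (i in seq_len(nb)) K[i, ] <- kern[((seq_len(nb) - i) %% nb) + 1]
  mt <- lapply(behaviors, function(b) {
    m <- match_table[match_table$behavior == b, , drop = FALSE]
    m$score[match(units, m$unit_id)]
  })
  names(mt) <- behaviors
  n_take <- NULL
  with_stream_seed(seed, "epoch-bootstrap", {
    rows <- lapply(seq_len(n_replicates), function(r) {
      w <- tabulate(sample.int(n_ep, n_ep, replace = TRUE), nbins = n_ep)
      v <- as.vector(cnt %*% w)
      counts <- matrix(v, nrow = nb)          # bins x units
      tot <- colSums(counts)
      ok <- tot >= cfg$min_spikes
      if (sum(ok) < 4) return(NULL)
      counts <- counts[, ok, drop = FALSE]
      if (equalize_counts) {
        for (u in seq_len(ncol(counts))) {
          if (tot[ok][u] > cfg$min_spikes) {
            picked <- sample.int(tot[ok][u], cfg$min_spikes)
            counts[, u] <- tabulate(
              findInterval(picked - 0.5, cumsum(c(0, counts[, u]))),
              nbins = nb)
          }
        }
        tot_ok <- rep(cfg$min_spikes, ncol(counts))
      } else {
        tot_ok <- tot[ok]
      }
      probs <- (K %*% counts) / rep(tot_ok, each = nb)
      uid <- units[ok]
      n_take <- ceiling(length(uid) * (1 - cfg$active_quartile))
      bind_rows(lapply(seq_len(nb), function(b) {
        o <- order(-probs[b, ], uid)[seq_len(n_take)]
        act <- uid[o]
        bind_rows(lapply(behaviors, function(bh) {
          m <- mt[[bh]][match(act, units)]
          m <- filter_specificity(m[!is.na(m)], cfg)
          if (length(m) < 2) return(NULL)
          tibble(behavior = bh, bin = b, replicate = r, phi = phi_of(m))
        }))
      }))
    })
    bind_rows(rows)
  })
}
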