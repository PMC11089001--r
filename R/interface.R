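#' Read a spike-train table
#'
#' Expects a delimited text file with columns `unit_id` and `time_s` (one
#' row per spike). Times must be numeric and non-negative; unsorted rows are
#' sorted with a warning and duplicate timestamps within a unit are collapsed
#' with a warning.
#'
#' @param path file path (tab- or comma-delimited, header required).
#' @return tibble `unit_id`, `time_s` sorted by unit then time.
#' @export
read_spikes <- function(path) {
  df <- utils::read.delim(path, sep = guess_sep(path),
                          stringsAsFactors = FALSE)
  if (!all(c("unit_id", "time_s") %in% names(df))) {
    abort("spike file must have columns unit_id and time_s")
  }
  bad <- which(!is.finite(suppressWarnings(as.numeric(df$time_s))) |
                 as.numeric(df$time_s) < 0)
  if (length(bad) > 0) {
    abort(sprintf("non-numeric or negative spike time at line %d",
                  bad[1] + 1))
  }
  df$time_s <- as.numeric(df$time_s)
  out <- as_tibble(df[c("unit_id", "time_s")])
  reordered <- out |> arrange(.data$unit_id, .data$time_s)
  if (!identical(reordered$time_s, out$time_s)) {
    warn("spike times were not sorted; sorting")
  }
  deduped <- dplyr::distinct(reordered)
  if (nrow(deduped) < nrow(reordered)) {
    warn("duplicate spike timestamps within a unit were collapsed")
  }
  deduped
}

guess_sep <- function(path) {
  first <- readLines(path, n = 1)
  if (grepl("\t", first)) "\t" else ","
}

#' Read an ethogram CSV
#'
#' @param path CSV with header `behavior,start_s,end_s`.
#' @return validated ethogram tibble (possibly empty).
#' @export
read_ethogram <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("behavior", "start_s", "end_s") %in% names(df))) {
    abort("ethogram must have columns behavior,start_s,end_s")
  }
  out <- as_tibble(df[c("behavior", "start_s", "end_s")])
  assert_ethogram(out)
  arrange(out, .data$start_s)
}

#' Read an LFP signal with its metadata sidecar
#'
#' The signal is one sample per line (no header) and `<path>.meta.json` (or
#' the file given in `meta`) must provide the sampling `rate` in samples/s.
#'
#' @param path signal file, one numeric sample per line.
#' @param meta metadata JSON path (default `<path>.meta.json`).
#' @return an [lfp_signal()] tibble.
#' @export
read_lfp <- function(path, meta = NULL) {
  meta <- meta %||% paste0(path, ".meta.json")
  if (!file.exists(meta)) abort("LFP metadata sidecar with sampling rate missing")
  md <- jsonlite::read_json(meta)
  if (is.null(md$rate)) abort("LFP metadata lacks field 'rate'")
  vals <- scan(path, what = numeric(), quiet = TRUE)
  lfp_signal(vals, as.numeric(md$rate))
}

#' Write a synthetic session to plain-text files
#'
#' Writes `spikes.tsv`, `lfp.csv` (+ `lfp.csv.meta.json`), `ethogram.csv`
#' and `ground_truth.json` under `dir`.
#'
#' @param session a [simulate_session()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(session$spikes, file.path(dir, "spikes.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  writeLines(format(session$lfp$value, trim = TRUE, digits = 10),
             file.path(dir, "lfp.csv"))
  jsonlite::write_json(list(rate = lfp_sampling_rate(session$lfp),
                            units = "a.u."),
                       file.path(dir, "lfp.csv.meta.json"),
                       auto_unbox = TRUE)
  utils::write.table(session$ethogram, file.path(dir, "ethogram.csv"),
                     sep = ",", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(session$ground_truth,
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}

label_epoch_class <- function(times, transitions) {
  ifelse(in_intervals(times, transitions$start_s, transitions$end_s),
         "transition", "control")
}

# Point signatures (phi per behavior x bin) for one epoch set; NULL when the
# set has too few well-sampled units.
set_point_signature <- function(spike_phases, epochs, match_table, behaviors,
                                cfg) {
  sp <- spike_phases[in_intervals(spike_phases$time_s, epochs$start_s,
                                  epochs$end_s), , drop = FALSE]
  hist <- tryCatch(unit_phase_histograms(sp, cfg), error = function(e) NULL)
  if (is.null(hist) || length(unique(hist$unit_id)) < 4) return(NULL)
  active <- highly_active_cells(hist, cfg)
  bind_rows(lapply(behaviors, function(b) {
    phase_signature(active, match_table, b, cfg)
  }))
}

#' Run the full analysis pipeline on a session
#'
#' Chains the stages in their canonical order: episode detection, Hilbert
#' phase assignment, match scores, transition/control epoch extraction,
#' phase signatures (bootstrap replicates for the transition class, one
#' point signature per randomly offset control set for the control class),
#' and transition-vs-control decoding with a label-permutation test, on the
#' original and on phase-shuffled spike phases. All stage outputs are
#' written to `out_dir` as plain text together with a provenance manifest;
#' results are deterministic given `seed`.
#'
#' @param session a [simulate_session()] result or a [generator_config()]
#'   (which is simulated first).
#' @param out_dir output directory.
#' @param seed integer seed driving every stage substream.
#' @param det_cfg,ms_cfg,sig_cfg,dec_cfg stage configurations; desk-scale
#'   defaults (200 surrogates / control sets / bootstrap replicates / 20
#'   repeats / 100 permutations) keep a 10-minute session tractable.
#' @param n_control_sets control epoch sets (= control-class replicate
#'   count).
#' @return a list of class `phasesig_run` with the stage results (episodes,
#'   spike_phases, match_scores, epochs, signatures, replicates, decoding)
#'   and the manifest.
#' @export
run_pipeline <- function(session, out_dir, seed = 1,
                         det_cfg = detection_config(),
                         ms_cfg = match_score_config(n_surrogates = 200,
                                                     seed = seed),
                         sig_cfg = signature_config(n_bootstrap = 200,
                                                    seed = seed),
                         dec_cfg = decoding_config(n_repeats = 20,
                                                   n_permutations = 100,
                                                   seed = seed),
                         n_control_sets = 200) {
  if (inherits(session, "generator_config")) {
    session <- simulate_session(session)
  }
  stopifnot(inherits(session, "phasesig_session"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  behaviors <- session$config$behaviors
  span <- session$config$session_length
  stage <- function(name, code) {
    t0 <- Sys.time()
    res <- tryCatch(code, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
    message(sprintf("[%s] done in %.1fs", name,
                    as.numeric(Sys.time() - t0, units = "secs")))
    res
  }

  write_session(session, out_dir)
  episodes <- stage("detect", detect_episodes(session$lfp, det_cfg))
  phase <- stage("phase", lfp_phase(session$lfp, det_cfg$band,
                                    det_cfg$filter_order))
  spike_phases <- stage("spike-phases",
                        assign_spike_phases(session$spikes, phase, episodes))
  match_scores <- stage("match-scores",
                        match_score_table(session$spikes, session$ethogram,
                                          behaviors, span, ms_cfg))
  transitions <- stage("epochs",
                       extract_transition_epochs(session$ethogram, behaviors))
  # state-matched controls: placed in unscored time only, like the
  # transition epochs they are compared against
  controls <- stage("controls",
                    generate_control_epochs(transitions, span,
                                            n = n_control_sets, seed = seed,
                                            avoid = session$ethogram))
  sig_cfg$n_bootstrap <- n_control_sets
  trans_sig <- stage("signatures-transition",
                     epoch_signatures(spike_phases, transitions, match_scores,
                                      behaviors, sig_cfg))
  # decoding rows for the transition class: epoch-level bootstrap, so both
  # classes carry epoch-sampling + cell-selection variability
  trans_reps <- stage("signatures-transition-bootstrap",
                      epoch_bootstrap_signatures(
                        spike_phases, transitions, match_scores, behaviors,
                        sig_cfg, n_replicates = n_control_sets, seed = seed))
  # control class rows: one point signature per independently placed
  # control epoch set
  ctrl_reps <- stage("signatures-control", {
    bind_rows(lapply(split(controls, controls$set_index), function(cs) {
      ps <- set_point_signature(spike_phases, cs, match_scores, behaviors,
                                sig_cfg)
      if (is.null(ps)) return(NULL)
      tibble(behavior = ps$behavior, bin = ps$bin,
             replicate = cs$set_index[1], phi = ps$phi)
    }))
  })
  if (nrow(trans_reps) == 0 || nrow(ctrl_reps) == 0) {
    abort(paste("no usable signature replicates: too few units reach",
                "min_spikes inside the epochs (consider a longer session,",
                "higher rates, or a lower min_spikes)"))
  }
  replicates <- bind_rows(
    mutate(trans_reps, label = "transition"),
    mutate(ctrl_reps, label = "control"))

  decoding <- stage("decode", {
    pk <- peak_bins(sig_cfg)
    # representative peak bin: largest transition-control phi difference
    amp <- replicates |>
      filter(.data$bin %in% pk, is.finite(.data$phi)) |>
      group_by(.data$bin, .data$label) |>
      summarise(m = mean(.data$phi), .groups = "drop") |>
      tidyr::pivot_wider(names_from = "label", values_from = "m") |>
      tidyr::drop_na()
    bin_star <- amp$bin[order(-abs(amp$transition - amp$control),
                              amp$bin)][1]
    # per-bin single-behavior and combined decoders across the peak
    # neighborhood; the single-vs-combined comparison averages over bins
    cfg_bins <- dec_cfg
    cfg_bins$n_repeats <- max(5L, dec_cfg$n_repeats %/% 2L)
    per_bin <- bind_rows(lapply(pk, function(b) {
      rows <- lapply(behaviors, function(beh) {
        ds <- build_dataset(replicates, beh, b, seed = seed)
        mutate(crossval_accuracy(ds, cfg_bins), model = "single",
               behavior = beh, bin = b)
      })
      ds_all_b <- build_dataset(replicates, behaviors, b, seed = seed)
      rows[[length(rows) + 1]] <- mutate(crossval_accuracy(ds_all_b,
                                                           cfg_bins),
                                         model = "combined",
                                         behavior = "all", bin = b)
      bind_rows(rows)
    }))
    single <- per_bin |>
      filter(.data$model == "single") |>
      group_by(.data$behavior) |>
      summarise(accuracy = mean(.data$accuracy), .groups = "drop") |>
      mutate(model = "single")
    combined <- per_bin |>
      filter(.data$model == "combined") |>
      summarise(accuracy = mean(.data$accuracy)) |>
      mutate(model = "combined", behavior = "all")
    ds_all <- build_dataset(replicates, behaviors, bin_star, seed = seed)
    perm <- permutation_test(ds_all, dec_cfg)

    # cross-bin (train best bin, test others) on the original phases
    bestbin <- train_best_bin_test_others(replicates, behaviors, dec_cfg,
                                          sig_cfg, permute = TRUE)

    # phase-shuffled control: scramble phases, rebuild both classes, redecode
    # with the same cross-bin protocol
    sp_sh <- spike_phases
    sp_sh$epoch_class <- label_epoch_class(sp_sh$time_s, transitions)
    sp_sh <- phase_shuffle(sp_sh, dec_cfg, seed = seed)
    tr_sh <- epoch_bootstrap_signatures(sp_sh, transitions, match_scores,
                                        behaviors, sig_cfg,
                                        n_replicates = n_control_sets,
                                        seed = seed)
    ct_sh <- bind_rows(lapply(split(controls, controls$set_index),
                              function(cs) {
      ps <- set_point_signature(sp_sh, cs, match_scores, behaviors, sig_cfg)
      if (is.null(ps)) return(NULL)
      tibble(behavior = ps$behavior, bin = ps$bin,
             replicate = cs$set_index[1], phi = ps$phi)
    }))
    reps_sh <- bind_rows(mutate(tr_sh, label = "transition"),
                         mutate(ct_sh, label = "control"))
    bestbin_sh <- train_best_bin_test_others(reps_sh, behaviors, dec_cfg,
                                             sig_cfg, permute = TRUE)

    list(bin = bin_star, single = single, combined = combined,
         per_bin_models = per_bin,
         permutation = perm, bestbin = bestbin,
         bestbin_shuffled = bestbin_sh)
  })

  ratio_trans <- peak_trough_preference(
    filter(trans_sig$signature, .data$behavior == behaviors[1]), sig_cfg)
  ctrl_mean_sig <- ctrl_reps |>
    filter(.data$behavior == behaviors[1]) |>
    group_by(.data$bin) |>
    summarise(phi = mean(.data$phi), .groups = "drop")
  ratio_ctrl <- peak_trough_preference(ctrl_mean_sig, sig_cfg)

  # stage outputs
  utils::write.table(episodes, file.path(out_dir, "episodes.csv"),
                     sep = ",", row.names = FALSE, quote = FALSE)
  utils::write.table(spike_phases, file.path(out_dir, "spike_phases.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(match_scores, file.path(out_dir, "match_scores.csv"),
                     sep = ",", row.names = FALSE, quote = FALSE)
  utils::write.table(bind_rows(mutate(transitions, set_index = 0L), controls),
                     file.path(out_dir, "epochs.csv"),
                     sep = ",", row.names = FALSE, quote = FALSE)
  utils::write.table(trans_sig$signature,
                     file.path(out_dir, "signatures.csv"),
                     sep = ",", row.names = FALSE, quote = FALSE)
  utils::write.table(replicates, file.path(out_dir, "replicates.csv"),
                     sep = ",", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(bin = decoding$bin,
         single = decoding$single[c("behavior", "accuracy")],
         combined = decoding$combined[c("behavior", "accuracy")],
         permutation = decoding$permutation[
           c("accuracy", "null_mean", "p_value")],
         bestbin = list(accuracy = decoding$bestbin$accuracy,
                        null_mean = decoding$bestbin$null_mean,
                        p_value = decoding$bestbin$p_value),
         bestbin_shuffled = list(
           accuracy = decoding$bestbin_shuffled$accuracy,
           null_mean = decoding$bestbin_shuffled$null_mean,
           p_value = decoding$bestbin_shuffled$p_value),
         peak_trough_transition = ratio_trans$ratio,
         peak_trough_control = ratio_ctrl$ratio),
    file.path(out_dir, "decoding.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "columns")

  manifest <- list(
    seed = seed,
    config_hash = derive_seed(0, paste(utils::capture.output(
      utils::str(session$config)), collapse = "")),
    n_control_sets = n_control_sets,
    n_surrogates = ms_cfg$n_surrogates,
    n_bootstrap = sig_cfg$n_bootstrap,
    n_repeats = dec_cfg$n_repeats,
    n_permutations = dec_cfg$n_permutations,
    package_version = as.character(utils::packageVersion("phasesig")),
    files = c("spikes.tsv", "lfp.csv", "lfp.csv.meta.json", "ethogram.csv",
              "ground_truth.json", "episodes.csv", "spike_phases.tsv",
              "match_scores.csv", "epochs.csv", "signatures.csv",
              "replicates.csv", "decoding.json"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  structure(list(session = session, episodes = episodes,
                 spike_phases = spike_phases, match_scores = match_scores,
                 transitions = transitions, controls = controls,
                 signatures = trans_sig$signature, replicates = replicates,
                 decoding = decoding, peak_trough = ratio_trans,
                 peak_trough_control = ratio_ctrl,
                 manifest = manifest, out_dir = out_dir),
            class = "phasesig_run")
}

#' @export
print.phasesig_run <- function(x, ...) {
  cat("<phasesig_run>\n")
  cat("  episodes detected:", nrow(x$episodes), "\n")
  cat("  transition epochs:", nrow(x$transitions), "\n")
  cat("  decoding (combined, bin", x$decoding$bin, "): accuracy",
      round(x$decoding$permutation$accuracy, 3), "p",
      signif(x$decoding$permutation$p_value, 3), "\n")
  cat("  cross-bin: accuracy", round(x$decoding$bestbin$accuracy, 3),
      "p", signif(x$decoding$bestbin$p_value, 3),
      "| phase-shuffled p:",
      signif(x$decoding$bestbin_shuffled$p_value, 3), "\n")
  invisible(x)
}
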