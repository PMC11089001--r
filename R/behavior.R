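#' Extract fixed-duration transition epochs from an ethogram
#'
#' A transition epoch is the `duration_s`-long window ending exactly at the
#' onset of a scored behavior. Epochs that would start before the session
#' (onset earlier than `duration_s + offset_s`) are dropped, and by default
#' epochs overlapping a preceding scored behavior are dropped too, so the
#' window covers unscored (locomotion/posture-change) time only.
#'
#' @param eth ethogram tibble (`behavior`, `start_s`, `end_s`).
#' @param behaviors behaviors whose onsets define epochs (default all).
#' @param duration_s epoch duration, seconds (default 2).
#' @param offset_s shift of the epoch end before the onset, seconds; 0 gives
#'   transition epochs, 2 gives the pre-transition (-4 s) epochs.
#' @param drop_overlapping drop epochs overlapping a preceding scored bout.
#' @return tibble `kind`, `behavior`, `start_s`, `end_s`.
#' @export
extract_transition_epochs <- function(eth, behaviors = NULL, duration_s = 2,
                                      offset_s = 0, drop_overlapping = TRUE) {
  stopifnot(duration_s > 0, offset_s >= 0)
  assert_ethogram(eth)
  eth <- arrange(eth, .data$start_s)
  if (is.null(behaviors)) behaviors <- unique(eth$behavior)
  kind <- if (offset_s > 0) "pre_transition" else "transition"
  onsets <- eth[eth$behavior %in% behaviors, , drop = FALSE]
  if (nrow(onsets) == 0) {
    return(tibble(kind = character(0), behavior = character(0),
                  start_s = numeric(0), end_s = numeric(0)))
  }
  end_s <- onsets$start_s - offset_s
  start_s <- end_s - duration_s
  out <- tibble(kind = kind, behavior = onsets$behavior,
                start_s = start_s, end_s = end_s)
  out <- out[out$start_s >= 0, , drop = FALSE]
  if (drop_overlapping && nrow(out) > 0) {
    ov <- vapply(seq_len(nrow(out)), function(k) {
      interval_overlap(out$start_s[k], out$end_s[k],
                       eth$start_s, eth$end_s) > 1e-9
    }, logical(1))
    out <- out[!ov, , drop = FALSE]
  }
  out
}

#' Epochs at behavior onset or at random positions inside behaviors
#'
#' Behavior-onset epochs start exactly at each onset; random behavior epochs
#' are `duration_s` windows drawn uniformly inside bouts at least
#' `duration_s` long (one per bout), used to characterize ongoing/current
#' behavior.
#'
#' @param eth ethogram tibble.
#' @param behaviors behaviors to use (default all).
#' @param duration_s epoch duration, seconds.
#' @param at `"onset"` or `"random"`.
#' @param seed seed for `at = "random"`.
#' @return tibble `kind`, `behavior`, `start_s`, `end_s`.
#' @export
extract_behavior_epochs <- function(eth, behaviors = NULL, duration_s = 2,
                                    at = c("onset", "random"), seed = 1) {
  at <- match.arg(at)
  assert_ethogram(eth)
  if (is.null(behaviors)) behaviors <- unique(eth$behavior)
  b <- eth[eth$behavior %in% behaviors &
             (eth$end_s - eth$start_s) >= duration_s, , drop = FALSE]
  if (nrow(b) == 0) {
    return(tibble(kind = character(0), behavior = character(0),
                  start_s = numeric(0), end_s = numeric(0)))
  }
  start_s <- if (at == "onset") {
    b$start_s
  } else {
    withr::with_seed(seed,
      runif(nrow(b), b$start_s, b$end_s - duration_s))
  }
  tibble(kind = "behavior_onset", behavior = b$behavior,
         start_s = start_s, end_s = start_s + duration_s)
}

#' Generate randomly offset control epoch sets
#'
#' Each control set shifts every transition time stamp by an independent
#' random circular offset over the session; an epoch placement is accepted
#' only if it does not overlap any transition epoch (checked exhaustively on
#' every run) and lies inside the session. A whole set can additionally be
#' conditioned on a caller predicate (e.g. a minimum spike count); rejected
#' placements are re-rolled, capped at `max_attempts` draws per epoch.
#'
#' @param transitions transition epoch tibble from
#'   [extract_transition_epochs()].
#' @param session_span session length, seconds.
#' @param n number of accepted control sets (default 1000).
#' @param seed integer seed.
#' @param accept optional predicate taking one candidate epoch tibble and
#'   returning TRUE/FALSE (the sufficiency filter).
#' @param avoid optional tibble of additional intervals (`start_s`, `end_s`)
#'   control epochs must not overlap - e.g. the scored behavior bouts, which
#'   yields behavioral-state-matched controls drawn from unscored time only.
#' @param max_attempts rejection-sampling cap per epoch (and per set for the
#'   sufficiency predicate).
#' @return tibble `kind` ("control"), `set_index`, `behavior`, `start_s`,
#'   `end_s`.
#' @export
generate_control_epochs <- function(transitions, session_span, n = 1000,
                                    seed = 1, accept = NULL, avoid = NULL,
                                    max_attempts = 10000) {
  stopifnot(nrow(transitions) > 0, session_span > 0)
  dur <- transitions$end_s - transitions$start_s
  if (sum(dur) >= session_span - max(dur)) {
    abort("session too densely covered by transition epochs to place controls")
  }
  av_s <- c(transitions$start_s, avoid$start_s)
  av_e <- c(transitions$end_s, avoid$end_s)
  one_set <- function(idx) {
    s <- numeric(length(dur))
    for (k in seq_along(dur)) {
      placed <- FALSE
      for (a in seq_len(max_attempts)) {
        cand <- (transitions$start_s[k] + runif(1, 0, session_span)) %%
          session_span
        if (cand + dur[k] > session_span) next
        if (interval_overlap(cand, cand + dur[k], av_s, av_e) > 1e-9) next
        s[k] <- cand; placed <- TRUE; break
      }
      if (!placed) {
        abort(sprintf(
          "could not place control epoch %d in %d attempts (transition-overlap constraint)",
          k, max_attempts))
      }
    }
    tibble(kind = "control", set_index = idx,
           behavior = transitions$behavior, start_s = s, end_s = s + dur)
  }
  withr::with_seed(derive_seed(seed, "controls"), {
    sets <- vector("list", n)
    got <- 0
    for (a in seq_len(max_attempts)) {
      if (got >= n) break
      cand <- one_set(got + 1L)
      if (!is.null(accept) && !isTRUE(accept(cand))) next
      got <- got + 1
      sets[[got]] <- cand
    }
    if (got < n) {
      abort(sprintf(
        "could only build %d of %d control sets in %d attempts (sufficiency constraint)",
        got, n, max_attempts))
    }
    bind_rows(sets)
  })
}

fit_markov <- function(train, states, order) {
  k <- length(states)
  if (order == 0) {
    cnt <- table(factor(train, levels = states))
    p <- (cnt + 1 / k) / (length(train) + 1)
    list(order = 0, p = as.numeric(p) / sum(p), states = states)
  } else {
    cnt <- matrix(0, k, k, dimnames = list(states, states))
    for (i in seq_len(length(train) - 1)) {
      cnt[train[i], train[i + 1]] <- cnt[train[i], train[i + 1]] + 1
    }
    p <- sweep(cnt + 1 / k, 1, rowSums(cnt) + 1, "/")
    list(order = 1, p = p, states = states)
  }
}

loglik_markov <- function(fit, test) {
  if (fit$order == 0) {
    sum(log(fit$p[match(test, fit$states)]))
  } else {
    if (length(test) < 2) return(0)
    pr <- fit$p[cbind(match(test[-length(test)], fit$states),
                      match(test[-1], fit$states))]
    sum(log(pr))
  }
}

#' Compare zeroth- and first-order Markov models of a behavior sequence
#'
#' Fits marginal (order 0) and conditional (order 1) categorical models with
#' additive 1/K smoothing on a training split and evaluates held-out
#' log-likelihood; a positive per-symbol improvement indicates that the
#' preceding behavior helps predict the next one. An optional label-shuffle
#' test gives the significance of the improvement.
#'
#' @param sequence character vector of behavior labels (>= 20 symbols).
#' @param split fraction of the sequence used for training.
#' @param n_shuffle number of sequence shuffles for the null (0 disables).
#' @param seed integer seed for the shuffle test.
#' @return a tibble of class `markov_fit`: `order0_loglik`, `order1_loglik`
#'   (held-out, nats), `n_heldout`, `improvement` (nats/symbol), `p_value`
#'   (NA when `n_shuffle = 0`).
#' @export
markov_order_analysis <- function(sequence, split = 0.5, n_shuffle = 0,
                                  seed = 1) {
  stopifnot(length(sequence) >= 20, split > 0, split < 1)
  states <- sort(unique(sequence))
  improvement_of <- function(s) {
    n_train <- floor(length(s) * split)
    train <- s[seq_len(n_train)]
    test <- s[-seq_len(n_train)]
    l0 <- loglik_markov(fit_markov(train, states, 0), test)
    # order-1 held-out likelihood over the same symbols, conditioning each
    # on its predecessor (the first held-out symbol conditions on the last
    # training symbol)
    l1 <- loglik_markov(fit_markov(train, states, 1),
                        c(train[n_train], test))
    c(l0 = l0, l1 = l1, n = length(test))
  }
  if (length(states) == 1) {
    return(structure(tibble(order0_loglik = 0, order1_loglik = 0,
                            n_heldout = length(sequence), improvement = 0,
                            p_value = NA_real_),
                     class = c("markov_fit", "tbl_df", "tbl", "data.frame")))
  }
  obs <- improvement_of(sequence)
  imp <- (obs["l1"] - obs["l0"]) / obs["n"]
  p <- NA_real_
  if (n_shuffle > 0) {
    null <- withr::with_seed(derive_seed(seed, "markov-shuffle"), {
      vapply(seq_len(n_shuffle), function(i) {
        o <- improvement_of(sample(sequence))
        (o["l1"] - o["l0"]) / o["n"]
      }, numeric(1))
    })
    p <- (1 + sum(null >= imp)) / (1 + n_shuffle)
  }
  structure(tibble(order0_loglik = unname(obs["l0"]),
                   order1_loglik = unname(obs["l1"]),
                   n_heldout = unname(obs["n"]),
                   improvement = unname(imp), p_value = p),
            class = c("markov_fit", "tbl_df", "tbl", "data.frame"))
}
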