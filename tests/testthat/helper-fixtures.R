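# Shared small fixtures, built once per test run.

fixture_env <- new.env(parent = emptyenv())

# A short session with strong structure, reused by several test files.
small_session <- function() {
  if (is.null(fixture_env$session)) {
    cfg <- generator_config(session_length = 240, n_cells = 60, seed = 101)
    fixture_env$session <- simulate_session(cfg)
  }
  fixture_env$session
}

# Ethogram with known geometry for epoch tests.
toy_ethogram <- function() {
  tibble::tibble(
    behavior = c("F", "S", "E", "F"),
    start_s = c(10, 25, 40, 55),
    end_s = c(18, 33, 48, 63))
}

# Homogeneous Poisson spike times over [0, span].
poisson_train <- function(rate, span, seed) {
  withr::with_seed(seed, sort(runif(rpois(1, rate * span), 0, span)))
}

# Interval Jaccard index.
jaccard <- function(a1, a2, b1, b2) {
  inter <- max(0, min(a2, b2) - max(a1, b1))
  inter / (max(a2, b2) - min(a1, b1))
}

# Event-matching metrics for detected vs true episode tables.
episode_metrics <- function(detected, truth) {
  overlaps <- function(a1, a2, b1, b2) pmin(a2, b2) - pmax(a1, b1) > 0
  hit <- vapply(seq_len(nrow(truth)), function(k) {
    any(overlaps(truth$start_s[k], truth$end_s[k],
                 detected$start_s, detected$end_s))
  }, logical(1))
  tp <- vapply(seq_len(nrow(detected)), function(j) {
    any(overlaps(detected$start_s[j], detected$end_s[j],
                 truth$start_s, truth$end_s))
  }, logical(1))
  mj <- mean(vapply(which(hit), function(k) {
    max(vapply(seq_len(nrow(detected)), function(j) {
      jaccard(truth$start_s[k], truth$end_s[k],
              detected$start_s[j], detected$end_s[j])
    }, numeric(1)))
  }, numeric(1)))
  list(recall = mean(hit), precision = mean(tp), mean_jaccard = mj)
}
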