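#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a phase signature
#'
#' @param x a [phase_signature()] result.
#' @param ... unused.
#' @return the per-bin tibble (`behavior`, `bin`, `bin_center_deg`,
#'   `n_active`, `c`, `phi`).
#' @export
tidy.phase_signature <- function(x, ...) as_tibble(x)

#' One-row summary of a phase signature
#'
#' @inheritParams tidy.phase_signature
#' @param cfg a [signature_config()] for the peak/trough bin geometry.
#' @return tibble with `behavior`, `n_bins`, `phi_max`, `phi_max_bin_deg`,
#'   `peak_trough_ratio`.
#' @export
glance.phase_signature <- function(x, cfg = signature_config(), ...) {
  pt <- tryCatch(peak_trough_preference(x, cfg)$ratio,
                 error = function(e) NA_real_)
  tibble(behavior = x$behavior[1], n_bins = nrow(x),
         phi_max = max(x$phi, na.rm = TRUE),
         phi_max_bin_deg = x$bin_center_deg[which.max(x$phi)],
         peak_trough_ratio = pt)
}

#' Tidy a permutation test result
#'
#' @param x a [permutation_test()] result.
#' @param ... unused.
#' @return tibble of the null accuracies, one row per permutation.
#' @export
tidy.permutation_result <- function(x, ...) {
  tibble(permutation = seq_along(x$null[[1]]), accuracy = x$null[[1]])
}

#' One-row summary of a permutation test
#'
#' @inheritParams tidy.permutation_result
#' @export
glance.permutation_result <- function(x, ...) {
  select(as_tibble(x), -"null")
}

#' One-row summary of a cross-validated decoder
#'
#' @param x a [crossval_accuracy()] result.
#' @param ... unused.
#' @export
glance.decoding_result <- function(x, ...) as_tibble(x)

#' One-row summary of a Markov order comparison
#'
#' @param x a [markov_order_analysis()] result.
#' @param ... unused.
#' @export
glance.markov_fit <- function(x, ...) as_tibble(x)

#' One-row summary of a full pipeline run
#'
#' @param x a [run_pipeline()] result.
#' @param ... unused.
#' @return tibble with episode/epoch counts, decoding accuracy and p-values,
#'   and the transition peak:trough ratio.
#' @export
glance.phasesig_run <- function(x, ...) {
  tibble(n_episodes = nrow(x$episodes),
         n_transitions = nrow(x$transitions),
         accuracy = x$decoding$permutation$accuracy,
         p_value = x$decoding$permutation$p_value,
         crossbin_accuracy = x$decoding$bestbin$accuracy,
         crossbin_p = x$decoding$bestbin$p_value,
         crossbin_p_shuffled = x$decoding$bestbin_shuffled$p_value,
         peak_trough_transition = x$peak_trough$ratio,
         peak_trough_control = x$peak_trough_control$ratio)
}
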