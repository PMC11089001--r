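#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_col geom_rect
#'   geom_point geom_histogram geom_vline labs theme_minimal facet_wrap
#' @export
ggplot2::autoplot

peak_shade <- function(cfg) {
  w <- cfg$peak_halfwidth_bins * 360 / cfg$n_bins
  ggplot2::annotate("rect", xmin = -w, xmax = w, ymin = -Inf, ymax = Inf,
                    alpha = 0.15, fill = "khaki")
}

#' Plot a phase signature across the oscillation cycle
#'
#' Phi per phase bin with the peak neighborhood shaded.
#'
#' @param object a [phase_signature()] result (one or more behaviors).
#' @param cfg a [signature_config()] for the neighborhood shading.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.phase_signature <- function(object, cfg = signature_config(), ...) {
  ggplot(object, aes(.data$bin_center_deg, .data$phi,
                     color = .data$behavior)) +
    peak_shade(cfg) +
    geom_line() + geom_point() +
    labs(x = "oscillation phase (deg, 0 = peak)",
         y = expression(phi == c / (N - c)), color = "behavior") +
    theme_minimal()
}

#' Plot a permutation-test null distribution
#'
#' Histogram of the permuted-label accuracies with the observed accuracy
#' marked.
#'
#' @param object a [permutation_test()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.permutation_result <- function(object, ...) {
  ggplot(tidy(object), aes(.data$accuracy)) +
    geom_histogram(bins = 30, fill = "grey70") +
    geom_vline(xintercept = object$accuracy, color = "firebrick") +
    labs(x = "decoding accuracy", y = "permutations",
         subtitle = sprintf("observed %.3f, null mean %.3f, p = %.3g",
                            object$accuracy, object$null_mean,
                            object$p_value)) +
    theme_minimal()
}

#' Plot detected episodes over the band-passed LFP envelope
#'
#' @param lfp an [lfp_signal()] tibble.
#' @param episodes tibble from [detect_episodes()].
#' @param cfg the [detection_config()] used.
#' @param window time range to show, seconds (default first 20 s).
#' @return a ggplot object.
#' @export
plot_episodes <- function(lfp, episodes, cfg = detection_config(),
                          window = c(0, 20)) {
  fs <- lfp_sampling_rate(lfp)
  sel <- lfp$time_s >= window[1] & lfp$time_s <= window[2]
  env <- detection_envelope(lfp$value[sel], fs, cfg)
  df <- tibble(time_s = lfp$time_s[sel], envelope = env)
  ep <- episodes[episodes$end_s >= window[1] &
                   episodes$start_s <= window[2], , drop = FALSE]
  ggplot(df, aes(.data$time_s, .data$envelope)) +
    geom_rect(data = ep, inherit.aes = FALSE,
              aes(xmin = .data$start_s, xmax = .data$end_s,
                  ymin = -Inf, ymax = Inf), alpha = 0.2, fill = "steelblue") +
    geom_line() +
    labs(x = "time (s)", y = "smoothed rectified amplitude") +
    theme_minimal()
}

#' Plot a smoothed spike-phase histogram
#'
#' @param hist tibble from [phase_histogram()] (optionally with a `unit_id`
#'   column from [unit_phase_histograms()], which is facetted).
#' @return a ggplot object.
#' @export
plot_phase_histogram <- function(hist) {
  p <- ggplot(hist, aes(.data$bin_center_deg, .data$prob)) +
    geom_col(fill = "grey40") +
    labs(x = "oscillation phase (deg, 0 = peak)", y = "firing probability") +
    theme_minimal()
  if ("unit_id" %in% names(hist)) p <- p + facet_wrap(~unit_id)
  p
}
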