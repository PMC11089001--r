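#' Decoding configuration
#'
#' @param n_folds stratified cross-validation folds (default 10).
#' @param n_repeats repeated cross-validations averaged into the reported
#'   accuracy (reference protocol 1000; desk default 50).
#' @param n_permutations label permutations for the significance test
#'   (reference 1000; desk default 200), each evaluated with a single
#'   cross-validation.
#' @param shuffle_offset_range range (radians) of the common random rotation
#'   in the phase shuffle; default 2.5 (the peak-neighborhood width) to pi.
#' @param per_spike_jitter range (degrees) of the uniform per-spike jitter in
#'   the phase shuffle; default 360 (full circle), which is what actually
#'   erases phase structure - the additional class-wise rotation then guards
#'   against any residual alignment. Smaller values (e.g. one bin width, 18)
#'   keep per-unit phase structure and only misalign the classes.
#' @param svm_dim_cutoff feature-count boundary between the radial-basis
#'   kernel (<= cutoff) and the linear kernel (> cutoff).
#' @param seed integer seed.
#' @return object of class `decoding_config`.
#' @export
decoding_config <- function(n_folds = 10, n_repeats = 50,
                            n_permutations = 200,
                            shuffle_offset_range = c(2.5, pi),
                            per_spike_jitter = 360, svm_dim_cutoff = 8,
                            seed = 1) {
  stopifnot(n_folds >= 2, n_repeats >= 1, n_permutations >= 1,
            shuffle_offset_range[1] < shuffle_offset_range[2])
  structure(list(n_folds = n_folds, n_repeats = n_repeats,
                 n_permutations = n_permutations,
                 shuffle_offset_range = shuffle_offset_range,
                 per_spike_jitter = per_spike_jitter,
                 svm_dim_cutoff = svm_dim_cutoff, seed = seed),
            class = "decoding_config")
}

#' Assemble a labeled feature matrix from signature replicates
#'
#' Builds the decoder input: one row per replicate, one feature per
#' (behavior x phase bin) phi value, one class label per row. Classes with
#' unequal replicate counts are subsampled (seeded) to the minimum so the
#' dataset is balanced. Feature layouts follow the model suite: one behavior
#' and one peak bin (1 feature), three behaviors and one bin (3 features),
#' three behaviors over the 8 peak-neighborhood bins (24 features), or all
#' 20 bins for phase-offset-tolerant decoding.
#'
#' @param replicates tibble with columns `label` (class), `behavior`, `bin`,
#'   `replicate`, `phi`.
#' @param behaviors behaviors whose signatures become features.
#' @param bins phase bins whose signatures become features.
#' @param seed seed for the balancing subsample.
#' @return tibble with a factor `label` column and `phi_<behavior>_b<bin>`
#'   feature columns.
#' @export
build_dataset <- function(replicates, behaviors, bins, seed = 1) {
  r <- replicates[replicates$behavior %in% behaviors &
                    replicates$bin %in% bins, , drop = FALSE]
  missing <- setdiff(
    paste0(rep(behaviors, each = length(bins)), "_b", bins),
    paste0(r$behavior, "_b", r$bin))
  if (length(missing) > 0) {
    abort(paste0("no finite signature replicates for feature(s): ",
                 paste(missing, collapse = ", ")))
  }
  wide <- r |>
    mutate(feature = paste0("phi_", .data$behavior, "_b", .data$bin)) |>
    select("label", "replicate", "feature", "phi") |>
    tidyr::pivot_wider(names_from = "feature", values_from = "phi") |>
    select(-"replicate") |>
    tidyr::drop_na()
  n_min <- min(table(wide$label))
  withr::with_seed(derive_seed(seed, "balance"), {
    wide <- wide |>
      group_by(.data$label) |>
      dplyr::slice_sample(n = n_min) |>
      ungroup()
  })
  wide$label <- factor(wide$label)
  wide
}

svm_kernel_for <- function(n_features, cfg) {
  if (n_features <= cfg$svm_dim_cutoff) "radial" else "linear"
}

fit_svm <- function(train, kernel) {
  e1071::svm(label ~ ., data = train, kernel = kernel, scale = FALSE)
}

# One stratified k-fold cross-validation; returns the fold-averaged accuracy.
one_crossval <- function(ds, n_folds, kernel) {
  folds <- integer(nrow(ds))
  for (cl in levels(ds$label)) {
    idx <- which(ds$label == cl)
    folds[idx] <- sample(rep(seq_len(n_folds), length.out = length(idx)))
  }
  accs <- vapply(seq_len(n_folds), function(f) {
    tr <- ds[folds != f, , drop = FALSE]
    te <- ds[folds == f, , drop = FALSE]
    if (nrow(te) == 0 || length(unique(tr$label)) < 2) return(NA_real_)
    fit <- fit_svm(tr, kernel)
    mean(stats::predict(fit, te) == te$label)
  }, numeric(1))
  mean(accs, na.rm = TRUE)
}

#' Repeated stratified cross-validated decoding accuracy
#'
#' Trains a support vector machine (radial-basis kernel for low-dimensional
#' inputs, linear for high-dimensional, per `svm_dim_cutoff`) under
#' stratified k-fold cross-validation, repeated `n_repeats` times with fresh
#' fold assignments; accuracies are averaged within, then across repeats.
#'
#' @param ds labeled feature tibble from [build_dataset()].
#' @param cfg a [decoding_config()].
#' @return one-row tibble of class `decoding_result`: `accuracy`, `kernel`,
#'   `n_features`, `n_rows`, `n_repeats`.
#' @export
crossval_accuracy <- function(ds, cfg = decoding_config()) {
  if (length(unique(ds$label)) < 2) {
    abort("decoding needs at least two classes")
  }
  if (min(table(ds$label)) < cfg$n_folds) {
    abort("fewer rows per class than folds")
  }
  nf <- ncol(ds) - 1
  kernel <- svm_kernel_for(nf, cfg)
  acc <- with_stream_seed(cfg$seed, "crossval", {
    mean(vapply(seq_len(cfg$n_repeats), function(r) {
      one_crossval(ds, cfg$n_folds, kernel)
    }, numeric(1)))
  })
  structure(tibble(accuracy = acc, kernel = kernel, n_features = nf,
                   n_rows = nrow(ds), n_repeats = cfg$n_repeats),
            class = c("decoding_result", "tbl_df", "tbl", "data.frame"))
}

#' Label-permutation significance test for a decoder
#'
#' Recomputes the cross-validated accuracy after randomly permuting the
#' class labels `n_permutations` times (one cross-validation per
#' permutation); chance performance is the mean of the permuted accuracies
#' and the right-tailed p-value is (1 + #{null >= observed}) /
#' (1 + n_permutations).
#'
#' @param ds labeled feature tibble from [build_dataset()].
#' @param cfg a [decoding_config()].
#' @return one-row tibble of class `permutation_result`: `accuracy`,
#'   `null_mean`, `p_value`, `n_permutations`, plus a `null` list-column
#'   with the permuted accuracies.
#' @export
permutation_test <- function(ds, cfg = decoding_config()) {
  obs <- crossval_accuracy(ds, cfg)$accuracy
  nf <- ncol(ds) - 1
  kernel <- svm_kernel_for(nf, cfg)
  null <- with_stream_seed(cfg$seed, "permutation", {
    vapply(seq_len(cfg$n_permutations), function(i) {
      dsp <- ds
      dsp$label <- sample(dsp$label)
      one_crossval(dsp, cfg$n_folds, kernel)
    }, numeric(1))
  })
  p <- (1 + sum(null >= obs)) / (1 + cfg$n_permutations)
  structure(tibble(accuracy = obs, null_mean = mean(null), p_value = p,
                   n_permutations = cfg$n_permutations, null = list(null)),
            class = c("permutation_result", "tbl_df", "tbl", "data.frame"))
}

#' Destroy phase-specific population structure by phase shuffling
#'
#' Jitters every spike phase by a uniform random offset (range
#' `per_spike_jitter`, default one bin width) and then rotates all spikes of
#' all cells belonging to the same epoch class by one common random phase
#' drawn between 2.5 radians (the peak-neighborhood width) and pi, with an
#' independent offset (and random sign) per class. Firing rates and epoch
#' membership are untouched; only the phase coordinate is scrambled.
#'
#' @param spike_phases tibble with a `phase_deg` column and an
#'   `epoch_class` column naming each spike's epoch class (e.g. "transition"
#'   / "control").
#' @param cfg a [decoding_config()].
#' @param seed integer seed (defaults to `cfg$seed`).
#' @return the input tibble with `phase_deg` replaced by shuffled phases,
#'   wrapped to (-180, 180].
#' @export
phase_shuffle <- function(spike_phases, cfg = decoding_config(),
                          seed = NULL) {
  stopifnot(all(c("phase_deg", "epoch_class") %in% names(spike_phases)))
  seed <- seed %||% cfg$seed
  with_stream_seed(seed, "phase-shuffle", {
    n <- nrow(spike_phases)
    jit <- runif(n, -cfg$per_spike_jitter / 2, cfg$per_spike_jitter / 2)
    classes <- unique(spike_phases$epoch_class)
    rot <- runif(length(classes), cfg$shuffle_offset_range[1],
                 cfg$shuffle_offset_range[2]) * 180 / pi *
      sample(c(-1, 1), length(classes), replace = TRUE)
    names(rot) <- classes
    out <- spike_phases
    out$phase_deg <- wrap_deg(spike_phases$phase_deg + jit +
                                unname(rot[spike_phases$epoch_class]))
    out
  })
}

# Aligned per-bin feature matrices: element [[b]] is the feature matrix
# (rows = replicates of both classes in fixed order, columns = behaviors)
# for bin b; `y` is the common label factor. Classes are balanced by seeded
# subsampling of replicate indices.
aligned_bin_matrices <- function(replicates, behaviors, bins, seed = 1) {
  r <- replicates[replicates$behavior %in% behaviors &
                    replicates$bin %in% bins, , drop = FALSE]
  wide <- r |>
    tidyr::pivot_wider(names_from = "behavior", values_from = "phi") |>
    tidyr::drop_na()
  labels <- sort(unique(wide$label))
  keep <- lapply(labels, function(L) {
    w <- wide[wide$label == L, , drop = FALSE]
    ok <- names(which(table(w$replicate) == length(bins)))
    sort(as.integer(ok))
  })
  n_min <- min(lengths(keep))
  if (n_min < 2) abort("too few complete replicates across the requested bins")
  keep <- withr::with_seed(derive_seed(seed, "align"), {
    lapply(keep, function(k) sort(sample(k, n_min)))
  })
  y <- factor(rep(labels, each = n_min))
  mats <- lapply(bins, function(b) {
    do.call(rbind, lapply(seq_along(labels), function(i) {
      w <- wide[wide$label == labels[i] & wide$bin == b, , drop = FALSE]
      as.matrix(w[match(keep[[i]], w$replicate), behaviors, drop = FALSE])
    }))
  })
  names(mats) <- as.character(bins)
  list(mats = mats, y = y, bins = bins)
}

# Core of the cross-bin protocol for a given label vector: pick the bin with
# the largest between-class signature-amplitude difference (anywhere in the
# cycle), train one SVM there, test on every peak-neighborhood bin except
# the training bin, which is tested by a second SVM trained on the
# second-best bin. Ties resolve to the lower bin index.
best_bin_pass <- function(am, y, test_bins, cfg) {
  l <- levels(y)
  diffs <- vapply(am$mats, function(X) {
    abs(mean(rowMeans(X)[y == l[1]]) - mean(rowMeans(X)[y == l[2]]))
  }, numeric(1))
  o <- order(-diffs, am$bins)
  best <- am$bins[o[1]]; second <- am$bins[o[2]]
  kernel <- svm_kernel_for(ncol(am$mats[[1]]), cfg)
  fit_on <- function(b) {
    e1071::svm(am$mats[[as.character(b)]], y, kernel = kernel, scale = FALSE)
  }
  f_best <- fit_on(best)
  f_second <- NULL
  acc <- vapply(test_bins, function(b) {
    fit <- if (b == best) {
      if (is.null(f_second)) f_second <<- fit_on(second)
      f_second
    } else {
      f_best
    }
    mean(stats::predict(fit, am$mats[[as.character(b)]]) == y)
  }, numeric(1))
  tibble(bin = test_bins,
         train_bin = ifelse(test_bins == best, second, best),
         accuracy = acc)
}

#' Cross-bin generalization: train on the best bin, test on the others
#'
#' The two-classifier protocol for transition-vs-control decoding across the
#' peak neighborhood: the training bin is the bin (anywhere in the cycle)
#' with the largest between-class difference in signature amplitude; the
#' trained decoder is tested on every peak-neighborhood bin except the
#' training bin, which is instead tested by a second decoder trained on the
#' bin with the second-largest difference. Because training and testing use
#' different phase bins, only class structure that generalizes across the
#' peak neighborhood (i.e. genuine phase-specific structure) yields high
#' accuracy - sampling quirks confined to one bin do not transfer. An
#' optional label-permutation test (the same protocol on permuted labels,
#' including re-selection of the training bin) gives chance levels.
#'
#' @param replicates tibble with columns `label` (two classes), `behavior`,
#'   `bin`, `replicate`, `phi`.
#' @param behaviors behaviors used as features (default all present).
#' @param cfg a [decoding_config()]; `n_permutations` used when
#'   `permute = TRUE`.
#' @param sig_cfg a [signature_config()] (for the peak-neighborhood bins).
#' @param permute run the label-permutation test.
#' @param test_bins bins to test on; default the whole peak neighborhood.
#'   The phase-shuffle control tests only the single bin where the original
#'   data decoded best, a choice made independently of the shuffled data.
#' @return a list of class `bestbin_result`: `per_bin` (tibble `bin`,
#'   `train_bin`, `accuracy`), `accuracy` (mean over test bins), and when
#'   permuted `null_mean`, `p_value`, `null`.
#' @export
train_best_bin_test_others <- function(replicates, behaviors = NULL,
                                       cfg = decoding_config(),
                                       sig_cfg = signature_config(),
                                       permute = FALSE, test_bins = NULL) {
  if (is.null(behaviors)) behaviors <- unique(replicates$behavior)
  all_bins <- sort(unique(replicates$bin))
  if (length(all_bins) < 2) abort("need at least 2 bins with finite signatures")
  am <- aligned_bin_matrices(replicates, behaviors, all_bins, seed = cfg$seed)
  test_bins <- intersect(test_bins %||% peak_bins(sig_cfg), all_bins)
  per_bin <- best_bin_pass(am, am$y, test_bins, cfg)
  out <- list(per_bin = per_bin, accuracy = mean(per_bin$accuracy))
  if (permute) {
    null <- with_stream_seed(cfg$seed, "bestbin-perm", {
      vapply(seq_len(cfg$n_permutations), function(i) {
        mean(best_bin_pass(am, sample(am$y), test_bins, cfg)$accuracy)
      }, numeric(1))
    })
    out$null_mean <- mean(null)
    out$p_value <- (1 + sum(null >= out$accuracy)) / (1 + cfg$n_permutations)
    out$null <- null
  }
  structure(out, class = "bestbin_result")
}

#' @export
print.bestbin_result <- function(x, ...) {
  cat("<bestbin_result> mean accuracy", round(x$accuracy, 3))
  if (!is.null(x$p_value)) {
    cat(", null mean", round(x$null_mean, 3), ", p", signif(x$p_value, 3))
  }
  cat("\n")
  invisible(x)
}
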