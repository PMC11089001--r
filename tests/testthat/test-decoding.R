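# Synthetic signature replicates: phi drawn per class around class means.
fake_replicates <- function(means_by_label, behaviors = c("F", "S", "E"),
                            bins = 1:20, n_rep = 120, sd = 0.3, seed = 1) {
  withr::with_seed(seed, {
    dplyr::bind_rows(lapply(names(means_by_label), function(L) {
      tidyr::expand_grid(label = L, behavior = behaviors, bin = bins,
                         replicate = seq_len(n_rep)) |>
        dplyr::mutate(phi = pmax(0.01, stats::rnorm(dplyr::n(),
                                                    means_by_label[[L]], sd)))
    }))
  })
}

test_that("datasets are assembled per model layout and balanced", {
  reps <- fake_replicates(list(transition = 2, control = 1))
  # one behavior, one bin: 1 feature
  d1 <- build_dataset(reps, "F", 10)
  expect_equal(ncol(d1) - 1, 1)
  # three behaviors, one bin: 3 features
  d2 <- build_dataset(reps, c("F", "S", "E"), 10)
  expect_equal(ncol(d2) - 1, 3)
  # three behaviors, all 8 peak-neighborhood bins: 24 features
  d4 <- build_dataset(reps, c("F", "S", "E"), 7:14)
  expect_equal(ncol(d4) - 1, 24)
  # unequal replicate counts are subsampled to the minimum
  reps_small <- dplyr::filter(reps, !(label == "control" & replicate > 80))
  d5 <- build_dataset(reps_small, "F", 10)
  expect_equal(as.integer(table(d5$label)), c(80L, 80L))
  expect_error(build_dataset(reps, "F", 99), "no finite")
})

test_that("identical class distributions decode at chance", {
  reps <- fake_replicates(list(a = 1.5, b = 1.5), n_rep = 150, seed = 2)
  ds <- build_dataset(reps, c("F", "S", "E"), 10)
  acc <- crossval_accuracy(ds, decoding_config(n_repeats = 5, seed = 2))
  expect_equal(acc$accuracy, 0.5, tolerance = 0.08)
})

test_that("separable classes decode near-perfectly", {
  reps <- fake_replicates(list(a = 3, b = 1), sd = 0.1, seed = 3)
  ds <- build_dataset(reps, c("F", "S", "E"), 10)
  acc <- crossval_accuracy(ds, decoding_config(n_repeats = 3, seed = 3))
  expect_gte(acc$accuracy, 0.98)
  expect_equal(acc$kernel, "radial")
  # high-dimensional input switches to the linear kernel
  ds24 <- build_dataset(reps, c("F", "S", "E"), 7:14)
  acc24 <- crossval_accuracy(ds24, decoding_config(n_repeats = 2, seed = 3))
  expect_equal(acc24$kernel, "linear")
  expect_error(crossval_accuracy(ds[ds$label == "a", ],
                                 decoding_config()), "two classes")
})

test_that("permutation nulls are centred at 1/K for balanced classes", {
  reps3 <- fake_replicates(list(x = 1.5, y = 1.5, z = 1.5), n_rep = 60,
                           seed = 4)
  ds <- build_dataset(reps3, c("F", "S", "E"), 10)
  cfg <- decoding_config(n_repeats = 2, n_permutations = 200, seed = 4)
  pt <- permutation_test(ds, cfg)
  expect_equal(pt$null_mean, 1 / 3, tolerance = 0.02)
  expect_gt(pt$p_value, 0.05)
  # separable data: smallest attainable p
  repsXY <- fake_replicates(list(x = 3, y = 1), sd = 0.1, n_rep = 60,
                            seed = 5)
  ds2 <- build_dataset(repsXY, "F", 10)
  cfg2 <- decoding_config(n_repeats = 2, n_permutations = 99, seed = 5)
  pt2 <- permutation_test(ds2, cfg2)
  expect_equal(pt2$p_value, 1 / 100)
})

test_that("phase shuffling rotates classes and erases phase structure", {
  # jitter 0, rotation forced to pi: every phase flips by 180 degrees
  sp <- tibble::tibble(phase_deg = c(-90, 0, 45, 180),
                       epoch_class = "transition")
  cfg <- decoding_config(per_spike_jitter = 0,
                         shuffle_offset_range = c(pi - 1e-12, pi))
  out <- phase_shuffle(sp, cfg, seed = 1)
  expect_equal(abs(wrap_deg(out$phase_deg - sp$phase_deg)), rep(180, 4))
  # full-circle jitter flattens a concentrated sample
  withr::with_seed(2, conc <- tibble::tibble(
    phase_deg = wrap_deg(stats::rnorm(4000, 0, 15)),
    epoch_class = rep(c("transition", "control"), 2000)))
  sh <- phase_shuffle(conc, decoding_config(), seed = 3)
  expect_gt(rayleigh_test(sh$phase_deg[conc$epoch_class == "transition"])$p_value,
            0.01)
  h <- phase_histogram(sh$phase_deg)
  expect_lt(max(h$prob) / min(h$prob), 1.5)
})

test_that("cross-bin decoding transfers real structure but not bin noise", {
  # class difference present in every bin: transfers
  reps <- fake_replicates(list(transition = 2.2, control = 1), sd = 0.35,
                          seed = 6)
  bb <- train_best_bin_test_others(reps, cfg = decoding_config(seed = 6))
  expect_gt(bb$accuracy, 0.9)
  expect_equal(nrow(bb$per_bin), 8)
  expect_true(all(bb$per_bin$train_bin != bb$per_bin$bin))
  # structure confined to one bin does not transfer to the others
  reps1 <- fake_replicates(list(transition = 1, control = 1), sd = 0.35,
                           seed = 7)
  reps1$phi[reps1$label == "transition" & reps1$bin == 3] <-
    reps1$phi[reps1$label == "transition" & reps1$bin == 3] + 3
  bb1 <- train_best_bin_test_others(reps1, cfg = decoding_config(seed = 7))
  expect_lt(bb1$accuracy, 0.6)
  # identical classes: permutation test is not significant
  bb0 <- train_best_bin_test_others(
    fake_replicates(list(transition = 1.5, control = 1.5), seed = 8),
    cfg = decoding_config(seed = 8, n_permutations = 60), permute = TRUE)
  expect_gt(bb0$p_value, 0.05)
})

test_that("decoders and shuffles are reproducible under a fixed seed", {
  reps <- fake_replicates(list(a = 1.8, b = 1.2), n_rep = 80, seed = 9)
  ds <- build_dataset(reps, c("F", "S", "E"), 10)
  cfg <- decoding_config(n_repeats = 3, seed = 11)
  expect_identical(crossval_accuracy(ds, cfg), crossval_accuracy(ds, cfg))
  sp <- tibble::tibble(phase_deg = runif(100, -180, 180),
                       epoch_class = "transition")
  expect_identical(phase_shuffle(sp, cfg), phase_shuffle(sp, cfg))
})
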