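test_that("behavior rate is spike count over scored duration", {
  eth <- tibble::tibble(behavior = "F", start_s = 10, end_s = 15)
  expect_equal(behavior_rate(seq(10.1, 14.9, length.out = 10), eth, "F"), 2)
  expect_equal(behavior_rate(c(1, 2, 20), eth, "F"), 0)
  expect_error(behavior_rate(1:3, eth, "S"), "zero scored time")
})

test_that("a cell firing only during the behavior scores 1", {
  eth <- tibble::tibble(behavior = c("F", "S"),
                        start_s = c(100, 300), end_s = c(150, 350))
  spikes <- withr::with_seed(1, sort(runif(200, 100, 150)))
  m <- match_score(spikes, eth, "F", session_span = 600,
                   match_score_config(n_surrogates = 200, seed = 1))
  expect_equal(m, 1)
  # absent behavior is reported as missing
  expect_true(is.na(match_score(spikes, eth, "E", 600)))
})

test_that("raising the in-behavior rate never lowers the match score", {
  eth <- tibble::tibble(behavior = "F", start_s = 200, end_s = 260)
  base <- poisson_train(4, 600, seed = 2)
  extra <- withr::with_seed(3, sort(runif(40, 200, 260)))
  cfg <- match_score_config(n_surrogates = 300, seed = 4)
  m0 <- match_score(base, eth, "F", 600, cfg)
  m1 <- match_score(sort(c(base, extra)), eth, "F", 600, cfg)
  expect_gte(m1, m0)
})

test_that("match scores of unmodulated cells are uniform", {
  eth <- tibble::tibble(behavior = rep(c("F", "S", "E"), 5),
                        start_s = seq(20, 560, length.out = 15),
                        end_s = seq(20, 560, length.out = 15) + 10)
  cfg <- match_score_config(n_surrogates = 100, seed = 5)
  m <- vapply(1:80, function(i) {
    match_score(poisson_train(5, 600, seed = 100 + i), eth, "F", 600, cfg,
                stream = i)
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(m, "punif"))$statistic
  expect_lt(unname(ks), 0.12)
})

test_that("match score is invariant to uniform time rescaling", {
  eth <- tibble::tibble(behavior = "F", start_s = c(50, 400),
                        end_s = c(80, 430))
  spikes <- poisson_train(6, 600, seed = 6)
  a <- 2
  cfg <- match_score_config(n_surrogates = 200, seed = 7)
  cfg_scaled <- match_score_config(n_surrogates = 200, seed = 7,
                                   offset_range = c(120, 240) * a)
  m1 <- match_score(spikes, eth, "F", 600, cfg)
  eth2 <- dplyr::mutate(eth, start_s = start_s * a, end_s = end_s * a)
  m2 <- match_score(spikes * a, eth2, "F", 600 * a, cfg_scaled)
  expect_equal(m1, m2)
})

test_that("the match-score table applies the minimum-spike filter", {
  eth <- toy_ethogram()
  spikes <- dplyr::bind_rows(
    tibble::tibble(unit_id = 1L, time_s = poisson_train(3, 100, seed = 8)),
    tibble::tibble(unit_id = 2L, time_s = c(1, 2, 3)))   # too few
  tab <- match_score_table(spikes, eth, session_span = 100,
                           cfg = match_score_config(n_surrogates = 100,
                                                    seed = 9))
  expect_setequal(unique(tab$unit_id), 1L)
  expect_setequal(tab$behavior, c("E", "F", "S"))
  expect_true(all(tab$score >= 0 & tab$score <= 1))
})

test_that("multimodal classification needs the upper quartile everywhere", {
  tab <- tidyr::expand_grid(unit_id = 1:8, behavior = c("F", "S", "E"))
  tab$score <- 0.5
  tab$score[tab$unit_id == 1] <- 0.99           # top for all three
  tab$score[tab$unit_id == 2 & tab$behavior != "E"] <- 0.98  # only two
  lab <- classify_multimodal(tab)
  expect_true(lab$multimodal[lab$unit_id == 1])
  expect_false(lab$multimodal[lab$unit_id == 2])
  expect_error(classify_multimodal(tab[tab$unit_id <= 3, ]), "4 units")
})

test_that("engineered conjunctive populations are recovered", {
  n <- 100; n_multi <- 20
  session <- 600
  eth <- tibble::tibble(behavior = rep(c("F", "S", "E"), 6),
                        start_s = seq(20, 540, length.out = 18),
                        end_s = seq(20, 540, length.out = 18) + 12)
  gain <- matrix(1, n, 3, dimnames = list(NULL, c("F", "S", "E")))
  gain[seq_len(n_multi), ] <- 3
  cfg <- generator_config(session_length = session, n_cells = n,
                          behavior_gain = gain, kappa = 0, burst_rate = 0,
                          base_rate = 4, seed = 10)
  sp <- generate_spikes(cfg, eth, generate_lfp(cfg)$episodes)
  tab <- match_score_table(sp, eth, session_span = session,
                           cfg = match_score_config(n_surrogates = 150,
                                                    seed = 11))
  lab <- classify_multimodal(tab)
  frac <- mean(lab$multimodal)
  expect_gte(frac, 0.15)
  expect_lte(frac, 0.25)
})

test_that("burst/tonic spike labels match an exhaustive oracle", {
  oracle <- function(times, cfg = burst_config()) {
    n <- length(times)
    out <- character(n)
    for (i in seq_len(n)) {
      prev <- if (i > 1) times[i] - times[i - 1] else Inf
      nxt <- if (i < n) times[i + 1] - times[i] else Inf
      out[i] <- if (min(prev, nxt) < cfg$burst_max_isi) "burst"
      else if (min(prev, nxt) > cfg$tonic_min_isi) "tonic" else "neither"
    }
    out
  }
  expect_equal(classify_isi(seq(0, 1, by = 0.1)), rep("neither", 11))
  expect_equal(classify_isi(c(0, 0.05)), c("burst", "burst"))
  withr::with_seed(12, {
    for (i in 1:50) {
      tr <- sort(runif(sample(2:40, 1), 0, 3))
      expect_identical(classify_isi(tr), oracle(tr))
    }
  })
})

test_that("putative dopamine selection uses a strict 10 Hz cutoff", {
  expect_equal(select_putative_dopamine(c(12, 4, 10, 9.999)),
               c(FALSE, TRUE, FALSE, TRUE))
})
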