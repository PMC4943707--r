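test_that("herd_config validates its inputs", {
  expect_error(herd_config(n_individuals = 2), "triad")
  expect_error(herd_config(true_rank = c(1, 2, 2, 4),
                           n_individuals = 4), "permutation")
  expect_error(herd_config(steepness_k = 0), "steepness_k")
  expect_error(herd_config(end_conflict_prob_after_grunt = 1.2),
               "probability")
})

test_that("signature minimum frequency follows the configured rank model", {
  # zero slope, zero between-individual noise: all means at the intercept
  cfg0 <- herd_config(minfreq_slope_hz_per_rank = 0,
                      between_individual_sd = c(duration_s = 0,
                                                peak_freq_hz = 0,
                                                min_freq_hz = 0,
                                                bandwidth_hz = 0,
                                                hnr_db = 0),
                      seed = 1)
  h0 <- generate_herd(cfg0)
  expect_true(all(h0$min_freq_hz == cfg0$minfreq_intercept_hz))

  # 5 Hz per rank, noise-free: exactly 5 Hz steps
  cfg5 <- herd_config(minfreq_slope_hz_per_rank = 5,
                      between_individual_sd = c(duration_s = 0,
                                                peak_freq_hz = 0,
                                                min_freq_hz = 0,
                                                bandwidth_hz = 0,
                                                hnr_db = 0),
                      seed = 1)
  h5 <- generate_herd(cfg5)
  expect_equal(diff(h5$min_freq_hz[order(h5$rank)]), rep(5, 18))

  # determinism
  expect_identical(generate_herd(herd_config(seed = 7)),
                   generate_herd(herd_config(seed = 7)))
})

test_that("interaction simulation respects the configured win and grunt
           models", {
  herd <- generate_herd(herd_config(seed = 1))
  ints <- simulate_interactions(herd, 500, seed = 2)
  expect_identical(ints, simulate_interactions(herd, 500, seed = 2))
  expect_true(all(ints$winner == ints$aggressor |
                    ints$winner == ints$victim))
  expect_true(all(is.na(ints$grunt_caller) == !ints$grunt_emitted))
  expect_true(all(is.na(ints$latency_s) == !ints$grunt_emitted))
  # grunt caller is always the loser
  loser <- ifelse(ints$winner == ints$aggressor, ints$victim,
                  ints$aggressor)
  expect_true(all(ints$grunt_caller[ints$grunt_emitted] ==
                    loser[ints$grunt_emitted]))
})

test_that("an infinitely steep hierarchy is fully unidirectional", {
  herd <- generate_herd(herd_config(steepness_k = 1e6, seed = 3))
  ints <- simulate_interactions(herd, 2000, seed = 4)
  X <- build_matrix(ints, ids = herd$id)
  expect_identical(dci(X), 1)
  expect_identical(landau_h_prime(X, n_random = 300, seed = 5)$h_prime, 1)
})

test_that("zero grunt-rate slope makes the per-loss grunt rate
           rank-independent", {
  # losses themselves depend on rank (low-ranked animals lose more), so the
  # null quantity is the grunt rate per loss, not the raw count
  cfg <- herd_config(grunt_base_prob = 0.3, grunt_rate_slope = 0, seed = 1)
  herd <- generate_herd(cfg)
  rs <- vapply(1:30, function(s) {
    ints <- simulate_interactions(herd, 1000, seed = s)
    loser <- ifelse(ints$winner == ints$aggressor, ints$victim,
                    ints$aggressor)
    losses <- table(factor(loser, herd$id))
    counts <- grunt_counts(ints, ids = herd$id)
    oracle_spearman(herd$rank, as.numeric(counts) / pmax(1, losses))
  }, numeric(1))
  expect_lt(abs(mean(rs)), 2 * sd(rs) / sqrt(length(rs)) + 0.1)
  # whereas a positive slope makes raw counts track rank
  herd2 <- generate_herd(herd_config(seed = 2))
  ints2 <- simulate_interactions(herd2, 1500, seed = 3)
  expect_gt(oracle_spearman(herd2$rank,
                            grunt_counts(ints2, ids = herd2$id)), 0.5)
})

test_that("conflict outcomes after a grunt reproduce the configured
           end/continue proportion within binomial error", {
  herd <- generate_herd(herd_config(seed = 1))
  ints <- simulate_interactions(herd, 4000, seed = 6)
  g <- ints[ints$grunt_emitted, ]
  n <- nrow(g)
  k <- sum(g$outcome == "end_conflict")
  p0 <- 400 / 413
  expect_gt(n, 100)
  expect_lt(abs(k / n - p0), 3 * sqrt(p0 * (1 - p0) / n))
})

test_that("latency families separate by outcome as configured", {
  herd <- generate_herd(herd_config(seed = 1))
  ints <- simulate_interactions(herd, 20000, seed = 7)
  ls <- latency_summary(ints)
  med_end <- median(ints$latency_s[ints$outcome == "end_conflict" &
                                     ints$grunt_emitted], na.rm = TRUE)
  med_cont <- median(ints$latency_s[ints$outcome == "aggression_continued"],
                     na.rm = TRUE)
  expect_equal(med_end, 1.3, tolerance = 0.1)
  expect_equal(med_cont, 6.8, tolerance = 0.25)
  expect_gt(ls$mean_latency_s[ls$outcome == "aggression_continued"],
            ls$mean_latency_s[ls$outcome == "end_conflict"])
})

test_that("feature tables respect the frequency ordering invariants", {
  herd <- generate_herd(herd_config(seed = 2))
  tab <- simulate_feature_table(herd, 20, seed = 3)
  expect_equal(nrow(tab), 19 * 20)
  expect_true(all(tab$min_freq_mean_hz <= tab$peak_freq_mean_hz))
  expect_true(all(tab$peak_freq_mean_hz <= tab$max_freq_mean_hz))
  expect_true(all(tab$min_freq_centre_hz <= tab$peak_freq_centre_hz))
  expect_true(all(tab$peak_freq_centre_hz <= tab$max_freq_centre_hz))
  expect_true(all(tab$entropy_mean >= 0 & tab$entropy_mean <= 1))
  expect_equal(tab$bandwidth_mean_hz,
               tab$max_freq_mean_hz - tab$min_freq_mean_hz)
  skip <- simulate_feature_table(herd, 5, seed = 3, skip_top_rank = TRUE)
  expect_false(any(skip$rank == 1))
})

test_that("bouts concatenate without overlap and reject bad gaps", {
  fs <- 48000
  e <- lapply(1:3, function(s) make_burst(0.08, fs, seed = s))
  bout <- render_bout(e, c(0.1, 0.1), fs)
  expect_length(bout, 3 * round(0.08 * fs) + 2 * round(0.1 * fs))
  expect_error(render_bout(e, c(0.1, -0.01), fs), "overlap")
  expect_error(render_bout(e, c(0.1), fs), "gaps")
  single <- render_bout(e[1], numeric(0), fs)
  expect_length(single, round(0.08 * fs))
})

test_that("bout sizes stay in 2-20 territory with mode 3", {
  sz <- sample_bout_sizes(1000, seed = 1)
  expect_true(all(sz >= 1 & sz <= 20))
  tab <- table(sz)
  expect_identical(as.integer(names(tab)[which.max(tab)]), 3L)
})

test_that("written datasets are byte-stable given the seed", {
  herd <- generate_herd(herd_config(n_individuals = 4, seed = 1))
  d1 <- file.path(tempdir(), "ds1"); d2 <- file.path(tempdir(), "ds2")
  f1 <- write_dataset(herd, d1, n_interactions = 50,
                      bouts_per_individual = 1, seed = 9)
  f2 <- write_dataset(herd, d2, n_interactions = 50,
                      bouts_per_individual = 1, seed = 9)
  for (p in c("interactions_csv", "annotations_csv")) {
    expect_identical(readBin(f1[[p]], "raw", file.size(f1[[p]])),
                     readBin(f2[[p]], "raw", file.size(f2[[p]])))
  }
  expect_identical(readBin(f1$wav_files[1], "raw", file.size(f1$wav_files[1])),
                   readBin(f2$wav_files[1], "raw", file.size(f2$wav_files[1])))
  wav <- read_wav(f1$wav_files[1])
  expect_identical(wav$sample_rate_hz, 48000L)
  expect_true(all(abs(wav$samples) <= 1))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("grunt synthesis rejects invalid signatures and durations", {
  sig <- list(min_freq_hz = 350, peak_freq_hz = 800, bandwidth_hz = 1500,
              hnr_db = 25)
  expect_error(synthesize_grunt(sig, duration_s = 3), "duration")
  bad <- list(min_freq_hz = 20000, peak_freq_hz = 21000,
              bandwidth_hz = 9000, hnr_db = 25)
  expect_error(synthesize_grunt(bad, 0.1), "Nyquist|band")
  w <- synthesize_grunt(sig, 0.1, seed = 1)
  expect_true(all(abs(w) <= 1))
  expect_identical(w, synthesize_grunt(sig, 0.1, seed = 1))
})
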