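#' Configuration for a synthetic peccary herd
#'
#' Collects every generative parameter of the synthetic herd: group size and
#' sex composition, the true linear hierarchy, how steeply win probability
#' rises with rank gap, how grunt emission and the acoustic signature depend
#' on rank, and the within-/between-individual spread of each acoustic
#' parameter. Defaults emulate a captive herd of 19 adults (9 males, 10
#' females) with an almost fully unidirectional hierarchy, a grunt rate that
#' rises as rank worsens (the top-ranked animal never grunts), and a mean
#' minimum frequency that increases by a fixed step per rank position.
#'
#' @param n_individuals Herd size (at least 3).
#' @param sex_labels Character vector of `"M"`/`"F"` per individual;
#'   default 9 males then 10 females truncated/recycled to `n_individuals`.
#' @param true_rank Permutation of `1:n_individuals` (1 = top).
#' @param steepness_k Logistic scale on rank gap for win probability (> 0).
#' @param grunt_base_prob Grunt probability of a top-ranked loser.
#' @param grunt_rate_slope Increase in grunt probability per rank step.
#' @param end_conflict_prob_after_grunt Probability that a grunt ends the
#'   conflict (default 400/413, the observed proportion).
#' @param latency_end_median_s,latency_end_sdlog Lognormal family for the
#'   grunt-to-end-of-conflict latency (median 1.3 s).
#' @param latency_cont_median_s,latency_cont_sdlog Lognormal family for the
#'   grunt-to-continued-aggression latency (median 6.8 s).
#' @param minfreq_intercept_hz,minfreq_slope_hz_per_rank Linear model of the
#'   signature mean minimum frequency on rank position.
#' @param signature_means Named vector of herd-level means for the remaining
#'   signature parameters (`duration_s`, `peak_freq_hz`, `bandwidth_hz`,
#'   `hnr_db`).
#' @param between_individual_sd,within_individual_sd Named vectors of
#'   between-individual (signature) and within-individual (call-to-call)
#'   standard deviations for `duration_s`, `peak_freq_hz`, `min_freq_hz`,
#'   `bandwidth_hz`, `hnr_db`.
#' @param sample_rate_hz Sampling rate for synthesised audio.
#' @param seed Master seed.
#' @return A list of class `herd_config`.
#' @export
herd_config <- function(n_individuals = 19,
                        sex_labels = NULL,
                        true_rank = seq_len(n_individuals),
                        steepness_k = 0.9,
                        grunt_base_prob = 0,
                        grunt_rate_slope = 0.025,
                        end_conflict_prob_after_grunt = 400 / 413,
                        latency_end_median_s = 1.3,
                        latency_end_sdlog = 0.45,
                        latency_cont_median_s = 6.8,
                        latency_cont_sdlog = 0.6,
                        minfreq_intercept_hz = 330,
                        minfreq_slope_hz_per_rank = 5,
                        signature_means = c(duration_s = 0.10,
                                            peak_freq_hz = 800,
                                            bandwidth_hz = 1650,
                                            hnr_db = 28),
                        between_individual_sd = c(duration_s = 0.035,
                                                  peak_freq_hz = 150,
                                                  min_freq_hz = 25,
                                                  bandwidth_hz = 300,
                                                  hnr_db = 4),
                        within_individual_sd = c(duration_s = 0.05,
                                                 peak_freq_hz = 400,
                                                 min_freq_hz = 110,
                                                 bandwidth_hz = 600,
                                                 hnr_db = 12),
                        sample_rate_hz = 48000,
                        seed = 1) {
  if (!is_count(n_individuals) || n_individuals < 3)
    stopf("n_individuals must be an integer >= 3 (hierarchy statistics are undefined below a triad)")
  n <- as.integer(n_individuals)
  if (is.null(sex_labels))
    sex_labels <- rep(rep(c("M", "F"), c(9, 10)), length.out = n)
  if (length(sex_labels) != n || !all(sex_labels %in% c("M", "F")))
    stopf("sex_labels must be %d values in {M, F}", n)
  if (!setequal(true_rank, seq_len(n)))
    stopf("true_rank must be a permutation of 1..%d", n)
  if (!(is.numeric(steepness_k) && steepness_k > 0))
    stopf("steepness_k must be > 0")
  assert_prob(grunt_base_prob, "grunt_base_prob")
  assert_prob(end_conflict_prob_after_grunt, "end_conflict_prob_after_grunt")
  if (any(between_individual_sd < 0) || any(within_individual_sd < 0))
    stopf("standard deviations must be >= 0")
  structure(list(
    n_individuals = n, sex_labels = sex_labels,
    true_rank = as.integer(true_rank),
    steepness_k = steepness_k,
    grunt_base_prob = grunt_base_prob,
    grunt_rate_slope = grunt_rate_slope,
    end_conflict_prob_after_grunt = end_conflict_prob_after_grunt,
    latency_end_median_s = latency_end_median_s,
    latency_end_sdlog = latency_end_sdlog,
    latency_cont_median_s = latency_cont_median_s,
    latency_cont_sdlog = latency_cont_sdlog,
    minfreq_intercept_hz = minfreq_intercept_hz,
    minfreq_slope_hz_per_rank = minfreq_slope_hz_per_rank,
    signature_means = signature_means,
    between_individual_sd = between_individual_sd,
    within_individual_sd = within_individual_sd,
    sample_rate_hz = sample_rate_hz, seed = seed),
    class = "herd_config")
}

#' Generate a synthetic herd
#'
#' Draws one herd from a [herd_config()]: individual IDs, sexes, true ranks,
#' and a per-individual acoustic signature. The signature mean minimum
#' frequency follows `minfreq_intercept_hz + minfreq_slope_hz_per_rank *
#' rank` plus between-individual noise, so higher rank numbers (lower
#' status) have higher-pitched grunts; the other signature parameters vary
#' around their herd means with the configured between-individual SDs.
#'
#' @param config A [herd_config()].
#' @return Data frame of class `herd_spec`, one row per individual: `id`,
#'   `sex`, `rank`, and signature columns `duration_s`, `peak_freq_hz`,
#'   `min_freq_hz`, `bandwidth_hz`, `hnr_db`. The config is attached as
#'   attribute `"config"`.
#' @export
generate_herd <- function(config = herd_config()) {
  stopifnot(inherits(config, "herd_config"))
  n <- config$n_individuals
  bsd <- config$between_individual_sd
  sm <- config$signature_means
  herd <- with_seed(config$seed, {
    data.frame(
      id = sprintf("ind%02d", seq_len(n)),
      sex = config$sex_labels,
      rank = config$true_rank,
      duration_s = pmax(0.03, rnorm(n, sm["duration_s"], bsd["duration_s"])),
      peak_freq_hz = pmax(200, rnorm(n, sm["peak_freq_hz"],
                                     bsd["peak_freq_hz"])),
      min_freq_hz = pmax(60, config$minfreq_intercept_hz +
                           config$minfreq_slope_hz_per_rank *
                           config$true_rank +
                           rnorm(n, 0, bsd["min_freq_hz"])),
      bandwidth_hz = pmax(300, rnorm(n, sm["bandwidth_hz"],
                                     bsd["bandwidth_hz"])),
      hnr_db = rnorm(n, sm["hnr_db"], bsd["hnr_db"]))
  })
  herd$peak_freq_hz <- pmin(pmax(herd$peak_freq_hz, herd$min_freq_hz + 50),
                            herd$min_freq_hz + herd$bandwidth_hz - 50)
  attr(herd, "config") <- config
  class(herd) <- c("herd_spec", "data.frame")
  herd
}

#' Simulate agonistic interactions in a herd
#'
#' Dyads are sampled uniformly; the higher-ranked member wins with
#' probability `plogis(steepness_k * rank_gap)`. The loser emits a grunt
#' with probability `grunt_base_prob + grunt_rate_slope * (rank - 1)`
#' (clamped to `[0, 1]`), so with the default zero base the top-ranked
#' animal never grunts and lower-ranked animals grunt more. After a grunt
#' the conflict ends with probability `end_conflict_prob_after_grunt`,
#' otherwise aggression continues; latencies come from two lognormal
#' families (short for ending, long for continuing).
#'
#' @param herd A [generate_herd()] result.
#' @param n_interactions Number of interactions (default 1880).
#' @param seed Integer seed.
#' @return Data frame, one row per interaction: `interaction_id`,
#'   `aggressor`, `victim`, `winner`, `grunt_emitted`, `grunt_caller`,
#'   `outcome`, `latency_s`.
#' @export
simulate_interactions <- function(herd, n_interactions = 1880, seed = 1) {
  config <- attr(herd, "config")
  if (is.null(config)) stopf("herd must come from generate_herd()")
  if (!is_count(n_interactions) || n_interactions < 1)
    stopf("n_interactions must be >= 1")
  n <- nrow(herd)
  with_seed(seed, {
    a <- sample.int(n, n_interactions, replace = TRUE)
    b <- (a - 1L + sample.int(n - 1L, n_interactions, replace = TRUE)) %% n + 1L
    rank_a <- herd$rank[a]
    rank_b <- herd$rank[b]
    hi <- ifelse(rank_a < rank_b, a, b)   # lower rank number = higher status
    lo <- ifelse(rank_a < rank_b, b, a)
    p_hi_wins <- stats::plogis(config$steepness_k * abs(rank_a - rank_b))
    hi_wins <- runif(n_interactions) < p_hi_wins
    winner <- ifelse(hi_wins, hi, lo)
    loser <- ifelse(hi_wins, lo, hi)
    p_grunt <- pmin(1, pmax(0, config$grunt_base_prob +
                              config$grunt_rate_slope *
                              (herd$rank[loser] - 1)))
    grunt <- runif(n_interactions) < p_grunt
    ends <- runif(n_interactions) < config$end_conflict_prob_after_grunt
    outcome <- ifelse(!grunt, "end_conflict",
                      ifelse(ends, "end_conflict", "aggression_continued"))
    latency <- rep(NA_real_, n_interactions)
    i_end <- which(grunt & ends)
    i_cont <- which(grunt & !ends)
    latency[i_end] <- rlnorm(length(i_end), log(config$latency_end_median_s),
                             config$latency_end_sdlog)
    latency[i_cont] <- rlnorm(length(i_cont),
                              log(config$latency_cont_median_s),
                              config$latency_cont_sdlog)
    data.frame(
      interaction_id = seq_len(n_interactions),
      aggressor = herd$id[a], victim = herd$id[b],
      winner = herd$id[winner],
      grunt_emitted = grunt,
      grunt_caller = ifelse(grunt, herd$id[loser], NA_character_),
      outcome = outcome,
      latency_s = ifelse(grunt, latency, NA_real_))
  })
}

#' Simulate a per-call acoustic feature table
#'
#' Draws calls directly on the feature scale (no audio synthesis): each call
#' is the caller's signature plus within-individual Gaussian noise, expanded
#' into the twelve measured parameters with the centre/mean pairing
#' structure of automatic measurements (centre values are noisy copies of
#' the call's underlying value, so centre/mean pairs are strongly
#' collinear, as in real measurement output).
#'
#' @param herd A [generate_herd()] result.
#' @param calls_per_individual Calls per animal (default 50). The top-ranked
#'   individual can be excluded with `skip_top_rank = TRUE` to emulate an
#'   alpha that never grunts.
#' @param seed Integer seed.
#' @param skip_top_rank Exclude the rank-1 animal (default FALSE).
#' @param centre_noise_frac SD of the centre-vs-mean measurement noise as a
#'   fraction of the within-individual SD (default 0.2).
#' @return Feature table: `caller`, `sex`, `rank` plus the 12 acoustic
#'   parameter columns used by [preprocess_features()] and [fit_dfa()].
#' @export
simulate_feature_table <- function(herd, calls_per_individual = 50, seed = 1,
                                   skip_top_rank = FALSE,
                                   centre_noise_frac = 0.2) {
  config <- attr(herd, "config")
  if (is.null(config)) stopf("herd must come from generate_herd()")
  wsd <- config$within_individual_sd
  callers <- if (skip_top_rank) herd[herd$rank > 1, , drop = FALSE] else herd
  m <- calls_per_individual
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(callers)), function(i) {
      sig <- callers[i, ]
      dur <- pmax(0.025, rnorm(m, sig$duration_s, wsd["duration_s"]))
      minf <- pmax(60, rnorm(m, sig$min_freq_hz, wsd["min_freq_hz"]))
      bw <- pmax(200, rnorm(m, sig$bandwidth_hz, wsd["bandwidth_hz"]))
      peak <- pmin(pmax(rnorm(m, sig$peak_freq_hz, wsd["peak_freq_hz"]),
                        minf + 1), minf + bw - 1)
      hnr <- rnorm(m, sig$hnr_db, wsd["hnr_db"])
      ent <- pmin(0.98, pmax(0.05,
                             rnorm(m, 0.75 - 0.004 * (hnr - 28), 0.08)))
      cn <- function(x, s) x + rnorm(m, 0, centre_noise_frac * s)
      minf_c <- pmax(60, cn(minf, wsd["min_freq_hz"]))
      bw_c <- pmax(200, cn(bw, wsd["bandwidth_hz"]))
      data.frame(
        caller = sig$id, sex = sig$sex, rank = sig$rank,
        duration_s = dur,
        peak_freq_centre_hz = pmin(pmax(cn(peak, wsd["peak_freq_hz"]),
                                        minf_c + 1), minf_c + bw_c - 1),
        peak_freq_mean_hz = peak,
        min_freq_centre_hz = minf_c,
        min_freq_mean_hz = minf,
        max_freq_centre_hz = minf_c + bw_c,
        max_freq_mean_hz = minf + bw,
        bandwidth_centre_hz = bw_c,
        bandwidth_mean_hz = bw,
        entropy_centre = pmin(0.98, pmax(0.02, cn(ent, 0.08))),
        entropy_mean = ent,
        hnr_centre_db = hnr)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Synthesise one grunt element
#'
#' Builds a short, noisy, low-frequency call: a harmonic stack with
#' fundamental at the signature's minimum frequency under a band-limited
#' spectral envelope (flat across the signature band, with a gain bump at
#' the peak frequency), mixed with spectrum-shaped noise so that the
#' harmonic-to-noise power ratio matches `hnr_db`. The amplitude envelope
#' has a fast attack; samples are returned in `[-1, 1]`.
#'
#' Because the call is a harmonic stack, the spectral peak is realised at
#' the harmonic nearest the requested peak frequency; the realised value is
#' attached as attribute `"realised_peak_hz"` and is the reference for
#' round-trip checks against [measure_element()].
#'
#' @param signature List or one-row data frame with `min_freq_hz`,
#'   `peak_freq_hz`, `bandwidth_hz`, `hnr_db`.
#' @param duration_s Element duration in seconds, `0 <` duration `<= 2`.
#' @param sample_rate_hz Sampling rate (default 48000).
#' @param seed Integer seed.
#' @param bump_gain_db Spectral gain at the peak frequency relative to the
#'   band floor (default 6).
#' @return Numeric waveform vector.
#' @export
synthesize_grunt <- function(signature, duration_s = 0.1,
                             sample_rate_hz = 48000, seed = 1,
                             bump_gain_db = 6) {
  if (!(duration_s > 0 && duration_s <= 2))
    stopf("duration_s must be in (0, 2]")
  f_lo <- signature$min_freq_hz
  f_hi <- signature$min_freq_hz + signature$bandwidth_hz
  nyq <- sample_rate_hz / 2
  if (!(f_lo > 0 && f_hi < nyq))
    stopf("signature band [%g, %g] must lie inside (0, %g) Hz",
          f_lo, f_hi, nyq)
  f_pk <- min(max(signature$peak_freq_hz, f_lo), f_hi)
  # the spectral peak is realised on the harmonic grid of the fundamental
  grid <- seq(f_lo, f_hi, by = f_lo)
  f_pk <- grid[which.min(abs(grid - f_pk))]
  n <- as.integer(round(duration_s * sample_rate_hz))
  env_gain <- function(f) {
    in_band <- f >= f_lo - 1e-9 & f <= f_hi + 1e-9
    g <- ifelse(in_band, 1, 0)
    g * (1 + (10^(bump_gain_db / 20) - 1) * exp(-(f - f_pk)^2 / (2 * 100^2)))
  }
  with_seed(seed, {
    t <- (seq_len(n) - 1) / sample_rate_hz
    harmonics <- seq(f_lo, f_hi, by = f_lo)
    amps <- env_gain(harmonics)
    harm <- rowSums(vapply(seq_along(harmonics), function(k) {
      amps[k] * sin(2 * pi * harmonics[k] * t + runif(1, 0, 2 * pi))
    }, numeric(n)))
    # spectrum-shaped noise built in the frequency domain
    nf <- nextn(n, 2)
    freqs <- (0:(nf / 2)) * sample_rate_hz / nf
    gains <- env_gain(freqs)
    half <- complex(real = rnorm(nf / 2 + 1), imaginary = rnorm(nf / 2 + 1)) *
      gains
    half[1] <- 0
    half[nf / 2 + 1] <- complex(real = Re(half[nf / 2 + 1]), imaginary = 0)
    spec <- c(half, Conj(rev(half[2:(nf / 2)])))
    noise <- Re(fft(spec, inverse = TRUE))[seq_len(n)] / nf
    p_h <- mean(harm^2)
    p_n <- mean(noise^2)
    ratio <- 10^(signature$hnr_db / 10)
    if (is.infinite(ratio)) {
      x <- harm
    } else if (ratio <= 0) {
      x <- noise
    } else {
      x <- harm + noise * sqrt(p_h / (p_n * ratio))
    }
    attack <- min(n, as.integer(0.003 * sample_rate_hz))
    release <- min(n, as.integer(0.004 * sample_rate_hz))
    env <- rep(1, n)
    env[seq_len(attack)] <- (1 - cos(pi * seq_len(attack) / attack)) / 2
    env[n - seq_len(release) + 1] <-
      (1 - cos(pi * seq_len(release) / release)) / 2
    x <- x * env
    structure(0.9 * x / max(abs(x)), realised_peak_hz = f_pk)
  })
}

#' Concatenate grunt elements into a bout
#'
#' @param elements List of waveform vectors.
#' @param gap_s Silent gaps between consecutive elements, in seconds
#'   (length `length(elements) - 1`); all gaps must be positive, elements
#'   may not overlap.
#' @param sample_rate_hz Sampling rate.
#' @return One waveform: elements separated by silence.
#' @export
render_bout <- function(elements, gap_s, sample_rate_hz = 48000) {
  if (!length(elements)) stopf("need at least one element")
  if (length(gap_s) != length(elements) - 1)
    stopf("need %d gaps for %d elements", length(elements) - 1,
          length(elements))
  if (any(gap_s <= 0)) stopf("elements may not overlap: all gaps must be > 0")
  pieces <- list(elements[[1]])
  for (i in seq_along(gap_s)) {
    pieces <- c(pieces,
                list(rep(0, as.integer(round(gap_s[i] * sample_rate_hz))),
                     elements[[i + 1]]))
  }
  unlist(pieces, use.names = FALSE)
}

#' Sample bout sizes
#'
#' Element counts per bout follow 1 + Poisson(`lambda`), truncated to
#' `[1, 20]`; the default `lambda = 2.5` puts the mode at 3 elements.
#'
#' @param n Number of bouts.
#' @param seed Integer seed.
#' @param lambda Poisson mean of the shifted count.
#' @return Integer vector of element counts.
#' @export
sample_bout_sizes <- function(n, seed = 1, lambda = 2.5) {
  with_seed(seed, pmin(20L, pmax(1L, 1L + stats::rpois(n, lambda))))
}

#' Write a synthetic dataset to disk
#'
#' Produces the on-disk form of a study dataset: an interaction log CSV, an
#' annotation CSV mapping each audio file to its caller, sex, rank and bout,
#' and one mono 16-bit PCM WAV file per bout. Outputs are byte-stable given
#' the same herd and seed.
#'
#' @param herd A [generate_herd()] result.
#' @param dir Output directory (created if needed).
#' @param n_interactions Interactions to simulate (default 1880).
#' @param bouts_per_individual WAV bouts rendered per individual (default 2;
#'   the rank-1 animal is skipped, emulating an alpha that never grunts).
#' @param seed Integer seed.
#' @return List with paths: `interactions_csv`, `annotations_csv`,
#'   `wav_files`.
#' @export
write_dataset <- function(herd, dir, n_interactions = 1880,
                          bouts_per_individual = 2, seed = 1) {
  config <- attr(herd, "config")
  if (is.null(config)) stopf("herd must come from generate_herd()")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(seed, 3)
  ints <- simulate_interactions(herd, n_interactions, seed = seeds[1])
  int_path <- file.path(dir, "interactions.csv")
  write.csv(ints, int_path, row.names = FALSE)
  callers <- herd[herd$rank > 1, , drop = FALSE]
  n_bouts <- nrow(callers) * bouts_per_individual
  sizes <- sample_bout_sizes(n_bouts, seed = seeds[2])
  bout_seeds <- derive_seeds(seeds[3], n_bouts * 22L)
  ann <- list()
  wavs <- character(0)
  b <- 0L
  for (i in seq_len(nrow(callers))) {
    for (k in seq_len(bouts_per_individual)) {
      b <- b + 1L
      sz <- sizes[b]
      es <- lapply(seq_len(sz), function(e) {
        synthesize_grunt(callers[i, ], duration_s = callers$duration_s[i],
                         sample_rate_hz = config$sample_rate_hz,
                         seed = bout_seeds[(b - 1L) * 22L + e])
      })
      gaps <- with_seed(bout_seeds[(b - 1L) * 22L + 21L],
                        runif(max(0, sz - 1), 0.08, 0.3))
      bout <- render_bout(es, gaps, config$sample_rate_hz)
      bout_id <- sprintf("bout%03d", b)
      path <- file.path(dir, paste0(bout_id, ".wav"))
      write_wav(bout, path, config$sample_rate_hz)
      wavs <- c(wavs, path)
      ann[[b]] <- data.frame(file = basename(path), bout_id = bout_id,
                             caller = callers$id[i], sex = callers$sex[i],
                             rank = callers$rank[i], n_elements = sz)
    }
  }
  ann_path <- file.path(dir, "annotations.csv")
  write.csv(do.call(rbind, ann), ann_path, row.names = FALSE)
  list(interactions_csv = int_path, annotations_csv = ann_path,
       wav_files = wavs)
}
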