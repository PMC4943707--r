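cfg <- spectrogram_config()

test_that("spectrogram settings derive the documented resolutions", {
  expect_equal(cfg$frequency_resolution_hz, 46.875)
  expect_equal(cfg$time_step_s, 128 / 48000)
  expect_error(spectrogram_config(overlap = 1), "overlap")
})

test_that("amplitude normalisation is a pure gain to -1 dBFS", {
  x <- 0.1 * sin(2 * pi * 440 * (0:4799) / 48000)
  y <- normalize_amplitude(x)
  expect_equal(max(abs(y)), 10^(-1 / 20))
  # idempotence and linearity
  expect_equal(normalize_amplitude(y), y)
  nz <- x != 0
  expect_equal(y[nz] / x[nz], rep(y[2] / x[2], sum(nz)))
  expect_error(normalize_amplitude(rep(0, 100)), "all-zero")
})

test_that("band-pass keeps the pass band and kills the stop band", {
  t <- (0:47999) / 48000
  stop_tone <- sin(2 * pi * 10000 * t)
  out <- bandpass(stop_tone)
  expect_lt(sqrt(mean(out^2)) / sqrt(mean(stop_tone^2)), 0.01)

  pass_tone <- sin(2 * pi * 400 * t)
  outp <- bandpass(pass_tone)
  expect_equal(sqrt(mean(outp^2)), sqrt(mean(pass_tone^2)), tolerance = 0.12)

  expect_error(bandpass(pass_tone, low_hz = 0), "Nyquist")
  expect_error(bandpass(pass_tone, low_hz = 500, high_hz = 400), "Nyquist")
})

test_that("element detection separates, merges and times bursts correctly", {
  b <- lapply(1:3, function(s) make_burst(0.08, seed = s))
  w3 <- normalize_amplitude(place_bursts(b, c(0.1, 0.1)))
  segs <- detect_elements(w3, cfg)
  expect_equal(nrow(segs), 3)
  # durations within two envelope frames of the constructed 80 ms
  expect_true(all(abs(segs$duration_s - 0.08) <= 2 * cfg$time_step_s))

  # a 30 ms gap is below the 50 ms hold time: one merged element
  w2 <- normalize_amplitude(place_bursts(b[1:2], 0.03))
  expect_equal(nrow(detect_elements(w2, cfg)), 1)
  # and survives as two elements when the hold time is shortened
  expect_equal(nrow(detect_elements(w2, cfg, hold_time_s = 0.02)), 2)

  expect_equal(nrow(detect_elements(rep(0, 48000) + 1e-15, cfg)), 1)
})

test_that("a pure tone measures at its frequency with near-zero entropy", {
  tone <- normalize_amplitude(sin(2 * pi * 1000 * (0:47999) / 48000))
  seg <- detect_elements(tone, cfg)[1, ]
  row <- measure_element(tone, seg, cfg)
  expect_lt(abs(row$peak_freq_centre_hz - 1000), 47)
  expect_lt(abs(row$peak_freq_mean_hz - 1000), 47)
  expect_identical(round(row$entropy_centre), 0)
  expect_gt(row$hnr_centre_db, 30)
})

test_that("spectral measurements are invariant under uniform gain", {
  sig <- list(min_freq_hz = 400, peak_freq_hz = 900, bandwidth_hz = 1400,
              hnr_db = 15)
  w <- synthesize_grunt(sig, 0.1, seed = 4)
  seg <- list(start_s = 0, end_s = 0.1)
  a <- measure_element(w, seg, cfg)
  b <- measure_element(0.05 * w, seg, cfg)
  spectral <- c("peak_freq_centre_hz", "peak_freq_mean_hz",
                "min_freq_mean_hz", "max_freq_mean_hz", "bandwidth_mean_hz",
                "entropy_centre", "entropy_mean", "hnr_centre_db")
  expect_equal(a[spectral], b[spectral])
})

test_that("frequency ordering and entropy bounds hold on every measured row", {
  herd <- generate_herd(herd_config(seed = 5))
  rows <- lapply(2:6, function(i) {
    w <- synthesize_grunt(herd[i, ], herd$duration_s[i], seed = i)
    measure_recording(w)
  })
  tab <- do.call(rbind, rows)
  expect_true(all(tab$min_freq_mean_hz <= tab$peak_freq_mean_hz + 1e-9))
  expect_true(all(tab$peak_freq_mean_hz <= tab$max_freq_mean_hz + 1e-9))
  expect_true(all(tab$entropy_mean >= 0 & tab$entropy_mean <= 1))
  expect_true(all(tab$bandwidth_mean_hz >= 0))
})

test_that("HNR tracks an analytic harmonic-plus-noise mixture", {
  # 1% relative noise power: r = 0.99 so HNR = 10*log10(0.99/0.01) ~ 20 dB
  t <- (0:23999) / 48000
  harm <- sqrt(2) * sin(2 * pi * 300 * t)   # unit power
  noise <- withr::with_seed(8, rnorm(length(t), sd = 0.1))
  w <- normalize_amplitude(harm + noise)
  row <- measure_element(w, list(start_s = 0, end_s = 0.5), cfg)
  expect_equal(row$hnr_centre_db, 20, tolerance = 3 / 20)

  # monotone decrease as generator noise weight rises
  sig <- function(h) list(min_freq_hz = 350, peak_freq_hz = 700,
                          bandwidth_hz = 1400, hnr_db = h)
  hn <- vapply(c(25, 10, -5), function(h) {
    w <- synthesize_grunt(sig(h), 0.1, seed = 9)
    measure_element(normalize_amplitude(w),
                    list(start_s = 0, end_s = 0.1), cfg)$hnr_centre_db
  }, numeric(1))
  expect_true(all(diff(hn) < 0))
})

test_that("segments shorter than one analysis frame are rejected", {
  w <- make_burst(0.5)
  expect_error(measure_element(w, list(start_s = 0, end_s = 0.01), cfg),
               "frame")
})

test_that("bout summaries count elements and durations", {
  segs <- data.frame(bout_id = c("b1", "b1", "b1", "b2", "b3", "b3", "b3"),
                     start_s = c(0, 0.2, 0.4, 0, 0, 0.1, 0.2),
                     end_s = c(0.1, 0.3, 0.5, 0.08, 0.05, 0.15, 0.25))
  s <- summarize_bouts(segs)
  expect_equal(s$per_bout$n_elements, c(3L, 1L, 3L))
  expect_equal(s$per_bout$duration_s, c(0.5, 0.08, 0.25))
  expect_identical(s$mode_elements, 3L)
})

test_that("WAV files round-trip within 16-bit quantisation", {
  x <- make_burst(0.05, seed = 3) / 3
  p <- tempfile(fileext = ".wav")
  write_wav(x, p, 48000)
  back <- read_wav(p)
  expect_identical(back$sample_rate_hz, 48000L)
  expect_lt(max(abs(back$samples - x)), 1 / 32768)
  unlink(p)
})
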