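#' Spectrogram analysis settings
#'
#' Settings of the automatic measurement: 1024-point FFT, 87.5% overlap,
#' Hamming window at 48 kHz, giving a frequency resolution of
#' `sample_rate / fft_size` (46.875 Hz) and a time step of
#' `fft_size * (1 - overlap) / sample_rate` (about 2.67 ms).
#'
#' @param fft_size FFT length in samples (default 1024).
#' @param overlap Fractional window overlap (default 0.875).
#' @param window Window type, currently `"hamming"`.
#' @param sample_rate_hz Sampling rate in Hz (default 48000).
#' @return A list of class `spectrogram_config` with the settings plus the
#'   derived `frequency_resolution_hz`, `time_step_s` and `hop` (samples).
#' @export
spectrogram_config <- function(fft_size = 1024, overlap = 0.875,
                               window = "hamming", sample_rate_hz = 48000) {
  if (overlap <= 0 || overlap >= 1) stopf("overlap must be in (0, 1)")
  hop <- as.integer(round(fft_size * (1 - overlap)))
  if (hop < 1) stopf("overlap too high for this fft_size")
  structure(list(fft_size = as.integer(fft_size), overlap = overlap,
                 window = window, sample_rate_hz = sample_rate_hz,
                 hop = hop,
                 frequency_resolution_hz = sample_rate_hz / fft_size,
                 time_step_s = hop / sample_rate_hz),
            class = "spectrogram_config")
}

#' Normalise a waveform to a target peak amplitude
#'
#' Pure gain: scales the signal so its peak absolute sample sits at
#' `target_peak_db` dBFS (default -1 dB, i.e. `10^(-1/20)` of full scale).
#'
#' @param waveform Numeric sample vector.
#' @param target_peak_db Target peak in dB re full scale (default -1).
#' @return Scaled waveform.
#' @export
normalize_amplitude <- function(waveform, target_peak_db = -1) {
  peak <- max(abs(waveform))
  if (peak == 0) stopf("cannot normalise an all-zero signal")
  waveform * 10^(target_peak_db / 20) / peak
}

#' Band-pass filter a recording
#'
#' Retains the band `low_hz`-`high_hz` (default 30 Hz - 8 kHz, the range of
#' grunt energy) to standardise recordings and remove out-of-band background
#' noise. Uses a zero-phase third-order Butterworth high-pass at the low
#' edge combined with a zero-phase 511-tap windowed-sinc FIR low-pass at the
#' high edge, giving over 40 dB of stop-band attenuation with in-band gain
#' within 1 dB.
#'
#' @param waveform Numeric sample vector.
#' @param low_hz,high_hz Band edges, `0 < low < high < Nyquist`.
#' @param sample_rate_hz Sampling rate in Hz.
#' @return Filtered waveform of the same length.
#' @export
bandpass <- function(waveform, low_hz = 30, high_hz = 8000,
                     sample_rate_hz = 48000) {
  nyq <- sample_rate_hz / 2
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq))
    stopf("need 0 < low_hz < high_hz < Nyquist (%g Hz)", nyq)
  hp <- signal::butter(3, low_hz / nyq, type = "high")
  x <- signal::filtfilt(hp, waveform)
  b <- as.numeric(signal::fir1(510, high_hz / nyq, type = "low"))
  # linear-phase FIR: apply causally and remove the (N-1)/2 group delay
  delay <- (length(b) - 1) / 2
  y <- signal::fftfilt(b, c(x, rep(0, delay)))
  y[(delay + 1):(delay + length(x))]
}

# magnitude spectrogram: rows = frequency bins (0..Nyquist), cols = frames;
# frame k covers samples (k-1)*hop + 1 .. (k-1)*hop + fft_size
stft_mag <- function(waveform, config) {
  n <- config$fft_size
  hop <- config$hop
  if (length(waveform) < n) return(NULL)
  n_frames <- 1L + (length(waveform) - n) %/% hop
  win <- signal::hamming(n)
  nb <- n %/% 2L + 1L
  mag <- matrix(0, nb, n_frames)
  for (k in seq_len(n_frames)) {
    seg <- waveform[(k - 1L) * hop + seq_len(n)]
    sp <- fft(seg * win)
    mag[, k] <- Mod(sp[seq_len(nb)])
  }
  list(mag = mag,
       freq = (seq_len(nb) - 1L) * config$sample_rate_hz / n,
       frame_centre_s = ((seq_len(n_frames) - 1L) * hop + n / 2) /
         config$sample_rate_hz)
}

#' Detect grunt elements by amplitude hysteresis
#'
#' Computes an RMS energy envelope on short frames (one spectrogram time
#' step each) in dB relative to the recording peak, then applies two-
#' threshold hysteresis: an element opens when the envelope rises above
#' `threshold_start_db` and closes when it falls below `threshold_stop_db`.
#' Elements separated by gaps shorter than `hold_time_s` are merged, so a
#' brief dip inside a call does not split it.
#'
#' @param waveform Numeric sample vector (normalise first; thresholds are
#'   relative to the recording's own peak envelope).
#' @param config A [spectrogram_config()].
#' @param threshold_start_db Opening threshold in dB re peak (default -9).
#' @param threshold_stop_db Closing threshold in dB re peak (default -10).
#' @param hold_time_s Minimum silent gap that separates elements
#'   (default 0.050 s).
#' @return Data frame with one row per element: `start_s`, `end_s`,
#'   `duration_s`. Zero rows when nothing exceeds the threshold.
#' @export
detect_elements <- function(waveform, config = spectrogram_config(),
                            threshold_start_db = -9,
                            threshold_stop_db = -10, hold_time_s = 0.050) {
  if (threshold_stop_db > threshold_start_db)
    stopf("stop threshold must not exceed start threshold")
  hop <- config$hop
  fs <- config$sample_rate_hz
  n_frames <- length(waveform) %/% hop
  if (n_frames == 0) return(data.frame(start_s = numeric(0),
                                       end_s = numeric(0),
                                       duration_s = numeric(0)))
  rms <- sqrt(colMeans(matrix(waveform[seq_len(n_frames * hop)]^2,
                              nrow = hop)))
  ref <- max(rms)
  if (ref == 0) return(data.frame(start_s = numeric(0), end_s = numeric(0),
                                  duration_s = numeric(0)))
  db <- 20 * log10(pmax(rms / ref, 1e-12))
  open <- FALSE
  starts <- integer(0); ends <- integer(0)
  for (k in seq_len(n_frames)) {
    if (!open && db[k] > threshold_start_db) {
      open <- TRUE
      starts <- c(starts, k)
    } else if (open && db[k] < threshold_stop_db) {
      open <- FALSE
      ends <- c(ends, k - 1L)
    }
  }
  if (open) ends <- c(ends, n_frames)
  if (!length(starts)) return(data.frame(start_s = numeric(0),
                                         end_s = numeric(0),
                                         duration_s = numeric(0)))
  # merge elements separated by less than the hold time
  keep_s <- starts[1]; keep_e <- ends[1]
  ms <- integer(0); me <- integer(0)
  if (length(starts) > 1) {
    for (i in 2:length(starts)) {
      gap_s <- (starts[i] - 1L - keep_e[length(keep_e)]) * hop / fs
      if (gap_s < hold_time_s) {
        keep_e[length(keep_e)] <- ends[i]
      } else {
        keep_s <- c(keep_s, starts[i]); keep_e <- c(keep_e, ends[i])
      }
    }
  }
  data.frame(start_s = (keep_s - 1L) * hop / fs,
             end_s = keep_e * hop / fs,
             duration_s = (keep_e - keep_s + 1L) * hop / fs)
}

# normalized Shannon entropy of one power spectrum: 0 pure tone, 1 flat
spectral_entropy <- function(mag) {
  p <- mag^2
  tot <- sum(p)
  if (tot <= 0) return(NA_real_)
  p <- p / tot
  p <- p[p > 0]
  -sum(p * log(p)) / log(length(mag))
}

# harmonic-to-noise ratio from the highest non-zero-lag normalized
# autocorrelation peak of a window centred on `centre_sample`
hnr_autocorr <- function(waveform, centre_sample, sample_rate_hz,
                         f0_range_hz = c(50, 1500), window_samples = 4096) {
  half <- window_samples %/% 2
  i0 <- max(1L, centre_sample - half)
  i1 <- min(length(waveform), centre_sample + half)
  x <- waveform[i0:i1]
  x <- x - mean(x)
  n <- length(x)
  lag_min <- max(2L, floor(sample_rate_hz / f0_range_hz[2]))
  lag_max <- min(n - 2L, ceiling(sample_rate_hz / f0_range_hz[1]))
  if (lag_max <= lag_min) return(NA_real_)
  # normalized autocorrelation via FFT, scaled per-lag to unit energy
  nfft <- nextn(2L * n, 2)
  sp <- fft(c(x, rep(0, nfft - n)))
  ac <- Re(fft(sp * Conj(sp), inverse = TRUE)) / nfft
  lags <- lag_min:lag_max
  # energy normalisation: r(k) = ac(k) / sqrt(E[1:n-k] * E[k+1:n])
  csum <- cumsum(x^2)
  e_head <- csum[n - lags]
  e_tail <- csum[n] - csum[lags]
  r <- ac[lags + 1L] / sqrt(pmax(e_head * e_tail, 1e-300))
  r_peak <- max(r)
  r_peak <- min(max(r_peak, 1e-6), 1 - 1e-6)
  10 * log10(r_peak / (1 - r_peak))
}

#' Measure the acoustic parameters of one element
#'
#' Computes the twelve parameters of a detected element from its short-time
#' spectra: duration, and peak/minimum/maximum frequency, bandwidth and
#' spectral entropy each at the centre of the call and as the mean over all
#' frames, plus the harmonic-to-noise ratio at the centre. Per frame, the
#' peak frequency is the bin of maximum magnitude and the minimum/maximum
#' frequencies are the lowest/highest bins whose magnitude lies within
#' `threshold_start_db` of that frame's peak; bandwidth is their difference.
#' Entropy is normalised Shannon spectral entropy (0 for a pure tone, 1 for
#' flat noise). HNR is `10 log10(r / (1 - r))` with `r` the height of the
#' highest non-zero-lag normalized autocorrelation peak at the call centre.
#' All spectral measures are invariant under uniform gain.
#'
#' @param waveform Full recording (numeric samples).
#' @param segment One row of [detect_elements()] output (or any list with
#'   `start_s` and `end_s`).
#' @param config A [spectrogram_config()].
#' @param threshold_start_db Amplitude threshold (dB re frame peak) defining
#'   the measured frequency extent (default -9).
#' @return One-row data frame with `duration_s`, `peak_freq_centre_hz`,
#'   `peak_freq_mean_hz`, `min_freq_centre_hz`, `min_freq_mean_hz`,
#'   `max_freq_centre_hz`, `max_freq_mean_hz`, `bandwidth_centre_hz`,
#'   `bandwidth_mean_hz`, `entropy_centre`, `entropy_mean`, `hnr_centre_db`.
#' @export
measure_element <- function(waveform, segment,
                            config = spectrogram_config(),
                            threshold_start_db = -9) {
  fs <- config$sample_rate_hz
  i0 <- max(1L, 1L + as.integer(round(segment$start_s * fs)))
  i1 <- min(length(waveform), as.integer(round(segment$end_s * fs)))
  if (i1 < i0) stopf("segment outside waveform")
  seg <- waveform[i0:i1]
  if (length(seg) < config$fft_size)
    stopf("segment shorter than one analysis frame (%d samples)",
          config$fft_size)
  st <- stft_mag(seg, config)
  thr <- 10^(threshold_start_db / 20)
  per_frame <- function(mag) {
    jpk <- which.max(mag)
    above <- which(mag >= mag[jpk] * thr)
    c(peak = st$freq[jpk],
      min = st$freq[min(above)],
      max = st$freq[max(above)],
      entropy = spectral_entropy(mag))
  }
  vals <- apply(st$mag, 2, per_frame)
  centre_t <- (segment$end_s - segment$start_s) / 2
  kc <- which.min(abs(st$frame_centre_s - centre_t))
  centre_sample <- as.integer(round((i0 + i1) / 2))
  hnr <- hnr_autocorr(waveform, centre_sample, fs)
  data.frame(
    duration_s = segment$end_s - segment$start_s,
    peak_freq_centre_hz = vals["peak", kc],
    peak_freq_mean_hz = mean(vals["peak", ]),
    min_freq_centre_hz = vals["min", kc],
    min_freq_mean_hz = mean(vals["min", ]),
    max_freq_centre_hz = vals["max", kc],
    max_freq_mean_hz = mean(vals["max", ]),
    bandwidth_centre_hz = vals["max", kc] - vals["min", kc],
    bandwidth_mean_hz = mean(vals["max", ] - vals["min", ]),
    entropy_centre = vals["entropy", kc],
    entropy_mean = mean(vals["entropy", ]),
    hnr_centre_db = hnr)
}

#' Detect and measure every element in a recording
#'
#' Convenience wrapper: normalises, detects elements, and measures each one,
#' attaching any annotation columns (caller, sex, rank, bout id).
#'
#' @inheritParams detect_elements
#' @param annotation Optional single-row data frame (or list) of metadata
#'   replicated onto every element row.
#' @param normalize Normalise the waveform to -1 dBFS first (default TRUE).
#' @return Feature table: one row per detected element.
#' @export
measure_recording <- function(waveform, config = spectrogram_config(),
                              annotation = NULL, normalize = TRUE,
                              threshold_start_db = -9,
                              threshold_stop_db = -10, hold_time_s = 0.050) {
  if (normalize) waveform <- normalize_amplitude(waveform)
  segs <- detect_elements(waveform, config, threshold_start_db,
                          threshold_stop_db, hold_time_s)
  if (!nrow(segs)) return(NULL)
  rows <- lapply(seq_len(nrow(segs)), function(i) {
    row <- measure_element(waveform, segs[i, ], config, threshold_start_db)
    cbind(row, segs[i, c("start_s", "end_s")], row.names = NULL)
  })
  out <- do.call(rbind, rows)
  if (!is.null(annotation)) out <- cbind(out, as.data.frame(annotation),
                                         row.names = NULL)
  out
}

#' Summarise bouts of elements
#'
#' @param segments Data frame of element segments with a `bout_id` column
#'   and `start_s`/`end_s` times within each bout.
#' @return List with `per_bout` (data frame: `bout_id`, `n_elements`,
#'   `duration_s` = last end minus first start), `mode_elements` (modal
#'   element count; smallest in case of ties), `mean_duration_s` and
#'   `sd_duration_s`.
#' @export
summarize_bouts <- function(segments) {
  if (!nrow(segments)) stopf("need at least one bout")
  per <- do.call(rbind, lapply(split(segments, segments$bout_id), function(b) {
    data.frame(bout_id = b$bout_id[1], n_elements = nrow(b),
               duration_s = max(b$end_s) - min(b$start_s))
  }))
  rownames(per) <- NULL
  tab <- table(per$n_elements)
  mode_n <- as.integer(names(tab)[which.max(tab)])
  list(per_bout = per, mode_elements = mode_n,
       mean_duration_s = mean(per$duration_s),
       sd_duration_s = if (nrow(per) > 1) sd(per$duration_s) else NA_real_)
}
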