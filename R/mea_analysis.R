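# Extracellular multi-electrode array analysis: zero-phase high-pass
# filtering, debounced absolute-threshold event rates, and Welch-style
# spectrograms, plus a seeded generator of spike-like transients on
# LFP-dominated noise.

#' A multi-electrode array recording
#'
#' @param data Channels-by-samples numeric matrix in microvolts.
#' @param sampling_rate Sampling rate in Hz (recordings here use 30 kHz).
#' @param channel_ids Channel labels; default `E1..En`.
#' @return An `mea_recording` object (attribute `filtered` records whether
#'   the high-pass filter has been applied).
#' @export
mea_recording <- function(data, sampling_rate, channel_ids = NULL) {
  stopifnot(is.matrix(data), is.numeric(data), sampling_rate > 0)
  if (!all(is.finite(data))) stop("MEA samples must be finite")
  if (is.null(channel_ids)) channel_ids <- paste0("E", seq_len(nrow(data)))
  stopifnot(length(channel_ids) == nrow(data))
  rownames(data) <- channel_ids
  structure(list(data = data, sampling_rate = sampling_rate,
                 channel_ids = channel_ids),
            class = "mea_recording", filtered = FALSE)
}

#' Zero-phase high-pass filter
#'
#' 4th-order Butterworth applied forward and backward (zero phase), which
#' removes DC and the low-frequency field-potential components so that
#' spike-like waveforms can be thresholded.
#'
#' @param rec An [mea_recording()].
#' @param cutoff Cutoff frequency in Hz (default 300); must be below
#'   Nyquist.
#' @return Filtered [mea_recording()] with attribute `filtered = TRUE`.
#' @export
mea_highpass <- function(rec, cutoff = 300) {
  stopifnot(inherits(rec, "mea_recording"))
  nyq <- rec$sampling_rate / 2
  if (cutoff >= nyq) stop("cutoff must be below the Nyquist frequency (",
                          nyq, " Hz)")
  bf <- signal::butter(4, cutoff / nyq, type = "high")
  out <- rec
  for (ch in seq_len(nrow(rec$data))) {
    out$data[ch, ] <- signal::filtfilt(bf, rec$data[ch, ])
  }
  attr(out, "filtered") <- TRUE
  out
}

#' Per-channel thresholded event rates
#'
#' Counts debounced excursions of the absolute signal above the threshold
#' (one event per excursion; excursions closer than the debounce interval
#' are merged) and divides by the recording duration.
#'
#' @param rec A high-passed [mea_recording()].
#' @param threshold Threshold in microvolts (default 40), applied to
#'   `|signal|`.
#' @param debounce_ms Minimum separation between counted events in ms.
#' @param require_filtered Refuse unfiltered input (default TRUE); pass
#'   FALSE to override for already-filtered external data.
#' @return List with `rates` (named events/s per channel), `counts`,
#'   `event_times` (per channel, s), `threshold`, `duration`.
#' @export
mea_event_rate <- function(rec, threshold = 40, debounce_ms = 1,
                           require_filtered = TRUE) {
  stopifnot(inherits(rec, "mea_recording"), threshold > 0)
  if (require_filtered && !isTRUE(attr(rec, "filtered"))) {
    stop("recording has not been high-pass filtered; run mea_highpass() ",
         "first or set require_filtered = FALSE")
  }
  fs <- rec$sampling_rate
  duration <- ncol(rec$data) / fs
  min_gap <- round(debounce_ms / 1000 * fs)
  event_times <- vector("list", nrow(rec$data))
  names(event_times) <- rec$channel_ids
  for (ch in seq_len(nrow(rec$data))) {
    above <- abs(rec$data[ch, ]) > threshold
    onsets <- which(diff(c(FALSE, above)) == 1L)
    if (length(onsets) > 1L) {
      kept <- onsets[1]
      for (i in onsets[-1]) {
        if (i - kept[length(kept)] >= min_gap) kept <- c(kept, i)
      }
      onsets <- kept
    }
    event_times[[ch]] <- (onsets - 1L) / fs
  }
  counts <- vapply(event_times, length, integer(1))
  list(rates = counts / duration, counts = counts,
       event_times = event_times, threshold = threshold,
       duration = duration)
}

#' Per-channel spectrogram (short-time power spectral density)
#'
#' Hann-windowed, overlap-averaged one-sided PSD per time window, scaled so
#' that integrating the PSD over frequency recovers the signal power
#' (Parseval, up to windowing tolerance).
#'
#' @param rec An [mea_recording()].
#' @param window Window length in seconds (default 0.2).
#' @param overlap Window overlap fraction in `[0, 1)` (default 0.5).
#' @return List with `power` (list per channel of frequency-by-time PSD
#'   matrices, units uV^2/Hz), `frequencies` (Hz), `times` (window centers,
#'   s), `window`, `overlap`.
#' @export
mea_spectrogram <- function(rec, window = 0.2, overlap = 0.5) {
  stopifnot(inherits(rec, "mea_recording"), overlap >= 0, overlap < 1)
  fs <- rec$sampling_rate
  nwin <- round(window * fs)
  if (nwin < 16L) stop("window too short: need window * sampling_rate >= 16")
  step <- max(1L, round(nwin * (1 - overlap)))
  n <- ncol(rec$data)
  starts <- seq(1L, n - nwin + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nwin) - 1) / (nwin - 1))  # Hann
  scale <- 1 / (fs * sum(w^2))
  nfreq <- nwin %/% 2 + 1L
  freqs <- (seq_len(nfreq) - 1L) * fs / nwin
  power <- vector("list", nrow(rec$data))
  names(power) <- rec$channel_ids
  for (ch in seq_len(nrow(rec$data))) {
    p <- matrix(0, nfreq, length(starts))
    for (j in seq_along(starts)) {
      seg <- rec$data[ch, starts[j]:(starts[j] + nwin - 1L)] * w
      sp <- abs(stats::fft(seg)[seq_len(nfreq)])^2 * scale
      # one-sided: double everything except DC (and Nyquist when nwin even)
      sp[-1] <- sp[-1] * 2
      if (nwin %% 2 == 0) sp[nfreq] <- sp[nfreq] / 2
      p[, j] <- sp
    }
    power[[ch]] <- p
  }
  list(power = power, frequencies = freqs,
       times = (starts - 1L + nwin / 2) / fs,
       window = window, overlap = overlap)
}

#' Simulate a multi-electrode array recording with known event times
#'
#' Per channel, events are drawn as a homogeneous Poisson train and
#' convolved with a biphasic 1 ms spike kernel of the given peak amplitude.
#' Noise emulates extracellular recordings, where slow local-field
#' components dominate: colored low-frequency noise carries most of the
#' noise power (this is what the 300 Hz high-pass is for) plus a smaller
#' broadband thermal component. Total noise SD equals `noise_sd`.
#'
#' @param n_channels Number of channels (default 16).
#' @param duration Recording length in s.
#' @param event_rate Mean event rate per channel in events/s.
#' @param event_amp Peak absolute amplitude of the spike kernel in uV.
#' @param noise_sd Total noise SD in uV.
#' @param sampling_rate Hz (default 30000).
#' @param broadband_frac Fraction of noise SD in the broadband component
#'   (default 0.25).
#' @param seed Integer seed (mandatory).
#' @return List with `recording` (unfiltered [mea_recording()]) and
#'   `event_times` (list per channel of true event times in s).
#' @export
simulate_mea <- function(n_channels = 16, duration = 60, event_rate = 2.5,
                         event_amp = 120, noise_sd = 10,
                         sampling_rate = 30000, broadband_frac = 0.25,
                         seed) {
  stopifnot(n_channels >= 1, duration > 0, event_rate >= 0, event_amp >= 0,
            broadband_frac >= 0, broadband_frac <= 1)
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  n <- round(duration * sampling_rate)
  # biphasic 1 ms kernel: negative-going main phase then positive rebound
  nk <- round(0.001 * sampling_rate)
  tk <- seq_len(nk) / nk
  kern <- -sin(2 * pi * tk) * exp(-2 * tk)
  kern <- kern / max(abs(kern)) * event_amp
  lfp_sd <- noise_sd * sqrt(1 - broadband_frac^2)
  bb_sd <- noise_sd * broadband_frac
  lp <- signal::butter(2, 100 / (sampling_rate / 2), type = "low")
  data <- matrix(0, n_channels, n)
  event_times <- vector("list", n_channels)
  for (ch in seq_len(n_channels)) {
    n_ev <- stats::rpois(1, event_rate * duration)
    # keep events off the very edges so every waveform is fully contained
    ev_t <- sort(stats::runif(n_ev, 0.01, duration - 0.01))
    x <- numeric(n)
    idx <- round(ev_t * sampling_rate)
    for (i in idx) x[i:(i + nk - 1L)] <- x[i:(i + nk - 1L)] + kern
    if (lfp_sd > 0) {
      slow <- signal::filtfilt(lp, stats::rnorm(n))
      slow <- slow / stats::sd(slow) * lfp_sd
      x <- x + slow
    }
    if (bb_sd > 0) x <- x + stats::rnorm(n, 0, bb_sd)
    data[ch, ] <- x
    event_times[[ch]] <- ev_t
  }
  rec <- mea_recording(data, sampling_rate)
  names(event_times) <- rec$channel_ids
  list(recording = rec, event_times = event_times)
}
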