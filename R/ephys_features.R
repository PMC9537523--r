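# Per-spike and per-cell intrinsic electrophysiology features.
#
# Feature definitions: spike threshold at 5% of the maximum rising-phase
# dV/dt (the upstroke); amplitude = peak - threshold; width at half-height
# with linear interpolation between samples; trough searched within five
# spike widths after threshold; AHP = trough - threshold. Rheobase is the
# first depolarizing sweep with a spike in the first 500 ms of the step.
# Input resistance from a linear fit of maximum deflection vs current; tau
# from a single-exponential fit over the 10-100% segment of the deflection;
# capacitance = mean tau / Rin. Sag ratio (Vpeak - Vsteady)/(Vpeak - Vbase)
# averaged over the two sweeps with Vpeak closest to -100 mV.

#' Spike detection settings
#'
#' @param dvdt_threshold Onset criterion on dV/dt in mV/ms (default 20).
#' @param min_peak Minimum peak voltage in mV for a deflection to count as a
#'   spike (default -20).
#' @param refractory_ms Minimum separation between accepted peaks in ms.
#' @param smooth_samples Width of an optional boxcar smoother (in samples)
#'   applied to the trace before differentiation; 0 disables it. At 50 kHz
#'   the derivative is usually clean enough unsmoothed.
#' @return A `spike_detect_config` object.
#' @export
spike_detect_config <- function(dvdt_threshold = 20, min_peak = -20,
                                refractory_ms = 1, smooth_samples = 0) {
  stopifnot(dvdt_threshold > 0, refractory_ms >= 0, smooth_samples >= 0)
  structure(list(dvdt_threshold = dvdt_threshold, min_peak = min_peak,
                 refractory_ms = refractory_ms,
                 smooth_samples = as.integer(smooth_samples)),
            class = "spike_detect_config")
}

boxcar <- function(x, w) {
  if (w <= 1L) return(x)
  y <- as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
  miss <- is.na(y)
  y[miss] <- x[miss]
  y
}

# Centered running mean with shrinking windows at the edges (no NA, no
# reintroduced raw noise at the trace ends). Used for noise-robust
# extremum location; features themselves are measured on the raw trace.
runmean <- function(x, w) {
  if (w <= 1L) return(x)
  n <- length(x)
  half <- w %/% 2
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# window (samples) of the extremum-location smoother: 2 ms
smooth_win <- function(rate) max(1L, round(0.002 * rate))

# dV/dt by central differences, in mV/ms.
dvdt_mv_per_ms <- function(v, sampling_rate) {
  n <- length(v)
  d <- numeric(n)
  dt_ms <- 1000 / sampling_rate
  d[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (2 * dt_ms)
  d[1] <- (v[2] - v[1]) / dt_ms
  d[n] <- (v[n] - v[n - 1]) / dt_ms
  d
}

#' Detect action potential peaks in a sweep
#'
#' A spike is a local maximum above `min_peak` whose preceding 2 ms contain
#' a dV/dt excursion of at least `dvdt_threshold`. Accepted peaks are at
#' least the refractory setting apart; detection is restricted to the
#' stimulus epoch.
#'
#' @param sw A [sweep()].
#' @param config A [spike_detect_config()].
#' @return Numeric vector of peak times in seconds (possibly empty), ordered.
#' @export
detect_spikes <- function(sw, config = spike_detect_config()) {
  stopifnot(inherits(sw, "sweep"))
  v <- sw$voltage
  if (config$smooth_samples > 1L) v <- boxcar(v, config$smooth_samples)
  rate <- sw$sampling_rate
  t <- sweep_times(sw)
  d <- dvdt_mv_per_ms(v, rate)
  ep <- sw$epoch
  in_epoch <- t >= ep$onset & t < ep$onset + ep$duration
  n <- length(v)
  is_max <- c(FALSE, v[2:(n - 1)] >= v[1:(n - 2)] & v[2:(n - 1)] > v[3:n], FALSE)
  cand <- which(is_max & v >= config$min_peak & in_epoch)
  if (!length(cand)) return(numeric(0))
  look_back <- max(1L, round(0.002 * rate))
  keep <- logical(length(cand))
  for (j in seq_along(cand)) {
    i <- cand[j]
    lo <- max(1L, i - look_back)
    keep[j] <- max(d[lo:i]) >= config$dvdt_threshold
  }
  cand <- cand[keep]
  if (!length(cand)) return(numeric(0))
  refrac_s <- config$refractory_ms / 1000
  accepted <- cand[1]
  if (length(cand) > 1L) {
    for (i in cand[-1]) {
      if (t[i] - t[accepted[length(accepted)]] >= refrac_s) {
        accepted <- c(accepted, i)
      }
    }
  }
  t[accepted]
}

linear_crossing <- function(t1, v1, t2, v2, level) {
  if (v2 == v1) return(t1)
  t1 + (level - v1) / (v2 - v1) * (t2 - t1)
}

#' Waveform features of one detected spike
#'
#' @param sw A [sweep()].
#' @param peak_t Peak time (s) of a detected spike.
#' @param config A [spike_detect_config()] (used for the derivative
#'   estimator settings).
#' @param prev_peak_t Peak time of the preceding spike, if any; limits the
#'   backward search for the threshold.
#' @return A list of class `spike_features`: `threshold_t`, `threshold_v`,
#'   `peak_t`, `peak_v`, `upstroke` (mV/ms), `amplitude` (mV), `width` (ms),
#'   `trough_t`, `trough_v`, `ahp` (mV), and `reliable` (FALSE when the
#'   trough search window ran past the end of the trace, in which case
#'   trough and AHP are `NA`).
#' @export
spike_waveform_features <- function(sw, peak_t, config = spike_detect_config(),
                                    prev_peak_t = NULL) {
  v <- sw$voltage
  if (config$smooth_samples > 1L) v <- boxcar(v, config$smooth_samples)
  rate <- sw$sampling_rate
  t <- sweep_times(sw)
  d <- dvdt_mv_per_ms(v, rate)
  peak_i <- which.min(abs(t - peak_t))
  ep <- sw$epoch
  back_limit <- max(1, floor(ep$onset * rate))
  if (!is.null(prev_peak_t)) {
    back_limit <- max(back_limit, which.min(abs(t - prev_peak_t)) + 1L)
  }
  back_limit <- max(back_limit, peak_i - round(0.010 * rate))  # <= 10 ms
  seg <- back_limit:peak_i
  up_i <- seg[which.max(d[seg])]
  upstroke <- d[up_i]
  cut <- 0.05 * upstroke
  # walk back from the upstroke sample along the contiguous rise; the
  # threshold is the first sample at which dV/dt reaches 5% of the upstroke
  th_i <- up_i
  for (i in rev(back_limit:up_i)) {
    if (d[i] < cut) break
    th_i <- i
  }
  threshold_v <- v[th_i]
  threshold_t <- t[th_i]
  amplitude <- v[peak_i] - threshold_v
  half <- threshold_v + amplitude / 2
  # rising half-height crossing
  ri <- th_i
  while (ri < peak_i && v[ri + 1] < half) ri <- ri + 1L
  t_rise <- linear_crossing(t[ri], v[ri], t[ri + 1], v[ri + 1], half)
  # falling half-height crossing
  fi <- peak_i
  n <- length(v)
  while (fi < n && v[fi] > half) fi <- fi + 1L
  if (fi >= n) {
    width <- NA_real_
  } else {
    t_fall <- linear_crossing(t[fi - 1], v[fi - 1], t[fi], v[fi], half)
    width <- (t_fall - t_rise) * 1000
  }
  out <- list(threshold_t = threshold_t, threshold_v = threshold_v,
              peak_t = t[peak_i], peak_v = v[peak_i], upstroke = upstroke,
              amplitude = amplitude, width = width,
              trough_t = NA_real_, trough_v = NA_real_, ahp = NA_real_,
              reliable = TRUE)
  if (is.na(width)) {
    out$reliable <- FALSE
    class(out) <- "spike_features"
    return(out)
  }
  # trough within five spike widths after the threshold
  trough_end <- threshold_t + 5 * width / 1000
  end_i <- floor(trough_end * rate) + 1L
  if (end_i > n) {
    out$reliable <- FALSE
  } else {
    win <- (peak_i + 1L):end_i
    ti <- win[which.min(v[win])]
    out$trough_t <- t[ti]
    out$trough_v <- v[ti]
    out$ahp <- v[ti] - threshold_v
  }
  class(out) <- "spike_features"
  out
}

hyperpolarizing_sweeps <- function(rec) {
  rec$sweeps[recording_amplitudes(rec) < 0]
}

depolarizing_sweeps <- function(rec) {
  rec$sweeps[recording_amplitudes(rec) > 0]
}

baseline_voltage <- function(sw, baseline_window) {
  rate <- sw$sampling_rate
  onset_i <- floor(sw$epoch$onset * rate)
  from_i <- max(1L, onset_i - round(baseline_window * rate) + 1L)
  if (onset_i < 1L) return(sw$voltage[1])
  mean(sw$voltage[from_i:onset_i])
}

#' Find the rheobase sweep of a recording
#'
#' The rheobase is the smallest depolarizing step that elicits at least one
#' action potential whose peak lies within 500 ms of the step onset.
#'
#' @param rec A [recording()].
#' @param config A [spike_detect_config()].
#' @param window Spike-search window after onset in s (default 0.5).
#' @return List with `status` (`"ok"` or `"no_rheobase"`), `index` (sweep
#'   index), `amplitude` (pA), and `spikes` (peak times of the rheobase
#'   sweep). For non-firing cells only `status` is informative.
#' @export
find_rheobase <- function(rec, config = spike_detect_config(), window = 0.5) {
  for (sw in depolarizing_sweeps(rec)) {
    st <- detect_spikes(sw, config)
    onset <- sw$epoch$onset
    if (any(st >= onset & st <= onset + window)) {
      return(list(status = "ok", index = sw$index,
                  amplitude = sw$epoch$amplitude, spikes = st))
    }
  }
  list(status = "no_rheobase", index = NA_integer_, amplitude = NA_real_,
       spikes = numeric(0))
}

# First-spike latency of one sweep in ms (threshold crossing of the first
# spike relative to step onset); NA when the sweep has no spikes.
first_spike_latency_ms <- function(sw, config = spike_detect_config()) {
  st <- detect_spikes(sw, config)
  if (!length(st)) return(NA_real_)
  sf <- spike_waveform_features(sw, st[1], config)
  (sf$threshold_t - sw$epoch$onset) * 1000
}

#' First-spike latency at rheobase + 5 pA
#'
#' If the protocol contains a sweep at exactly rheobase + 5 pA, its
#' first-spike latency is returned. Otherwise (10 pA steps) the latency is
#' linearly interpolated over current between the two sweeps bracketing the
#' target. No extrapolation is attempted.
#'
#' @param rec A [recording()].
#' @param config A [spike_detect_config()].
#' @return List with `latency` (ms, or `NA`) and `reason` (`"ok"`,
#'   `"exact"`, `"interpolated"`, `"no_rheobase"`, or `"no_bracket"`).
#' @export
latency_at_rheo_plus5 <- function(rec, config = spike_detect_config()) {
  rb <- find_rheobase(rec, config)
  if (rb$status != "ok") {
    return(list(latency = NA_real_, reason = "no_rheobase"))
  }
  target <- rb$amplitude + 5
  deps <- depolarizing_sweeps(rec)
  amps <- vapply(deps, function(s) s$epoch$amplitude, numeric(1))
  lat <- vapply(deps, first_spike_latency_ms, numeric(1), config = config)
  ok <- !is.na(lat)
  exact <- which(ok & abs(amps - target) < 1e-9)
  if (length(exact)) {
    return(list(latency = lat[exact[1]], reason = "exact"))
  }
  below <- which(ok & amps < target)
  above <- which(ok & amps > target)
  if (!length(below) || !length(above)) {
    return(list(latency = NA_real_, reason = "no_bracket"))
  }
  i1 <- below[which.max(amps[below])]
  i2 <- above[which.min(amps[above])]
  w <- (target - amps[i1]) / (amps[i2] - amps[i1])
  list(latency = (1 - w) * lat[i1] + w * lat[i2], reason = "interpolated")
}

#' Adaptation index from a sequence of inter-spike intervals
#'
#' Each consecutive ISI pair contributes `(ISI2 - ISI1) / (ISI1 + ISI2)`;
#' only the first two pairwise indices are averaged, so sweeps with
#' different spike counts contribute comparably.
#'
#' @param isis Numeric vector of inter-spike intervals (any time unit).
#' @return Mean of the first two pairwise indices (for exactly two ISIs the
#'   single pairwise index is returned); `NA` for fewer than two ISIs.
#' @export
adaptation_index_from_isis <- function(isis) {
  if (length(isis) < 2L) return(NA_real_)
  idx <- (isis[-1] - isis[-length(isis)]) / (isis[-1] + isis[-length(isis)])
  mean(utils::head(idx, 2))
}

#' Spike-frequency adaptation index of a cell
#'
#' Defined only for cells with at least three suprathreshold sweeps each
#' containing at least four spikes; the per-sweep indices (mean of the
#' first two pairwise ISI indices) of the first three qualifying sweeps are
#' averaged. Cells not meeting the eligibility rule get a missing value —
#' the only feature allowed to be missing downstream.
#'
#' @param rec A [recording()].
#' @param config A [spike_detect_config()].
#' @return List with `value` (unitless or `NA`), `qualifying` (sweep
#'   indices used), and `per_sweep` (per-sweep indices).
#' @export
adaptation_index <- function(rec, config = spike_detect_config()) {
  deps <- depolarizing_sweeps(rec)
  window <- min(1, rec$sweeps[[1]]$epoch$duration)
  sweep_vals <- numeric(0)
  qual <- integer(0)
  for (sw in deps) {
    st <- detect_spikes(sw, config)
    st <- st[st >= sw$epoch$onset & st <= sw$epoch$onset + window]
    if (length(st) >= 4L) {
      sweep_vals <- c(sweep_vals, adaptation_index_from_isis(diff(st)))
      qual <- c(qual, sw$index)
      if (length(qual) == 3L) break
    }
  }
  if (length(qual) < 3L) {
    return(list(value = NA_real_, qualifying = qual, per_sweep = sweep_vals))
  }
  list(value = mean(sweep_vals), qualifying = qual, per_sweep = sweep_vals)
}

#' Slope of the firing-rate vs current (F-I) curve
#'
#' Ordinary least-squares slope of rate against current amplitude, using
#' samples up to and including the first attainment of the maximum rate;
#' later samples (where firing saturates or fails) are excluded. Cells
#' whose maximum firing is a single spike per sweep get a slope of zero.
#'
#' @param samples Data frame with columns `amplitude` (pA), `n_spikes`, and
#'   `rate` (Hz), one row per suprathreshold sweep, any order.
#' @return Slope in Hz/pA.
#' @export
fi_slope <- function(samples) {
  stopifnot(is.data.frame(samples),
            all(c("amplitude", "n_spikes", "rate") %in% names(samples)))
  if (!nrow(samples)) return(NA_real_)
  samples <- samples[order(samples$amplitude), ]
  if (max(samples$n_spikes) <= 1L) return(0)
  i_max <- which.max(samples$rate)
  kept <- samples[seq_len(i_max), ]
  if (nrow(kept) < 2L) return(NA_real_)
  unname(stats::coef(stats::lm(rate ~ amplitude, data = kept))[2])
}

# Fit v(t) = A + B exp(-t/tau) over the 10-100% segment of the deflection
# of one hyperpolarizing sweep. The segment boundaries are located on a
# lightly smoothed trace (noise-robust); the exponential is fitted to the
# raw samples, seeded from the 63% crossing time. Returns tau in ms or NA
# on failure.
fit_sweep_tau <- function(sw, baseline_window) {
  rate <- sw$sampling_rate
  t <- sweep_times(sw)
  ep <- sw$epoch
  vb <- baseline_voltage(sw, baseline_window)
  on <- which(t >= ep$onset & t < ep$onset + ep$duration)
  defl_s <- runmean(sw$voltage[on], smooth_win(rate)) - vb
  i_ext <- which.min(defl_s)  # most negative deflection
  max_defl <- defl_s[i_ext]
  if (max_defl >= 0) return(NA_real_)
  i10 <- which(defl_s <= 0.10 * max_defl)[1]
  if (is.na(i10) || i_ext - i10 < 5L) return(NA_real_)
  seg <- i10:i_ext
  ts_ms <- (t[on][seg] - ep$onset) * 1000
  vs <- sw$voltage[on][seg]
  i63 <- which(defl_s <= 0.632 * max_defl)[1]
  tau0 <- (t[on][i63] - t[on][i10]) * 1000
  if (!is.finite(tau0) || tau0 <= 0) tau0 <- diff(range(ts_ms)) / 3
  fit <- tryCatch(
    minpack.lm::nlsLM(vs ~ A + B * exp(-ts_ms / tau),
                      start = list(A = vb + max_defl, B = -max_defl,
                                   tau = tau0),
                      lower = c(A = -Inf, B = -Inf, tau = 1e-3),
                      upper = c(A = Inf, B = Inf,
                                tau = 20 * max(tau0, diff(range(ts_ms)))),
                      control = minpack.lm::nls.lm.control(maxiter = 200,
                                                           ftol = 1e-10)),
    error = function(e) NULL)
  if (is.null(fit)) return(NA_real_)
  tau <- stats::coef(fit)[["tau"]]
  if (!is.finite(tau) || tau <= 0) NA_real_ else tau
}

#' Passive membrane properties of a cell
#'
#' Input resistance is the slope of the linear fit (with intercept) of the
#' maximum voltage deflection of each hyperpolarizing sweep against the
#' injected current. Tau is the mean of the per-sweep single-exponential
#' fits over the 10-100% deflection segment; sweeps whose fit fails are
#' excluded. Capacitance is mean tau divided by input resistance
#' (`C[pF] = 1000 * tau[ms] / Rin[MOhm]`).
#'
#' @param rec A [recording()].
#' @return List with `input_resistance` (MOhm), `tau` (ms), `capacitance`
#'   (pF), `per_sweep_tau`, and `n_excluded` (tau fits that failed). All
#'   values `NA` when fewer than two hyperpolarizing sweeps are available.
#' @export
passive_properties <- function(rec) {
  hyp <- hyperpolarizing_sweeps(rec)
  if (length(hyp) < 2L) {
    return(list(input_resistance = NA_real_, tau = NA_real_,
                capacitance = NA_real_, per_sweep_tau = numeric(0),
                n_excluded = 0L))
  }
  bw <- rec$baseline_window
  amps <- vapply(hyp, function(s) s$epoch$amplitude, numeric(1))
  defl <- vapply(hyp, function(s) {
    t <- sweep_times(s)
    on <- t >= s$epoch$onset & t < s$epoch$onset + s$epoch$duration
    vsm <- runmean(s$voltage[on], smooth_win(s$sampling_rate))
    min(vsm) - baseline_voltage(s, bw)
  }, numeric(1))
  slope <- unname(stats::coef(stats::lm(defl ~ amps))[2])  # mV/pA = GOhm
  rin <- slope * 1000  # MOhm
  taus <- vapply(hyp, fit_sweep_tau, numeric(1), baseline_window = bw)
  n_excluded <- sum(is.na(taus))
  taus_ok <- taus[!is.na(taus)]
  if (!length(taus_ok) || !is.finite(rin) || rin <= 0) {
    return(list(input_resistance = rin, tau = NA_real_, capacitance = NA_real_,
                per_sweep_tau = taus, n_excluded = n_excluded))
  }
  tau <- mean(taus_ok)
  list(input_resistance = rin, tau = tau,
       capacitance = 1000 * tau / rin,  # ms / MOhm -> nF -> pF
       per_sweep_tau = taus, n_excluded = n_excluded)
}

#' Sag ratio of a cell
#'
#' Per hyperpolarizing sweep, sag = (Vpeak - Vsteady)/(Vpeak - Vbaseline)
#' where Vpeak is the maximum deflection within the first 500 ms of the
#' step and Vsteady the mean over the last 100 ms of the injection. The
#' cell value averages the two sweeps whose Vpeak is closest to -100 mV
#' (ties broken toward the more hyperpolarized sweep; a single
#' hyperpolarizing sweep is used alone).
#'
#' @param rec A [recording()].
#' @return List with `value` and `per_sweep` (data frame: sweep index,
#'   v_baseline, v_peak, v_steady, sag).
#' @export
sag_ratio <- function(rec) {
  hyp <- hyperpolarizing_sweeps(rec)
  if (!length(hyp)) {
    return(list(value = NA_real_, per_sweep = NULL))
  }
  bw <- rec$baseline_window
  rows <- lapply(hyp, function(s) {
    t <- sweep_times(s)
    ep <- s$epoch
    vb <- baseline_voltage(s, bw)
    vsm <- runmean(s$voltage, smooth_win(s$sampling_rate))
    early <- t >= ep$onset & t < ep$onset + min(0.5, ep$duration)
    vp <- min(vsm[early])
    late <- t >= ep$onset + ep$duration - 0.1 & t < ep$onset + ep$duration
    vs <- mean(s$voltage[late])
    sag <- if (abs(vp - vb) < 1e-12) 0 else (vp - vs) / (vp - vb)
    data.frame(sweep_index = s$index, v_baseline = vb, v_peak = vp,
               v_steady = vs, sag = sag)
  })
  per_sweep <- do.call(rbind, rows)
  ord <- order(abs(per_sweep$v_peak + 100), per_sweep$v_peak)
  sel <- utils::head(ord, 2)
  list(value = mean(per_sweep$sag[sel]), per_sweep = per_sweep,
       selected = per_sweep$sweep_index[sel])
}

#' Extract the full per-cell feature vector
#'
#' Orchestrates the feature extractors: the recording is truncated to the
#' first second of the step, then passive, sag, rheobase, spike-shape, F-I
#' and adaptation features are computed. Spike-shape fields come from the
#' first spike of the rheobase sweep. The resting potential is taken from
#' `metadata$rmp_mV` (the I = 0 measurement at break-in) and corrected for
#' the liquid junction potential; it is missing when the metadata lacks it.
#' Non-firing cells keep their passive features and get missing
#' spike-dependent fields plus a `non_firing` flag.
#'
#' @param rec A [recording()].
#' @param config A [spike_detect_config()].
#' @param truncate Clip the analysis to the first second of the step
#'   (default TRUE).
#' @return One-row data frame with the [feature_table_schema()] columns;
#'   attributes `non_firing` (logical) and `diagnostics` (per-sweep sag and
#'   tau, qualifying adaptation sweeps).
#' @export
extract_cell_features <- function(rec, config = spike_detect_config(),
                                  truncate = TRUE) {
  stopifnot(inherits(rec, "recording"))
  if (truncate) rec <- truncate_analysis_window(rec)
  window <- min(1, rec$sweeps[[1]]$epoch$duration)

  pass <- passive_properties(rec)
  sag <- sag_ratio(rec)
  rb <- find_rheobase(rec, config)
  non_firing <- rb$status != "ok"

  rmp <- NA_real_
  if (!is.null(rec$metadata$rmp_mV)) {
    rmp <- apply_ljp_correction(as.numeric(rec$metadata$rmp_mV), rec$ljp)
  }

  rheo_lat <- NA_real_
  lat5 <- list(latency = NA_real_, reason = "no_rheobase")
  adapt <- list(value = NA_real_, qualifying = integer(0))
  slope <- NA_real_
  max_rate <- NA_real_
  sf <- NULL
  if (!non_firing) {
    rheo_sweep <- rec$sweeps[[rb$index]]
    rheo_lat <- first_spike_latency_ms(rheo_sweep, config)
    lat5 <- latency_at_rheo_plus5(rec, config)
    adapt <- adaptation_index(rec, config)
    deps <- depolarizing_sweeps(rec)
    counts <- vapply(deps, function(s) {
      st <- detect_spikes(s, config)
      sum(st >= s$epoch$onset & st <= s$epoch$onset + window)
    }, integer(1))
    amps <- vapply(deps, function(s) s$epoch$amplitude, numeric(1))
    supra <- counts > 0L
    first_supra <- which(supra)[1]
    fi <- data.frame(amplitude = amps, n_spikes = counts,
                     rate = counts / window)[first_supra:length(deps), ]
    slope <- fi_slope(fi)
    max_rate <- max(fi$rate)
    st <- detect_spikes(rheo_sweep, config)
    sf <- spike_waveform_features(rheo_sweep, st[1], config)
  }

  out <- data.frame(
    cell_id = rec$cell_id,
    resting_potential = rmp,
    rheobase = rb$amplitude,
    rheobase_latency = rheo_lat,
    latency_rheo_plus5 = lat5$latency,
    adaptation_index = adapt$value,
    fi_slope = slope,
    max_rate = max_rate,
    input_resistance = pass$input_resistance,
    tau = pass$tau,
    capacitance = pass$capacitance,
    sag_ratio = sag$value,
    threshold_v = if (is.null(sf)) NA_real_ else sf$threshold_v,
    amplitude = if (is.null(sf)) NA_real_ else sf$amplitude,
    width = if (is.null(sf)) NA_real_ else sf$width,
    ahp = if (is.null(sf)) NA_real_ else sf$ahp,
    upstroke = if (is.null(sf)) NA_real_ else sf$upstroke,
    stringsAsFactors = FALSE
  )
  attr(out, "non_firing") <- non_firing
  attr(out, "diagnostics") <- list(
    per_sweep_sag = sag$per_sweep, sag_sweeps_used = sag$selected,
    per_sweep_tau = pass$per_sweep_tau, tau_fits_excluded = pass$n_excluded,
    adaptation_qualifying_sweeps = adapt$qualifying,
    latency_reason = lat5$reason)
  out
}

#' Extract a feature table for a set of recordings
#'
#' @param recordings List of [recording()] objects.
#' @param config A [spike_detect_config()].
#' @param truncate Passed to [extract_cell_features()].
#' @return Data frame, one row per cell, columns per
#'   [feature_table_schema()]; attribute `non_firing` holds the per-cell
#'   flags.
#' @export
extract_feature_table <- function(recordings, config = spike_detect_config(),
                                  truncate = TRUE) {
  rows <- lapply(recordings, extract_cell_features, config = config,
                 truncate = truncate)
  ft <- do.call(rbind, rows)
  rownames(ft) <- NULL
  attr(ft, "non_firing") <- vapply(rows, attr, logical(1), "non_firing")
  ft
}
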