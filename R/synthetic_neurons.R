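# Ground-truth generator for current-clamp recordings.
#
# Cells are adaptive leaky integrate-and-fire neurons with an optional slow
# rebound (h-current caricature) conductance. Passive responses have a
# closed-form solution used as the oracle; spiking sweeps are integrated by
# forward Euler in C++ with a stereotyped waveform stamped at each firing
# threshold crossing so that dV/dt-based detection operates on realistic
# upstrokes.

#' Ground-truth parameters of a simulated neuron
#'
#' @param capacitance Membrane capacitance in pF.
#' @param resistance Input resistance in MOhm. The membrane time constant
#'   is derived as `tau = R * C` (MOhm * pF = us, reported in ms).
#' @param rest Resting potential in mV.
#' @param spike_threshold Firing threshold in mV.
#' @param reset Post-spike reset potential in mV.
#' @param adaptation_increment Adaptation current increment per spike in pA
#'   (0 disables spike-frequency adaptation).
#' @param adaptation_tau Adaptation current decay time constant in ms.
#' @param sag_strength Unitless strength of the slow rebound current. For a
#'   step the steady-state deflection is reduced to `R*I/(1 + sag_strength)`,
#'   so the asymptotic sag ratio is `sag_strength / (1 + sag_strength)`.
#' @param sag_tau Rebound current time constant in ms.
#' @param refractory Absolute refractory period in ms.
#' @param peak_v Stamped spike peak voltage in mV.
#' @param spike_width_scale Multiplier on the stamped waveform's rise/fall
#'   times (1 gives a ~2 ms spike with ~0.6 ms half-height width).
#' @return A `neuron_ground_truth` object; element `tau` holds the derived
#'   membrane time constant in ms.
#' @export
neuron_ground_truth <- function(capacitance, resistance, rest = -65,
                                spike_threshold = -45, reset = -58,
                                adaptation_increment = 0,
                                adaptation_tau = 100,
                                sag_strength = 0, sag_tau = 150,
                                refractory = 3, peak_v = 30,
                                spike_width_scale = 1) {
  stopifnot(capacitance > 0, resistance > 0, adaptation_tau > 0, sag_tau > 0,
            refractory >= 0, spike_width_scale > 0, sag_strength >= 0,
            spike_threshold > rest, reset < spike_threshold)
  tau <- resistance * capacitance / 1000  # MOhm * pF -> us -> ms
  structure(list(capacitance = capacitance, resistance = resistance,
                 tau = tau, rest = rest, spike_threshold = spike_threshold,
                 reset = reset, adaptation_increment = adaptation_increment,
                 adaptation_tau = adaptation_tau, sag_strength = sag_strength,
                 sag_tau = sag_tau, refractory = refractory, peak_v = peak_v,
                 spike_width_scale = spike_width_scale),
            class = "neuron_ground_truth")
}

#' Analytic rheobase of the integrate-and-fire model
#'
#' With adaptation and sag off, a step of amplitude I reaches threshold iff
#' `R * I > threshold - rest`; the minimal current is returned in pA.
#'
#' @param gt A [neuron_ground_truth()].
#' @return Rheobase current in pA.
#' @export
lif_rheobase_analytic <- function(gt) {
  (gt$spike_threshold - gt$rest) / gt$resistance * 1000
}

#' Simulation protocol settings
#'
#' @param sampling_rate Sampling rate in Hz (default 50000, matching typical
#'   current-clamp digitization).
#' @param step_onset Step onset in s from sweep start.
#' @param step_duration Step duration in s (1 or 2).
#' @param amplitudes Step amplitudes in pA; must form a constant-step grid
#'   (conventionally 5 or 10 pA increments).
#' @param tail Post-step trace length in s.
#' @param noise_sd Additive Gaussian measurement noise SD in mV.
#' @param seed Integer seed; mandatory when `noise_sd > 0`.
#' @return A `sim_config` object.
#' @export
sim_config <- function(sampling_rate = 50000, step_onset = 0.2,
                       step_duration = 1, amplitudes = seq(-40, 80, by = 10),
                       tail = 0.1, noise_sd = 0, seed = NULL) {
  stopifnot(sampling_rate > 0, step_onset >= 0, step_duration > 0, tail >= 0)
  amplitudes <- sort(as.numeric(amplitudes))
  if (length(amplitudes) > 2L && diff(range(diff(amplitudes))) > 1e-9) {
    stop("amplitudes must form a constant-step grid")
  }
  if (noise_sd > 0 && is.null(seed)) {
    stop("a seed is mandatory for any noisy simulation")
  }
  structure(list(sampling_rate = sampling_rate, step_onset = step_onset,
                 step_duration = step_duration, amplitudes = amplitudes,
                 tail = tail, noise_sd = noise_sd, seed = seed),
            class = "sim_config")
}

sim_n_samples <- function(cfg) {
  round((cfg$step_onset + cfg$step_duration + cfg$tail) * cfg$sampling_rate)
}

#' Closed-form passive response to a current step
#'
#' During the step the deflection follows
#' `R*I*(1 - exp(-t/tau)) - R*I*s/(1+s)*(1 - exp(-t/tau_sag))`: a fast
#' charging exponential plus, when `sag_strength > 0`, a slower rebound
#' toward the reduced steady state `R*I/(1+s)`. After the step the trace
#' relaxes back to rest with the membrane time constant. Seeded Gaussian
#' noise is added when `cfg$noise_sd > 0`.
#'
#' @param gt A [neuron_ground_truth()].
#' @param amp Step amplitude in pA (hyperpolarizing or subthreshold).
#' @param cfg A [sim_config()].
#' @param index Sweep index to record.
#' @return A [sweep()].
#' @export
simulate_passive_sweep <- function(gt, amp, cfg, index = NA_integer_) {
  n <- sim_n_samples(cfg)
  t <- (seq_len(n) - 1L) / cfg$sampling_rate
  tau_s <- gt$tau / 1000
  sag_tau_s <- gt$sag_tau / 1000
  ri <- amp * gt$resistance / 1000  # pA * MOhm -> uV*? : 1 pA * 1 MOhm = 1e-3 mV
  s <- gt$sag_strength
  v <- rep(gt$rest, n)
  on <- t >= cfg$step_onset & t < cfg$step_onset + cfg$step_duration
  te <- t[on] - cfg$step_onset
  defl <- ri * (1 - exp(-te / tau_s))
  if (s > 0) defl <- defl - ri * s / (1 + s) * (1 - exp(-te / sag_tau_s))
  v[on] <- gt$rest + defl
  off <- t >= cfg$step_onset + cfg$step_duration
  if (any(off)) {
    v_off <- gt$rest + ri * (1 - exp(-cfg$step_duration / tau_s))
    if (s > 0) {
      v_off <- v_off - ri * s / (1 + s) *
        (1 - exp(-cfg$step_duration / sag_tau_s))
    }
    v[off] <- gt$rest + (v_off - gt$rest) *
      exp(-(t[off] - cfg$step_onset - cfg$step_duration) / tau_s)
  }
  if (cfg$noise_sd > 0) v <- v + stats::rnorm(n, 0, cfg$noise_sd)
  sweep(v, cfg$sampling_rate,
        stimulus_epoch(cfg$step_onset, cfg$step_duration, amp), index)
}

# Stereotyped spike waveform stamped at each threshold crossing, sampled at
# dt_ms. Smooth rise (max dV/dt mid-rise), fall to a trough below reset,
# settle back to reset.
spike_stamp <- function(gt, dt_ms) {
  w <- gt$spike_width_scale
  rise_ms <- 0.4 * w
  fall_ms <- 0.8 * w
  settle_ms <- 0.6 * w
  trough_v <- gt$reset - 4
  n_rise <- max(2L, round(rise_ms / dt_ms))
  n_fall <- max(2L, round(fall_ms / dt_ms))
  n_settle <- max(2L, round(settle_ms / dt_ms))
  xr <- seq_len(n_rise) / n_rise
  rise <- gt$spike_threshold +
    (gt$peak_v - gt$spike_threshold) * sin(pi / 2 * xr)^2
  xf <- seq_len(n_fall) / n_fall
  fall <- trough_v + (gt$peak_v - trough_v) * cos(pi / 2 * xf)^2
  xs <- seq_len(n_settle) / n_settle
  settle <- trough_v + (gt$reset - trough_v) * xs
  list(v = c(rise, fall, settle), peak_offset = n_rise)
}

#' Simulate a full square-step protocol on an integrate-and-fire neuron
#'
#' Every sweep of `cfg$amplitudes` is integrated by forward Euler at the
#' sampling rate. Ground truth (per-sweep spike peak times, rheobase under
#' the first-500-ms rule, inter-spike intervals, and F-I spike counts over
#' the first second of the step) is recorded in
#' `metadata$ground_truth` of the returned recording.
#'
#' @param gt A [neuron_ground_truth()].
#' @param cfg A [sim_config()].
#' @param cell_id Cell identifier for the recording.
#' @return A [recording()].
#' @export
simulate_spiking_sweeps <- function(gt, cfg, cell_id = "sim") {
  dt_ms <- 1000 / cfg$sampling_rate
  tau_min <- min(gt$tau, gt$adaptation_tau, gt$sag_tau)
  if (dt_ms >= tau_min / 50) {
    stop("sampling rate too low for stable integration: need dt < ",
         format(tau_min / 50), " ms; increase sampling_rate")
  }
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- sim_n_samples(cfg)
  stamp <- spike_stamp(gt, dt_ms)
  onset_ms <- cfg$step_onset * 1000
  dur_ms <- cfg$step_duration * 1000
  sweeps <- vector("list", length(cfg$amplitudes))
  spike_times <- vector("list", length(cfg$amplitudes))
  for (i in seq_along(cfg$amplitudes)) {
    amp <- cfg$amplitudes[i]
    out <- lif_integrate(n, dt_ms, onset_ms, dur_ms, amp, gt$rest,
                         gt$spike_threshold, gt$reset, gt$resistance, gt$tau,
                         gt$adaptation_increment, gt$adaptation_tau,
                         gt$sag_strength, gt$sag_tau, gt$refractory, stamp$v)
    v <- out$v
    if (cfg$noise_sd > 0) v <- v + stats::rnorm(n, 0, cfg$noise_sd)
    sweeps[[i]] <- sweep(v, cfg$sampling_rate,
                         stimulus_epoch(cfg$step_onset, cfg$step_duration, amp), i)
    spike_times[[i]] <- (out$spike_idx + stamp$peak_offset) / cfg$sampling_rate
  }
  window <- min(1, cfg$step_duration)
  fi <- data.frame(
    amplitude = cfg$amplitudes,
    n_spikes = vapply(spike_times, function(st) {
      sum(st >= cfg$step_onset & st <= cfg$step_onset + window)
    }, integer(1))
  )
  fi$rate <- fi$n_spikes / window
  rheo <- NA_real_
  for (i in seq_along(cfg$amplitudes)) {
    if (cfg$amplitudes[i] > 0 &&
        any(spike_times[[i]] >= cfg$step_onset &
            spike_times[[i]] <= cfg$step_onset + 0.5)) {
      rheo <- cfg$amplitudes[i]
      break
    }
  }
  truth <- list(params = gt, spike_times = spike_times, rheobase = rheo,
                fi = fi,
                isis = lapply(spike_times, function(st) diff(st)))
  recording(cell_id, sweeps, metadata = list(ground_truth = truth))
}

#' Default electrophysiological archetypes for cohort simulation
#'
#' Five archetypes spanning the phenotype space seen in organoid slices:
#' \describe{
#'   \item{immature_high_rin}{very high input resistance, small capacitance,
#'     no adaptation or sag}
#'   \item{adapting_regular}{mature regular-spiking cell: deep resting
#'     potential, low threshold, wide large-amplitude spikes, strong
#'     adaptation, no sag}
#'   \item{ispn_like}{large capacitance, low input resistance, long spike
#'     latency, no sag and no adaptation (striatal projection neuron
#'     signature)}
#'   \item{sag_adapting}{prominent rebound sag and strong adaptation}
#'   \item{small_fast}{small, excitable cell with brief spikes}
#' }
#'
#' @return Named list of [neuron_ground_truth()] objects.
#' @export
default_archetypes <- function() {
  list(
    immature_high_rin = neuron_ground_truth(
      capacitance = 35, resistance = 800, rest = -62, spike_threshold = -38,
      reset = -55, adaptation_increment = 2, sag_strength = 0,
      spike_width_scale = 1.4),
    adapting_regular = neuron_ground_truth(
      capacitance = 100, resistance = 250, rest = -70, spike_threshold = -52,
      reset = -63, adaptation_increment = 18, sag_strength = 0,
      peak_v = 40, spike_width_scale = 1.6),
    ispn_like = neuron_ground_truth(
      capacitance = 150, resistance = 150, rest = -72, spike_threshold = -48,
      reset = -60, adaptation_increment = 0, sag_strength = 0,
      spike_width_scale = 1.1),
    sag_adapting = neuron_ground_truth(
      capacitance = 60, resistance = 500, rest = -64, spike_threshold = -34,
      reset = -52, adaptation_increment = 25, sag_strength = 0.45,
      sag_tau = 120, spike_width_scale = 0.8),
    small_fast = neuron_ground_truth(
      capacitance = 20, resistance = 1000, rest = -68, spike_threshold = -44,
      reset = -62, adaptation_increment = 5, sag_strength = 0.05,
      spike_width_scale = 0.6)
  )
}

# Protocol grid for one cell, mirroring the experimental convention of
# choosing the step size from the input resistance.
protocol_for_cell <- function(gt, n_hyper = 4, top_factor = 2.2,
                              max_sweeps = 30) {
  step <- if (gt$resistance >= 400) 5 else 10
  i_star <- lif_rheobase_analytic(gt)
  top <- ceiling(top_factor * i_star / step) * step
  amps <- seq(-n_hyper * step, top, by = step)
  if (length(amps) > max_sweeps) amps <- amps[seq_len(max_sweeps)]
  amps
}

jitter_ground_truth <- function(gt, cv = 0.08, v_sd = 1.5) {
  neuron_ground_truth(
    capacitance = gt$capacitance * stats::rlnorm(1, 0, cv),
    resistance = gt$resistance * stats::rlnorm(1, 0, cv),
    rest = gt$rest + stats::rnorm(1, 0, v_sd),
    spike_threshold = gt$spike_threshold + stats::rnorm(1, 0, v_sd),
    reset = gt$reset + stats::rnorm(1, 0, v_sd / 2),
    adaptation_increment = gt$adaptation_increment * stats::rlnorm(1, 0, cv),
    adaptation_tau = gt$adaptation_tau,
    sag_strength = gt$sag_strength * stats::rlnorm(1, 0, cv),
    sag_tau = gt$sag_tau,
    refractory = gt$refractory,
    peak_v = gt$peak_v + stats::rnorm(1, 0, v_sd),
    spike_width_scale = gt$spike_width_scale * stats::rlnorm(1, 0, cv / 2)
  )
}

#' Simulate a cohort of neurons drawn from jittered archetypes
#'
#' Each cell receives a protocol whose step size (5 or 10 pA) follows its
#' input resistance and whose depolarizing range covers the analytic
#' rheobase with margin. All randomness flows through `seed`.
#'
#' @param n Number of cells.
#' @param archetypes Named list of [neuron_ground_truth()] archetypes.
#' @param mix Mixing proportions (must sum to 1); default equal.
#' @param sampling_rate Hz; the cohort default of 25000 keeps memory modest
#'   while leaving the 2 ms stamped spikes heavily oversampled.
#' @param noise_sd Measurement noise SD in mV (default 0.3).
#' @param seed Integer seed.
#' @return List with `recordings` (list of [recording()]) and `truth`
#'   (data frame: cell_id, archetype label, ground-truth parameters,
#'   simulated rheobase).
#' @export
simulate_population <- function(n, archetypes = default_archetypes(),
                                mix = NULL, sampling_rate = 25000,
                                noise_sd = 0.3, seed = 1) {
  if (is.null(mix)) mix <- rep(1 / length(archetypes), length(archetypes))
  stopifnot(length(mix) == length(archetypes), abs(sum(mix) - 1) < 1e-9)
  set.seed(seed)
  labels <- sample(names(archetypes), n, replace = TRUE, prob = mix)
  recordings <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    gt <- jitter_ground_truth(archetypes[[labels[i]]])
    amps <- protocol_for_cell(gt)
    cfg <- sim_config(sampling_rate = sampling_rate, amplitudes = amps,
                      noise_sd = noise_sd,
                      seed = sample.int(.Machine$integer.max, 1))
    cell_id <- sprintf("cell_%03d", i)
    rec <- simulate_spiking_sweeps(gt, cfg, cell_id = cell_id)
    rec$metadata$archetype <- labels[i]
    rec$metadata$rmp_mV <- gt$rest
    recordings[[i]] <- rec
    rows[[i]] <- data.frame(
      cell_id = cell_id, archetype = labels[i],
      capacitance = gt$capacitance, resistance = gt$resistance, tau = gt$tau,
      rest = gt$rest, spike_threshold = gt$spike_threshold,
      adaptation_increment = gt$adaptation_increment,
      sag_strength = gt$sag_strength,
      rheobase = rec$metadata$ground_truth$rheobase)
  }
  list(recordings = recordings, truth = do.call(rbind, rows))
}
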