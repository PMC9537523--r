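test_that("spike detection finds stamped spikes and rejects sub-threshold bumps", {
  # flat trace: nothing
  flat <- sweep(rep(-65, 20000), 20000, stimulus_epoch(0.1, 0.8, 20))
  expect_identical(detect_spikes(flat), numeric(0))

  # slow 5 mV bump: below both the dV/dt and the peak criteria
  t <- seq_len(20000) / 20000
  bump <- -65 + 5 * exp(-((t - 0.5) / 0.05)^2)
  bsw <- sweep(bump, 20000, stimulus_epoch(0.1, 0.8, 20))
  expect_identical(detect_spikes(bsw), numeric(0))

  # simulated sweeps: every ground-truth spike recovered within 1 ms
  gt <- neuron_ground_truth(capacitance = 80, resistance = 300,
                            adaptation_increment = 10)
  cfg <- sim_config(sampling_rate = 25000, amplitudes = c(80, 120),
                    noise_sd = 0.3, seed = 4)
  rec <- simulate_spiking_sweeps(gt, cfg)
  for (i in seq_along(rec$sweeps)) {
    truth <- rec$metadata$ground_truth$spike_times[[i]]
    got <- detect_spikes(rec$sweeps[[i]])
    expect_length(got, length(truth))
    expect_lt(max(abs(got - truth)), 1e-3)
  }
})

test_that("spike waveform features match the piecewise-linear closed form", {
  tri <- make_triangle_spike_sweep()
  pk <- detect_spikes(tri$sweep)
  expect_length(pk, 1)
  sf <- spike_waveform_features(tri$sweep, pk)
  expect_equal(sf$threshold_v, tri$v_thr, tolerance = 0.1)
  expect_equal(sf$peak_v, tri$v_peak, tolerance = 0.01)
  expect_equal(sf$amplitude, tri$amplitude, tolerance = 0.15)
  expect_equal(sf$width, tri$width_ms, tolerance = 0.05)
  expect_equal(sf$trough_v, tri$v_trough, tolerance = 0.01)
  expect_equal(sf$ahp, tri$ahp, tolerance = 0.15)
  expect_true(sf$reliable)
  expect_lt(sf$threshold_t, sf$peak_t)
  expect_lte(sf$peak_t, sf$trough_t)

  # constant-slope ramp: threshold lands at the ramp start
  rate <- 50000
  n_base <- 5000
  n_rise <- round(95 / 100 * rate / 1000)  # -65 -> +30 at 100 mV/ms
  n_fall <- round(90 / 50 * rate / 1000)   # +30 -> -60 at -50 mV/ms
  ramp <- c(rep(-65, n_base),
            -65 + seq_len(n_rise) * 100 / rate * 1000,
            30 - seq_len(n_fall) * 50 / rate * 1000,
            rep(-60, 2000))
  rsw <- sweep(ramp, rate, stimulus_epoch(0.05, 0.09, 50))
  pk2 <- detect_spikes(rsw)
  expect_length(pk2, 1)
  sf2 <- spike_waveform_features(rsw, pk2[1])
  t0 <- n_base / rate
  expect_lt(abs(sf2$threshold_t - t0), 3 / rate)
})

test_that("rheobase follows the first-500-ms rule", {
  gt <- neuron_ground_truth(capacitance = 100, resistance = 250)
  cfg <- sim_config(sampling_rate = 20000,
                    amplitudes = seq(-20, 140, by = 10))
  rec <- simulate_spiking_sweeps(gt, cfg)
  rb <- find_rheobase(rec)
  expect_equal(rb$status, "ok")
  expect_equal(rb$amplitude, rec$metadata$ground_truth$rheobase)
  # the analytic LIF threshold current rounded up to the grid, allowing for
  # the 500 ms window (time to threshold diverges just above I*)
  istar <- lif_rheobase_analytic(gt)
  tau_s <- gt$tau / 1000
  t_star <- function(a) -tau_s * log(1 - (gt$spike_threshold - gt$rest) /
                                       (a * gt$resistance / 1000))
  cand <- cfg$amplitudes[cfg$amplitudes > istar]
  expect_equal(rb$amplitude, min(cand[t_star(cand) <= 0.5]))

  # a cell whose only spikes come after 500 ms has no rheobase: build one
  # by placing a single stamped-like spike at 600 ms post-onset
  rate <- 20000
  v <- rep(-65, round(1.2 * rate))
  i0 <- round((0.2 + 0.6) * rate)
  v[i0:(i0 + 20)] <- c(seq(-65, 30, length.out = 11),
                       seq(30, -60, length.out = 10))
  late <- sweep(v, rate, stimulus_epoch(0.2, 1, 20))
  sub <- sweep(rep(-65, round(1.2 * rate)), rate, stimulus_epoch(0.2, 1, 10))
  rec2 <- recording("late", list(sub, late))
  expect_length(detect_spikes(late), 1)  # the spike is detectable...
  rb2 <- find_rheobase(rec2)              # ...but outside the window
  expect_equal(rb2$status, "no_rheobase")
})

test_that("latency at rheobase + 5 pA interpolates over current", {
  gt <- neuron_ground_truth(capacitance = 100, resistance = 250)
  # 10 pA protocol: interpolation between rheobase and rheobase + 10
  cfg10 <- sim_config(sampling_rate = 20000, amplitudes = seq(-20, 140, 10))
  rec10 <- simulate_spiking_sweeps(gt, cfg10)
  rb <- find_rheobase(rec10)
  lat_lo <- organoidkit:::first_spike_latency_ms
  l1 <- lat_lo(rec10$sweeps[[rb$index]])
  l2 <- lat_lo(rec10$sweeps[[rb$index + 1]])
  got <- latency_at_rheo_plus5(rec10)
  expect_equal(got$reason, "interpolated")
  expect_equal(got$latency, (l1 + l2) / 2, tolerance = 1e-9)

  # 5 pA protocol: the rheobase + 5 sweep is used directly
  cfg5 <- sim_config(sampling_rate = 20000, amplitudes = seq(-10, 130, 5))
  rec5 <- simulate_spiking_sweeps(gt, cfg5)
  rb5 <- find_rheobase(rec5)
  got5 <- latency_at_rheo_plus5(rec5)
  expect_equal(got5$reason, "exact")
  expect_equal(got5$latency, lat_lo(rec5$sweeps[[rb5$index + 1]]))

  # no sweep above rheobase: missing, not extrapolated
  top <- rb$amplitude
  cfg_top <- sim_config(sampling_rate = 20000,
                        amplitudes = seq(top - 40, top, 10))
  rec_top <- simulate_spiking_sweeps(gt, cfg_top)
  got_top <- latency_at_rheo_plus5(rec_top)
  expect_true(is.na(got_top$latency))
  expect_equal(got_top$reason, "no_bracket")

  # latency decreases with current and extraction preserves the order
  deps <- Filter(function(s) s$epoch$amplitude >= rb$amplitude,
                 rec10$sweeps)
  lats <- vapply(deps, lat_lo, numeric(1))
  expect_true(all(diff(lats[!is.na(lats)]) < 0))
})

test_that("adaptation index follows the printed formula and eligibility", {
  # direct evaluation of the pairwise formula
  expect_equal(adaptation_index_from_isis(c(100, 100, 100)), 0)
  expect_equal(adaptation_index_from_isis(c(100, 150, 200)),
               mean(c(50 / 250, 50 / 350)), tolerance = 1e-12)
  # antisymmetry and range
  set.seed(8)
  for (i in 1:20) {
    isis <- runif(4, 10, 300)
    a <- adaptation_index_from_isis(isis)
    b <- adaptation_index_from_isis(rev(isis))
    expect_gt(a, -1); expect_lt(a, 1)
    if (length(isis) == 4) {
      # reversing each pair flips each pairwise index's sign
      pair_fwd <- (isis[2] - isis[1]) / (isis[1] + isis[2])
      pair_rev <- (isis[1] - isis[2]) / (isis[1] + isis[2])
      expect_equal(pair_fwd, -pair_rev)
    }
  }

  # eligibility: a non-adapting simulated cell has index ~0; removing
  # sweeps below the 3-qualifying-sweep minimum yields missing
  gt <- neuron_ground_truth(capacitance = 80, resistance = 300,
                            adaptation_increment = 0)
  cfg <- sim_config(sampling_rate = 20000, amplitudes = seq(-20, 160, 10))
  rec <- simulate_spiking_sweeps(gt, cfg)
  ad <- adaptation_index(rec)
  expect_length(ad$qualifying, 3)
  expect_lt(abs(ad$value), 0.02)
  # doubling the adaptation increment increases the index
  gt1 <- neuron_ground_truth(capacitance = 80, resistance = 300,
                             adaptation_increment = 8)
  gt2 <- neuron_ground_truth(capacitance = 80, resistance = 300,
                             adaptation_increment = 16)
  a1 <- adaptation_index(simulate_spiking_sweeps(gt1, cfg))$value
  a2 <- adaptation_index(simulate_spiking_sweeps(gt2, cfg))$value
  expect_gt(a1, 0.01)
  expect_gt(a2, a1)

  # truncate the protocol so fewer than three sweeps have four spikes
  keep <- rec$sweeps[recording_amplitudes(rec) <= rec$metadata$ground_truth$rheobase]
  rec_short <- recording("short", keep)
  expect_true(is.na(adaptation_index(rec_short)$value))
})

test_that("F-I slope matches the closed-form OLS fit with the exclusion rule", {
  s1 <- data.frame(amplitude = c(10, 20, 30), n_spikes = c(2, 4, 6),
                   rate = c(2, 4, 6))
  expect_equal(fi_slope(s1), 0.2, tolerance = 1e-12)
  expect_equal(fi_slope(s1), ols_slope(s1$amplitude, s1$rate))
  # points after the first attainment of the max rate are excluded
  s2 <- data.frame(amplitude = seq(10, 50, 10), n_spikes = c(2, 4, 6, 5, 3),
                   rate = c(2, 4, 6, 5, 3))
  expect_equal(fi_slope(s2), 0.2, tolerance = 1e-12)
  # single-spike-per-sweep cells are assigned zero
  s3 <- data.frame(amplitude = c(10, 20, 30), n_spikes = c(0, 1, 1),
                   rate = c(0, 1, 1))
  expect_equal(fi_slope(s3), 0)
  # randomized: retained-points OLS equals the brute-force slope
  set.seed(5)
  for (i in 1:10) {
    amps <- seq(10, 80, 10)
    rates <- cummax(sample(0:40, 8, replace = TRUE))
    rates[sample(5:8, 2)] <- rates[4]  # force a post-max plateau/decline
    df <- data.frame(amplitude = amps, n_spikes = rates, rate = rates)
    i_max <- which.max(df$rate)
    if (i_max >= 2 && max(rates) > 1) {
      expect_equal(fi_slope(df),
                   ols_slope(amps[1:i_max], df$rate[1:i_max]),
                   tolerance = 1e-10)
    }
  }
})

test_that("passive properties recover closed-form ground truth", {
  # noiseless deflections: Rin = dV/dI exactly
  rec <- make_passive_recording(C = 100, R = 200)
  pp <- passive_properties(rec)
  expect_equal(pp$input_resistance, 200, tolerance = 2e-3)
  expect_equal(pp$tau, 20, tolerance = 1e-3)
  expect_equal(pp$capacitance, 100, tolerance = 3e-3)
  # capacitance identity holds exactly for the emitted values
  expect_equal(pp$capacitance, 1000 * pp$tau / pp$input_resistance,
               tolerance = 1e-12)
  # analytic single-exponential trace recovers its tau
  sw <- rec$sweeps[[1]]
  expect_equal(organoidkit:::fit_sweep_tau(sw, rec$baseline_window), 20,
               tolerance = 1e-3)
  expect_true(is.na(passive_properties(
    recording("one", rec$sweeps[1]))$input_resistance))
})

test_that("sag ratio follows the formula, selection, and invariances", {
  ssw <- make_sag_sweep()  # Vb -70, Vp -100, Vss -90
  rec <- recording("sag", list(ssw))
  sg <- sag_ratio(rec)
  expect_equal(sg$value, 1 / 3, tolerance = 1e-9)
  # invariant to adding a constant to the whole trace
  shifted <- sweep(ssw$voltage + 7, ssw$sampling_rate, ssw$epoch)
  expect_equal(sag_ratio(recording("s", list(shifted)))$value, 1 / 3,
               tolerance = 1e-9)
  # monotone exponential (no rebound): sag 0
  mono <- make_passive_recording(C = 100, R = 200, amps = c(-20, -10))
  expect_lt(abs(sag_ratio(mono)$value), 1e-6)
  # Vsteady == Vbaseline gives sag 1
  one <- make_sag_sweep(v_base = -70, v_peak = -100, v_steady = -70)
  expect_equal(sag_ratio(recording("x", list(one)))$value, 1,
               tolerance = 1e-9)
  # selection: sweeps with Vpeak closest to -100 are used
  s1 <- make_sag_sweep(v_peak = -80, amp = -30)
  s2 <- make_sag_sweep(v_peak = -95, amp = -40)
  s3 <- make_sag_sweep(v_peak = -105, amp = -50)
  rec3 <- recording("sel", list(s1, s2, s3))
  sg3 <- sag_ratio(rec3)
  used_peaks <- sg3$per_sweep$v_peak[match(sg3$selected,
                                           sg3$per_sweep$sweep_index)]
  expect_setequal(round(used_peaks), c(-95, -105))
})

test_that("cell feature extraction is deterministic and flags non-firing cells", {
  gt <- neuron_ground_truth(capacitance = 80, resistance = 300,
                            adaptation_increment = 10, sag_strength = 0.2)
  cfg <- sim_config(sampling_rate = 20000, amplitudes = seq(-40, 160, 10),
                    noise_sd = 0.3, seed = 31)
  rec <- simulate_spiking_sweeps(gt, cfg)
  rec$metadata$rmp_mV <- gt$rest
  f1 <- extract_cell_features(rec)
  f2 <- extract_cell_features(rec)
  expect_identical(f1, f2)
  expect_false(attr(f1, "non_firing"))
  expect_equal(f1$resting_potential, gt$rest - 9.4)
  expect_equal(f1$rheobase, rec$metadata$ground_truth$rheobase)
  expect_equal(f1$capacitance, 1000 * f1$tau / f1$input_resistance,
               tolerance = 1e-12)

  # passive-only cell: passive features present, spike fields missing
  pas <- make_passive_recording(C = 100, R = 200,
                                amps = seq(-40, 40, 10))
  fp <- extract_cell_features(pas)
  expect_true(attr(fp, "non_firing"))
  expect_false(is.na(fp$input_resistance))
  expect_false(is.na(fp$sag_ratio))
  expect_true(is.na(fp$rheobase))
  expect_true(is.na(fp$threshold_v))
})

test_that("voltage-shift equivariance: shifting the trace shifts only voltage features", {
  gt <- neuron_ground_truth(capacitance = 80, resistance = 300,
                            adaptation_increment = 10)
  cfg <- sim_config(sampling_rate = 20000, amplitudes = seq(-40, 160, 10))
  rec <- simulate_spiking_sweeps(gt, cfg)
  shift <- -9.4
  rec_s <- rec
  rec_s$sweeps <- lapply(rec$sweeps, function(s) {
    sweep(s$voltage + shift, s$sampling_rate, s$epoch, s$index)
  })
  f0 <- extract_cell_features(rec)
  fs <- extract_cell_features(rec_s)
  expect_equal(fs$threshold_v, f0$threshold_v + shift, tolerance = 1e-6)
  for (col in c("rheobase", "rheobase_latency", "latency_rheo_plus5",
                "fi_slope", "max_rate", "input_resistance", "tau",
                "capacitance", "sag_ratio", "amplitude", "width", "ahp",
                "upstroke", "adaptation_index")) {
    expect_equal(fs[[col]], f0[[col]], tolerance = 1e-6, label = col)
  }
})
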