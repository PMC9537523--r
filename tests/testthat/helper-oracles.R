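# Independent oracles and small fixture builders shared across tests.

# Closed-form OLS slope, computed directly from the normal equations.
ols_slope <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

# Brute-force O(n^3) average-linkage agglomeration on a distance matrix.
# Returns the merge heights in order. Inter-cluster distance is the mean of
# all cross-pair distances in the ORIGINAL matrix (UPGMA definition,
# weighted by cluster sizes).
bf_average_linkage_heights <- function(d) {
  n <- nrow(d)
  clusters <- lapply(seq_len(n), identity)
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    m <- length(clusters)
    best <- c(NA, NA)
    best_h <- Inf
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        h <- mean(d[clusters[[i]], clusters[[j]]])
        if (h < best_h - 1e-15) {
          best_h <- h
          best <- c(i, j)
        }
      }
    }
    heights <- c(heights, best_h)
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- c(clusters[-best], list(merged))
  }
  heights
}

# Piecewise-linear single-spike sweep with analytically known threshold,
# peak, width, and trough. Baseline -65 mV; slow pre-ramp (1 mV/ms) from
# -65 to v_thr, steep rise (100 mV/ms) to v_peak, fall (-100 mV/ms) to
# v_trough, then flat. Returns the sweep plus the analytic values.
make_triangle_spike_sweep <- function(v_thr = -40, v_peak = 20,
                                      v_trough = -60, rate = 50000) {
  onset <- 0.05
  dt <- 1 / rate
  seg_t <- function(ms) round(ms / 1000 * rate)
  base1 <- rep(-65, seg_t(onset * 1000))
  pre_ms <- (v_thr - (-65)) / 1  # 1 mV/ms
  pre <- -65 + (seq_len(seg_t(pre_ms))) * 1 * dt * 1000
  rise_ms <- (v_peak - v_thr) / 100
  rise <- v_thr + (seq_len(seg_t(rise_ms))) * 100 * dt * 1000
  fall_ms <- (v_peak - v_trough) / 100
  fall <- v_peak - (seq_len(seg_t(fall_ms))) * 100 * dt * 1000
  tail <- rep(v_trough, seg_t(100))
  v <- c(base1, pre, rise, fall, tail)
  dur <- length(v) / rate - onset
  half <- v_thr + (v_peak - v_thr) / 2
  width_ms <- (v_peak - half) / 100 + (v_peak - half) / 100
  list(sweep = sweep(v, rate, stimulus_epoch(onset, dur, 50)),
       v_thr = v_thr, v_peak = v_peak, v_trough = v_trough,
       amplitude = v_peak - v_thr, width_ms = width_ms,
       ahp = v_trough - v_thr)
}

# Hyperpolarizing sweep with piecewise-constant plateaus giving exact
# baseline / peak / steady-state voltages for the sag formula.
make_sag_sweep <- function(v_base = -70, v_peak = -100, v_steady = -90,
                           rate = 10000, amp = -50) {
  onset <- 0.2
  n_base <- round(onset * rate)
  n_dip <- round(0.2 * rate)     # plateau at v_peak inside first 500 ms
  n_mid <- round(0.3 * rate)
  n_steady <- round(0.5 * rate)  # covers the last 100 ms exactly
  v <- c(rep(v_base, n_base), rep(v_peak, n_dip), rep(v_steady, n_mid),
         rep(v_steady, n_steady))
  sweep(v, rate, stimulus_epoch(onset, 1, amp))
}

# Recording of noiseless closed-form passive sweeps.
make_passive_recording <- function(C = 100, R = 200, amps = seq(-40, -10, 10),
                                   noise_sd = 0, seed = NULL,
                                   cell_id = "passive") {
  gt <- neuron_ground_truth(capacitance = C, resistance = R)
  cfg <- sim_config(amplitudes = amps, noise_sd = noise_sd, seed = seed)
  if (!is.null(seed)) set.seed(seed)
  sweeps <- lapply(seq_along(amps), function(i)
    simulate_passive_sweep(gt, amps[i], cfg, i))
  recording(cell_id, sweeps)
}

# Adjusted Rand index (mclust) with a plain fallback name.
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# Toy count matrix whose cells follow a tight genes-vs-UMIs power law, with
# optional planted violations of each QC rule.
make_qc_toy <- function(n_genes = 2000, n_cells = 24, seed = 99) {
  set.seed(seed)
  counts <- matrix(0L, n_genes, n_cells,
                   dimnames = list(sprintf("G%04d", seq_len(n_genes)),
                                   sprintf("c%02d", seq_len(n_cells))))
  for (j in seq_len(n_cells)) {
    umis <- round(stats::runif(1, 2500, 6000))
    n_det <- round(300 * umis^0.20)  # ~1450-1700 detected genes
    det <- sample(n_genes, n_det)
    x <- stats::rmultinom(1, umis - n_det, rep(1, n_det))[, 1]
    counts[det, j] <- as.integer(1L + x)
  }
  counts
}
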