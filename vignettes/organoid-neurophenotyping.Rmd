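---
title: "Methods: intrinsic-property extraction, neuron phenotyping, MEA and single-cell procedures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: intrinsic-property extraction, neuron phenotyping, MEA and single-cell procedures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

organoidkit analyzes three kinds of data produced when characterizing
neurons in stem-cell-derived telencephalic organoids: whole-cell
current-clamp recordings, implanted multi-electrode-array (MEA) recordings,
and droplet single-cell RNA-seq count matrices. This vignette documents the
models and procedures each function implements, the tunable parameters and
their defaults, the numerical choices, and what the synthetic-data
generators do and do not emulate.

## Current-clamp feature extraction

A `recording` is one cell's ordered set of sweeps under a square
current-step protocol: steps of 1 or 2 s injected from hyperpolarizing to
depolarizing amplitudes on a constant 5 or 10 pA grid (the step size is
conventionally chosen from the cell's input resistance). Sweeps are
digitized at tens of kHz; all voltages are mV, currents pA, times s. Only
the first second of the injection is analyzed
(`truncate_analysis_window()`), so 2-s protocols are comparable with 1-s
ones. Reported membrane potentials are corrected for the liquid junction
potential as `v - ljp` with a default of 9.4 mV, the junction potential of
a potassium-methanesulfonate internal solution against ACSF; the
correction makes true membrane potentials more negative than measured
ones. The resting potential is measured at break-in in I = 0 mode and is
therefore not recoverable from the step sweeps; it is read from recording
metadata (`rmp_mV`) when present and missing otherwise.

**Spike detection.** The recordings themselves define spikes only
implicitly, so the detector uses standard intracellular criteria: a spike
is a local maximum above −20 mV whose preceding 2 ms contain a dV/dt
excursion of at least 20 mV/ms, with a 1 ms refractory separation between
accepted peaks. dV/dt is estimated by central differences on the raw
trace; a boxcar smoother is available (`spike_detect_config()`) but off by
default, since at 20–50 kHz the derivative of a genuine upstroke is far
above the criterion.

**Per-spike features.** The spike threshold is the first sample, walking
back from the point of maximum rising dV/dt (the upstroke), at which dV/dt
reaches 5% of the upstroke. Amplitude is peak minus threshold voltage;
width is measured at half that amplitude, with linear interpolation
between samples at both flank crossings; the trough is the minimum within
five spike widths after the threshold, and the AHP is trough minus
threshold voltage. When the trough window runs past the end of the trace
the features are flagged unreliable and trough/AHP are missing.

**Per-cell features.** The rheobase sweep is the first depolarizing sweep
with at least one spike peak within 500 ms of step onset; spike-shape
features come from its first spike. First-spike latency (threshold
crossing relative to onset) is reported at rheobase + 5 pA: directly for
5 pA protocols, otherwise linearly interpolated over current between the
two sweeps bracketing the target; no extrapolation is attempted when no
sweep lies above the target. The adaptation index of a pair of consecutive
inter-spike intervals is (ISI2 − ISI1)/(ISI1 + ISI2); a sweep's index
averages its first two pairwise indices, and a cell's index averages the
first three suprathreshold sweeps with at least four spikes each. Cells
without three such sweeps have a missing adaptation index — the only
feature allowed to be missing downstream. The F-I slope is the OLS slope
of firing rate (spikes in the analysis window / 1 s) against current,
using points up to and including the first attainment of the maximum rate;
cells never firing more than one spike per sweep are assigned slope zero.
The F-I samples start at the first suprathreshold sweep; whether
sub-rheobase zero-rate points should enter the fit is ambiguous, and we
exclude them so the slope describes the suprathreshold gain.

**Passive properties.** Input resistance is the slope (with intercept) of
the maximum voltage deflection of each hyperpolarizing sweep against the
injected current; with deflection in mV and current in pA the slope is in
GΩ and reported in MΩ. The membrane time constant is fitted per sweep as
a single exponential with offset over the 10–100% segment of the
deflection, and averaged over sweeps; capacitance is
`C[pF] = 1000 · tau[ms] / Rin[MΩ]`, an identity every emitted feature
vector satisfies exactly. The sag ratio of a hyperpolarizing sweep is
(Vpeak − Vsteady)/(Vpeak − Vbaseline), with Vpeak the maximum deflection
in the first 500 ms, Vsteady the mean over the last 100 ms of the
injection, and Vbaseline the mean over the 200 ms before onset (the
baseline window length is a package choice; the quantity is a mean, so
modest changes are immaterial). The cell's sag averages the two sweeps
whose Vpeak is closest to −100 mV, taking the more hyperpolarized sweep on
ties and the single sweep when only one exists.

**Numerical choices.** Extremum locations (maximum deflection, sag Vpeak,
and the 10%/63% crossing times that bound and seed the tau fit) are found
on a 2 ms running-mean of the trace; picking a raw minimum under 0.3 mV
noise would bias deflections by about three noise SDs, whereas the
smoothed estimate is effectively unbiased for membrane time constants well
above 2 ms. The exponential itself is fitted to raw samples by
Levenberg–Marquardt least squares, seeded with the 10-to-63% crossing
interval and bounded away from degenerate time constants; sweeps whose fit
fails are excluded and counted in the per-cell diagnostics. All features
are deterministic functions of the trace: running the extractor twice
gives identical output.

## Phenotype clustering

Firing cells are clustered on a cells × features matrix assembled from the
feature table. The default feature set keeps one member of each redundant
pair: the latency at rheobase + 5 pA stands in for the raw rheobase
latency, and the resting potential is excluded because it depends on
optional metadata. Spike width, first-spike latency, input resistance and
capacitance are right-skewed and are log-transformed; every column is then
centered and scaled to unit variance. Sample (n − 1) SD is used — the
choice only affects reported scaled values, not correlations. Zero-variance
columns are dropped with a warning rather than erroring, which keeps small
or homogeneous cohorts usable.

The pairwise distance is 1 minus the Pearson correlation of the two cells'
scaled feature vectors. For any pair in which either cell has a missing
adaptation index, the correlation is computed over all features except the
adaptation index, so missingness never contaminates a distance and the
matrix stays complete. The tree is built by average linkage (UPGMA, via
`hclust`) and cut into k groups; k = 5 is the default used for phenotype
analysis. Average-linkage heights are monotone, and the package's tests
check them against a brute-force O(n³) agglomeration oracle.

## The integrate-and-fire ground-truth generator

The simulator exists to give every extractor a known answer. A cell is an
adaptive leaky integrate-and-fire neuron: membrane time constant
`tau = R·C`, firing threshold, reset, a per-spike adaptation current
increment decaying with its own time constant (100 ms default), and an
optional slow rebound current — a first-order h-current caricature whose
strength s reduces the steady-state step deflection to `R·I/(1+s)`, so the
asymptotic sag ratio is `s/(1+s)` and target sag ratios are analytically
reachable. Passive responses have a closed-form double-exponential
solution (`simulate_passive_sweep()`), which is the oracle for the passive
extractors; spiking sweeps are integrated by forward Euler at the sampling
rate with a hard stability guard (`dt < tau/50`). At each threshold
crossing a stereotyped ~2 ms waveform (smooth rise to +30 mV, fall to a
trough below reset) is stamped into the trace so that the 5%-of-upstroke
threshold operator and the width/trough measurements act on a realistic
spike, not on an integration artifact. Measurement noise is additive
Gaussian (0.3 mV default for cohorts), added after integration so ground
truth spike times are exact; all randomness flows through a single seed
and identical seeds give bit-identical recordings.

`simulate_population()` draws cells from five archetypes spanning the
phenotypes seen in organoid slices — an immature high-input-resistance
cell; a mature regular-spiking cell with deep rest, wide large spikes and
strong adaptation; a striatal-projection-neuron-like cell (large
capacitance, low input resistance, long latency, no sag or adaptation); a
prominently sagging, strongly adapting cell; and a small fast cell with
brief spikes. Parameters are jittered log-normally (8% CV, ±1.5 mV on
voltages). Each cell's protocol mimics experimental practice: 5 pA steps
when input resistance is at least 400 MΩ, otherwise 10 pA, with four
hyperpolarizing steps and a depolarizing range covering 2.2× the analytic
rheobase (at most 30 sweeps). Cohorts default to 25 kHz sampling — far
above what a 2 ms spike requires — to keep a 100-cell cohort's memory
footprint modest; single-cell simulations default to 50 kHz.

What the generator does not emulate: channel noise and stochastic firing,
slow drift, bridge-balance and access-resistance artifacts, bursting, and
spike-shape changes within a train. Passing the recovery tests therefore
shows the extractors implement their definitions correctly on clean,
well-behaved cells; it does not certify robustness to pathological
recordings.

## MEA analysis

Extracellular recordings (channels × samples, µV, 30 kHz) are high-pass
filtered at 300 Hz with a 4th-order Butterworth applied forward and
backward (zero phase; the filter order is a package choice, the cutoff is
the standard one for separating spikes from field potentials). Event rates
count debounced excursions of the absolute filtered signal above a 40 µV
threshold — one event per excursion, excursions closer than 1 ms merged —
divided by duration. Thresholding the absolute value rather than one side
makes the count insensitive to spike polarity. The function refuses
unfiltered input unless overridden. Spectrograms are Hann-windowed,
50%-overlapped short-time one-sided PSDs over 0.2 s windows, scaled so the
PSD integrates to signal power (the tests check Parseval to within
windowing tolerance).

The generator produces per-channel Poisson event trains convolved with a
biphasic 1 ms kernel plus noise, and returns the true event times. The
noise model matters: extracellular noise is dominated by low-frequency
field potentials — that is precisely why the rate estimate high-passes
first — so the generator puts most of the noise SD into a colored
(<100 Hz) component and a smaller fraction (default 25%) into broadband
noise. A generator that put the whole 10 µV SD into white noise at 30 kHz
would cross a 40 µV threshold by chance about twice per second
(P(|z| > 4) ≈ 6.3 × 10⁻⁵ per sample), which corresponds to no physical
recording front-end and would swamp any rate in false positives; the
colored model reproduces the regime in which a 300 Hz high-pass plus 4 SD
threshold is a sensible detector.

## Single-cell procedures

**Cell QC** (`filter_cells()`) applies, in order: library-size bounds
(defaults: at least 2000 UMIs and 1200 detected genes, at most 14,000 UMIs
and 4000 genes); a loess fit (span 0.5, local linear) of log10 detected
genes against log10 UMIs over the in-bounds cells, removing cells whose
residual is more than three SDs from the mean residual (log axes are the
natural scale for this trend; the rule catches barcodes whose gene
diversity is inconsistent with their depth); and a 6% cap on the fraction
of UMIs from mitochondrial genes. Mitochondrial genes are matched by the
`MT-` prefix by default — a bare `MT` prefix also matches nuclear families
like MTRNR, so the prefix set is configurable. Every input cell receives
exactly one disposition, counts are never altered, and fewer than ten
in-bounds cells is an error because the loess is underdetermined. Genes
are kept when they have at least one UMI in at least two cells
(`filter_genes()`). Expression is normalized per cell to 10,000 and
log(1 + x)-transformed.

**HVG selection** (`select_hvgs()`) restricts candidates to genes detected
in at least 10 cells but fewer than 90% of cells, with mean de-logged
normalized expression between 0.03 and 3 — the lower bounds drop noise,
the upper bounds drop housekeeping-like genes. Dispersion is the log
variance-to-mean ratio of de-logged normalized expression, z-scored within
20 equal-frequency bins of mean expression so that the mean-variance
relation of counts does not rank highly expressed genes first. The top
1200 genes by scaled dispersion are selected, then ribosomal and
mitochondrial symbols (RPL/RPS/MT prefixes) are removed; every removal is
recorded in a ledger, so the final set size is always the top-n size minus
the ledgered removals.

**Cell-cycle removal** (`remove_cell_cycle()`) is a three-step ledgered
procedure against a known cell-cycle list (default: the 97 core S and G2/M
genes of Tirosh et al. 2016, the standard reference list): (1) known
cell-cycle genes inside the HVG set are dropped outright; (2) a robust
subset of the known list is formed from genes with Spearman correlation
above 0.3 (average ranks on ties) to at least one other known cell-cycle
gene, so annotation not supported by the data at hand is not used as bait;
(3) remaining HVGs correlated above 0.3 with any robust-subset gene are
dropped. The threshold 0.3 is the conventional, deliberately permissive
choice for removing a coherent program.

**Markers and Jaccard similarity.** `rank_markers()` tests every gene per
group (two-sided Wilcoxon rank-sum of in-group vs rest, normal
approximation with tie correction — exact at the hundreds-of-cells scale
this is used at, and cross-checked against `wilcox.test` in the tests),
adjusts by Benjamini–Hochberg (Bonferroni is available for threshold-style
marker definitions; ranking is insensitive to which monotone adjustment is
used), and ranks the group-enriched genes; the top 1000 form the group's
marker list. `select_region_genes()` ranks reference genes by the sum of
adjusted p values across the pairwise regional comparisons and takes the
100 lowest — a gene must be strong in every comparison to rank highly.
`jaccard_matrix()` compares marker lists as sets: |A∩B|/|A∪B|, symmetric,
in [0, 1], 1 only for identical sets, and 0 with a warning for
empty-vs-empty.

**The count generator** (`simulate_counts()`) draws negative-binomial
counts with log-normal gene means and per-cell size factors, and plants:
group markers (4× fold change), high-dispersion genes, a latent cell-cycle
program loading known and novel genes (which produces the mutual Spearman
correlations the removal procedure looks for), high-expression
housekeeping genes that carry the library depth and exercise the
candidacy bounds, ribosomal/mitochondrial decoys, and optional cells whose
counts concentrate in few genes (off the genes-vs-UMIs trend). It emulates
the informative slice of a transcriptome at 2000 genes, not a full 20,000-
gene matrix; batch effects, doublets and ambient RNA are out of scope, so
recovery results certify the selection/removal logic, not robustness to
those artifacts.

## Validation scale and known limitations

The test suite validates passive recovery on 50-cell grids (noiseless
recovery within 1%; 0.3 mV noise, median relative error under 5%),
rheobase/latency and clustering on a 100-cell five-archetype cohort
(exact rheobase match; adjusted Rand index above 0.9 at k = 5), MEA rates
on 16 channels × 60 s at 2.5 events/s (per-channel error within 10%, zero
rate when events are removed, Parseval within 5%), and the transcriptomic
recoveries at 2000 genes × 600 cells. These sizes are chosen so the whole
suite runs in minutes on a laptop while keeping the statistical checks
meaningful.

Limitations worth knowing: the spike detector and threshold operator
assume clean somatic spikes with a distinct upstroke and will misbehave on
strongly filtered or very noisy traces; latency interpolation is linear in
current by construction; the sag measurement reports whatever rebound the
trace shows within the 1 s window, which underestimates asymptotic sag for
slow h-currents; the MEA event counter does not sort spikes and a single
threshold cannot separate overlapping units; and the Wilcoxon marker
ranking, like any one-vs-rest test, favors genes private to one group over
graded programs.
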