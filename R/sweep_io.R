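# Data model and I/O for current-clamp recordings.
#
# Units are fixed throughout the package: voltage mV, current pA, time s
# (feature values that are conventionally reported in ms are converted at
# the feature-extraction boundary). A Recording is an ordered set of Sweeps
# sharing one square-step stimulus protocol.

#' Stimulus epoch of a square current step
#'
#' Describes the square current-step injection shared by all sweeps of a
#' recording: a step of `amplitude` pA switched on at `onset` seconds for
#' `duration` seconds. Negative amplitudes are hyperpolarizing.
#'
#' @param onset Seconds from sweep start to step onset (>= 0).
#' @param duration Step duration in seconds (> 0; protocols here use 1 or 2 s).
#' @param amplitude Step amplitude in pA (signed).
#' @return A `stimulus_epoch` object.
#' @export
stimulus_epoch <- function(onset, duration, amplitude) {
  stopifnot(is.numeric(onset), is.numeric(duration), is.numeric(amplitude))
  if (!is.finite(onset) || onset < 0) stop("epoch onset must be finite and >= 0")
  if (!is.finite(duration) || duration <= 0) stop("epoch duration must be > 0")
  if (!is.finite(amplitude)) stop("epoch amplitude must be finite")
  structure(list(onset = onset, duration = duration, amplitude = amplitude),
            class = "stimulus_epoch")
}

#' A single current-clamp sweep
#'
#' @param voltage Numeric vector of membrane voltage samples in mV.
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @param epoch A [stimulus_epoch()].
#' @param index Ordinal position of the sweep in the protocol.
#' @return A `sweep` object.
#' @export
sweep <- function(voltage, sampling_rate, epoch, index = NA_integer_) {
  stopifnot(is.numeric(voltage), inherits(epoch, "stimulus_epoch"))
  if (!is.numeric(sampling_rate) || sampling_rate <= 0) {
    stop("sampling_rate must be > 0")
  }
  if (length(voltage) < 2L) stop("sweep must contain at least two samples")
  if (!all(is.finite(voltage))) stop("sweep voltage must be finite everywhere")
  len_s <- length(voltage) / sampling_rate
  if (epoch$onset + epoch$duration > len_s + 1e-9) {
    stop("stimulus epoch (onset + duration) extends past the end of the sweep")
  }
  structure(list(voltage = as.numeric(voltage),
                 sampling_rate = sampling_rate,
                 epoch = epoch,
                 index = as.integer(index)),
            class = "sweep")
}

#' Time axis of a sweep
#'
#' @param sw A [sweep()].
#' @return Numeric vector of sample times in seconds (first sample at 0).
#' @export
sweep_times <- function(sw) {
  (seq_along(sw$voltage) - 1L) / sw$sampling_rate
}

#' One cell's current-clamp recording
#'
#' Bundles the ordered sweeps of a square-step protocol with the per-cell
#' constants needed by the feature extractors. Sweeps are validated to share
#' the sampling rate and epoch timing and to form a strictly monotone
#' amplitude grid with a constant step (typically 5 or 10 pA, chosen by the
#' experimenter according to the cell's input resistance); they are stored
#' sorted from most hyperpolarizing to most depolarizing.
#'
#' @param cell_id Opaque cell identifier string.
#' @param sweeps List of [sweep()] objects.
#' @param ljp Liquid junction potential in mV used to correct reported
#'   membrane potentials (default 9.4).
#' @param baseline_window Seconds of pre-stimulus trace averaged to obtain
#'   the baseline voltage (default 0.2).
#' @param metadata Free-form named list. A numeric entry `rmp_mV` (resting
#'   membrane potential measured in I = 0 mode at break-in) is used by
#'   [extract_cell_features()].
#' @return A `recording` object.
#' @export
recording <- function(cell_id, sweeps, ljp = 9.4, baseline_window = 0.2,
                      metadata = list()) {
  if (!is.character(cell_id) || length(cell_id) != 1L) {
    stop("cell_id must be a single string")
  }
  if (!is.list(sweeps) || length(sweeps) == 0L) {
    stop("recording requires a non-empty list of sweeps")
  }
  if (!all(vapply(sweeps, inherits, logical(1), "sweep"))) {
    stop("all elements of sweeps must be sweep objects")
  }
  rates <- vapply(sweeps, function(s) s$sampling_rate, numeric(1))
  if (length(unique(rates)) != 1L) {
    stop("all sweeps must share the same sampling_rate")
  }
  lens <- vapply(sweeps, function(s) length(s$voltage), integer(1))
  if (length(unique(lens)) != 1L) {
    stop("all sweeps must have the same number of samples")
  }
  onsets <- vapply(sweeps, function(s) s$epoch$onset, numeric(1))
  durs <- vapply(sweeps, function(s) s$epoch$duration, numeric(1))
  if (diff(range(onsets)) > 1e-9 || diff(range(durs)) > 1e-9) {
    stop("all sweeps must share the stimulus epoch timing (onset, duration)")
  }
  amps <- vapply(sweeps, function(s) s$epoch$amplitude, numeric(1))
  ord <- order(amps)
  sweeps <- sweeps[ord]
  amps <- amps[ord]
  if (any(duplicated(amps))) stop("sweep amplitudes must be strictly monotone")
  if (length(amps) > 2L) {
    steps <- diff(amps)
    if (diff(range(steps)) > 1e-6) {
      stop("sweep amplitudes must form a grid with a constant step")
    }
  }
  if (baseline_window < 0) stop("baseline_window must be >= 0")
  for (i in seq_along(sweeps)) sweeps[[i]]$index <- i
  structure(list(cell_id = cell_id, sweeps = sweeps, ljp = ljp,
                 baseline_window = baseline_window, metadata = metadata),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  amps <- recording_amplitudes(x)
  cat(sprintf(
    "<recording> cell %s: %d sweeps, %.0f Hz, step %s pA, amplitudes [%g, %g] pA\n",
    x$cell_id, length(x$sweeps), x$sweeps[[1]]$sampling_rate,
    if (length(amps) > 1L) format(amps[2] - amps[1]) else "NA",
    min(amps), max(amps)))
  invisible(x)
}

#' Amplitudes of the sweeps of a recording
#'
#' @param rec A [recording()].
#' @return Numeric vector of step amplitudes (pA), ascending.
#' @export
recording_amplitudes <- function(rec) {
  vapply(rec$sweeps, function(s) s$epoch$amplitude, numeric(1))
}

#' Apply the liquid-junction-potential correction
#'
#' Reported membrane potentials are corrected as `v - ljp`: the junction
#' potential of the potassium-methanesulfonate internal solution against the
#' bath makes the true membrane potential more negative than the measured
#' value, so the correction shifts potentials downward.
#'
#' @param v Measured potential(s) in mV.
#' @param ljp Liquid junction potential in mV.
#' @return Corrected potential(s) in mV.
#' @export
apply_ljp_correction <- function(v, ljp) {
  stopifnot(is.numeric(v), is.numeric(ljp), all(is.finite(ljp)))
  v - ljp
}

#' Truncate sweeps to the first second of the stimulus epoch
#'
#' Only the first second of the current injection is analyzed; sweeps
#' recorded with a 2-s step are clipped so that at most `window` seconds of
#' stimulus-epoch data remain. The pre-stimulus baseline is always retained;
#' sweeps whose epoch already fits in the window are returned unchanged.
#'
#' @param rec A [recording()].
#' @param window Analysis window length in seconds (default 1).
#' @return A [recording()] with clipped sweeps.
#' @export
truncate_analysis_window <- function(rec, window = 1) {
  stopifnot(inherits(rec, "recording"), window > 0)
  ep <- rec$sweeps[[1]]$epoch
  if (ep$duration <= window + 1e-12) return(rec)
  rate <- rec$sweeps[[1]]$sampling_rate
  n_keep <- floor((ep$onset + window) * rate + 1e-9)
  sweeps <- lapply(rec$sweeps, function(s) {
    sweep(s$voltage[seq_len(min(n_keep, length(s$voltage)))], s$sampling_rate,
          stimulus_epoch(s$epoch$onset, window, s$epoch$amplitude), s$index)
  })
  recording(rec$cell_id, sweeps, ljp = rec$ljp,
            baseline_window = rec$baseline_window, metadata = rec$metadata)
}

#' Write a recording as a plain-text fixture
#'
#' The fixture is a directory holding `recording.json` (protocol constants,
#' identifiers, metadata) and one `sweep_NNN.csv` per sweep with columns
#' `time_s` and `voltage_mV`. The format is diff-able and language-neutral;
#' [read_recording()] restores the object up to float round-trip.
#'
#' @param rec A [recording()].
#' @param path Directory to create (must not require parents).
#' @return Invisibly, `path`.
#' @export
write_fixture <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stop("cannot create fixture directory: ", path)
  meta <- list(
    format = "organoidkit-fixture",
    format_version = 1L,
    cell_id = rec$cell_id,
    ljp = rec$ljp,
    baseline_window = rec$baseline_window,
    sampling_rate = rec$sweeps[[1]]$sampling_rate,
    epoch_onset = rec$sweeps[[1]]$epoch$onset,
    epoch_duration = rec$sweeps[[1]]$epoch$duration,
    amplitudes = recording_amplitudes(rec),
    n_samples = length(rec$sweeps[[1]]$voltage),
    metadata = rec$metadata
  )
  jsonlite::write_json(meta, file.path(path, "recording.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (i in seq_along(rec$sweeps)) {
    sw <- rec$sweeps[[i]]
    df <- data.frame(time_s = sweep_times(sw), voltage_mV = sw$voltage)
    f <- file.path(path, sprintf("sweep_%03d.csv", i))
    utils::write.csv(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                     f, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a current-clamp recording
#'
#' @param path Path to the recording (for the `fixture` format, the
#'   directory written by [write_fixture()]).
#' @param format Input format. Only `"fixture"` is built in; additional
#'   formats can be registered with [register_recording_reader()] (adapter
#'   hook for vendor or archive formats).
#' @return A validated [recording()] with sweeps sorted by amplitude.
#' @export
read_recording <- function(path, format = "fixture") {
  reader <- .recording_readers$readers[[format]]
  if (is.null(reader)) {
    stop("unknown recording format '", format, "'; registered formats: ",
         paste(names(.recording_readers$readers), collapse = ", "))
  }
  reader(path)
}

.recording_readers <- new.env(parent = emptyenv())
.recording_readers$readers <- list()

#' Register a reader for an additional recording format
#'
#' @param format Format name used as the `format` argument of
#'   [read_recording()].
#' @param reader Function of one argument (the path) returning a
#'   [recording()].
#' @return Invisibly, the previous reader for that format (or `NULL`).
#' @export
register_recording_reader <- function(format, reader) {
  stopifnot(is.character(format), length(format) == 1L, is.function(reader))
  old <- .recording_readers$readers[[format]]
  .recording_readers$readers[[format]] <- reader
  invisible(old)
}

read_fixture_recording <- function(path) {
  jf <- file.path(path, "recording.json")
  if (!file.exists(jf)) stop("not a recording fixture (missing recording.json): ", path)
  meta <- jsonlite::read_json(jf, simplifyVector = TRUE)
  for (field in c("cell_id", "sampling_rate", "epoch_onset", "epoch_duration",
                  "amplitudes", "n_samples")) {
    if (is.null(meta[[field]])) {
      stop("malformed fixture: recording.json is missing field '", field, "'")
    }
  }
  amps <- as.numeric(meta$amplitudes)
  sweeps <- vector("list", length(amps))
  for (i in seq_along(amps)) {
    f <- file.path(path, sprintf("sweep_%03d.csv", i))
    if (!file.exists(f)) stop("malformed fixture: missing ", basename(f))
    df <- utils::read.csv(f)
    if (!all(c("time_s", "voltage_mV") %in% names(df))) {
      stop("malformed fixture: ", basename(f),
           " lacks time_s/voltage_mV columns")
    }
    if (nrow(df) != meta$n_samples) {
      stop("malformed fixture: ", basename(f), " has ", nrow(df),
           " samples, expected ", meta$n_samples)
    }
    dt <- diff(df$time_s)
    if (length(dt) && diff(range(dt)) > 1e-9 / meta$sampling_rate + 1e-12) {
      stop("non-uniform sampling in ", basename(f))
    }
    sweeps[[i]] <- sweep(df$voltage_mV, meta$sampling_rate,
                         stimulus_epoch(meta$epoch_onset, meta$epoch_duration,
                                        amps[i]), i)
  }
  md <- meta$metadata
  if (is.null(md) || (is.list(md) && length(md) == 0L)) md <- list()
  recording(meta$cell_id, sweeps,
            ljp = meta$ljp %||% 9.4,
            baseline_window = meta$baseline_window %||% 0.2,
            metadata = as.list(md))
}

.recording_readers$readers[["fixture"]] <- read_fixture_recording

# ---- feature tables ---------------------------------------------------------

#' Column schema of the per-cell feature table
#'
#' @return Character vector of column names, in order.
#' @export
feature_table_schema <- function() {
  c("cell_id", "resting_potential", "rheobase", "rheobase_latency",
    "latency_rheo_plus5", "adaptation_index", "fi_slope", "max_rate",
    "input_resistance", "tau", "capacitance", "sag_ratio", "threshold_v",
    "amplitude", "width", "ahp", "upstroke")
}

.feature_table_version <- "organoidkit-feature-table v1"

#' Write a feature table as TSV
#'
#' The first line is a `#`-prefixed version stamp so downstream tools can
#' check the column schema.
#'
#' @param ft Data frame with the [feature_table_schema()] columns.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_feature_table <- function(ft, path) {
  stopifnot(is.data.frame(ft))
  missing_cols <- setdiff(feature_table_schema(), names(ft))
  if (length(missing_cols)) {
    stop("feature table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", .feature_table_version), con)
  utils::write.table(ft[, feature_table_schema()], con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path TSV file path.
#' @return Data frame with one row per cell.
#' @export
read_feature_table <- function(path) {
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "#") || !grepl("feature-table", first)) {
    stop("not an organoidkit feature table: ", path)
  }
  ft <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (anyDuplicated(ft$cell_id)) stop("feature table has duplicated cell_id")
  ft
}
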