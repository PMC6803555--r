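EPOCH_LABELS <- c("baseline", "harmaline", "dbs_on", "dbs_off", "post_dbs")
REGIONS <- c("M1", "VLT")
FP_SAMPLING_RATE <- 100      # Hz, fixed by the force-plate actimeter
FP_FRAME_LEN <- 1024L        # samples per frame (10.24 s)

stop_validation <- function(...) {
  stop(structure(class = c("tremordbs_validation_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' Construct an epoch
#'
#' An epoch is a labelled half-open time interval `[start, end)` in seconds
#' from recording start. Half-open intervals make epoch partitions exact: a
#' spike or frame belongs to exactly one epoch.
#'
#' @param label one of `"baseline"`, `"harmaline"`, `"dbs_on"`, `"dbs_off"`,
#'   `"post_dbs"`.
#' @param start,end boundaries in seconds, `start < end`.
#' @return an object of class `"epoch"`.
#' @export
epoch <- function(label, start, end) {
  label <- match.arg(label, EPOCH_LABELS)
  if (!is.finite(start) || !is.finite(end))
    stop_validation("epoch boundaries must be finite")
  if (start >= end)
    stop_validation("epoch '", label, "': start (", start,
                    ") must be < end (", end, ")")
  structure(list(label = label, start = start, end = end), class = "epoch")
}

#' @export
print.epoch <- function(x, ...) {
  cat(sprintf("<epoch> %s [%g, %g) s\n", x$label, x$start, x$end))
  invisible(x)
}

#' Construct a spike train
#'
#' @param unit_id unit identifier string.
#' @param region recording region, `"M1"` or `"VLT"`.
#' @param spike_times numeric vector of spike times in seconds, strictly
#'   increasing, within `[0, duration]`.
#' @param duration recording duration in seconds.
#' @param spike_width optional spike waveform width in microseconds
#'   (metadata used by the unit-inclusion filters for M1).
#' @return an object of class `"spike_train"` with fields `unit_id`, `region`,
#'   `spike_times`, `duration`, `mean_rate` (Hz) and `spike_width`.
#' @export
spike_train <- function(unit_id, region, spike_times, duration,
                        spike_width = NA_real_) {
  region <- match.arg(region, REGIONS)
  spike_times <- as.numeric(spike_times)
  if (!is.finite(duration) || duration < 0)
    stop_validation("duration must be finite and >= 0")
  if (anyNA(spike_times) || (length(spike_times) && !all(is.finite(spike_times))))
    stop_validation("spike times must be finite")
  if (length(spike_times) > 1 && any(diff(spike_times) <= 0)) {
    bad <- which(diff(spike_times) <= 0)[1] + 1L
    stop_validation("spike times must be strictly increasing (violated at index ",
                    bad, ")")
  }
  if (length(spike_times) &&
      (spike_times[1] < 0 || spike_times[length(spike_times)] > duration))
    stop_validation("spike times must lie within [0, duration]")
  structure(list(unit_id = as.character(unit_id), region = region,
                 spike_times = spike_times, duration = duration,
                 mean_rate = if (duration > 0) length(spike_times) / duration else 0,
                 spike_width = spike_width),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %s (%s): %d spikes over %.1f s (%.2f Hz)\n",
              x$unit_id, x$region, length(x$spike_times), x$duration,
              x$mean_rate))
  invisible(x)
}

#' Construct a force-plate recording
#'
#' Force-plate data are organized in frames of 1024 samples at 100 Hz
#' (10.24 s per frame). The sample count must be an exact number of frames.
#'
#' @param force numeric vector of per-sample force values.
#' @param centroid two-column matrix of per-sample centroid (x, y) in mm.
#' @return an object of class `"forceplate_recording"`.
#' @export
forceplate_recording <- function(force, centroid) {
  force <- as.numeric(force)
  centroid <- as.matrix(centroid)
  if (!all(is.finite(force))) stop_validation("force values must be finite")
  if (nrow(centroid) != length(force) || ncol(centroid) != 2)
    stop_validation("centroid must be an n x 2 matrix matching force length")
  if (!all(is.finite(centroid))) stop_validation("centroid values must be finite")
  if (length(force) %% FP_FRAME_LEN != 0)
    stop_validation("sample count (", length(force),
                    ") is not a multiple of the 1024-sample frame length")
  structure(list(sampling_rate = FP_SAMPLING_RATE, force = force,
                 centroid = centroid,
                 n_frames = length(force) %/% FP_FRAME_LEN),
            class = "forceplate_recording")
}

#' @export
print.forceplate_recording <- function(x, ...) {
  cat(sprintf("<forceplate_recording> %d frames (%.1f s at %d Hz)\n",
              x$n_frames, length(x$force) / x$sampling_rate, x$sampling_rate))
  invisible(x)
}

#' Construct a session manifest
#'
#' @param epochs list of [epoch()] objects; must be time-ordered and
#'   non-overlapping.
#' @param dose_mg_per_kg harmaline dose (mg/kg).
#' @param stim_freq_hz DBS stimulation frequency (Hz).
#' @param pulse_width_us DBS pulse width (microseconds).
#' @param amplitude_ua DBS current amplitude (microamperes).
#' @return an object of class `"session_manifest"`.
#' @export
session_manifest <- function(epochs, dose_mg_per_kg = 0, stim_freq_hz = 0,
                             pulse_width_us = 0, amplitude_ua = 0) {
  if (!length(epochs)) stop_validation("manifest needs at least one epoch")
  if (!all(vapply(epochs, inherits, logical(1), "epoch")))
    stop_validation("epochs must be epoch objects")
  starts <- vapply(epochs, `[[`, numeric(1), "start")
  ends <- vapply(epochs, `[[`, numeric(1), "end")
  if (is.unsorted(starts, strictly = TRUE))
    stop_validation("epochs must be in increasing time order")
  if (any(ends[-length(ends)] > starts[-1]))
    stop_validation("epochs overlap: ", paste(
      sprintf("[%g,%g)", starts, ends), collapse = " "))
  meta <- c(dose_mg_per_kg = dose_mg_per_kg, stim_freq_hz = stim_freq_hz,
            pulse_width_us = pulse_width_us, amplitude_ua = amplitude_ua)
  if (any(!is.finite(meta)) || any(meta < 0))
    stop_validation("intervention metadata must be finite and non-negative")
  structure(list(epochs = epochs, metadata = as.list(meta)),
            class = "session_manifest")
}

#' @export
print.session_manifest <- function(x, ...) {
  cat("<session_manifest>\n")
  for (e in x$epochs)
    cat(sprintf("  %-10s [%g, %g) s\n", e$label, e$start, e$end))
  cat(sprintf("  dose %g mg/kg, stim %g Hz, %g us, %g uA\n",
              x$metadata$dose_mg_per_kg, x$metadata$stim_freq_hz,
              x$metadata$pulse_width_us, x$metadata$amplitude_ua))
  invisible(x)
}

find_epoch <- function(manifest, label) {
  for (e in manifest$epochs) if (e$label == label) return(e)
  NULL
}

#' Slice a spike train to an epoch
#'
#' Keeps spikes with `start <= t < end` (half-open) and re-references them to
#' the epoch start, so the returned train spans `[0, end - start]`.
#'
#' @param train a [spike_train()].
#' @param ep an [epoch()] within `[0, duration]`.
#' @return a [spike_train()] of duration `end - start`.
#' @export
slice_train <- function(train, ep) {
  stopifnot(inherits(train, "spike_train"), inherits(ep, "epoch"))
  if (ep$start < 0 || ep$end > train$duration + 1e-9)
    stop_validation("epoch [", ep$start, ", ", ep$end,
                    ") outside recording [0, ", train$duration, "]")
  t <- train$spike_times
  keep <- t >= ep$start & t < ep$end
  spike_train(train$unit_id, train$region, t[keep] - ep$start,
              ep$end - ep$start, train$spike_width)
}

# ---- file formats -----------------------------------------------------------
# spikes CSV : unit_id,region,t_spike_s   (one row per spike)
# force CSV  : t_s,force,x_mm,y_mm        (one row per sample at 100 Hz)
# manifest   : JSON {epochs:[{label,start_s,end_s}], interventions:{...}}

#' Write a session bundle to a directory
#'
#' Emits `spikes.csv` (`unit_id,region,t_spike_s`, optional `spike_width_us`),
#' `force.csv` (`t_s,force,x_mm,y_mm`) and `manifest.json`.
#'
#' @param trains list of [spike_train()] objects.
#' @param recording a [forceplate_recording()] or `NULL`.
#' @param manifest a [session_manifest()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_session <- function(trains, recording, manifest, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- do.call(rbind, lapply(trains, function(tr) {
    n <- length(tr$spike_times)
    data.frame(unit_id = rep(tr$unit_id, n), region = rep(tr$region, n),
               t_spike_s = tr$spike_times,
               spike_width_us = rep(tr$spike_width, n))
  }))
  if (is.null(sp))
    sp <- data.frame(unit_id = character(), region = character(),
                     t_spike_s = numeric(), spike_width_us = numeric())
  utils::write.csv(sp, file.path(dir, "spikes.csv"), row.names = FALSE)
  durations <- vapply(trains, `[[`, numeric(1), "duration")
  if (!is.null(recording)) {
    n <- length(recording$force)
    fp <- data.frame(t_s = (seq_len(n) - 1) / recording$sampling_rate,
                     force = recording$force,
                     x_mm = recording$centroid[, 1],
                     y_mm = recording$centroid[, 2])
    utils::write.csv(fp, file.path(dir, "force.csv"), row.names = FALSE)
  }
  mj <- list(
    epochs = lapply(manifest$epochs, function(e)
      list(label = e$label, start_s = e$start, end_s = e$end)),
    interventions = manifest$metadata,
    duration_s = if (length(durations)) max(durations) else
      max(vapply(manifest$epochs, `[[`, numeric(1), "end")))
  jsonlite::write_json(mj, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a session bundle from a directory
#'
#' Parses and validates `spikes.csv`, `force.csv` (optional) and
#' `manifest.json` as written by [write_session()]. Unsorted spike files are
#' rejected, not silently sorted; malformed rows raise errors naming the line.
#'
#' @param dir session directory.
#' @return a list with elements `trains` (list of [spike_train()]),
#'   `recording` (a [forceplate_recording()] or `NULL`) and `manifest`
#'   (a [session_manifest()]).
#' @export
read_session <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  spath <- file.path(dir, "spikes.csv")
  if (!file.exists(mpath)) stop_validation("missing manifest.json in ", dir)
  if (!file.exists(spath)) stop_validation("missing spikes.csv in ", dir)
  mj <- jsonlite::read_json(mpath)
  eps <- lapply(mj$epochs, function(e) epoch(e$label, e$start_s, e$end_s))
  iv <- mj$interventions
  manifest <- session_manifest(eps,
    dose_mg_per_kg = iv$dose_mg_per_kg %||% 0,
    stim_freq_hz = iv$stim_freq_hz %||% 0,
    pulse_width_us = iv$pulse_width_us %||% 0,
    amplitude_ua = iv$amplitude_ua %||% 0)
  duration <- mj$duration_s %||%
    max(vapply(manifest$epochs, `[[`, numeric(1), "end"))

  sp <- utils::read.csv(spath, stringsAsFactors = FALSE)
  need <- c("unit_id", "region", "t_spike_s")
  if (!all(need %in% names(sp)))
    stop_validation("spikes.csv must have columns ", paste(need, collapse = ", "))
  if (nrow(sp) && (anyNA(sp$t_spike_s) || !all(is.finite(sp$t_spike_s)))) {
    bad <- which(!is.finite(sp$t_spike_s))[1]
    stop_validation("spikes.csv line ", bad + 1L, ": non-numeric spike time")
  }
  trains <- list()
  for (uid in unique(sp$unit_id)) {
    rows <- which(sp$unit_id == uid)
    tt <- sp$t_spike_s[rows]
    if (length(tt) > 1 && any(diff(tt) <= 0)) {
      bad <- rows[which(diff(tt) <= 0)[1] + 1L]
      stop_validation("spikes.csv line ", bad + 1L,
                      ": spike times for unit '", uid,
                      "' are not strictly increasing")
    }
    wid <- if ("spike_width_us" %in% names(sp)) sp$spike_width_us[rows[1]] else NA_real_
    trains[[length(trains) + 1L]] <-
      spike_train(uid, sp$region[rows[1]], tt, duration, wid)
  }

  fpath <- file.path(dir, "force.csv")
  recording <- NULL
  if (file.exists(fpath)) {
    fp <- utils::read.csv(fpath)
    needf <- c("t_s", "force", "x_mm", "y_mm")
    if (!all(needf %in% names(fp)))
      stop_validation("force.csv must have columns ", paste(needf, collapse = ", "))
    recording <- forceplate_recording(fp$force, cbind(fp$x_mm, fp$y_mm))
  }
  list(trains = trains, recording = recording, manifest = manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
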