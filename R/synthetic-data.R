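# Synthetic session generation: spike trains of the four firing-pattern
# archetypes and epoch-structured force-plate sessions. These define the
# study conditions under which the downstream analyses are exercised.

PATTERN_CLASSES <- c("os-burst", "os-non-burst", "irr-burst", "irr-non-burst")

#' Specification for a synthetic spike train
#'
#' Each of the four firing-pattern archetypes is realized as a point process:
#' \describe{
#'   \item{irr-non-burst}{homogeneous Poisson at `base_rate`.}
#'   \item{os-non-burst}{inhomogeneous Poisson with rate
#'     `base_rate * (1 + mod_depth * sin(2*pi*osc_freq*t))`, realized by
#'     thinning from the rate ceiling `base_rate * (1 + mod_depth)`.}
#'   \item{irr-burst}{homogeneous Poisson burst *events* at
#'     `burst_event_rate` superimposed on homogeneous Poisson background
#'     spikes at `base_rate`.}
#'   \item{os-burst}{as irr-burst, but the burst events (not single spikes)
#'     are rate-modulated at `osc_freq`.}
#' }
#' Burst events carry `burst_size` spikes (uniform over `burst_size_range`)
#' with intra-burst ISIs uniform in `intra_burst_isi_range` ms — safely inside
#' the 10 ms burst-definition rule — and consecutive burst starts are kept
#' >= 120 ms apart so the >100 ms burst-separation rule holds by construction.
#' A 1.5 ms refractory floor is imposed on all ISIs after superposition.
#'
#' Default rates are chosen so that *-burst trains have expected
#' burst-count/spike-count ratio 1/(1 + 4/... ) well above the 0.10 burst-cell
#' cutoff (1 burst/s over ~4-spike bursts plus 2 Hz background gives ~0.17)
#' and all classes stay under the 10 Hz inclusion ceiling.
#'
#' @param pattern_class one of `"os-burst"`, `"os-non-burst"`, `"irr-burst"`,
#'   `"irr-non-burst"`.
#' @param duration train duration in seconds (> 0; 0 allowed and yields an
#'   empty train).
#' @param base_rate background/single-spike rate in events/s.
#' @param osc_freq modulation frequency in Hz, within \[0.4, 1.5\] (os-* only).
#' @param mod_depth modulation depth in \[0, 1\] (os-* only; must be > 0).
#' @param burst_event_rate burst events per second (*-burst only).
#' @param burst_size_range integer pair, spikes per burst (min >= 2).
#' @param intra_burst_isi_range ISI pair in ms, within (0, 10\].
#' @param seed integer RNG seed; fixed seed gives byte-identical trains.
#' @return an object of class `"spike_gen_spec"`.
#' @export
spike_gen_spec <- function(pattern_class,
                           duration = 600,
                           base_rate = if (grepl("burst$", pattern_class) &&
                                           !grepl("non-burst$", pattern_class)) 2 else 5,
                           osc_freq = 1.0,
                           mod_depth = 0.9,
                           burst_event_rate = 1.0,
                           burst_size_range = c(2L, 6L),
                           intra_burst_isi_range = c(3, 8),
                           seed = 1L) {
  pattern_class <- match.arg(pattern_class, PATTERN_CLASSES)
  chk <- function(ok, field, msg)
    if (!ok) stop_validation("spike_gen_spec: field '", field, "' ", msg)
  chk(is.finite(duration) && duration >= 0, "duration", "must be finite and >= 0")
  chk(is.finite(base_rate) && base_rate > 0, "base_rate", "must be > 0")
  is_osc <- startsWith(pattern_class, "os")
  is_burst <- pattern_class %in% c("os-burst", "irr-burst")
  if (is_osc) {
    chk(is.finite(osc_freq) && osc_freq >= 0.4 && osc_freq <= 1.5,
        "osc_freq", "must be in [0.4, 1.5] Hz for oscillatory classes")
    chk(is.finite(mod_depth) && mod_depth > 0 && mod_depth <= 1,
        "mod_depth", "must be in (0, 1] for oscillatory classes")
  }
  if (is_burst) {
    chk(is.finite(burst_event_rate) && burst_event_rate > 0,
        "burst_event_rate", "must be > 0 for burst classes")
    chk(length(burst_size_range) == 2 && all(burst_size_range >= 2) &&
          burst_size_range[1] <= burst_size_range[2],
        "burst_size_range", "must be an ordered pair with min >= 2")
    chk(length(intra_burst_isi_range) == 2 &&
          all(intra_burst_isi_range > 0) && all(intra_burst_isi_range <= 10) &&
          intra_burst_isi_range[1] <= intra_burst_isi_range[2],
        "intra_burst_isi_range", "must be an ordered pair within (0, 10] ms")
  }
  structure(list(pattern_class = pattern_class, duration = duration,
                 base_rate = base_rate, osc_freq = osc_freq,
                 mod_depth = mod_depth, burst_event_rate = burst_event_rate,
                 burst_size_range = as.integer(burst_size_range),
                 intra_burst_isi_range = intra_burst_isi_range,
                 seed = as.integer(seed)),
            class = "spike_gen_spec")
}

# Homogeneous Poisson event times on [0, duration].
rpoisson_times <- function(rate, duration) {
  n <- stats::rpois(1, rate * duration)
  sort(stats::runif(n, 0, duration))
}

# Inhomogeneous Poisson by thinning from ceiling rate*(1+depth).
rpoisson_times_mod <- function(rate, duration, freq, depth) {
  lam_max <- rate * (1 + depth)
  cand <- rpoisson_times(lam_max, duration)
  lam <- rate * (1 + depth * sin(2 * pi * freq * cand))
  cand[stats::runif(length(cand)) < lam / lam_max]
}

# Expand burst-event start times into spikes; enforce >=120 ms between
# consecutive burst starts by dropping too-close events.
expand_bursts <- function(starts, size_range, isi_range_ms, duration) {
  if (!length(starts)) return(numeric(0))
  keep <- c(TRUE, diff(starts) >= 0.120)
  # iterate: dropping an event can bring the next one within range of the
  # previous kept one
  while (TRUE) {
    kept <- starts[keep]
    if (length(kept) < 2 || all(diff(kept) >= 0.120)) break
    idx <- which(keep)
    bad <- idx[which(diff(starts[keep]) < 0.120) + 1L]
    keep[bad] <- FALSE
  }
  starts <- starts[keep]
  sizes <- sample(seq(size_range[1], size_range[2]), length(starts),
                  replace = TRUE)
  spikes <- unlist(lapply(seq_along(starts), function(i) {
    isis <- stats::runif(sizes[i] - 1L, isi_range_ms[1], isi_range_ms[2]) / 1000
    starts[i] + c(0, cumsum(isis))
  }))
  spikes[spikes <= duration]
}

#' Generate a synthetic spike train
#'
#' Realizes the point process described by a [spike_gen_spec()]; see that
#' help page for the per-class models. Output times are strictly increasing
#' within `[0, duration]` and reproducible for a fixed seed.
#'
#' @param spec a [spike_gen_spec()].
#' @param unit_id,region,spike_width metadata attached to the returned train
#'   (defaults give an M1 unit passing the width filter).
#' @return a [spike_train()].
#' @export
gen_spike_train <- function(spec, unit_id = "u1", region = "M1",
                            spike_width = 250) {
  stopifnot(inherits(spec, "spike_gen_spec"))
  if (spec$duration == 0)
    return(spike_train(unit_id, region, numeric(0), 0, spike_width))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  t <- switch(spec$pattern_class,
    "irr-non-burst" = rpoisson_times(spec$base_rate, spec$duration),
    "os-non-burst" = rpoisson_times_mod(spec$base_rate, spec$duration,
                                        spec$osc_freq, spec$mod_depth),
    "irr-burst" = {
      ev <- rpoisson_times(spec$burst_event_rate, spec$duration)
      sort(c(expand_bursts(ev, spec$burst_size_range,
                           spec$intra_burst_isi_range, spec$duration),
             rpoisson_times(spec$base_rate, spec$duration)))
    },
    "os-burst" = {
      ev <- rpoisson_times_mod(spec$burst_event_rate, spec$duration,
                               spec$osc_freq, spec$mod_depth)
      sort(c(expand_bursts(ev, spec$burst_size_range,
                           spec$intra_burst_isi_range, spec$duration),
             rpoisson_times(spec$base_rate, spec$duration)))
    })
  # refractory floor: drop spikes closer than 1.5 ms to their predecessor
  if (length(t) > 1) {
    keep <- logical(length(t)); keep[1] <- TRUE; last <- t[1]
    for (i in 2:length(t)) {
      if (t[i] - last >= 0.0015) { keep[i] <- TRUE; last <- t[i] }
    }
    t <- t[keep]
  }
  spike_train(unit_id, region, t, spec$duration, spike_width)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Specification for a synthetic force-plate session
#'
#' The per-sample force signal is band-limited noise (white noise low-pass
#' filtered at 8 Hz, zero-phase, then scaled so its variance equals
#' `noise_band_power`) plus an epoch-dependent tremor component
#' `amplitude * sin(2*pi*tremor_freq*t)` plus optional white measurement
#' noise. The centroid is a bounded random walk on the 440 x 440 mm plate.
#'
#' @param epoch_schedule list of [epoch()] objects; must tile a duration that
#'   is a whole number of 10.24 s frames, without gaps or overlaps.
#' @param tremor_freq tremor frequency in Hz (default 10, the center of the
#'   8-12 Hz harmaline tremor band).
#' @param tremor_amplitude_by_epoch named numeric vector, force units >= 0 per
#'   epoch label; labels absent from the map get amplitude 0.
#' @param noise_band_power variance of the 0-8 Hz background noise
#'   (force^2 units).
#' @param measurement_noise_sd SD of additive white sensor noise (force
#'   units); keep small relative to `sqrt(noise_band_power)` so the
#'   no-tremor spectrum stays confined below 8 Hz.
#' @param centroid_step_sd random-walk step SD in mm per sample (>= 0).
#' @param seed integer RNG seed.
#' @return an object of class `"tremor_gen_spec"`.
#' @export
tremor_gen_spec <- function(epoch_schedule,
                            tremor_freq = 10,
                            tremor_amplitude_by_epoch = c(harmaline = 1),
                            noise_band_power = 1,
                            measurement_noise_sd = 0.01,
                            centroid_step_sd = 0.5,
                            seed = 1L) {
  if (!length(epoch_schedule) ||
      !all(vapply(epoch_schedule, inherits, logical(1), "epoch")))
    stop_validation("epoch_schedule must be a list of epoch objects")
  starts <- vapply(epoch_schedule, `[[`, numeric(1), "start")
  ends <- vapply(epoch_schedule, `[[`, numeric(1), "end")
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  if (starts[1] != 0 || any(abs(ends[-length(ends)] - starts[-1]) > 1e-9))
    stop_validation("epoch_schedule must tile [0, T] without gaps or overlaps")
  total <- ends[length(ends)]
  frame_s <- FP_FRAME_LEN / FP_SAMPLING_RATE
  if (abs(total / frame_s - round(total / frame_s)) > 1e-9)
    stop_validation("total duration (", total,
                    " s) must be a whole number of 10.24 s frames")
  amp <- tremor_amplitude_by_epoch
  if (length(amp) && (any(!is.finite(amp)) || any(amp < 0)))
    stop_validation("tremor amplitudes must be finite and >= 0")
  if (!is.finite(tremor_freq) || tremor_freq <= 0)
    stop_validation("tremor_freq must be > 0")
  if (!is.finite(noise_band_power) || noise_band_power < 0)
    stop_validation("noise_band_power must be >= 0")
  if (!is.finite(centroid_step_sd) || centroid_step_sd < 0)
    stop_validation("centroid_step_sd must be >= 0")
  structure(list(epoch_schedule = epoch_schedule[o], tremor_freq = tremor_freq,
                 tremor_amplitude_by_epoch = amp,
                 noise_band_power = noise_band_power,
                 measurement_noise_sd = measurement_noise_sd,
                 centroid_step_sd = centroid_step_sd, seed = as.integer(seed)),
            class = "tremor_gen_spec")
}

#' Generate a synthetic force-plate session
#'
#' @param spec a [tremor_gen_spec()].
#' @param dose_mg_per_kg,stim_freq_hz,pulse_width_us,amplitude_ua intervention
#'   metadata recorded in the manifest.
#' @return a list with elements `recording` (a [forceplate_recording()]) and
#'   `manifest` (a [session_manifest()] matching the schedule).
#' @export
gen_forceplate_session <- function(spec, dose_mg_per_kg = 10,
                                   stim_freq_hz = 130, pulse_width_us = 100,
                                   amplitude_ua = 50) {
  stopifnot(inherits(spec, "tremor_gen_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  fs <- FP_SAMPLING_RATE
  total <- max(vapply(spec$epoch_schedule, `[[`, numeric(1), "end"))
  n <- round(total * fs)
  tt <- (seq_len(n) - 1) / fs

  # 0-8 Hz background: white noise -> zero-phase Butterworth low-pass.
  # Cutoff 6.5 Hz keeps >99% of the noise power below the 8 Hz band edge
  # after the squared (filtfilt) order-4 response.
  bf <- signal::butter(4, 6.5 / (fs / 2), type = "low")
  noise <- signal::filtfilt(bf, stats::rnorm(n))
  if (spec$noise_band_power > 0) {
    noise <- noise * sqrt(spec$noise_band_power) / stats::sd(noise)
  } else noise <- numeric(n)

  amps <- numeric(n)
  for (e in spec$epoch_schedule) {
    a <- unname(spec$tremor_amplitude_by_epoch[e$label] %|na|% 0)
    if (a != 0) amps[tt >= e$start & tt < e$end] <- a
  }
  force <- noise + amps * sin(2 * pi * spec$tremor_freq * tt) +
    stats::rnorm(n, 0, spec$measurement_noise_sd)

  # bounded random walk on the plate, reflecting at the 440 mm walls
  reflect <- function(x, lo = 0, hi = 440) {
    x <- (x - lo) %% (2 * (hi - lo))
    lo + ifelse(x > hi - lo, 2 * (hi - lo) - x, x)
  }
  cx <- reflect(220 + cumsum(stats::rnorm(n, 0, spec$centroid_step_sd)))
  cy <- reflect(220 + cumsum(stats::rnorm(n, 0, spec$centroid_step_sd)))

  manifest <- session_manifest(spec$epoch_schedule,
                               dose_mg_per_kg = dose_mg_per_kg,
                               stim_freq_hz = stim_freq_hz,
                               pulse_width_us = pulse_width_us,
                               amplitude_ua = amplitude_ua)
  list(recording = forceplate_recording(force, cbind(cx, cy)),
       manifest = manifest)
}

`%|na|%` <- function(a, b) if (length(a) == 0 || is.na(a)) b else a
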