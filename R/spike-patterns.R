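# Four-way firing-pattern classification: autocorrelogram-based oscillation
# detection (0.4-1.5 Hz), ISI-based burst detection (<=10 ms ISIs, >100 ms
# burst separation, >10% burst-cell rule), CV of ISI, and the unit-inclusion
# filters.

OSC_BAND <- c(0.4, 1.5)        # Hz, oscillation detection band
BURST_MAX_ISI <- 0.010         # s, max intra-burst ISI
BURST_MIN_SEP <- 0.100         # s, min separation between counted bursts
BURST_CELL_CUTOFF <- 0.10      # bursts / spikes, strict inequality
ACH_BIN_MS <- 1                # ms, autocorrelogram bin width
ACH_SMOOTH_SD_MS <- 2          # ms, Gaussian smoothing kernel SD
ACH_CENTER_CUT_MS <- 10        # ms, extent of central-peak removal
ACH_FFT_N <- 16384L            # zero-padded FFT length (~0.061 Hz resolution)
ACH_EVAL_RANGE <- c(0.1, 100)  # Hz, range over which threshold stats are taken
ACH_SPEC_SMOOTH_HZ <- 1.0      # Hz, Daniell window for periodogram smoothing

#' Autocorrelogram of a spike train
#'
#' Counts ordered spike pairs by lag in 1 ms bins over `[-max_lag, +max_lag]`
#' ms (bin `l` covers lags in `[l - 0.5, l + 0.5)` ms). Self-pairs are
#' excluded, so the histogram is symmetric with no zero-lag spike count.
#'
#' @param train a [spike_train()].
#' @param max_lag_ms maximum lag in ms. The default 5000 ms covers two full
#'   cycles at the 0.4 Hz lower band edge (2500 ms period).
#' @return an object of class `"autocorrelogram"` with fields `lags_ms`
#'   (integer lags from -max_lag to +max_lag), `counts`, `bin_width_ms`,
#'   `n_spikes` and `duration`.
#' @export
compute_ach <- function(train, max_lag_ms = 5000) {
  stopifnot(inherits(train, "spike_train"))
  if (max_lag_ms <= 0) stop_validation("max_lag_ms must be > 0")
  L <- as.integer(round(max_lag_ms))
  t <- train$spike_times
  n <- length(t)
  half <- integer(L + 1L)               # lag bins 0..L (positive side)
  max_lag_s <- (L + 0.5) / 1000
  if (n >= 2) {
    k <- 1L
    repeat {
      if (k >= n) break
      d <- t[(1L + k):n] - t[1L:(n - k)]
      d <- d[d < max_lag_s]
      if (!length(d)) break
      b <- as.integer(round(d * 1000)) + 1L       # bin index for lag 0 is 1
      half <- half + tabulate(b, nbins = L + 1L)
      k <- k + 1L
    }
  }
  counts <- c(rev(half[-1L]), half[1L] * 2L, half[-1L])
  # lag-0 bin: ordered pairs with |dt| < 0.5 ms counted in both directions
  structure(list(lags_ms = seq(-L, L), counts = counts,
                 bin_width_ms = ACH_BIN_MS, n_spikes = n,
                 duration = train$duration),
            class = "autocorrelogram")
}

gaussian_kernel_ms <- function(sd_ms) {
  r <- ceiling(4 * sd_ms)
  k <- exp(-0.5 * (seq(-r, r) / sd_ms)^2)
  k / sum(k)
}

#' Oscillation test on an autocorrelogram
#'
#' Pipeline: Gaussian smoothing (2 ms SD kernel, truncated at 4 SD) ->
#' removal of the central peak (bins with |lag| <= 10 ms replaced by the mean
#' of the remaining histogram) -> mean subtraction -> FFT of the one-sided
#' half, zero-padded to 16384 bins -> squared-magnitude power ->
#' Daniell-type periodogram smoothing (1 Hz running mean). The unit is
#' called oscillatory when some frequency bin inside the detection band
#' exceeds mean(power) + 3 * sd(power), with the threshold statistics taken
#' over 0.1-100 Hz.
#'
#' The periodogram smoothing step exists because raw periodogram ordinates
#' are approximately exponentially distributed, so under a flat (Poisson)
#' null some in-band ordinate exceeds mean + 3 SD far too often for a usable
#' classifier; averaging ~5 independent spectral bins (the intrinsic
#' resolution of a 5 s one-sided lag window is 0.2 Hz) lightens the tail so
#' the 3-SD rule has the intended specificity, while a genuine rate
#' modulation in band remains orders of magnitude above threshold. The
#' deterministic gain of the 2 ms lag-domain smoothing is divided out first
#' so the null spectrum is flat over the evaluation range.
#'
#' @param ach an [compute_ach()] result.
#' @param band detection band in Hz (default 0.4-1.5, the slow oscillation
#'   band used for harmaline-driven rhythmicity; configurable).
#' @return a list with `oscillatory` (logical), `peak_freq` (Hz inside the
#'   band when oscillatory, otherwise `NA`), `power`, `frequencies` and
#'   `threshold`.
#' @export
oscillation_test <- function(ach, band = OSC_BAND) {
  stopifnot(inherits(ach, "autocorrelogram"))
  if (all(ach$counts == 0))
    return(list(oscillatory = FALSE, peak_freq = NA_real_,
                power = NULL, frequencies = NULL, threshold = NA_real_))
  sm <- stats::filter(ach$counts, gaussian_kernel_ms(ACH_SMOOTH_SD_MS),
                      sides = 2)
  sm[is.na(sm)] <- 0
  sm <- as.numeric(sm)
  central <- abs(ach$lags_ms) <= ACH_CENTER_CUT_MS
  sm[central] <- mean(sm[!central])
  one_sided <- sm[ach$lags_ms >= 0]
  x <- one_sided - mean(one_sided)
  nfft <- max(ACH_FFT_N, 2^ceiling(log2(length(x))))
  X <- stats::fft(c(x, numeric(nfft - length(x))))
  nb <- nfft %/% 2
  power <- Mod(X[seq_len(nb)])^2
  freqs <- (seq_len(nb) - 1) * (1000 / ACH_BIN_MS) / nfft
  # undo the known gain of the 2-ms Gaussian lag smoothing so the null
  # spectrum is flat; otherwise threshold stats pooled over 0.1-100 Hz sit
  # below the low-frequency noise floor
  kern <- gaussian_kernel_ms(ACH_SMOOTH_SD_MS)
  gain <- Mod(stats::fft(c(kern, numeric(nfft - length(kern)))))[seq_len(nb)]^2
  power <- power / pmax(gain, 1e-6)
  raw_power <- power
  df <- freqs[2] - freqs[1]
  span <- 2L * floor(ACH_SPEC_SMOOTH_HZ / df / 2) + 1L   # odd window
  if (span >= 3) {
    power <- as.numeric(stats::filter(power, rep(1 / span, span), sides = 2))
    pad <- (span - 1L) %/% 2L
    power[seq_len(pad)] <- power[pad + 1L]
    power[(nb - pad + 1L):nb] <- power[nb - pad]
  }
  eval_bins <- freqs >= ACH_EVAL_RANGE[1] & freqs <= ACH_EVAL_RANGE[2]
  threshold <- mean(power[eval_bins]) + 3 * stats::sd(power[eval_bins])
  in_band <- freqs >= band[1] & freqs <= band[2]
  hit <- any(power[in_band] > threshold)
  # detection runs on the smoothed spectrum; the peak is localized on the
  # raw periodogram, whose in-band maximum is not blurred by the window
  peak <- if (hit) freqs[in_band][which.max(raw_power[in_band])] else NA_real_
  list(oscillatory = hit, peak_freq = peak, power = power,
       frequencies = freqs, threshold = threshold)
}

#' Detect bursts in a spike train
#'
#' A burst is a maximal run of >= 2 spikes whose consecutive ISIs are all
#' <= 10 ms. A candidate burst is *counted* only when more than 100 ms
#' separates its first spike from the last spike of the previously counted
#' burst; candidates failing the separation rule are discarded (their spikes
#' remain non-burst spikes), not merged.
#'
#' @param train a [spike_train()].
#' @param max_isi,min_sep burst definition parameters in seconds
#'   (defaults 0.010 and 0.100).
#' @return an object of class `"burst_set"`: list with `bursts` (list of
#'   spike index vectors), `n_bursts`, `n_spikes` and `burst_fraction`
#'   (= n_bursts / n_spikes, 0 for an empty train).
#' @export
detect_bursts <- function(train, max_isi = BURST_MAX_ISI,
                          min_sep = BURST_MIN_SEP) {
  stopifnot(inherits(train, "spike_train"))
  t <- train$spike_times
  n <- length(t)
  empty <- structure(list(bursts = list(), n_bursts = 0L, n_spikes = n,
                          burst_fraction = 0),
                     class = "burst_set")
  if (n < 2) return(empty)
  short <- diff(t) <= max_isi
  # candidate runs: maximal stretches of consecutive short ISIs
  r <- rle(short)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand_idx <- which(r$values)
  if (!length(cand_idx)) return(empty)
  bursts <- list()
  last_end_time <- -Inf
  for (j in cand_idx) {
    first <- starts[j]               # index of first spike in run
    last <- ends[j] + 1L             # run of k ISIs spans k+1 spikes
    if (t[first] - last_end_time > min_sep) {
      bursts[[length(bursts) + 1L]] <- first:last
      last_end_time <- t[last]
    }
  }
  structure(list(bursts = bursts, n_bursts = length(bursts), n_spikes = n,
                 burst_fraction = length(bursts) / n),
            class = "burst_set")
}

#' Burst-cell test
#'
#' A unit is a burst cell when its counted bursts exceed 10% of its total
#' spike count in the period (strict inequality).
#'
#' @param burstset a [detect_bursts()] result.
#' @param cutoff burst-fraction cutoff (default 0.10).
#' @return logical.
#' @export
burst_cell_test <- function(burstset, cutoff = BURST_CELL_CUTOFF) {
  stopifnot(inherits(burstset, "burst_set"))
  if (burstset$n_spikes == 0) {
    warning("burst_cell_test on a unit with zero spikes; returning FALSE")
    return(FALSE)
  }
  burstset$burst_fraction > cutoff
}

#' Coefficient of variation of interspike intervals
#'
#' SD of the ISIs divided by their mean: 0 for a clock-like train, ~1 for a
#' Poisson train.
#'
#' @param train a [spike_train()] with >= 3 spikes (>= 2 ISIs).
#' @return the CV, or `NA` (with a warning) when fewer than 2 ISIs exist.
#' @export
compute_cv <- function(train) {
  stopifnot(inherits(train, "spike_train"))
  isi <- diff(train$spike_times)
  if (length(isi) < 2) {
    warning("compute_cv needs >= 2 ISIs; returning NA")
    return(NA_real_)
  }
  stats::sd(isi) / mean(isi)
}

#' Classify the firing pattern of a unit
#'
#' Conjunction of the oscillation test and the burst-cell test:
#' (TRUE, TRUE) -> os-burst, (TRUE, FALSE) -> os-non-burst,
#' (FALSE, TRUE) -> irr-burst, (FALSE, FALSE) -> irr-non-burst.
#'
#' @param train a [spike_train()] (callers normally pre-filter with
#'   [select_units()]).
#' @param band oscillation detection band in Hz.
#' @param max_lag_ms autocorrelogram extent in ms.
#' @param max_isi,min_sep,burst_cutoff burst-detection parameters, see
#'   [detect_bursts()] and [burst_cell_test()].
#' @return an object of class `"pattern_label"`: list with `label`,
#'   `oscillatory`, `burst`, `peak_freq` (present iff oscillatory),
#'   `burst_fraction`, `cv` and `n_spikes`.
#' @export
classify_pattern <- function(train, band = OSC_BAND, max_lag_ms = 5000,
                             max_isi = BURST_MAX_ISI, min_sep = BURST_MIN_SEP,
                             burst_cutoff = BURST_CELL_CUTOFF) {
  stopifnot(inherits(train, "spike_train"))
  osc <- oscillation_test(compute_ach(train, max_lag_ms), band)
  bs <- detect_bursts(train, max_isi, min_sep)
  is_burst <- if (bs$n_spikes > 0) burst_cell_test(bs, burst_cutoff) else FALSE
  label <- paste0(if (osc$oscillatory) "os" else "irr",
                  if (is_burst) "-burst" else "-non-burst")
  cv <- if (length(train$spike_times) >= 3) compute_cv(train) else NA_real_
  structure(list(label = label, oscillatory = osc$oscillatory,
                 burst = is_burst,
                 peak_freq = if (osc$oscillatory) osc$peak_freq else NA_real_,
                 burst_fraction = bs$burst_fraction, cv = cv,
                 n_spikes = length(train$spike_times)),
            class = "pattern_label")
}

#' @export
print.pattern_label <- function(x, ...) {
  cat(sprintf("<pattern_label> %s (osc=%s%s, burst=%s, fraction %.3f, CV %.2f)\n",
              x$label, x$oscillatory,
              if (x$oscillatory) sprintf(" @ %.2f Hz", x$peak_freq) else "",
              x$burst, x$burst_fraction, x$cv))
  invisible(x)
}

#' Unit-inclusion filters
#'
#' M1 units are kept as putative pyramidal neurons when mean rate <= 10 Hz
#' and spike width < 280 microseconds, and must additionally exceed 200
#' spikes in the 20-min analysis window. VLT units face only the spike-count
#' filter: thalamic nuclei in rodents have under 1% interneurons, so no
#' waveform subgrouping is applied.
#'
#' @param trains list of [spike_train()] objects spanning the analysis
#'   window.
#' @param region `"M1"` or `"VLT"`; only trains from this region are
#'   considered.
#' @param window_s analysis window length in seconds over which the spike
#'   count is evaluated (default 20 min). Trains shorter than the window are
#'   counted over their whole extent.
#' @param max_rate,max_width_us,min_spikes filter thresholds.
#' @return the subset of `trains` passing the region's filters.
#' @export
select_units <- function(trains, region, window_s = 1200,
                         max_rate = 10, max_width_us = 280,
                         min_spikes = 200) {
  region <- match.arg(region, REGIONS)
  keep <- vapply(trains, function(tr) {
    if (tr$region != region) return(FALSE)
    n_window <- sum(tr$spike_times < window_s)
    if (n_window <= min_spikes) return(FALSE)
    if (region == "M1") {
      if (is.na(tr$spike_width))
        stop_validation("M1 unit '", tr$unit_id,
                        "' lacks spike_width metadata required by the filter")
      if (tr$mean_rate > max_rate) return(FALSE)
      if (tr$spike_width >= max_width_us) return(FALSE)
    }
    TRUE
  }, logical(1))
  trains[keep]
}
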