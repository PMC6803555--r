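# Motion Power Ratio (MPR) tremor quantification from framed force-plate
# signals: per-frame Hanning-windowed power spectra, the 8-12 Hz / 0-8 Hz
# band-power ratio, baseline-normalized epoch means, peak frequency, and the
# convex-hull moving-area mobility control.

MPR_TREMOR_BAND <- c(8, 12)   # Hz, numerator (8 Hz edge assigned here)
MPR_MOTION_BAND <- c(0, 8)    # Hz, denominator, DC excluded, open at 8

#' Power spectrum of one force-plate frame
#'
#' Applies a Hanning window to the 1024-sample frame and returns the
#' one-sided squared-magnitude spectrum. The normalization is chosen so that
#' the spectrum sums to the windowed signal's sum of squares (Parseval);
#' the window's coherent gain is deliberately not corrected because the MPR
#' is a ratio of band powers and the gain cancels.
#'
#' @param frame numeric vector of exactly 1024 finite force samples.
#' @return an object of class `"frame_spectrum"` with fields `frequencies`
#'   (513 values, 0 to 50 Hz in steps of 100/1024 Hz) and `power`.
#' @export
frame_power_spectrum <- function(frame) {
  n <- FP_FRAME_LEN
  if (length(frame) != n)
    stop_validation("frame must have exactly ", n, " samples, got ",
                    length(frame))
  if (!all(is.finite(frame)))
    stop_validation("frame contains non-finite samples")
  w <- 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / n))   # periodic Hanning window
  x <- frame * w
  X <- stats::fft(x)
  nb <- n / 2 + 1                                   # 513 one-sided bins
  p <- Mod(X[seq_len(nb)])^2 / n
  p[2:(nb - 1)] <- 2 * p[2:(nb - 1)]                # fold negative freqs
  structure(list(frequencies = (0:(nb - 1)) * FP_SAMPLING_RATE / n,
                 power = p),
            class = "frame_spectrum")
}

#' Motion Power Ratio of one frame spectrum
#'
#' The MPR is the tremor-band power (8 <= f <= 12 Hz) divided by the motion
#' band power (0 < f < 8 Hz). The DC bin is excluded from the denominator so
#' a constant force offset (the animal's weight) cannot dominate it; the
#' shared 8 Hz edge is assigned to the tremor band.
#'
#' @param spectrum a [frame_spectrum()].
#' @return the ratio (>= 0), or `NA` when the denominator is zero (callers
#'   exclude such frames from epoch means and count them).
#' @export
frame_mpr <- function(spectrum) {
  stopifnot(inherits(spectrum, "frame_spectrum"))
  f <- spectrum$frequencies
  num <- sum(spectrum$power[f >= MPR_TREMOR_BAND[1] & f <= MPR_TREMOR_BAND[2]])
  den <- sum(spectrum$power[f > MPR_MOTION_BAND[1] & f < MPR_MOTION_BAND[2]])
  if (den == 0) return(NA_real_)
  num / den
}

frames_of <- function(recording) {
  matrix(recording$force, nrow = FP_FRAME_LEN)   # one column per frame
}

#' Per-frame and per-epoch Motion Power Ratio series
#'
#' Splits the recording into its consecutive non-overlapping 1024-sample
#' frames, computes the MPR of each, averages per epoch (a frame belongs to
#' the epoch containing its start time), and normalizes the per-epoch means
#' by the baseline-epoch mean so the baseline maps to 1.
#'
#' Frames with an undefined MPR (zero denominator) are dropped from epoch
#' means; their count is reported in `n_undefined`.
#'
#' @param recording a [forceplate_recording()].
#' @param manifest a [session_manifest()] whose epochs include `"baseline"`.
#' @return an object of class `"mpr_series"`: a list with `per_frame`
#'   (data.frame: frame_idx, t_start_s, epoch, mpr), `per_epoch_mpr` and
#'   `normalized_epoch_mpr` (named numeric), and `n_undefined`.
#' @export
epoch_mpr <- function(recording, manifest) {
  stopifnot(inherits(recording, "forceplate_recording"),
            inherits(manifest, "session_manifest"))
  if (is.null(find_epoch(manifest, "baseline")))
    stop_validation("manifest has no baseline epoch; normalization undefined")
  fr <- frames_of(recording)
  t_start <- (seq_len(ncol(fr)) - 1) * FP_FRAME_LEN / recording$sampling_rate
  ep_label <- rep(NA_character_, ncol(fr))
  for (e in manifest$epochs)
    ep_label[t_start >= e$start & t_start < e$end] <- e$label
  mpr <- vapply(seq_len(ncol(fr)),
                function(i) frame_mpr(frame_power_spectrum(fr[, i])),
                numeric(1))
  n_undef <- sum(is.na(mpr) & !is.na(ep_label))
  labels <- vapply(manifest$epochs, `[[`, character(1), "label")
  per_epoch <- vapply(labels, function(lb)
    mean(mpr[!is.na(ep_label) & ep_label == lb], na.rm = TRUE), numeric(1))
  normalized <- per_epoch / per_epoch[["baseline"]]
  structure(list(per_frame = data.frame(frame_idx = seq_len(ncol(fr)),
                                        t_start_s = t_start,
                                        epoch = ep_label, mpr = mpr),
                 per_epoch_mpr = per_epoch,
                 normalized_epoch_mpr = normalized,
                 n_undefined = n_undef),
            class = "mpr_series")
}

#' @export
print.mpr_series <- function(x, ...) {
  cat("<mpr_series>\n")
  for (lb in names(x$per_epoch_mpr))
    cat(sprintf("  %-10s mean MPR %.4f  (normalized %.3f)\n", lb,
                x$per_epoch_mpr[[lb]], x$normalized_epoch_mpr[[lb]]))
  if (x$n_undefined > 0)
    cat("  frames with undefined MPR dropped:", x$n_undefined, "\n")
  invisible(x)
}

#' Peak frequency of a set of frame spectra
#'
#' Argmax frequency of the mean spectrum, excluding the DC and near-DC bins
#' (f <= 0.3 Hz) so constant offsets and slow drift do not win.
#'
#' @param spectra a list of [frame_power_spectrum()] results (>= 1).
#' @return the peak frequency in Hz.
#' @export
tremor_peak_frequency <- function(spectra) {
  if (!length(spectra)) stop_validation("need at least one spectrum")
  stopifnot(all(vapply(spectra, inherits, logical(1), "frame_spectrum")))
  p <- rowMeans(vapply(spectra, `[[`, numeric(513), "power"))
  f <- spectra[[1]]$frequencies
  keep <- f > 0.3
  f[keep][which.max(p[keep])]
}

#' Gross moving area of the animal in an epoch
#'
#' Area (mm^2) of the convex hull of the centroid trajectory within the
#' epoch, the mobility control used to check that tremor-band changes are
#' not movement artifacts. Collinear or stationary trajectories have area 0.
#'
#' @param centroid n x 2 matrix of per-sample (x, y) positions in mm at the
#'   force-plate sampling rate.
#' @param ep an [epoch()]; samples with start <= t < end are used.
#' @return hull area in mm^2.
#' @export
moving_area <- function(centroid, ep) {
  stopifnot(inherits(ep, "epoch"))
  centroid <- as.matrix(centroid)
  tt <- (seq_len(nrow(centroid)) - 1) / FP_SAMPLING_RATE
  pts <- centroid[tt >= ep$start & tt < ep$end, , drop = FALSE]
  if (nrow(pts) < 1)
    stop_validation("no centroid samples in epoch [", ep$start, ", ", ep$end, ")")
  pts <- unique(pts)
  if (nrow(pts) < 3) return(0)
  h <- grDevices::chull(pts[, 1], pts[, 2])
  hx <- pts[h, 1]; hy <- pts[h, 2]
  # shoelace formula over the hull vertices (chull returns them in order)
  abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
}
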