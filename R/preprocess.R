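#' Reject trials by amplitude thresholds
#'
#' An epoch is discarded when its absolute signal exceeds `eog_thresh_uv` on
#' any EOG channel or `grad_thresh_ftcm` on any gradiometer channel,
#' evaluated over the full epoch including the baseline. Defaults are the
#' standard 150 uV / 3000 fT/cm thresholds. The order of surviving epochs
#' is preserved.
#'
#' @param trials a [trial_set()].
#' @param eog_thresh_uv EOG rejection threshold in uV (default 150).
#' @param grad_thresh_ftcm gradiometer rejection threshold in fT/cm
#'   (default 3000).
#' @return list with `trials` (surviving epochs) and `rejected` (integer
#'   indices of discarded epochs in the input). Warns if nothing survives.
#' @export
reject_trials <- function(trials, eog_thresh_uv = 150, grad_thresh_ftcm = 3000) {
  stopifnot(eog_thresh_uv > 0, grad_thresh_ftcm > 0)
  eog <- .eog_idx(trials)
  grads <- .grad_idx(trials)
  n <- n_epochs(trials)
  bad <- logical(n)
  for (e in seq_len(n)) {
    over_eog <- length(eog) > 0 &&
      max(abs(trials$data[e, eog, , drop = FALSE])) > eog_thresh_uv
    over_grad <- length(grads) > 0 &&
      max(abs(trials$data[e, grads, , drop = FALSE])) > grad_thresh_ftcm
    bad[e] <- over_eog || over_grad
  }
  if (all(bad)) warning("all epochs rejected")
  kept <- subset_epochs(trials, which(!bad))
  attr(kept, "artifact_epochs") <- NULL
  list(trials = kept, rejected = which(bad))
}

#' Condition-averaged evoked response
#'
#' Arithmetic mean across the epochs whose label is in `condition`,
#' time-locked to stimulus onset. Target-variant epochs are not pulled in
#' implicitly: only exact label matches are averaged.
#'
#' @param trials a [trial_set()].
#' @param condition one or more condition labels to average (epochs with any
#'   of these labels are pooled).
#' @return object of class `evoked`: channels x samples matrix plus
#'   metadata (`n_trials`, `condition`, `times_ms`, processing history).
#' @export
average_evoked <- function(trials, condition) {
  idx <- which(trials$labels %in% condition)
  if (length(idx) == 0) {
    stop("missing condition: no epochs labeled ", paste(condition, collapse = "/"))
  }
  dat <- trials$data[idx, , , drop = FALSE]
  avg <- apply(dat, c(2, 3), mean)
  structure(list(
    data = avg,
    channel_meta = trials$channel_meta,
    sfreq_hz = trials$sfreq_hz,
    times_ms = trials$times_ms,
    condition = paste(condition, collapse = "+"),
    n_trials = length(idx),
    baseline_window_ms = NULL,
    filter_applied_hz = NULL,
    amplitude = FALSE
  ), class = "evoked")
}

#' @export
print.evoked <- function(x, ...) {
  cat(sprintf("<evoked> '%s': %d channels x %d samples, n_trials=%d\n",
              x$condition, nrow(x$data), ncol(x$data), x$n_trials))
  if (!is.null(x$filter_applied_hz))
    cat(sprintf("  low-pass %g Hz\n", x$filter_applied_hz))
  if (isTRUE(x$amplitude)) cat("  combined gradient amplitude (fT/cm)\n")
  invisible(x)
}

# zero-phase FIR low-pass applied to each row of a matrix
.lp_matrix <- function(mat, sfreq_hz, cutoff_hz) {
  if (cutoff_hz <= 0 || cutoff_hz >= sfreq_hz / 2) {
    stop("invalid parameter: cutoff must lie in (0, Nyquist)")
  }
  ord <- 2L * ceiling(1.65 * sfreq_hz / cutoff_hz)
  b <- as.numeric(signal::fir1(ord, cutoff_hz / (sfreq_hz / 2), type = "low"))
  t(apply(mat, 1, function(x) signal::filtfilt(b, 1, x)))
}

#' Zero-phase low-pass filter
#'
#' Forward-backward FIR filtering (Hamming-window design), so the filter is
#' zero-phase and onsets are not delayed. The realized response has unity
#' passband gain (within 1%) below half the cutoff and at least 20 dB
#' attenuation above twice the cutoff.
#'
#' @param x an `evoked`, a `source_estimate`, or a numeric matrix/vector.
#' @param cutoff_hz cutoff frequency in Hz; must be below Nyquist.
#' @param ... passed to methods; the default method requires `sfreq_hz`.
#' @return the filtered object, same class and dimensions as the input.
#' @export
lowpass <- function(x, cutoff_hz, ...) UseMethod("lowpass")

#' @rdname lowpass
#' @export
lowpass.evoked <- function(x, cutoff_hz, ...) {
  x$data <- .lp_matrix(x$data, x$sfreq_hz, cutoff_hz)
  x$filter_applied_hz <- cutoff_hz
  x
}

#' @rdname lowpass
#' @param sfreq_hz sampling rate in Hz (default method only).
#' @export
lowpass.default <- function(x, cutoff_hz, sfreq_hz, ...) {
  if (is.matrix(x)) .lp_matrix(x, sfreq_hz, cutoff_hz)
  else drop(.lp_matrix(matrix(x, 1), sfreq_hz, cutoff_hz))
}

#' Baseline-correct an evoked response
#'
#' Subtracts each channel's mean over the pre-stimulus baseline window.
#' Applies only to signed channel data; combined gradient amplitudes have a
#' positive noise floor and are deliberately never re-baselined (the onset
#' detector accounts for the floor instead).
#'
#' @param evoked an `evoked` with signed channels.
#' @param window_ms baseline window in ms, default `c(-200, 0)`
#'   (right-open: the stimulus-onset sample is excluded).
#' @return the baseline-corrected `evoked`.
#' @export
baseline_correct <- function(evoked, window_ms = c(-200, 0)) {
  if (isTRUE(evoked$amplitude)) {
    stop("combined amplitude channels are not baseline-corrected")
  }
  idx <- .window_idx(evoked$times_ms, window_ms)
  if (length(idx) == 0) stop("invalid window: baseline outside epoch")
  bl <- rowMeans(evoked$data[, idx, drop = FALSE])
  evoked$data <- evoked$data - bl
  evoked$baseline_window_ms <- window_ms
  evoked
}

#' Combine planar-gradiometer pairs into amplitudes
#'
#' At each sensor location the two orthogonal planar gradiometers measure
#' field gradients bx and by; their Euclidean amplitude sqrt(bx^2 + by^2)
#' is orientation-invariant and nonnegative. Channel count halves: one
#' amplitude channel per location. Non-gradiometer channels (EOG) are
#' dropped.
#'
#' @param evoked an `evoked` with complete grad_x/grad_y pairs.
#' @return an `evoked` of combined amplitudes (`amplitude = TRUE`), one
#'   channel per `location_id`.
#' @export
gradient_amplitude <- function(evoked) {
  cm <- evoked$channel_meta
  ix <- which(cm$kind == "grad_x")
  iy <- which(cm$kind == "grad_y")
  if (!setequal(cm$location_id[ix], cm$location_id[iy])) {
    stop("channel-pairing error: unpaired gradiometer channel")
  }
  locs <- sort(unique(cm$location_id[ix]))
  amp <- matrix(0, length(locs), ncol(evoked$data))
  for (i in seq_along(locs)) {
    bx <- evoked$data[ix[cm$location_id[ix] == locs[i]], ]
    by <- evoked$data[iy[cm$location_id[iy] == locs[i]], ]
    amp[i, ] <- sqrt(bx^2 + by^2)
  }
  evoked$data <- amp
  evoked$channel_meta <- data.frame(
    name = sprintf("AMP%03d", locs), kind = "grad_amp",
    unit = "fT/cm", location_id = locs)
  evoked$amplitude <- TRUE
  evoked
}

#' Select the sensor location with the maximal early response
#'
#' Returns the `location_id` whose combined gradient amplitude attains the
#' largest value inside the search window (default 70-130 ms, bracketing
#' the ~100 ms sensory-specific deflection). Ties break to the lowest
#' location id.
#'
#' @param evoked_amplitude an `evoked` from [gradient_amplitude()].
#' @param search_window_ms window in ms, default `c(70, 130)`.
#' @return integer `location_id`.
#' @export
select_max_sensor <- function(evoked_amplitude, search_window_ms = c(70, 130)) {
  stopifnot(isTRUE(evoked_amplitude$amplitude))
  idx <- .window_idx(evoked_amplitude$times_ms, search_window_ms, right_open = FALSE)
  if (length(idx) == 0) stop("invalid window: search window outside epoch")
  peaks <- apply(evoked_amplitude$data[, idx, drop = FALSE], 1, max)
  locs <- evoked_amplitude$channel_meta$location_id
  best <- which(peaks == max(peaks))
  locs[best[which.min(locs[best])]]
}

#' Sensor-space evoked amplitude pipeline
#'
#' Convenience composition of the standard sensor-space order of
#' operations: average epochs, low-pass filter, baseline-correct the signed
#' signals, then combine gradiometer pairs into amplitudes.
#'
#' @param trials a [trial_set()] (after rejection).
#' @param condition condition label(s) to average.
#' @param lowpass_hz low-pass cutoff in Hz (default 40; `NULL` to skip).
#' @param baseline_window_ms baseline window (default `c(-200, 0)`).
#' @return a combined-amplitude `evoked`.
#' @export
evoked_amplitude <- function(trials, condition, lowpass_hz = 40,
                             baseline_window_ms = c(-200, 0)) {
  ev <- average_evoked(trials, condition)
  if (!is.null(lowpass_hz)) ev <- lowpass(ev, lowpass_hz)
  ev <- baseline_correct(ev, baseline_window_ms)
  gradient_amplitude(ev)
}
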