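#' Trial-level MEG data container
#'
#' A `trial_set` holds epoched multichannel data as a 3-D array
#' (epochs x channels x samples) together with channel metadata, the time
#' axis, and per-epoch condition labels. Planar-gradiometer channels come in
#' x/y pairs sharing a `location_id`; EOG channels carry `location_id` 0.
#'
#' @param data numeric array, epochs x channels x samples.
#' @param channel_meta data.frame with columns `name`, `kind`
#'   (`"grad_x"`, `"grad_y"` or `"eog"`), `unit` (`"fT/cm"` or `"uV"`) and
#'   `location_id` (integer; grad_x/grad_y pairs share one id).
#' @param sfreq_hz sampling rate in Hz.
#' @param times_ms sample times in ms, length equal to `dim(data)[3]`.
#' @param labels condition label per epoch (e.g. `"A"`, `"V"`, `"AV"`,
#'   `"A_Target"`, ..., `"Noise"`).
#' @param run_id integer run identifier per epoch.
#' @param subject_id subject identifier string.
#' @return an object of class `trial_set`.
#' @export
trial_set <- function(data, channel_meta, sfreq_hz, times_ms, labels,
                      run_id = rep(1L, dim(data)[1]), subject_id = "sim") {
  stopifnot(is.array(data), length(dim(data)) == 3)
  n_epochs <- dim(data)[1]
  n_channels <- dim(data)[2]
  n_samples <- dim(data)[3]
  stopifnot(nrow(channel_meta) == n_channels,
            length(times_ms) == n_samples,
            length(labels) == n_epochs)
  if (length(run_id) == 1) run_id <- rep(as.integer(run_id), n_epochs)
  stopifnot(length(run_id) == n_epochs)
  step <- .times_step(times_ms)
  stopifnot(abs(step - 1000 / sfreq_hz) < 1e-6)
  # every grad location must have exactly one grad_x and one grad_y
  gx <- channel_meta$location_id[channel_meta$kind == "grad_x"]
  gy <- channel_meta$location_id[channel_meta$kind == "grad_y"]
  if (!setequal(gx, gy) || anyDuplicated(gx) || anyDuplicated(gy)) {
    stop("grad_x/grad_y channels must come in pairs sharing a location_id")
  }
  structure(list(
    data = data,
    channel_meta = channel_meta,
    sfreq_hz = sfreq_hz,
    times_ms = times_ms,
    labels = as.character(labels),
    run_id = as.integer(run_id),
    subject_id = subject_id
  ), class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<trial_set> %d epochs x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$sfreq_hz))
  cat(sprintf("  time %g..%g ms, subject %s\n",
              min(x$times_ms), max(x$times_ms), x$subject_id))
  tab <- table(x$labels)
  cat("  conditions:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Number of epochs in a trial set
#' @param trials a [trial_set()].
#' @return integer epoch count.
#' @export
n_epochs <- function(trials) dim(trials$data)[1]

#' Subset epochs of a trial set
#'
#' @param trials a [trial_set()].
#' @param idx integer epoch indices (duplicates allowed, e.g. for bootstrap
#'   resampling).
#' @return a `trial_set` with the selected epochs, in the given order.
#' @export
subset_epochs <- function(trials, idx) {
  stopifnot(all(idx >= 1), all(idx <= n_epochs(trials)))
  out <- trials
  out$data <- trials$data[idx, , , drop = FALSE]
  out$labels <- trials$labels[idx]
  out$run_id <- trials$run_id[idx]
  out
}

# channel index helpers
.grad_idx <- function(trials) which(trials$channel_meta$kind %in% c("grad_x", "grad_y"))
.eog_idx <- function(trials) which(trials$channel_meta$kind == "eog")
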