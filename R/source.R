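#' Baseline noise covariance
#'
#' Empirical covariance of the gradiometer channels over pre-stimulus
#' baseline samples pooled across epochs, with diagonal loading
#' `epsilon * trace(C) / n_channels` added so the matrix is invertible.
#' When fewer pooled samples than channels are available the estimate is
#' rank-deficient; a warning is issued and the loading is increased
#' tenfold.
#'
#' @param trials a [trial_set()].
#' @param baseline_window_ms baseline window in ms, default `c(-200, 0)`.
#' @param epsilon relative diagonal loading (default 1e-3).
#' @return object of class `noise_cov`: list with `matrix`
#'   (channels x channels, gradiometers only) and `n_samples_used`.
#' @export
estimate_noise_cov <- function(trials, baseline_window_ms = c(-200, 0),
                               epsilon = 1e-3) {
  grads <- .grad_idx(trials)
  idx <- .window_idx(trials$times_ms, baseline_window_ms)
  if (length(idx) == 0) stop("invalid window: baseline outside epoch")
  n_ep <- n_epochs(trials)
  # pooled baseline samples: (epochs * samples) x channels
  X <- matrix(aperm(trials$data[, grads, idx, drop = FALSE], c(1, 3, 2)),
              n_ep * length(idx), length(grads))
  if (nrow(X) < ncol(X)) {
    warning("fewer baseline samples than channels; increasing diagonal loading")
    epsilon <- epsilon * 10
  }
  C <- cov(X)
  scale <- mean(diag(C))
  if (scale == 0) scale <- 1
  C <- C + diag(epsilon * scale, ncol(C))
  structure(list(matrix = C, n_samples_used = nrow(X)), class = "noise_cov")
}

#' Minimum-norm source estimate
#'
#' Linear minimum-norm inverse with identity source covariance:
#' `W = L' (L L' + lambda2 C_eff)^-1`, applied to the evoked sensor data
#' (gradiometer channels). `C_eff = C / nave` is the noise covariance of
#' the *averaged* data: the single-trial covariance divided by the number
#' of averaged trials, following the standard convention. `lambda2` is the
#' regularization weight; the conventional default 1/9 corresponds to an
#' assumed amplitude SNR of 3 in the average.
#'
#' @param evoked a signed `evoked` (gradiometer channels are used).
#' @param leadfield a [make_leadfield()] object, gain channels x sources.
#' @param noise_cov a [estimate_noise_cov()] object (single-trial baseline
#'   covariance).
#' @param lambda2 regularization parameter (default 1/9).
#' @param nave number of trials averaged into `evoked`; defaults to
#'   `evoked$n_trials`. Pass 1 for single-trial data.
#' @return object of class `source_estimate`: `values` (sources x samples),
#'   `kind = "mne"`, the inverse operator `W`, `nave`, `times_ms`,
#'   `lambda2` and the leadfield's `roi_map`.
#' @export
compute_mne <- function(evoked, leadfield, noise_cov, lambda2 = 1/9,
                        nave = evoked$n_trials) {
  stopifnot(lambda2 >= 0, nave >= 1)
  G <- leadfield$gain
  grads <- which(evoked$channel_meta$kind %in% c("grad_x", "grad_y"))
  if (length(grads) != nrow(G) || nrow(noise_cov$matrix) != nrow(G)) {
    stop("channel sets of evoked, leadfield and noise covariance must agree")
  }
  M <- G %*% t(G) + lambda2 * noise_cov$matrix / nave
  Minv <- tryCatch(solve(M), error = function(e) {
    stop("singular system after regularization: ", conditionMessage(e))
  })
  W <- t(G) %*% Minv
  structure(list(
    values = W %*% evoked$data[grads, , drop = FALSE],
    kind = "mne",
    W = W,
    nave = nave,
    times_ms = evoked$times_ms,
    sfreq_hz = evoked$sfreq_hz,
    lambda2 = lambda2,
    roi_map = leadfield$roi_map,
    condition = evoked$condition
  ), class = "source_estimate")
}

#' @export
print.source_estimate <- function(x, ...) {
  cat(sprintf("<source_estimate> kind=%s: %d sources x %d samples (lambda2=%g)\n",
              x$kind, nrow(x$values), ncol(x$values), x$lambda2))
  invisible(x)
}

#' dSPM noise normalization
#'
#' Divides each source's minimum-norm time course by its projected noise
#' standard deviation `sqrt(w_s C_eff w_s')`, where `w_s` is the source's
#' row of the inverse operator and `C_eff = C / nave` is the noise
#' covariance of the averaged data. Under pure noise the normalized
#' baseline then has unit SD per source; the normalized estimate behaves
#' as a signed square-root F statistic and has reduced point spread
#' relative to the raw estimate.
#'
#' @param mne a `source_estimate` of kind `"mne"` (from [compute_mne()]).
#' @param noise_cov the [estimate_noise_cov()] used for the inverse.
#' @return a `source_estimate` of kind `"dspm"`.
#' @export
dspm_normalize <- function(mne, noise_cov) {
  stopifnot(inherits(mne, "source_estimate"), mne$kind == "mne")
  sd_s <- sqrt(rowSums((mne$W %*% (noise_cov$matrix / mne$nave)) * mne$W))
  if (any(sd_s <= 0)) stop("zero projected noise variance for a source")
  out <- mne
  out$values <- mne$values / sd_s
  out$kind <- "dspm"
  out$noise_sd_per_source <- sd_s
  out
}

#' Extract ROI time courses from a source estimate
#'
#' Mean absolute source value across each ROI's source indices, per sample.
#' With `combine_hemispheres = TRUE` a requested name like `"A1"` is
#' resolved to the `"A1_left"`/`"A1_right"` entries of the ROI map and the
#' two hemisphere time courses are averaged sample-wise (magnitudes are
#' taken per source before any averaging).
#'
#' @param ste a `source_estimate`.
#' @param roi_names ROI names to extract (default `c("A1", "V1")` with
#'   hemisphere combination).
#' @param combine_hemispheres average `_left`/`_right` pairs (default TRUE).
#' @return object of class `roi_tc`: list with `data` (ROIs x samples
#'   matrix, rownames = ROI names) and `times_ms`.
#' @export
extract_roi_timecourse <- function(ste, roi_names = c("A1", "V1"),
                                   combine_hemispheres = TRUE) {
  one <- function(name) {
    idx <- ste$roi_map[[name]]
    if (is.null(idx) || length(idx) == 0) {
      stop("config error: empty or unknown ROI '", name, "'")
    }
    colMeans(abs(ste$values[idx, , drop = FALSE]))
  }
  rows <- lapply(roi_names, function(name) {
    if (combine_hemispheres && is.null(ste$roi_map[[name]])) {
      lr <- paste0(name, c("_left", "_right"))
      if (!all(lr %in% names(ste$roi_map))) {
        stop("config error: neither '", name, "' nor its _left/_right pair found")
      }
      (one(lr[1]) + one(lr[2])) / 2
    } else {
      one(name)
    }
  })
  structure(list(
    data = do.call(rbind, stats::setNames(rows, roi_names)),
    times_ms = ste$times_ms,
    sfreq_hz = ste$sfreq_hz,
    kind = ste$kind
  ), class = "roi_tc")
}

#' @export
print.roi_tc <- function(x, ...) {
  cat(sprintf("<roi_tc> %s x %d samples (%s)\n",
              paste(rownames(x$data), collapse = ", "), ncol(x$data),
              if (is.null(x$kind)) "sensor" else x$kind))
  invisible(x)
}

#' Audiovisual interaction contrast AV - (A + V)
#'
#' Sample-wise deviation from additivity of the audiovisual response:
#' `AV - (A + V)`. The contrast is formed on signed waveforms (sensor
#' signals or signed source estimates), never on rectified amplitudes, and
#' is by default low-pass filtered at 20 Hz because the three-way
#' combination raises the noise SD by sqrt(3) over its constituents.
#'
#' @param A,V,AV responses of identical class and time axis: `evoked`
#'   (signed), `source_estimate`, or numeric matrix/vector.
#' @param lowpass_hz cutoff for the stricter interaction filtering
#'   (default 20; `NULL` to skip).
#' @param sfreq_hz sampling rate, required only for plain numeric input
#'   when `lowpass_hz` is not `NULL`.
#' @return the interaction response, same class as the inputs.
#' @export
interaction_response <- function(A, V, AV, lowpass_hz = 20, sfreq_hz = NULL) {
  if (inherits(A, "evoked")) {
    stopifnot(inherits(V, "evoked"), inherits(AV, "evoked"))
    if (isTRUE(A$amplitude) || isTRUE(V$amplitude) || isTRUE(AV$amplitude)) {
      stop("interaction contrast requires signed waveforms, not amplitudes")
    }
    .check_times(A$times_ms, V$times_ms, AV$times_ms)
    out <- AV
    out$data <- AV$data - (A$data + V$data)
    out$condition <- "AV_interaction"
    out$n_trials <- min(A$n_trials, V$n_trials, AV$n_trials)
    if (!is.null(lowpass_hz)) out <- lowpass(out, lowpass_hz)
    return(out)
  }
  if (inherits(A, "source_estimate")) {
    stopifnot(inherits(V, "source_estimate"), inherits(AV, "source_estimate"))
    .check_times(A$times_ms, V$times_ms, AV$times_ms)
    out <- AV
    out$values <- AV$values - (A$values + V$values)
    out$condition <- "AV_interaction"
    if (!is.null(lowpass_hz)) {
      out$values <- .lp_matrix(out$values, out$sfreq_hz, lowpass_hz)
    }
    return(out)
  }
  # plain numeric vector or matrix
  if (!identical(dim(A), dim(V)) || !identical(dim(A), dim(AV)) ||
      length(A) != length(V) || length(A) != length(AV)) {
    stop("alignment error: A, V, AV must share dimensions")
  }
  out <- AV - (A + V)
  if (!is.null(lowpass_hz)) {
    if (is.null(sfreq_hz)) stop("sfreq_hz required to filter numeric input")
    out <- lowpass(out, lowpass_hz, sfreq_hz = sfreq_hz)
  }
  out
}

.check_times <- function(...) {
  ts <- list(...)
  for (i in seq_along(ts)[-1]) {
    if (length(ts[[1]]) != length(ts[[i]]) ||
        any(abs(ts[[1]] - ts[[i]]) > 1e-9)) {
      stop("alignment error: time axes differ")
    }
  }
  invisible(TRUE)
}

#' Single-trial ROI time courses
#'
#' Applies the (optionally dSPM-normalized) inverse operator to every epoch
#' and averages the absolute source values within one ROI, yielding a
#' trials x samples matrix of ROI time courses for decoding analyses.
#'
#' @param trials a [trial_set()].
#' @param leadfield a [make_leadfield()] object.
#' @param noise_cov a [estimate_noise_cov()] object.
#' @param roi ROI name (hemisphere-specific, or a base name resolved to its
#'   `_left`/`_right` pair when `combine_hemispheres`).
#' @param lambda2 regularization (default 1/9).
#' @param combine_hemispheres average `_left`/`_right` extractions
#'   (default TRUE).
#' @param dspm noise-normalize the inverse rows (default TRUE).
#' @return list with `data` (trials x samples), `times_ms`, `labels`,
#'   `run_id`.
#' @export
single_trial_roi_timecourses <- function(trials, leadfield, noise_cov, roi,
                                         lambda2 = 1/9,
                                         combine_hemispheres = TRUE,
                                         dspm = TRUE) {
  G <- leadfield$gain
  grads <- .grad_idx(trials)
  stopifnot(length(grads) == nrow(G))
  M <- G %*% t(G) + lambda2 * noise_cov$matrix
  W <- t(G) %*% solve(M)
  if (dspm) {
    sd_s <- sqrt(rowSums((W %*% noise_cov$matrix) * W))
    W <- W / sd_s
  }
  rois <- if (combine_hemispheres && is.null(leadfield$roi_map[[roi]])) {
    paste0(roi, c("_left", "_right"))
  } else roi
  idx_list <- lapply(rois, function(r) {
    idx <- leadfield$roi_map[[r]]
    if (is.null(idx)) stop("config error: unknown ROI '", r, "'")
    idx
  })
  n <- n_epochs(trials)
  out <- matrix(0, n, length(trials$times_ms))
  for (e in seq_len(n)) {
    src <- W %*% trials$data[e, grads, ]
    tc <- rowMeans(vapply(idx_list, function(idx) {
      colMeans(abs(src[idx, , drop = FALSE]))
    }, numeric(ncol(src))))
    out[e, ] <- tc
  }
  list(data = out, times_ms = trials$times_ms, labels = trials$labels,
       run_id = trials$run_id)
}
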