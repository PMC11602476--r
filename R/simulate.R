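#' Default ground-truth source activity table
#'
#' One row per (ROI, driving condition): when the condition occurs, a
#' ramp-burst response with the given onset and amplitude is placed on the
#' ROI's sources. Defaults follow the across-subjects bootstrap medians of
#' the letter study: sensory-specific onsets 25 ms (A1, auditory) and 48 ms
#' (V1, visual); cross-sensory onsets 65 ms (A1, visual) and 62 ms (V1,
#' auditory), i.e. conduction delays of 17 and 37 ms; audiovisual
#' interaction components at 125 ms (A1) and 133 ms (V1), 60 and 71 ms
#' after the unimodal inputs converge. Cross-sensory and interaction
#' amplitudes are weaker than sensory-specific ones, as in real recordings.
#'
#' @param interaction include the AV interaction component (default TRUE).
#' @return data.frame with columns `roi`, `condition` (`"A"`, `"V"` or
#'   `"interaction"`), `onset_ms`, `amplitude` (arbitrary source units).
#' @export
default_true_onsets <- function(interaction = TRUE) {
  rows <- rbind(
    data.frame(roi = c("A1_left", "A1_right"), condition = "A",
               onset_ms = 25, amplitude = 50),
    data.frame(roi = c("A1_left", "A1_right"), condition = "V",
               onset_ms = 65, amplitude = 20),
    data.frame(roi = c("V1_left", "V1_right"), condition = "V",
               onset_ms = 48, amplitude = 50),
    data.frame(roi = c("V1_left", "V1_right"), condition = "A",
               onset_ms = 62, amplitude = 20)
  )
  if (interaction) {
    rows <- rbind(rows,
      data.frame(roi = c("A1_left", "A1_right"), condition = "interaction",
                 onset_ms = 125, amplitude = 15),
      data.frame(roi = c("V1_left", "V1_right"), condition = "interaction",
                 onset_ms = 133, amplitude = 15))
  }
  rows
}

#' Simulation configuration
#'
#' Parameters of the synthetic MEG session generator. All stimuli last
#' `response_duration_ms` (default 300 ms, the stimulus duration); the
#' response in each ROI is a half-sine rise over `rise_ms` into a plateau
#' lasting until `response_duration_ms` after onset, then an exponential
#' decay with time constant `decay_tau_ms`. Epoch-to-epoch variability is a
#' multiplicative Gaussian amplitude jitter with SD `amp_jitter`.
#'
#' @param true_onsets data.frame as [default_true_onsets()].
#' @param response_duration_ms response plateau duration in ms (default 300).
#' @param rise_ms half-sine rise time in ms (default 20).
#' @param decay_tau_ms offset decay time constant in ms (default 50).
#' @param amp_jitter SD of the per-epoch multiplicative amplitude jitter
#'   (default 0.10).
#' @param noise_sd_sensor additive sensor noise SD in fT/cm (default 30).
#' @param noise_sd_eog EOG channel noise SD in uV (default 15).
#' @param n_epochs_per_run non-target epochs per category for the long,
#'   intermediate and short ISI runs (default `c(100, 125, 150)`).
#' @param artifact_rate fraction of epochs to contaminate when artifacts are
#'   injected (default 0.05).
#' @param seed master seed.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(true_onsets = default_true_onsets(),
                       response_duration_ms = 300,
                       rise_ms = 20,
                       decay_tau_ms = 50,
                       amp_jitter = 0.10,
                       noise_sd_sensor = 30,
                       noise_sd_eog = 15,
                       n_epochs_per_run = c(100L, 125L, 150L),
                       artifact_rate = 0.05,
                       seed = 1) {
  stopifnot(is.data.frame(true_onsets),
            all(c("roi", "condition", "onset_ms", "amplitude") %in% names(true_onsets)))
  if (any(true_onsets$onset_ms < 0)) stop("invalid config: onsets must be >= 0")
  if (noise_sd_sensor <= 0 || noise_sd_eog <= 0) {
    stop("invalid config: noise SDs must be > 0")
  }
  if (any(n_epochs_per_run <= 0)) stop("invalid config: n_epochs_per_run must be positive")
  structure(list(
    true_onsets = true_onsets,
    response_duration_ms = response_duration_ms,
    rise_ms = rise_ms,
    decay_tau_ms = decay_tau_ms,
    amp_jitter = amp_jitter,
    noise_sd_sensor = noise_sd_sensor,
    noise_sd_eog = noise_sd_eog,
    n_epochs_per_run = as.integer(n_epochs_per_run),
    artifact_rate = artifact_rate,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Synthetic leadfield (forward model)
#'
#' Random Gaussian gain matrix mapping source amplitudes to planar
#' gradiometer signals, with a named ROI-to-source-index map. Real head
#' geometry is out of scope; a random well-conditioned gain is sufficient to
#' exercise the inverse, normalization and ROI-extraction stages. The first
#' sources are assigned to the four ROIs (A1/V1, left/right); the remainder
#' are unassigned "background" sources.
#'
#' @param n_locations number of sensor locations; each contributes a
#'   grad_x/grad_y pair, so there are `2 * n_locations` gradiometer
#'   channels (default 30 locations = 60 channels).
#' @param n_sources number of sources (default 20).
#' @param sources_per_roi sources per ROI (default 2).
#' @param col_corr correlation between gain columns in `[0, 1)`; 0 gives
#'   independent columns (default 0).
#' @param seed seed for the Gaussian gain.
#' @return object of class `leadfield`: list with `gain`
#'   (channels x sources, fT/cm per unit source) and `roi_map` (named list
#'   of source index vectors).
#' @export
make_leadfield <- function(n_locations = 30, n_sources = 20,
                           sources_per_roi = 2, col_corr = 0, seed = 1) {
  rois <- c("A1_left", "A1_right", "V1_left", "V1_right")
  stopifnot(n_sources >= length(rois) * sources_per_roi,
            col_corr >= 0, col_corr < 1)
  set.seed(seed)
  n_ch <- 2L * n_locations
  gain <- matrix(rnorm(n_ch * n_sources), n_ch, n_sources)
  if (col_corr > 0) {
    common <- rnorm(n_ch)
    gain <- sqrt(1 - col_corr) * gain + sqrt(col_corr) * common
  }
  roi_map <- split(seq_len(length(rois) * sources_per_roi),
                   rep(seq_along(rois), each = sources_per_roi))
  names(roi_map) <- rois
  structure(list(gain = gain, roi_map = roi_map, source_orient = "fixed"),
            class = "leadfield")
}

#' Ramp-burst response waveform
#'
#' Canonical single-trial response: zero before `onset_ms`, a half-sine
#' rise over `rise_ms`, a unit plateau until `duration_ms` after onset, then
#' exponential decay with time constant `decay_tau_ms`. The rise phase is
#' evaluated at `(t - onset + dt)` where `dt` is the sample interval, so the
#' first sample at or after the configured onset is already nonzero and the
#' ground-truth onset lies on the sampling grid.
#'
#' @param times_ms sample times in ms.
#' @param onset_ms response onset in ms.
#' @param rise_ms rise time in ms.
#' @param duration_ms plateau end (ms after onset).
#' @param decay_tau_ms decay time constant in ms.
#' @return numeric vector of unit-amplitude response values.
#' @export
ramp_burst <- function(times_ms, onset_ms, rise_ms = 20, duration_ms = 300,
                       decay_tau_ms = 50) {
  dt <- .times_step(times_ms)
  y <- numeric(length(times_ms))
  rel <- times_ms - onset_ms
  rising <- rel >= -1e-9 & rel < rise_ms - dt
  y[rising] <- sin(pi / 2 * pmin(1, (rel[rising] + dt) / rise_ms))
  plateau <- rel >= rise_ms - dt & rel <= duration_ms
  y[plateau] <- 1
  decay <- rel > duration_ms
  y[decay] <- exp(-(rel[decay] - duration_ms) / decay_tau_ms)
  y
}

# row indices (into config$true_onsets) of the components one epoch's
# condition label drives
.components_for <- function(config, label) {
  base <- sub("_Target$", "", label)
  tab <- config$true_onsets
  if (base == "A") which(tab$condition == "A")
  else if (base == "V") which(tab$condition == "V")
  else if (base == "AV") seq_len(nrow(tab)) # A- + V-driven + interaction
  else integer(0) # e.g. "Noise"
}

#' Simulate a trial-level MEG session
#'
#' Generates one epoch per event of `design`. Each epoch's noiseless source
#' activity is the superposition of the [ramp_burst()] components that the
#' epoch's condition drives (AV epochs superpose the auditory- and
#' visually-driven components plus the optional interaction component), with
#' per-epoch multiplicative amplitude jitter. Sensor data are the
#' leadfield-projected sources plus i.i.d. Gaussian noise; one EOG channel
#' carries pure noise. Epochs are generated independently (no inter-trial
#' crosstalk), time-locked from `tmin_ms` to `tmax_ms` around each event.
#'
#' @param config a [sim_config()].
#' @param design a `stimulus_sequence` (see [make_design()]).
#' @param leadfield a [make_leadfield()] object.
#' @param sfreq_hz sampling rate (default 600 Hz).
#' @param tmin_ms,tmax_ms epoch window (default -250..1150 ms).
#' @param seed seed; defaults to a child of `config$seed` keyed by run.
#' @return a [trial_set()] carrying the config as attribute `"sim_config"`.
#' @export
simulate_trials <- function(config, design, leadfield, sfreq_hz = 600,
                            tmin_ms = -250, tmax_ms = 1150, seed = NULL) {
  rois_needed <- unique(config$true_onsets$roi)
  missing <- setdiff(rois_needed, names(leadfield$roi_map))
  if (length(missing) > 0) {
    stop("config error: ROI(s) not in leadfield roi_map: ",
         paste(missing, collapse = ", "))
  }
  if (is.null(seed)) seed <- child_seeds(config$seed, design$run_id + 1L)[design$run_id]
  times <- epoch_times(sfreq_hz, tmin_ms, tmax_ms)
  n_samples <- length(times)
  n_sources <- ncol(leadfield$gain)
  n_grad <- nrow(leadfield$gain)
  labels <- design$events$condition
  n_ep <- length(labels)

  # unit-amplitude waveform per (roi, condition) row, shared across epochs
  tab <- config$true_onsets
  waves <- lapply(seq_len(nrow(tab)), function(i) {
    ramp_burst(times, tab$onset_ms[i], config$rise_ms,
               config$response_duration_ms, config$decay_tau_ms)
  })

  set.seed(seed)
  data <- array(0, dim = c(n_ep, n_grad + 1L, n_samples))
  for (e in seq_len(n_ep)) {
    comp <- .components_for(config, labels[e])
    if (length(comp) > 0) {
      S <- matrix(0, n_sources, n_samples)
      jit <- 1 + rnorm(length(comp), 0, config$amp_jitter)
      for (j in seq_along(comp)) {
        r <- comp[j]
        idx <- leadfield$roi_map[[tab$roi[r]]]
        w <- tab$amplitude[r] * jit[j] * waves[[r]]
        S[idx, ] <- S[idx, ] + matrix(w, length(idx), n_samples, byrow = TRUE)
      }
      data[e, seq_len(n_grad), ] <- leadfield$gain %*% S
    }
    data[e, seq_len(n_grad), ] <- data[e, seq_len(n_grad), ] +
      rnorm(n_grad * n_samples, 0, config$noise_sd_sensor)
    data[e, n_grad + 1L, ] <- rnorm(n_samples, 0, config$noise_sd_eog)
  }

  n_loc <- n_grad %/% 2L
  channel_meta <- rbind(
    data.frame(name = sprintf("MEG%03d%s", rep(seq_len(n_loc), each = 2),
                              rep(c("x", "y"), n_loc)),
               kind = rep(c("grad_x", "grad_y"), n_loc),
               unit = "fT/cm",
               location_id = rep(seq_len(n_loc), each = 2)),
    data.frame(name = "EOG001", kind = "eog", unit = "uV", location_id = 0L)
  )
  out <- trial_set(data, channel_meta, sfreq_hz, times, labels,
                   run_id = design$run_id)
  attr(out, "sim_config") <- config
  out
}

#' Inject blink and spike artifacts into a trial set
#'
#' Contaminates a fraction of epochs with a blink transient on the EOG
#' channel (Gaussian bump, peak `blink_amp_uv`) and/or a brief gradiometer
#' spike (peak `spike_amp_ftcm` on one random channel), so that downstream
#' amplitude-threshold rejection can be validated against known indices.
#'
#' @param trials a [trial_set()].
#' @param artifact_rate fraction of epochs to contaminate, in `[0, 1]`.
#' @param blink_amp_uv blink peak amplitude in uV (default 300, above the
#'   150 uV rejection threshold).
#' @param spike_amp_ftcm spike peak amplitude in fT/cm (default 5000, above
#'   the 3000 fT/cm rejection threshold).
#' @param seed seed for epoch and artifact-type selection.
#' @return the trial set with attribute `"artifact_epochs"` listing the
#'   contaminated epoch indices; with `artifact_rate = 0` the input is
#'   returned unchanged.
#' @export
inject_artifacts <- function(trials, artifact_rate = 0.05,
                             blink_amp_uv = 300, spike_amp_ftcm = 5000,
                             seed = 1) {
  stopifnot(artifact_rate >= 0, artifact_rate <= 1)
  n <- n_epochs(trials)
  n_art <- round(artifact_rate * n)
  if (n_art == 0) return(trials)
  set.seed(seed)
  bad <- sort(sample(n, n_art))
  eog <- .eog_idx(trials)
  grads <- .grad_idx(trials)
  times <- trials$times_ms
  for (e in bad) {
    type <- sample(c("blink", "spike", "both"), 1, prob = c(0.5, 0.3, 0.2))
    if (type %in% c("blink", "both")) {
      center <- runif(1, min(times) + 100, max(times) - 100)
      bump <- blink_amp_uv * exp(-0.5 * ((times - center) / 50)^2)
      trials$data[e, eog, ] <- trials$data[e, eog, ] +
        matrix(bump, length(eog), length(times), byrow = TRUE)
    }
    if (type %in% c("spike", "both")) {
      ch <- sample(grads, 1)
      at <- sample(3:(length(times) - 2), 1)
      trials$data[e, ch, (at - 1):(at + 1)] <-
        trials$data[e, ch, (at - 1):(at + 1)] +
        spike_amp_ftcm * c(0.5, 1, 0.5)
    }
  }
  attr(trials, "artifact_epochs") <- bad
  trials
}

#' Indices of artifact-contaminated epochs
#' @param trials a [trial_set()] returned by [inject_artifacts()].
#' @return integer vector (empty when no artifacts were injected).
#' @export
artifact_epochs <- function(trials) {
  a <- attr(trials, "artifact_epochs")
  if (is.null(a)) integer(0) else a
}
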