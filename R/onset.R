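#' Baseline noise statistics of a time course
#'
#' Sample mean and SD (denominator n-1) of the pre-stimulus baseline
#' samples of a time course. The window is right-open, so a window ending
#' at 0 ms excludes the stimulus-onset sample.
#'
#' @param x numeric time course.
#' @param times_ms sample times in ms.
#' @param baseline_window_ms baseline window, default `c(-200, 0)`.
#' @return list with `noise_mean`, `noise_sd`, `n_samples`, and `degenerate`
#'   (TRUE when the baseline is constant, i.e. SD 0).
#' @export
estimate_noise <- function(x, times_ms, baseline_window_ms = c(-200, 0)) {
  idx <- .window_idx(times_ms, baseline_window_ms)
  if (length(idx) < 10) stop("need at least 10 baseline samples")
  b <- x[idx]
  s <- sd(b)
  list(noise_mean = mean(b), noise_sd = s, n_samples = length(b),
       degenerate = (s == 0))
}

#' Detect the onset latency of a response time course
#'
#' The onset is the earliest sample time `t >= min_latency_ms` at which the
#' time course exceeds the threshold `noise_mean + k * noise_sd` (noise
#' statistics from the pre-stimulus baseline) and stays above it for every
#' sample in `[t, t + sustain_ms]` (window inclusive of the onset sample; a
#' partial window at the end of the epoch fails). The minimum-latency rule
#' reflects finite conduction delays in sensory pathways; the sustain rule
#' protects against brief noise spikes. Onsets are reported on the sampling
#' grid without sub-sample interpolation.
#'
#' The threshold includes the baseline mean because amplitude and
#' magnitude time courses have positive noise floors. With
#' `sustain_above = "noise_mean"` the sustain test is relaxed to staying
#' above the baseline mean instead of the full threshold.
#'
#' @param x numeric time course (e.g. combined gradient amplitude or ROI
#'   dSPM magnitude).
#' @param times_ms sample times in ms; must cover the baseline and at least
#'   `min_latency_ms + sustain_ms` post-stimulus.
#' @param k threshold in baseline SDs above the baseline mean (default 3).
#' @param min_latency_ms earliest physiologically admissible onset
#'   (default 15).
#' @param sustain_ms required suprathreshold duration (default 20).
#' @param baseline_window_ms baseline window (default `c(-200, 0)`).
#' @param sustain_above `"threshold"` (default) or `"noise_mean"`: the level
#'   the response must stay above during the sustain window.
#' @return object of class `onset_result` with fields `onset_ms` (NA when
#'   no qualifying time exists), `threshold`, `noise_mean`, `noise_sd`,
#'   `k`, `min_latency_ms`, `sustain_ms`, `first_crossing_ms`, `sustained`,
#'   and `degenerate_noise`.
#' @export
detect_onset <- function(x, times_ms, k = 3, min_latency_ms = 15,
                         sustain_ms = 20, baseline_window_ms = c(-200, 0),
                         sustain_above = c("threshold", "noise_mean")) {
  sustain_above <- match.arg(sustain_above)
  noise <- estimate_noise(x, times_ms, baseline_window_ms)
  thr <- noise$noise_mean + k * noise$noise_sd
  dt <- .times_step(times_ms)
  n_sustain <- floor(sustain_ms / dt + 1e-9) + 1L # inclusive of onset sample
  level <- if (sustain_above == "threshold") thr else noise$noise_mean
  n <- length(x)

  cross <- x > thr
  above <- x > level
  # ok_sustain[i]: all samples i..i+n_sustain-1 are above `level`
  cs <- cumsum(c(0, !above))
  last_start <- n - n_sustain + 1L
  ok_sustain <- rep(FALSE, n)
  if (last_start >= 1) {
    ok_sustain[seq_len(last_start)] <-
      (cs[seq_len(last_start) + n_sustain] - cs[seq_len(last_start)]) == 0
  }

  eligible <- times_ms >= min_latency_ms - 1e-9
  first_cross <- which(eligible & cross)[1]
  hit <- which(eligible & cross & ok_sustain)[1]
  structure(list(
    onset_ms = if (is.na(hit)) NA_real_ else times_ms[hit],
    threshold = thr,
    noise_mean = noise$noise_mean,
    noise_sd = noise$noise_sd,
    k = k,
    min_latency_ms = min_latency_ms,
    sustain_ms = sustain_ms,
    first_crossing_ms = if (is.na(first_cross)) NA_real_ else times_ms[first_cross],
    sustained = !is.na(hit),
    degenerate_noise = noise$degenerate
  ), class = "onset_result")
}

#' @export
print.onset_result <- function(x, ...) {
  if (is.na(x$onset_ms)) {
    cat(sprintf("<onset_result> no onset (threshold %.3g; first crossing %s)\n",
                x$threshold,
                if (is.na(x$first_crossing_ms)) "none"
                else sprintf("%.1f ms, sustain failed", x$first_crossing_ms)))
  } else {
    cat(sprintf("<onset_result> onset %.2f ms (threshold %.3g = mean %.3g + %g SD)\n",
                x$onset_ms, x$threshold, x$noise_mean, x$k))
  }
  invisible(x)
}

#' Bootstrap distribution of onset latencies
#'
#' Resamples epochs with replacement `B` times (each resample the size of
#' the original trial set), pushes each resample through a user-supplied
#' averaging pipeline to a single time course, and detects its onset.
#' Resamples in which no onset qualifies are counted and excluded from the
#' moments.
#'
#' @param trials a [trial_set()] restricted to one condition (or whatever
#'   set the pipeline expects to average).
#' @param pipeline function taking a `trial_set` and returning a time
#'   course: either a list with `x` and `times_ms`, an `roi_tc` with one
#'   row, or a numeric vector with a `times_ms` attribute.
#' @param B number of bootstrap resamples (default 1000).
#' @param seed seed for resampling.
#' @param ... passed to [detect_onset()] (e.g. `k`, `sustain_ms`).
#' @return object of class `onset_boot`: list with `onsets` (length-B,
#'   NA for failures), `mean_ms`, `sd_ms`, `median_ms`, `n_failed`, `B`.
#' @export
bootstrap_onset <- function(trials, pipeline, B = 1000, seed = 1, ...) {
  n <- n_epochs(trials)
  stopifnot(n >= 2, B >= 1)
  set.seed(seed)
  onsets <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    tc <- .as_timecourse(pipeline(subset_epochs(trials, idx)))
    res <- detect_onset(tc$x, tc$times_ms, ...)
    onsets[b] <- res$onset_ms
  }
  ok <- onsets[!is.na(onsets)]
  if (length(ok) == 0) stop("empty distribution: all bootstrap resamples failed detection")
  structure(list(
    onsets = onsets,
    mean_ms = mean(ok),
    sd_ms = if (length(ok) > 1) sd(ok) else 0,
    median_ms = median(ok),
    n_failed = sum(is.na(onsets)),
    B = B
  ), class = "onset_boot")
}

#' @export
print.onset_boot <- function(x, ...) {
  cat(sprintf("<onset_boot> B=%d: %.1f +/- %.1f ms (median %.1f), %d failed\n",
              x$B, x$mean_ms, x$sd_ms, x$median_ms, x$n_failed))
  invisible(x)
}

.as_timecourse <- function(obj) {
  if (is.list(obj) && !is.null(obj$x) && !is.null(obj$times_ms)) {
    return(list(x = obj$x, times_ms = obj$times_ms))
  }
  if (inherits(obj, "roi_tc")) {
    stopifnot(nrow(obj$data) == 1)
    return(list(x = drop(obj$data), times_ms = obj$times_ms))
  }
  if (is.numeric(obj) && !is.null(attr(obj, "times_ms"))) {
    return(list(x = as.numeric(obj), times_ms = attr(obj, "times_ms")))
  }
  stop("pipeline must return a time course with a time axis")
}

#' Convergence latency of two unimodal inputs
#'
#' The time by which inputs from both sensory modalities have reached a
#' region: the later of the two unimodal onset latencies. Audiovisual
#' interactions are timed relative to this convergence point.
#'
#' @param onset_a_ms,onset_v_ms unimodal onset latencies in ms.
#' @return `max(onset_a_ms, onset_v_ms)`.
#' @export
#' @examples
#' convergence_latency(25, 65) # 65
convergence_latency <- function(onset_a_ms, onset_v_ms) {
  .check_onsets(onset_a_ms, onset_v_ms, what = "convergence")
  max(onset_a_ms, onset_v_ms)
}

#' Cross-modal conduction delay
#'
#' Delay for a stimulus' activation to spread from its own sensory cortex
#' to the opposite-modality cortex: the cross-sensory onset minus the
#' sensory-specific onset of the same stimulus.
#'
#' @param cross_onset_ms onset in the opposite-modality cortex (ms).
#' @param specific_onset_ms onset in the stimulus' own cortex (ms).
#' @return `cross_onset_ms - specific_onset_ms`.
#' @export
#' @examples
#' conduction_delay(62, 25) # auditory stimulus, A1 -> V1: 37 ms
#' conduction_delay(65, 48) # visual stimulus, V1 -> A1: 17 ms
conduction_delay <- function(cross_onset_ms, specific_onset_ms) {
  .check_onsets(cross_onset_ms, specific_onset_ms, what = "conduction delay")
  cross_onset_ms - specific_onset_ms
}

#' Interaction lag after convergence
#'
#' Time from the convergence of both unimodal inputs in a region to the
#' onset of the audiovisual interaction there.
#'
#' @param interaction_onset_ms onset of the AV - (A + V) interaction (ms).
#' @param convergence_ms [convergence_latency()] of the region (ms).
#' @return `interaction_onset_ms - convergence_ms`.
#' @export
#' @examples
#' interaction_lag(125, convergence_latency(25, 65)) # 60 ms
interaction_lag <- function(interaction_onset_ms, convergence_ms) {
  .check_onsets(interaction_onset_ms, convergence_ms, what = "interaction lag")
  interaction_onset_ms - convergence_ms
}

.check_onsets <- function(a, b, what) {
  if (is.null(a) || is.null(b) || is.na(a) || is.na(b)) {
    stop("undefined ", what, ": missing onset")
  }
  invisible(TRUE)
}

#' Aggregate onsets into a latency table
#'
#' Per-(ROI, condition) mean, SD (denominator n-1) and median across
#' subjects. With `average_hemispheres = TRUE`, `_left`/`_right` ROI onsets
#' are averaged within subject before aggregation (regions with similar
#' timings across hemispheres are conventionally reported combined). Cells
#' with a single subject get SD `NA`.
#'
#' @param onsets data.frame with columns `roi`, `condition`, `subject`,
#'   `onset_ms` (NA onsets are dropped per cell).
#' @param average_hemispheres collapse `_left`/`_right` ROI names
#'   (default FALSE).
#' @param provenance free-text provenance tag (e.g. `"sensor"`, `"dspm"`,
#'   `"bootstrap"`).
#' @return data.frame of class `latency_table` with columns `roi`,
#'   `condition`, `mean_ms`, `sd_ms`, `median_ms`, `n`, `formatted`.
#' @export
build_latency_table <- function(onsets, average_hemispheres = FALSE,
                                provenance = "dspm") {
  stopifnot(all(c("roi", "condition", "subject", "onset_ms") %in% names(onsets)))
  onsets <- onsets[!is.na(onsets$onset_ms), , drop = FALSE]
  if (nrow(onsets) == 0) stop("no onsets to aggregate")
  if (average_hemispheres) {
    onsets$roi <- sub("_(left|right)$", "", onsets$roi)
    onsets <- aggregate(onset_ms ~ roi + condition + subject, onsets, mean)
  }
  agg <- aggregate(onset_ms ~ roi + condition, onsets, function(v) {
    c(mean = mean(v), sd = if (length(v) > 1) sd(v) else NA_real_,
      median = median(v), n = length(v))
  })
  out <- data.frame(
    roi = agg$roi,
    condition = agg$condition,
    mean_ms = agg$onset_ms[, "mean"],
    sd_ms = agg$onset_ms[, "sd"],
    median_ms = agg$onset_ms[, "median"],
    n = as.integer(agg$onset_ms[, "n"])
  )
  out$formatted <- format_latency_cell(out$mean_ms, out$sd_ms, out$median_ms)
  attr(out, "provenance") <- provenance
  class(out) <- c("latency_table", "data.frame")
  out
}

#' Format a latency cell as "mean ± SD (median)"
#'
#' Integer-millisecond rounding, matching conventional latency-table
#' precision: mean 25.4, SD 2.1, median 25.0 renders as `"25 ± 2 (25)"`.
#'
#' @param mean_ms,sd_ms,median_ms numeric (vectors allowed; `sd_ms` may be
#'   NA for single-subject cells).
#' @return character vector.
#' @export
format_latency_cell <- function(mean_ms, sd_ms, median_ms) {
  ifelse(is.na(sd_ms),
         sprintf("%d (%d)", round(mean_ms), round(median_ms)),
         sprintf("%d ± %d (%d)", round(mean_ms), round(sd_ms), round(median_ms)))
}
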