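#' Default three-run stimulus design
#'
#' The study design uses three runs differing only in their mean
#' interstimulus interval (ISI): a short-ISI run (mean 1.5 s, 150 non-target
#' trials per category), an intermediate run (3.1 s, 125 per category) and a
#' long-ISI run (6.1 s, 100 per category), giving 375 non-target trials per
#' category in total. ISIs are jittered in 1.15 s steps.
#'
#' @return data.frame with columns `run_id`, `mean_isi_s`, `n_per_category`.
#' @export
default_run_specs <- function() {
  data.frame(
    run_id = 1:3,
    mean_isi_s = c(1.5, 3.1, 6.1),
    n_per_category = c(150L, 125L, 100L)
  )
}

#' Generate pseudorandom stimulus sequences
#'
#' Builds one stimulus sequence per run. Within each run the non-target
#' categories A, V and AV are exactly equiprobable (`n_per_category` each);
#' rare target variants (`A_Target`, `V_Target`, `AV_Target`) are added so
#' that targets make up about `target_fraction` of all events, split as
#' evenly as possible across the three target types. Event order is
#' shuffled, and every inter-event interval is a positive integer multiple
#' of `jitter_step_s` drawn so the run's mean ISI matches `mean_isi_s`.
#'
#' @param run_specs data.frame as from [default_run_specs()]: one row per
#'   run with `run_id`, `mean_isi_s`, `n_per_category`.
#' @param target_fraction fraction of all events that are targets
#'   (default 0.10); must lie in `[0, 1)`.
#' @param jitter_step_s ISI jitter step in seconds (default 1.15).
#' @param seed master seed; per-run seeds are derived from it.
#' @return list of `stimulus_sequence` objects, one per run. Each has an
#'   `$events` data.frame (`onset_s`, `condition`) plus `run_id`,
#'   `mean_isi_s`, `jitter_step_s` fields.
#' @export
#' @examples
#' des <- make_design(seed = 1)
#' sum(sapply(des, function(r) sum(r$events$condition == "A")))  # 375
make_design <- function(run_specs = default_run_specs(),
                        target_fraction = 0.10,
                        jitter_step_s = 1.15,
                        seed = 1) {
  stopifnot(is.data.frame(run_specs),
            all(c("run_id", "mean_isi_s", "n_per_category") %in% names(run_specs)))
  if (any(run_specs$n_per_category <= 0)) {
    stop("invalid config: n_per_category must be positive")
  }
  if (target_fraction < 0 || target_fraction >= 1) {
    stop("invalid config: target_fraction must lie in [0, 1)")
  }
  seeds <- child_seeds(seed, nrow(run_specs))
  lapply(seq_len(nrow(run_specs)), function(i) {
    .make_run_sequence(run_specs$run_id[i], run_specs$mean_isi_s[i],
                       run_specs$n_per_category[i], target_fraction,
                       jitter_step_s, seeds[i])
  })
}

.make_run_sequence <- function(run_id, mean_isi_s, n_per_category,
                               target_fraction, jitter_step_s, seed) {
  set.seed(seed)
  conds <- rep(c("A", "V", "AV"), each = n_per_category)
  n_nontarget <- length(conds)
  # targets are a fraction of ALL events: n_t/(n_t + n_nt) ~= target_fraction
  n_targets <- round(target_fraction * n_nontarget / (1 - target_fraction))
  if (n_targets > 0) {
    base <- n_targets %/% 3
    extra <- sample(c("A_Target", "V_Target", "AV_Target"), n_targets %% 3)
    conds <- c(conds,
               rep(c("A_Target", "V_Target", "AV_Target"), each = base),
               extra)
  }
  conds <- sample(conds)
  n_events <- length(conds)
  # integer ISI multiples with the configured mean: floor(m) plus a
  # Bernoulli carry of the fractional part
  m <- mean_isi_s / jitter_step_s
  k <- pmax(1L, floor(m) + rbinom(n_events - 1, 1, m - floor(m)))
  onsets <- cumsum(c(2 * jitter_step_s, k * jitter_step_s))
  structure(list(
    events = data.frame(onset_s = onsets, condition = conds),
    run_id = as.integer(run_id),
    mean_isi_s = mean_isi_s,
    jitter_step_s = jitter_step_s
  ), class = "stimulus_sequence")
}

#' @export
print.stimulus_sequence <- function(x, ...) {
  tab <- table(x$events$condition)
  cat(sprintf("<stimulus_sequence> run %d, mean ISI %g s, %d events\n",
              x$run_id, x$mean_isi_s, nrow(x$events)))
  cat(" ", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Write / read a stimulus design as CSV
#'
#' One row per event with columns `onset_s`, `condition`, `run_id`.
#'
#' @param design list of `stimulus_sequence` objects (one per run).
#' @param path output CSV path.
#' @return `design_to_csv` returns `path` invisibly; `design_from_csv`
#'   returns a list of `stimulus_sequence` objects.
#' @export
design_to_csv <- function(design, path) {
  rows <- do.call(rbind, lapply(design, function(r) {
    data.frame(onset_s = r$events$onset_s,
               condition = r$events$condition,
               run_id = r$run_id,
               mean_isi_s = r$mean_isi_s,
               jitter_step_s = r$jitter_step_s)
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname design_to_csv
#' @export
design_from_csv <- function(path) {
  rows <- read.csv(path, stringsAsFactors = FALSE)
  lapply(split(rows, rows$run_id), function(r) {
    structure(list(
      events = data.frame(onset_s = r$onset_s, condition = r$condition),
      run_id = r$run_id[1],
      mean_isi_s = r$mean_isi_s[1],
      jitter_step_s = r$jitter_step_s[1]
    ), class = "stimulus_sequence")
  })
}

#' Place noise pseudo-events in the gaps of a stimulus sequence
#'
#' For decoding contrasts that need a "noise" class, exemplar epochs are
#' taken from silent stretches between stimuli. This helper inserts events
#' labeled `"Noise"` at times that leave at least `margin_s` after the
#' preceding stimulus onset (so the preceding response has decayed) and at
#' least `lead_s` before the next stimulus. Gaps that cannot satisfy both
#' margins yield no noise event, so long-ISI runs contribute most exemplars.
#'
#' @param sequence a `stimulus_sequence`.
#' @param n maximum number of noise events to place.
#' @param margin_s minimum delay after the previous stimulus onset
#'   (default 2.3 s: stimulus + response comfortably over).
#' @param lead_s minimum lead before the next stimulus onset (default 1.3 s,
#'   covering the post-stimulus analysis window).
#' @param seed seed for choosing among eligible gaps.
#' @return a `stimulus_sequence` containing only the `"Noise"` events.
#' @export
make_noise_design <- function(sequence, n, margin_s = 2.3, lead_s = 1.3,
                              seed = 1) {
  on_s <- sequence$events$onset_s
  gaps <- data.frame(lo = head(on_s, -1) + margin_s,
                     hi = on_s[-1] - lead_s)
  gaps <- gaps[gaps$hi > gaps$lo, , drop = FALSE]
  if (nrow(gaps) == 0) stop("no inter-stimulus gap long enough for noise epochs")
  set.seed(seed)
  pick <- gaps[sample(nrow(gaps), min(n, nrow(gaps))), , drop = FALSE]
  onsets <- sort(pick$lo + runif(nrow(pick)) * (pick$hi - pick$lo))
  structure(list(
    events = data.frame(onset_s = onsets,
                        condition = rep("Noise", length(onsets))),
    run_id = sequence$run_id,
    mean_isi_s = sequence$mean_isi_s,
    jitter_step_s = sequence$jitter_step_s
  ), class = "stimulus_sequence")
}
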