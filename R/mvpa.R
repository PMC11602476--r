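#' Sliding windows for temporal-searchlight decoding
#'
#' Windows of `width_ms` advance in steps of `step_ms` (default one sample
#' at 600 Hz, i.e. 1.7 ms); each window is labeled by its center time.
#' Truncated windows at the epoch edges are dropped.
#'
#' @param times_ms sample times in ms.
#' @param width_ms window width in ms (default 50; 30 samples at 600 Hz).
#' @param step_ms step between consecutive windows in ms (default 1.7).
#' @return data.frame with columns `start`, `end` (sample indices,
#'   inclusive) and `centroid_ms`.
#' @export
sliding_windows <- function(times_ms, width_ms = 50, step_ms = 1.7) {
  dt <- .times_step(times_ms)
  n_w <- round(width_ms / dt)
  if (n_w >= length(times_ms)) stop("window width must be below epoch length")
  step <- max(1L, round(step_ms / dt))
  starts <- seq.int(1L, length(times_ms) - n_w + 1L, by = step)
  data.frame(
    start = starts,
    end = starts + n_w - 1L,
    centroid_ms = vapply(starts, function(s) mean(times_ms[s:(s + n_w - 1L)]),
                         numeric(1))
  )
}

#' Cross-validated two-class decoding of one feature window
#'
#' Linear support-vector machine (cost C = 1) evaluated over `n_folds`
#' random stratified train/test splits (default 80/20). The reported
#' accuracy is the mean test accuracy across folds.
#'
#' @param X numeric matrix, trials x features (the within-window samples of
#'   a single-trial ROI time course).
#' @param y class labels, exactly two classes with at least 2 trials each.
#' @param n_folds number of random folds (default 100).
#' @param train_frac fraction of trials used for training, per class
#'   (default 0.8).
#' @param seed seed making the fold draws deterministic.
#' @return mean test accuracy in `[0, 1]`.
#' @export
decode_window <- function(X, y, n_folds = 100, train_frac = 0.8, seed = 1) {
  y <- factor(y)
  if (nlevels(y) != 2 || any(table(y) < 2)) {
    stop("invalid labels: need exactly two classes with >= 2 trials each")
  }
  X <- as.matrix(X)
  set.seed(seed)
  idx_by_class <- split(seq_along(y), y)
  acc <- numeric(n_folds)
  for (f in seq_len(n_folds)) {
    train <- unlist(lapply(idx_by_class, function(ii) {
      n_tr <- max(1L, min(length(ii) - 1L, floor(train_frac * length(ii))))
      sample(ii, n_tr)
    }), use.names = FALSE)
    test <- setdiff(seq_along(y), train)
    fit <- e1071::svm(X[train, , drop = FALSE], y[train],
                      kernel = "linear", cost = 1, scale = FALSE)
    pred <- predict(fit, X[test, , drop = FALSE])
    acc[f] <- mean(pred == y[test])
  }
  mean(acc)
}

#' Temporal-searchlight decoding curve
#'
#' Runs [decode_window()] in every sliding window of the single-trial ROI
#' time courses for a two-class contrast, producing time-resolved decoding
#' accuracy. Windows inherit deterministic child seeds from `seed`.
#'
#' Recordings with very short ISIs have crosstalk between consecutive
#' trials; pass `include_runs` to restrict to the longer-ISI runs when run
#' identifiers are available.
#'
#' @param tc list as from [single_trial_roi_timecourses()] (`data` trials x
#'   samples, `times_ms`, `labels`, optional `run_id`), or a plain matrix
#'   with `labels` and `times_ms` given separately.
#' @param contrast length-2 character: the two class labels to decode.
#' @param labels,times_ms,run_id required when `tc` is a plain matrix.
#' @param include_runs optional run ids to keep (default all).
#' @param width_ms,step_ms searchlight window parameters (default 50 / 1.7).
#' @param n_folds,train_frac cross-validation parameters (default 100, 0.8).
#' @param seed master seed.
#' @return object of class `decoding_curve`: `centroids_ms`, `accuracy`,
#'   `p_values` / `fdr_mask` / `first_significant_ms` (NA until
#'   [significance_curve()] is applied), and the parameters used.
#' @export
searchlight_decode <- function(tc, contrast, labels = NULL, times_ms = NULL,
                               run_id = NULL, include_runs = NULL,
                               width_ms = 50, step_ms = 1.7,
                               n_folds = 100, train_frac = 0.8, seed = 1) {
  if (is.list(tc) && !is.null(tc$data)) {
    labels <- tc$labels
    times_ms <- tc$times_ms
    run_id <- tc$run_id
    tc <- tc$data
  }
  stopifnot(is.matrix(tc), length(labels) == nrow(tc),
            length(times_ms) == ncol(tc), length(contrast) == 2)
  keep <- labels %in% contrast
  if (!is.null(include_runs) && !is.null(run_id)) {
    keep <- keep & run_id %in% include_runs
  }
  if (!any(labels[keep] == contrast[1]) || !any(labels[keep] == contrast[2])) {
    stop("config error: both contrast classes must be present")
  }
  X_all <- tc[keep, , drop = FALSE]
  y <- factor(labels[keep], levels = contrast)
  win <- sliding_windows(times_ms, width_ms, step_ms)
  seeds <- child_seeds(seed, nrow(win))
  accuracy <- vapply(seq_len(nrow(win)), function(w) {
    decode_window(X_all[, win$start[w]:win$end[w], drop = FALSE], y,
                  n_folds = n_folds, train_frac = train_frac,
                  seed = seeds[w])
  }, numeric(1))
  structure(list(
    centroids_ms = win$centroid_ms,
    accuracy = accuracy,
    p_values = rep(NA_real_, nrow(win)),
    fdr_mask = rep(NA, nrow(win)),
    first_significant_ms = NA_real_,
    window_width_ms = width_ms,
    step_ms = step_ms,
    n_folds = n_folds,
    contrast = contrast
  ), class = "decoding_curve")
}

#' @export
print.decoding_curve <- function(x, ...) {
  cat(sprintf("<decoding_curve> %s vs %s: %d windows (%g ms wide), mean acc %.3f\n",
              x$contrast[1], x$contrast[2], length(x$accuracy),
              x$window_width_ms, mean(x$accuracy)))
  if (!is.na(x$first_significant_ms)) {
    cat(sprintf("  first significant centroid: %.1f ms\n", x$first_significant_ms))
  }
  invisible(x)
}

#' Significance of a decoding curve against chance
#'
#' One-sample t-test (one-sided, greater) of the per-window accuracies
#' against the chance level, followed by Benjamini-Hochberg FDR correction
#' across windows. The first significant window centroid is reported. A
#' window with zero variance is flagged and assigned p = 0 when its mean
#' exceeds chance, else p = 1.
#'
#' @param accuracies matrix of accuracies, replicates (subjects or folds) x
#'   windows; a `decoding_curve` list may be passed instead, in which case
#'   `accuracies` must be supplied via `replicate_acc`.
#' @param chance chance level (default 0.5).
#' @param q FDR level (default 0.05).
#' @param centroids_ms window centroid times (required to report the first
#'   significant latency).
#' @return list with `p_values`, `p_adjusted`, `fdr_mask`,
#'   `first_significant_ms`, `zero_variance` (flag vector).
#' @export
significance_curve <- function(accuracies, chance = 0.5, q = 0.05,
                               centroids_ms = NULL) {
  accuracies <- as.matrix(accuracies)
  if (nrow(accuracies) < 2) stop("need >= 2 replicates (subjects or folds)")
  n_w <- ncol(accuracies)
  p <- numeric(n_w)
  zero_var <- logical(n_w)
  for (w in seq_len(n_w)) {
    v <- accuracies[, w]
    if (sd(v) == 0) {
      zero_var[w] <- TRUE
      p[w] <- if (mean(v) > chance) 0 else 1
    } else {
      p[w] <- t.test(v, mu = chance, alternative = "greater")$p.value
    }
  }
  p_adj <- p.adjust(p, method = "BH")
  mask <- p_adj <= q
  first_sig <- NA_real_
  if (!is.null(centroids_ms) && any(mask)) {
    first_sig <- centroids_ms[which(mask)[1]]
  }
  list(p_values = p, p_adjusted = p_adj, fdr_mask = mask,
       first_significant_ms = first_sig, zero_variance = zero_var)
}

#' Attach significance results to a decoding curve
#'
#' @param curve a `decoding_curve`.
#' @param accuracies replicates x windows accuracy matrix (e.g. one row per
#'   subject at matching centroids).
#' @param chance,q see [significance_curve()].
#' @return the curve with `p_values`, `fdr_mask` and
#'   `first_significant_ms` filled in.
#' @export
add_significance <- function(curve, accuracies, chance = 0.5, q = 0.05) {
  sig <- significance_curve(accuracies, chance = chance, q = q,
                            centroids_ms = curve$centroids_ms)
  curve$p_values <- sig$p_values
  curve$fdr_mask <- sig$fdr_mask
  curve$first_significant_ms <- sig$first_significant_ms
  curve
}

#' Synthesize A+V composite trials for interaction decoding
#'
#' For the audiovisual-interaction decoding contrast, the comparison class
#' for AV trials is built by sample-wise summation of randomly paired
#' auditory-only and visual-only trials; under pure additivity the
#' composites are statistically indistinguishable from AV trials.
#'
#' @param tc_a,tc_v numeric matrices (trials x samples) of single-trial ROI
#'   time courses for the A and V conditions.
#' @param n number of composites (default the smaller trial count).
#' @param seed seed for the random pairing.
#' @return numeric matrix, `n` x samples.
#' @export
make_av_composites <- function(tc_a, tc_v, n = min(nrow(tc_a), nrow(tc_v)),
                               seed = 1) {
  stopifnot(ncol(tc_a) == ncol(tc_v))
  set.seed(seed)
  ia <- sample(nrow(tc_a), n, replace = n > nrow(tc_a))
  iv <- sample(nrow(tc_v), n, replace = n > nrow(tc_v))
  tc_a[ia, , drop = FALSE] + tc_v[iv, , drop = FALSE]
}
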