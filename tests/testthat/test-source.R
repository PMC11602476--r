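test_that("baseline noise covariance is symmetric and converges to the truth", {
  times <- epoch_times(600, -250, 100)
  ts <- noise_trial_set(250, 3, times, ch_sd = 1, seed = 3)
  nc <- estimate_noise_cov(ts)
  expect_identical(nc$matrix, t(nc$matrix))
  expect_equal(diag(nc$matrix), rep(1, 6), tolerance = 0.05)
  off <- nc$matrix[upper.tri(nc$matrix)]
  expect_lt(max(abs(off)), 0.05)

  # zero data -> pure loading term
  ts0 <- ts
  ts0$data[] <- 0
  nc0 <- estimate_noise_cov(ts0, epsilon = 1e-3)
  expect_equal(nc0$matrix, diag(1e-3, 6))

  # too few samples triggers the stronger-loading warning
  short <- noise_trial_set(1, 5, epoch_times(600, -10, 20), ch_sd = 1, seed = 1)
  expect_warning(estimate_noise_cov(short, baseline_window_ms = c(-10, 0)),
                 "loading")
})

test_that("the minimum-norm inverse reduces to identity when L = C = I, lambda2 = 0", {
  times <- epoch_times(600, -250, 100)
  n <- length(times)
  lf <- list(gain = diag(4), roi_map = list(all = 1:4))
  class(lf) <- "leadfield"
  set.seed(8)
  mat <- matrix(rnorm(4 * n), 4, n)
  ev <- evoked_from_matrix(mat, times)
  nc <- structure(list(matrix = diag(4), n_samples_used = n), class = "noise_cov")
  st <- compute_mne(ev, lf, nc, lambda2 = 0)
  expect_equal(st$values, mat, tolerance = 1e-10)

  # zero data -> zero estimate
  ev0 <- evoked_from_matrix(matrix(0, 4, n), times)
  expect_equal(max(abs(compute_mne(ev0, lf, nc, lambda2 = 1/9)$values)), 0)
})

test_that("the inverse is linear in the data", {
  times <- epoch_times(600, -250, 100)
  ts <- noise_trial_set(40, 5, times, seed = 4)
  nc <- estimate_noise_cov(ts)
  lf <- make_leadfield(n_locations = 5, n_sources = 8, sources_per_roi = 1,
                       seed = 4)
  set.seed(5)
  X <- matrix(rnorm(10 * length(times)), 10)
  Y <- matrix(rnorm(10 * length(times)), 10)
  st <- function(m) compute_mne(evoked_from_matrix(rbind(m, 0), times), lf, nc)$values
  expect_equal(st(2 * X + 3 * Y), 2 * st(X) + 3 * st(Y), tolerance = 1e-8)
})

test_that("a single active source is localized at the argmax", {
  times <- epoch_times(600, -250, 300)
  lf <- make_leadfield(n_locations = 15, n_sources = 8, sources_per_roi = 1,
                       seed = 11)
  ts <- noise_trial_set(60, 15, times, ch_sd = 1, seed = 11)
  nc <- estimate_noise_cov(ts)
  src <- 5
  sig <- matrix(0, 8, length(times))
  sig[src, ] <- 50 * ramp_burst(times, 50)
  ev <- evoked_from_matrix(rbind(lf$gain %*% sig, 0), times)
  st <- compute_mne(ev, lf, nc, lambda2 = 0.01)
  post <- which(times > 80 & times < 300)
  winners <- apply(abs(st$values[, post]), 2, which.max)
  expect_true(all(winners == src))
})

test_that("dSPM baselines have unit SD and the normalization is scale-invariant", {
  times <- epoch_times(600, -250, 300)
  ts <- noise_trial_set(80, 10, times, ch_sd = runif(20, 3, 25), seed = 21)
  nc <- estimate_noise_cov(ts)
  lf <- make_leadfield(n_locations = 10, n_sources = 10, seed = 21)

  # a fresh pure-noise epoch projected through the inverse
  ev <- average_evoked(ts, "Noise")
  ev$data <- ts$data[1, , ]
  ev$n_trials <- 1L # single epoch, so the covariance is used unscaled
  dspm <- dspm_normalize(compute_mne(ev, lf, nc), nc)
  bl_sd <- apply(dspm$values[, times < 0], 1, sd)
  expect_true(all(abs(bl_sd - 1) < 0.25))

  # doubling the noise (C -> 4C, data -> 2x) with the regularization weight
  # rescaled accordingly (lambda2 -> lambda2/4) leaves the dSPM unchanged
  nc2 <- nc
  nc2$matrix <- 4 * nc$matrix
  ev2 <- ev
  ev2$data <- 2 * ev$data
  d_a <- dspm_normalize(compute_mne(ev, lf, nc, lambda2 = 1/9), nc)
  d_b <- dspm_normalize(compute_mne(ev2, lf, nc2, lambda2 = 1/36), nc2)
  expect_equal(d_b$values, d_a$values, tolerance = 1e-8)

  # zero data -> zero dSPM
  ev0 <- ev
  ev0$data[] <- 0
  expect_equal(max(abs(dspm_normalize(compute_mne(ev0, lf, nc), nc)$values)), 0)
})

test_that("dSPM reduces point spread relative to raw MNE on average", {
  times <- epoch_times(600, -250, 300)
  ts <- noise_trial_set(60, 20, times, ch_sd = runif(40, 3, 25), seed = 31)
  nc <- estimate_noise_cov(ts)
  lf <- make_leadfield(n_locations = 20, n_sources = 15, seed = 31)
  ev <- average_evoked(ts, "Noise")
  ev$n_trials <- 1L # fixtures below are single noisy projections
  post <- times > 60 & times < 300
  set.seed(32)
  ratios <- vapply(1:15, function(src) {
    sig <- matrix(0, 15, length(times))
    sig[src, ] <- 100 * ramp_burst(times, 50)
    ev$data <- rbind(lf$gain %*% sig + matrix(rnorm(40 * length(times)), 40), 0)
    mne <- compute_mne(ev, lf, nc)
    dspm <- dspm_normalize(mne, nc)
    ratio <- function(v) mean(abs(v[src, post])) / mean(abs(v[-src, post]))
    c(mne = ratio(mne$values), dspm = ratio(dspm$values))
  }, numeric(2))
  expect_gt(mean(ratios["dspm", ]), mean(ratios["mne", ]))
})

test_that("ROI extraction averages magnitudes and combines hemispheres", {
  times <- epoch_times(600, -250, 100)
  st <- structure(list(
    values = rbind(sin(times / 50), -sin(times / 50), rep(2, length(times)),
                   rep(4, length(times))),
    kind = "dspm", times_ms = times, sfreq_hz = 600, lambda2 = 1/9,
    roi_map = list(A1_left = 1:2, A1_right = 3, V1_left = 4)
  ), class = "source_estimate")

  # single-source ROI returns that source's magnitude
  v1 <- extract_roi_timecourse(st, "V1_left", combine_hemispheres = FALSE)
  expect_equal(unname(v1$data[1, ]), rep(4, length(times)))

  # two opposite-signed sources: magnitudes average, no cancellation
  a1l <- extract_roi_timecourse(st, "A1_left", combine_hemispheres = FALSE)
  expect_equal(unname(a1l$data[1, ]), abs(sin(times / 50)))

  # combined L/R equals the mean of the per-hemisphere extractions
  a1 <- extract_roi_timecourse(st, "A1")
  expect_equal(unname(a1$data[1, ]), (abs(sin(times / 50)) + 2) / 2)

  expect_error(extract_roi_timecourse(st, "S1"), "config error")
})

test_that("the interaction contrast obeys its algebraic identities", {
  times <- epoch_times(600, -250, 300)
  set.seed(41)
  A <- evoked_from_matrix(matrix(rnorm(2 * length(times)), 2), times)
  V <- evoked_from_matrix(matrix(rnorm(2 * length(times)), 2), times)
  AV <- A
  AV$data <- A$data + V$data

  # additivity null: AV = A + V gives a zero interaction (before filtering)
  zero <- interaction_response(A, V, AV, lowpass_hz = NULL)
  expect_equal(max(abs(zero$data)), 0)

  # A = V = 0 gives interaction = AV
  Z <- A
  Z$data[] <- 0
  same <- interaction_response(Z, Z, AV, lowpass_hz = NULL)
  expect_equal(same$data, AV$data)

  # rectified inputs are refused
  expect_error(interaction_response(gradient_amplitude(A), V, AV),
               "signed")

  # mismatched time axes are refused
  B <- evoked_from_matrix(A$data[, -1], times[-1])
  expect_error(interaction_response(B, V, AV), "alignment")
})

test_that("interaction noise SD scales as sqrt(3) over its constituents", {
  set.seed(51)
  n <- 10000
  sigma <- 2
  A <- rnorm(n, 0, sigma)
  V <- rnorm(n, 0, sigma)
  AV <- rnorm(n, 0, sigma)
  inter <- interaction_response(A, V, AV, lowpass_hz = NULL)
  expect_lt(abs(sd(inter) / sigma - sqrt(3)), 0.03 * sqrt(3))
})

test_that("no interaction onset is detected when AV responses are exactly additive", {
  # additive generator (no interaction component, no amplitude jitter);
  # the contrast is examined unfiltered so the baseline threshold retains
  # its nominal calibration
  hits <- 0
  n_sim <- 50
  for (i in seq_len(n_sim)) {
    cfg <- sim_config(true_onsets = default_true_onsets(interaction = FALSE),
                      amp_jitter = 0, noise_sd_sensor = 30, seed = 5000 + i)
    des <- make_design(data.frame(run_id = 3, mean_isi_s = 6.1,
                                  n_per_category = 12L),
                       target_fraction = 0, seed = 6000 + i)[[1]]
    lf <- make_leadfield(n_locations = 8, n_sources = 8, sources_per_roi = 1,
                         seed = 7000 + i)
    ts <- simulate_trials(cfg, des, lf, tmax_ms = 500)
    nc <- estimate_noise_cov(ts)
    evs <- lapply(c("A", "V", "AV"),
                  function(cc) baseline_correct(average_evoked(ts, cc)))
    inter <- interaction_response(evs[[1]], evs[[2]], evs[[3]], lowpass_hz = NULL)
    st <- dspm_normalize(compute_mne(inter, lf, nc), nc)
    for (roi in c("A1", "V1")) {
      rt <- extract_roi_timecourse(st, roi)
      if (!is.na(detect_onset(rt$data[roi, ], rt$times_ms)$onset_ms)) {
        hits <- hits + 1
      }
    }
  }
  expect_lte(hits / (2 * n_sim), 0.10)
})
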