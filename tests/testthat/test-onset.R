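times_short <- epoch_times(600, -250, 300)
dt <- 1000 / 600

test_that("baseline noise statistics match a two-pass recomputation", {
  x <- rep(2, length(times_short))
  n0 <- estimate_noise(x, times_short)
  expect_equal(n0$noise_mean, 2)
  expect_equal(n0$noise_sd, 0)
  expect_true(n0$degenerate)

  set.seed(1)
  y <- rnorm(length(times_short))
  n1 <- estimate_noise(y, times_short)
  bl <- y[times_short >= -200 & times_short < 0]
  m <- sum(bl) / length(bl)
  expect_equal(n1$noise_mean, m)
  expect_equal(n1$noise_sd, sqrt(sum((bl - m)^2) / (length(bl) - 1)))
})

test_that("a clean step is detected at its onset sample", {
  set.seed(2)
  for (step_ms in c(50, 100, 200)) {
    x <- rnorm(length(times_short), 0, 1)
    x[times_short >= step_ms - 1e-9] <- x[times_short >= step_ms - 1e-9] + 10
    res <- detect_onset(x, times_short)
    expect_equal(res$onset_ms, times_short[which(times_short >= step_ms - 1e-9)[1]])
    expect_true(res$sustained)
  }
})

test_that("brief bursts fail the sustain criterion", {
  set.seed(3)
  x <- rnorm(length(times_short), 0, 1)
  i0 <- which(times_short >= 50)[1]
  x[i0:(i0 + 5)] <- 20 # 10 ms burst < 20 ms sustain
  res <- detect_onset(x, times_short)
  expect_true(is.na(res$onset_ms))
  expect_false(res$sustained)
  expect_equal(res$first_crossing_ms, times_short[i0])
})

test_that("responses before the 15 ms minimum latency are deferred", {
  x <- numeric(length(times_short))
  bl <- times_short >= -200 & times_short < 0
  set.seed(4)
  x[bl] <- rnorm(sum(bl), 0, 0.5)
  x[times_short >= 10] <- 10 # step at 10 ms, before the physiological minimum
  res <- detect_onset(x, times_short)
  expect_equal(res$onset_ms, times_short[which(times_short >= 15 - 1e-9)[1]])
  expect_gte(res$onset_ms, 15)
})

test_that("the detector equals an exhaustive brute-force scan on random fixtures", {
  set.seed(5)
  for (i in 1:300) {
    x <- rnorm(length(times_short), 0, 1)
    if (i %% 3 == 0) { # sometimes add a ramp so both outcomes occur
      on <- runif(1, 0, 200)
      x <- x + runif(1, 0, 8) * ramp_burst(times_short, on, duration_ms = runif(1, 5, 100))
    }
    got <- detect_onset(x, times_short)$onset_ms
    want <- brute_force_onset(x, times_short)
    expect_identical(is.na(got), is.na(want))
    if (!is.na(got)) expect_equal(got, want)
  }
})

test_that("raising k or lengthening the sustain never gives an earlier onset", {
  set.seed(6)
  for (i in 1:40) {
    x <- rnorm(length(times_short), 0, 1) +
      runif(1, 2, 6) * ramp_burst(times_short, runif(1, 20, 150))
    o3 <- detect_onset(x, times_short, k = 3)$onset_ms
    o5 <- detect_onset(x, times_short, k = 5)$onset_ms
    if (!is.na(o3) && !is.na(o5)) expect_gte(o5, o3)
    s20 <- detect_onset(x, times_short, sustain_ms = 20)$onset_ms
    s40 <- detect_onset(x, times_short, sustain_ms = 40)$onset_ms
    if (!is.na(s20) && !is.na(s40)) expect_gte(s40, s20)
  }
})

test_that("time-shifting the response shifts the onset equally", {
  # baseline noise fixes the threshold; the post-stimulus response is clean
  # so the crossing depends only on the response's own leading edge
  set.seed(7)
  x0 <- numeric(length(times_short))
  pre <- times_short < 0
  x0[pre] <- rnorm(sum(pre), 0, 1)
  o0 <- detect_onset(x0 + 10 * ramp_burst(times_short, 50), times_short)$onset_ms
  for (shift_samples in c(6, 30, 60)) {
    x1 <- x0 + 10 * ramp_burst(times_short, 50 + shift_samples * dt)
    o1 <- detect_onset(x1, times_short)$onset_ms
    expect_lte(abs((o1 - o0) - shift_samples * dt), dt + 1e-9)
  }
})

test_that("onsets are recovered within one sample at high SNR, none on pure noise", {
  set.seed(8)
  truths <- c(25, 48, 62, 65)
  n_sim <- 200
  hits <- 0
  for (i in seq_len(n_sim)) {
    truth <- truths[(i - 1) %% 4 + 1]
    # high SNR: amplitude 20x the noise SD, as in the worked recovery setup
    x <- rnorm(length(times_short), 0, 1) + 20 * ramp_burst(times_short, truth)
    got <- detect_onset(x, times_short)$onset_ms
    grid_truth <- times_short[which(times_short >= truth - 1e-9)[1]]
    if (!is.na(got) && abs(got - grid_truth) <= dt + 1e-9) hits <- hits + 1
  }
  expect_gte(hits / n_sim, 0.95)

  false_pos <- 0
  for (i in seq_len(n_sim)) {
    got <- detect_onset(rnorm(length(times_short)), times_short)$onset_ms
    if (!is.na(got)) false_pos <- false_pos + 1
  }
  expect_lte(false_pos / n_sim, 0.05)
})

test_that("bootstrap onsets are degenerate for identical trials and reproducible", {
  times <- epoch_times(600, -250, 200)
  n_loc <- 2
  one <- rbind(matrix(10 * ramp_burst(times, 50), 2 * n_loc, length(times),
                      byrow = TRUE),
               matrix(0, 1, length(times)))
  dat <- array(0, c(8, 2 * n_loc + 1, length(times)))
  for (e in 1:8) dat[e, , ] <- one
  ts <- trial_set(dat, grad_channel_meta(n_loc), 600, times, rep("A", 8))
  pipe <- function(tr) {
    ev <- average_evoked(tr, "A")
    list(x = ev$data[1, ], times_ms = ev$times_ms)
  }
  # identical noiseless trials: noise SD 0, detection against the mean
  bs <- bootstrap_onset(ts, pipe, B = 20, seed = 1)
  expect_equal(bs$sd_ms, 0)
  expect_equal(unique(bs$onsets), detect_onset(one[1, ], times)$onset_ms)

  b1 <- bootstrap_onset(ts, pipe, B = 1, seed = 5)
  b2 <- bootstrap_onset(ts, pipe, B = 1, seed = 5)
  expect_identical(b1$onsets, b2$onsets)
})

test_that("bootstrap SD tracks the across-session onset variability at high SNR", {
  # the bootstrap is used on high-SNR averaged source signals; in that
  # regime its onset SD should match the across-session SD of the onset
  times <- epoch_times(600, -250, 200)
  make_session <- function(seed, n_tr = 24) {
    set.seed(seed)
    dat <- array(rnorm(n_tr * 3 * length(times), 0, 6),
                 c(n_tr, 3, length(times)))
    resp <- 16 * ramp_burst(times, 60)
    for (e in seq_len(n_tr)) {
      dat[e, 1:2, ] <- dat[e, 1:2, ] + rbind(resp, resp)
    }
    trial_set(dat, grad_channel_meta(1), 600, times, rep("A", n_tr))
  }
  pipe <- function(tr) {
    ev <- average_evoked(tr, "A")
    list(x = ev$data[1, ], times_ms = ev$times_ms)
  }
  emp <- vapply(1:60, function(s) {
    tc <- pipe(make_session(s))
    detect_onset(tc$x, tc$times_ms)$onset_ms
  }, numeric(1))
  emp_sd <- sd(emp, na.rm = TRUE)
  boot_sds <- vapply(1001:1005, function(s) {
    bootstrap_onset(make_session(s), pipe, B = 100, seed = 2)$sd_ms
  }, numeric(1))
  expect_gt(median(boot_sds), emp_sd / 2)
  expect_lt(median(boot_sds), emp_sd * 2)
})

test_that("latency arithmetic reproduces the worked cross-modal examples", {
  expect_equal(convergence_latency(25, 65), 65)
  expect_equal(convergence_latency(40, 40), 40)
  expect_equal(conduction_delay(62, 25), 37)
  expect_equal(conduction_delay(65, 48), 17)
  expect_equal(conduction_delay(30, 30), 0)
  expect_equal(interaction_lag(125, 65), 60)
  expect_equal(interaction_lag(133, 62), 71)
  expect_equal(interaction_lag(80, 80), 0)
  expect_error(convergence_latency(NA, 10), "undefined")
  expect_error(conduction_delay(10, NULL), "missing onset")
})

test_that("latency tables aggregate correctly and format as mean ± SD (median)", {
  onsets <- data.frame(
    roi = rep(c("A1_left", "A1_right"), each = 3),
    condition = "A",
    subject = rep(c("s1", "s2", "s3"), 2),
    onset_ms = c(30, 32, 28, 34, 30, 30))
  lt <- build_latency_table(onsets, average_hemispheres = TRUE)
  expect_equal(nrow(lt), 1)
  # within-subject L/R means: 32, 31, 29
  expect_equal(lt$mean_ms, mean(c(32, 31, 29)))
  expect_equal(lt$median_ms, 31)
  expect_equal(lt$sd_ms, sd(c(32, 31, 29)))
  expect_equal(lt$n, 3L)

  # independent per-cell recomputation on a random fixture
  set.seed(9)
  rnd <- data.frame(
    roi = sample(c("A1", "V1"), 60, TRUE),
    condition = sample(c("A", "V"), 60, TRUE),
    subject = sample(paste0("s", 1:5), 60, TRUE),
    onset_ms = runif(60, 20, 120))
  lt2 <- build_latency_table(rnd)
  for (r in seq_len(nrow(lt2))) {
    v <- rnd$onset_ms[rnd$roi == lt2$roi[r] & rnd$condition == lt2$condition[r]]
    expect_equal(lt2$mean_ms[r], mean(v))
    expect_equal(lt2$median_ms[r], median(v))
    expect_equal(lt2$sd_ms[r], sd(v))
  }

  single <- build_latency_table(data.frame(roi = "A1", condition = "A",
                                           subject = "s1", onset_ms = 27))
  expect_equal(single$mean_ms, 27)
  expect_equal(single$median_ms, 27)
  expect_true(is.na(single$sd_ms))

  expect_equal(format_latency_cell(25.4, 2.1, 25.0), "25 ± 2 (25)")
  expect_equal(format_latency_cell(c(25.4, 131.2), c(2.1, 27.4), c(25, 125.4)),
               c("25 ± 2 (25)", "131 ± 27 (125)"))
})
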