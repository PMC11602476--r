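# Fixture builders shared across test files. Everything is generated in
# code; no data files.

# channel metadata for n_loc gradiometer locations plus one EOG channel
grad_channel_meta <- function(n_loc) {
  rbind(
    data.frame(name = sprintf("MEG%03d%s", rep(seq_len(n_loc), each = 2),
                              rep(c("x", "y"), n_loc)),
               kind = rep(c("grad_x", "grad_y"), n_loc),
               unit = "fT/cm",
               location_id = rep(seq_len(n_loc), each = 2)),
    data.frame(name = "EOG001", kind = "eog", unit = "uV", location_id = 0L)
  )
}

# trial set of pure Gaussian noise; ch_sd may be scalar or per-grad-channel
noise_trial_set <- function(n_epochs, n_loc, times, ch_sd = 10, eog_sd = 15,
                            labels = rep("Noise", n_epochs), seed = 1) {
  set.seed(seed)
  n_grad <- 2L * n_loc
  if (length(ch_sd) == 1) ch_sd <- rep(ch_sd, n_grad)
  dat <- array(0, c(n_epochs, n_grad + 1L, length(times)))
  for (e in seq_len(n_epochs)) {
    dat[e, seq_len(n_grad), ] <- rnorm(n_grad * length(times), 0, ch_sd)
    dat[e, n_grad + 1L, ] <- rnorm(length(times), 0, eog_sd)
  }
  trial_set(dat, grad_channel_meta(n_loc), 600, times, labels)
}

# evoked built directly from a channels x samples matrix
evoked_from_matrix <- function(mat, times, channel_meta = NULL,
                               amplitude = FALSE) {
  if (is.null(channel_meta)) {
    n_loc <- nrow(mat) %/% 2
    channel_meta <- grad_channel_meta(n_loc)[seq_len(nrow(mat)), ]
  }
  structure(list(
    data = mat, channel_meta = channel_meta, sfreq_hz = 600,
    times_ms = times, condition = "test", n_trials = 1L,
    baseline_window_ms = NULL, filter_applied_hz = NULL,
    amplitude = amplitude
  ), class = "evoked")
}

# small simulated session: one run, reduced leadfield, shortened epochs
small_session <- function(n_per_category = 30L, noise_sd = 30,
                          n_locations = 10, n_sources = 10,
                          tmax_ms = 500, seed = 42,
                          true_onsets = default_true_onsets()) {
  cfg <- sim_config(true_onsets = true_onsets, noise_sd_sensor = noise_sd,
                    seed = seed)
  des <- make_design(data.frame(run_id = 3L, mean_isi_s = 6.1,
                                n_per_category = n_per_category),
                     seed = seed + 1)[[1]]
  lf <- make_leadfield(n_locations = n_locations, n_sources = n_sources,
                       seed = seed + 2)
  list(config = cfg, design = des, leadfield = lf,
       trials = simulate_trials(cfg, des, lf, tmax_ms = tmax_ms))
}

## Independent oracles --------------------------------------------------

# exhaustive onset scan: earliest t >= min_latency with x > thr sustained
# over the inclusive window [t, t + sustain_ms]
brute_force_onset <- function(x, times, k = 3, min_latency = 15,
                              sustain = 20, baseline = c(-200, 0)) {
  b <- x[times >= baseline[1] & times < baseline[2]]
  thr <- mean(b) + k * sd(b)
  dt <- times[2] - times[1]
  n_sus <- floor(sustain / dt + 1e-9) + 1
  for (i in seq_along(times)) {
    if (times[i] < min_latency) next
    if (i + n_sus - 1 > length(x)) break
    if (all(x[i:(i + n_sus - 1)] > thr)) return(times[i])
  }
  NA_real_
}

# Benjamini-Hochberg step-up: reject the i smallest p-values where i is the
# largest index with p_(i) <= (i/m) q
brute_force_bh <- function(p, q = 0.05) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  below <- which(ps <= (seq_len(m) / m) * q)
  mask <- rep(FALSE, m)
  if (length(below) > 0) mask[ord[seq_len(max(below))]] <- TRUE
  mask
}

# exact two-sided signed-rank p by enumerating all 2^n sign assignments of
# the (nonzero, untied) differences
brute_force_signed_rank <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  p_ge <- mean(v_all >= v_obs)
  p_le <- mean(v_all <= v_obs)
  min(1, 2 * min(p_ge, p_le))
}
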