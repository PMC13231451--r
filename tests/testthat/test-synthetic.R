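test_that("degenerate hypnogram is a single pre-sleep block", {
  cfg <- sim_config(duration_s = 600, pre_s = 600, post_s = 0)
  hyp <- generate_hypnogram(cfg)
  expect_equal(nrow(hyp), 1L)
  expect_equal(hyp$onset_s, 0)
  expect_equal(hyp$offset_s, 600)
  expect_equal(hyp$stage, "Pre")
})

test_that("hypnogram generation is deterministic and gap-free", {
  cfg <- sim_config(duration_s = 3600, seed = 1)
  h1 <- generate_hypnogram(cfg)
  h2 <- generate_hypnogram(cfg)
  expect_identical(h1, h2)
  expect_equal(h1$onset_s[-1], h1$offset_s[-nrow(h1)])
  expect_equal(h1$onset_s[1], 0)
  expect_equal(h1$offset_s[nrow(h1)], 3600)
  expect_error(generate_hypnogram(sim_config(duration_s = 100, pre_s = 300,
                                             post_s = 300)),
               "shorter")
})

test_that("stage occupancy matches a brute-force chain simulation oracle", {
  cfg <- sim_config(duration_s = 8 * 3600, pre_s = 600, post_s = 600, seed = 5)
  hyp <- generate_hypnogram(cfg)
  sleep_len <- cfg$duration_s - cfg$pre_s - cfg$post_s
  occ <- function(h) {
    len <- tapply(h$offset_s - h$onset_s, h$stage, sum)
    states <- rownames(cfg$stage_transition)
    out <- setNames(numeric(length(states)), states)
    out[names(len)[names(len) %in% states]] <- len[names(len) %in% states]
    out / sleep_len
  }
  ## independent oracle: plain loop over exponential dwells and
  ## categorical transitions, many replicates
  oracle_occ <- withr::with_seed(99, {
    replicate(150, {
      t <- 0
      state <- "Wake"
      len <- setNames(numeric(5), rownames(cfg$stage_transition))
      while (t < sleep_len) {
        d <- min(rexp(1, 1 / cfg$stage_dwell_s[[state]]), sleep_len - t)
        len[state] <- len[state] + d
        t <- t + d
        state <- sample(colnames(cfg$stage_transition), 1,
                        prob = cfg$stage_transition[state, ])
      }
      len / sleep_len
    })
  })
  mu <- rowMeans(oracle_occ)
  sdv <- apply(oracle_occ, 1, sd)
  got <- occ(hyp)
  expect_true(all(abs(got - mu) <= 3 * sdv))
})

test_that("IED kernels have the documented morphology and depth gradient", {
  cfg <- sim_config()
  for (id in 1:2) {
    k <- make_ied_kernel(id, cfg)
    ## sharp positive transient peaking at kernel time 0 on the deepest channel
    tpk <- k$times_s[which.max(k$waveform[1, ])]
    expect_lte(abs(tpk), 0.010)
    ## amplitude decays from deepest to most superficial contact
    peaks <- apply(k$waveform, 1, max)
    expect_true(all(diff(peaks) < 0))
    expect_gt(peaks[1], peaks[5])
    ## a slower negative wave follows the spike
    expect_lt(min(k$waveform[1, k$times_s > 0.05]), 0)
    ## kernel fits in the epoch window
    expect_lte(length(k$times_s) / k$sample_rate_hz, 1.5)
  }
  k1 <- make_ied_kernel(1, cfg)
  k2 <- make_ied_kernel(2, cfg)
  expect_lt(cor(as.vector(k1$waveform), as.vector(k2$waveform)), 0.9)
})

test_that("zero IED rate yields an empty ground truth", {
  cfg <- sim_config(duration_s = 300, pre_s = 60, post_s = 60,
                    ied_base_rate_per_min = 0, artefact_rate_per_hour = 0)
  out <- generate_recording(cfg)
  expect_equal(nrow(out$ground_truth), 0L)
  expect_error(generate_recording(sim_config(ied_base_rate_per_min = 600)),
               "separation")
})

test_that("per-stage IED rates and amplitudes follow the configured multipliers", {
  cfg <- sim_config(duration_s = 7200, pre_s = 1200, post_s = 600,
                    ied_base_rate_per_min = 3, artefact_rate_per_hour = 0,
                    seed = 17)
  out <- generate_recording(cfg)
  gt <- out$ground_truth
  hyp <- out$hypnogram
  occ <- tapply(hyp$offset_s - hyp$onset_s, hyp$stage, sum)
  n <- table(gt$stage)
  ## S3 vs Pre rate ratio: configured 4, Poisson counting error
  r_s3 <- n[["S3"]] / occ[["S3"]]
  r_pre <- n[["Pre"]] / occ[["Pre"]]
  ratio <- r_s3 / r_pre
  se <- ratio * sqrt(1 / n[["S3"]] + 1 / n[["Pre"]])
  expect_lt(abs(ratio - 4), 3 * se)
  ## amplitude ordering S3 > S2 > S1 in the injected events
  amp <- tapply(gt$amplitude_uv, gt$stage, mean)
  expect_gt(amp[["S3"]], amp[["S2"]])
  expect_gt(amp[["S2"]], amp[["S1"]])
})

test_that("identical seeds reproduce the ground truth bit for bit", {
  cfg <- sim_config(duration_s = 400, pre_s = 60, post_s = 60, seed = 23)
  a <- simulate_session(cfg)
  b <- simulate_session(cfg)
  expect_identical(a$ground_truth, b$ground_truth)
  expect_identical(a$spike_trains, b$spike_trains)
  expect_identical(a$recording$samples, b$recording$samples)
})

test_that("averaging epochs at ground-truth times recovers the kernel", {
  ses <- small_session(seed = 8, duration_s = 1200, n_templates = 1, rate = 10)
  expect_gt(nrow(ses$ground_truth), 100)
  ep <- extract_epochs(ses$recording, ses$ground_truth$time_s)
  avg <- apply(ep$trials, c(2, 3), mean)
  k <- make_ied_kernel(1, ses$config)
  tt <- ep$window[1] + (seq_len(dim(ep$trials)[3]) - 1) / ep$sample_rate_hz
  sel <- tt >= min(k$times_s) & tt < max(k$times_s) + 1e-9
  expect_gt(cor(as.vector(avg[, sel]), as.vector(k$waveform)), 0.99)
})

test_that("spike trains express the configured PDS modulation", {
  ## null modulation: flat PSTH around IEDs
  cfg0 <- sim_config(duration_s = 2000, pre_s = 2000, post_s = 0,
                     g_spike = 1, g_wave = 1, burst_prob = 0, n_units = 1,
                     ied_base_rate_per_min = 30, ied_min_separation_s = 1.6,
                     seed = 31)
  hyp0 <- generate_hypnogram(cfg0)
  gt0 <- data.frame(time_s = seq(30, 1970, by = 1.6))
  tr0 <- generate_spike_trains(cfg0, gt0, hyp0)[[1]]
  p0 <- compute_psth(tr0$spike_times_s, gt0$time_s)
  base <- p0$baseline_mean
  ## binomial/Poisson error of a bin mean across n events
  se_bin <- sqrt(base / (p0$bin_s * p0$n_events))
  expect_lt(max(abs(p0$mean_rate - base)), 4 * se_bin)

  ## g_spike = 3: peak-bin rate close to 3x baseline
  cfg3 <- sim_config(duration_s = 3400, pre_s = 3400, post_s = 0,
                     g_spike = 3, g_wave = 0.3, burst_prob = 0, n_units = 1,
                     ied_base_rate_per_min = 40, ied_min_separation_s = 1.6,
                     seed = 32)
  hyp3 <- generate_hypnogram(cfg3)
  gt3 <- data.frame(time_s = seq(30, 3350, by = 1.66))
  expect_gt(nrow(gt3), 1900)
  tr3 <- generate_spike_trains(cfg3, gt3, hyp3)[[1]]
  p3 <- compute_psth(tr3$spike_times_s, gt3$time_s)
  gain_bins <- p3$bin_centers > -0.025 & p3$bin_centers < 0.075
  peak_gain <- mean(p3$mean_rate[gain_bins]) / p3$baseline_mean
  se_gain <- 3 * sqrt(1 / (sum(gain_bins) * p3$bin_s * p3$n_events * p3$baseline_mean))
  expect_lt(abs(peak_gain - 3), 3 * se_gain + 0.1)

  ## no doublet injection: ISI < 5 ms only at the baseline chance level
  isi <- diff(tr0$spike_times_s)
  frac <- mean(isi < 0.005)
  lambda_hat <- 1 / mean(isi)
  expected <- 1 - exp(-lambda_hat * 0.005)
  expect_lt(frac, expected + 3 * sqrt(expected / length(isi)))

  expect_error(sim_config(g_wave = -1), "g_wave")
})
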