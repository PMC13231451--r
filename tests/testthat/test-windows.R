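test_that("window segmentation labels stages and excludes overlaps", {
  hyp <- data.frame(onset_s = c(0, 40), offset_s = c(40, 100),
                    stage = c("Pre", "S2"))
  w <- segment_windows(100, hyp)
  expect_equal(nrow(w), 10L)
  expect_equal(w$stage, c(rep("Pre", 4), rep("S2", 6)))

  ## an IED at 35 s removes window [30, 40) in baseline mode
  wb <- segment_windows(100, hyp, ied_times = 35, mode = "baseline")
  expect_true(wb$excluded[wb$onset_s == 30])
  expect_equal(wb$reason[wb$onset_s == 30], "ied")
  expect_equal(sum(wb$excluded), 1L)

  ## artefact overlap of any amount excludes
  wa <- segment_windows(100, hyp, artefacts = data.frame(onset_s = 39.99,
                                                         offset_s = 40.01))
  expect_equal(which(wa$excluded), 4:5)

  ## exclusion count equals a naive interval-intersection oracle
  ses <- simulate_session(sim_config(duration_s = 900, pre_s = 200, post_s = 100,
                                     artefact_rate_per_hour = 40, seed = 19))
  w2 <- segment_windows(900, ses$hypnogram, ses$artefacts,
                        ses$ground_truth$time_s, mode = "baseline")
  naive <- sapply(seq_len(nrow(w2)), function(i) {
    art <- any(w2$onset_s[i] < ses$artefacts$offset_s &
               ses$artefacts$onset_s < w2$offset_s[i])
    ied <- any(ses$ground_truth$time_s >= w2$onset_s[i] &
               ses$ground_truth$time_s < w2$offset_s[i])
    art || ied
  })
  expect_equal(w2$excluded, naive)
})

test_that("Hann FFT power sits on a 0.1 Hz grid and respects Parseval", {
  fs <- 1000
  tt <- (0:(10 * fs - 1)) / fs
  sp <- window_power(sin(2 * pi * 1.0 * tt), fs)
  expect_equal(diff(sp$freq_hz)[1], 0.1, tolerance = 1e-12)
  expect_equal(sp$freq_hz[which.max(sp$power)], 1.0)
  expect_gt(band_power(sp, 0.1, 2.5), 100 * band_power(sp, 2.5, 4))

  ## white noise: total one-sided power equals the tapered-signal variance
  withr::with_seed(2, x <- rnorm(10 * fs))
  sp2 <- window_power(x, fs)
  w <- 0.5 * (1 - cos(2 * pi * (seq_along(x) - 1) / length(x)))
  ref <- sum((w * (x - mean(x)))^2) / sum(w^2)
  expect_lt(abs(sum(sp2$power) - ref) / ref, 1e-6)

  expect_error(window_power(c(1, NaN, 3), fs), "NaN")
})

test_that("relative power normalizes to the pre-sleep mean per channel", {
  tbl <- data.frame(stage = rep(c("Pre", "S3"), each = 4),
                    channel = 1, swa = c(rep(2, 4), rep(4, 4)))
  out <- relative_power(tbl, "swa")
  expect_equal(mean(out$swa[out$stage == "Pre"]), 1.0)
  expect_equal(out$swa[out$stage == "S3"], rep(2, 4))
  expect_error(relative_power(data.frame(stage = "S3", channel = 1, swa = 1),
                              "swa"), "Pre")
})

test_that("CV2 identities hold", {
  expect_equal(cv2(rep(0.1, 100)), 0.0)
  expect_equal(cv2(c(1, 3)), 1.0)
  ## scale invariance
  withr::with_seed(6, isi <- rexp(500))
  expect_equal(cv2(isi), cv2(isi * 37.5))
  expect_true(is.na(cv2(0.5)))
  expect_error(cv2(c(0.1, 0, 0.1)), "non-positive")
})

test_that("burst detection follows the strict 5 ms cutoff", {
  t <- c(0, 0.003, 0.006, 0.100)
  b <- detect_bursts(t)
  expect_equal(nrow(b), 1L)
  expect_equal(b$n_spikes, 3L)
  expect_equal(correct_bursts(t), c(0, 0.100))

  ## exactly 5 ms is not a burst
  expect_equal(nrow(detect_bursts(c(0, 0.005))), 0L)
  expect_equal(correct_bursts(c(0, 0.005)), c(0, 0.005))

  ## random trains match a naive run-length oracle
  withr::with_seed(8, {
    for (rep in 1:10) {
      tt <- sort(cumsum(rexp(300, 200)))
      naive <- 0L
      run <- 1L
      for (i in seq_along(tt)[-1]) {
        if (tt[i] - tt[i - 1] < 0.005) run <- run + 1L
        else {
          if (run >= 2) naive <- naive + 1L
          run <- 1L
        }
      }
      if (run >= 2) naive <- naive + 1L
      expect_equal(nrow(detect_bursts(tt)), naive)
      ## corrected rate can never exceed the raw rate
      expect_lte(length(correct_bursts(tt)), length(tt))
    }
  })
})

test_that("unit window metrics summarize rate, variability and bursts", {
  t <- seq(0.1, 9.9, length.out = 50)
  m <- unit_window_metrics(t, 0, 10)
  expect_equal(m$firing_rate, 5)
  expect_equal(m$cv2, 0, tolerance = 1e-9)
  expect_equal(m$corrected_rate, m$firing_rate)

  e <- unit_window_metrics(numeric(0), 0, 10)
  expect_equal(e$firing_rate, 0)
  expect_true(is.na(e$cv2))

  ## stage-dependent firing ordering survives windowing
  ses <- simulate_session(sim_config(duration_s = 2400, pre_s = 400,
                                     post_s = 200, ied_base_rate_per_min = 1,
                                     artefact_rate_per_hour = 0, n_units = 1,
                                     unit_baseline_hz = 10, seed = 29))
  w <- segment_windows(2400, ses$hypnogram, mode = "all")
  tbl <- unit_window_table(ses$spike_trains, w)
  rates <- tapply(tbl$firing_rate, tbl$stage, mean)
  if (all(c("Pre", "S3") %in% names(rates))) {
    expect_gt(rates[["Pre"]], rates[["S3"]])
  }
  expect_true(all(tbl$corrected_rate <= tbl$firing_rate))
})
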