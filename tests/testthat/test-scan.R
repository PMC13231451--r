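toy_templates <- function(waveform, fs = 1000, peak_offset_s = NULL) {
  if (is.null(dim(waveform))) waveform <- matrix(waveform, nrow = 1)
  structure(list(templates = list(waveform), member_counts = 2L,
                 peak_offset_s = peak_offset_s %||%
                   (which.max(waveform[1, ]) - 1) / fs,
                 window = c(0, ncol(waveform) / fs), sample_rate_hz = fs),
            class = "ied_templates")
}

test_that("a clean embedded template is found with correlation 1 at its peak", {
  fs <- 1000
  tpl_wave <- rbind(sin(seq(0, 3 * pi, length.out = 200)),
                    0.5 * sin(seq(0, 3 * pi, length.out = 200)))
  x <- matrix(0, 2, 3000)
  t0_lag <- 1200                       # segment start (0-based)
  x[, (t0_lag + 1):(t0_lag + 200)] <- tpl_wave
  rec <- recording(x, fs)
  tpl <- toy_templates(tpl_wave, fs)
  sc <- scan_templates(rec, tpl, threshold = 0.8)
  expect_equal(nrow(sc$detections), 1L)
  expect_equal(sc$detections$r, 1.0, tolerance = 1e-9)
  expect_equal(sc$detections$time_s, t0_lag / fs + tpl$peak_offset_s)
})

test_that("the correlation trace equals the brute-force per-lag Pearson oracle", {
  fs <- 1000
  withr::with_seed(12, {
    x <- matrix(rnorm(2 * 10000), 2)
    w <- matrix(rnorm(2 * 300), 2)
  })
  rec <- recording(x, fs)
  tpl <- toy_templates(w, fs)
  sc <- scan_templates(rec, tpl, threshold = 2, keep_traces = TRUE)
  r <- sc$traces[[1]]
  oracle <- vapply(seq_len(10000 - 300 + 1), function(tau) {
    cor(as.vector(x[, tau:(tau + 299)]), as.vector(w))
  }, 0)
  expect_lt(max(abs(r - oracle)), 1e-10)

  ## scale/offset invariance of the trace
  rec2 <- recording(3.5 * x + 42, fs)
  sc2 <- scan_templates(rec2, tpl, threshold = 2, keep_traces = TRUE)
  expect_lt(max(abs(sc2$traces[[1]] - r)), 1e-9)

  ## zero-variance segments get r = 0
  xz <- x
  xz[, 501:900] <- 7
  scz <- scan_templates(recording(xz, fs), tpl, threshold = 2, keep_traces = TRUE)
  expect_equal(scz$traces[[1]][601], 0)
})

test_that("thresholds above 1 yield no detections and raising them is monotone", {
  ses <- small_session(seed = 5, duration_s = 400, rate = 12)
  recf <- highpass_recording(ses$recording, 4)
  ep <- align_epochs(extract_epochs(recf, ses$ground_truth$time_s))
  tpl <- build_templates(ep, rep(1L, dim(ep$trials)[1]))
  expect_equal(nrow(scan_templates(recf, tpl, threshold = 1.1)$detections), 0L)
  n_by_thr <- vapply(c(0.2, 0.4, 0.6, 0.8),
                     function(th) nrow(scan_templates(recf, tpl, threshold = th)$detections),
                     0L)
  expect_true(all(diff(n_by_thr) <= 0))
})

test_that("automated thresholds reflect their documented definitions", {
  withr::with_seed(3, r <- rnorm(20000))
  thr <- choose_threshold(r, method = "mad", z = 6)
  expect_equal(as.numeric(thr), median(r) + 6 * mad(r))
  expect_equal(attr(thr, "method"), "mad")

  fixed <- choose_threshold(r, method = "fixed", value = 0.5)
  expect_equal(as.numeric(fixed), 0.5)
  expect_equal(attr(fixed, "method"), "fixed")
  expect_false(identical(attr(thr, "method"), attr(fixed, "method")))

  ## valley method splits a bimodal peak-height sample in the gap
  withr::with_seed(4, h <- c(runif(300, 0.2, 0.45), runif(80, 0.65, 0.95)))
  v <- choose_threshold(h, method = "valley")
  expect_gt(v, 0.45)
  expect_lt(v, 0.65)

  expect_error(choose_threshold(rep(0.2, 100), method = "mad"), "constant")
})

test_that("deduplication keeps the best-correlated detection per +-50 ms group", {
  d <- data.frame(time_s = c(1.000, 1.030), template_id = c(2L, 4L),
                  r = c(0.8, 0.9))
  out <- deduplicate_detections(d)
  expect_equal(out$time_s, 1.030)
  expect_equal(out$template_id, 4L)

  ## 60 ms apart: both kept
  d2 <- data.frame(time_s = c(1.0, 1.06), template_id = 1:2, r = c(0.8, 0.9))
  expect_equal(nrow(deduplicate_detections(d2)), 2L)

  ## tie on r: lower template id wins
  d3 <- data.frame(time_s = c(2.0, 2.0), template_id = c(3L, 1L), r = c(0.7, 0.7))
  expect_equal(deduplicate_detections(d3)$template_id, 1L)

  ## idempotence on random detection sets
  withr::with_seed(9, {
    for (rep in 1:10) {
      dd <- data.frame(time_s = sort(runif(50, 0, 20)),
                       template_id = sample(1:6, 50, TRUE),
                       r = runif(50, 0.3, 1))
      once <- deduplicate_detections(dd)
      twice <- deduplicate_detections(once)
      attr(once, "n_removed") <- attr(twice, "n_removed") <- NULL
      expect_equal(twice, once)
      expect_true(all(diff(once$time_s) > 0.05))
    }
  })
})

test_that("detection scoring uses greedy one-to-one matching within +-50 ms", {
  refs <- 1:10
  sc <- evaluate_detections(refs, refs)
  expect_equal(sc$hit_rate, 1.0)
  expect_equal(sc$false_alarm_rate, 0.0)

  ## 10 refs, 11 detections, 9 matchable
  dets <- c(refs[1:9] + 0.01, 100, 101)
  sc2 <- evaluate_detections(dets, refs)
  expect_equal(sc2$hits, 9L)
  expect_equal(sc2$hit_rate, 0.9)
  expect_equal(sc2$false_alarm_rate, 2 / 11)
  expect_equal(sc2$hits + sc2$misses, sc2$n_ref)
  expect_equal(sc2$hits + sc2$false_alarms, sc2$n_det)

  ## tolerance boundary: 49 ms matches, 51 ms does not
  expect_equal(evaluate_detections(1.049, 1.0)$hits, 1L)
  s51 <- evaluate_detections(1.051, 1.0)
  expect_equal(s51$hits, 0L)
  expect_equal(s51$misses, 1L)
  expect_equal(s51$false_alarms, 1L)

  ## greedy equals exhaustive optimal assignment on a crossing toy set
  refs3 <- c(1.00, 1.06)
  dets3 <- c(1.04, 1.07)
  sc3 <- evaluate_detections(dets3, refs3)
  expect_equal(sc3$hits, 2L)

  sc0 <- evaluate_detections(numeric(0), refs)
  expect_equal(sc0$hit_rate, 0)
  expect_equal(sc0$false_alarm_rate, 0)
  expect_equal(sc0$flag, "no detections")
})
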