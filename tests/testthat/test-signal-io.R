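test_that("binary recording round-trip preserves samples to float32 precision", {
  x <- matrix(seq(-100, 100, length.out = 5 * 10000), nrow = 5)
  rec <- recording(x, 1000)
  path <- file.path(tempdir(), "roundtrip")
  write_recording(rec, path)
  back <- read_recording(path)
  rng <- diff(range(x))
  expect_lt(max(abs(back$samples - x)), 1e-6 * rng)
  expect_equal(back$sample_rate_hz, 1000)
  expect_equal(dim(back$samples), c(5L, 10000L))
})

test_that("malformed recordings are rejected", {
  expect_error(recording(matrix(c(1, NaN), 1), 1000), "NaN")
  expect_error(recording(matrix(1:10, 2), 0), "positive")

  ## header with per-channel sample rates that differ
  path <- file.path(tempdir(), "mixedfs")
  writeBin(rep(0, 20), paste0(path, ".bin"), size = 4L)
  jsonlite::write_json(list(dtype = "float32le", n_channels = 2, n_samples = 10,
                            sample_rate_hz = c(1000, 500),
                            channel_labels = c("a", "b"),
                            start_time = "2024-01-01T00:00:00"),
                       paste0(path, ".json"), auto_unbox = TRUE)
  expect_error(read_recording(path), "different sample rates")

  ## truncated payload
  path2 <- file.path(tempdir(), "trunc")
  rec <- recording(matrix(rnorm(300), 3), 1000)
  write_recording(rec, path2)
  con <- file(paste0(path2, ".bin"), "wb")
  writeBin(rep(0, 10), con, size = 4L)
  close(con)
  expect_error(read_recording(path2), "truncated")
})

test_that("declared binary header shape drives the loaded matrix", {
  path <- file.path(tempdir(), "shape")
  n <- 123
  rec <- recording(matrix(rnorm(3 * n), 3), 1000)
  write_recording(rec, path)
  back <- read_recording(path)
  expect_equal(dim(back$samples), c(3L, n))
})

test_that("stage_at applies the strict majority rule on half-open intervals", {
  hyp <- data.frame(onset_s = c(0, 100, 200), offset_s = c(100, 200, 300),
                    stage = c("S2", "S3", "REM"))
  expect_equal(stage_at(hyp, 10, 20), "S2")
  ## exact 50/50 split: 50% is not > 50%
  expect_true(is.na(stage_at(hyp, 95, 105)))
  ## 6 s in S3, 4 s in S2
  expect_equal(stage_at(hyp, 96, 106), "S3")
  ## half-open: a window starting exactly at a boundary belongs to the
  ## next interval entirely
  expect_equal(stage_at(hyp, 100, 110), "S3")
  ## invariance to splitting a stage interval into same-label pieces
  hyp2 <- data.frame(onset_s = c(0, 50, 100, 200), offset_s = c(50, 100, 200, 300),
                     stage = c("S2", "S2", "S3", "REM"))
  w_on <- c(10, 40, 95, 96, 150)
  w_off <- w_on + 10
  expect_equal(stage_at(hyp, w_on, w_off), stage_at(hyp2, w_on, w_off))
  expect_error(stage_at(hyp, 20, 10), "malformed")
})

test_that("stage lookups at points follow half-open conventions", {
  hyp <- data.frame(onset_s = c(0, 100), offset_s = c(100, 200),
                    stage = c("S2", "S3"))
  expect_equal(stage_of_time(hyp, c(0, 99.999, 100, 199.999, 200)),
               c("S2", "S2", "S3", "S3", NA))
})

test_that("exclude_overlaps drops exactly the intersecting items", {
  w <- data.frame(onset_s = seq(0, 90, 10), offset_s = seq(10, 100, 10))
  expect_equal(nrow(exclude_overlaps(w, NULL)), 10)
  expect_equal(attr(exclude_overlaps(w, NULL), "n_dropped"), 0L)

  all_cover <- data.frame(onset_s = 0, offset_s = 100)
  expect_equal(nrow(exclude_overlaps(w, all_cover)), 0)

  art <- data.frame(onset_s = c(5, 35, 98), offset_s = c(6, 36, 99))
  out <- exclude_overlaps(w, art)
  expect_equal(nrow(out), 7)
  expect_equal(attr(out, "n_dropped"), 3L)

  ## randomized agreement with a naive pairwise oracle
  withr::with_seed(4, {
    for (rep in 1:20) {
      on <- sort(runif(15, 0, 100))
      wnd <- data.frame(onset_s = on, offset_s = on + runif(15, 0.5, 5))
      ia <- sort(runif(4, 0, 100))
      art <- data.frame(onset_s = ia, offset_s = ia + runif(4, 0.1, 8))
      keep_oracle <- sapply(seq_len(nrow(wnd)), function(i) {
        !any(wnd$onset_s[i] < art$offset_s & art$onset_s < wnd$offset_s[i])
      })
      expect_equal(exclude_overlaps(wnd, art)$onset_s, wnd$onset_s[keep_oracle])
    }
  })

  ## point events: half-open membership
  ev <- data.frame(time_s = c(1, 5, 6, 7))
  out <- exclude_overlaps(ev, data.frame(onset_s = 5, offset_s = 7))
  expect_equal(out$time_s, c(1, 7))
})

test_that("hypnogram, event and spike-train files round-trip", {
  hyp <- data.frame(onset_s = c(0, 100), offset_s = c(100, 250),
                    stage = c("Pre", "S2"))
  f <- tempfile(fileext = ".tsv")
  write_hypnogram(hyp, f)
  expect_equal(read_hypnogram(f), hyp)

  ev <- data.frame(time_s = c(1.5, 2.25), label = "ied",
                   template_id = c(1L, 2L), stage = c("Pre", "S2"))
  fe <- tempfile(fileext = ".tsv")
  write_events(ev, fe)
  expect_equal(read_events(fe), ev)

  trains <- list(u1 = list(unit_id = "u1", quality = "SUA",
                           spike_times_s = c(0.1, 0.5, 1.25),
                           amplitude = c(40, 42, 39)))
  fs <- tempfile(fileext = ".json")
  write_spike_trains(trains, fs)
  back <- read_spike_trains(fs)
  expect_equal(back$u1$spike_times_s, trains$u1$spike_times_s)
  expect_equal(back$u1$quality, "SUA")
  expect_error(write_spike_trains(list(list(unit_id = "x",
                                            spike_times_s = c(2, 1))), fs),
               "strictly increasing")
})

test_that("refractory violation fraction counts sub-millisecond intervals", {
  expect_equal(rpv_fraction(c(0, 0.0005, 0.1, 0.2)), 1 / 3)
  expect_true(is.na(rpv_fraction(1)))
})
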