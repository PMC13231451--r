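test_that("PSTH binning is half-open with rates in Hz", {
  p0 <- compute_psth(numeric(0), c(10, 20, 30))
  expect_true(all(p0$rates == 0))
  expect_equal(dim(p0$rates), c(3L, 150L))
  expect_equal(p0$flag, "zero baseline rate")
  expect_true(all(is.na(p0$norm_rate)))

  ## a spike exactly at the event time lands in the [0, 10) ms bin
  p1 <- compute_psth(10, 10)
  hit_bin <- which(p1$rates[1, ] > 0)
  expect_equal(p1$bin_edges[hit_bin], 0)
  expect_equal(p1$rates[1, hit_bin], 100)  # 1 spike / 10 ms

  expect_error(compute_psth(1, 1, window = c(-0.5, 1), bin_s = 0.007), "divide")
})

test_that("a homogeneous Poisson train yields a flat PSTH with unit-normalized baseline", {
  events <- seq(10, by = 2, length.out = 2000)
  spikes <- withr::with_seed(21, {
    n <- rpois(1, 10 * 4020)
    sort(runif(n, 0, 4020))
  })
  p <- compute_psth(spikes, events)
  se <- sqrt(10 / (0.01 * 2000))
  expect_lt(max(abs(p$mean_rate - 10)), 3 * se)
  ## normalized baseline mean is exactly 1
  expect_equal(mean(p$norm_rate[p$baseline_bins]), 1, tolerance = 1e-12)
})

test_that("cluster permutation test flags synthetic modulation where it occurs", {
  cfg <- sim_config(duration_s = 1200, pre_s = 1200, post_s = 0, g_spike = 3,
                    g_wave = 0.3, burst_prob = 0, n_units = 1,
                    unit_baseline_hz = 8, seed = 41)
  hyp <- generate_hypnogram(cfg)
  gt <- data.frame(time_s = seq(20, 1180, by = 2))
  expect_gte(nrow(gt), 500)
  tr <- generate_spike_trains(cfg, gt, hyp)[[1]]
  p <- compute_psth(tr$spike_times_s, gt$time_s)
  ct <- cluster_permutation_test(p, n_perm = 1000, seed = 2)
  expect_true(ct$responsive)
  pos <- ct$clusters[ct$clusters$sign > 0 & ct$clusters$p < 0.05, ]
  expect_gt(nrow(pos), 0)
  ## a significant positive cluster overlaps the generator's gain window [0, 50] ms
  centers <- p$bin_centers
  overlaps <- any(vapply(seq_len(nrow(pos)), function(i) {
    span <- centers[pos$bin_lo[i]:pos$bin_hi[i]]
    any(span >= 0 & span <= 0.05)
  }, TRUE))
  expect_true(overlaps)
  ## suppression during the slow wave shows as a negative cluster
  neg <- ct$clusters[ct$clusters$sign < 0 & ct$clusters$p < 0.05, ]
  expect_gt(nrow(neg), 0)
})

test_that("permutation p-values are deterministic given a seed", {
  withr::with_seed(5, {
    rates <- matrix(rpois(30 * 150, 5), 30, 150) / 0.01
  })
  p <- structure(list(rates = rates, bin_edges = seq(-0.5, 1, 0.01),
                      bin_centers = seq(-0.495, 0.995, 0.01), bin_s = 0.01,
                      window = c(-0.5, 1), baseline_window = c(-0.3, -0.1),
                      baseline_bins = 21:40,
                      baseline_per_event = rowMeans(rates[, 21:40]),
                      baseline_mean = mean(rates[, 21:40]),
                      mean_rate = colMeans(rates),
                      norm_rate = colMeans(rates) / mean(rates[, 21:40]),
                      n_events = 30), class = "ied_psth")
  a <- cluster_permutation_test(p, n_perm = 10, seed = 7)
  b <- cluster_permutation_test(p, n_perm = 10, seed = 7)
  expect_identical(a$clusters, b$clusters)

  ## degenerate input: no variance anywhere -> skipped, non-responsive
  pz <- p
  pz$rates <- matrix(5, 30, 150) / 0.01
  pz$baseline_per_event <- rowMeans(pz$rates[, 21:40])
  ctz <- cluster_permutation_test(pz, n_perm = 10, seed = 1)
  expect_true(ctz$skipped)
  expect_false(ctz$responsive)

  p5 <- p
  p5$n_events <- 5
  expect_error(cluster_permutation_test(p5), ">= 10 events")
})

test_that("half-prominence intervals bracket the PSTH extrema", {
  rate <- c(rep(10, 50), 10 + 10 * sin(seq(0, pi, length.out = 11))[2:10],
            rep(10, 41))
  p <- structure(list(mean_rate = rate, baseline_mean = 10,
                      bin_centers = seq_len(100) / 100), class = "ied_psth")
  hp <- half_prominence_intervals(p)
  ## brute-force oracle: bins above baseline + prominence / 2 around the max
  prom <- max(rate) - 10
  above <- which(rate >= 10 + prom / 2)
  i_max <- which.max(rate)
  run <- above[cumsum(c(1, diff(above) > 1)) ==
               cumsum(c(1, diff(above) > 1))[match(i_max, above)]]
  expect_equal(hp$peak_interval$bins, run)
  ## unimodal peak of 2x baseline: the interval is where the rate clears
  ## baseline plus half the prominence
  expect_true(all(rate[hp$peak_interval$bins] >= 15))
  expect_match(half_prominence_intervals(rep(4, 50), baseline_level = 4)$flags,
               "flat")
})

test_that("per-stage PSTH measures track stage-dependent firing", {
  cfg <- sim_config(duration_s = 3000, pre_s = 600, post_s = 300,
                    ied_base_rate_per_min = 6, artefact_rate_per_hour = 0,
                    n_units = 1, unit_baseline_hz = 8, seed = 51)
  ses <- simulate_session(cfg)
  tr <- ses$spike_trains[[1]]
  gt <- ses$ground_truth
  p_all <- compute_psth(tr$spike_times_s, gt$time_s)
  hp <- half_prominence_intervals(p_all)
  tbl <- psth_stage_measures(tr$spike_times_s, gt$time_s, gt$stage, hp,
                             ids = data.frame(unit = "u1"))
  expect_true(all(c("rate_spike", "rate_wave", "norm_difference") %in% names(tbl)))
  expect_gt(nrow(tbl), 1)
  ## firing gain during the spike exceeds the slow-wave rate in every stage
  expect_true(all(tbl$rate_spike > tbl$rate_wave))
})
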