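# Shared fixtures, built in code at test time.

# Small fast session: single morphology, no artefacts.
small_session <- function(seed = 3, duration_s = 600, n_templates = 1,
                          rate = 10) {
  simulate_session(sim_config(duration_s = duration_s, pre_s = 120, post_s = 60,
                              ied_base_rate_per_min = rate,
                              n_templates = n_templates,
                              artefact_rate_per_hour = 0, seed = seed))
}

# Epochs built directly from a kernel plus white noise (n trials, 1 channel).
kernel_epochs <- function(kernel_row, n, noise_sd, fs = 1000, seed = 1,
                          window = c(-0.5, 1.0)) {
  nt <- round((window[2] - window[1]) * fs)
  stopifnot(length(kernel_row) <= nt)
  base <- numeric(nt)
  i0 <- round(0.2 * fs)
  base[i0 + seq_along(kernel_row)] <- kernel_row
  trials <- withr::with_seed(seed, {
    a <- array(0, c(n, 1, nt))
    for (i in seq_len(n)) a[i, 1, ] <- base + rnorm(nt, sd = noise_sd)
    a
  })
  structure(list(trials = trials, times_s = seq_len(n), lags_s = numeric(n),
                 window = window, sample_rate_hz = fs, channels = 1L),
            class = "ied_epochs")
}

# Balanced synthetic stage table with random patient intercepts.
make_stage_table <- function(effects = c(Pre = 0, S1 = 1, S3 = 2),
                             n_patients = 8, n_obs = 20, sd_patient = 1,
                             sd_noise = 1, seed = 1) {
  withr::with_seed(seed, {
    u <- rnorm(n_patients, 0, sd_patient)
    rows <- expand.grid(patient = seq_len(n_patients),
                        stage = names(effects), obs = seq_len(n_obs),
                        stringsAsFactors = FALSE)
    rows$y <- effects[rows$stage] + u[rows$patient] + rnorm(nrow(rows), 0, sd_noise)
    rows
  })
}

# Adjusted Rand index between two labelings (independent implementation).
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  exp_ <- si * sj / n2
  (sij - exp_) / ((si + sj) / 2 - exp_)
}
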