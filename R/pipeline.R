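#' Configuration of an end-to-end pipeline run
#'
#' Bundles the simulator configuration with all detector and analysis
#' parameters and the stage toggles. Every random operation downstream
#' receives an explicit seed derived from `sim$seed`, so a rerun with the
#' same configuration reproduces all tabular outputs bit-identically.
#'
#' @param sim a [sim_config()] describing the synthetic session (or the
#'   session to analyse).
#' @param stages pipeline stages to run, in dependency order; a subset of
#'   `c("simulate", "detect", "timelocked", "windows", "circadian",
#'   "stats")`.
#' @param k,min_frac,threshold_z,tol_s detector parameters.
#' @param n_perm permutations for the responsiveness test.
#' @param psth_window,psth_bin_s,psth_baseline PSTH parameters.
#' @param write_recording also write the raw signal to disk (off by
#'   default; the binary is large).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(duration_s = 600, pre_s = 120,
                                             post_s = 60,
                                             ied_base_rate_per_min = 12,
                                             artefact_rate_per_hour = 0),
                            stages = c("simulate", "detect", "timelocked",
                                       "windows", "circadian", "stats"),
                            k = 6, min_frac = 0.025, threshold_z = 6,
                            tol_s = 0.05, n_perm = 1000,
                            psth_window = c(-0.5, 1.0), psth_bin_s = 0.01,
                            psth_baseline = c(-0.3, -0.1),
                            write_recording = FALSE) {
  structure(list(sim = sim, stages = stages, k = k, min_frac = min_frac,
                 threshold_z = threshold_z, tol_s = tol_s, n_perm = n_perm,
                 psth_window = psth_window, psth_bin_s = psth_bin_s,
                 psth_baseline = psth_baseline,
                 write_recording = write_recording),
            class = "pipeline_config")
}

#' Run the analysis pipeline end to end
#'
#' Executes the enabled stages in dependency order on a seeded synthetic
#' session -- simulate, detect (templates from the first-half
#' annotations), time-locked LFP/PSTH analyses, 10 s window metrics,
#' circadian statistics, and stage-wise mixed-model contrasts -- writing
#' tidy TSV outputs and a JSON manifest (parameters, seeds, row counts,
#' file hashes) to `out_dir`. A stage whose upstream output is disabled
#' fails with a dependency error.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- config$stages
  manifest <- list(package = "iedsleep",
                   version = as.character(packageVersion("iedsleep")),
                   seed = config$sim$seed, stages = stages,
                   parameters = list(k = config$k, min_frac = config$min_frac,
                                     threshold_z = config$threshold_z,
                                     tol_s = config$tol_s, n_perm = config$n_perm),
                   outputs = list())
  outfile <- function(name) file.path(out_dir, name)
  need <- function(stage, what) {
    if (!stage %in% stages)
      stop(sprintf("dependency error: stage '%s' needs '%s' output", what, stage))
  }

  ses <- NULL
  if ("simulate" %in% stages) {
    ses <- simulate_session(config$sim)
    write_hypnogram(ses$hypnogram, outfile("hypnogram.tsv"))
    gt <- ses$ground_truth
    gt$label <- "ied"
    write_events(gt, outfile("ground_truth.tsv"))
    write_spike_trains(ses$spike_trains, outfile("spike_trains.json"))
    if (nrow(ses$artefacts))
      write.table(ses$artefacts, outfile("artefacts.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    if (config$write_recording)
      write_recording(ses$recording, outfile("recording"))
  }

  det <- NULL
  if ("detect" %in% stages) {
    need("simulate", "detect")
    half <- recording_duration(ses$recording) / 2
    ann <- ses$ground_truth$time_s[ses$ground_truth$time_s < half]
    det <- detect_ieds(ses$recording, ann, k = config$k,
                       min_frac = config$min_frac,
                       threshold_z = config$threshold_z,
                       dedup_tol_s = config$tol_s)
    det$detections$label <- "ied"
    write_events(det$detections, outfile("detections.tsv"))
    score <- evaluate_detections(det$detections$time_s,
                                 ses$ground_truth$time_s, config$tol_s)
    jsonlite::write_json(score[c("n_ref", "n_det", "hits", "misses",
                                 "false_alarms", "hit_rate", "false_alarm_rate")],
                         outfile("detection_score.json"), auto_unbox = TRUE,
                         digits = NA)
  }

  tl <- NULL
  if ("timelocked" %in% stages) {
    need("detect", "timelocked")
    ep <- extract_epochs(ses$recording, det$detections$time_s)
    avg <- average_lfp(ep)
    iv <- find_component_intervals(avg)
    stg <- stage_of_time(ses$hypnogram, ep$times_s)
    lfp_tbl <- stage_component_measures(ep, stg, iv,
                                        ids = data.frame(patient = "sim01"))
    tid <- det$detections$template_id[match(ep$times_s, det$detections$time_s)]
    lfp_tbl$template <- tid[!is.na(stg)]
    write.table(lfp_tbl, outfile("lfp_measures.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    unit_rows <- list()
    resp_rows <- list()
    for (u in names(ses$spike_trains)) {
      tr <- ses$spike_trains[[u]]
      p <- compute_psth(tr$spike_times_s, ep$times_s, config$psth_window,
                        config$psth_bin_s, config$psth_baseline)
      ct <- cluster_permutation_test(p, n_perm = config$n_perm,
                                     seed = config$sim$seed + 10L)
      resp_rows[[u]] <- data.frame(unit = u, quality = tr$quality,
                                   responsive = ct$responsive,
                                   n_clusters = nrow(ct$clusters))
      hp <- half_prominence_intervals(p)
      if (!is.null(hp$peak_interval) && !is.null(hp$trough_interval)) {
        unit_rows[[u]] <- psth_stage_measures(
          tr$spike_times_s, ep$times_s, stg, hp,
          window = config$psth_window, bin_s = config$psth_bin_s,
          baseline = config$psth_baseline,
          ids = data.frame(unit = u, patient = "sim01"))
      }
    }
    tl <- list(responsiveness = do.call(rbind, resp_rows),
               unit_measures = do.call(rbind, unit_rows))
    write.table(tl$responsiveness, outfile("responsiveness.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (!is.null(tl$unit_measures))
      write.table(tl$unit_measures, outfile("unit_measures.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
  }

  win_lfp <- win_units <- NULL
  if ("windows" %in% stages) {
    need("simulate", "windows")
    ied_times <- if (!is.null(det)) det$detections$time_s else ses$ground_truth$time_s
    w <- segment_windows(ses$recording, ses$hypnogram, ses$artefacts,
                         ied_times, mode = "baseline")
    win_lfp <- window_power_table(ses$recording, w, channels = 1)
    win_units <- unit_window_table(ses$spike_trains, w)
    write.table(win_lfp, outfile("windows_lfp.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(win_units, outfile("windows_units.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  if ("circadian" %in% stages) {
    need("detect", "circadian")
    ang <- phase_of_day(det$detections$time_s, ses$recording$start_time)
    rt <- rayleigh_test(ang)
    jsonlite::write_json(rt, outfile("circadian.json"), auto_unbox = TRUE,
                         digits = NA)
  }

  if ("stats" %in% stages) {
    need("timelocked", "stats")
    lfp_tbl <- read.delim(outfile("lfp_measures.tsv"))
    ctr <- tryCatch({
      fit <- fit_stage_model(lfp_tbl, "deflection", random = "template",
                             reference = "Pre")
      posthoc_contrasts(fit)$vs_reference
    }, error = function(e) {
      message("stage model skipped: ", conditionMessage(e))
      NULL
    })
    if (!is.null(ctr))
      write.table(ctr, outfile("contrasts.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
  }

  files <- list.files(out_dir, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest$outputs <- lapply(setNames(files, basename(files)), function(f) {
    list(md5 = unname(tools::md5sum(f)), bytes = unname(file.info(f)$size))
  })
  jsonlite::write_json(manifest, outfile("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Summarize a pipeline run as a markdown report
#'
#' Reads the manifest and tabular outputs of a [run_pipeline()] directory
#' and writes `report.md` with the sections available for that run
#' (detection benchmark, stage-wise IED rates and amplitudes, unit
#' responsiveness, window metrics, circadian statistics, contrasts).
#' Partial runs produce partial reports; regeneration is idempotent.
#'
#' @param run_dir directory written by [run_pipeline()].
#' @return Path of the report, invisibly.
#' @export
make_report <- function(run_dir) {
  mf <- file.path(run_dir, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json: not a pipeline run directory")
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  lines <- c("# iedsleep run report", "",
             sprintf("Seed %s; stages: %s.", manifest$seed,
                     paste(manifest$stages, collapse = ", ")), "")
  f <- function(name) file.path(run_dir, name)
  if (file.exists(f("detection_score.json"))) {
    sc <- jsonlite::read_json(f("detection_score.json"), simplifyVector = TRUE)
    lines <- c(lines, "## IED detection", "",
               sprintf("- references: %d, detections: %d", sc$n_ref, sc$n_det),
               sprintf("- hit rate: %.1f%%, false-alarm rate: %.1f%%",
                       100 * sc$hit_rate, 100 * sc$false_alarm_rate), "")
  }
  if (file.exists(f("lfp_measures.tsv"))) {
    x <- read.delim(f("lfp_measures.tsv"))
    s <- aggregate(cbind(V_peak, deflection) ~ stage, x, mean)
    lines <- c(lines, "## IED amplitude by stage", "",
               "| stage | V_peak (uV) | deflection (uV) |", "|---|---|---|",
               sprintf("| %s | %.1f | %.1f |", s$stage, s$V_peak, s$deflection), "")
  }
  if (file.exists(f("responsiveness.tsv"))) {
    x <- read.delim(f("responsiveness.tsv"))
    lines <- c(lines, "## Unit responsiveness", "",
               sprintf("- %d / %d units responsive to IEDs",
                       sum(x$responsive), nrow(x)), "")
  }
  if (file.exists(f("windows_units.tsv"))) {
    x <- read.delim(f("windows_units.tsv"))
    s <- aggregate(firing_rate ~ stage, x, mean)
    lines <- c(lines, "## Background firing by stage", "",
               "| stage | rate (Hz) |", "|---|---|",
               sprintf("| %s | %.2f |", s$stage, s$firing_rate), "")
  }
  if (file.exists(f("circadian.json"))) {
    rt <- jsonlite::read_json(f("circadian.json"), simplifyVector = TRUE)
    lines <- c(lines, "## Circadian phase of IEDs", "",
               sprintf("- Rayleigh Rbar = %.3f, p = %.3g; mean phase = %.1f h",
                       rt$Rbar, rt$p, rt$mean_angle / (2 * pi) * 24), "")
  }
  if (file.exists(f("contrasts.tsv"))) {
    x <- read.delim(f("contrasts.tsv"))
    lines <- c(lines, "## Stage contrasts vs pre-sleep (deflection)", "",
               "| stage | estimate | p (Tukey) | |", "|---|---|---|---|",
               sprintf("| %s | %.2f | %.2g | %s |", x$stage, x$estimate,
                       x$p_adj, x$stars), "")
  }
  out <- f("report.md")
  writeLines(lines, out)
  invisible(out)
}
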