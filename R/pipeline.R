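# Disk-driven pipeline: each stage reads its inputs from the output
# directory of the previous stage, so stages are independently runnable
# from the command line and intermediates are inspectable.

.log_line <- function(out_dir, ...) {
  msg <- sprintf(...)
  cat(msg, "\n", sep = "", file = stderr())
  cat(msg, "\n", sep = "", file = file.path(out_dir, "log.txt"),
      append = TRUE)
}

.subject_paths <- function(out_dir, sub = "epochs") {
  dir <- file.path(out_dir, sub)
  sort(list.files(dir, pattern = "\\.epo$", full.names = TRUE))
}

#' Pipeline stage: simulate
#'
#' Generates the configured synthetic dataset, writing one epochs
#' container per subject plus the ground-truth ledger
#' (\code{ledger.json}) and the effective configuration with its hash.
#'
#' @param cfg a \code{run_config}
#' @param out_dir output directory (created if needed)
#' @return invisibly, the simulated dataset
#' @export
stage_simulate <- function(cfg, out_dir) {
  validate_config(cfg)
  dir.create(file.path(out_dir, "epochs"), recursive = TRUE,
             showWarnings = FALSE)
  # drop stale containers from any previous run so downstream stages
  # never mix subjects across configurations
  unlink(c(.subject_paths(out_dir, "epochs"),
           .subject_paths(out_dir, "epochs_clean")))
  hash <- config_hash(cfg)
  write_config(cfg, file.path(out_dir, "config.json"))
  ds <- simulate_dataset(sim_config_from_run(cfg))
  for (s in seq_along(ds$subjects))
    write_epochs(ds$subjects[[s]],
                 file.path(out_dir, "epochs", sprintf("subj%02d.epo", s)),
                 provenance = list(config_hash = hash, seed = cfg$seed,
                                   subject = s))
  ledger <- lapply(ds$ledger, function(entry) {
    eff <- entry$effect
    c(list(subject = entry$subject, trials = entry$trials),
      eff[!vapply(eff, is.null, logical(1))])
  })
  writeLines(jsonlite::toJSON(list(config_hash = hash, effects = ledger),
                              auto_unbox = TRUE, digits = NA, pretty = TRUE,
                              null = "null"),
             file.path(out_dir, "ledger.json"))
  .log_line(out_dir, "[simulate] %d subjects, %d trials each, seed %d, config %s",
            length(ds$subjects), n_trials(ds$subjects[[1]]), cfg$seed, hash)
  invisible(ds)
}

#' Pipeline stage: preprocess
#'
#' Applies frontal amplitude rejection (and, when enabled, infomax ICA
#' with heuristic component removal) to every subject container under
#' \code{epochs/}, writing cleaned containers to \code{epochs_clean/}.
#' The synthetic data are generated band-limited and epoched, so the
#' continuous-recording steps (detrend, re-reference, filter, segment)
#' apply when raw recordings are the input; see
#' \code{\link{detrend_and_reference}}, \code{\link{bandpass_zero_phase}}
#' and \code{\link{segment}}.
#'
#' @inheritParams stage_simulate
#' @export
stage_preprocess <- function(cfg, out_dir) {
  validate_config(cfg)
  paths <- .subject_paths(out_dir, "epochs")
  if (!length(paths)) stop_data("no epochs containers under %s", out_dir)
  dir.create(file.path(out_dir, "epochs_clean"), showWarnings = FALSE)
  montage <- make_montage(cfg$montage)
  hash <- config_hash(cfg)
  for (p in paths) {
    ep <- read_epochs(p)
    ep <- reject_amplitude(ep, cfg$preprocess$reject$channel_group,
                           cfg$preprocess$reject$threshold_uv,
                           montage = montage,
                           method = cfg$preprocess$reject$method)
    n_flagged <- 0L
    if (isTRUE(cfg$preprocess$ica$enabled)) {
      model <- ica_fit(ep, maxit = cfg$preprocess$ica$maxit,
                       seed = derive_seed(cfg$seed, paste0("ica/", p)))
      model <- ica_flag(model, ep, montage)
      n_flagged <- sum(model$component_flags$flag)
      ep <- ica_remove(model, ep)
    }
    write_epochs(ep, file.path(out_dir, "epochs_clean", basename(p)),
                 provenance = list(config_hash = hash, seed = cfg$seed))
    .log_line(out_dir, "[preprocess] %s: %d/%d trials kept, %d ICA component(s) removed",
              basename(p), sum(ep$kept_mask), n_trials(ep), n_flagged)
  }
  invisible(NULL)
}

#' Pipeline stage: ERSP
#'
#' Per subject and condition, decomposes the kept trials, normalizes to
#' the rest baseline, summarises per band and adaptation window, and
#' writes the long-format table \code{tables/band_window.tsv}.
#'
#' @inheritParams stage_simulate
#' @export
stage_ersp <- function(cfg, out_dir) {
  validate_config(cfg)
  paths <- .subject_paths(out_dir, "epochs_clean")
  if (!length(paths)) paths <- .subject_paths(out_dir, "epochs")
  if (!length(paths)) stop_data("no epochs containers under %s", out_dir)
  dir.create(file.path(out_dir, "tables"), showWarnings = FALSE)
  summaries <- list()
  for (s in seq_along(paths)) {
    ep <- epochs_kept(read_epochs(paths[s]))
    per_cond <- list()
    for (cond in unique(ep$condition)) {
      sub <- epochs_subset(ep, ep$condition == cond)
      tfp <- tf_decompose(sub, freq_range = cfg$ersp$freq_range,
                          time_step_ms = cfg$ersp$time_step_ms,
                          keep_trials = FALSE)
      emap <- ersp_map(tfp, baseline_window = cfg$ersp$baseline_window)
      per_cond[[cond]] <- band_window_summary(
        emap, adaptation_onset_ms = cfg$ersp$adaptation_onset_ms)
    }
    summaries[[s]] <- per_cond
  }
  export_band_window_tsv(summaries,
                         file.path(out_dir, "tables", "band_window.tsv"))
  .log_line(out_dir, "[ersp] wrote band_window.tsv for %d subject(s)",
            length(paths))
  invisible(summaries)
}

#' Pipeline stage: connectivity
#'
#' Per subject, computes the seed-based ER-ciCOH maps per condition and
#' writes \code{tables/er_cicoh.tsv}.
#'
#' @inheritParams stage_simulate
#' @export
stage_connect <- function(cfg, out_dir) {
  validate_config(cfg)
  paths <- .subject_paths(out_dir, "epochs_clean")
  if (!length(paths)) paths <- .subject_paths(out_dir, "epochs")
  if (!length(paths)) stop_data("no epochs containers under %s", out_dir)
  dir.create(file.path(out_dir, "tables"), showWarnings = FALSE)
  cc <- cfg$connectivity
  mtc <- multitaper_config(cc$window_ms, cc$step_ms, cc$bandwidth_param)
  maps <- lapply(paths, function(p) {
    er_cicoh(read_epochs(p), seeds = cc$seeds, config = mtc,
             toi_window = cc$toi_window,
             baseline_window = cc$baseline_window, eps = cc$eps,
             fisher_before_contrast = isTRUE(cc$fisher_before_contrast))
  })
  export_er_cicoh_tsv(maps, file.path(out_dir, "tables", "er_cicoh.tsv"))
  .log_line(out_dir, "[connect] wrote er_cicoh.tsv for %d subject(s)",
            length(paths))
  invisible(maps)
}

# subject x electrode matrix from a long table for one condition/cell
.table_matrix <- function(df, cond, value_col, electrode_col, subset) {
  d <- df[df$condition == cond & subset, , drop = FALSE]
  stats::xtabs(stats::reformulate(c("subject", electrode_col),
                                  response = value_col), data = d)
}

#' Pipeline stage: cluster statistics
#'
#' Reads the band-by-window ERSP table and the ER-ciCOH table, compares
#' the two conditions per cell with the cluster-based permutation test,
#' and writes \code{stats/clusters.tsv} plus a JSON summary.
#'
#' @inheritParams stage_simulate
#' @export
stage_stats <- function(cfg, out_dir) {
  validate_config(cfg)
  montage <- make_montage(cfg$montage)
  graph <- build_neighbors(montage,
                           threshold = cfg$stats$neighbor_threshold)
  conds <- cfg$simulate$conditions
  if (length(conds) != 2)
    stop_config("cluster statistics need exactly 2 conditions")
  dir.create(file.path(out_dir, "stats"), showWarnings = FALSE)
  rows <- list()
  run_one <- function(a, b, analysis, band, window, seed_tag) {
    # align electrode columns with the montage order
    labs <- intersect(montage$labels, colnames(a))
    res <- permutation_test(a[, labs, drop = FALSE],
                            b[, labs, drop = FALSE], list(
                              adjacency = graph$adjacency[labs, labs]),
                            n_perm = cfg$stats$n_perm,
                            seed = derive_seed(cfg$seed, seed_tag),
                            alpha_cluster = cfg$stats$alpha_cluster,
                            alpha = cfg$stats$alpha)
    for (i in seq_along(res$clusters)) {
      cl <- res$clusters[[i]]
      rows[[length(rows) + 1]] <<- data.frame(
        analysis = analysis, band = band, window = window, cluster_id = i,
        sign = cl$sign, electrodes = paste(labs[cl$electrodes],
                                           collapse = ","),
        mass = cl$mass, p_corrected = cl$p_corrected,
        significant = cl$significant)
    }
    res
  }
  bw_path <- file.path(out_dir, "tables", "band_window.tsv")
  if (file.exists(bw_path)) {
    bw <- utils::read.delim(bw_path)
    for (band in unique(bw$band))
      for (win in unique(bw$window)) {
        sel <- bw$band == band & bw$window == win
        a <- .table_matrix(bw, conds[1], "value_db", "channel", sel)
        b <- .table_matrix(bw, conds[2], "value_db", "channel", sel)
        run_one(a, b, "ersp", band, win,
                paste("stats/ersp", band, win, sep = "/"))
      }
  }
  er_path <- file.path(out_dir, "tables", "er_cicoh.tsv")
  if (file.exists(er_path)) {
    er <- utils::read.delim(er_path)
    er <- er[!is.na(er$value), , drop = FALSE]     # seed electrodes are NA
    for (band in unique(er$band)) {
      sel <- er$band == band
      a <- .table_matrix(er, conds[1], "value", "electrode", sel)
      b <- .table_matrix(er, conds[2], "value", "electrode", sel)
      run_one(a, b, "er_cicoh", band, "",
              paste("stats/ercicoh", band, sep = "/"))
    }
  }
  report <- if (length(rows)) do.call(rbind, rows) else
    data.frame(analysis = character(), band = character(),
               window = character(), cluster_id = integer(),
               sign = integer(), electrodes = character(),
               mass = numeric(), p_corrected = numeric(),
               significant = logical())
  utils::write.table(report, file.path(out_dir, "stats", "clusters.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  writeLines(jsonlite::toJSON(list(config_hash = config_hash(cfg),
                                   n_perm = cfg$stats$n_perm,
                                   clusters = report),
                              auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             file.path(out_dir, "stats", "clusters.json"))
  .log_line(out_dir, "[stats] %d cluster(s), %d significant",
            nrow(report), sum(report$significant))
  invisible(report)
}

#' Run the full pipeline
#'
#' simulate -> preprocess -> ersp + connectivity -> cluster statistics,
#' writing all intermediates, tables and cluster reports under
#' \code{out_dir}, with a log capturing seeds, trial counts,
#' rejected-trial counts and flagged ICA components per subject.
#'
#' @param cfg a \code{run_config}
#' @param out_dir output directory
#' @return the cluster report data.frame, invisibly
#' @export
run_pipeline <- function(cfg, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- list(simulate = stage_simulate, preprocess = stage_preprocess,
                 ersp = stage_ersp, connect = stage_connect,
                 stats = stage_stats)
  res <- NULL
  for (nm in names(stages)) {
    res <- tryCatch(stages[[nm]](cfg, out_dir), error = function(e) {
      stop_data("stage '%s' failed: %s", nm, conditionMessage(e))
    })
  }
  invisible(res)
}

#' Demo scenario configuration
#'
#' The end-to-end validation scenario: a -3 dB alpha and beta
#' desynchronization over a connected parieto-occipital electrode set and
#' a pi/2-lagged gamma-band coupling from the parieto-occipital seeds to
#' four frontal electrodes, both confined to the system-adaptation window
#' of the supportive condition, plus 250 uV blink-like artifacts on AFp1
#' in two trials. With the paired contrast supportive - impeding, the ERD
#' must surface as a negative significant ERSP cluster at the injected
#' electrodes and the coupling as positive ER-ciCOH clusters at the
#' targets.
#'
#' @param seed root seed
#' @param n_subjects,n_trials_per_condition scenario size
#' @return a \code{run_config}
#' @export
demo_config <- function(seed = 1L, n_subjects = 16,
                        n_trials_per_condition = 30) {
  cfg <- default_config(seed)
  cfg$simulate$n_subjects <- n_subjects
  cfg$simulate$n_trials_per_condition <- n_trials_per_condition
  po <- c("P3", "P4", "PPO1h", "PPO2h", "POO1", "POO2")
  cfg$simulate$effects <- list(
    effect_spec("power_modulation", channels = po, band = c(8, 14),
                window = c(1000, 2000), magnitude = -3,
                condition = "supportive"),
    effect_spec("power_modulation", channels = po, band = c(15, 35),
                window = c(1000, 2000), magnitude = -3,
                condition = "supportive"),
    effect_spec("lagged_coupling", source = "POO1",
                channels = c("AFp1", "AFp2", "F1", "F2"),
                band = c(35, 45), window = c(1000, 2000), magnitude = 0.8,
                phase_lag = pi / 2, condition = "supportive"),
    effect_spec("lagged_coupling", source = "POO2",
                channels = c("AFp1", "AFp2", "F1", "F2"),
                band = c(35, 45), window = c(1000, 2000), magnitude = 0.8,
                phase_lag = pi / 2, condition = "supportive"),
    effect_spec("amplitude_artifact", channels = "AFp1",
                window = c(-3500, -3100), magnitude = 250,
                trials = c(3, 7))
  )
  cfg
}
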