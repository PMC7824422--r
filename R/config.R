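#' Default run configuration
#'
#' Every parameter defaults to the analysis' stated value where one
#' exists: 0.5-48 Hz band-pass, 200 uV frontal rejection, alpha/beta/gamma
#' bands, 1000 ms multitaper windows with 100 ms step and 5 tapers, 1000
#' permutations at corrected p < 0.05.
#'
#' @param seed root seed; all stage randomness derives from it
#' @return nested list of class \code{run_config}
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    montage = "study32",
    simulate = list(
      fs = 250, n_subjects = 16, n_trials_per_condition = 30,
      conditions = c("supportive", "impeding"),
      epoch_ms = c(-4000, 2000),
      noise = list(beta = 1, sd = 10, white_sd = 1),
      effects = list()
    ),
    preprocess = list(
      f_lo = 0.5, f_hi = 48,
      reject = list(channel_group = "frontal", threshold_uv = 200,
                    method = "mean_dev"),
      ica = list(enabled = FALSE, maxit = 200)
    ),
    ersp = list(
      freq_range = c(1, 45),
      time_step_ms = 100 / 3,
      baseline_window = c(-4000, -2000),
      adaptation_onset_ms = 1000
    ),
    connectivity = list(
      seeds = c("POO1", "POO2"),
      window_ms = 1000, step_ms = 100, bandwidth_param = 3,
      toi_window = c(1000, 2000), baseline_window = c(-3000, -2000),
      eps = 1e-3, fisher_before_contrast = FALSE
    ),
    stats = list(
      n_perm = 1000, alpha = 0.05, alpha_cluster = 0.05,
      neighbor_threshold = NULL
    )
  ), class = "run_config")
}

#' Read a run configuration from a JSON file
#'
#' Values present in the file override the defaults; everything else keeps
#' its default. Unknown top-level sections are an error.
#'
#' @param path JSON file
#' @param seed overrides the file's seed when not NULL
#' @return a \code{run_config}
#' @export
read_config <- function(path, seed = NULL) {
  if (!file.exists(path)) stop_config("config file not found: %s", path)
  user <- jsonlite::fromJSON(paste(readLines(path, warn = FALSE),
                                   collapse = "\n"),
                             simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  cfg <- unclass(default_config())
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    stop_config("unknown config section(s): %s",
                paste(unknown, collapse = ", "))
  merge_lists <- function(base, over) {
    for (nm in names(over)) {
      if (is.list(base[[nm]]) && is.list(over[[nm]]) &&
          !is.null(names(base[[nm]])))
        base[[nm]] <- merge_lists(base[[nm]], over[[nm]])
      else base[[nm]] <- over[[nm]]
    }
    base
  }
  cfg <- merge_lists(cfg, user)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  structure(cfg, class = "run_config")
}

#' Build a simulation configuration from a run configuration
#'
#' @param cfg a \code{run_config}
#' @return a \code{\link{simulation_config}}
#' @export
sim_config_from_run <- function(cfg) {
  s <- cfg$simulate
  effects <- lapply(s$effects, function(e) {
    if (inherits(e, "effect_spec")) e else do.call(effect_spec, e)
  })
  simulation_config(fs = s$fs, n_subjects = s$n_subjects,
                    n_trials_per_condition = s$n_trials_per_condition,
                    conditions = s$conditions, epoch_ms = s$epoch_ms,
                    noise = s$noise, effects = effects,
                    montage = cfg$montage,
                    seed = derive_seed(cfg$seed, "synth"))
}

#' Validate a run configuration
#'
#' @param cfg a \code{run_config}
#' @return invisibly, \code{cfg}; errors of class
#'   \code{erspconn_config_error} otherwise
#' @export
validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  p <- cfg$preprocess
  if (!(p$f_lo > 0 && p$f_lo < p$f_hi && p$f_hi < cfg$simulate$fs / 2))
    stop_config("band-pass corners invalid: %g-%g Hz at fs %g",
                p$f_lo, p$f_hi, cfg$simulate$fs)
  if (p$reject$threshold_uv <= 0)
    stop_config("rejection threshold must be positive")
  if (cfg$stats$n_perm < 1)
    stop_config("n_perm must be >= 1 (got %s, refusing to run the stats stage)",
                cfg$stats$n_perm)
  if (cfg$connectivity$bandwidth_param < 1)
    stop_config("bandwidth_param must be >= 1")
  invisible(cfg)
}


# strip S3 classes recursively so jsonlite can serialize a config
.config_plain <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    lapply(x, .config_plain)
  } else x
}

#' Hash of a configuration
#'
#' MD5 of the canonical (sorted-key) JSON serialization. Embedded in every
#' output file so that re-running with any changed parameter changes the
#' hash.
#'
#' @param cfg a \code{run_config}
#' @return 32-character hex string
#' @export
config_hash <- function(cfg) {
  js <- jsonlite::toJSON(.config_plain(cfg), auto_unbox = TRUE,
                         digits = NA, null = "null", force = TRUE)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(js, tmp)
  unname(tools::md5sum(tmp))
}

#' Write a configuration to JSON
#' @param cfg a \code{run_config}
#' @param path output path
#' @export
write_config <- function(cfg, path) {
  writeLines(jsonlite::toJSON(.config_plain(cfg), auto_unbox = TRUE,
                              digits = NA, pretty = TRUE, null = "null"),
             path)
  invisible(path)
}
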