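#' Construct an epoched EEG set
#'
#' The unit of data every analysis stage consumes and produces: a
#' trials x channels x samples array in microvolts, with a uniform time
#' axis in milliseconds (0 = replay onset), per-trial condition labels and
#' a kept/rejected mask.
#'
#' @param data numeric array, trials x channels x samples (microvolts)
#' @param fs sampling rate in Hz
#' @param labels channel labels (length = dim(data)[2])
#' @param time_ms per-sample time axis; default builds \code{t0 + k/fs}
#' @param t0_ms time of the first sample, used when \code{time_ms} is NULL
#' @param condition per-trial condition labels
#' @param kept_mask per-trial logical, default all TRUE
#' @return object of class \code{eeg_epochs}
#' @export
eeg_epochs <- function(data, fs, labels,
                       time_ms = NULL, t0_ms = -4000,
                       condition = NULL, kept_mask = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3, fs > 0)
  n_trials <- dim(data)[1]; n_chan <- dim(data)[2]; n_samp <- dim(data)[3]
  if (length(labels) != n_chan)
    stop_data("labels length (%d) != channel dim (%d)", length(labels), n_chan)
  if (is.null(time_ms))
    time_ms <- t0_ms + (seq_len(n_samp) - 1) * 1000 / fs
  if (length(time_ms) != n_samp)
    stop_data("time_ms length != sample dim")
  step <- diff(time_ms)
  if (any(step <= 0) || max(abs(step - 1000 / fs)) > 1e-6)
    stop_data("time axis must increase uniformly in steps of 1000/fs ms")
  condition <- condition %||% rep("unlabelled", n_trials)
  if (length(condition) != n_trials)
    stop_data("condition length != trial dim")
  kept_mask <- kept_mask %||% rep(TRUE, n_trials)
  stopifnot(is.logical(kept_mask), length(kept_mask) == n_trials)
  structure(list(data = data, fs = fs, labels = as.character(labels),
                 time_ms = time_ms, condition = as.character(condition),
                 kept_mask = kept_mask),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat(sprintf(
    "<eeg_epochs> %d trials (%d kept) x %d channels x %d samples @ %g Hz\n",
    dim(x$data)[1], sum(x$kept_mask), dim(x$data)[2], dim(x$data)[3], x$fs))
  tab <- table(x$condition)
  cat("  conditions:", paste(sprintf("%s (%d)", names(tab), tab),
                             collapse = ", "), "\n")
  invisible(x)
}

n_trials <- function(epochs) dim(epochs$data)[1]
n_channels <- function(epochs) dim(epochs$data)[2]
n_samples <- function(epochs) dim(epochs$data)[3]

#' Subset epochs by trial
#' @param epochs an \code{eeg_epochs} object
#' @param trials integer or logical trial index
#' @return an \code{eeg_epochs} object
#' @export
epochs_subset <- function(epochs, trials) {
  eeg_epochs(epochs$data[trials, , , drop = FALSE], epochs$fs, epochs$labels,
             time_ms = epochs$time_ms,
             condition = epochs$condition[trials],
             kept_mask = epochs$kept_mask[trials])
}

#' Keep only non-rejected trials
#' @inheritParams epochs_subset
#' @export
epochs_kept <- function(epochs) epochs_subset(epochs, epochs$kept_mask)

# sample indices whose time lies in [t_lo, t_hi) ms
window_idx <- function(time_ms, t_lo, t_hi) {
  which(time_ms >= t_lo - 1e-9 & time_ms < t_hi - 1e-9)
}
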