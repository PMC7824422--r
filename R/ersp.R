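#' Short-time Fourier decomposition of epoched EEG
#'
#' Computes per-trial power on a uniform time-frequency grid (default
#' spacing about 0.48 Hz and 33.33 ms, the configuration used for the
#' event-related spectral perturbation maps). A Hann window of about half
#' a second (128 samples at 250 Hz, 512 at 1000 Hz) is zero-padded
#' fourfold, which fixes the frequency grid; window centres span the full
#' epoch, with frames that overhang the epoch edges zero-filled and
#' rescaled by their window-energy coverage so stationary power is
#' unbiased at the edges.
#'
#' Power is scaled as a one-sided spectral density (per Hz), so values are
#' directly comparable to a Welch periodogram.
#'
#' @param epochs an \code{eeg_epochs} object (all trials are decomposed;
#'   subset beforehand if needed)
#' @param freq_range c(lo, hi) in Hz, default 1-45
#' @param time_step_ms time grid step, default 100/3 ms
#' @param win_samples analysis window length; default
#'   \code{2^round(log2(fs/2))}
#' @param nfft_factor zero-padding factor, default 4
#' @param keep_trials if FALSE, accumulate the trial average instead of the
#'   full trials x channels x freqs x times array (which at study scale
#'   would need several GB)
#' @return object of class \code{tf_power} with \code{power} (trials x
#'   channels x freqs x times, or channels x freqs x times when averaged),
#'   \code{freqs}, \code{times}, \code{n_trials_used}
#' @export
tf_decompose <- function(epochs, freq_range = c(1, 45),
                         time_step_ms = 100 / 3, win_samples = NULL,
                         nfft_factor = 4, keep_trials = TRUE) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  fs <- epochs$fs
  if (freq_range[2] > fs / 2)
    stop_config("frequency grid top %g Hz exceeds Nyquist %g Hz",
                freq_range[2], fs / 2)
  win <- win_samples %||% 2^round(log2(fs / 2))
  nsmp <- n_samples(epochs)
  if (nsmp < win)
    stop_data("epoch (%d samples) shorter than analysis window (%d)",
              nsmp, win)
  nfft <- nfft_factor * win
  hann <- 0.5 * (1 - cos(2 * pi * seq_len(win) / (win + 1)))
  u <- sum(hann^2)
  freqs_all <- (seq_len(nfft / 2 + 1) - 1) * fs / nfft
  fsel <- which(freqs_all >= freq_range[1] - 1e-9 &
                  freqs_all <= freq_range[2] + 1e-9)
  freqs <- freqs_all[fsel]
  t0 <- epochs$time_ms[1]
  t_end <- epochs$time_ms[nsmp]
  times <- seq(t0, t_end, by = time_step_ms)
  half <- win %/% 2
  # centre sample (1-based, unpadded coords) per frame
  centers <- round((times - t0) / 1000 * fs) + 1
  starts <- centers - half                   # may be < 1 (overhang)
  # window-energy coverage of each frame within the epoch
  cov <- vapply(starts, function(s) {
    idx <- s:(s + win - 1)
    sum(hann[idx >= 1 & idx <= nsmp]^2) / u
  }, numeric(1))
  nt <- length(times); nf <- length(freqs)
  ntr <- n_trials(epochs); nc <- n_channels(epochs)
  scale <- 2 / (fs * u)
  out <- if (keep_trials) array(0, c(ntr, nc, nf, nt)) else
    array(0, c(nc, nf, nt))
  padded <- matrix(0, nsmp + 2 * win, nc)
  for (tr in seq_len(ntr)) {
    padded[win + seq_len(nsmp), ] <- t(epochs$data[tr, , ])
    # build win x (frames*channels) segment matrix, one FFT batch per trial
    seg <- matrix(0, nfft, nt * nc)
    for (j in seq_len(nt)) {
      rows <- win + starts[j] + 0:(win - 1)
      seg[seq_len(win), (j - 1) * nc + seq_len(nc)] <-
        padded[rows, ] * hann
    }
    sp <- Mod(stats::mvfft(seg)[fsel, , drop = FALSE])^2 * scale
    p <- aperm(array(sp, c(nf, nc, nt)), c(2, 1, 3))
    p <- sweep(p, 3, cov, "/")
    if (keep_trials) out[tr, , , ] <- p else out <- out + p / ntr
  }
  structure(list(power = out, freqs = freqs, times = times, fs = fs,
                 labels = epochs$labels, condition = epochs$condition,
                 n_trials_used = ntr, keep_trials = keep_trials),
            class = "tf_power")
}

#' Event-related spectral perturbation map
#'
#' Averages per-trial power across trials, then expresses it in dB
#' relative to the mean power over the baseline (rest) window:
#' \code{ERSP(c,f,t) = 10*log10(meanTrials P / meanBaselineTime meanTrials P)}.
#'
#' @param tfp a \code{tf_power} object
#' @param baseline_window c(lo, hi) ms; default the rest phase
#' @return object of class \code{tf_map}: \code{values} (channels x freqs
#'   x times, dB), \code{freqs}, \code{times}, \code{baseline_window}
#' @export
ersp_map <- function(tfp, baseline_window = c(-4000, -2000)) {
  stopifnot(inherits(tfp, "tf_power"))
  pbar <- if (tfp$keep_trials) {
    apply(tfp$power, c(2, 3, 4), mean)
  } else tfp$power
  bsel <- which(tfp$times >= baseline_window[1] - 1e-9 &
                  tfp$times < baseline_window[2] - 1e-9)
  if (!length(bsel))
    stop_config("baseline window outside the time grid")
  base <- apply(pbar[, , bsel, drop = FALSE], c(1, 2), mean)
  if (any(base == 0)) {
    bad <- which(base == 0, arr.ind = TRUE)[1, ]
    stop_data("zero baseline power at channel %s, %.2f Hz",
              tfp$labels[bad[1]], tfp$freqs[bad[2]])
  }
  vals <- 10 * log10(sweep(pbar, c(1, 2), base, "/"))
  structure(list(values = vals, freqs = tfp$freqs, times = tfp$times,
                 labels = tfp$labels, baseline_window = baseline_window,
                 n_trials_used = tfp$n_trials_used),
            class = "tf_map")
}

#' @export
print.tf_map <- function(x, ...) {
  cat(sprintf(
    "<tf_map> %d channels x %d freqs (%.2f-%.2f Hz) x %d times; baseline [%g, %g] ms\n",
    dim(x$values)[1], dim(x$values)[2], min(x$freqs), max(x$freqs),
    dim(x$values)[3], x$baseline_window[1], x$baseline_window[2]))
  invisible(x)
}

#' Frequency bands of interest
#'
#' The three analysis bands: alpha 8-14 Hz, beta 15-35 Hz, gamma 35-45 Hz.
#' @export
foi_bands <- function() {
  list(alpha = c(8, 14), beta = c(15, 35), gamma = c(35, 45))
}

#' Band-by-window ERSP summary
#'
#' Mean ERSP per channel over each frequency band of interest and each of
#' four 250 ms intervals following the onset of the system adaptation
#' (epoch time +1000 ms). These per-channel cells are the inputs to the
#' electrode-level cluster statistics.
#'
#' @param tf_map a \code{tf_map}
#' @param adaptation_onset_ms epoch time of adaptation onset
#' @param bands named list of c(lo, hi) Hz; default \code{foi_bands()}
#' @param windows list of c(lo, hi) ms relative to adaptation onset
#' @return object of class \code{band_window_summary} whose \code{values}
#'   is channels x bands x windows (dB), with dimnames
#' @export
band_window_summary <- function(tf_map, adaptation_onset_ms = 1000,
                                bands = foi_bands(),
                                windows = list(c(0, 250), c(250, 500),
                                               c(500, 750), c(750, 1000))) {
  stopifnot(inherits(tf_map, "tf_map"))
  last <- adaptation_onset_ms + max(vapply(windows, max, numeric(1)))
  if (max(tf_map$times) < last - 50)
    stop_config("time grid ends at %g ms; need coverage to %g ms",
                max(tf_map$times), last)
  nc <- dim(tf_map$values)[1]
  vals <- array(NA_real_, c(nc, length(bands), length(windows)),
                dimnames = list(tf_map$labels, names(bands),
                                vapply(windows, function(w)
                                  sprintf("%g-%g", w[1], w[2]),
                                  character(1))))
  for (b in seq_along(bands)) {
    fsel <- tf_map$freqs >= bands[[b]][1] & tf_map$freqs <= bands[[b]][2]
    for (w in seq_along(windows)) {
      tsel <- tf_map$times >= adaptation_onset_ms + windows[[w]][1] - 1e-9 &
        tf_map$times < adaptation_onset_ms + windows[[w]][2] - 1e-9
      vals[, b, w] <- apply(
        tf_map$values[, fsel, tsel, drop = FALSE], 1, mean)
    }
  }
  structure(list(values = vals, bands = bands, windows = windows,
                 adaptation_onset_ms = adaptation_onset_ms),
            class = "band_window_summary")
}
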