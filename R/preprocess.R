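#' Construct a continuous raw EEG recording
#'
#' @param data channels x samples matrix, microvolts
#' @param fs sampling rate, Hz
#' @param labels channel labels
#' @param events data.frame with columns \code{sample} (1-based index) and
#'   \code{marker} (character)
#' @return object of class \code{eeg_raw}
#' @export
eeg_raw <- function(data, fs, labels, events = NULL) {
  stopifnot(is.matrix(data), fs > 0, nrow(data) == length(labels))
  events <- events %||% data.frame(sample = integer(), marker = character())
  stopifnot(all(c("sample", "marker") %in% names(events)))
  if (nrow(events) &&
      (any(events$sample < 1) || any(events$sample > ncol(data))))
    stop_data("event sample indices outside recording bounds")
  structure(list(data = data, fs = fs, labels = as.character(labels),
                 events = events),
            class = "eeg_raw")
}

#' @export
print.eeg_raw <- function(x, ...) {
  cat(sprintf("<eeg_raw> %d channels x %d samples @ %g Hz, %d events\n",
              nrow(x$data), ncol(x$data), x$fs, nrow(x$events)))
  invisible(x)
}

#' Detrend and re-reference to linked mastoids
#'
#' Removes the per-channel least-squares linear trend over the whole
#' continuous recording, then subtracts the mean of the two mastoid
#' channels from every channel (mathematically linked mastoid reference).
#'
#' @param raw an \code{eeg_raw} object
#' @param mastoid_labels the two mastoid channel labels
#' @return re-referenced \code{eeg_raw}
#' @export
detrend_and_reference <- function(raw, mastoid_labels = c("TP9", "TP10")) {
  stopifnot(inherits(raw, "eeg_raw"), length(mastoid_labels) == 2)
  mi <- match_channels(raw$labels, mastoid_labels, "mastoid channel")
  n <- ncol(raw$data)
  t <- seq_len(n) - (n + 1) / 2                  # centred regressor
  x <- raw$data
  slope <- (x %*% t) / sum(t * t)
  x <- x - drop(slope) %o% t - rowMeans(x)
  ref <- colMeans(x[mi, , drop = FALSE])
  x <- sweep(x, 2, ref)
  raw$data <- x
  raw
}

# Windowed-sinc linear-phase band-pass FIR; Hamming window.
# Transition width set by the low edge (0.5 Hz default corner needs a
# narrow transition, which dictates the filter length).
design_fir_bandpass <- function(f_lo, f_hi, fs, transition_hz = 0.5) {
  ntaps <- ceiling(3.3 * fs / transition_hz)
  if (ntaps %% 2 == 0) ntaps <- ntaps + 1       # odd -> exact linear phase
  m <- (ntaps - 1) / 2
  k <- -m:m
  sinc <- function(fc) {
    h <- 2 * fc / fs * sin(2 * pi * fc / fs * k + 1e-300) /
      (2 * pi * fc / fs * k + 1e-300)
    h[m + 1] <- 2 * fc / fs
    h
  }
  h <- sinc(f_hi) - sinc(f_lo)
  w <- 0.54 + 0.46 * cos(pi * k / m)            # Hamming
  h <- h * w
  # normalise passband gain at the geometric band centre
  fc <- sqrt(f_lo * f_hi)
  g <- abs(sum(h * exp(-2i * pi * fc / fs * k)))
  h / g
}

# FFT convolution of each column of x (samples x channels) with kernel h,
# returning the "same" central part
conv_same <- function(x, h) {
  n <- nrow(x); L <- length(h)
  nfft <- next_pow2(n + L - 1)
  H <- stats::fft(c(h, rep(0, nfft - L)))
  X <- stats::mvfft(rbind(x, matrix(0, nfft - n, ncol(x))))
  y <- Re(stats::mvfft(X * H, inverse = TRUE)) / nfft
  m <- (L - 1) / 2
  y[(m + 1):(m + n), , drop = FALSE]
}

#' Zero-phase FIR band-pass filter
#'
#' Applies a windowed-sinc linear-phase FIR forward and backward
#' (filtfilt), giving exactly zero phase and squared magnitude response.
#' Edges are reflection-padded to suppress filter transients.
#'
#' @param raw an \code{eeg_raw} object
#' @param f_lo,f_hi corner frequencies, Hz
#' @param transition_hz transition band width at the low edge, Hz
#' @return filtered \code{eeg_raw}
#' @export
bandpass_zero_phase <- function(raw, f_lo = 0.5, f_hi = 48,
                                transition_hz = 0.5) {
  stopifnot(inherits(raw, "eeg_raw"))
  if (!(f_lo > 0 && f_lo < f_hi && f_hi < raw$fs / 2))
    stop_config("need 0 < f_lo < f_hi < fs/2 (got %g, %g at fs %g)",
                f_lo, f_hi, raw$fs)
  h <- design_fir_bandpass(f_lo, f_hi, raw$fs, transition_hz)
  x <- t(raw$data)
  n <- nrow(x)
  pad <- min(length(h), n - 1)
  xp <- rbind(2 * x[rep(1, pad), , drop = FALSE] -
                x[(pad + 1):2, , drop = FALSE],
              x,
              2 * x[rep(n, pad), , drop = FALSE] -
                x[(n - 1):(n - pad), , drop = FALSE])
  y <- conv_same(xp, h)
  y <- y[nrow(y):1, , drop = FALSE]
  y <- conv_same(y, h)
  y <- y[nrow(y):1, , drop = FALSE]
  raw$data <- t(y[pad + seq_len(n), , drop = FALSE])
  raw
}

#' Segment a continuous recording into stimulus-locked epochs
#'
#' Cuts one epoch per replay-onset marker, with time 0 at the marker.
#' Markers too close to the recording edges are skipped; the number of
#' skipped markers is reported via a warning and the \code{"n_skipped"}
#' attribute.
#'
#' @param raw an \code{eeg_raw} object
#' @param marker_prefix condition markers are taken as events whose marker
#'   string starts with this prefix; the remainder is the condition label
#' @param pre_ms,post_ms epoch extent before/after the marker, ms
#' @return an \code{eeg_epochs} object (possibly with zero trials)
#' @export
segment <- function(raw, marker_prefix = "cond:",
                    pre_ms = 4000, post_ms = 2000) {
  stopifnot(inherits(raw, "eeg_raw"))
  fs <- raw$fs
  pre <- round(pre_ms / 1000 * fs)
  post <- round(post_ms / 1000 * fs)
  ev <- raw$events[startsWith(raw$events$marker, marker_prefix), ,
                   drop = FALSE]
  nsmp <- pre + post
  ok <- ev$sample - pre >= 1 & ev$sample + post - 1 <= ncol(raw$data)
  n_skipped <- sum(!ok)
  if (n_skipped > 0)
    warning(sprintf("%d marker(s) too close to recording edges; skipped",
                    n_skipped))
  ev <- ev[ok, , drop = FALSE]
  dat <- array(0, c(nrow(ev), length(raw$labels), nsmp))
  for (i in seq_len(nrow(ev)))
    dat[i, , ] <- raw$data[, (ev$sample[i] - pre):(ev$sample[i] + post - 1)]
  out <- eeg_epochs(dat, fs, raw$labels, t0_ms = -pre_ms,
                    condition = sub(marker_prefix, "", ev$marker,
                                    fixed = TRUE))
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Reject trials by amplitude in a channel group
#'
#' A trial is rejected when the maximum absolute deviation (from the
#' per-channel epoch mean, or peak-to-peak if \code{method =
#' "peak_to_peak"}) strictly exceeds \code{threshold_uv} in any channel of
#' the group. Only the kept mask is updated; signal values are never
#' modified.
#'
#' @param epochs an \code{eeg_epochs} object
#' @param channel_group a montage group name (resolved against
#'   \code{montage}) or a character vector of channel labels
#' @param threshold_uv rejection threshold, microvolts
#' @param montage an \code{eeg_montage} used to resolve group names
#' @param method deviation definition; default deviation from epoch mean
#' @return \code{eeg_epochs} with updated \code{kept_mask}
#' @export
reject_amplitude <- function(epochs, channel_group = "frontal",
                             threshold_uv = 200,
                             montage = make_montage("study32"),
                             method = c("mean_dev", "peak_to_peak")) {
  method <- match.arg(method)
  if (length(channel_group) == 1 && channel_group %in% names(montage$groups))
    channel_group <- montage$groups[[channel_group]]
  channel_group <- intersect(channel_group, epochs$labels)
  if (!length(channel_group))
    stop_config("empty channel group for amplitude rejection")
  ch <- match_channels(epochs$labels, channel_group)
  for (tr in seq_len(n_trials(epochs))) {
    x <- epochs$data[tr, ch, , drop = FALSE][1, , , drop = TRUE]
    if (length(ch) == 1) x <- matrix(epochs$data[tr, ch, ], nrow = 1)
    dev <- if (method == "mean_dev") {
      max(abs(x - rowMeans(x)))
    } else {
      max(apply(x, 1, function(r) diff(range(r))))
    }
    if (dev > threshold_uv) epochs$kept_mask[tr] <- FALSE
  }
  epochs
}
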