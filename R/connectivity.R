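#' Multitaper configuration
#'
#' Defaults follow the connectivity analysis settings: 1000 ms windows
#' stepped by 100 ms, time-bandwidth parameter 3 giving
#' \code{2*3 - 1 = 5} Slepian tapers, FFT length the next power of two
#' at or above the window length (1024 at 1 kHz, hence a spectral
#' resolution of 1000/1024 = 0.98 Hz).
#'
#' @param window_ms analysis window length, ms
#' @param step_ms window step, ms
#' @param bandwidth_param time-bandwidth parameter NW
#' @return object of class \code{mt_config}
#' @export
multitaper_config <- function(window_ms = 1000, step_ms = 100,
                              bandwidth_param = 3) {
  stopifnot(window_ms > 0, step_ms > 0, bandwidth_param >= 1)
  structure(list(window_ms = window_ms, step_ms = step_ms,
                 bandwidth_param = bandwidth_param,
                 n_tapers = 2 * bandwidth_param - 1),
            class = "mt_config")
}

#' Spectral grid implied by a multitaper configuration
#'
#' @param fs sampling rate, Hz
#' @param config an \code{mt_config}
#' @return list(n_window, nfft, df, freqs): window samples, FFT length
#'   (next power of two), frequency-bin spacing in Hz, one-sided grid
#' @export
spectral_grid <- function(fs, config = multitaper_config()) {
  n <- round(config$window_ms / 1000 * fs)
  nfft <- next_pow2(n)
  df <- fs / nfft
  list(n_window = n, nfft = nfft, df = df,
       freqs = (seq_len(nfft / 2 + 1) - 1) * df)
}

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computes the \code{K = 2*bandwidth_param - 1} most concentrated Slepian
#' sequences via the classic symmetric-tridiagonal eigenproblem (solved
#' with LAPACK's dstevr for the top K pairs only), plus their in-band
#' energy concentration eigenvalues from the sinc-kernel quadratic form.
#'
#' @param n_samples taper length
#' @param bandwidth_param time-bandwidth parameter NW
#' @return list(tapers = K x n_samples orthonormal matrix,
#'   eigenvalues = K concentrations, strictly decreasing)
#' @export
dpss_tapers <- function(n_samples, bandwidth_param = 3) {
  k <- 2 * bandwidth_param - 1
  if (k >= n_samples)
    stop_config("need n_samples > %d tapers (got %d)", k, n_samples)
  if (n_samples < 2 * k)
    stop_config("n_samples must be at least 2*K = %d", 2 * k)
  n <- n_samples
  w <- bandwidth_param / n
  i <- 0:(n - 1)
  d <- ((n - 1 - 2 * i) / 2)^2 * cos(2 * pi * w)
  e <- (1:(n - 1)) * (n - (1:(n - 1))) / 2
  res <- .Call(C_tridiag_topk, as.double(d), as.double(e), as.integer(k))
  v <- res$vectors[, k:1, drop = FALSE]          # most concentrated first
  v <- sweep(v, 2, sqrt(colSums(v^2)), "/")
  # sign convention: symmetric tapers have positive mean; antisymmetric
  # ones start with a positive lobe
  for (j in seq_len(k)) {
    s <- sum(v[, j])
    ref <- if (abs(s) > 1e-8) s else v[which(abs(v[, j]) > 1e-12)[1], j]
    if (ref < 0) v[, j] <- -v[, j]
  }
  # concentration lambda_k = h' A h, A_ij = sin(2 pi W (i-j)) / (pi (i-j))
  dif <- outer(i, i, "-")
  a <- sin(2 * pi * w * dif) / (pi * dif)
  diag(a) <- 2 * w
  lam <- colSums(v * (a %*% v))
  ord <- order(lam, decreasing = TRUE)
  list(tapers = t(v[, ord, drop = FALSE]), eigenvalues = lam[ord])
}

#' Multitaper cross-spectral matrix
#'
#' Averages the tapered cross-periodogram over the Slepian tapers and over
#' every analysis window that fits in the segment (slid by the configured
#' step). The result is Hermitian with real non-negative diagonal.
#'
#' @param segment channels x samples numeric matrix (microvolts)
#' @param fs sampling rate, Hz
#' @param config an \code{mt_config}
#' @return list(S = channels x channels x nfreq complex array,
#'   freqs, n_windows)
#' @export
cross_spectrum <- function(segment, fs, config = multitaper_config()) {
  stopifnot(is.matrix(segment))
  if (anyNA(segment)) stop_data("NaN/NA in input segment")
  g <- spectral_grid(fs, config)
  n <- g$n_window
  if (ncol(segment) < n)
    stop_data("segment (%d samples) shorter than window (%d)",
              ncol(segment), n)
  step <- max(1, round(config$step_ms / 1000 * fs))
  starts <- seq(1, ncol(segment) - n + 1, by = step)
  dp <- dpss_tapers(n, config$bandwidth_param)
  nc <- nrow(segment); nf <- length(g$freqs); k <- nrow(dp$tapers)
  s <- array(0i, c(nc, nc, nf))
  for (st in starts) {
    x <- segment[, st:(st + n - 1), drop = FALSE]
    x <- x - rowMeans(x)
    seg <- matrix(0, g$nfft, nc * k)
    for (j in seq_len(k))
      seg[seq_len(n), (j - 1) * nc + seq_len(nc)] <- t(x) * dp$tapers[j, ]
    xf <- stats::mvfft(seg)[seq_len(nf), , drop = FALSE]
    xf <- array(xf, c(nf, nc, k))
    for (f in seq_len(nf)) {
      m <- matrix(xf[f, , ], nc, k)
      s[, , f] <- s[, , f] + m %*% Conj(t(m)) / k
    }
  }
  s <- s / length(starts)
  list(S = s, freqs = g$freqs, n_windows = length(starts))
}

#' Complex coherency from a cross-spectral matrix
#'
#' \code{COH_ij(f) = S_ij(f) / sqrt(S_ii(f) S_jj(f))}: the normalized
#' cross-spectrum. Its magnitude is at most 1 and its diagonal exactly 1.
#'
#' @param cs result of \code{\link{cross_spectrum}} (or any list with
#'   \code{S} and \code{freqs})
#' @return list(COH = channels x channels x nfreq complex, freqs)
#' @export
coherency <- function(cs) {
  s <- cs$S
  nc <- dim(s)[1]; nf <- dim(s)[3]
  auto <- matrix(0, nc, nf)
  for (i in seq_len(nc)) auto[i, ] <- Re(s[i, i, ])
  if (any(auto <= 0)) {
    bad <- which(auto <= 0, arr.ind = TRUE)[1, ]
    stop_data("zero auto-spectrum at channel %d, frequency index %d",
              bad[1], bad[2])
  }
  coh <- array(0i, dim(s))
  for (f in seq_len(nf)) {
    d <- 1 / sqrt(auto[, f])
    coh[, , f] <- s[, , f] * (d %o% d)
  }
  list(COH = coh, freqs = cs$freqs)
}

#' Corrected imaginary coherence
#'
#' \code{ciCOH = Im(COH) / sqrt(1 - Re(COH)^2)}. The correction rescales
#' the imaginary part by the residual after removing the real
#' (zero-phase-lag) component, compensating the plain imaginary coherence's
#' bias towards long-range interactions while keeping its insensitivity to
#' volume conduction. Where \code{|Re(COH)|} reaches 1 (pure real
#' coherency, e.g. a channel with itself) the value is set to 0.
#'
#' @param coh complex array or scalar of coherency values (or the list
#'   returned by \code{\link{coherency}})
#' @return numeric array of the same shape, values in [-1, 1]
#' @export
cicoh <- function(coh) {
  if (is.list(coh)) coh <- coh$COH
  re <- Re(coh); im <- Im(coh)
  out <- im / sqrt(pmax(1 - re^2, 1e-12))
  out[abs(re) > 1 - 1e-6] <- 0
  out
}

#' Fisher z-transform
#'
#' \code{z = atanh(x)}; values at or beyond +-1 are clipped to
#' \code{1 - 1e-12} with a warning.
#'
#' @param x numeric values in (-1, 1)
#' @return transformed values
#' @export
fisher_z <- function(x) {
  if (any(abs(x) >= 1, na.rm = TRUE)) {
    warning("values with |x| >= 1 clipped before atanh")
    x <- pmin(pmax(x, -1 + 1e-12), 1 - 1e-12)
  }
  atanh(x)
}

#' Event-related contrast of coupling magnitudes
#'
#' \code{(toi - base) / max(base, eps)}: the relative change of coupling
#' strength in the window of interest versus baseline. Positive values
#' mean stronger coupling during the TOI.
#'
#' @param toi,base coupling magnitudes (e.g. \code{|ciCOH|}), same shape
#' @param eps denominator floor
#' @return numeric array of relative changes
#' @export
er_contrast <- function(toi, base, eps = 1e-3) {
  (toi - base) / pmax(base, eps)
}

#' Event-related ciCOH seed maps
#'
#' For every kept trial and each of the two 1000 ms windows -- the
#' baseline (last second of the rest phase) and the time window of
#' interest (first second of the system adaptation) -- computes the
#' multitaper coherency between each seed electrode and every other
#' electrode, takes \code{|ciCOH|} averaged over the bins of each
#' frequency band of interest, and forms the relative contrast
#' \code{(|ciCOH|_TOI - |ciCOH|_Base) / max(|ciCOH|_Base, eps)}.
#' Values are averaged over trials and then over the seeds; seed
#' electrodes themselves are NA in the map. One map per condition.
#'
#' @param epochs an \code{eeg_epochs} object
#' @param seeds seed electrode labels
#' @param config an \code{mt_config}
#' @param bands named list of frequency bands, default \code{foi_bands()}
#' @param toi_window,baseline_window c(lo, hi) epoch ms
#' @param eps denominator floor for the relative contrast; per-trial
#'   five-taper \code{|ciCOH|} estimates near zero would otherwise explode
#'   the ratio
#' @param fisher_before_contrast apply \code{\link{fisher_z}} to the
#'   per-trial \code{|ciCOH|} values before contrasting
#' @return object of class \code{er_cicoh_map}: \code{values} is
#'   electrodes x bands x conditions
#' @export
er_cicoh <- function(epochs, seeds = c("POO1", "POO2"),
                     config = multitaper_config(), bands = foi_bands(),
                     toi_window = c(1000, 2000),
                     baseline_window = c(-3000, -2000),
                     eps = 1e-3, fisher_before_contrast = FALSE) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  kept <- epochs_kept(epochs)
  si <- match_channels(kept$labels, seeds, "seed electrode")
  g <- spectral_grid(kept$fs, config)
  n <- g$n_window
  toi_idx <- window_idx(kept$time_ms, toi_window[1], toi_window[2])
  base_idx <- window_idx(kept$time_ms, baseline_window[1],
                         baseline_window[2])
  if (length(toi_idx) < n || length(base_idx) < n)
    stop_config("TOI/baseline window shorter than the multitaper window")
  toi_idx <- toi_idx[seq_len(n)]
  base_idx <- base_idx[seq_len(n)]
  dp <- dpss_tapers(n, config$bandwidth_param)
  k <- nrow(dp$tapers)
  nc <- n_channels(kept)
  nb <- length(bands)
  bsel <- lapply(bands, function(b) which(g$freqs >= b[1] &
                                            g$freqs <= b[2]))
  conds <- unique(kept$condition)
  vals <- array(NA_real_, c(nc, nb, length(conds)),
                dimnames = list(kept$labels, names(bands), conds))
  n_floored <- 0L; n_total <- 0L
  abs_cicoh_win <- function(x) {
    # x: channels x n window; returns |ciCOH| seed x electrode x band
    x <- x - rowMeans(x)
    seg <- matrix(0, g$nfft, nc * k)
    for (j in seq_len(k))
      seg[seq_len(n), (j - 1) * nc + seq_len(nc)] <- t(x) * dp$tapers[j, ]
    nf <- length(g$freqs)
    xf <- array(stats::mvfft(seg)[seq_len(nf), , drop = FALSE],
                c(nf, nc, k))
    auto <- apply(Mod(xf)^2, c(1, 2), mean)          # nf x nc
    out <- array(NA_real_, c(length(si), nc, nb))
    for (s_k in seq_along(si)) {
      cross <- matrix(0i, nf, nc)
      for (j in seq_len(k))
        cross <- cross + xf[, si[s_k], j] * Conj(xf[, , j])
      cross <- cross / k
      coh <- cross / sqrt(pmax(auto[, si[s_k]] %o% rep(1, nc) * auto,
                               1e-300))
      ci <- abs(cicoh(coh))                          # nf x nc
      for (b in seq_len(nb))
        out[s_k, , b] <- colMeans(ci[bsel[[b]], , drop = FALSE])
    }
    out
  }
  for (cond in conds) {
    trs <- which(kept$condition == cond)
    acc <- array(0, c(length(si), nc, nb))
    for (tr in trs) {
      a_toi <- abs_cicoh_win(kept$data[tr, , toi_idx])
      a_base <- abs_cicoh_win(kept$data[tr, , base_idx])
      if (fisher_before_contrast) {
        a_toi <- fisher_z(pmin(a_toi, 1 - 1e-12))
        a_base <- fisher_z(pmin(a_base, 1 - 1e-12))
      }
      n_floored <- n_floored + sum(a_base < eps)
      n_total <- n_total + length(a_base)
      acc <- acc + er_contrast(a_toi, a_base, eps)
    }
    m <- apply(acc / length(trs), c(2, 3), mean)     # mean over seeds
    m[si, ] <- NA_real_
    vals[, , cond] <- m
  }
  if (n_total > 0 && n_floored / n_total > 0.2)
    warning(sprintf("baseline |ciCOH| below eps=%g in %d of %d cells",
                    eps, n_floored, n_total))
  structure(list(values = vals, seeds = seeds, bands = bands,
                 toi_window = toi_window, baseline_window = baseline_window,
                 conditions = conds),
            class = "er_cicoh_map")
}

#' @export
print.er_cicoh_map <- function(x, ...) {
  cat(sprintf(
    "<er_cicoh_map> %d electrodes x %d bands x %d condition(s); seeds %s\n",
    dim(x$values)[1], dim(x$values)[2], dim(x$values)[3],
    paste(x$seeds, collapse = "/")))
  invisible(x)
}
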