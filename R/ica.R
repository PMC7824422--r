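#' Fit a logistic infomax ICA decomposition
#'
#' Whitens the concatenated kept trials and runs natural-gradient logistic
#' infomax (the classic runica update) to estimate an unmixing matrix.
#' The logistic nonlinearity separates super-Gaussian sources, which is
#' what EEG artifacts (blinks, cardiac, muscle bursts) are.
#'
#' @param epochs an \code{eeg_epochs} object; only kept trials are used
#' @param maxit maximum number of sweeps over the data
#' @param lrate initial learning rate
#' @param tol stop when the sweep-to-sweep weight change falls below this
#' @param seed seed for the block shuffling (fitting is deterministic
#'   given this seed)
#' @return an \code{ica_model}: \code{unmixing} (components x channels),
#'   \code{mixing} (channels x components), \code{labels},
#'   \code{component_flags} data.frame(flag, reason)
#' @export
ica_fit <- function(epochs, maxit = 200, lrate = NULL, tol = 1e-7,
                    seed = 1L) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  kept <- epochs_kept(epochs)
  nc <- n_channels(kept)
  x <- matrix(aperm(kept$data, c(2, 3, 1)), nrow = nc)  # ch x (samp*trial)
  n <- ncol(x)
  if (n < 20 * nc^2)
    stop_data(paste0("too few samples for ICA: need >= 20*nchan^2 = %d, ",
                     "have %d"), 20 * nc^2, n)
  x <- x - rowMeans(x)
  cv <- tcrossprod(x) / n
  eg <- eigen(cv, symmetric = TRUE)
  if (min(eg$values) < 1e-10 * max(eg$values))
    stop_data(paste0("rank-deficient data (smallest eigenvalue ratio %.2e);",
                     " reduce dimensionality before ICA"),
              min(eg$values) / max(eg$values))
  sphere <- diag(1 / sqrt(eg$values)) %*% t(eg$vectors)
  xs <- sphere %*% x
  w <- diag(nc)
  lrate <- lrate %||% 0.01 / log(nc^2)
  block <- max(nc, min(256L, floor(n / 10)))
  set.seed(seed)
  eye <- diag(nc)
  for (sweep in seq_len(maxit)) {
    perm <- sample.int(n)
    w_old <- w
    for (start in seq(1, n - block + 1, by = block)) {
      u <- w %*% xs[, perm[start:(start + block - 1)], drop = FALSE]
      y <- 1 / (1 + exp(-u))
      dw <- lrate * (eye + ((1 - 2 * y) %*% t(u)) / block) %*% w
      w <- w + dw
      if (!all(is.finite(w)) || max(abs(w)) > 1e8) {  # diverged: restart
        w <- diag(nc); lrate <- lrate / 2
        break
      }
    }
    delta <- max(abs(w - w_old))
    lrate <- lrate * 0.98
    if (delta < tol) break
  }
  unmixing <- w %*% sphere
  mixing <- solve(unmixing)
  # order components by contributed variance, largest first
  act_var <- apply(unmixing %*% x, 1, stats::var)
  contrib <- colSums(mixing^2) * act_var
  ord <- order(contrib, decreasing = TRUE)
  unmixing <- unmixing[ord, , drop = FALSE]
  mixing <- mixing[, ord, drop = FALSE]
  structure(list(unmixing = unmixing, mixing = mixing,
                 labels = kept$labels,
                 component_flags = data.frame(
                   flag = rep(FALSE, nc),
                   reason = rep("", nc),
                   stringsAsFactors = FALSE)),
            class = "ica_model")
}

#' @export
print.ica_model <- function(x, ...) {
  cat(sprintf("<ica_model> %d components over %d channels; %d flagged\n",
              nrow(x$unmixing), ncol(x$unmixing),
              sum(x$component_flags$flag)))
  invisible(x)
}

# mean power spectral density of a component activation across trials
.component_psd <- function(model, epochs, comp) {
  kept <- epochs_kept(epochs)
  nsmp <- n_samples(kept)
  nfft <- next_pow2(nsmp)
  acc <- 0
  for (tr in seq_len(n_trials(kept))) {
    a <- drop(model$unmixing[comp, , drop = FALSE] %*% kept$data[tr, , ])
    a <- a - mean(a)
    acc <- acc + Mod(stats::fft(c(a, rep(0, nfft - nsmp))))^2
  }
  half <- seq_len(nfft / 2)
  list(freq = (half - 1) * kept$fs / nfft,
       power = acc[half] / n_trials(kept))
}

#' Flag artifact components by deterministic heuristics
#'
#' Ocular components: frontal topography dominance together with most
#' spectral power below 4 Hz. Muscular components: power spectrum rising
#' above 20 Hz together with a scalp-edge focal topography. Thresholds are
#' configuration, not magic: they are exposed as arguments. A manual
#' \code{override} (component indices) replaces the heuristics entirely,
#' preserving the visual-inspection workflow.
#'
#' @param model an \code{ica_model}
#' @param epochs the epochs the model was fitted on
#' @param montage montage used for topography heuristics
#' @param frontal_dominance ratio of mean absolute frontal weight to mean
#'   absolute weight above which a topography counts as frontal
#' @param low_freq_fraction fraction of power below 4 Hz above which a
#'   component counts as slow/ocular
#' @param edge_radius normalized scalp radius beyond which the peak
#'   electrode counts as edge-focal
#' @param override integer vector of component indices to flag manually
#'   (bypasses all heuristics)
#' @return the model with updated \code{component_flags}
#' @export
ica_flag <- function(model, epochs, montage = make_montage("study32"),
                     frontal_dominance = 2, low_freq_fraction = 0.55,
                     edge_radius = 0.85, override = NULL) {
  stopifnot(inherits(model, "ica_model"))
  nc <- nrow(model$unmixing)
  flags <- rep(FALSE, nc)
  reasons <- rep("", nc)
  if (!is.null(override)) {
    stopifnot(all(override %in% seq_len(nc)))
    flags[override] <- TRUE
    reasons[override] <- "manual"
  } else {
    fr <- intersect(montage$groups$frontal, model$labels)
    fi <- match(fr, model$labels)
    pos <- montage$pos2d[match(model$labels, montage$labels), , drop = FALSE]
    radius <- sqrt(rowSums(pos^2))
    radius <- radius / max(radius)
    for (k in seq_len(nc)) {
      topo <- abs(model$mixing[, k])
      psd <- .component_psd(model, epochs, k)
      low <- sum(psd$power[psd$freq < 4]) / sum(psd$power)
      frontal_dom <- if (length(fi)) mean(topo[fi]) / mean(topo) else 0
      if (frontal_dom > frontal_dominance && low > low_freq_fraction) {
        flags[k] <- TRUE
        reasons[k] <- "ocular"
        next
      }
      hi <- psd$freq >= 20 & psd$freq <= min(45, max(psd$freq))
      if (sum(hi) > 2) {
        slope <- stats::coef(stats::lm(10 * log10(psd$power[hi] + 1e-30) ~
                                         psd$freq[hi]))[2]
        focal <- radius[which.max(topo)] > edge_radius
        if (slope > 0 && focal) {
          flags[k] <- TRUE
          reasons[k] <- "muscular"
        }
      }
    }
  }
  model$component_flags <- data.frame(flag = flags, reason = reasons,
                                      stringsAsFactors = FALSE)
  model
}

#' Reconstruct epochs excluding flagged components
#'
#' With no flagged components the reconstruction is the identity up to
#' floating-point round-off.
#'
#' @param model an \code{ica_model} with \code{component_flags}
#' @param epochs epochs to clean (all trials, kept or not)
#' @return cleaned \code{eeg_epochs}
#' @export
ica_remove <- function(model, epochs) {
  stopifnot(inherits(model, "ica_model"), inherits(epochs, "eeg_epochs"))
  keep <- !model$component_flags$flag
  proj <- model$mixing[, keep, drop = FALSE] %*%
    model$unmixing[keep, , drop = FALSE]
  for (tr in seq_len(n_trials(epochs)))
    epochs$data[tr, , ] <- proj %*% epochs$data[tr, , ]
  epochs
}
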