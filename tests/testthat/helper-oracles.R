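# Independent oracles used across tests. Deliberately simple, direct
# implementations that share no code with the package's own paths.

# one-sided periodogram band power of a vector (density units irrelevant,
# used only for ratios)
oracle_band_power <- function(x, fs, band) {
  n <- length(x)
  x <- x - mean(x)
  p <- Mod(stats::fft(x))^2 / n
  f <- (seq_len(n) - 1) * fs / n
  sel <- f >= band[1] & f <= band[2] & f <= fs / 2
  mean(p[sel])
}

# Welch PSD with 50% overlapping Hann windows (density scaling)
oracle_welch_psd <- function(x, fs, nseg = 256) {
  x <- x - mean(x)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(nseg) / (nseg + 1)))
  u <- sum(w^2)
  starts <- seq(1, length(x) - nseg + 1, by = nseg %/% 2)
  acc <- 0
  for (s in starts)
    acc <- acc + Mod(stats::fft(x[s:(s + nseg - 1)] * w))^2
  p <- acc / length(starts) * 2 / (fs * u)
  list(freq = (seq_len(nseg %/% 2 + 1) - 1) * fs / nseg,
       psd = p[seq_len(nseg %/% 2 + 1)])
}

# connected components among supra-threshold nodes via igraph (oracle for
# the hand-rolled BFS)
oracle_components <- function(nodes, adj) {
  if (!length(nodes)) return(list())
  sub <- adj[nodes, nodes, drop = FALSE]
  g <- igraph::graph_from_adjacency_matrix(sub, mode = "undirected")
  comp <- igraph::components(g)
  lapply(seq_len(comp$no),
         function(k) sort(nodes[comp$membership == k]))
}

# brute-force max-|summed-t| cluster statistic for one t vector
oracle_max_mass <- function(t, tcrit, adj) {
  best <- 0
  for (sgn in c(1, -1)) {
    nodes <- which(sgn * t > tcrit)
    for (comp in oracle_components(nodes, adj)) {
      m <- abs(sum(t[comp]))
      best <- max(best, m)
    }
  }
  best
}

# tiny epochs object with given channel count, white-noise content
make_noise_epochs <- function(n_trials, labels, n_samples = 1500, fs = 250,
                              sd = 10, t0_ms = -4000, condition = NULL) {
  dat <- array(stats::rnorm(n_trials * length(labels) * n_samples, sd = sd),
               c(n_trials, length(labels), n_samples))
  eeg_epochs(dat, fs, labels, t0_ms = t0_ms, condition = condition)
}
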