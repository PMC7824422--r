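# The generator is validated against independent spectral oracles
# (periodogram band power) and, for coupling, against the downstream
# multitaper connectivity estimate whose own correctness is established in
# test-connectivity.R.

test_that("simulated dataset has the configured shape and is deterministic", {
  cfg <- simulation_config(fs = 250, n_subjects = 2,
                           n_trials_per_condition = 10, seed = 7)
  ds <- simulate_dataset(cfg)
  expect_length(ds$subjects, 2)
  expect_equal(dim(ds$subjects[[1]]$data), c(20, 32, 1500))
  expect_equal(ds$subjects[[1]]$time_ms[1], -4000)
  expect_equal(table(ds$subjects[[1]]$condition)[["supportive"]], 10)
  ds2 <- simulate_dataset(cfg)
  expect_identical(ds$subjects[[1]]$data, ds2$subjects[[1]]$data)
  expect_identical(ds$subjects[[2]]$data, ds2$subjects[[2]]$data)
  # different seed changes the data
  ds3 <- simulate_dataset(simulation_config(fs = 250, n_subjects = 2,
                                            n_trials_per_condition = 10,
                                            seed = 8))
  expect_false(identical(ds$subjects[[1]]$data, ds3$subjects[[1]]$data))
})

test_that("with no effects, adaptation and rest band power agree within 0.5 dB", {
  cfg <- simulation_config(n_subjects = 1, n_trials_per_condition = 60,
                           seed = 11)
  ep <- simulate_dataset(cfg)$subjects[[1]]
  rest <- erspconn:::window_idx(ep$time_ms, -4000, -2000)
  adap <- erspconn:::window_idx(ep$time_ms, 1000, 2000)
  for (band in list(c(8, 14), c(15, 35))) {
    ratio <- mean(vapply(seq_len(120), function(tr) {
      oracle_band_power(ep$data[tr, 5, adap], ep$fs, band) /
        oracle_band_power(ep$data[tr, 5, rest], ep$fs, band)
    }, numeric(1)))
    expect_lt(abs(10 * log10(ratio)), 0.5)
  }
})

test_that("power modulation scales band power by the stated dB", {
  eff <- effect_spec("power_modulation", channels = c("P3", "P4", "PPO1h",
                                                      "PPO2h"),
                     band = c(8, 14), window = c(1000, 2000),
                     magnitude = -3)
  cfg <- simulation_config(n_subjects = 1, n_trials_per_condition = 100,
                           effects = list(eff), seed = 12)
  ep <- simulate_dataset(cfg)$subjects[[1]]
  ep0 <- simulate_dataset(
    simulation_config(n_subjects = 1, n_trials_per_condition = 100,
                      seed = 12))$subjects[[1]]
  win <- erspconn:::window_idx(ep$time_ms, 1050, 1950)  # taper interior
  rest <- erspconn:::window_idx(ep$time_ms, -4000, -2000)
  ch <- match("P3", ep$labels)
  delta <- 10 * log10(mean(vapply(seq_len(200), function(tr)
    oracle_band_power(ep$data[tr, ch, win], ep$fs, c(8, 14)) /
      oracle_band_power(ep0$data[tr, ch, win], ep0$fs, c(8, 14)),
    numeric(1))))
  expect_lt(abs(delta - (-3)), 0.7)
  # non-target window unchanged
  delta_rest <- 10 * log10(mean(vapply(seq_len(200), function(tr)
    oracle_band_power(ep$data[tr, ch, rest], ep$fs, c(8, 14)) /
      oracle_band_power(ep0$data[tr, ch, rest], ep0$fs, c(8, 14)),
    numeric(1))))
  expect_lt(abs(delta_rest), 0.5)
  # non-target channel untouched exactly
  other <- match("F1", ep$labels)
  expect_identical(ep$data[, other, ], ep0$data[, other, ])
})

test_that("zero-magnitude modulation is the identity", {
  set.seed(1)
  ep <- make_noise_epochs(3, c("P3", "F1"))
  out <- inject_power_modulation(ep, effect_spec(
    "power_modulation", channels = "P3", band = c(8, 14),
    window = c(1000, 2000), magnitude = 0))
  expect_identical(out$data, ep$data)
})

test_that("lagged coupling produces imaginary coherence; zero lag does not", {
  mk_ep <- function(lag, n_tr, seed) {
    cfg <- simulation_config(
      n_subjects = 1, n_trials_per_condition = ceiling(n_tr / 2),
      effects = list(effect_spec("lagged_coupling", source = "POO1",
                                 channels = "AFp1", band = c(8, 12),
                                 window = c(1000, 2000), magnitude = 0.8,
                                 phase_lag = lag)),
      seed = seed)
    simulate_dataset(cfg)$subjects[[1]]
  }
  mean_cicoh <- function(ep, n_tr) {
    mtc <- multitaper_config()
    n <- spectral_grid(ep$fs, mtc)$n_window
    toi <- erspconn:::window_idx(ep$time_ms, 1000, 2000)[seq_len(n)]
    idx <- match(c("POO1", "AFp1"), ep$labels)
    mean(vapply(seq_len(n_tr), function(tr) {
      cs <- cross_spectrum(ep$data[tr, idx, toi], ep$fs, mtc)
      fsel <- cs$freqs >= 8 & cs$freqs <= 12
      mean(cicoh(coherency(cs))[1, 2, fsel])
    }, numeric(1)))
  }
  ep <- mk_ep(pi / 2, 100, 21)
  expect_gt(abs(mean_cicoh(ep, 100)), 0.3)
  ep0 <- mk_ep(0, 500, 22)
  expect_lt(abs(mean_cicoh(ep0, 500)), 0.05)
})

test_that("coupling confined to the adaptation window raises ER-ciCOH at targets", {
  cfg <- simulation_config(
    n_subjects = 1, n_trials_per_condition = 50,
    effects = list(effect_spec("lagged_coupling", source = "POO1",
                               channels = c("AFp1", "AFp2"),
                               band = c(8, 12), window = c(1000, 2000),
                               magnitude = 0.8, phase_lag = pi / 2)),
    seed = 23)
  ep <- simulate_dataset(cfg)$subjects[[1]]
  m <- er_cicoh(ep, bands = list(alpha = c(8, 14)))
  v <- rowMeans(m$values[, "alpha", , drop = FALSE][, 1, ])
  others <- setdiff(names(v), c("AFp1", "AFp2", "POO1", "POO2"))
  # targets well above the ratio-estimator noise floor of the rest
  expect_gt(min(v[c("AFp1", "AFp2")]), max(0.5, quantile(v[others], 0.95)))
})

test_that("zero-lag mixing leaves ciCOH at zero while |COH| is high", {
  mtc <- multitaper_config()
  set.seed(24)
  mix <- matrix(c(1, 0.6, 0.6, 1), 2)
  acc_coh <- 0; acc_ci <- 0; n_tr <- 500
  ci_all <- numeric(n_tr)
  for (tr in seq_len(n_tr)) {
    x <- mix %*% matrix(rnorm(2 * 250), 2)
    cs <- cross_spectrum(x, 250, mtc)
    coh <- coherency(cs)
    fsel <- cs$freqs >= 8 & cs$freqs <= 14
    acc_coh <- acc_coh + mean(Mod(coh$COH[1, 2, fsel])) / n_tr
    ci_all[tr] <- mean(cicoh(coh)[1, 2, fsel])
  }
  expect_gt(acc_coh, 0.3)
  expect_lt(abs(mean(ci_all)), 0.05)
  # |mean ciCOH| < 2 SE over the simulated trials
  expect_lt(abs(mean(ci_all)), 2 * sd(ci_all) / sqrt(n_tr))
})

test_that("apply_mixing validates shape, preserves rank, identity is exact", {
  set.seed(25)
  ep <- make_noise_epochs(2, c("A", "B", "C"), n_samples = 400)
  expect_error(apply_mixing(ep, diag(2)), "3 x 3")
  out <- apply_mixing(ep, diag(3))
  expect_equal(out$data, ep$data)
  mix <- matrix(c(1, .2, .1, .3, 1, .2, .1, .1, 1), 3)
  out2 <- apply_mixing(ep, mix)
  expect_equal(qr(out2$data[1, , ])$rank, qr(ep$data[1, , ])$rank)
})

test_that("amplitude artifacts are ledgered and trigger only the frontal rule", {
  cfg <- simulation_config(
    n_subjects = 1, n_trials_per_condition = 5,
    effects = list(effect_spec("amplitude_artifact", channels = "AFp1",
                               window = c(-3500, -3100), magnitude = 250,
                               trials = c(3, 7))),
    seed = 26)
  ds <- simulate_dataset(cfg)
  ep <- reject_amplitude(ds$subjects[[1]])
  art <- Filter(function(e) e$effect$kind == "amplitude_artifact",
                ds$ledger)
  expect_equal(art[[1]]$trials, c(3, 7))
  expect_equal(which(!ep$kept_mask), c(3, 7))
  # same artifact on a non-frontal channel: frontal rule keeps everything
  cfg2 <- simulation_config(
    n_subjects = 1, n_trials_per_condition = 5,
    effects = list(effect_spec("amplitude_artifact", channels = "Pz",
                               window = c(-3500, -3100), magnitude = 250,
                               trials = c(3, 7))),
    seed = 26)
  ep2 <- reject_amplitude(simulate_dataset(cfg2)$subjects[[1]])
  expect_true(all(ep2$kept_mask))
})

test_that("effect validation catches bad configurations", {
  expect_error(effect_spec("wobble"), "unknown effect kind")
  expect_error(effect_spec("power_modulation", channels = "P3",
                           band = c(8, 14), phase_lag = 1, window = NULL),
               NA)  # lag with band is fine
  expect_error(effect_spec("power_modulation", phase_lag = 1),
               "without a frequency band")
  expect_error(simulation_config(fs = 100, effects = list(
    effect_spec("power_modulation", channels = "P3", band = c(35, 60),
                window = c(0, 500), magnitude = -3))),
    "Nyquist")
  expect_error(simulate_dataset(simulation_config(effects = list(
    effect_spec("power_modulation", channels = "NOPE", band = c(8, 14),
                window = c(0, 500), magnitude = -3)))),
    "NOPE")
})

test_that("the ground-truth ledger records every injected effect", {
  effects <- list(
    effect_spec("power_modulation", channels = "P3", band = c(8, 14),
                window = c(1000, 2000), magnitude = -3,
                condition = "supportive"),
    effect_spec("lagged_coupling", source = "POO1", channels = "F1",
                band = c(35, 45), window = c(1000, 2000), magnitude = 0.5,
                phase_lag = pi / 2),
    effect_spec("amplitude_artifact", channels = "AFp1", magnitude = 300,
                trials = 1))
  ds <- simulate_dataset(simulation_config(
    n_subjects = 2, n_trials_per_condition = 3, effects = effects,
    seed = 27))
  expect_length(ds$ledger, 3 * 2)
  kinds <- vapply(ds$ledger, function(e) e$effect$kind, character(1))
  expect_equal(sort(unique(kinds)),
               c("amplitude_artifact", "lagged_coupling",
                 "power_modulation"))
  subj <- vapply(ds$ledger, function(e) e$subject, numeric(1))
  expect_setequal(unique(subj), c(1, 2))
  # condition-restricted effect touches only supportive trials
  pm <- Filter(function(e) e$effect$kind == "power_modulation", ds$ledger)
  expect_true(all(ds$subjects[[1]]$condition[pm[[1]]$trials] ==
                    "supportive"))
})
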