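test_that("DPSS construction yields the expected taper family", {
  d <- dpss_tapers(1000, 3)
  expect_equal(nrow(d$tapers), 5)                  # 2*3 - 1
  # orthonormal within 1e-8
  expect_lt(max(abs(tcrossprod(d$tapers) - diag(5))), 1e-8)
  # concentrations strictly decreasing, all well-concentrated
  expect_true(all(diff(d$eigenvalues) < 0))
  expect_equal(sum(d$eigenvalues > 0.9), 5)
  expect_error(dpss_tapers(4, 3), "tapers")
})

test_that("spectral grid reproduces the stated resolution", {
  g <- spectral_grid(1000, multitaper_config())
  expect_equal(g$n_window, 1000)
  expect_equal(g$nfft, 1024)
  expect_equal(round(g$df, 2), 0.98)
})

test_that("cross-spectra are Hermitian with sensible auto-spectra", {
  set.seed(61)
  mtc <- multitaper_config()
  x <- matrix(rnorm(3 * 250), 3)
  cs <- cross_spectrum(x, 250, mtc)
  for (f in c(3, 20, 70)) {
    s <- cs$S[, , f]
    expect_equal(s, Conj(t(s)))
    expect_true(all(Re(diag(s)) >= 0))
    expect_lt(max(abs(Im(diag(s)))), 1e-12)
  }
  expect_error(cross_spectrum(matrix(c(1, NA, 3, 4), 2), 250, mtc), "NaN")
  # white noise: averaged auto-spectrum flat within 3 dB over 5-45 Hz
  acc <- 0
  for (tr in 1:100)
    acc <- acc + Re(cross_spectrum(matrix(rnorm(250), 1), 250,
                                   mtc)$S[1, 1, ]) / 100
  fsel <- cs$freqs >= 5 & cs$freqs <= 45
  expect_lt(10 * log10(max(acc[fsel]) / min(acc[fsel])), 3)
  # a 10 Hz tone peaks at the nearest bin
  tone <- sin(2 * pi * 10 * (1:250) / 250)
  cst <- cross_spectrum(matrix(tone, 1), 250, mtc)
  pk <- cst$freqs[which.max(Re(cst$S[1, 1, ]))]
  expect_lt(abs(pk - 10), 2 * diff(cst$freqs)[1])
})

test_that("coherency is normalized, symmetric in magnitude, unity on the diagonal", {
  set.seed(62)
  mtc <- multitaper_config()
  cs <- cross_spectrum(matrix(rnorm(3 * 250), 3), 250, mtc)
  coh <- coherency(cs)$COH
  expect_true(all(Mod(coh) <= 1 + 1e-9))
  for (f in c(5, 40)) {
    expect_equal(diag(coh[, , f]), rep(1 + 0i, 3))
    expect_equal(Mod(coh[1, 2, f]), Mod(coh[2, 1, f]))
  }
  # independent channels: trial-averaged |COH| small at 500 trials
  acc <- 0
  for (tr in 1:500) {
    c2 <- cross_spectrum(matrix(rnorm(2 * 250), 2), 250, mtc)
    acc <- acc + coherency(c2)$COH[1, 2, ] / 500
  }
  expect_lt(max(Mod(acc)), 0.1)
  # zero auto-spectrum errors
  cs0 <- cs
  cs0$S[1, 1, ] <- 0
  expect_error(coherency(cs0), "zero auto-spectrum")
})

test_that("ciCOH matches the direct formula on random coherencies", {
  set.seed(63)
  # random coherency values inside the unit disk
  re <- runif(500, -0.99, 0.99)
  im_max <- sqrt(1 - re^2)
  im <- runif(500, -1, 1) * im_max * 0.999
  z <- complex(real = re, imaginary = im)
  got <- cicoh(z)
  oracle <- vapply(seq_along(z), function(i)
    Im(z[i]) / sqrt(1 - Re(z[i])^2), numeric(1))
  expect_equal(got, oracle, tolerance = 1e-12)
  expect_true(all(abs(got) <= 1))
  # fixed points of the definition
  expect_equal(cicoh(0.7 + 0i), 0)
  expect_equal(cicoh(0 + 0.5i), 0.5)
  # degenerate pure-real coherency maps to 0 (the self-coherency case)
  expect_equal(cicoh(1 + 0i), 0)
})

test_that("fisher z is atanh with clipping", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), atanh(0.5))
  x <- seq(-0.9, 0.9, by = 0.1)
  expect_equal(fisher_z(-x), -fisher_z(x))
  expect_warning(z <- fisher_z(1), "clipped")
  expect_true(is.finite(z))
})

test_that("the event-related contrast follows its definition", {
  expect_equal(er_contrast(0.2, 0.1), 1)
  expect_equal(er_contrast(0.15, 0.15), 0)
  # floor guards the denominator
  expect_equal(er_contrast(0.1, 0), 0.1 / 1e-3)
})

test_that("band averaging commutes with trial averaging", {
  set.seed(64)
  x <- array(runif(10 * 7), c(10, 7))      # trials x freq bins
  expect_equal(mean(rowMeans(x)), mean(colMeans(x)))
})

test_that("er_cicoh recovers window-confined coupling at target electrodes", {
  cfg <- simulation_config(
    n_subjects = 1, n_trials_per_condition = 40,
    effects = list(effect_spec("lagged_coupling", source = "POO1",
                               channels = c("F1", "F2"), band = c(16, 24),
                               window = c(1000, 2000), magnitude = 0.8,
                               phase_lag = pi / 2,
                               condition = "supportive")),
    seed = 65)
  ep <- simulate_dataset(cfg)$subjects[[1]]
  m <- er_cicoh(ep, bands = list(beta = c(15, 35)))
  expect_true(all(is.na(m$values[c("POO1", "POO2"), , ])))
  sup <- m$values[, "beta", "supportive"]
  imp <- m$values[, "beta", "impeding"]
  # targets stand out in the supportive map but not the impeding one;
  # the contrast between conditions cancels the ratio-estimator bias
  diffv <- sup - imp
  others <- setdiff(names(diffv), c("F1", "F2", "POO1", "POO2"))
  expect_gt(min(diffv[c("F1", "F2")]), 0.4)
  expect_lt(max(abs(diffv[others])), 0.4)
})
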