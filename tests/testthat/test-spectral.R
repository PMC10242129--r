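test_that("bipolar derivation cancels common signal exactly", {
  set.seed(51)
  n <- 1000
  s <- rnorm(n); c0 <- rnorm(n)
  rec <- lfp_recording(rbind(s + c0, c0), fs = 500,
                       channel_ids = c("ch001", "ch002"))
  em <- tiny_emap(2)
  bp <- bipolar_pairs(rec, em)
  expect_equal(nrow(bp$pairs), 1)
  # algebraic identity (s + c) - c = s, up to one float rounding
  expect_equal(bp$series[1, ], s, tolerance = 1e-12)
  # identical channels give the all-zero differential
  rec0 <- lfp_recording(rbind(c0, c0), fs = 500,
                        channel_ids = c("ch001", "ch002"))
  expect_true(all(bipolar_pairs(rec0, em)$series == 0))
})

test_that("pair enumeration respects mode and structure boundaries", {
  set.seed(52)
  rec <- lfp_recording(matrix(rnorm(6 * 200), 6), fs = 100,
                       channel_ids = sprintf("ch%03d", 1:6))
  em4 <- tiny_emap(6)
  em4$anatomical_label[5:6] <- "lonely"          # 4 + 2 channel structures
  em4$row[5:6] <- 5:6; em4$col[5:6] <- 0
  bp <- bipolar_pairs(rec, electrode_map(as.data.frame(em4)))
  expect_equal(sum(bp$pairs$structure == "mPFC"), choose(4, 2))
  # neighbors mode: Chebyshev distance 1 on the (row, col) grid
  bn <- bipolar_pairs(rec, electrode_map(as.data.frame(em4)),
                      mode = "neighbors")
  grid <- as.data.frame(em4)[, c("row", "col")]
  for (k in seq_len(nrow(bn$pairs))) {
    i <- match(bn$pairs$chan_i[k], em4$channel_id)
    j <- match(bn$pairs$chan_j[k], em4$channel_id)
    expect_equal(max(abs(grid[i, ] - grid[j, ])), 1)
  }
  one <- tiny_emap(1)
  rec1 <- lfp_recording(matrix(rnorm(200), 1), fs = 100,
                        channel_ids = "ch001")
  expect_error(suppressMessages(bipolar_pairs(rec1, one)), ">= 2 channels")
})

test_that("spectrogram has density scaling and satisfies Parseval per window", {
  set.seed(53)
  fs <- 1000
  x <- rnorm(60 * fs)
  sg <- compute_spectrogram(x, fs, window_s = 2, overlap_frac = 0.5)
  # unit-variance white noise: one-sided density 2/fs
  expect_lt(abs(mean(sg$power) - 2 / fs) / (2 / fs), 0.05)
  # Parseval identity per window, within 1%
  nper <- 2 * fs
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nper) - 1) / nper)
  df <- fs / nper
  for (k in c(1, 10, 30)) {
    i0 <- (k - 1) * nper / 2
    seg <- x[(i0 + 1):(i0 + nper)]
    expect_lt(abs(sum(sg$power[k, ]) * df -
                    sum((w * seg)^2) / sum(w^2)) /
                (sum((w * seg)^2) / sum(w^2)), 0.01)
  }
  # pure tone lands in its own bin; constant signal is all DC
  t <- seq_len(4 * fs) / fs
  sg50 <- compute_spectrogram(sin(2 * pi * 50 * t), fs, 2)
  expect_equal(sg50$freqs[which.max(sg50$power[1, ])], 50)
  # constant signal: all power at DC, bar the Hann taper's one-bin leakage
  sgdc <- compute_spectrogram(rep(3, 4 * fs), fs, 2)
  expect_equal(which.max(sgdc$power[1, ]), 1)
  expect_lt(sum(sgdc$power[1, -(1:2)]), sgdc$power[1, 1] * 1e-12)
  expect_error(compute_spectrogram(rnorm(100), fs, 2), "shorter")
  expect_error(compute_spectrogram(rnorm(100), 10, 2), ">= 64")
})

test_that("median spectrum selects windows by center and is robust", {
  sg <- list(power = rbind(rep(1, 4), rep(1, 4), rep(100, 4)),
             freqs = c(1, 2, 3, 4), times = c(0.5, 1.5, 2.5),
             fs = 4, window_s = 1)
  class(sg) <- "lfp_spectrogram"
  ms <- median_spectrum(sg)
  expect_equal(ms$power, rep(1, 4))              # robust to the transient
  one <- median_spectrum(sg, c(2, 3))            # single qualifying window
  expect_equal(one$power, rep(100, 4))
  expect_error(median_spectrum(sg, c(10, 20)), "no spectrogram window")
})

test_that("median across windows tracks the chi-square prediction", {
  # each windowed periodogram bin is ~exponential, so the across-window
  # median sits near ln 2 of the mean
  set.seed(54)
  sg <- compute_spectrogram(rnorm(120 * 500), 500, 2, 0)
  med <- apply(sg$power, 2, stats::median)
  mn <- colMeans(sg$power)
  ratio <- median(med / mn)
  expect_lt(abs(ratio - log(2)), 0.07)
})

test_that("power-law fit is exact on noiseless spectra over the whole grid", {
  f_lin <- seq(1, 300, by = 0.25)
  f_irr <- sort(c(seq(1, 40, by = 0.13), seq(40.5, 300, by = 2.1)))
  for (A in c(-3, -1, 0, 1.5, 3)) {
    for (B in c(0, 0.5, 2, 4)) {
      for (f in list(f_lin, f_irr)) {
        fit <- fit_powerlaw(power_spectrum(f, 10^A / f^B), c(1, 300))
        expect_lt(abs(fit$A - A), 1e-10)
        expect_lt(abs(fit$B - B), 1e-10)
        expect_gt(fit$r2_loglog, 1 - 1e-10)
      }
    }
  }
  flat <- fit_powerlaw(power_spectrum(f_lin, rep(10^0.5, length(f_lin))),
                       c(1, 300))
  expect_equal(unname(coef(flat)), c(0.5, 0), tolerance = 1e-12)
})

test_that("power-law fit rejects degenerate input", {
  f <- seq(1, 300, by = 1)
  p <- 10 / f
  p[30] <- -1
  expect_error(fit_powerlaw(power_spectrum(f, p)), "nonpositive|positive")
  expect_error(fit_powerlaw(power_spectrum(f[1:5], p[1:5]), c(1, 300)),
               ">= 10 bins")
})

test_that("offset and exponent separate cleanly (scaling identities)", {
  f <- seq(1, 300, by = 0.5)
  base <- fit_powerlaw(power_spectrum(f, 10^1 / f^2))
  up <- fit_powerlaw(power_spectrum(f, 10^0.7 * 10^1 / f^2))
  expect_equal(up$A - base$A, 0.7, tolerance = 1e-10)
  expect_equal(up$B, base$B, tolerance = 1e-10)
  steeper <- fit_powerlaw(power_spectrum(f, 10^1 / f^2.6))
  expect_equal(steeper$A, base$A, tolerance = 1e-10)
  expect_equal(steeper$B - base$B, 0.6, tolerance = 1e-10)
})

test_that("aperiodic separation masks humps and spikes, not power laws", {
  f <- seq(1, 300, by = 0.5)
  pure <- power_spectrum(f, 10^1.2 / f^1.8)
  sep <- separate_aperiodic(pure, mains = NULL)
  expect_length(sep$excluded_bands, 0)
  expect_equal(sep$aperiodic$power, pure$power)
  # power law + gaussian hump at 140 Hz, +10 dB at peak
  bump <- 10^1.2 / f^1.8 * (1 + 9 * exp(-(f - 145)^2 / (2 * 8^2)))
  sepb <- separate_aperiodic(power_spectrum(f, bump), mains = NULL)
  covered <- vapply(sepb$excluded_bands,
                    function(b) b[1] <= 135 && b[2] >= 155, logical(1))
  expect_true(any(covered))
  fitb <- fit_powerlaw(sepb$aperiodic)
  expect_lt(abs(fitb$B - 1.8), 0.05)
  expect_lt(abs(fitb$A - 1.2), 0.05)
  # flat spectrum with one spiked bin: that bin is excluded
  sp <- rep(1, length(f)); sp[200] <- 50
  seps <- separate_aperiodic(power_spectrum(f, sp), mains = NULL)
  expect_true(any(vapply(seps$excluded_bands,
                         function(b) b[1] <= f[200] && b[2] >= f[200],
                         logical(1))))
})

test_that("separation never hurts on bump-free spectra and flags mains", {
  set.seed(55)
  x <- generate_aperiodic_noise(0.8, 1.5, 1000, 60)
  sp <- median_spectrum(compute_spectrogram(x, 1000))
  direct <- fit_powerlaw(sp)
  sep <- fit_aperiodic(sp, mains = 50)
  expect_lte(abs(sep$B - 1.5), abs(direct$B - 1.5) + 0.02)
  # mains bands always excluded
  expect_true(any(vapply(sep$excluded_bands,
                         function(b) b[1] <= 50 && b[2] >= 50, logical(1))))
})

test_that("aperiodic_fit behaves like a model object", {
  f <- seq(1, 300, by = 0.5)
  fit <- fit_powerlaw(power_spectrum(f, 10^1 / f^2))
  expect_named(coef(fit), c("offset", "exponent"))
  expect_equal(predict(fit, c(1, 10)), c(10, 0.1), tolerance = 1e-10)
  expect_lt(max(abs(residuals(fit))), 1e-10)
  expect_output(print(fit), "offset")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("per-structure spectral change table summarizes per-pair fits", {
  sim <- std_sim()
  sc <- structure_spectral_change(sim$recording, sim$emap,
                                  baseline_epoch = c(-210, -30),
                                  post_epoch = c(30, 210))
  expect_equal(nrow(sc), 4)
  expect_true(all(sc$n_pairs == choose(6, 2)))
  fits <- attr(sc, "pair_fits")
  expect_equal(nrow(fits), 4 * 15 * 2)
  # fitted baseline exponents near the generator truth
  expect_lt(max(abs(sc$B_base - 2)), 0.1)
})
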