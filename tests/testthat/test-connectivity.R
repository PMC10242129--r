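test_that("copula transform maps ranks onto the normal quantile grid", {
  x <- c(10, 2, 7)
  expect_equal(copula_transform(x),
               stats::qnorm(c(3, 1, 2) / 4))
  expect_equal(stats::qnorm(c(0.25, 0.5, 0.75)),
               sort(copula_transform(x)), tolerance = 1e-12)
  srt <- sort(rnorm(20))
  expect_equal(copula_transform(srt), stats::qnorm(1:20 / 21))
  # invariance under strictly increasing transforms, elementwise identical
  z <- rnorm(50)
  expect_identical(copula_transform(z), copula_transform(exp(z)))
  expect_identical(copula_transform(z), copula_transform(z^3))
  expect_error(copula_transform(rep(1, 20)), "constant")
})

test_that("GCMI matches the closed-form Gaussian MI", {
  # oracle: I = -0.5 * log2(1 - rho^2) for a bivariate Gaussian
  set.seed(61)
  n <- 4000
  for (rho in c(0.4, 0.8)) {
    err <- mean(replicate(10, {
      x <- rnorm(n); y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
      gcmi_pair(x, y) - (-0.5 * log2(1 - rho^2))
    }))
    expect_lt(abs(err), 0.02)
  }
  # independence null with bias correction
  x <- rnorm(n); y <- rnorm(n)
  expect_lt(abs(gcmi_pair(x, y)), 0.01)
})

test_that("GCMI is symmetric, unit-aware and guards edge cases", {
  set.seed(62)
  x <- rnorm(500); y <- 0.5 * x + rnorm(500)
  expect_identical(gcmi_pair(x, y), gcmi_pair(y, x))
  expect_equal(gcmi_pair(x, y, units = "nats"),
               gcmi_pair(x, y, units = "bits") * log(2), tolerance = 1e-12)
  expect_warning(res <- gcmi_pair(x, 2 * x + 1), "singular|dependent")
  expect_true(is.infinite(res))
  expect_error(gcmi_pair(x[1:5], y[1:5]), "n >= 8")
  expect_error(gcmi_pair(x, y[1:10]), "equal length")
})

test_that("GCMI is invariant to positive rescaling of either channel", {
  set.seed(63)
  x <- rnorm(300); y <- 0.6 * x + rnorm(300)
  base <- gcmi_pair(x, y)
  expect_identical(gcmi_pair(1e4 * x, y), base)
  expect_identical(gcmi_pair(x, 1e-3 * y), base)
})

test_that("windowed MI tiles epochs with floor(T / window)", {
  set.seed(64)
  rec <- lfp_recording(matrix(rnorm(3 * 90000), 3), fs = 100, t0 = -450,
                       channel_ids = sprintf("ch%03d", 1:3))
  mw <- windowed_mi(rec, c(-450, 450), window_s = 2)
  expect_equal(ncol(mw$mi), 450)                  # 15 min / 2 s
  expect_equal(nrow(mw$pairs), 3)
  expect_equal(mw$n_per_window, 200)
  short <- windowed_mi(rec, c(-450, -445), window_s = 2)
  expect_equal(ncol(short$mi), 2)                 # 5 s -> 2, remainder dropped
  # stationary coupled pair: window-median close to full-epoch MI
  n <- 60000
  s <- rnorm(n)
  rec2 <- lfp_recording(rbind(rnorm(n) + s, rnorm(n) + s), fs = 100,
                        channel_ids = c("a", "b"))
  mw2 <- windowed_mi(rec2, c(0, 600), window_s = 10)
  full <- gcmi_pair(rec2$data[1, ], rec2$data[2, ])
  expect_lt(abs(stats::median(mw2$mi[1, ]) - full), 0.05)
})

test_that("pair connectivity forms medians, ratios and the floor flag", {
  mk <- function(mi) structure(list(
    pairs = data.frame(chan_i = c("a", "c"), chan_j = c("b", "d")),
    mi = mi, times = seq_len(ncol(mi)), n_per_window = 100,
    units = "bits"), class = "mi_window_series")
  base <- mk(rbind(c(0.2, 0.3, 0.4), c(1e-5, -1e-4, 1e-5)))
  post <- mk(rbind(c(0.1, 0.15, 0.2), c(1e-5, 1e-5, 1e-5)))
  pc <- pair_connectivity(base, post)
  expect_equal(pc$mi_base[1], 0.3)
  expect_equal(pc$ratio[1], 0.15 / 0.3)
  expect_false(pc$reliable[2])                   # below the 0.001 floor
  expect_true(is.na(pc$ratio[2]))
  ident <- pair_connectivity(base, base)
  expect_equal(ident$ratio[1], 1)
})

test_that("baseline split control stays near unity under stationarity", {
  # pink (1/f) background: red (1/f^2) noise needs far longer halves for
  # its low-frequency band power to stabilise (see methods vignette)
  cfg <- sim_config(
    structures = four_structures()[1:2, ], fs = 250, A = 1, B = 1,
    duration_pre = 660, duration_post = 10,
    oscillations = list(list(center = 60, bandwidth = 20,
                             amplitude = 0.5, channels = 1:12)),
    drug_effect = list(dA = 0, dB = 0, coupling_scale = 1), seed = 101)
  sim <- simulate_experiment(cfg)
  ctrl <- baseline_control(sim$recording, c(-630, -30), window_s = 2)
  expect_gt(stats::median(ctrl$ratio, na.rm = TRUE), 0.95)
  expect_lt(stats::median(ctrl$ratio, na.rm = TRUE), 1.05)
  expect_error(baseline_control(sim$recording, c(-3, -2), window_s = 2),
               "too short")
})

test_that("baseline control is sensitive to an injected trend", {
  set.seed(65)
  n <- 120000
  s1 <- rnorm(n); s2 <- rnorm(n)
  gain <- seq(0.2, 2, length.out = n)           # coupling grows in time
  shared <- rnorm(n) * gain
  rec <- lfp_recording(rbind(s1 + shared, s2 + shared), fs = 200,
                       t0 = -600, channel_ids = c("a", "b"))
  ctrl <- baseline_control(rec, c(-600, 0), window_s = 2)
  expect_gt(ctrl$ratio[1], 1.3)                  # second half more coupled
})

test_that("structure summary: symmetry, scopes and the uniform-ratio fit", {
  pc <- data.frame(chan_i = c("ch001", "ch001", "ch003", "ch002"),
                   chan_j = c("ch002", "ch003", "ch004", "ch004"),
                   mi_base = c(0.5, 0.2, 0.4, 0.3),
                   mi_post = 0.8 * c(0.5, 0.2, 0.4, 0.3),
                   ratio = rep(0.8, 4), reliable = TRUE)
  class(pc) <- c("pair_connectivity", class(pc))
  em <- tiny_emap(4)
  em$anatomical_label[3:4] <- "S1"; em$region[3:4] <- "SenC"
  em <- electrode_map(as.data.frame(em))
  ss <- structure_summary(pc, em)
  expect_true(isSymmetric(ss$matrix))
  expect_equal(sum(ss$pairs$within), 2)
  # uniform ratio r: fitted slope r, R^2 = 1, in both scopes
  expect_equal(ss$fits$slope, c(0.8, 0.8), tolerance = 1e-10)
  expect_equal(ss$fits$r_squared, c(1, 1), tolerance = 1e-10)
  expect_equal(ss$matrix["PFC", "PFC"], 0.8)
})

test_that("within-structure baseline connectivity exceeds between", {
  sim <- std_sim()
  mb <- windowed_mi(sim$recording, c(-210, -30))
  mp <- windowed_mi(sim$recording, c(30, 210))
  ss <- structure_summary(pair_connectivity(mb, mp), sim$emap)
  w <- ss$pairs$within & ss$pairs$reliable
  b <- !ss$pairs$within & ss$pairs$reliable
  expect_gt(mean(ss$pairs$mi_base[w]), mean(ss$pairs$mi_base[b]))
  expect_gt(ss$within_between_pct, 0)
  # null drug: ratios near unity in both scopes
  expect_lt(abs(stats::median(ss$pairs$ratio[w]) - 1), 0.1)
})
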