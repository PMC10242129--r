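# Shared fixtures, memoised so expensive simulations are built once per
# test run. All sizes are scaled-down desk versions of the experiment
# timeline (injection at t = 0, baseline before, drug epoch after).

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures))
    assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

four_structures <- function(n_channels = 6L) {
  data.frame(structure = c("mPFC", "S1", "MD", "NAc"),
             region = c("PFC", "SenC", "IntTh", "vStr"),
             n_channels = n_channels)
}

# null experiment (no drug effect), heterogeneous coupling
std_sim <- function() fixture("std_sim", function() {
  simulate_experiment(sim_config(
    structures = four_structures(), fs = 1000,
    duration_pre = 240, duration_post = 240,
    drug_effect = list(dA = 0, dB = 0, coupling_scale = 1), seed = 101))
})

# tiny electrode map built by hand
tiny_emap <- function(n = 6, region = "PFC", structure = "mPFC",
                      animals = rep("rat01", n)) {
  electrode_map(data.frame(
    channel_id = sprintf("ch%03d", seq_len(n)),
    animal_id = animals,
    anatomical_label = rep(structure, n), region = rep(region, n),
    ap_mm = rep(NA_real_, n), ml_mm = rep(NA_real_, n),
    dv_mm = rep(NA_real_, n),
    row = (seq_len(n) - 1L) %/% 4L, col = (seq_len(n) - 1L) %% 4L))
}

# independent oracle for the aperiodic fit: smoothed periodogram
# (stats::spec.pgram, no code shared with the package's Welch path)
# regressed log-log over a frequency band
oracle_loglog_fit <- function(x, fs, band = c(1, 300)) {
  sp <- stats::spec.pgram(stats::ts(x, frequency = fs), spans = 51,
                          taper = 0.1, plot = FALSE, detrend = FALSE)
  keep <- sp$freq >= band[1] & sp$freq <= band[2]
  # spec.pgram returns power per unit frequency (two-sided convention);
  # only the slope/intercept relationship matters for the oracle
  cf <- stats::coef(stats::lm(log10(sp$spec[keep]) ~ log10(sp$freq[keep])))
  c(A = unname(cf[1]), B = unname(-cf[2]))
}

# exhaustive-enumeration oracles for the Wilcoxon tests
enum_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  min(1, 2 * min(mean(v_all <= v_obs), mean(v_all >= v_obs)))
}

enum_rank_sum_p <- function(g1, g2) {
  n1 <- length(g1)
  r <- rank(c(g1, g2))
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- utils::combn(length(r), n1)
  w_all <- apply(idx, 2, function(i) sum(r[i])) - n1 * (n1 + 1) / 2
  min(1, 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs)))
}
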