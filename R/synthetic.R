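# Synthetic multi-structure LFP generator with known spectral and coupling
# ground truth. Channels are built as
#   private 1/f^B noise + sum_k loading[k] * latent source_k + common mode
# (+ narrowband oscillations on selected channels), with a step change in
# (A, B, coupling) at t = 0 emulating a systemic drug injection.

#' Generate aperiodic (1/f^B) noise by spectral shaping
#'
#' Gaussian white noise is shaped in the frequency domain so that its
#' expected one-sided power spectral density is exactly
#' `10^A / f^B` (microvolts^2/Hz). The DC coefficient is zeroed to avoid the
#' 1/f singularity; analyses fit from 1 Hz upward so this is invisible to
#' the power-law fit.
#'
#' @param A Offset, log10(uV^2/Hz) at 1 Hz.
#' @param B Aperiodic exponent (>= 0); `B = 0` gives white noise.
#' @param fs Sampling rate, Hz (> 0).
#' @param duration Duration in seconds (> 0, with `duration * fs >= 2`).
#' @param seed Optional integer; identical seeds give bit-identical series.
#' @return Numeric vector of `round(duration * fs)` samples (microvolts).
#' @export
generate_aperiodic_noise <- function(A, B, fs, duration, seed = NULL) {
  if (!is.numeric(fs) || fs <= 0) stop("fs must be positive, got ", fs)
  if (!is.numeric(duration) || duration <= 0)
    stop("duration must be positive, got ", duration)
  if (B < 0) stop("exponent B must be >= 0")
  n <- as.integer(round(duration * fs))
  if (n < 2L) stop("duration * fs must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  w <- stats::rnorm(n)
  shape_noise_spectrum(w, A, B, fs)
}

# Shape an existing white-noise vector to one-sided PSD 10^A/f^B.
shape_noise_spectrum <- function(w, A, B, fs) {
  n <- length(w)
  k <- 0:(n - 1L)
  f <- pmin(k, n - k) * fs / n          # symmetric frequency of each bin
  psd <- ifelse(f > 0, 10^A / f^B, 0)   # target one-sided density
  gain <- sqrt(psd * fs / 2)            # unit-variance white PSD is 2/fs
  x <- Re(stats::fft(stats::fft(w) * gain, inverse = TRUE) / n)
  x
}

# Narrowband oscillation: band-pass filtered Gaussian noise scaled to a
# target in-band RMS amplitude (uV). Filtered noise, not a sinusoid, so the
# spectral signature is a hump of finite bandwidth.
make_oscillation <- function(center, bandwidth, amplitude, fs, n) {
  lo <- center - bandwidth / 2
  hi <- center + bandwidth / 2
  if (lo <= 0 || hi >= fs / 2)
    stop("oscillation band [", lo, ", ", hi, "] Hz outside (0, fs/2)")
  filt <- signal::butter(4, c(lo, hi) / (fs / 2), type = "pass")
  x <- signal::filtfilt(filt, stats::rnorm(n))
  x * amplitude / stats::sd(x)
}

#' Simulation configuration
#'
#' Defines a multi-structure recording: per-channel aperiodic parameters,
#' latent coupling sources, oscillations, a global common-mode signal and a
#' step drug effect at t = 0.
#'
#' @param structures Data frame with columns `structure`, `region`,
#'   `n_channels` and optionally `n_animals` (default 3): each structure
#'   contributes `n_channels` channels assigned round-robin to its animals.
#' @param fs Sampling rate, Hz.
#' @param duration_pre,duration_post Seconds of recording before/after the
#'   injection at t = 0.
#' @param A,B Baseline aperiodic offset/exponent; scalars are recycled to
#'   all channels.
#' @param oscillations List of `list(center, bandwidth, amplitude,
#'   channels)` entries (Hz, Hz, uV RMS, channel indices); default one HFO
#'   band at 145 Hz (130-160 Hz) on all channels at modest amplitude.
#' @param coupling_within,coupling_between Loading of each channel on its
#'   structure's shared latent source, and of all channels on one global
#'   cross-structure source. Latent sources carry the same exponent as the
#'   channels so mixtures remain exact power laws.
#' @param coupling_jitter Fractional per-channel loading spread: each
#'   loading is multiplied by one Uniform(1 - j, 1 + j) draw per channel
#'   and source, fixed across epochs. Emulates the broad pair-to-pair
#'   spread of baseline connectivity seen in real recordings; 0 gives
#'   homogeneous coupling.
#' @param common_mode_amplitude RMS (uV) of the common-mode signal added
#'   identically to every channel.
#' @param drug_effect List `list(dA, dB, coupling_scale)`: offset and
#'   exponent shifts and the multiplicative factor (>= 0) applied to the
#'   latent coupling variance for t >= 0.
#' @param seed Integer RNG seed; the full simulation is reproducible from
#'   the config alone.
#' @return A validated `sim_config` object.
#' @export
sim_config <- function(structures = NULL,
                       fs = 1000,
                       duration_pre = 3600,
                       duration_post = 3600,
                       A = 1, B = 2,
                       oscillations = NULL,
                       coupling_within = 0.9,
                       coupling_between = 0.45,
                       coupling_jitter = 0.5,
                       common_mode_amplitude = 1,
                       drug_effect = list(dA = 0, dB = 0,
                                          coupling_scale = 1),
                       seed = 1L) {
  if (is.null(structures)) {
    structures <- data.frame(
      structure = c("mPFC", "OFC", "NAc", "CPu", "S1", "MD", "Po", "Sept",
                    "Pir"),
      region = c("PFC", "OFC", "vStr", "dStr", "SenC", "IntTh", "SenTh",
                 "SepA", "OlfC"),
      n_channels = 6L)
  }
  if (is.null(structures$n_animals)) structures$n_animals <- 3L
  stopifnot(all(c("structure", "region", "n_channels") %in%
                  names(structures)))
  if (fs <= 0) stop("fs must be positive")
  if (duration_pre <= 0 || duration_post <= 0)
    stop("durations must be positive")
  n_ch <- sum(structures$n_channels)
  A <- rep_len(A, n_ch); B <- rep_len(B, n_ch)
  if (any(B < 0)) stop("exponent B must be >= 0")
  if (is.null(oscillations))
    oscillations <- list(list(center = 145, bandwidth = 30, amplitude = 0.5,
                              channels = seq_len(n_ch)))
  for (o in oscillations) {
    if (o$center + o$bandwidth / 2 >= fs / 2)
      stop("oscillation at ", o$center, " Hz exceeds Nyquist band")
  }
  de <- drug_effect
  for (f in c("dA", "dB", "coupling_scale"))
    if (is.null(de[[f]])) stop("drug_effect missing `", f, "`")
  if (de$coupling_scale < 0) stop("coupling scale must be >= 0")
  if (coupling_jitter < 0 || coupling_jitter >= 1)
    stop("coupling_jitter must be in [0, 1)")
  structure(
    list(structures = structures, fs = fs, duration_pre = duration_pre,
         duration_post = duration_post, A = A, B = B,
         oscillations = oscillations, coupling_within = coupling_within,
         coupling_between = coupling_between,
         coupling_jitter = coupling_jitter,
         common_mode_amplitude = common_mode_amplitude,
         drug_effect = de, seed = as.integer(seed), n_channels = n_ch),
    class = "sim_config")
}

# Channel indices of each structure, in config order.
structure_channels <- function(cfg) {
  idx <- split(seq_len(cfg$n_channels),
               rep(seq_len(nrow(cfg$structures)),
                   cfg$structures$n_channels))
  names(idx) <- cfg$structures$structure
  idx
}

# Loading matrix (channels x sources): one shared source per structure plus
# one global cross-structure source.
loading_matrix <- function(cfg) {
  sc <- structure_channels(cfg)
  L <- matrix(0, cfg$n_channels, length(sc) + 1L)
  for (k in seq_along(sc)) L[sc[[k]], k] <- cfg$coupling_within
  L[, length(sc) + 1L] <- cfg$coupling_between
  colnames(L) <- c(names(sc), ".global")
  L
}

#' Mix private noises, latent sources and a common mode into a recording
#'
#' Channel i is `private_i + sum_k loadings[i, k] * sources[[k]] +
#' common_mode`; pairwise dependence grows with the shared loading product.
#'
#' @param channel_noises Channels x samples matrix of private noise.
#' @param sources List of latent source series (each length = samples).
#' @param loadings Channels x sources loading matrix.
#' @param common_mode Optional series added identically to all channels.
#' @param fs,t0,channel_ids Passed to [lfp_recording].
#' @return An `lfp_recording`.
#' @export
mix_latent_sources <- function(channel_noises, sources, loadings,
                               common_mode = NULL, fs = 1000, t0 = 0,
                               channel_ids = NULL) {
  n_ch <- nrow(channel_noises); n <- ncol(channel_noises)
  if (length(sources)) {
    if (!is.matrix(loadings) || nrow(loadings) != n_ch ||
        ncol(loadings) != length(sources))
      stop("loadings must be a ", n_ch, " x ", length(sources), " matrix")
    if (any(lengths(sources) != n))
      stop("source length != n samples [", n, "]")
    channel_noises <- add_sources(channel_noises, loadings, sources)
  }
  if (!is.null(common_mode)) {
    if (length(common_mode) != n)
      stop("common_mode length mismatch")
    channel_noises <- sweep(channel_noises, 2L, common_mode, "+")
  }
  lfp_recording(channel_noises, fs = fs, t0 = t0,
                channel_ids = channel_ids)
}

# Scale-and-add source mixing with explicit loops: a BLAS gemm can give
# run-to-run float differences under threading, which would break the
# bit-identical reproducibility contract of the generator.
add_sources <- function(x, L, sources) {
  for (k in seq_along(sources)) {
    sk <- sources[[k]]
    for (i in which(L[, k] != 0))
      x[i, ] <- x[i, ] + L[i, k] * sk
  }
  x
}

# One epoch's worth of signal under epoch-specific parameters. RNG state is
# whatever the caller set; everything is drawn sequentially. `L` is the
# (already jittered) baseline loading matrix.
simulate_epoch <- function(cfg, duration, A, B, coupling_scale, L) {
  n <- as.integer(round(duration * cfg$fs))
  n_ch <- cfg$n_channels
  priv <- matrix(0, n_ch, n)
  for (i in seq_len(n_ch))
    priv[i, ] <- shape_noise_spectrum(stats::rnorm(n), A[i], B[i], cfg$fs)
  L <- L * sqrt(coupling_scale)
  # sources share the channels' median exponent and the median offset so
  # that every mixture stays an exact power law in expectation
  srcs <- lapply(seq_len(ncol(L)), function(k)
    shape_noise_spectrum(stats::rnorm(n), stats::median(A),
                         stats::median(B), cfg$fs))
  # always drawn so the RNG stream is invariant to the amplitude setting
  cm <- shape_noise_spectrum(stats::rnorm(n), stats::median(A),
                             stats::median(B), cfg$fs)
  cm <- cm * cfg$common_mode_amplitude / stats::sd(cm)
  x <- add_sources(priv, L, srcs)
  for (o in cfg$oscillations) {
    osc_ch <- o$channels
    for (i in osc_ch)
      x[i, ] <- x[i, ] + make_oscillation(o$center, o$bandwidth,
                                          o$amplitude, cfg$fs, n)
  }
  x <- sweep(x, 2L, cm, "+")
  # explicit loop for the same determinism reason as add_sources
  cpl <- matrix(0, n_ch, n_ch)
  for (i in seq_len(n_ch)) for (j in i:n_ch)
    cpl[i, j] <- cpl[j, i] <- sum(L[i, ] * L[j, ])
  list(x = x, coupling = cpl)
}

#' Simulate a full drug-injection experiment
#'
#' Generates one continuous recording spanning
#' `[-duration_pre, +duration_post)` with the drug effect (shifted offset
#' and exponent, rescaled latent coupling) applied as a step at t = 0, plus
#' the matching electrode map and the ground truth needed for parameter
#' recovery: true per-channel (A, B) per epoch and the true latent coupling
#' matrix per epoch.
#'
#' @param cfg A [sim_config].
#' @return List of class `lfp_simulation` with elements `recording`
#'   ([lfp_recording]), `emap` ([electrode_map]) and `truth` (list with
#'   `params` data frame, `coupling` per-epoch matrices, `oscillations`).
#' @export
simulate_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  de <- cfg$drug_effect
  L <- loading_matrix(cfg)
  jit <- cfg$coupling_jitter
  if (is.null(jit)) jit <- 0
  if (jit > 0)
    L <- L * matrix(stats::runif(length(L), 1 - jit, 1 + jit),
                    nrow(L), ncol(L))
  pre <- simulate_epoch(cfg, cfg$duration_pre, cfg$A, cfg$B, 1, L)
  post <- simulate_epoch(cfg, cfg$duration_post, cfg$A + de$dA,
                         pmax(cfg$B + de$dB, 0), de$coupling_scale, L)
  ids <- sprintf("ch%03d", seq_len(cfg$n_channels))
  rec <- lfp_recording(cbind(pre$x, post$x), fs = cfg$fs,
                       t0 = -cfg$duration_pre, channel_ids = ids)
  sc <- structure_channels(cfg)
  st <- cfg$structures
  emap <- data.frame(
    channel_id = ids,
    animal_id = unlist(lapply(seq_len(nrow(st)), function(k)
      sprintf("rat%02d", 1L + (seq_len(st$n_channels[k]) - 1L) %%
                st$n_animals[k]))),
    anatomical_label = rep(st$structure, st$n_channels),
    region = rep(st$region, st$n_channels),
    ap_mm = NA_real_, ml_mm = NA_real_, dv_mm = NA_real_,
    row = unlist(lapply(st$n_channels, function(m) (seq_len(m) - 1L) %/% 4L)),
    col = unlist(lapply(st$n_channels, function(m) (seq_len(m) - 1L) %% 4L)))
  emap <- electrode_map(emap)
  params <- rbind(
    data.frame(channel_id = ids, epoch = "baseline", A = cfg$A, B = cfg$B),
    data.frame(channel_id = ids, epoch = "post", A = cfg$A + de$dA,
               B = pmax(cfg$B + de$dB, 0)))
  truth <- list(params = params,
                coupling = list(baseline = pre$coupling,
                                post = post$coupling),
                oscillations = cfg$oscillations)
  structure(list(recording = rec, emap = emap, truth = truth, config = cfg),
            class = "lfp_simulation")
}

#' @export
print.lfp_simulation <- function(x, ...) {
  cat("<lfp_simulation> ", x$config$n_channels, " channels, ",
      nrow(x$config$structures), " structures, drug effect dA=",
      x$config$drug_effect$dA, " dB=", x$config$drug_effect$dB,
      " coupling x", x$config$drug_effect$coupling_scale, "\n", sep = "")
  print(x$recording)
  invisible(x)
}

#' Write a simulated experiment to disk
#'
#' Writes the recording directory, the electrode-map TSV and a ground-truth
#' JSON sidecar.
#'
#' @param sim An `lfp_simulation`.
#' @param dir Output directory.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "lfp_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_recording(sim$recording, file.path(dir, "recording"))
  write_electrode_map(sim$emap, file.path(dir, "electrode_map.tsv"))
  gt <- sim$truth
  gt$coupling <- lapply(gt$coupling, function(m) unclass(as.data.frame(m)))
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}
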