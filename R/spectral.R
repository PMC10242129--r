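# Spectral stage: bipolar derivation, Welch spectrogram, median spectra,
# aperiodic/periodic separation and the power-law fit y = 10^A / f^B whose
# parameters A (offset, overall population activity) and B (exponent,
# proxy for excitation-inhibition balance) are the analysis endpoints.

#' Bipolar (differential) derivation of electrode pairs
#'
#' Subtracts pairs of channels recorded in the same structure, cancelling
#' any far-field source common to both electrodes exactly.
#'
#' @param rec An [lfp_recording].
#' @param emap An [electrode_map]; pairing is restricted to channels sharing
#'   an `anatomical_label` (the implanted structure).
#' @param mode `"all_within_structure"` (every same-structure pair) or
#'   `"neighbors"` (pairs at Chebyshev distance 1 in the array `(row, col)`
#'   grid).
#' @return List of class `bipolar_set`: `series` (pairs x samples matrix of
#'   channel_i - channel_j), `pairs` (data frame `chan_i`, `chan_j`,
#'   `structure`, `region`), `fs`, `t0`. Structures with fewer than two
#'   channels are skipped with a message.
#' @export
bipolar_pairs <- function(rec, emap,
                          mode = c("all_within_structure", "neighbors")) {
  stopifnot(inherits(rec, "lfp_recording"))
  mode <- match.arg(mode)
  emap <- electrode_map(as.data.frame(emap))
  emap <- emap[match(rec$channel_ids, emap$channel_id), ]
  if (anyNA(emap$channel_id))
    stop("electrode map does not cover all recorded channels")
  pairs <- NULL
  for (st in unique(emap$anatomical_label)) {
    idx <- which(emap$anatomical_label == st)
    if (length(idx) < 2L) {
      message("structure ", st, " skipped: fewer than 2 channels")
      next
    }
    cmb <- utils::combn(idx, 2L)
    if (mode == "neighbors") {
      keep <- apply(cmb, 2L, function(p) {
        dr <- abs(emap$row[p[1]] - emap$row[p[2]])
        dc <- abs(emap$col[p[1]] - emap$col[p[2]])
        is.finite(dr) && is.finite(dc) && max(dr, dc) == 1
      })
      cmb <- cmb[, keep, drop = FALSE]
      if (!ncol(cmb)) next
    }
    pairs <- rbind(pairs, data.frame(
      i = cmb[1, ], j = cmb[2, ],
      chan_i = emap$channel_id[cmb[1, ]],
      chan_j = emap$channel_id[cmb[2, ]],
      structure = st, region = emap$region[cmb[1, ]]))
  }
  if (is.null(pairs)) stop("no structure has >= 2 channels")
  series <- rec$data[pairs$i, , drop = FALSE] -
    rec$data[pairs$j, , drop = FALSE]
  structure(list(series = series,
                 pairs = pairs[, c("chan_i", "chan_j", "structure",
                                   "region")],
                 fs = rec$fs, t0 = rec$t0),
            class = "bipolar_set")
}

#' Welch spectrogram of a single series
#'
#' Hann-tapered, one-sided power spectral density (density scaling,
#' uV^2/Hz) in sliding windows. Per window, Parseval's identity
#' `sum(psd) * df = sum((w*x)^2) / sum(w^2)` holds to rounding error.
#'
#' @param x Numeric series (uV).
#' @param fs Sampling rate, Hz.
#' @param window_s Window length in seconds (default 2 s; `window_s * fs`
#'   must be >= 64).
#' @param overlap_frac Fractional overlap between consecutive windows
#'   (default 0.5).
#' @param t0 Time of the first sample, s (for window-center timestamps).
#' @return List of class `lfp_spectrogram`: `power` (windows x frequency),
#'   `freqs` (Hz), `times` (window centers, s), `fs`, `window_s`.
#' @export
compute_spectrogram <- function(x, fs, window_s = 2, overlap_frac = 0.5,
                                t0 = 0) {
  nper <- as.integer(round(window_s * fs))
  if (nper < 64L) stop("window too short: window_s * fs must be >= 64")
  if (length(x) < nper) stop("series shorter than one window")
  step <- max(1L, as.integer(round(nper * (1 - overlap_frac))))
  starts <- seq(1L, length(x) - nper + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nper) - 1L) / nper)  # periodic Hann
  scale <- 1 / (fs * sum(w^2))
  nf <- nper %/% 2L + 1L
  pow <- matrix(0, length(starts), nf)
  for (k in seq_along(starts)) {
    seg <- x[starts[k]:(starts[k] + nper - 1L)] * w
    X <- stats::fft(seg)[seq_len(nf)]
    p <- (Re(X)^2 + Im(X)^2) * scale
    dbl <- 2:(nf - 1L)
    if (nper %% 2L == 1L) dbl <- 2:nf      # odd n: no Nyquist bin
    p[dbl] <- 2 * p[dbl]
    pow[k, ] <- p
  }
  structure(list(power = pow,
                 freqs = (seq_len(nf) - 1L) * fs / nper,
                 times = t0 + (starts - 1L + nper / 2) / fs,
                 fs = fs, window_s = window_s),
            class = "lfp_spectrogram")
}

#' A power spectrum
#'
#' @param freqs Ascending frequencies, Hz.
#' @param power Power spectral density, uV^2/Hz (same length as `freqs`).
#' @param source Identifier of the originating channel pair or aggregate.
#' @param n_windows Number of windows aggregated into this spectrum.
#' @return Object of class `power_spectrum`.
#' @export
power_spectrum <- function(freqs, power, source = NA, n_windows = 1L) {
  if (length(freqs) != length(power))
    stop("freqs and power lengths differ")
  if (is.unsorted(freqs)) stop("freqs must be ascending")
  structure(list(freqs = as.numeric(freqs), power = as.numeric(power),
                 source = source, n_windows = n_windows),
            class = "power_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat("<power_spectrum> ", length(x$freqs), " bins, ",
      format(min(x$freqs)), "-", format(max(x$freqs)), " Hz (",
      x$n_windows, " window(s))\n", sep = "")
  invisible(x)
}

#' Median spectrum over an epoch
#'
#' Element-wise median over the spectrogram windows whose centers fall in
#' the half-open epoch `[t_start, t_end)`. The median (rather than mean)
#' makes the estimate robust to transient artifacts.
#'
#' @param sg An `lfp_spectrogram`.
#' @param epoch An [epoch_spec] or numeric `c(t_start, t_end)` in seconds;
#'   `NULL` uses every window.
#' @return A [power_spectrum].
#' @export
median_spectrum <- function(sg, epoch = NULL) {
  stopifnot(inherits(sg, "lfp_spectrogram"))
  keep <- rep(TRUE, length(sg$times))
  if (!is.null(epoch)) {
    epoch <- as_epoch(epoch)
    keep <- sg$times >= epoch$t_start & sg$times < epoch$t_end
  }
  if (!any(keep))
    stop("no spectrogram window centers inside the requested epoch")
  p <- sg$power[keep, , drop = FALSE]
  power_spectrum(sg$freqs, apply(p, 2L, stats::median),
                 n_windows = sum(keep))
}

# log-spaced resampling of a spectrum for fitting: averages log10(f) and
# log10(power) within log-spaced bins so every decade gets equal leverage
# (points already on a log-log line stay exactly on it).
log_resample <- function(lf, lp, n_bins) {
  if (length(lf) <= n_bins) return(list(x = lf, y = lp))
  brk <- seq(min(lf), max(lf), length.out = n_bins + 1L)
  g <- findInterval(lf, brk, rightmost.closed = TRUE)
  list(x = as.numeric(tapply(lf, g, mean)),
       y = as.numeric(tapply(lp, g, mean)))
}

#' Fit the aperiodic power law y = 10^A / f^B
#'
#' Least squares of log10(power) on log10(frequency) over `fit_range`,
#' after resampling onto log-spaced bins so high frequencies do not
#' dominate the fit. The intercept is the offset A (log10 uV^2/Hz at 1 Hz)
#' and the negative slope the aperiodic exponent B. Exact on noiseless
#' power-law input for any frequency grid.
#'
#' @param spec A [power_spectrum] (e.g. from [median_spectrum] or the
#'   masked output of [separate_aperiodic]).
#' @param fit_range Numeric `c(lo, hi)` in Hz; default 1-300 Hz.
#' @param n_logbins Number of log-spaced bins used for the regression.
#' @param excluded_bands Optional list of `c(lo, hi)` Hz intervals treated
#'   as periodic and masked before fitting (recorded on the fit object).
#' @return Object of class `aperiodic_fit` with fields `A`, `B`,
#'   `fit_range`, `r2_loglog`, `excluded_bands`, `n_bins`, plus the fitted
#'   bins; supports `print`, `coef`, `predict`, `plot` and `residuals`.
#' @export
fit_powerlaw <- function(spec, fit_range = c(1, 300), n_logbins = 100L,
                         excluded_bands = list()) {
  stopifnot(inherits(spec, "power_spectrum"))
  keep <- spec$freqs >= fit_range[1] & spec$freqs <= fit_range[2]
  for (b in excluded_bands)
    keep <- keep & !(spec$freqs >= b[1] & spec$freqs <= b[2])
  f <- spec$freqs[keep]; p <- spec$power[keep]
  if (length(f) < 10L)
    stop("need >= 10 bins in fit range, have ", length(f))
  if (any(p <= 0))
    stop("nonpositive power in fit range at ",
         paste(format(f[p <= 0][seq_len(min(5, sum(p <= 0)))]),
               collapse = ", "), " Hz")
  rs <- log_resample(log10(f), log10(p), n_logbins)
  fit <- stats::lm.fit(cbind(1, rs$x), rs$y)
  a <- fit$coefficients[1]; b <- -fit$coefficients[2]
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((rs$y - mean(rs$y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(list(A = unname(a), B = unname(b), fit_range = fit_range,
                 r2_loglog = r2, excluded_bands = excluded_bands,
                 n_bins = length(rs$x), freqs = f, power = p,
                 source = spec$source),
            class = "aperiodic_fit")
}

#' @export
print.aperiodic_fit <- function(x, ...) {
  cat("Aperiodic power-law fit: y = 10^A / f^B\n")
  cat(sprintf("  offset   A = %.4f  (log10 uV^2/Hz)\n", x$A))
  cat(sprintf("  exponent B = %.4f\n", x$B))
  cat(sprintf("  fit range %g-%g Hz, %d bins, R^2(log-log) = %.4f\n",
              x$fit_range[1], x$fit_range[2], x$n_bins, x$r2_loglog))
  if (length(x$excluded_bands))
    cat("  excluded bands (Hz):",
        paste(vapply(x$excluded_bands,
                     function(b) sprintf("%.1f-%.1f", b[1], b[2]), ""),
              collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.aperiodic_fit <- function(object, ...) {
  c(offset = object$A, exponent = object$B)
}

#' @export
predict.aperiodic_fit <- function(object, freqs = NULL, ...) {
  if (is.null(freqs)) freqs <- object$freqs
  10^object$A / freqs^object$B
}

#' @export
residuals.aperiodic_fit <- function(object, ...) {
  log10(object$power) - (object$A - object$B * log10(object$freqs))
}

#' @export
plot.aperiodic_fit <- function(x, ...) {
  graphics::plot(x$freqs, x$power, log = "xy", type = "l", col = "grey40",
                 xlab = "frequency (Hz)", ylab = "PSD (uV^2/Hz)", ...)
  graphics::lines(x$freqs, predict(x), col = "red", lwd = 2)
  graphics::legend("bottomleft", bty = "n",
                   legend = sprintf("10^%.2f / f^%.2f", x$A, x$B))
  invisible(x)
}

# Mains frequency and harmonics inside the fit range, as exclusion bands.
mains_bands <- function(fit_range, mains = 50, halfwidth = 2) {
  if (is.null(mains) || mains <= 0) return(list())
  h <- seq(mains, fit_range[2], by = mains)
  lapply(h[h >= fit_range[1]], function(f) c(f - halfwidth, f + halfwidth))
}

#' Separate aperiodic from periodic spectral activity
#'
#' Iterative peak-pruning in log-log space: (1) fit the power law to the
#' unmasked bins, (2) flag contiguous runs of bins whose positive residual
#' exceeds `peak_threshold_sd` standard deviations of the current
#' residuals, (3) mask and refit, until no new bins are flagged or
#' `max_iters` is reached. Mains (50 Hz) and harmonics are always masked.
#'
#' @param spec A [power_spectrum], positive over `fit_range`.
#' @param fit_range Hz interval considered (default 1-300).
#' @param peak_threshold_sd Residual threshold in SD units (default 2.5).
#' @param max_iters Maximum prune-refit iterations (default 5).
#' @param mains Mains frequency in Hz masked with all harmonics (default
#'   50; set `NULL` to disable).
#' @return List with `aperiodic` (the masked [power_spectrum] restricted to
#'   the fit range) and `excluded_bands` (list of `c(lo, hi)` Hz). Warns,
#'   but still returns, if more than half of the bins end up masked.
#' @export
separate_aperiodic <- function(spec, fit_range = c(1, 300),
                               peak_threshold_sd = 2.5, max_iters = 5L,
                               mains = 50) {
  stopifnot(inherits(spec, "power_spectrum"))
  inr <- spec$freqs >= fit_range[1] & spec$freqs <= fit_range[2]
  f <- spec$freqs[inr]; p <- spec$power[inr]
  if (any(p <= 0)) stop("spectrum must be positive over the fit range")
  lf <- log10(f); lp <- log10(p)
  masked <- rep(FALSE, length(f))
  for (b in mains_bands(fit_range, mains))
    masked <- masked | (f >= b[1] & f <= b[2])
  for (it in seq_len(max_iters)) {
    rs <- log_resample(lf[!masked], lp[!masked], 100L)
    cf <- stats::lm.fit(cbind(1, rs$x), rs$y)$coefficients
    resid <- lp - (cf[1] + cf[2] * lf)
    s <- stats::sd(resid[!masked])
    new_flags <- !masked & resid > peak_threshold_sd * s
    if (!any(new_flags)) break
    # grow each flagged core outward into adjacent bins still > 1 SD above
    # the fit, so peak shoulders are masked along with the core
    shoulder <- resid > s
    flag <- new_flags
    repeat {
      nb <- length(flag)
      grow <- (c(FALSE, flag[-nb]) | c(flag[-1], FALSE)) & shoulder &
        !flag & !masked
      if (!any(grow)) break
      flag <- flag | grow
    }
    masked <- masked | flag
  }
  bands <- flagged_bands(f, masked, mains_only = FALSE)
  if (mean(masked) > 0.5)
    warning("more than 50% of bins masked as periodic; fit unreliable")
  out <- power_spectrum(f[!masked], p[!masked], source = spec$source,
                        n_windows = spec$n_windows)
  list(aperiodic = out, excluded_bands = bands)
}

# Convert a logical mask over an ascending frequency grid into merged
# [lo, hi] bands.
flagged_bands <- function(f, masked, mains_only = FALSE) {
  if (!any(masked)) return(list())
  r <- rle(masked)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  idx <- which(r$values)
  lapply(idx, function(k) c(f[starts[k]], f[ends[k]]))
}

#' Fit the aperiodic component of a spectrum
#'
#' Convenience wrapper: [separate_aperiodic] then [fit_powerlaw] on the
#' masked spectrum.
#'
#' @inheritParams separate_aperiodic
#' @param ... Passed to [fit_powerlaw].
#' @return An `aperiodic_fit` carrying the detected `excluded_bands`.
#' @export
fit_aperiodic <- function(spec, fit_range = c(1, 300),
                          peak_threshold_sd = 2.5, max_iters = 5L,
                          mains = 50, ...) {
  sep <- separate_aperiodic(spec, fit_range = fit_range,
                            peak_threshold_sd = peak_threshold_sd,
                            max_iters = max_iters, mains = mains)
  fit <- fit_powerlaw(sep$aperiodic, fit_range = fit_range, ...)
  fit$excluded_bands <- sep$excluded_bands
  fit
}

#' Per-structure aperiodic change between two epochs
#'
#' For every structure passing the region inclusion rule, derives bipolar
#' pairs, computes median spectra for the baseline and post epochs, fits
#' the aperiodic power law per pair and epoch, and summarizes the
#' per-pair offset and exponent changes.
#'
#' @param rec An [lfp_recording] spanning both epochs.
#' @param emap An [electrode_map].
#' @param baseline_epoch,post_epoch [epoch_spec]s or numeric `c(start,
#'   end)` in seconds (defaults: -32 to -2 min and 30 to 60 min).
#' @param fit_range Hz interval of the power-law fit (default 1-300).
#' @param mode Pairing mode, see [bipolar_pairs].
#' @param window_s,overlap_frac Spectrogram parameters (2 s Hann windows,
#'   50% overlap by default).
#' @param min_recordings,min_animals Region inclusion thresholds
#'   (see [group_regions]).
#' @param ... Passed to [fit_aperiodic].
#' @return Data frame of class `spectral_change` with one row per
#'   structure: `structure`, `region`, `n_pairs`, medians of per-pair
#'   A/B in both epochs and of the per-pair deltas (`dA`, `dB`). The
#'   per-pair fit tables are attached as attribute `"pair_fits"`.
#' @export
structure_spectral_change <- function(rec, emap,
                                      baseline_epoch = c(-32, -2) * 60,
                                      post_epoch = c(30, 60) * 60,
                                      fit_range = c(1, 300),
                                      mode = "all_within_structure",
                                      window_s = 2, overlap_frac = 0.5,
                                      min_recordings = 6, min_animals = 3,
                                      ...) {
  emap <- electrode_map(as.data.frame(emap))
  regions <- group_regions(emap, min_recordings, min_animals)
  if (!length(regions)) stop("no region passes the inclusion rule")
  keep_ch <- unlist(regions, use.names = FALSE)
  sub <- select_channels(rec, keep_ch)
  bp <- bipolar_pairs(sub, emap, mode = mode)
  base_ep <- as_epoch(baseline_epoch, "baseline")
  post_ep <- as_epoch(post_epoch, "post")
  fits <- NULL
  for (k in seq_len(nrow(bp$pairs))) {
    for (ep in list(base_ep, post_ep)) {
      seg <- window_series(bp$series[k, ], bp$fs, bp$t0, ep)
      sg <- compute_spectrogram(seg$x, bp$fs, window_s, overlap_frac,
                                t0 = seg$t0)
      fit <- fit_aperiodic(median_spectrum(sg), fit_range = fit_range, ...)
      fits <- rbind(fits, data.frame(
        pair = k, chan_i = bp$pairs$chan_i[k], chan_j = bp$pairs$chan_j[k],
        structure = bp$pairs$structure[k], region = bp$pairs$region[k],
        epoch = ep$label, A = fit$A, B = fit$B, r2 = fit$r2_loglog))
    }
  }
  out <- NULL
  for (st in unique(fits$structure)) {
    fb <- fits[fits$structure == st & fits$epoch == "baseline", ]
    fp <- fits[fits$structure == st & fits$epoch == "post", ]
    out <- rbind(out, data.frame(
      structure = st, region = fb$region[1], n_pairs = nrow(fb),
      A_base = stats::median(fb$A), A_post = stats::median(fp$A),
      dA = stats::median(fp$A - fb$A),
      B_base = stats::median(fb$B), B_post = stats::median(fp$B),
      dB = stats::median(fp$B - fb$B)))
  }
  attr(out, "pair_fits") <- fits
  class(out) <- c("spectral_change", class(out))
  out
}

# Restrict a recording to a subset of channel ids (kept in recording order).
select_channels <- function(rec, channel_ids) {
  idx <- which(rec$channel_ids %in% channel_ids)
  lfp_recording(rec$data[idx, , drop = FALSE], fs = rec$fs, t0 = rec$t0,
                channel_ids = rec$channel_ids[idx])
}

# Cut one epoch out of a plain series with its own time origin.
window_series <- function(x, fs, t0, epoch) {
  i0 <- round((epoch$t_start - t0) * fs)
  i1 <- round((epoch$t_end - t0) * fs)
  if (i0 < 0 || i1 > length(x))
    stop("epoch outside series span")
  list(x = x[(i0 + 1):i1], t0 = t0 + i0 / fs)
}
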