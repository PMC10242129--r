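# Gaussian-copula mutual information (GCMI) and the windowed pairwise
# connectivity analysis. GCMI rank-transforms each margin to a standard
# normal and computes parametric Gaussian MI from the covariance
# determinants of the transformed pair; it is a lower bound on the true MI
# and exactly invariant to strictly monotone marginal transforms.

#' Copula transform: empirical ranks to standard-normal margins
#'
#' Maps `x` to `qnorm(rank(x) / (n + 1))` using average ranks for ties.
#' The result depends on `x` only through its ordering, so any strictly
#' increasing transform of `x` leaves the output unchanged.
#'
#' @param x Numeric vector (`length(x) >= 2`), not constant. MI estimation
#'   ([gcmi_pair]) additionally requires `n >= 8`.
#' @return Numeric vector with (empirical) standard-normal marginal.
#' @export
copula_transform <- function(x) {
  n <- length(x)
  if (n < 2L) stop("copula transform requires n >= 2, got ", n)
  if (min(x) == max(x))
    stop("constant input: mutual information undefined for a degenerate margin")
  stats::qnorm(rank(x, ties.method = "average") / (n + 1))
}

# Small-sample bias of the plug-in Gaussian MI estimate, in nats.
# Derived from the expected log-determinant of a Wishart covariance
# estimate: the bias-corrected entropy subtracts
# d*log(2/(n-1))/2 + sum_i psi((n-i)/2)/2, which for the 1+1 -> 2
# dimensional MI combination collapses to psi((n-1)/2)/2 - psi((n-2)/2)/2.
gcmi_bias_nats <- function(n) {
  (digamma((n - 1) / 2) - digamma((n - 2) / 2)) / 2
}

#' Gaussian-copula mutual information between two series
#'
#' Both inputs are copula-transformed ([copula_transform]) and the MI of
#' the resulting bivariate distribution is computed parametrically from
#' the correlation r of the transformed pair:
#' `I = -0.5 * log(1 - r^2)` (nats), optionally minus the analytic
#' half-integer digamma small-sample bias term.
#'
#' @param x,y Equal-length numeric vectors (`n >= 8`, neither constant).
#' @param bias_correct Subtract the analytic small-sample bias
#'   (default TRUE).
#' @param units `"bits"` (default) or `"nats"`.
#' @return Single MI value; `+Inf` with a warning when the transformed
#'   pair is perfectly dependent.
#' @export
gcmi_pair <- function(x, y, bias_correct = TRUE,
                      units = c("bits", "nats")) {
  units <- match.arg(units)
  if (length(x) != length(y))
    stop("x and y must have equal length")
  if (length(x) < 8L)
    stop("GCMI requires n >= 8 samples, got ", length(x))
  cx <- copula_transform(x)
  cy <- copula_transform(y)
  r <- stats::cor(cx, cy)
  n <- length(x)
  if (1 - r^2 < 1e-12) {
    warning("perfectly dependent inputs: joint covariance singular")
    return(Inf)
  }
  mi <- -0.5 * log(1 - r^2)
  if (bias_correct) mi <- mi - gcmi_bias_nats(n)
  if (units == "bits") mi <- mi / log(2)
  mi
}

# All-pairs GCMI for one window: Z is samples x channels raw data; each
# column is copula-transformed once and reused for every pair.
gcmi_window <- function(Z, pairs_i, pairs_j, bias_correct, units) {
  n <- nrow(Z)
  C <- apply(Z, 2L, function(col)
    stats::qnorm(rank(col, ties.method = "average") / (n + 1)))
  R <- stats::cor(C)
  r2 <- R[cbind(pairs_i, pairs_j)]^2
  r2 <- pmin(r2, 1 - .Machine$double.eps)
  mi <- -0.5 * log(1 - r2)
  if (bias_correct) mi <- mi - gcmi_bias_nats(n)
  if (units == "bits") mi <- mi / log(2)
  mi
}

#' Windowed pairwise mutual information
#'
#' Tiles the epoch with consecutive non-overlapping windows of `window_s`
#' seconds (`floor(epoch / window_s)` windows; the remainder is dropped)
#' and computes GCMI for every requested channel pair in each window.
#' A 15-min epoch at 2-s windows yields exactly 450 values per pair.
#'
#' @param rec An [lfp_recording] (monopolar, typically downsampled to
#'   1 kHz beforehand).
#' @param epoch [epoch_spec] or numeric `c(t_start, t_end)`, s.
#' @param window_s Window length, s (default 2).
#' @param pairs Data frame with columns `chan_i`, `chan_j` (channel ids);
#'   `NULL` means all channel pairs.
#' @param bias_correct,units See [gcmi_pair].
#' @return List of class `mi_window_series`: `pairs`, `mi` (pairs x
#'   windows matrix), `times` (window start times, s), `n_per_window`,
#'   `units`.
#' @export
windowed_mi <- function(rec, epoch, window_s = 2, pairs = NULL,
                        bias_correct = TRUE, units = c("bits", "nats")) {
  units <- match.arg(units)
  seg <- select_epoch(rec, epoch)
  nper <- as.integer(round(window_s * seg$fs))
  n_win <- ncol(seg$data) %/% nper
  if (n_win < 1L) stop("epoch shorter than one window")
  if (is.null(pairs)) {
    cmb <- utils::combn(seg$channel_ids, 2L)
    pairs <- data.frame(chan_i = cmb[1, ], chan_j = cmb[2, ])
  }
  pi_ <- match(pairs$chan_i, seg$channel_ids)
  pj_ <- match(pairs$chan_j, seg$channel_ids)
  if (anyNA(pi_) || anyNA(pj_))
    stop("pair channel id not present in recording")
  mi <- matrix(NA_real_, nrow(pairs), n_win)
  for (w in seq_len(n_win)) {
    cols <- ((w - 1L) * nper + 1L):(w * nper)
    mi[, w] <- gcmi_window(t(seg$data[, cols, drop = FALSE]),
                           pi_, pj_, bias_correct, units)
  }
  structure(list(pairs = pairs, mi = mi,
                 times = seg$t0 + (seq_len(n_win) - 1L) * window_s,
                 n_per_window = nper, units = units),
            class = "mi_window_series")
}

#' @export
print.mi_window_series <- function(x, ...) {
  cat("<mi_window_series> ", nrow(x$pairs), " pair(s) x ", ncol(x$mi),
      " window(s) of ", x$n_per_window, " samples (", x$units, ")\n",
      sep = "")
  invisible(x)
}

#' Per-pair connectivity summary: epoch medians and their ratio
#'
#' The median MI over windows is computed for each epoch and the relative
#' change expressed as `ratio = mi_post / mi_baseline`. Bias-corrected MI
#' medians are clamped at zero, and pairs whose baseline median falls
#' below `floor` are flagged unreliable (ratio of a near-zero denominator)
#' and excluded from downstream summaries.
#'
#' @param baseline_mws,post_mws `mi_window_series` for the two epochs,
#'   with identical pair tables.
#' @param floor Minimum baseline median MI for a defined ratio (default
#'   0.001 bits).
#' @return Data frame of class `pair_connectivity`: `chan_i`, `chan_j`,
#'   `mi_base`, `mi_post`, `ratio`, `reliable`.
#' @export
pair_connectivity <- function(baseline_mws, post_mws, floor = 0.001) {
  stopifnot(inherits(baseline_mws, "mi_window_series"),
            inherits(post_mws, "mi_window_series"))
  if (!identical(baseline_mws$pairs, post_mws$pairs))
    stop("baseline and post series cover different pair sets")
  if (!ncol(baseline_mws$mi) || !ncol(post_mws$mi))
    stop("empty MI window series")
  mb <- pmax(apply(baseline_mws$mi, 1L, stats::median), 0)
  mp <- pmax(apply(post_mws$mi, 1L, stats::median), 0)
  reliable <- mb >= floor
  out <- data.frame(baseline_mws$pairs, mi_base = mb, mi_post = mp,
                    ratio = ifelse(reliable, mp / mb, NA_real_),
                    reliable = reliable)
  class(out) <- c("pair_connectivity", class(out))
  out
}

#' Baseline-split stationarity control
#'
#' Applies the identical windowed-MI machinery to the first and second
#' halves of the baseline epoch; under stationarity the per-pair
#' half2/half1 ratio is close to 1, providing the reference distribution
#' against which drug-induced ratios are judged.
#'
#' @param rec An [lfp_recording].
#' @param baseline_epoch Baseline [epoch_spec]; must be at least two
#'   windows long.
#' @inheritParams windowed_mi
#' @param floor See [pair_connectivity].
#' @return A [pair_connectivity] data frame (half 2 vs half 1).
#' @export
baseline_control <- function(rec, baseline_epoch, window_s = 2,
                             pairs = NULL, bias_correct = TRUE,
                             units = "bits", floor = 0.001) {
  ep <- as_epoch(baseline_epoch, "baseline")
  mid <- (ep$t_start + ep$t_end) / 2
  if (mid - ep$t_start < window_s)
    stop("baseline too short to split: each half must hold >= 1 window")
  h1 <- windowed_mi(rec, epoch_spec(ep$t_start, mid), window_s, pairs,
                    bias_correct, units)
  h2 <- windowed_mi(rec, epoch_spec(mid, ep$t_end), window_s, pairs,
                    bias_correct, units)
  pair_connectivity(h1, h2, floor = floor)
}

#' Structure-level connectivity summary
#'
#' Classifies pairs as within- or between-structure, builds the
#' region-by-region matrix of mean relative change, fits post-median vs
#' baseline-median MI by least squares in each scope, and reports the
#' baseline within-vs-between mean MI difference in percent.
#'
#' @param pc A [pair_connectivity] table.
#' @param emap An [electrode_map] covering the pairs' channels.
#' @return List of class `connectivity_summary`: `pairs` (the input with
#'   `region_i`, `region_j`, `within` added), `matrix` (region x region
#'   mean ratio), `counts` (pairs per cell), `fits` (data frame with
#'   `scope`, `slope`, `intercept`, `r_squared`, `n`), and
#'   `within_between_pct` (baseline mean difference, %).
#' @export
structure_summary <- function(pc, emap) {
  stopifnot(inherits(pc, "pair_connectivity"))
  emap <- electrode_map(as.data.frame(emap))
  ri <- emap$region[match(pc$chan_i, emap$channel_id)]
  rj <- emap$region[match(pc$chan_j, emap$channel_id)]
  si <- emap$anatomical_label[match(pc$chan_i, emap$channel_id)]
  sj <- emap$anatomical_label[match(pc$chan_j, emap$channel_id)]
  if (anyNA(ri) || anyNA(rj))
    stop("electrode map does not cover all pair channels")
  pc$region_i <- ri; pc$region_j <- rj
  pc$within <- si == sj
  regs <- intersect(lfp_regions, unique(c(ri, rj)))
  M <- matrix(NA_real_, length(regs), length(regs),
              dimnames = list(regs, regs))
  N <- matrix(0L, length(regs), length(regs), dimnames = list(regs, regs))
  ok <- pc$reliable
  for (a in regs) for (b in regs) {
    sel <- ok & ((ri == a & rj == b) | (ri == b & rj == a))
    N[a, b] <- sum(sel)
    if (any(sel)) M[a, b] <- mean(pc$ratio[sel])
  }
  fits <- NULL
  for (scope in c("within", "between")) {
    sel <- ok & (pc$within == (scope == "within"))
    if (sum(sel) < 2L) {
      message("scope `", scope, "` omitted: fewer than 2 reliable pairs")
      next
    }
    fit <- stats::lm(mi_post ~ mi_base, data = pc[sel, ])
    fits <- rbind(fits, data.frame(
      scope = scope, slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      r_squared = summary(fit)$r.squared, n = sum(sel)))
  }
  wb <- NA_real_
  if (any(ok & pc$within) && any(ok & !pc$within)) {
    mw <- mean(pc$mi_base[ok & pc$within])
    mb <- mean(pc$mi_base[ok & !pc$within])
    wb <- 100 * (mw - mb) / mb
  }
  structure(list(pairs = pc, matrix = M, counts = N, fits = fits,
                 within_between_pct = wb),
            class = "connectivity_summary")
}

#' @export
print.connectivity_summary <- function(x, ...) {
  cat("<connectivity_summary> ", nrow(x$pairs), " pairs (",
      sum(x$pairs$within), " within-structure), ",
      sum(x$pairs$reliable), " reliable\n", sep = "")
  if (!is.na(x$within_between_pct))
    cat(sprintf("  baseline within vs between mean MI: %+.1f%%\n",
                x$within_between_pct))
  if (!is.null(x$fits)) {
    for (k in seq_len(nrow(x$fits)))
      cat(sprintf("  %s fit: post = %.3f * base %+.4f, R^2 = %.3f (n=%d)\n",
                  x$fits$scope[k], x$fits$slope[k], x$fits$intercept[k],
                  x$fits$r_squared[k], x$fits$n[k]))
  }
  invisible(x)
}

#' Zero-phase low-pass filter a recording
#'
#' Butterworth (order 4) low-pass applied forward-backward per channel;
#' used for the robustness control in which connectivity is recomputed
#' after removing high-frequency content.
#'
#' @param rec An [lfp_recording].
#' @param cutoff_hz Cutoff frequency, Hz (< Nyquist).
#' @return Filtered `lfp_recording`.
#' @export
lowpass_recording <- function(rec, cutoff_hz) {
  stopifnot(inherits(rec, "lfp_recording"))
  if (cutoff_hz <= 0 || cutoff_hz >= rec$fs / 2)
    stop("cutoff must lie in (0, fs/2)")
  filt <- signal::butter(4, cutoff_hz / (rec$fs / 2), type = "low")
  out <- t(apply(rec$data, 1L, function(ch) signal::filtfilt(filt, ch)))
  lfp_recording(out, fs = rec$fs, t0 = rec$t0,
                channel_ids = rec$channel_ids)
}
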