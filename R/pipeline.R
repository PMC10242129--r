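# End-to-end orchestration: recording -> spectral change tables ->
# connectivity summaries -> nonparametric contrasts, with a run log.

#' Pipeline configuration
#'
#' Collects every tunable of the full analysis. Epochs are stage-specific
#' (seconds relative to injection): the spectral stage defaults to
#' -32 to -2 min vs 30 to 60 min and the connectivity stage to
#' -20 to -5 min vs 45 to 60 min.
#'
#' @param spectral_baseline,spectral_post Spectral-stage epochs, s.
#' @param conn_baseline,conn_post Connectivity-stage epochs, s.
#' @param fit_range Power-law fit interval, Hz (default 1-300).
#' @param window_s MI window length, s (default 2).
#' @param target_fs Connectivity sampling rate after downsampling, Hz
#'   (default 1000).
#' @param alpha Significance level (default 0.05).
#' @param pair_mode Bipolar pairing mode (see [bipolar_pairs]).
#' @param bias_correct,units GCMI settings (see [gcmi_pair]).
#' @param mi_floor Baseline MI floor for ratio reliability (bits).
#' @param min_recordings,min_animals Region inclusion rule.
#' @param stat_unit `"pairs"` (pool electrode pairs within structure; the
#'   default) or `"animal_median"` (test per-animal medians, avoiding
#'   pseudo-replication).
#' @param p_adjust `"none"` (default, uncorrected per-structure tests) or
#'   any method of [stats::p.adjust] such as `"BH"`.
#' @param run_baseline_control Also compute the split-baseline
#'   stationarity control (needs a baseline at least two windows long).
#' @param seed Integer seed recorded in the report.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(spectral_baseline = c(-32, -2) * 60,
                            spectral_post = c(30, 60) * 60,
                            conn_baseline = c(-20, -5) * 60,
                            conn_post = c(45, 60) * 60,
                            fit_range = c(1, 300),
                            window_s = 2,
                            target_fs = 1000,
                            alpha = 0.05,
                            pair_mode = "all_within_structure",
                            bias_correct = TRUE,
                            units = "bits",
                            mi_floor = 0.001,
                            min_recordings = 6,
                            min_animals = 3,
                            stat_unit = c("pairs", "animal_median"),
                            p_adjust = "none",
                            run_baseline_control = TRUE,
                            seed = 1L) {
  stat_unit <- match.arg(stat_unit)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Orchestrates region grouping, per-structure aperiodic change
#' estimation with paired signed-rank contrasts, downsampling, windowed
#' GCMI connectivity with ratio summaries and contrasts, and (optionally)
#' the split-baseline control. Deterministic given the inputs and config.
#'
#' @param rec An [lfp_recording] or a recording directory path.
#' @param emap An [electrode_map] or a TSV path.
#' @param config A [pipeline_config].
#' @return List of class `lfp_report`: `spectral` (per-structure table
#'   with dA/dB and p-values), `connectivity` (a
#'   [structure_summary] plus scope-level contrasts), `control`
#'   (baseline-split [pair_connectivity] or NULL), `config`, `log`.
#' @export
run_pipeline <- function(rec, emap, config = pipeline_config()) {
  if (is.character(rec)) rec <- read_recording(rec)
  if (is.character(emap)) emap <- read_electrode_map(emap)
  stopifnot(inherits(rec, "lfp_recording"),
            inherits(config, "pipeline_config"))
  emap <- electrode_map(as.data.frame(emap))
  logline <- character(0)
  note <- function(...) logline <<- c(logline, paste0(...))
  note("pipeline seed: ", config$seed)
  set.seed(config$seed)

  ## --- spectral stage -------------------------------------------------
  note("spectral epochs: baseline [",
       paste(config$spectral_baseline, collapse = ", "), ") s, post [",
       paste(config$spectral_post, collapse = ", "), ") s; fit range ",
       paste(config$fit_range, collapse = "-"), " Hz; pair mode ",
       config$pair_mode)
  sc <- structure_spectral_change(
    rec, emap,
    baseline_epoch = config$spectral_baseline,
    post_epoch = config$spectral_post,
    fit_range = config$fit_range, mode = config$pair_mode,
    min_recordings = config$min_recordings,
    min_animals = config$min_animals)
  fits <- attr(sc, "pair_fits")
  sc$p_dA <- NA_real_; sc$p_dB <- NA_real_
  for (k in seq_len(nrow(sc))) {
    st <- sc$structure[k]
    fb <- fits[fits$structure == st & fits$epoch == "baseline", ]
    fp <- fits[fits$structure == st & fits$epoch == "post", ]
    if (config$stat_unit == "animal_median") {
      an <- emap$animal_id[match(fb$chan_i, emap$channel_id)]
      a_b <- tapply(fb$A, an, stats::median)
      a_p <- tapply(fp$A, an, stats::median)
      b_b <- tapply(fb$B, an, stats::median)
      b_p <- tapply(fp$B, an, stats::median)
    } else {
      a_b <- fb$A; a_p <- fp$A; b_b <- fb$B; b_p <- fp$B
    }
    if (length(a_b) >= 2) {
      sc$p_dA[k] <- paired_contrast(a_b, a_p, config$alpha)$p_value
      sc$p_dB[k] <- paired_contrast(b_b, b_p, config$alpha)$p_value
    }
  }
  sc$p_dA_adj <- stats::p.adjust(sc$p_dA, method = config$p_adjust)
  sc$p_dB_adj <- stats::p.adjust(sc$p_dB, method = config$p_adjust)
  sc$sig_dA <- ifelse(is.na(sc$p_dA_adj), "",
                      ifelse(sc$p_dA_adj < config$alpha, "*", ""))
  sc$sig_dB <- ifelse(is.na(sc$p_dB_adj), "",
                      ifelse(sc$p_dB_adj < config$alpha, "*", ""))
  if (config$stat_unit == "pairs")
    note("statistical unit: electrode pairs pooled within structure; ",
         "pairs sharing channels/animals are not independent ",
         "(pseudo-replication) - see stat_unit = 'animal_median'")
  ks <- tryCatch(
    ks_normality_gate(fits$A[fits$epoch == "baseline"], config$alpha),
    error = function(e) NULL)
  if (!is.null(ks))
    note("KS normality gate on baseline offsets: p = ",
         format.pval(ks$p_value, digits = 3),
         "; proceeding nonparametrically")

  ## --- connectivity stage ---------------------------------------------
  regions <- group_regions(emap, config$min_recordings,
                           config$min_animals)
  keep_ch <- unlist(regions, use.names = FALSE)
  mono <- select_channels(rec, keep_ch)
  if (config$target_fs < mono$fs) {
    mono <- downsample(mono, config$target_fs)
    note("connectivity input downsampled to ", config$target_fs, " Hz")
  }
  note("connectivity epochs: baseline [",
       paste(config$conn_baseline, collapse = ", "), ") s, post [",
       paste(config$conn_post, collapse = ", "), ") s; ",
       config$window_s, " s windows; monopolar signals")
  mb <- windowed_mi(mono, config$conn_baseline, config$window_s,
                    bias_correct = config$bias_correct,
                    units = config$units)
  mp <- windowed_mi(mono, config$conn_post, config$window_s,
                    bias_correct = config$bias_correct,
                    units = config$units)
  pc <- pair_connectivity(mb, mp, floor = config$mi_floor)
  summ <- structure_summary(pc, emap)
  conn_tests <- NULL
  for (scope in c("within", "between")) {
    sel <- summ$pairs$reliable & (summ$pairs$within == (scope == "within"))
    if (sum(sel) >= 2) {
      ct <- paired_contrast(summ$pairs$mi_base[sel],
                            summ$pairs$mi_post[sel], config$alpha)
      conn_tests <- rbind(conn_tests, data.frame(
        scope = scope, n = sum(sel),
        median_ratio = stats::median(summ$pairs$ratio[sel]),
        p = ct$p_value, sig = ifelse(ct$p_value < config$alpha, "*", "")))
    }
  }
  control <- NULL
  if (isTRUE(config$run_baseline_control)) {
    control <- tryCatch(
      baseline_control(mono, config$conn_baseline, config$window_s,
                       bias_correct = config$bias_correct,
                       units = config$units, floor = config$mi_floor),
      error = function(e) {
        note("baseline control skipped: ", conditionMessage(e)); NULL
      })
    if (!is.null(control))
      note("baseline-split control median ratio: ",
           format(stats::median(control$ratio, na.rm = TRUE),
                  digits = 4))
  }
  structure(list(spectral = sc, connectivity = summ,
                 connectivity_tests = conn_tests, control = control,
                 config = config, log = logline),
            class = "lfp_report")
}

#' @export
print.lfp_report <- function(x, ...) {
  cat("== Aperiodic spectral change (per structure) ==\n")
  df <- as.data.frame(x$spectral)
  df[] <- lapply(df, function(cl) if (is.numeric(cl)) signif(cl, 4) else cl)
  print(df[, c("structure", "region", "n_pairs", "dA", "p_dA", "sig_dA",
               "dB", "p_dB", "sig_dB")], row.names = FALSE)
  cat("\n== Functional connectivity ==\n")
  print(x$connectivity)
  if (!is.null(x$connectivity_tests)) {
    ct <- x$connectivity_tests
    ct$median_ratio <- signif(ct$median_ratio, 4)
    ct$p <- signif(ct$p, 4)
    print(ct, row.names = FALSE)
  }
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Emits TSV tables (per-structure spectral change, per-pair
#' connectivity, region-by-region change matrix, scope fits and
#' contrasts) and a plain-text run log. The log header carries the only
#' timestamp; all tables are byte-deterministic given config and seed.
#'
#' @param report An `lfp_report`.
#' @param dir Output directory.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "lfp_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(d, f) utils::write.table(
    d, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(as.data.frame(report$spectral), "spectral_change.tsv")
  wt(report$connectivity$pairs, "pair_connectivity.tsv")
  m <- report$connectivity$matrix
  wt(cbind(region = rownames(m), as.data.frame(m)),
     "region_change_matrix.tsv")
  if (!is.null(report$connectivity$fits))
    wt(report$connectivity$fits, "connectivity_fits.tsv")
  if (!is.null(report$connectivity_tests))
    wt(report$connectivity_tests, "connectivity_tests.tsv")
  if (!is.null(report$control))
    wt(report$control, "baseline_control.tsv")
  writeLines(c(paste("# run at", format(Sys.time())), report$log),
             file.path(dir, "run_log.txt"))
  invisible(dir)
}
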