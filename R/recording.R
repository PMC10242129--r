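#' @keywords internal
"_PACKAGE"

# Fixed vocabulary of functional regions used for anatomical grouping.
#' Functional region vocabulary
#'
#' The ten broad functional regions used to group anatomical labels:
#' olfactory cortex and associated structures (OlfC), orbitofrontal cortex
#' (OFC), prefrontal cortex (PFC), ventral striatum (vStr), septal area
#' (SepA), integrative thalamic nuclei (IntTh), primary sensorimotor cortex
#' (SenC), dorsal striatum (dStr), temporal association area (TemAA) and
#' sensory thalamic nuclei (SenTh).
#'
#' @format Character vector of length 10.
#' @export
lfp_regions <- c("OlfC", "OFC", "PFC", "vStr", "SepA",
                 "IntTh", "SenC", "dStr", "TemAA", "SenTh")

#' Construct a multichannel LFP recording
#'
#' A recording is a channels-by-samples voltage matrix (microvolts) with a
#' sampling rate and a time origin expressed relative to the drug injection
#' (t = 0 at injection; negative times are pre-drug).
#'
#' @param data Numeric matrix, channels x samples, in microvolts.
#' @param fs Sampling rate in Hz (> 0).
#' @param t0 Time of the first sample in seconds relative to injection.
#' @param channel_ids Character or integer vector, one id per row of `data`.
#' @return An object of class `lfp_recording`.
#' @export
lfp_recording <- function(data, fs, t0 = 0, channel_ids = NULL) {
  if (!is.matrix(data) || !is.numeric(data))
    stop("`data` must be a numeric channels x samples matrix")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a single positive number (Hz)")
  if (anyNA(data))
    stop("recording contains NaN/NA values; gapless data required")
  if (is.null(channel_ids))
    channel_ids <- paste0("ch", seq_len(nrow(data)))
  if (length(channel_ids) != nrow(data))
    stop("length(channel_ids) [", length(channel_ids),
         "] != number of rows in data [", nrow(data), "]")
  if (anyDuplicated(channel_ids))
    stop("channel_ids must be unique")
  structure(
    list(data = data, fs = as.numeric(fs), t0 = as.numeric(t0),
         channel_ids = as.character(channel_ids)),
    class = "lfp_recording")
}

#' @export
print.lfp_recording <- function(x, ...) {
  n <- ncol(x$data)
  cat("<lfp_recording> ", nrow(x$data), " channels x ", n, " samples @ ",
      x$fs, " Hz\n", sep = "")
  cat("  span: [", format(x$t0, digits = 6), ", ",
      format(x$t0 + n / x$fs, digits = 6), ") s relative to injection\n",
      sep = "")
  invisible(x)
}

#' Number of channels / samples in a recording
#' @param rec An `lfp_recording`.
#' @return Integer count.
#' @export
n_channels <- function(rec) nrow(rec$data)

#' @rdname n_channels
#' @export
n_samples <- function(rec) ncol(rec$data)

#' Validate an electrode map
#'
#' The electrode map assigns each channel to an animal, an anatomical label
#' and one of the fixed functional regions (see [lfp_regions]), with
#' optional stereotaxic coordinates (mm) and array grid position
#' (250 um pitch).
#'
#' @param df Data frame with columns `channel_id`, `animal_id`,
#'   `anatomical_label`, `region`, and optionally `ap_mm`, `ml_mm`, `dv_mm`,
#'   `row`, `col`.
#' @return The validated data frame with class `electrode_map`.
#' @export
electrode_map <- function(df) {
  req <- c("channel_id", "animal_id", "anatomical_label", "region")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("electrode map missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$channel_id))
    stop("electrode map channel_id values must be unique")
  bad <- setdiff(unique(df$region), lfp_regions)
  if (length(bad))
    stop("unknown region(s): ", paste(bad, collapse = ", "),
         " (must be one of: ", paste(lfp_regions, collapse = ", "), ")")
  df$channel_id <- as.character(df$channel_id)
  class(df) <- unique(c("electrode_map", class(df)))
  df
}

#' Coerce numeric data to 32-bit float precision
#'
#' Rounds each value to the nearest IEEE-754 single-precision float. The
#' on-disk format stores samples as float32, so a recording round-trips
#' losslessly exactly when its values are float32-representable; this helper
#' makes that explicit.
#'
#' @param x Numeric vector or matrix.
#' @return `x` with every element coerced through float32.
#' @export
as_float32 <- function(x) {
  d <- dim(x)
  out <- readBin(writeBin(as.numeric(x), raw(), size = 4L,
                          endian = "little"),
                 what = "numeric", n = length(x), size = 4L,
                 endian = "little")
  dim(out) <- d
  out
}

#' Write / read a recording directory
#'
#' On-disk layout: `data.bin` (little-endian float32, channel-major: all
#' samples of channel 1, then channel 2, ...) plus a `meta.json` sidecar
#' holding `fs`, `t0`, `channel_ids`, `n_samples` and units. Values are
#' stored at float32 precision (see [as_float32]).
#'
#' @param rec An `lfp_recording`.
#' @param path Directory to create/populate (write) or read from.
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns an `lfp_recording`.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "lfp_recording"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(format = "lfpconnect-rec-v1", fs = rec$fs, t0 = rec$t0,
               channel_ids = rec$channel_ids,
               n_channels = nrow(rec$data), n_samples = ncol(rec$data),
               units = "uV", dtype = "float32-le", order = "channel-major")
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  con <- file(file.path(path, "data.bin"), "wb")
  on.exit(close(con))
  # t() so each channel's samples are contiguous (channel-major)
  writeBin(as.numeric(t(rec$data)), con, size = 4L, endian = "little")
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  mfile <- file.path(path, "meta.json")
  dfile <- file.path(path, "data.bin")
  if (!file.exists(mfile)) stop("no meta.json sidecar in ", path)
  if (!file.exists(dfile)) stop("no data.bin in ", path)
  meta <- jsonlite::read_json(mfile, simplifyVector = TRUE)
  for (f in c("fs", "t0", "channel_ids", "n_channels", "n_samples")) {
    if (is.null(meta[[f]]))
      stop("meta.json missing required field `", f, "`")
  }
  if (meta$fs <= 0) stop("invalid metadata: fs must be > 0, got ", meta$fs)
  nc <- as.integer(meta$n_channels); ns <- as.integer(meta$n_samples)
  if (length(meta$channel_ids) != nc)
    stop("invalid metadata: length(channel_ids) [",
         length(meta$channel_ids), "] != n_channels [", nc, "]")
  con <- file(dfile, "rb")
  on.exit(close(con))
  x <- readBin(con, what = "numeric", n = nc * ns + 1L, size = 4L,
               endian = "little")
  if (length(x) != nc * ns)
    stop("data.bin length mismatch: expected ", nc * ns,
         " samples, found ", length(x))
  if (anyNA(x) || any(!is.finite(x)))
    stop("data.bin contains NaN/Inf values")
  data <- matrix(x, nrow = nc, ncol = ns, byrow = TRUE)
  lfp_recording(data, fs = meta$fs, t0 = meta$t0,
                channel_ids = meta$channel_ids)
}

#' Write / read an electrode map TSV
#'
#' Tab-separated with fixed header `channel_id animal_id anatomical_label
#' region ap_mm ml_mm dv_mm row col`; missing coordinates are written as NA.
#'
#' @param emap An `electrode_map`.
#' @param path File path of the TSV.
#' @export
write_electrode_map <- function(emap, path) {
  emap <- electrode_map(as.data.frame(emap))
  cols <- c("channel_id", "animal_id", "anatomical_label", "region",
            "ap_mm", "ml_mm", "dv_mm", "row", "col")
  for (cl in setdiff(cols, names(emap))) emap[[cl]] <- NA
  utils::write.table(emap[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_electrode_map
#' @export
read_electrode_map <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  electrode_map(df)
}

#' Define an analysis epoch
#'
#' @param t_start,t_end Epoch bounds in seconds relative to injection
#'   (`t_start < t_end`).
#' @param label One of `"baseline"`, `"post"`, `"custom"`.
#' @return An `epoch_spec` object.
#' @export
epoch_spec <- function(t_start, t_end, label = "custom") {
  if (!is.numeric(t_start) || !is.numeric(t_end) || t_start >= t_end)
    stop("epoch requires t_start < t_end, got [", t_start, ", ", t_end, "]")
  label <- match.arg(label, c("baseline", "post", "custom"))
  structure(list(t_start = as.numeric(t_start), t_end = as.numeric(t_end),
                 label = label),
            class = "epoch_spec")
}

as_epoch <- function(x, label = "custom") {
  if (inherits(x, "epoch_spec")) return(x)
  if (is.numeric(x) && length(x) == 2L) return(epoch_spec(x[1], x[2], label))
  stop("epoch must be an epoch_spec or a numeric length-2 vector")
}

#' Extract an epoch from a recording
#'
#' Selects the half-open sample interval corresponding to
#' `[t_start, t_end)`; the epoch must lie entirely within the recording
#' span (no silent clipping).
#'
#' @param rec An `lfp_recording`.
#' @param epoch An [epoch_spec] or numeric `c(t_start, t_end)` in seconds.
#' @return An `lfp_recording` with updated `t0`.
#' @export
select_epoch <- function(rec, epoch) {
  stopifnot(inherits(rec, "lfp_recording"))
  epoch <- as_epoch(epoch)
  n <- ncol(rec$data)
  i0 <- round((epoch$t_start - rec$t0) * rec$fs)
  i1 <- round((epoch$t_end - rec$t0) * rec$fs)
  if (i0 < 0 || i1 > n)
    stop("epoch [", epoch$t_start, ", ", epoch$t_end,
         ") s outside recording span [", rec$t0, ", ", rec$t0 + n / rec$fs,
         ") s")
  lfp_recording(rec$data[, (i0 + 1):i1, drop = FALSE], fs = rec$fs,
                t0 = rec$t0 + i0 / rec$fs, channel_ids = rec$channel_ids)
}

# Split an integer decimation factor into stages <= 10 so the per-stage
# anti-alias filter keeps a numerically safe relative cutoff.
decim_stages <- function(q) {
  stages <- integer(0)
  while (q > 10L) {
    f <- max(Filter(function(d) q %% d == 0L, 2:10), -1L)
    if (f < 2L) break                       # prime factor > 10: single stage
    stages <- c(stages, f)
    q <- q %/% f
  }
  c(stages, q)
}

#' Downsample a recording with anti-alias filtering
#'
#' Zero-phase Chebyshev type-I low-pass (order 8, 0.01 dB ripple, cutoff
#' 0.8 x new Nyquist = 0.4 x target rate) applied forward-backward before
#' decimation; large factors are decimated in stages. Only integer
#' decimation factors are supported.
#'
#' @param rec An `lfp_recording`.
#' @param target_fs Target sampling rate in Hz (must divide `fs`).
#' @return Downsampled `lfp_recording` of length `floor(n * target_fs / fs)`.
#' @export
downsample <- function(rec, target_fs) {
  stopifnot(inherits(rec, "lfp_recording"))
  if (target_fs > rec$fs)
    stop("upsampling not supported: target_fs [", target_fs,
         "] > fs [", rec$fs, "]")
  q <- rec$fs / target_fs
  if (abs(q - round(q)) > 1e-9)
    stop("fs/target_fs must be an integer decimation factor, got ", q)
  q <- as.integer(round(q))
  if (q == 1L) return(rec)
  n_out <- floor(ncol(rec$data) / q)
  x <- rec$data
  fs <- rec$fs
  for (qs in decim_stages(q)) {
    filt <- signal::cheby1(8, 0.01, 0.8 / qs)
    x <- t(apply(x, 1L, function(ch) signal::filtfilt(filt, ch)))
    x <- x[, seq(1L, ncol(x), by = qs), drop = FALSE]
    fs <- fs / qs
  }
  x <- x[, seq_len(n_out), drop = FALSE]
  lfp_recording(x, fs = target_fs, t0 = rec$t0,
                channel_ids = rec$channel_ids)
}

#' Group channels into analyzable regions
#'
#' A region enters the analysis only if it has at least `min_recordings`
#' recorded channels contributed by at least `min_animals` distinct
#' animals; failing regions are dropped with a message.
#'
#' @param emap An [electrode_map].
#' @param min_recordings Minimum channel count per region (default 6).
#' @param min_animals Minimum distinct animals per region (default 3).
#' @return Named list mapping region name to the character vector of
#'   channel_ids; empty list (with a warning) if nothing qualifies.
#' @export
group_regions <- function(emap, min_recordings = 6, min_animals = 3) {
  emap <- electrode_map(as.data.frame(emap))
  out <- list()
  for (rg in intersect(lfp_regions, unique(emap$region))) {
    sub <- emap[emap$region == rg, ]
    if (nrow(sub) >= min_recordings &&
        length(unique(sub$animal_id)) >= min_animals) {
      out[[rg]] <- sub$channel_id
    } else {
      message("region ", rg, " excluded: ", nrow(sub), " recording(s) from ",
              length(unique(sub$animal_id)), " animal(s) (need >= ",
              min_recordings, " from >= ", min_animals, ")")
    }
  }
  if (!length(out) && nrow(emap))
    warning("no region passed the inclusion criterion")
  out
}
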