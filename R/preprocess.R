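#' Deterministic ECoG preprocessing chain
#'
#' The cleaning chain producing 64 Hz, per-block z-scored ROI matrices:
#' drop bad channels, high-pass at 0.1 Hz, despike, common-average reference,
#' 50 Hz notch (2 Hz width), ROI channel selection, downsample to 64 Hz, clip
#' at 3 SD, z-score. High-pass and notch are zero-phase (forward-backward)
#' so that no filter-induced lag contaminates the delay analyses.
#'
#' @name preprocess
NULL

as_channel_matrix <- function(x) {
  if (is.null(dim(x))) matrix(x, ncol = 1) else as.matrix(x)
}

# zero-phase filtering with odd-reflection padding, so that filter start-up
# transients decay inside the pad instead of contaminating the signal (the
# 0.1 Hz high-pass has a multi-second transient)
filtfilt_padded <- function(bf, v) {
  n <- length(v)
  np <- n - 1L  # full-length odd reflection: safest for very low cutoffs
  head_pad <- 2 * v[1] - v[(np + 1L):2L]
  tail_pad <- 2 * v[n] - v[(n - 1L):(n - np)]
  y <- signal::filtfilt(bf, c(head_pad, v, tail_pad))
  y[(np + 1L):(np + n)]
}

#' Zero-phase Butterworth high-pass filter
#'
#' @param x numeric vector or time-by-channels matrix.
#' @param rate_hz sampling rate.
#' @param cutoff_hz cutoff frequency (default 0.1 Hz).
#' @param order filter order (default 2; applied forward and backward).
#' @return filtered data, same shape as `x`.
#' @export
highpass <- function(x, rate_hz, cutoff_hz = 0.1, order = 2) {
  if (cutoff_hz >= rate_hz / 2) stop("cutoff must be below Nyquist")
  bf <- signal::butter(order, cutoff_hz / (rate_hz / 2), type = "high")
  X <- as_channel_matrix(x)
  out <- apply(X, 2, function(v) filtfilt_padded(bf, v))
  if (is.null(dim(x))) drop(out) else out
}

#' Detect and interpolate spikes
#'
#' Samples whose robust z score (median/MAD per channel) exceeds `z_thresh`
#' are replaced by linear interpolation over neighboring clean samples.
#'
#' @param x numeric vector or time-by-channels matrix (finite values).
#' @param z_thresh robust z threshold (default 8).
#' @return repaired data with attribute `n_repaired` (total samples altered).
#' @export
despike <- function(x, z_thresh = 8) {
  X <- as_channel_matrix(x)
  if (any(!is.finite(X))) stop("input must be finite")
  n_rep <- 0L
  for (j in seq_len(ncol(X))) {
    v <- X[, j]
    s <- stats::mad(v)
    if (s == 0) next  # constant (or majority-constant) channel: leave as is
    bad <- abs(v - stats::median(v)) / s > z_thresh
    if (mean(bad) > 0.5) stop("more than 50% of samples flagged in channel ", j)
    if (any(bad)) {
      idx <- which(!bad)
      X[bad, j] <- stats::approx(idx, v[idx], xout = which(bad), rule = 2)$y
      n_rep <- n_rep + sum(bad)
    }
  }
  out <- if (is.null(dim(x))) drop(X) else X
  attr(out, "n_repaired") <- n_rep
  out
}

#' Common average reference
#'
#' Subtracts the per-sample mean across channels from every channel.
#'
#' @param X time-by-channels matrix with >= 2 channels.
#' @return re-referenced matrix (row sums exactly 0).
#' @export
common_average_reference <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) < 2) stop("common average reference needs >= 2 channels")
  X - rowMeans(X)
}

#' Zero-phase notch filter for line noise
#'
#' Band-stop of width `width_hz` centered at `freq_hz` (default 50 +/- 1 Hz).
#'
#' @param x numeric vector or time-by-channels matrix.
#' @param rate_hz sampling rate.
#' @param freq_hz line frequency (default 50).
#' @param width_hz stop-band width (default 2).
#' @param order filter order per edge (default 2).
#' @return filtered data, same shape as `x`.
#' @export
notch <- function(x, rate_hz, freq_hz = 50, width_hz = 2, order = 2) {
  if (freq_hz >= rate_hz / 2) stop("notch frequency must be below Nyquist")
  band <- c(freq_hz - width_hz / 2, freq_hz + width_hz / 2) / (rate_hz / 2)
  bf <- signal::butter(order, band, type = "stop")
  X <- as_channel_matrix(x)
  out <- apply(X, 2, function(v) filtfilt_padded(bf, v))
  if (is.null(dim(x))) drop(out) else out
}

#' Anti-aliased downsampling to the analysis rate
#'
#' Integer-factor decimation with a zero-phase low-pass anti-aliasing filter;
#' non-integer ratios go through polyphase resampling.
#'
#' @param x numeric vector or time-by-channels matrix.
#' @param rate_hz input rate.
#' @param target_hz output rate (default 64).
#' @return downsampled data.
#' @export
downsample <- function(x, rate_hz, target_hz = 64) {
  if (target_hz > rate_hz) stop("target rate exceeds input rate")
  if (target_hz == rate_hz) return(x)
  X <- as_channel_matrix(x)
  if (rate_hz %% target_hz == 0) {
    q <- rate_hz / target_hz
    bf <- signal::butter(6, (0.8 * target_hz / 2) / (rate_hz / 2), type = "low")
    out <- apply(X, 2, function(v) {
      filtfilt_padded(bf, v)[seq(1, length(v), by = q)]
    })
  } else {
    out <- apply(X, 2, function(v) signal::resample(v, target_hz, rate_hz))
  }
  if (is.null(dim(x))) drop(out) else out
}

#' Clip at 3 SD and z-score
#'
#' Values beyond mean +/- 3 SD (per channel, SD computed before clipping) are
#' clamped to the clip limits; the clipped data are then z-scored per channel.
#'
#' @param x numeric vector or time-by-channels matrix.
#' @param n_sd clip limit in SD units (default 3).
#' @return z-scored data (per-channel mean 0 to machine precision).
#' @export
clip_and_zscore <- function(x, n_sd = 3) {
  X <- as_channel_matrix(x)
  for (j in seq_len(ncol(X))) {
    v <- X[, j]
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) stop("zero-variance channel ", j)
    m <- mean(v)
    v <- pmin(pmax(v, m - n_sd * s), m + n_sd * s)
    X[, j] <- (v - mean(v)) / stats::sd(v)
  }
  if (is.null(dim(x))) drop(X) else X
}

#' Read a channel/ROI table
#'
#' TSV with columns `name`, `brodmann`, `roi` (one of `low`, `high`, `none`)
#' and `status` (`good`/`bad`).
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_channel_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "roi", "status")
  if (!all(need %in% names(d)))
    stop("channel table needs columns: ", paste(need, collapse = ", "))
  d
}

#' Run the full preprocessing chain on a raw recording
#'
#' Applies, in order: drop bad channels, high-pass, despike, re-reference
#' (common average, or pass-through for externally re-referenced data), notch,
#' ROI channel selection, downsample to 64 Hz, then per speech block: clip at
#' 3 SD and z-score per channel.
#'
#' @param X time-by-channels matrix at `rate_hz`.
#' @param rate_hz input sampling rate (>= 512 in the intended use).
#' @param channels data.frame as from [read_channel_table()], one row per
#'   column of `X`.
#' @param schedule block schedule ([block_schedule()]).
#' @param target_hz analysis rate (default 64).
#' @param reference `"car"` (default) or `"none"`.
#' @param highpass_hz,notch_hz,notch_width_hz,despike_z,clip_sd stage
#'   parameters.
#' @return list with one element per ROI present (`low`, `high`); each a list
#'   of time-by-electrodes block matrices (speech blocks, in schedule order),
#'   plus attribute `log` describing channels dropped and samples repaired.
#' @export
preprocess_recording <- function(X, rate_hz, channels, schedule,
                                 target_hz = 64, reference = c("car", "none"),
                                 highpass_hz = 0.1, notch_hz = 50,
                                 notch_width_hz = 2, despike_z = 8,
                                 clip_sd = 3) {
  reference <- match.arg(reference)
  X <- as.matrix(X)
  stopifnot(nrow(channels) == ncol(X))
  good <- channels$status != "bad"
  log <- list(n_bad_dropped = sum(!good))
  X <- X[, good, drop = FALSE]
  ch <- channels[good, , drop = FALSE]

  X <- highpass(X, rate_hz, highpass_hz)
  X <- despike(X, despike_z)
  log$n_spike_samples <- attr(X, "n_repaired")
  if (reference == "car") X <- common_average_reference(X)
  X <- notch(X, rate_hz, notch_hz, notch_width_hz)

  sp <- speech_blocks(schedule)
  out <- list()
  for (roi in intersect(c("low", "high"), unique(ch$roi))) {
    Xr <- X[, ch$roi == roi, drop = FALSE]
    if (ncol(Xr) == 0) next
    Xd <- downsample(Xr, rate_hz, target_hz)
    blocks <- lapply(seq_len(nrow(sp)), function(b) {
      i0 <- half_up(sp$start_s[b] * target_hz)
      i1 <- half_up(sp$end_s[b] * target_hz)
      clip_and_zscore(Xd[(i0 + 1):min(i1, nrow(Xd)), , drop = FALSE], clip_sd)
    })
    out[[roi]] <- blocks
  }
  attr(out, "log") <- log
  out
}
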