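#' Boundary timelines on the 64 Hz analysis grid
#'
#' A boundary timeline is a binary sequence per 30-s speech block, with 1s at
#' stimulus-feature on/offsets or at neural state boundaries and 0s elsewhere.
#' It is the common currency of all alignment analyses: stimulus annotations
#' and state segmentations are both reduced to timelines before any match or
#' delay statistic is computed.
#'
#' Internally a timeline stores the 0-based sample indices of its marks per
#' block (equivalent to, and convertible to, the binary vectors); blocks are
#' half-open `[start, end)` intervals of the stimulus.
#'
#' @name timelines
NULL

half_up <- function(x) floor(x + 0.5)

#' Construct a block schedule
#'
#' Alternating music/speech blocks of equal length, starting with music, as in
#' the movie stimulus (13 blocks of 30 s: 7 music, 6 speech). Only speech
#' blocks are materialized in timelines.
#'
#' @param n_speech number of speech blocks (default 6).
#' @param block_s block duration in seconds (default 30).
#' @return data.frame with columns `index`, `kind` ("music"/"speech"),
#'   `start_s`, `end_s`.
#' @export
block_schedule <- function(n_speech = 6, block_s = 30) {
  n <- 2L * n_speech + 1L
  kind <- rep(c("music", "speech"), length.out = n)
  start <- (seq_len(n) - 1L) * block_s
  data.frame(index = seq_len(n), kind = kind,
             start_s = start, end_s = start + block_s)
}

speech_blocks <- function(schedule) schedule[schedule$kind == "speech", , drop = FALSE]

new_boundary_timeline <- function(marks, n_samples, rate_hz, provenance,
                                  block_index = NULL, n_offsets_only = NA_integer_) {
  stopifnot(is.list(marks), length(marks) == length(n_samples), rate_hz > 0)
  marks <- lapply(seq_along(marks), function(i) {
    m <- sort(unique(as.integer(marks[[i]])))
    if (length(m) && (min(m) < 0L || max(m) >= n_samples[i]))
      stop("mark outside block in block ", i)
    m
  })
  structure(list(
    rate_hz = rate_hz,
    marks = marks,
    n_samples = as.integer(n_samples),
    block_index = if (is.null(block_index)) seq_along(marks) else as.integer(block_index),
    provenance = match.arg(provenance, c("stimulus_feature", "neural")),
    n_offsets_only = n_offsets_only
  ), class = "boundary_timeline")
}

#' Number of marks in a boundary timeline
#' @param t a `boundary_timeline`.
#' @return integer total across blocks.
#' @export
n_marks <- function(t) sum(lengths(t$marks))

#' Marks of a timeline as binary vectors
#' @param t a `boundary_timeline`.
#' @return list of 0/1 integer vectors, one per block.
#' @export
timeline_binary <- function(t) {
  lapply(seq_along(t$marks), function(i) {
    v <- integer(t$n_samples[i])
    v[t$marks[[i]] + 1L] <- 1L
    v
  })
}

#' @export
print.boundary_timeline <- function(x, ...) {
  cat(sprintf("<boundary_timeline> %s, %d block(s) @ %g Hz, %d mark(s)\n",
              x$provenance, length(x$marks), x$rate_hz, n_marks(x)))
  invisible(x)
}

#' Read a BIDS-style events table
#'
#' Tab-separated annotation file with an `onset` column plus either `duration`
#' or `offset`, and a feature column (`trial_type` or `feature`); a `label`
#' column is optional.
#'
#' @param path TSV file path.
#' @param feature optionally restrict to one feature (e.g. "word", "clause").
#' @return data.frame with columns `feature`, `onset_s`, `offset_s`, `label`.
#' @export
read_events_tsv <- function(path, feature = NULL) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  fcol <- intersect(c("trial_type", "feature"), names(d))
  if (!length(fcol)) stop("events file needs a trial_type or feature column")
  onset <- as.numeric(d$onset)
  offset <- if ("offset" %in% names(d)) as.numeric(d$offset)
            else if ("duration" %in% names(d)) onset + as.numeric(d$duration)
            else stop("events file needs a duration or offset column")
  ev <- data.frame(feature = d[[fcol[1]]], onset_s = onset, offset_s = offset,
                   label = if ("label" %in% names(d)) d$label else NA_character_,
                   stringsAsFactors = FALSE)
  if (!is.null(feature)) ev <- ev[ev$feature %in% feature, , drop = FALSE]
  validate_events(ev)
}

validate_events <- function(ev) {
  stopifnot(all(c("feature", "onset_s", "offset_s") %in% names(ev)))
  if (any(ev$onset_s >= ev$offset_s)) stop("event onset must precede offset")
  ev <- ev[order(ev$onset_s), , drop = FALSE]
  for (f in unique(ev$feature)) {
    e <- ev[ev$feature == f, ]
    if (nrow(e) > 1 && any(e$onset_s[-1] < e$offset_s[-nrow(e)] - 1e-9))
      warning("overlapping events within feature '", f, "'")
  }
  rownames(ev) <- NULL
  ev
}

# Map a time to (block row, 0-based sample) on the grid; NA row when the time
# falls outside every speech block. Nearest-sample rounding, half-up.
locate_time <- function(time_s, sp, rate_hz) {
  row <- findInterval(time_s, sp$start_s)
  inside <- row >= 1 & row <= nrow(sp) & time_s < sp$end_s[pmax(row, 1L)]
  row[!inside] <- NA_integer_
  samp <- half_up((time_s - sp$start_s[row]) * rate_hz)
  L <- as.integer(half_up((sp$end_s - sp$start_s) * rate_hz))
  samp <- pmin(pmax(samp, 0L), L[row] - 1L)
  list(row = row, sample = as.integer(samp))
}

#' Build a stimulus-feature boundary timeline
#'
#' Places a 1 at the nearest grid sample of every event onset and every event
#' offset within speech blocks. An offset that lands on the same grid sample
#' as a subsequent onset yields a single mark; the tally of
#' offsets-without-coincident-onset is retained on the timeline.
#'
#' @param events data.frame as returned by [read_events_tsv()].
#' @param schedule block schedule from [block_schedule()].
#' @param rate_hz grid rate (default 64).
#' @param out_of_block policy for events outside every speech block:
#'   `"drop"` (with warning, default) or `"error"`. Events spanning a block
#'   edge are clipped to the block containing their onset, with a warning.
#' @return a `boundary_timeline` with provenance `"stimulus_feature"`.
#' @export
build_feature_timeline <- function(events, schedule, rate_hz = 64,
                                   out_of_block = c("drop", "error")) {
  out_of_block <- match.arg(out_of_block)
  events <- validate_events(events)
  sp <- speech_blocks(schedule)
  L <- as.integer(half_up((sp$end_s - sp$start_s) * rate_hz))

  on <- locate_time(events$onset_s, sp, rate_hz)
  off <- locate_time(events$offset_s, sp, rate_hz)

  oob <- is.na(on$row) & is.na(off$row)
  if (any(oob)) {
    msg <- sprintf("%d event(s) outside every speech block", sum(oob))
    if (out_of_block == "error") stop(msg)
    warning(msg, "; dropped")
  }
  span <- !oob & (is.na(on$row) | is.na(off$row) |
                    (!is.na(on$row) & !is.na(off$row) & on$row != off$row))
  if (any(span)) {
    warning(sum(span), " event(s) span a block edge; clipped to the block")
    # an onset (offset) outside the partner's block snaps to that block's
    # edge sample
    fix <- which(span & !is.na(on$row) & is.na(off$row))
    off$row[fix] <- on$row[fix]; off$sample[fix] <- L[on$row[fix]] - 1L
    fix <- which(span & is.na(on$row) & !is.na(off$row))
    on$row[fix] <- off$row[fix]; on$sample[fix] <- 0L
    fix <- which(span & !is.na(on$row) & !is.na(off$row) & on$row != off$row)
    off$row[fix] <- on$row[fix]; off$sample[fix] <- L[on$row[fix]] - 1L
  }

  keep <- !oob
  marks <- vector("list", nrow(sp))
  n_offsets_only <- 0L
  for (b in seq_len(nrow(sp))) {
    ons <- on$sample[keep & on$row == b]
    offs <- off$sample[keep & off$row == b]
    n_offsets_only <- n_offsets_only + sum(!(offs %in% ons))
    marks[[b]] <- sort(unique(c(ons, offs)))
  }
  new_boundary_timeline(marks, L, rate_hz, "stimulus_feature",
                        block_index = sp$index, n_offsets_only = n_offsets_only)
}

#' Shift a timeline by a whole number of samples
#'
#' Marks move by `delay_samples` within their block; marks shifted past a
#' block edge are dropped (blocks are separate recordings of stimulus context,
#' so wrapping would fabricate cross-block alignments).
#'
#' @param t a `boundary_timeline`.
#' @param delay_samples integer shift (positive = later).
#' @return shifted `boundary_timeline`.
#' @export
shift_timeline <- function(t, delay_samples) {
  d <- as.integer(delay_samples)
  if (abs(d) > max(t$n_samples)) stop("|delay_samples| exceeds block length")
  t$marks <- lapply(seq_along(t$marks), function(i) {
    m <- t$marks[[i]] + d
    m[m >= 0L & m < t$n_samples[i]]
  })
  t
}

#' Convert state-segmentation boundaries to a neural timeline
#'
#' A boundary is the first sample of a new state; the block start is not a
#' mark.
#'
#' @param boundaries list (one element per block) of strictly increasing
#'   0-based boundary sample indices, or a single integer vector for one
#'   block.
#' @param n_samples samples per block (recycled).
#' @param rate_hz grid rate.
#' @param block_index optional stimulus block indices.
#' @return a `boundary_timeline` with provenance `"neural"`.
#' @export
boundaries_to_timeline <- function(boundaries, n_samples = 1920, rate_hz = 64,
                                   block_index = NULL) {
  if (!is.list(boundaries)) boundaries <- list(boundaries)
  n_samples <- rep_len(as.integer(n_samples), length(boundaries))
  for (i in seq_along(boundaries)) {
    b <- boundaries[[i]]
    if (length(b) && (any(diff(b) <= 0) || min(b) <= 0 || max(b) >= n_samples[i]))
      stop("boundaries must be strictly increasing within (0, block length)")
  }
  new_boundary_timeline(boundaries, n_samples, rate_hz, "neural",
                        block_index = block_index)
}

#' Marks and offset-only tallies of a stimulus timeline
#'
#' @param t a `boundary_timeline` built by [build_feature_timeline()].
#' @return list with `n_marks` (total 1s) and `n_offsets_only` (offsets with
#'   no coincident onset at the same grid sample).
#' @export
count_events <- function(t) {
  if (t$provenance != "stimulus_feature" || is.na(t$n_offsets_only))
    stop("offset tallies are defined only for stimulus-feature timelines")
  list(n_marks = n_marks(t), n_offsets_only = t$n_offsets_only)
}

#' Write / read a timeline as TSV with a JSON tally sidecar
#'
#' The TSV has one row per mark (`block`, `sample`, `time_s`, time relative to
#' block start); `<path>.json` records rate, provenance, block lengths and
#' tallies so the timeline round-trips.
#'
#' @param t a `boundary_timeline`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_timeline_tsv <- function(t, path) {
  rows <- do.call(rbind, lapply(seq_along(t$marks), function(i) {
    m <- t$marks[[i]]
    if (!length(m)) return(NULL)
    data.frame(block = t$block_index[i], sample = m, time_s = m / t$rate_hz)
  }))
  if (is.null(rows)) rows <- data.frame(block = integer(), sample = integer(),
                                        time_s = numeric())
  utils::write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
  side <- list(rate_hz = t$rate_hz, provenance = t$provenance,
               block_index = t$block_index, n_samples = t$n_samples,
               n_marks = n_marks(t))
  if (!is.na(t$n_offsets_only)) side$n_offsets_only <- t$n_offsets_only
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_timeline_tsv
#' @export
read_timeline_tsv <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  d <- utils::read.delim(path)
  marks <- lapply(side$block_index, function(b) d$sample[d$block == b])
  new_boundary_timeline(marks, side$n_samples, side$rate_hz, side$provenance,
                        block_index = side$block_index,
                        n_offsets_only = if (is.null(side$n_offsets_only))
                          NA_integer_ else side$n_offsets_only)
}
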