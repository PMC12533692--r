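#' Ground-truthed synthetic cohorts
#'
#' Generates block-structured two-ROI recordings with piecewise-stable
#' multivariate patterns (states change instantaneously), a planted inter-ROI
#' boundary lag, stimulus event tables locked to the neural boundaries at
#' planted delays with jitter, and configurable spurious/missing stimulus
#' marks. Every pipeline stage is testable against the emitted ground truth
#' without any external data.
#'
#' @name synthetic
NULL

#' Specification of a synthetic cohort
#'
#' Defaults describe the emulated study conditions: 6 speech blocks of 30 s at
#' 64 Hz, 16 electrodes per ROI, 15 to 40 states per block with a minimum
#' state duration of 8 samples, unit-norm i.i.d. Gaussian state patterns with
#' white noise of SD 0.3, 70% of boundaries shared between ROIs at an
#' inter-ROI lag of -123 ms (high-level leads), stimulus-to-neural delays of
#' 273 ms (low ROI) and 150 ms (high ROI) so that the lag equals the delay
#' difference, 1-sample event jitter, and 10% extra / 10% dropped stimulus
#' marks.
#'
#' @param n_subjects number of subjects.
#' @param n_blocks number of speech blocks.
#' @param block_s block duration (seconds).
#' @param rate_hz sampling rate of the emitted (preprocessed-equivalent)
#'   recordings.
#' @param n_channels electrodes per ROI.
#' @param n_states_range inclusive integer range for the per-block number of
#'   states.
#' @param min_duration minimum state duration in samples (>= 2).
#' @param noise_sd white-noise SD relative to the unit-norm state patterns.
#' @param shared_fraction fraction of low-ROI boundaries copied (with lag)
#'   into the high ROI.
#' @param lag_s planted inter-ROI lag in seconds (negative: high-level ROI
#'   leads).
#' @param delay_s named vector `c(low = , high = )`: stimulus-to-neural delay
#'   per ROI in seconds.
#' @param jitter_sd_s SD of stimulus event-time jitter (seconds).
#' @param extra_rate expected fraction of spurious stimulus marks added.
#' @param drop_rate probability that a designated stimulus mark is dropped.
#' @param event_fraction fraction of low-ROI boundaries designated as clause
#'   on/offsets.
#' @param stimulus_locked if `FALSE`, stimulus marks are placed uniformly at
#'   random instead of at boundaries (planted-null cohorts).
#' @param orthogonal_patterns if `TRUE`, the state mean patterns of a block
#'   are mutually orthogonal (requires `n_states <= n_channels`); the default
#'   `FALSE` draws i.i.d. unit-norm patterns, which carry chance similarity
#'   between states. Orthogonal patterns give every boundary equal strength
#'   and are the right stress test for boundary-recovery checks.
#' @param seed RNG seed for the cohort.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_subjects = 10, n_blocks = 6, block_s = 30,
                           rate_hz = 64, n_channels = 16,
                           n_states_range = c(15, 40), min_duration = 8,
                           noise_sd = 0.3, shared_fraction = 0.7,
                           lag_s = -0.123,
                           delay_s = c(low = 0.273, high = 0.150),
                           jitter_sd_s = 1 / 64, extra_rate = 0.1,
                           drop_rate = 0.1, event_fraction = 0.8,
                           stimulus_locked = TRUE,
                           orthogonal_patterns = FALSE, seed = 1) {
  stopifnot(n_subjects >= 1, min_duration >= 2, abs(lag_s) <= 0.6,
            all(abs(delay_s) <= 0.6),
            shared_fraction >= 0, shared_fraction <= 1,
            extra_rate >= 0, extra_rate <= 1, drop_rate >= 0, drop_rate <= 1,
            event_fraction >= 0, event_fraction <= 1)
  structure(as.list(environment()), class = "synthetic_spec")
}

sample_vec <- function(x, n) x[sample.int(length(x), n)]  # no length-1 surprise

# k state durations >= min_dur summing to T, uniformly over compositions
random_durations <- function(T_, k, min_dur) {
  if (k * min_dur > T_) stop("infeasible duration constraints: ",
                             k, " states of >= ", min_dur, " samples in ", T_)
  extra <- T_ - k * min_dur
  as.vector(min_dur + stats::rmultinom(1, extra, rep(1, k)))
}

# fresh boundaries keeping >= 2 samples from existing ones and block edges
draw_fresh_boundaries <- function(existing, n, T_) {
  cand <- setdiff(2:(T_ - 2), unique(as.vector(outer(existing, -1:1, "+"))))
  picked <- integer(0)
  while (length(picked) < n && length(cand) > 0) {
    p <- cand[sample.int(length(cand), 1)]
    picked <- c(picked, p)
    cand <- setdiff(cand, (p - 1):(p + 1))
  }
  sort(picked)
}

emit_state_data <- function(boundaries, T_, n_channels, noise_sd,
                            orthogonal = FALSE) {
  k <- length(boundaries) + 1L
  if (orthogonal) {
    if (k > n_channels)
      stop("orthogonal patterns need n_states <= n_channels")
    pat <- t(qr.Q(qr(matrix(stats::rnorm(n_channels * k), n_channels, k))))
  } else {
    pat <- matrix(stats::rnorm(k * n_channels), k)
    pat <- pat / sqrt(rowSums(pat^2))
  }
  state_id <- findInterval(0:(T_ - 1), boundaries) + 1L
  X <- pat[state_id, , drop = FALSE]
  if (noise_sd > 0) X <- X + noise_sd * matrix(stats::rnorm(T_ * n_channels), T_)
  scale(X)[, , drop = FALSE]
}

#' Generate one synthetic block for both ROIs
#'
#' Low-ROI boundaries are drawn first (durations from the spec); the high ROI
#' copies a shared fraction of them shifted by the planted lag (clipped to the
#' block) and replaces the rest with independent boundaries. Each state emits
#' its unit-norm mean pattern plus i.i.d. Gaussian noise; channels are
#' z-scored. Uses R's global RNG.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `low` and `high` (time-by-electrodes matrices) and
#'   `truth` (planted boundaries per ROI, shared set, lag in samples).
#' @export
generate_block <- function(spec) {
  T_ <- round(spec$block_s * spec$rate_hz)
  k <- spec$n_states_range[1] +
    sample.int(spec$n_states_range[2] - spec$n_states_range[1] + 1L, 1) - 1L
  b_low <- cumsum(random_durations(T_, k, spec$min_duration))
  b_low <- b_low[-length(b_low)]
  lag <- round(spec$lag_s * spec$rate_hz)

  n_shared <- round(spec$shared_fraction * length(b_low))
  shared <- sort(sample_vec(b_low, n_shared))
  shifted <- sort(unique(pmin(pmax(shared + lag, 1L), T_ - 1L)))
  b_high <- sort(unique(c(shifted,
                          draw_fresh_boundaries(c(0L, shifted, T_),
                                                length(b_low) - length(shifted),
                                                T_))))
  list(low = emit_state_data(b_low, T_, spec$n_channels, spec$noise_sd,
                             spec$orthogonal_patterns),
       high = emit_state_data(b_high, T_, spec$n_channels, spec$noise_sd,
                              spec$orthogonal_patterns),
       truth = list(b_low = b_low, b_high = b_high, shared = shared,
                    lag_samples = lag, n_states_low = k))
}

#' Generate a stimulus event table locked to planted boundaries
#'
#' A random subset of the planted low-ROI boundaries is designated as clause
#' on/offsets placed at `boundary_time - delay_s["low"]` with Gaussian jitter;
#' spurious marks are inserted and a fraction of marks dropped. Consecutive
#' marks within a block are paired into (onset, offset) events, so the feature
#' timeline built from the table reproduces exactly the surviving mark set.
#'
#' @param truths list of per-block `truth` elements from [generate_block()].
#' @param spec a [synthetic_spec()].
#' @param schedule block schedule covering the speech blocks.
#' @return data.frame event table (`feature`, `onset_s`, `offset_s`, `label`).
#' @export
generate_stimulus_events <- function(truths, spec, schedule) {
  sp <- speech_blocks(schedule)
  stopifnot(nrow(sp) == length(truths))
  rate <- spec$rate_hz
  rows <- list()
  for (b in seq_along(truths)) {
    bl <- truths[[b]]$b_low
    if (spec$stimulus_locked) {
      n_des <- round(spec$event_fraction * length(bl))
      des <- sort(sample_vec(bl, n_des))
      times <- des / rate - spec$delay_s[["low"]] +
        stats::rnorm(n_des, 0, spec$jitter_sd_s)
    } else {
      n_des <- round(spec$event_fraction * length(bl))
      times <- stats::runif(n_des, 0, spec$block_s)
    }
    n_extra <- stats::rbinom(1, length(times), spec$extra_rate)
    times <- c(times, stats::runif(n_extra, 0, spec$block_s))
    times <- times[stats::runif(length(times)) >= spec$drop_rate]
    times <- sort(times[times >= 0 & times < spec$block_s - 1 / rate])
    if (length(times) > 1)
      times <- times[c(TRUE, diff(times) >= 1 / rate)]
    if (length(times) %% 2 == 1) times <- times[-length(times)]
    if (!length(times)) next
    on <- times[seq(1, length(times), by = 2)] + sp$start_s[b]
    off <- times[seq(2, length(times), by = 2)] + sp$start_s[b]
    rows[[b]] <- data.frame(feature = "clause", onset_s = on, offset_s = off,
                            label = NA_character_)
  }
  ev <- do.call(rbind, rows)
  if (is.null(ev))
    ev <- data.frame(feature = character(), onset_s = numeric(),
                     offset_s = numeric(), label = character())
  rownames(ev) <- NULL
  ev
}

#' Generate a full synthetic cohort
#'
#' Independent subjects from one seed sequence; the manifest (returned as part
#' of the cohort) records the spec and every per-subject seed so any subject
#' can be regenerated in isolation.
#'
#' @param spec a [synthetic_spec()].
#' @return list of class `synthetic_cohort`: `subjects` (each with `id`,
#'   `blocks` = list of `low`/`high` block matrices, `truths`, `events`,
#'   `seed`), `schedule`, `spec`.
#' @export
generate_cohort <- function(spec) {
  set.seed(spec$seed)
  schedule <- block_schedule(spec$n_blocks, spec$block_s)
  seeds <- sample.int(.Machine$integer.max, spec$n_subjects)
  subjects <- lapply(seq_len(spec$n_subjects), function(i) {
    set.seed(seeds[i])
    blocks <- lapply(seq_len(spec$n_blocks), function(b) generate_block(spec))
    truths <- lapply(blocks, `[[`, "truth")
    list(id = sprintf("sub-%02d", i),
         blocks = list(low = lapply(blocks, `[[`, "low"),
                       high = lapply(blocks, `[[`, "high")),
         truths = truths,
         events = generate_stimulus_events(truths, spec, schedule),
         seed = seeds[i])
  })
  structure(list(subjects = subjects, schedule = schedule, spec = spec),
            class = "synthetic_cohort")
}

#' Planted ground-truth boundary timeline of one subject
#'
#' @param subject one element of a `synthetic_cohort`'s `subjects`.
#' @param roi `"low"` or `"high"`.
#' @param spec the cohort's `synthetic_spec`.
#' @return a neural `boundary_timeline` of the planted boundaries.
#' @export
ground_truth_timeline <- function(subject, roi = c("low", "high"), spec) {
  roi <- match.arg(roi)
  f <- if (roi == "low") "b_low" else "b_high"
  boundaries_to_timeline(lapply(subject$truths, `[[`, f),
                         n_samples = round(spec$block_s * spec$rate_hz),
                         rate_hz = spec$rate_hz)
}

#' Raw-mode synthetic block (512 Hz with artifacts)
#'
#' Emits the same piecewise-stable pattern structure at 512 Hz with a slow
#' drift, common 50 Hz line noise, and sparse large spikes, to exercise the
#' preprocessing chain. Returns the raw matrix together with the planted
#' boundaries (in 64 Hz samples).
#'
#' @param spec a [synthetic_spec()].
#' @param raw_rate_hz raw sampling rate (multiple of `rate_hz`).
#' @param drift_amp,line_amp,spike_rate artifact amplitudes (SD units) and
#'   per-sample spike probability.
#' @return list with `raw` (time-by-channels at `raw_rate_hz`) and `truth`.
#' @export
generate_block_raw <- function(spec, raw_rate_hz = 512, drift_amp = 5,
                               line_amp = 2, spike_rate = 2e-4) {
  stopifnot(raw_rate_hz %% spec$rate_hz == 0)
  up <- raw_rate_hz / spec$rate_hz
  blk <- generate_block(spec)
  T64 <- round(spec$block_s * spec$rate_hz)
  Tr <- T64 * up
  raws <- lapply(c("low", "high"), function(roi) {
    X <- blk[[roi]][rep(seq_len(T64), each = up), , drop = FALSE]
    tt <- (0:(Tr - 1)) / raw_rate_hz
    drift <- drift_amp * sin(2 * pi * 0.02 * tt + stats::runif(1, 0, 2 * pi))
    line <- line_amp * sin(2 * pi * 50 * tt + stats::runif(1, 0, 2 * pi))
    X <- X + drift + line
    n_spk <- stats::rbinom(1, Tr * ncol(X), spike_rate)
    if (n_spk > 0) {
      i <- sample.int(Tr * ncol(X), n_spk)
      X[i] <- X[i] + sample(c(-1, 1), n_spk, TRUE) * stats::runif(n_spk, 30, 60)
    }
    X
  })
  names(raws) <- c("low", "high")
  list(raw = raws, truth = blk$truth, clean = blk[c("low", "high")])
}
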