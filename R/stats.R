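#' Subject- and group-level analyses
#'
#' Orchestrates the per-subject segmentation and alignment analyses and the
#' nonparametric group tests: one-tailed Wilcoxon signed-rank tests on
#' relative Gaussian matches (stimulus alignment, inter-ROI alignment) and the
#' two-tailed test on the per-subject difference of optimal delays between
#' ROIs, which carries the top-down versus bottom-up conclusion.
#'
#' @name stats_pipeline
NULL

#' Wilcoxon signed-rank test
#'
#' One-sample signed-rank test against zero. Zeros are dropped (standard
#' convention). The p-value is exact for small samples: for n <= 16 the full
#' sign-flip distribution of the statistic is enumerated (valid with tied
#' absolute values, which arise naturally for delays on a sample grid); for
#' 16 < n <= 25 without ties the exact distribution from
#' [stats::wilcox.test()] is used; otherwise the normal approximation with
#' continuity correction.
#'
#' @param values numeric vector.
#' @param alternative `"greater"` (one-tailed) or `"two_sided"`.
#' @return list of class `group_test`: `statistic`, `p_value`, `n` (after
#'   zero removal), `n_zeros_dropped`, `alternative`, `values`.
#' @export
wilcoxon_signed_rank <- function(values, alternative = c("greater", "two_sided")) {
  alternative <- match.arg(alternative)
  x <- values[values != 0]
  n <- length(x)
  if (!n) stop("all values are zero; signed-rank test undefined")
  r <- rank(abs(x))
  V <- sum(r[x > 0])
  if (n <= 16) {
    # all 2^n sign assignments; the null distribution is symmetric about
    # sum(r)/2, so the two-sided p is the centered tail probability
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    Vs <- drop(signs %*% r)
    p <- if (alternative == "greater") mean(Vs >= V - 1e-9)
         else mean(abs(Vs - sum(r) / 2) >= abs(V - sum(r) / 2) - 1e-9)
  } else {
    exact <- n <= 25 && !any(duplicated(abs(x)))
    ht <- suppressWarnings(stats::wilcox.test(
      x, mu = 0,
      alternative = if (alternative == "greater") "greater" else "two.sided",
      exact = exact, correct = TRUE))
    p <- ht$p.value
  }
  structure(list(statistic = V, p_value = p,
                 n = n, n_zeros_dropped = length(values) - n,
                 alternative = alternative, values = values),
            class = "group_test")
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf("<group_test> Wilcoxon signed-rank (%s), n = %d: V = %g, p = %.4g\n",
              x$alternative, x$n, x$statistic, x$p_value))
  invisible(x)
}

#' Segment all blocks of one ROI and stabilize the state count
#'
#' Runs states-GSBS per block, averages the t-distance curves across blocks to
#' pick the cross-block optimal number of states, fine-tunes the count per
#' block to the nearest t-distance peak, and assembles the neural boundary
#' timeline.
#'
#' @param blocks list of time-by-electrodes matrices (one per speech block).
#' @param config a [gsbs_config()].
#' @param rate_hz sampling rate of the blocks.
#' @return list of class `roi_segmentation`: `fits`, `k_star`, `k_blocks`,
#'   `boundaries` (per block), `timeline`, `n_boundaries`.
#' @export
segment_roi_blocks <- function(blocks, config = gsbs_config(), rate_hz = 64) {
  fits <- lapply(blocks, gsbs_segment, config = config)
  k_star <- select_nstates_global(fits)
  k_blocks <- vapply(fits, select_nstates_block, integer(1), k_star = k_star)
  boundaries <- Map(gsbs_boundaries, fits, k_blocks)
  timeline <- boundaries_to_timeline(boundaries,
                                     n_samples = vapply(blocks, nrow, 1L),
                                     rate_hz = rate_hz)
  structure(list(fits = fits, k_star = k_star, k_blocks = k_blocks,
                 boundaries = boundaries, timeline = timeline,
                 n_boundaries = sum(k_blocks - 1L)),
            class = "roi_segmentation")
}

#' Group-level stimulus-alignment analysis
#'
#' Per subject, the chance-normalized maximum Gaussian match between the
#' stimulus feature timeline (seed) and the subject's neural timeline, then a
#' one-tailed Wilcoxon signed-rank test on the per-subject relative matches.
#' Subjects with a missing neural timeline (e.g. no electrodes in the ROI) are
#' excluded and reported.
#'
#' @param neural list (one per subject, possibly with `NULL` entries) of
#'   neural `boundary_timeline` objects.
#' @param stimulus a stimulus `boundary_timeline`, or a list of them (one per
#'   subject, e.g. synthetic cohorts with per-subject annotations).
#' @param n_perm permutations for the null (default 1000).
#' @param sigma_s,max_delay_s match parameters.
#' @param rng_seed optional seed set once before the per-subject loop.
#' @return list of class `alignment_analysis`: `group` ([wilcoxon_signed_rank()]
#'   on the relative matches), `per_subject` (named `relative_match_result`
#'   list), `relative`, `optimal_delay_s`, `excluded`.
#' @export
run_alignment_analysis <- function(neural, stimulus, n_perm = 1000,
                                   sigma_s = 0.332, max_delay_s = 0.6,
                                   rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  ids <- names(neural)
  if (is.null(ids)) ids <- sprintf("sub-%02d", seq_along(neural))
  keep <- !vapply(neural, is.null, logical(1))
  if (any(!keep))
    message("excluding ", sum(!keep), " subject(s) without this ROI: ",
            paste(ids[!keep], collapse = ", "))
  per <- lapply(which(keep), function(i) {
    st <- if (inherits(stimulus, "boundary_timeline")) stimulus else stimulus[[i]]
    relative_match(st, neural[[i]], mode = "stimulus_vs_neural",
                   shuffle_target = "other", n_perm = n_perm,
                   sigma_s = sigma_s, max_delay_s = max_delay_s)
  })
  names(per) <- ids[keep]
  rel <- vapply(per, `[[`, numeric(1), "relative")
  if (length(rel) < 2) warning("group test over fewer than 2 subjects is degenerate")
  structure(list(group = wilcoxon_signed_rank(rel, "greater"),
                 per_subject = per, relative = rel,
                 optimal_delay_s = vapply(per, `[[`, numeric(1), "optimal_delay_s"),
                 excluded = ids[!keep]),
            class = "alignment_analysis")
}

#' Contrast of optimal stimulus delays between ROIs
#'
#' Subtracts each subject's optimal delay with the stimulus feature in the
#' low-level ROI from the delay in the high-level ROI and applies a two-tailed
#' Wilcoxon signed-rank test. Only subjects with an above-chance relative
#' match (relative > 0) in both ROIs enter the contrast; a negative mean
#' difference means boundaries occur in the high-level ROI first (top-down).
#'
#' @param low,high `alignment_analysis` objects for the two ROIs.
#' @return list of class `delay_contrast`: `group`, `diff_s` (per eligible
#'   subject, high minus low, seconds), `eligible`, `excluded`.
#' @export
run_delay_contrast <- function(low, high) {
  ids <- intersect(names(low$per_subject), names(high$per_subject))
  eligible <- ids[low$relative[ids] > 0 & high$relative[ids] > 0]
  if (length(eligible) < 2)
    stop("fewer than 2 subjects with above-chance match in both ROIs")
  diffs <- high$optimal_delay_s[eligible] - low$optimal_delay_s[eligible]
  structure(list(group = wilcoxon_signed_rank(diffs, "two_sided"),
                 diff_s = diffs, eligible = eligible,
                 excluded = setdiff(ids, eligible)),
            class = "delay_contrast")
}

#' Alignment at a matched (non-optimal) number of states
#'
#' Re-runs the stimulus-alignment analysis for one subject using the greedy
#' path solution whose total boundary count equals `target_count` (e.g. the
#' number of word on/offset marks) instead of the t-distance optimum. Starting
#' from the selected per-block counts, boundaries are added to the blocks with
#' the fewest (or removed from the blocks with the most) until the total
#' matches, so a target equal to the selected total reproduces the main
#' analysis exactly.
#'
#' @param roi_seg a `roi_segmentation` (with retained `fits`).
#' @param stimulus stimulus `boundary_timeline`.
#' @param target_count desired total number of neural boundaries.
#' @param n_perm,sigma_s,max_delay_s match parameters.
#' @return list: `result` (a `relative_match_result`), `timeline`,
#'   `k_blocks`, `n_boundaries` (achieved total).
#' @export
run_matched_nstates_control <- function(roi_seg, stimulus, target_count,
                                        n_perm = 1000, sigma_s = 0.332,
                                        max_delay_s = 0.6) {
  fits <- roi_seg$fits
  nb <- length(fits)
  cnt_max <- vapply(fits, function(f) f$kmax - 1L, integer(1))
  if (target_count > sum(cnt_max))
    stop("target_count exceeds the maximum boundaries on the greedy paths (",
         sum(cnt_max), ")")
  cnt <- roi_seg$k_blocks - 1L
  while (sum(cnt) < target_count) {
    i <- which(cnt < cnt_max)
    i <- i[which.min(cnt[i])]
    cnt[i] <- cnt[i] + 1L
  }
  while (sum(cnt) > target_count) {
    i <- which(cnt > 0L)
    i <- i[which.max(cnt[i])]
    cnt[i] <- cnt[i] - 1L
  }
  k_blocks <- cnt + 1L
  boundaries <- Map(gsbs_boundaries, fits, k_blocks)
  timeline <- boundaries_to_timeline(
    boundaries, n_samples = vapply(fits, `[[`, 1L, "n_time"),
    rate_hz = stimulus$rate_hz)
  res <- relative_match(stimulus, timeline, mode = "stimulus_vs_neural",
                        shuffle_target = "other", n_perm = n_perm,
                        sigma_s = sigma_s, max_delay_s = max_delay_s)
  list(result = res, timeline = timeline, k_blocks = k_blocks,
       n_boundaries = sum(k_blocks - 1L))
}

#' Median neural state duration
#'
#' Pools state durations (including first and last partial states) across all
#' blocks of a segmentation and returns the median in seconds.
#'
#' @param boundaries list of per-block boundary vectors, or a
#'   `roi_segmentation`.
#' @param n_samples samples per block (recycled).
#' @param rate_hz sampling rate.
#' @return median duration in seconds.
#' @export
median_state_duration <- function(boundaries, n_samples = 1920, rate_hz = 64) {
  if (inherits(boundaries, "roi_segmentation")) {
    n_samples <- vapply(boundaries$fits, `[[`, 1L, "n_time")
    boundaries <- boundaries$boundaries
  }
  n_samples <- rep_len(as.integer(n_samples), length(boundaries))
  dur <- unlist(lapply(seq_along(boundaries), function(i) {
    diff(c(0L, boundaries[[i]], n_samples[i]))
  }))
  stats::median(dur) / rate_hz
}
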