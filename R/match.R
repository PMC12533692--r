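#' Gaussian boundary match, delay scanning, and the state-shuffle null
#'
#' The Gaussian match between two boundary timelines is the mean, over marks
#' of a seed timeline, of a unit-amplitude Gaussian (SD 332 ms, mean 0)
#' evaluated at the distance to the temporally closest mark in the other
#' timeline within the same block. It is 1 when every seed mark has an exact
#' counterpart and decays smoothly with misalignment; it is deliberately
#' asymmetric in the choice of seed. Scanning the match over a grid of
#' sample-step delays yields the optimal delay between the timelines; a
#' permutation null obtained by shuffling state durations converts the raw
#' match into a chance-normalized (relative) match.
#'
#' @name match
NULL

#' Gaussian boundary weight
#'
#' `exp(-delta^2 / (2 sigma^2))`: the amplitude of a unit Gaussian projected
#' on one boundary, evaluated at temporal distance `delta_s` from it.
#'
#' @param delta_s temporal distance in seconds (sign irrelevant).
#' @param sigma_s Gaussian SD in seconds (default 0.332).
#' @return weight in (0, 1].
#' @export
gaussian_weight <- function(delta_s, sigma_s = 0.332) {
  stopifnot(sigma_s > 0)
  exp(-delta_s^2 / (2 * sigma_s^2))
}

check_compatible <- function(a, b) {
  if (length(a$marks) != length(b$marks) ||
      any(a$n_samples != b$n_samples) || a$rate_hz != b$rate_hz)
    stop("timelines have incompatible block structure")
}

# Gaussian match for each delay in `delays` (samples): the seed timeline is
# shifted by the delay; marks shifted past a block edge, and seed marks in
# blocks where `other` has no marks, are excluded from the mean.
match_over_delays <- function(seed, other, delays, sigma_s) {
  rate <- seed$rate_hz
  nd <- length(delays)
  wsum <- numeric(nd)
  wn <- numeric(nd)
  for (i in seq_along(seed$marks)) {
    s <- seed$marks[[i]]
    o <- other$marks[[i]]
    if (!length(s) || !length(o)) next
    L <- seed$n_samples[i]
    pos <- outer(s, delays, "+")
    p <- as.vector(pos)
    idx <- findInterval(p, o)
    no <- length(o)
    dl <- p - o[pmax(idx, 1L)]
    dl[idx < 1L] <- Inf
    dr <- o[pmin(idx + 1L, no)] - p
    dr[idx >= no] <- Inf
    w <- gaussian_weight(pmin(dl, dr) / rate, sigma_s)
    w[p < 0 | p >= L] <- NA
    W <- matrix(w, nrow = length(s))
    wsum <- wsum + colSums(W, na.rm = TRUE)
    wn <- wn + colSums(!is.na(W))
  }
  ifelse(wn > 0, wsum / wn, NA_real_)
}

count_excluded <- function(seed, other) {
  sum(lengths(seed$marks)[lengths(other$marks) == 0])
}

#' Gaussian match between two timelines
#'
#' For every mark in the seed timeline, the weight of the closest mark in the
#' other timeline (same block; the search never crosses block edges); the
#' match is the mean weight pooled over all seed marks across blocks. Seed
#' marks in blocks where `other` has no marks are excluded from the mean
#' (their count is returned as attribute `n_excluded`).
#'
#' @param seed,other `boundary_timeline` objects with identical block
#'   structure; `seed` must have at least one usable mark.
#' @param sigma_s Gaussian SD in seconds (default 0.332).
#' @return match value in `[0, 1]`.
#' @export
gaussian_match <- function(seed, other, sigma_s = 0.332) {
  check_compatible(seed, other)
  if (n_marks(seed) == 0) stop("seed timeline has no marks")
  v <- match_over_delays(seed, other, 0L, sigma_s)
  if (!is.finite(v)) stop("no usable seed marks (every block of `other` is empty)")
  attr(v, "n_excluded") <- count_excluded(seed, other)
  v
}

#' Choose the seed timeline for a comparison
#'
#' Stimulus-vs-neural comparisons seed on the stimulus feature timeline (extra
#' neural boundaries must not penalize the match); neural-vs-neural
#' comparisons seed on the timeline with fewer marks (ties keep the first
#' argument).
#'
#' @param a,b `boundary_timeline` objects.
#' @param mode `"stimulus_vs_neural"` or `"neural_vs_neural"`.
#' @return list with `seed`, `other`, and `seed_is_first`.
#' @export
choose_seed <- function(a, b, mode = c("stimulus_vs_neural", "neural_vs_neural")) {
  mode <- match.arg(mode)
  if (n_marks(a) == 0 || n_marks(b) == 0) stop("both timelines must be non-empty")
  first <- if (mode == "stimulus_vs_neural") {
    if (a$provenance == "stimulus_feature") TRUE
    else if (b$provenance == "stimulus_feature") FALSE
    else stop("stimulus_vs_neural mode needs a stimulus-feature timeline")
  } else {
    n_marks(a) <= n_marks(b)
  }
  if (first) list(seed = a, other = b, seed_is_first = TRUE)
  else list(seed = b, other = a, seed_is_first = FALSE)
}

#' Delay grid for a comparison mode
#'
#' Integer sample steps (1/64 s at the default rate) spanning 0 to 600 ms for
#' stimulus-vs-neural comparisons and -600 to 600 ms for neural-vs-neural
#' comparisons; 600 ms is not a multiple of the step, so the grid stops at the
#' last step within range (38 samples = 593.75 ms at 64 Hz).
#'
#' @param mode comparison mode.
#' @param rate_hz sampling rate (default 64).
#' @param max_delay_s range limit in seconds (default 0.6).
#' @return integer vector of delays in samples.
#' @export
delay_grid <- function(mode = c("stimulus_vs_neural", "neural_vs_neural"),
                       rate_hz = 64, max_delay_s = 0.6) {
  mode <- match.arg(mode)
  dmax <- floor(max_delay_s * rate_hz)
  if (mode == "stimulus_vs_neural") 0:dmax else (-dmax):dmax
}

#' Gaussian match as a function of delay
#'
#' Shifts the seed timeline by every delay on the grid (forward-only for
#' stimulus-vs-neural; both directions for neural-vs-neural) and computes the
#' Gaussian match at each delay. The optimal delay is the argmax; ties prefer
#' the smallest absolute delay, then the smallest delay.
#'
#' @param seed,other `boundary_timeline` objects (seed already chosen, see
#'   [choose_seed()]).
#' @param mode comparison mode (sets the delay range).
#' @param sigma_s Gaussian SD in seconds.
#' @param max_delay_s delay range limit in seconds.
#' @return object of class `match_curve`: list with `delays` (samples),
#'   `delays_s`, `match`, `optimal_delay` (samples), `optimal_delay_s`,
#'   `max_match`, `mode`.
#' @export
delay_scan <- function(seed, other,
                       mode = c("stimulus_vs_neural", "neural_vs_neural"),
                       sigma_s = 0.332, max_delay_s = 0.6) {
  mode <- match.arg(mode)
  check_compatible(seed, other)
  delays <- delay_grid(mode, seed$rate_hz, max_delay_s)
  m <- match_over_delays(seed, other, delays, sigma_s)
  if (all(!is.finite(m)))
    stop("no delay leaves a usable seed mark in any block")
  cand <- which(is.finite(m) & m >= max(m, na.rm = TRUE) - 1e-12)
  best <- cand[order(abs(delays[cand]), delays[cand])][1]
  structure(list(delays = delays, delays_s = delays / seed$rate_hz,
                 match = m, optimal_delay = delays[best],
                 optimal_delay_s = delays[best] / seed$rate_hz,
                 max_match = m[best], mode = mode),
            class = "match_curve")
}

#' @export
print.match_curve <- function(x, ...) {
  cat(sprintf("<match_curve> %s: max match %.4f at delay %+d samples (%+.1f ms)\n",
              x$mode, x$max_match, x$optimal_delay, 1000 * x$optimal_delay_s))
  invisible(x)
}

#' Write a match curve as TSV
#' @param curve a `match_curve`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_match_curve_tsv <- function(curve, path) {
  utils::write.table(
    data.frame(delay_samples = curve$delays, delay_s = curve$delays_s,
               match = curve$match),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Shuffle the states of a neural timeline
#'
#' Per block, the sequence of inter-boundary state durations (including the
#' first and last partial states) is randomly permuted and the boundaries are
#' rebuilt from cumulative sums. Mark counts and the multiset of state
#' durations are preserved exactly per block. Uses R's global RNG.
#'
#' @param t a neural `boundary_timeline`.
#' @return shuffled `boundary_timeline`.
#' @export
shuffle_states <- function(t) {
  t$marks <- lapply(seq_along(t$marks), function(i) {
    m <- t$marks[[i]]
    if (length(m) < 1) return(m)
    d <- diff(c(0L, m, t$n_samples[i]))
    b <- cumsum(sample(d))
    sort(unique(b[-length(b)]))
  })
  t
}

#' Chance-normalized (relative) Gaussian match
#'
#' Computes the maximum Gaussian match over the delay grid on the data, then
#' builds a permutation null by state-shuffling one timeline `n_perm` times
#' and recomputing the max-over-delays per permutation. The relative match is
#' `(match_data - match_null) / (1 - match_null)` with `match_null` the mean
#' of the permuted maxima: about 0 at chance, 1 at perfect alignment.
#'
#' @param seed,other `boundary_timeline` objects (seed already chosen).
#' @param mode comparison mode.
#' @param shuffle_target which timeline is shuffled for the null: `"other"`
#'   (default; the neural timeline when comparing to a stimulus feature) or
#'   `"seed"`.
#' @param n_perm number of permutations (default 1000).
#' @param sigma_s,max_delay_s match parameters.
#' @param rng_seed optional integer; when given, `set.seed(rng_seed)` is
#'   called and the seed is recorded in the result.
#' @return object of class `relative_match_result`: list with `match_data`,
#'   `match_null`, `relative`, `perm_maxima`, `optimal_delay`,
#'   `optimal_delay_s`, `curve`, `n_perm`, `rng_seed`.
#' @export
relative_match <- function(seed, other,
                           mode = c("stimulus_vs_neural", "neural_vs_neural"),
                           shuffle_target = c("other", "seed"),
                           n_perm = 1000, sigma_s = 0.332, max_delay_s = 0.6,
                           rng_seed = NULL) {
  mode <- match.arg(mode)
  shuffle_target <- match.arg(shuffle_target)
  stopifnot(n_perm >= 1)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  curve <- delay_scan(seed, other, mode, sigma_s, max_delay_s)
  delays <- curve$delays
  perm_max <- vapply(seq_len(n_perm), function(p) {
    if (shuffle_target == "other") {
      m <- match_over_delays(seed, shuffle_states(other), delays, sigma_s)
    } else {
      m <- match_over_delays(shuffle_states(seed), other, delays, sigma_s)
    }
    max(m, na.rm = TRUE)
  }, numeric(1))
  match_null <- mean(perm_max)
  if (match_null >= 1 - 1e-12)
    stop("degenerate permutation null (match_null = 1)")
  structure(list(match_data = curve$max_match, match_null = match_null,
                 relative = (curve$max_match - match_null) / (1 - match_null),
                 perm_maxima = perm_max, optimal_delay = curve$optimal_delay,
                 optimal_delay_s = curve$optimal_delay_s, curve = curve,
                 n_perm = n_perm, mode = mode, rng_seed = rng_seed),
            class = "relative_match_result")
}

#' @export
print.relative_match_result <- function(x, ...) {
  cat(sprintf(paste0("<relative_match_result> data %.4f, null %.4f, ",
                     "relative %.4f, optimal delay %+.1f ms (%d perms)\n"),
              x$match_data, x$match_null, x$relative,
              1000 * x$optimal_delay_s, x$n_perm))
  invisible(x)
}

#' Write a relative-match result as JSON
#' @param res a `relative_match_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_relative_match_json <- function(res, path) {
  jsonlite::write_json(
    list(match_data = res$match_data, match_null = res$match_null,
         relative = res$relative, optimal_delay_s = res$optimal_delay_s,
         n_perm = res$n_perm, rng_seed = res$rng_seed),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Optimal inter-ROI boundary delay
#'
#' Delay between two neural timelines with a fixed sign convention: negative
#' values mean the high-level timeline's boundaries lead (top-down), positive
#' values mean the low-level timeline leads (bottom-up). The seed is the
#' timeline with fewer marks; the scan covers -600 to 600 ms.
#'
#' @param low,high neural `boundary_timeline` objects for the low- and
#'   high-level ROI.
#' @param sigma_s,max_delay_s match parameters.
#' @return list with `delay` (samples), `delay_s`, `curve` (in the reported
#'   sign convention), and `seed_roi`.
#' @export
inter_roi_delay <- function(low, high, sigma_s = 0.332, max_delay_s = 0.6) {
  ch <- choose_seed(low, high, "neural_vs_neural")
  curve <- delay_scan(ch$seed, ch$other, "neural_vs_neural",
                      sigma_s, max_delay_s)
  # delay_scan shifts the seed forward; with the low timeline as seed a
  # negative optimal delay already means "high leads", otherwise flip signs
  if (!ch$seed_is_first) {
    o <- order(-curve$delays)
    curve$delays <- (-curve$delays)[o]
    curve$delays_s <- curve$delays / low$rate_hz
    curve$match <- curve$match[o]
    curve$optimal_delay <- -curve$optimal_delay
    curve$optimal_delay_s <- -curve$optimal_delay_s
  }
  list(delay = curve$optimal_delay, delay_s = curve$optimal_delay_s,
       curve = curve, seed_roi = if (ch$seed_is_first) "low" else "high")
}
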