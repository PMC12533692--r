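#' Greedy state boundary search (states variant) with t-distance model selection
#'
#' Segments a time-by-electrodes block into neural states: contiguous runs of
#' timepoints with a stable multivariate activity pattern. Boundaries are
#' placed greedily to maximize a fit criterion (the mean, over timepoints, of
#' the Pearson correlation between each timepoint's channel pattern and the
#' mean pattern of its state); each iteration may place either a single
#' boundary or a pair of boundaries delimiting one full new state, whichever
#' yields the larger fit gain per boundary added (a pair must earn its second
#' boundary, which is what lets a state sandwiched inside an existing state
#' be recovered in one iteration without spraying marginal boundaries).
#' After each
#' iteration every boundary may shift by one sample if that improves the fit
#' (fine-tuning). The number of states is selected by the t-distance metric:
#' a two-sample t statistic contrasting correlations of within-state timepoint
#' pairs against pairs spanning two consecutive states.
#'
#' @name gsbs
NULL

# --- fit criterion ----------------------------------------------------------
# With each timepoint's channel pattern standardized across channels, the sum
# over a segment of corr(pattern_t, segment mean pattern) equals the
# across-channel sample SD of the segment's channel-sum vector. This makes
# segment fits O(C) from a prefix-sum matrix.

row_standardize <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) < 2) stop("need at least 2 electrodes")
  mu <- rowMeans(X)
  s <- sqrt(rowSums((X - mu)^2) / (ncol(X) - 1))
  if (any(s <= 0)) stop("zero-variance timepoint pattern at t = ",
                        which(s <= 0)[1])
  (X - mu) / s
}

prefix_sums <- function(Z) rbind(0, apply(Z, 2, cumsum))

# scalar fast path of seg_fit
seg_fit1 <- function(P, a, b) {
  C <- ncol(P)
  v <- P[b + 1L, ] - P[a + 1L, ]
  rs <- sum(v)
  s2 <- (sum(v * v) - rs * rs / C) / (C - 1)
  if (s2 > 0) sqrt(s2) else 0
}

# fit of segments [a, b) (0-based half-open), vectorized over segments
seg_fit <- function(P, a, b) {
  C <- ncol(P)
  M <- P[b + 1L, , drop = FALSE] - P[a + 1L, , drop = FALSE]
  rs <- rowSums(M)
  v <- (rowSums(M^2) - rs^2 / C) / (C - 1)
  sqrt(pmax(v, 0))
}

# best single split of state [a, b): earliest argmax of the two-segment fit
best_split <- function(P, a, b) {
  if (b - a < 2L) return(list(s = NA_integer_, fit2 = -Inf))
  s <- (a + 1L):(b - 1L)
  tot <- seg_fit(P, rep(a, length(s)), s) + seg_fit(P, s, rep(b, length(s)))
  i <- which.max(tot)
  list(s = s[i], fit2 = tot[i])
}

# best completing boundary given split s1 already placed in [a, b)
best_completion <- function(P, a, b, s1) {
  cand <- setdiff((a + 1L):(b - 1L), s1)
  if (!length(cand)) return(list(s = NA_integer_, fit3 = -Inf))
  lo <- cand[cand < s1]; hi <- cand[cand > s1]
  f <- numeric(0); s <- integer(0)
  if (length(lo)) {
    f <- c(f, seg_fit(P, rep(a, length(lo)), lo) +
             seg_fit(P, lo, rep(s1, length(lo))) +
             rep(seg_fit(P, s1, b), length(lo)))
    s <- c(s, lo)
  }
  if (length(hi)) {
    f <- c(f, rep(seg_fit(P, a, s1), length(hi)) +
             seg_fit(P, rep(s1, length(hi)), hi) +
             seg_fit(P, hi, rep(b, length(hi))))
    s <- c(s, hi)
  }
  o <- order(s)
  s <- s[o]; f <- f[o]
  i <- which.max(f)
  list(s = s[i], fit3 = f[i])
}

# exhaustive search over all candidate new states [s, e) within [a, b)
# (s == a or e == b degenerate to a single boundary); candidates are ranked
# by fit gain per boundary added, so a pair wins only when both boundaries
# pull their weight; small-T oracle mode
exhaustive_candidate <- function(P, a, b) {
  best <- list(score = -Inf, add = integer(0))
  if (b - a < 2L) return(best)
  f0 <- seg_fit(P, a, b)
  for (s in a:(b - 2L)) {
    for (e in (s + 1L):b) {
      if (s == a && e == b) next
      add <- setdiff(c(s, e), c(a, b))
      if (!length(add)) next
      parts <- rbind(c(a, s), c(s, e), c(e, b))
      parts <- parts[parts[, 1] < parts[, 2], , drop = FALSE]
      sc <- (sum(seg_fit(P, parts[, 1], parts[, 2])) - f0) / length(add)
      if (sc > best$score + 1e-12) best <- list(score = sc, add = add)
    }
  }
  best
}

#' Time-by-time correlation matrix of a block
#'
#' Entry (i, j) is the Pearson correlation between the channel patterns at
#' timepoints i and j.
#'
#' @param X time-by-electrodes matrix (>= 2 electrodes; every timepoint
#'   pattern must have nonzero across-channel variance).
#' @return symmetric T-by-T matrix with unit diagonal.
#' @export
timepoint_correlation_matrix <- function(X) {
  Z <- row_standardize(X)
  R <- tcrossprod(Z) / (ncol(Z) - 1)
  diag(R) <- 1
  R[R > 1] <- 1; R[R < -1] <- -1
  R
}

#' Configuration for greedy state boundary search
#'
#' @param kmax maximum number of states; default half the number of
#'   timepoints.
#' @param finetune 1 to allow each boundary to shift by one sample after each
#'   iteration (default), 0 to disable.
#' @param pair_search `"two_stage"` (default; best single split, then best
#'   completing boundary within the same state) or `"exhaustive"` (all
#'   candidate new states, O(T^2) per iteration; small blocks only).
#' @return list of class `gsbs_config`.
#' @export
gsbs_config <- function(kmax = NULL, finetune = 1L,
                        pair_search = c("two_stage", "exhaustive")) {
  stopifnot(is.null(kmax) || kmax >= 2, finetune %in% c(0L, 1L))
  structure(list(kmax = kmax, finetune = as.integer(finetune),
                 pair_search = match.arg(pair_search)),
            class = "gsbs_config")
}

#' Greedy state segmentation of one block
#'
#' Runs states-GSBS on a time-by-electrodes matrix, recording the boundary set
#' at every number of states along the greedy path (when a pair is placed, the
#' intermediate single-boundary solution is recorded before fine-tuning, so
#' the path covers every k from 1 to `kmax`). The t-distance is computed for
#' every recorded k >= 2.
#'
#' @param X time-by-electrodes matrix.
#' @param config a [gsbs_config()].
#' @return object of class `gsbs_fit` with elements `path` (list indexed by
#'   number of states; each entry the 0-based boundary sample indices),
#'   `tdist` (data.frame `k`, `tdist`), `n_time`, `n_channels`, `config`.
#' @export
gsbs_segment <- function(X, config = gsbs_config()) {
  X <- as.matrix(X)
  T_ <- nrow(X)
  if (T_ < 4) stop("need at least 4 timepoints")
  kmax <- as.integer(
    if (is.null(config$kmax)) floor(T_ / 2) else min(config$kmax, floor(T_ / 2)))
  Z <- row_standardize(X)
  P <- prefix_sums(Z)

  path <- vector("list", kmax)
  path[[1]] <- integer(0)

  # per-state vectors, updated incrementally: span, fit, cached best split
  st_a <- 0L; st_b <- T_
  st_fit <- seg_fit(P, 0L, T_)
  bs0 <- best_split(P, 0L, T_)
  st_s <- bs0$s; st_f2 <- bs0$fit2

  refresh_state <- function(i) {
    st_fit[i] <<- seg_fit1(P, st_a[i], st_b[i])
    bs <- best_split(P, st_a[i], st_b[i])
    st_s[i] <<- bs$s; st_f2[i] <<- bs$fit2
  }

  # one fine-tuning sweep: each boundary may move +/- 1 sample if the fit
  # improves. Candidate gains are computed vectorized for all boundaries;
  # a boundary whose left edge was just moved gets a scalar recomputation.
  # Neighbor states of a moved boundary get their caches rebuilt.
  finetune_sweep <- function() {
    k <- length(st_a)
    if (k < 2) return(invisible())
    j <- seq_len(k - 1L)
    prev <- st_a[j]; b0 <- st_b[j]; nxt <- st_b[j + 1L]
    base <- seg_fit(P, prev, b0) + seg_fit(P, b0, nxt)
    okm <- b0 - 1L > prev
    dm <- rep(-Inf, k - 1L)
    if (any(okm)) {
      bm <- pmax(b0 - 1L, prev + 1L)
      dm[okm] <- (seg_fit(P, prev, bm) + seg_fit(P, bm, nxt) - base)[okm]
    }
    okp <- b0 + 1L < nxt
    dp <- rep(-Inf, k - 1L)
    if (any(okp)) {
      bp <- pmin(b0 + 1L, nxt - 1L)
      dp[okp] <- (seg_fit(P, prev, bp) + seg_fit(P, bp, nxt) - base)[okp]
    }
    left_moved <- FALSE
    for (jj in j) {
      b <- st_b[jj]
      if (left_moved) {  # left edge changed since the vectorized pass
        pr <- st_a[jj]; nx <- st_b[jj + 1L]
        bas <- seg_fit1(P, pr, b) + seg_fit1(P, b, nx)
        dmm <- if (b - 1L > pr) seg_fit1(P, pr, b - 1L) + seg_fit1(P, b - 1L, nx) - bas else -Inf
        dpp <- if (b + 1L < nx) seg_fit1(P, pr, b + 1L) + seg_fit1(P, b + 1L, nx) - bas else -Inf
      } else {
        dmm <- dm[jj]; dpp <- dp[jj]
      }
      step <- 0L
      if (dmm > 1e-12 && dmm >= dpp) step <- -1L
      else if (dpp > 1e-12) step <- 1L
      if (step != 0L) {
        st_b[jj] <<- b + step; st_a[jj + 1L] <<- b + step
        refresh_state(jj); refresh_state(jj + 1L)
        left_moved <- TRUE
      } else left_moved <- FALSE
    }
    invisible()
  }

  insert_states <- function(i, cuts) {
    # replace state i by the segments cut at `cuts` (sorted, strictly inside)
    a <- st_a[i]; b <- st_b[i]
    na <- c(a, cuts); nb <- c(cuts, b)
    st_a <<- append(st_a[-i], na, after = i - 1L)
    st_b <<- append(st_b[-i], nb, after = i - 1L)
    st_fit <<- append(st_fit[-i], rep(NA_real_, length(na)), after = i - 1L)
    st_s <<- append(st_s[-i], rep(NA_integer_, length(na)), after = i - 1L)
    st_f2 <<- append(st_f2[-i], rep(NA_real_, length(na)), after = i - 1L)
    for (j in seq_along(na)) refresh_state(i + j - 1L)
  }

  while (length(st_a) < kmax) {
    gain <- st_f2 - st_fit
    if (!any(is.finite(gain))) break
    mx <- max(gain, na.rm = TRUE)
    cand <- which(is.finite(gain) & gain >= mx - 1e-12)
    i <- cand[which.min(st_s[cand])]   # ties: earliest candidate index
    a <- st_a[i]; b <- st_b[i]; s1 <- st_s[i]

    if (config$pair_search == "exhaustive") {
      add <- exhaustive_candidate(P, a, b)$add
      if (!length(add)) break
      if (length(add) == 2L && length(st_a) + 2L > kmax) add <- add[1]
      B1 <- sort(c(st_b[-length(st_b)], add[1]))
      path[[length(B1) + 1L]] <- B1
      insert_states(i, sort(add))
    } else {
      B1 <- sort(c(st_b[-length(st_b)], s1))
      path[[length(B1) + 1L]] <- B1
      cuts <- s1
      if (length(st_a) + 2L <= kmax && b - a >= 3L) {
        comp <- best_completion(P, a, b, s1)
        # a pair is placed only when its fit gain per added boundary beats
        # the single boundary's gain
        if (is.finite(comp$fit3) &&
            (comp$fit3 - st_fit[i]) / 2 > (st_f2[i] - st_fit[i]) + 1e-12)
          cuts <- sort(c(s1, comp$s))
      }
      insert_states(i, cuts)
    }
    if (config$finetune == 1L) finetune_sweep()
    path[[length(st_a)]] <- st_b[-length(st_b)]
  }

  fit <- structure(list(path = path, n_time = T_, n_channels = ncol(X),
                        kmax = kmax, config = config, tdist = NULL),
                   class = "gsbs_fit")
  fit$tdist <- tdist_curve(fit, X)
  fit
}

#' @export
print.gsbs_fit <- function(x, ...) {
  cat(sprintf("<gsbs_fit> T = %d, %d channels, path to k = %d\n",
              x$n_time, x$n_channels, x$kmax))
  invisible(x)
}

#' Boundaries of the greedy path at a given number of states
#'
#' @param fit a `gsbs_fit`.
#' @param k number of states.
#' @return 0-based boundary sample indices (length k - 1).
#' @export
gsbs_boundaries <- function(fit, k) {
  if (k < 1 || k > length(fit$path) || is.null(fit$path[[k]]))
    stop("k = ", k, " is not on the greedy path")
  fit$path[[k]]
}

# --- t-distance -------------------------------------------------------------

# summed-area table of M: S[i+1, j+1] = sum(M[1:i, 1:j])
summed_area <- function(M) {
  cs <- apply(M, 2, cumsum)
  cs <- t(apply(cs, 1, cumsum))
  rbind(0, cbind(0, cs))
}

sat_rect <- function(S, r1, r2, c1, c2) {
  S[cbind(r2 + 1L, c2 + 1L)] - S[cbind(r1, c2 + 1L)] -
    S[cbind(r2 + 1L, c1)] + S[cbind(r1, c1)]
}

tdist_from_sats <- function(boundaries, T_, S1, S2) {
  k <- length(boundaries) + 1L
  if (k < 2) return(NA_real_)
  a <- c(0L, boundaries) + 1L       # 1-based first row of each state
  b <- c(boundaries, T_)            # 1-based last row of each state
  L <- b - a + 1L
  # within-state pairs (i < j): square block sums minus the unit diagonal
  W1 <- sat_rect(S1, a, b, a, b); W2 <- sat_rect(S2, a, b, a, b)
  n_w <- sum(L * (L - 1) / 2)
  sum_w <- sum((W1 - L) / 2); ssq_w <- sum((W2 - L) / 2)
  # pairs spanning two consecutive states
  i <- seq_len(k - 1L)
  C1 <- sat_rect(S1, a[i], b[i], a[i + 1L], b[i + 1L])
  C2 <- sat_rect(S2, a[i], b[i], a[i + 1L], b[i + 1L])
  n_b <- sum(L[i] * L[i + 1L])
  sum_b <- sum(C1); ssq_b <- sum(C2)
  if (n_w < 1 || n_b < 1 || (n_w + n_b) < 3) return(NA_real_)
  m_w <- sum_w / n_w; m_b <- sum_b / n_b
  v_w <- if (n_w > 1) max((ssq_w - n_w * m_w^2) / (n_w - 1), 0) else 0
  v_b <- if (n_b > 1) max((ssq_b - n_b * m_b^2) / (n_b - 1), 0) else 0
  sp2 <- ((n_w - 1) * v_w + (n_b - 1) * v_b) / (n_w + n_b - 2)
  se <- sqrt(sp2 * (1 / n_w + 1 / n_b))
  d <- m_w - m_b
  if (se == 0) return(if (abs(d) < 1e-12) 0 else sign(d) * Inf)
  d / se
}

#' t-distance of a segmentation
#'
#' Two-sample Student t statistic comparing the pool of correlations between
#' timepoint pairs within the same state against the pool of correlations
#' between pairs spanning two consecutive states (pairs spanning non-adjacent
#' states are excluded). Higher values indicate more coherent states with
#' sharper transitions; its maximum over k selects the number of states.
#'
#' @param boundaries 0-based boundary sample indices (>= 1 boundary).
#' @param corr_matrix T-by-T timepoint correlation matrix.
#' @return the t statistic; `NA` when a pool is empty.
#' @export
tdistance <- function(boundaries, corr_matrix) {
  T_ <- nrow(corr_matrix)
  if (length(boundaries) < 1) return(NA_real_)
  tdist_from_sats(as.integer(boundaries), T_,
                  summed_area(corr_matrix), summed_area(corr_matrix^2))
}

# t-distance for every recorded k of a greedy path
tdist_curve <- function(fit, X) {
  R <- timepoint_correlation_matrix(X)
  S1 <- summed_area(R); S2 <- summed_area(R^2)
  ks <- 2:fit$kmax
  td <- vapply(ks, function(k) {
    if (k > length(fit$path) || is.null(fit$path[[k]])) return(NA_real_)
    tdist_from_sats(fit$path[[k]], fit$n_time, S1, S2)
  }, numeric(1))
  data.frame(k = ks, tdist = td)
}

# --- model selection --------------------------------------------------------

#' Cross-block selection of the number of states
#'
#' Averages the t-distance curves of all blocks on their shared k grid and
#' returns the k maximizing the mean curve (ties take the smallest k; a k with
#' missing values in some blocks is averaged over the blocks that define it,
#' with a warning).
#'
#' @param curves list of `gsbs_fit` objects or data.frames with columns `k`
#'   and `tdist`.
#' @return integer `k_star`.
#' @export
select_nstates_global <- function(curves) {
  if (length(curves) < 1) stop("need at least one t-distance curve")
  dfs <- lapply(curves, function(cv) if (inherits(cv, "gsbs_fit")) cv$tdist else cv)
  ks <- sort(unique(unlist(lapply(dfs, `[[`, "k"))))
  M <- vapply(dfs, function(d) d$tdist[match(ks, d$k)], numeric(length(ks)))
  M <- matrix(M, nrow = length(ks))
  M[!is.finite(M)] <- NA
  if (anyNA(M)) warning("missing t-distance values ignored in the cross-block mean")
  m <- rowMeans(M, na.rm = TRUE)
  ok <- is.finite(m)
  ks[ok][which.max(m[ok])]
}

#' Peaks of a t-distance curve
#'
#' A peak is any point, or a pair of adjacent points with the exact same
#' value, with a lower value on both the left and the right side. A plateau
#' pair is represented by its lower k.
#'
#' @param curve data.frame with columns `k`, `tdist` (or a `gsbs_fit`).
#' @return integer vector of peak k values (possibly empty).
#' @export
tdist_peaks <- function(curve) {
  if (inherits(curve, "gsbs_fit")) curve <- curve$tdist
  d <- curve[is.finite(curve$tdist), , drop = FALSE]
  n <- nrow(d)
  if (n < 3) return(integer(0))
  k <- d$k; v <- d$tdist
  peaks <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (v[i] > v[i - 1L]) {
      if (v[i] > v[i + 1L]) {
        peaks <- c(peaks, k[i])
      } else if (i <= n - 2L && v[i] == v[i + 1L] && v[i + 1L] > v[i + 2L]) {
        peaks <- c(peaks, k[i])  # plateau pair, lower k
        i <- i + 1L
      }
    }
    i <- i + 1L
  }
  peaks
}

#' Per-block fine-tuning of the number of states
#'
#' Among the peaks of a block's t-distance curve, returns the k closest to the
#' cross-block optimum `k_star` (equidistant peaks take the smaller k). With
#' no peak (monotone curve) the block's argmax is returned with a warning.
#'
#' @param curve data.frame `k`, `tdist` or a `gsbs_fit`.
#' @param k_star cross-block optimal number of states.
#' @return integer number of states for this block.
#' @export
select_nstates_block <- function(curve, k_star) {
  if (inherits(curve, "gsbs_fit")) curve <- curve$tdist
  d <- curve[is.finite(curve$tdist), , drop = FALSE]
  if (nrow(d) < 3) stop("t-distance curve needs at least 3 defined points")
  pk <- tdist_peaks(d)
  if (!length(pk)) {
    warning("no t-distance peak; falling back to the block argmax")
    return(d$k[which.max(d$tdist)])
  }
  dist <- abs(pk - k_star)
  pk[order(dist, pk)][1]
}

#' Segmentation TSV serialization
#'
#' One row per boundary: `block`, `boundary_sample` (0-based), and
#' `boundary_time_s` relative to block start.
#'
#' @param boundaries list of boundary vectors, one per block.
#' @param path output TSV path.
#' @param rate_hz sampling rate.
#' @return `path`, invisibly.
#' @export
write_segmentation_tsv <- function(boundaries, path, rate_hz = 64) {
  rows <- do.call(rbind, lapply(seq_along(boundaries), function(i) {
    b <- boundaries[[i]]
    if (!length(b)) return(NULL)
    data.frame(block = i, boundary_sample = b, boundary_time_s = b / rate_hz)
  }))
  if (is.null(rows))
    rows <- data.frame(block = integer(), boundary_sample = integer(),
                       boundary_time_s = numeric())
  utils::write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
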