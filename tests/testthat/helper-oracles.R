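# Independent oracles and small fixture builders, used across test files.
# The oracles implement definitions directly (and slowly); they never share
# code with the package internals they check.

# fit criterion from its definition: mean over timepoints of the Pearson
# correlation between the timepoint's channel pattern and the mean pattern of
# its state (state means over spatially standardized patterns; a
# single-timepoint state contributes 1)
oracle_fit <- function(X, boundaries) {
  T_ <- nrow(X)
  Z <- t(apply(X, 1, function(v) (v - mean(v)) / stats::sd(v)))
  state <- findInterval(0:(T_ - 1), boundaries) + 1L
  tot <- 0
  for (s in unique(state)) {
    rows <- which(state == s)
    if (length(rows) == 1) { tot <- tot + 1; next }
    m <- colMeans(Z[rows, , drop = FALSE])
    tot <- tot + sum(apply(Z[rows, , drop = FALSE], 1, stats::cor, y = m))
  }
  tot / T_
}

# brute-force best single boundary under the fit criterion (earliest argmax)
oracle_best_single <- function(X) {
  T_ <- nrow(X)
  f <- vapply(1:(T_ - 1), function(b) oracle_fit(X, b), numeric(1))
  which.max(f)
}

# brute-force best boundary pair under the fit criterion (earliest argmax)
oracle_best_pair <- function(X) {
  T_ <- nrow(X)
  best <- NULL; bf <- -Inf
  for (b1 in 1:(T_ - 2)) for (b2 in (b1 + 1):(T_ - 1)) {
    f <- oracle_fit(X, c(b1, b2))
    if (f > bf + 1e-12) { bf <- f; best <- c(b1, b2) }
  }
  best
}

# t-distance from its definition, by explicit double loop over timepoint pairs
oracle_tdistance <- function(boundaries, R) {
  T_ <- nrow(R)
  state <- findInterval(0:(T_ - 1), boundaries) + 1L
  within <- c(); between <- c()
  for (i in 1:(T_ - 1)) for (j in (i + 1):T_) {
    if (state[i] == state[j]) within <- c(within, R[i, j])
    else if (state[j] == state[i] + 1L) between <- c(between, R[i, j])
  }
  if (!length(within) || !length(between)) return(NA_real_)
  if (stats::sd(c(within, between)) == 0) return(0)
  unname(stats::t.test(within, between, var.equal = TRUE)$statistic)
}

# block of k noiseless or noisy states with i.i.d. unit-norm mean patterns
make_state_block <- function(T_, boundaries, n_channels = 4, noise_sd = 0) {
  k <- length(boundaries) + 1L
  pat <- matrix(stats::rnorm(k * n_channels), k)
  pat <- pat / sqrt(rowSums(pat^2))
  X <- pat[findInterval(0:(T_ - 1), boundaries) + 1L, , drop = FALSE]
  if (noise_sd > 0) X <- X + noise_sd * matrix(stats::rnorm(T_ * n_channels), T_)
  X
}

# timeline with given marks in a single block
tl <- function(marks, n_samples = 1920, rate_hz = 64) {
  boundaries_to_timeline(list(as.integer(marks)), n_samples, rate_hz)
}

# random multi-block neural timeline
random_timeline <- function(n_blocks = 3, n_samples = 640, max_marks = 20) {
  marks <- lapply(seq_len(n_blocks), function(i) {
    n <- sample.int(max_marks, 1)
    sort(sample(seq_len(n_samples - 1), n))
  })
  boundaries_to_timeline(marks, n_samples)
}
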