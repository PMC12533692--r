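test_that("timepoint correlation matrix reflects pattern structure", {
  set.seed(31)
  A <- rnorm(8); B <- rnorm(8)
  X <- rbind(matrix(A, 2, 8, byrow = TRUE), matrix(B, 2, 8, byrow = TRUE))
  R <- timepoint_correlation_matrix(X)
  expect_equal(diag(R), rep(1, 4))
  expect_equal(R[1, 2], 1)
  expect_equal(R[3, 4], 1)
  expect_lt(abs(R[1, 3]), 1)
  expect_equal(R, t(R))
  # standardizing each timepoint pattern across channels changes nothing:
  # Pearson correlation is invariant to per-row affine transforms
  Xz <- t(apply(X, 1, function(v) (v - mean(v)) / sd(v)))
  expect_equal(timepoint_correlation_matrix(Xz), R, tolerance = 1e-12)
  expect_error(timepoint_correlation_matrix(matrix(1, 4, 3)), "variance")
})

test_that("first greedy boundary matches the exhaustive fit optimum", {
  set.seed(32)
  for (rep in 1:15) {
    T_ <- sample(8:24, 1)
    X <- make_state_block(T_, sort(sample(2:(T_ - 2), 2)), 4, noise_sd = 0.4)
    fit <- gsbs_segment(X, gsbs_config(kmax = 2))
    expect_identical(gsbs_boundaries(fit, 2), oracle_best_single(X))
  }
})

test_that("a sandwiched state is recovered as a pair in one iteration", {
  set.seed(33)
  for (rep in 1:5) {
    # noiseless A..A B..B A..A: the new state must be delimited by 2 boundaries
    la <- sample(2:4, 1); lb <- sample(3:6, 1); lc <- sample(2:4, 1)
    A <- rnorm(6); B <- rnorm(6)
    X <- rbind(matrix(A, la, 6, byrow = TRUE), matrix(B, lb, 6, byrow = TRUE),
               matrix(A, lc, 6, byrow = TRUE))
    truth <- c(la, la + lb)
    for (mode in c("two_stage", "exhaustive")) {
      fit <- gsbs_segment(X, gsbs_config(kmax = 3, pair_search = mode))
      expect_identical(gsbs_boundaries(fit, 3), truth)
    }
    expect_identical(oracle_best_pair(X), truth)
  }
})

test_that("t-distance matches a naive pairwise reimplementation", {
  set.seed(34)
  for (rep in 1:10) {
    T_ <- 20
    X <- make_state_block(T_, c(7, 13), 5, noise_sd = 0.5)
    R <- timepoint_correlation_matrix(X)
    b <- sort(sample(2:(T_ - 2), sample(1:3, 1)))
    expect_equal(tdistance(b, R), oracle_tdistance(b, R), tolerance = 1e-9)
  }
})

test_that("t-distance peaks at the true segmentation and degrades when perturbed", {
  # idealized block-diagonal correlation matrix: within 1, between 0
  b <- c(5L, 11L); T_ <- 16
  state <- findInterval(0:(T_ - 1), b) + 1
  R <- outer(state, state, function(i, j) as.numeric(i == j))
  t_true <- tdistance(b, R)
  for (d in c(-2L, 2L)) {
    t_pert <- tdistance(c(b[1] + d, b[2]), R)
    expect_gt(t_true, t_pert)
  }
  # identical pools give t = 0
  expect_equal(tdistance(c(4L), matrix(0.5, 8, 8) + diag(0.5, 8)), 0)
})

test_that("cross-block state-count selection averages curves and breaks ties low", {
  c1 <- data.frame(k = 2:8, tdist = exp(-(2:8 - 4)^2 / 8))
  expect_equal(select_nstates_global(list(c1)), 4)
  c2 <- data.frame(k = 2:8, tdist = exp(-(2:8 - 6)^2 / 8))
  # symmetric bells peaking at 4 and 6: the mean curve peaks between them
  expect_equal(select_nstates_global(list(c1, c2)), 5)
  tie <- data.frame(k = 2:5, tdist = c(1, 3, 3, 1))
  expect_equal(select_nstates_global(list(tie)), 3)
  expect_error(select_nstates_global(list()), "at least one")
})

test_that("per-block peak selection follows the peak definition", {
  cv <- data.frame(k = 1:6, tdist = c(1, 3, 2, 2, 4, 1))
  expect_equal(select_nstates_block(cv, k_star = 3), 2)  # peaks at 2 and 5
  expect_equal(select_nstates_block(cv, k_star = 5), 5)
  # a pair of equal points with lower values on both sides is one peak
  plateau <- data.frame(k = 1:4, tdist = c(1, 2, 2, 1))
  expect_equal(tdist_peaks(plateau), 2)
  # equidistant peaks on both sides: the smaller k wins
  two <- data.frame(k = 1:7, tdist = c(1, 4, 1, 1, 1, 4, 1))
  expect_equal(select_nstates_block(two, k_star = 4), 2)
  mono <- data.frame(k = 1:5, tdist = 1:5)
  expect_warning(kb <- select_nstates_block(mono, k_star = 3), "no t-distance peak")
  expect_equal(kb, 5)
})

test_that("the greedy path is deterministic with valid segmentations at every k", {
  set.seed(36)
  X <- make_state_block(60, c(15, 30, 45), 6, noise_sd = 0.3)
  f1 <- gsbs_segment(X)
  f2 <- gsbs_segment(X)
  expect_identical(f1$path, f2$path)
  expect_identical(gsbs_boundaries(f1, 1), integer(0))
  for (k in 1:f1$kmax) {
    b <- gsbs_boundaries(f1, k)
    expect_equal(length(b), k - 1)
    if (k > 1) {
      expect_true(all(diff(b) > 0))
      expect_true(all(b > 0 & b < 60))
      expect_equal(sum(diff(c(0, b, 60))), 60)
    }
  }
  # t-distance curve defined on the full k grid
  expect_false(anyNA(f1$tdist$tdist))
})

test_that("planted states are recovered at high SNR", {
  set.seed(37)
  hits <- 0
  for (rep in 1:5) {
    spec <- synthetic_spec(n_states_range = c(10, 10), noise_sd = 0.3,
                           orthogonal_patterns = TRUE)
    blk <- generate_block(spec)
    fit <- gsbs_segment(blk$low, gsbs_config(kmax = 40))
    karg <- fit$tdist$k[which.max(fit$tdist$tdist)]
    b <- gsbs_boundaries(fit, karg)
    recall <- mean(vapply(blk$truth$b_low,
                          function(p) any(abs(b - p) <= 1), logical(1)))
    if (abs(karg - 10) <= 1 && recall >= 0.9) hits <- hits + 1
  }
  expect_gte(hits, 4)
})
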