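test_that("gaussian weight follows the closed form and is symmetric", {
  expect_equal(gaussian_weight(0), 1)
  expect_equal(gaussian_weight(0.332), exp(-1 / 2))
  set.seed(41)
  d <- runif(20, -2, 2)
  expect_equal(gaussian_weight(d), gaussian_weight(-d))
  expect_error(gaussian_weight(0.1, sigma_s = 0), "sigma_s")
})

test_that("gaussian match agrees with hand-computed closed forms", {
  expect_equal(as.numeric(gaussian_match(tl(c(5, 50, 500)), tl(c(5, 50, 500)))), 1)
  # single marks 21 samples apart: exp(-(21/64)^2 / (2 * 0.332^2))
  expect_equal(as.numeric(gaussian_match(tl(64), tl(85))),
               exp(-(21 / 64)^2 / (2 * 0.332^2)), tolerance = 1e-12)
  # two seed marks, one partner: mean of exact weight and a far-away weight
  expected <- mean(c(1, exp(-(90 / 64)^2 / (2 * 0.332^2))))
  expect_equal(as.numeric(gaussian_match(tl(c(10, 100)), tl(10))), expected,
               tolerance = 1e-12)
  # non-commutativity: extra unmatched marks penalize only their own seed
  a <- tl(c(100, 200)); b <- tl(c(100, 200, 900, 1200))
  expect_equal(as.numeric(gaussian_match(a, b)), 1)
  expect_lt(as.numeric(gaussian_match(b, a)), 1)
  expect_error(gaussian_match(tl(integer(0)), a), "no marks")
})

test_that("seed marks in blocks without partner marks are excluded", {
  seed <- boundaries_to_timeline(list(c(10L, 20L), c(30L, 40L)), 640)
  other <- boundaries_to_timeline(list(c(10L, 20L), integer(0)), 640)
  m <- gaussian_match(seed, other)
  expect_equal(as.numeric(m), 1)
  expect_equal(attr(m, "n_excluded"), 2)
  none <- boundaries_to_timeline(list(integer(0), integer(0)), 640)
  expect_error(gaussian_match(seed, none), "usable")
})

test_that("seed choice follows the comparison mode", {
  stim <- build_feature_timeline(
    data.frame(feature = "clause", onset_s = c(31, 40), offset_s = c(33, 44),
               label = NA), block_schedule(1))
  neur <- tl(sort(sample(1:1900, 200)))
  ch <- choose_seed(neur, stim, "stimulus_vs_neural")
  expect_identical(ch$seed$provenance, "stimulus_feature")
  a <- tl(1:200); b <- tl(seq(2, 600, by = 2))
  expect_true(choose_seed(a, b, "neural_vs_neural")$seed_is_first)   # 200 < 300
  expect_true(choose_seed(b, a, "neural_vs_neural")$seed_is_first == FALSE)
  expect_true(choose_seed(a, tl(801:1000), "neural_vs_neural")$seed_is_first)  # tie
})

test_that("delay scan recovers constructed and jittered shifts", {
  t0 <- tl(c(100, 400, 800, 1200, 1600))
  sc <- delay_scan(t0, shift_timeline(t0, 8), "stimulus_vs_neural")
  expect_equal(sc$optimal_delay, 8)
  expect_equal(sc$max_match, 1)
  expect_gte(sc$max_match, sc$match[sc$delays == 0])
  # planted 10-sample delay with +/-1 sample jitter, 50 marks: recovered
  set.seed(42)
  for (rep in 1:20) {
    marks <- sort(sample(30:1850, 50))
    jit <- sample(-1:1, 50, replace = TRUE)
    seed <- tl(marks)
    other <- tl(sort(unique(pmin(pmax(marks + 10 + jit, 1), 1919))))
    sc <- delay_scan(seed, other, "stimulus_vs_neural")
    expect_lte(abs(sc$optimal_delay - 10), 1)
  }
  # neural mode scans both directions
  scn <- delay_scan(shift_timeline(t0, 6), t0, "neural_vs_neural")
  expect_equal(scn$optimal_delay, -6)
})

test_that("expected match degrades monotonically with jitter", {
  set.seed(43)
  sds <- c(0, 2, 5, 10, 20)
  means <- sapply(sds, function(s) {
    mean(replicate(20, {
      marks <- sort(sample(50:1850, 40))
      jit <- round(rnorm(40, 0, s))
      as.numeric(gaussian_match(tl(marks),
                                tl(sort(unique(pmin(pmax(marks + jit, 1),
                                                    1919))))))
    }))
  })
  expect_true(all(diff(means) <= 0.005))  # non-increasing up to MC noise
})

test_that("state shuffling preserves counts and the duration multiset", {
  set.seed(44)
  for (rep in 1:50) {
    t <- random_timeline()
    s <- shuffle_states(t)
    expect_equal(lengths(s$marks), lengths(t$marks))
    for (i in seq_along(t$marks)) {
      d1 <- sort(diff(c(0, t$marks[[i]], t$n_samples[i])))
      d2 <- sort(diff(c(0, s$marks[[i]], s$n_samples[i])))
      expect_identical(d1, d2)
    }
  }
  # no boundaries: unchanged
  empty <- boundaries_to_timeline(list(integer(0)), 100)
  expect_identical(shuffle_states(empty)$marks, empty$marks)
})

test_that("relative match is 0 at chance, 1 at perfection, reproducible", {
  set.seed(45)
  neur <- random_timeline(3, 1920, 25)
  # perfect alignment: match_data = 1 so relative = 1 whatever the null
  res <- relative_match(neur, neur, "neural_vs_neural", n_perm = 50,
                        rng_seed = 7)
  expect_equal(res$relative, 1)
  expect_equal(res$match_data, 1)
  expect_lt(res$match_null, 1)
  # reproducibility with the recorded seed
  res2 <- relative_match(neur, neur, "neural_vs_neural", n_perm = 50,
                         rng_seed = 7)
  expect_identical(res$perm_maxima, res2$perm_maxima)
  expect_equal(res$relative,
               (res$match_data - res$match_null) / (1 - res$match_null))
  # independent random timelines: relative near 0 on average
  set.seed(46)
  rel <- replicate(12, {
    a <- random_timeline(3, 1920, 25)
    b <- random_timeline(3, 1920, 25)
    relative_match(a, b, "neural_vs_neural", n_perm = 60)$relative
  })
  expect_lt(abs(mean(rel)), 0.08)
})

test_that("inter-ROI delay uses the high-leads-negative convention", {
  low <- tl(c(200, 600, 1000, 1400))
  high <- shift_timeline(low, -8)  # high boundaries 8 samples earlier
  d1 <- inter_roi_delay(low, high)
  expect_equal(d1$delay, -8)
  # same answer when the seed lands on the other timeline
  high2 <- boundaries_to_timeline(list(sort(c(low$marks[[1]] - 8, 300L, 900L))),
                                  1920)
  d2 <- inter_roi_delay(low, high2)
  expect_equal(d2$delay, -8)
  expect_identical(d2$seed_roi, "low")
})

test_that("match curves serialize to TSV and results to JSON", {
  t0 <- tl(c(100, 500, 900))
  sc <- delay_scan(t0, shift_timeline(t0, 3), "stimulus_vs_neural")
  p <- file.path(tempdir(), "curve.tsv")
  write_match_curve_tsv(sc, p)
  d <- read.delim(p)
  expect_equal(nrow(d), length(sc$delays))
  expect_equal(d$match[d$delay_samples == 3], 1)
  res <- relative_match(t0, shift_timeline(t0, 3), "stimulus_vs_neural",
                        n_perm = 20, rng_seed = 1)
  pj <- file.path(tempdir(), "res.json")
  write_relative_match_json(res, pj)
  j <- jsonlite::read_json(pj)
  expect_equal(j$relative, res$relative)
  expect_equal(j$n_perm, 20)
})
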