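rate <- 512
tt <- seq(1 / rate, 60, by = 1 / rate)

amp_ratio <- function(y, x) {
  core <- seq(round(length(x) * 0.2), round(length(x) * 0.8))
  stats::sd(y[core]) / stats::sd(x[core])
}

test_that("high-pass removes slow drift and preserves the signal band", {
  expect_lt(max(abs(highpass(rep(3, length(tt)), rate))), 1e-6)
  x10 <- sin(2 * pi * 10 * tt)
  expect_equal(amp_ratio(highpass(x10, rate), x10), 1, tolerance = 0.01)
  drift <- sin(2 * pi * 0.01 * tt)
  expect_lt(20 * log10(amp_ratio(highpass(drift, rate), drift)), -20)
  expect_error(highpass(x10, rate, cutoff_hz = 300), "Nyquist")
})

test_that("despiking repairs isolated outliers and leaves clean data alone", {
  set.seed(21)
  x <- rnorm(5000)
  xs <- x; xs[2500] <- 50
  d <- despike(xs)
  expect_equal(attr(d, "n_repaired"), 1)
  expect_lt(max(abs(d - x)[-2500]), 1e-12)
  expect_lt(abs(d[2500]), 5)
  # clean Gaussian noise at threshold 8: essentially nothing is altered
  xc <- rnorm(1e5)
  expect_lte(attr(despike(xc), "n_repaired"), 10)  # <= 0.01%
  # constant signal is untouched
  expect_identical(as.numeric(despike(rep(1, 100))), rep(1, 100))
  # bimodal data where the minority cluster is flagged wholesale still stays
  # below the unusable-signal guard, and the clean cluster is untouched
  xb <- c(rnorm(60), rnorm(40, 1000, 5))
  db <- despike(xb)
  expect_equal(attr(db, "n_repaired"), 40)
  expect_identical(db[1:60], xb[1:60])
})

test_that("common average reference removes shared components exactly", {
  X <- matrix(rnorm(400), 100, 4)
  same <- matrix(rnorm(100), 100, 4)
  expect_lt(max(abs(common_average_reference(same))), 1e-12)
  expect_lt(max(abs(rowSums(common_average_reference(X)))), 1e-9)
  artifact <- rnorm(100)
  expect_equal(common_average_reference(X + artifact),
               common_average_reference(X), tolerance = 1e-12)
  expect_error(common_average_reference(X[, 1, drop = FALSE]), "2 channels")
})

test_that("notch suppresses 50 Hz, spares 40 Hz and broadband power", {
  x50 <- sin(2 * pi * 50 * tt)
  expect_lt(var(notch(x50, rate)) / var(x50), 1e-3)
  x40 <- sin(2 * pi * 40 * tt)
  expect_equal(amp_ratio(notch(x40, rate), x40), 1, tolerance = 0.05)
  set.seed(22)
  w <- rnorm(length(tt))
  expect_gt(var(notch(w, rate)) / var(w), 0.95)
})

test_that("downsampling is anti-aliased with the expected length", {
  x <- sin(2 * pi * 1 * tt)
  y <- downsample(x, rate, 64)
  expect_equal(length(y), 60 * 64)
  core_y <- seq(round(length(y) * 0.2), round(length(y) * 0.8))
  expect_equal(sd(y[core_y]) / sd(x[round(length(x) * 0.2):round(length(x) * 0.8)]),
               1, tolerance = 0.01)
  x100 <- sin(2 * pi * 100 * tt)  # above the new Nyquist
  expect_lt(20 * log10(sd(downsample(x100, rate, 64)) / sd(x100)), -20)
  expect_error(downsample(x, 64, 512), "exceeds")
})

test_that("clipping caps at 3 SD before z-scoring and the mean is exactly 0", {
  set.seed(23)
  x <- rnorm(2000)
  m <- mean(x); s <- sd(x)
  x[1] <- m + 5 * s
  z <- clip_and_zscore(x)
  expect_equal(z[1], max(z))  # the outlier sits exactly at the clip ceiling
  expect_lt(abs(mean(z)), 1e-9)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  # data already within the limits: clipping is the identity up to z-scoring
  xin <- pmin(pmax(rnorm(1000), -2.5), 2.5)
  expect_equal(clip_and_zscore(xin), (xin - mean(xin)) / sd(xin),
               tolerance = 1e-12)
  expect_error(clip_and_zscore(rep(1, 10)), "zero-variance")
})

test_that("the full chain is transparent for band-limited clean data", {
  set.seed(24)
  n <- rate * 120
  X <- sapply(1:6, function(j) {
    v <- rnorm(n)
    as.numeric(signal::filtfilt(signal::butter(4, 30 / (rate / 2), "low"), v))
  })
  X <- highpass(X, rate, 1)  # keep content well above the 0.1 Hz cutoff
  chain <- clip_and_zscore(
    downsample(notch(highpass(despike(X), rate), rate), rate, 64))
  bypass <- clip_and_zscore(downsample(X, rate, 64))
  expect_gt(min(diag(cor(chain, bypass))), 0.99)
})

test_that("preprocess_recording drops bad channels and cuts z-scored blocks", {
  set.seed(25)
  spec <- synthetic_spec(n_states_range = c(8, 8))
  raw <- generate_block_raw(spec)
  chs <- data.frame(name = paste0("e", 1:16),
                    roi = rep(c("low", "high"), each = 8),
                    status = c("bad", rep("good", 15)))
  sch <- data.frame(index = 1, kind = "speech", start_s = 0, end_s = 30)
  out <- preprocess_recording(cbind(raw$raw$low[, 1:8], raw$raw$high[, 1:8]),
                              512, chs, sch)
  expect_named(out, c("low", "high"))
  expect_equal(dim(out$low[[1]]), c(1920, 7))   # one bad channel dropped
  expect_equal(dim(out$high[[1]]), c(1920, 8))
  expect_lt(max(abs(colMeans(out$high[[1]]))), 1e-9)
  expect_equal(attr(out, "log")$n_bad_dropped, 1)
})

test_that("state structure survives the preprocessing chain", {
  set.seed(26)
  spec <- synthetic_spec(n_states_range = c(10, 10))
  blk <- generate_block(spec)
  raw <- blk$low[rep(1:1920, each = 8), ]  # clean 512 Hz rendering
  chs <- data.frame(name = paste0("e", 1:16), roi = "low", status = "good")
  sch <- data.frame(index = 1, kind = "speech", start_s = 0, end_s = 30)
  pp <- preprocess_recording(raw, 512, chs, sch, reference = "none")$low[[1]]
  fit <- gsbs_segment(pp, gsbs_config(kmax = 30))
  b <- gsbs_boundaries(fit, 10)
  recall <- mean(vapply(blk$truth$b_low,
                        function(p) any(abs(b - p) <= 1), logical(1)))
  expect_gte(recall, 0.8)
})
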