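test_that("accel_magnitude is the quantised Euclidean norm", {
  expect_equal(accel_magnitude(3, 4, 0, precision = NULL), 5)
  expect_equal(accel_magnitude(0, 0, 0), 0)
  expect_equal(accel_magnitude(1, 2, 2, precision = NULL), 3)
  # quantisation to 1/2048 g after the norm
  m <- accel_magnitude(0.1, 0.2, 0.3)
  expect_equal(m, round(sqrt(0.14) * 2048) / 2048)
  expect_error(accel_magnitude(1:3, 1:2, 1:3), "length mismatch")
})

test_that("decimate_every_nth keeps indices 0, n, 2n, ...", {
  expect_equal(decimate_every_nth(c(10, 20, 30, 40), 2), c(10, 30))
  x <- rnorm(17)
  expect_equal(decimate_every_nth(x, 1), x)
  expect_equal(length(decimate_every_nth(rnorm(40), 40)), 1L)
  expect_error(decimate_every_nth(x, 0), "positive integer")
})

test_that("decimation equals the index-selection oracle for n in 1..50", {
  set.seed(5)
  x <- rnorm(997)
  for (n in 1:50) {
    oracle <- x[which((seq_along(x) - 1L) %% n == 0L)]
    expect_equal(decimate_every_nth(x, n), oracle)
    expect_equal(length(oracle), ceiling(length(x) / n))
  }
})

test_that("median_filter3 matches the brute-force window oracle", {
  brute <- function(x) {
    n <- length(x)
    vapply(seq_len(n), function(i) {
      w <- x[pmin(pmax(c(i - 1L, i, i + 1L), 1L), n)]  # edge replication
      stats::median(w)
    }, numeric(1))
  }
  expect_equal(median_filter3(c(0, 0, 100, 0, 0)), c(0, 0, 0, 0, 0))
  expect_equal(median_filter3(c(1, 9, 1, 9, 1)), c(1, 1, 9, 1, 1))
  expect_equal(median_filter3(rep(7, 20)), rep(7, 20))
  set.seed(8)
  for (i in 1:10) {
    x <- rnorm(sample(3:60, 1))
    y <- median_filter3(x)
    expect_equal(y, brute(x))
    expect_true(all(y %in% x))  # order-statistic: outputs are input elements
  }
})

test_that("LMS enhances a noisy sinusoid and is exact on degenerate inputs", {
  # all-zero input -> all-zero output
  expect_equal(as.numeric(lms_denoise(rep(0, 100), lms_config())), rep(0, 100))

  # mu = 0: weights never move, the prediction stays at its zero initial
  # value, so input minus output is the identity
  x <- rnorm(200)
  out0 <- lms_denoise(x, lms_config(mu = 0), standardize = FALSE)
  expect_equal(as.numeric(out0), rep(0, 200))
  expect_equal(x - as.numeric(out0), x)

  # constant series: output converges to (here: equals) the constant
  cc <- lms_denoise(rep(3.7, 500), lms_config())
  expect_lt(max(abs(tail(as.numeric(cc), 100) - 3.7)), 1e-8)

  # noisy unit sinusoid, 0.05 cycles/sample: the enhanced output is closer
  # to the clean signal than the input is (fixed seed)
  set.seed(7)
  n <- 2000
  clean <- sin(2 * pi * 0.05 * (0:(n - 1)))
  noisy <- clean + rnorm(n, 0, 0.5)
  out <- as.numeric(lms_denoise(noisy, lms_config()))
  expect_lt(mean((out - clean)^2), mean((noisy - clean)^2))
})

test_that("LMS divergence is caught and names mu", {
  set.seed(2)
  expect_error(lms_denoise(rnorm(500), lms_config(mu = 10)), "mu = 10")
})

test_that("external-reference mode subtracts the predicted interference", {
  set.seed(13)
  n <- 3000
  noise_src <- rnorm(n)
  signal <- sin(2 * pi * 0.01 * (0:(n - 1)))
  # interference is a lagged copy of the reference
  contaminated <- signal + 0.8 * c(0, noise_src[-n])
  out <- as.numeric(lms_denoise(contaminated, lms_config(reference = "external", mu = 0.02),
                                reference = noise_src))
  expect_lt(mean((out - signal)[500:n]^2),
            mean((contaminated - signal)[500:n]^2))
})

test_that("extract_window aligns to the prompt and scores completeness", {
  ch <- raw_channel(seq_len(2000), "HR", 1, t0 = 1000)
  w <- extract_window(ch, esm_timestamp = 1000 + 1900, window_s = 1800)
  expect_equal(w$completeness, 1.0)
  expect_true(w$ok)
  expect_equal(length(w$values), 1800L)
  # last sample is the one immediately before the prompt
  expect_equal(w$values[1800], 1900)
  expect_equal(w$values[1], 101)

  half <- extract_window(ch, esm_timestamp = 1000 + 900, window_s = 1800)
  expect_equal(half$completeness, 0.5)
  expect_false(half$ok)

  before <- extract_window(ch, esm_timestamp = 500, window_s = 1800)
  expect_equal(before$completeness, 0)
  expect_false(before$ok)
})

test_that("preprocess_subject yields labelled 1 Hz segments and reports gaps", {
  st <- simulate_subject(desk_sim_config(31), "p1", 1L)
  res <- preprocess_subject(st$channels, st$esm, desk_window_config())
  expect_equal(length(res$segments), nrow(st$esm))
  s1 <- res$segments[[1]]
  expect_equal(dim(s1$matrix), c(300L, 3L))
  expect_equal(colnames(s1$matrix), c("HR", "GSR", "ACCEL"))
  expect_false(anyNA(s1$matrix))
  expect_s3_class(s1$labels, "data.frame")
  expect_true(all(res$report$status == "ok"))

  # a prompt in a recording gap is excluded and reported
  ch2 <- st$channels
  hrv <- ch2$hr$values
  t_gap <- st$esm$timestamp[2]
  gap_idx <- seq(floor(t_gap - ch2$hr$t0) - 100, floor(t_gap - ch2$hr$t0))
  hrv[gap_idx] <- NA
  ch2$hr <- raw_channel(hrv, "HR", 1, ch2$hr$t0, "p1")
  res2 <- preprocess_subject(ch2, st$esm, desk_window_config())
  expect_equal(length(res2$segments), nrow(st$esm) - 1L)
  expect_equal(res2$report$status[2], "incomplete")

  # missing modality -> informative error (preprocess_study turns it into a
  # skip report)
  expect_error(preprocess_subject(ch2[c("hr", "gsr")], st$esm,
                                  desk_window_config()),
               "missing modality")
})

test_that("with filtering disabled the chain is pure decimation + windowing", {
  st <- simulate_subject(desk_sim_config(32), "p2", 2L)
  cfg <- desk_window_config(lms_enabled = FALSE, median_enabled = FALSE,
                            standardize = FALSE)
  res <- preprocess_subject(st$channels, st$esm, cfg)
  gsr_1hz <- decimate_every_nth(st$channels$gsr$values, 40L)
  ts <- st$esm$timestamp[1]
  k_last <- ceiling(ts - st$channels$gsr$t0) - 1
  expect_equal(res$segments[[1]]$matrix[, "GSR"],
               gsr_1hz[(k_last - 299):(k_last) + 1])
  # deterministic: a second run is identical
  res_again <- preprocess_subject(st$channels, st$esm, cfg)
  expect_identical(res_again$segments[[1]]$matrix, res$segments[[1]]$matrix)
})

test_that("the filter cascade is causal up to the median's one-sample lookahead", {
  # LMS is strictly causal; the centred kernel-3 median looks one sample
  # ahead, so changing inputs at times >= t can only affect outputs at
  # >= t - 1. (Whole-recording standardisation is held fixed here: scaling
  # by global statistics is the one deliberately non-causal step.)
  set.seed(17)
  chain <- function(x) {
    median_filter3(as.numeric(lms_denoise(x, lms_config(), standardize = FALSE)))
  }
  x <- rnorm(600)
  y1 <- chain(x)
  t_mod <- 400L
  x2 <- x
  x2[t_mod:600] <- x2[t_mod:600] + rnorm(201, 0, 2)
  y2 <- chain(x2)
  expect_equal(y1[1:(t_mod - 2L)], y2[1:(t_mod - 2L)])
  # and the outputs do differ after the modification point
  expect_false(isTRUE(all.equal(y1[t_mod:600], y2[t_mod:600])))
})
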