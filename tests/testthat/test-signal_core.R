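test_that("acceleration norm is the Euclidean magnitude of the axes", {
  rec <- suppressMessages(raw_recording(rbind(c(0, 0, 0),
                                              c(1, 0, 0),
                                              c(0.6, 0.8, 0),
                                              c(2, 3, 6))))
  nrm <- acceleration_norm(rec)
  expect_equal(nrm$values, c(0, 1, 1, 7))
  expect_equal(acceleration_norm(rec, squared = TRUE)$values, c(0, 1, 1, 49))
})

test_that("empty and non-finite input is handled explicitly", {
  expect_error(raw_recording(matrix(numeric(0), 0, 3)), "empty")
  expect_message(rec <- raw_recording(rbind(c(1, 0, 0), c(NA, 0, 0), c(0, 1, 0))),
                 "non-finite")
  expect_equal(rec$valid, c(TRUE, FALSE, TRUE))
  expect_equal(is.na(acceleration_norm(rec)$values), c(FALSE, TRUE, FALSE))
})

test_that("moving SD matches closed forms on constant, alternating and sine input", {
  # constant signal: zero variance at every emitted position
  ms <- moving_sd(as_norm(rep(3.7, 200)), msda_config())
  expect_true(all(is.na(ms[1:49])))
  expect_equal(unname(ms[50:200]), rep(0, 151))

  # alternating +a/-a over a 50-sample window: sample SD = a*sqrt(50/49)
  a <- 0.25
  ms <- moving_sd(as_norm(rep(c(a, -a), 100)), msda_config())
  expect_equal(unname(ms[50]), a * sqrt(50 / 49), tolerance = 1e-12)

  # sinusoid sampled over whole periods: population SD ~ A/sqrt(2)
  A <- 0.4
  fs <- 25
  v <- A * sin(2 * pi * 2 * (0:(fs * 4 - 1)) / fs)  # 2 Hz, 4 s
  ms <- moving_sd(as_norm(v, fs), msda_config(sd_denominator = "population"))
  expect_equal(unname(ms[50]), A / sqrt(2), tolerance = 0.01)
})

test_that("moving SD equals the brute-force window oracle on random series", {
  set.seed(404)
  for (i in 1:25) {
    n <- sample(60:160, 1)
    k <- sample(5:30, 1)
    denom <- sample(c("sample", "population"), 1)
    v <- rnorm(n, 1, 0.3)
    if (runif(1) < 0.5) v[sample(n, 3)] <- NA  # gaps
    ms <- moving_sd(as_norm(v), msda_config(window_samples = k,
                                            sd_denominator = denom))
    oracle <- brute_moving_sd(v, k, denom)
    expect_equal(as.numeric(ms), oracle, tolerance = 1e-10)
  }
})

test_that("moving SD is translation invariant, scales linearly, and is nonnegative", {
  set.seed(11)
  v <- rnorm(300, 1, 0.1)
  cfg <- msda_config(window_samples = 25)
  base <- moving_sd(as_norm(v), cfg)
  shifted <- moving_sd(as_norm(v + 5), cfg)
  scaled <- moving_sd(as_norm(v * 3), cfg)
  expect_equal(unname(base), unname(shifted), tolerance = 1e-9)
  expect_equal(unname(scaled), unname(base * 3), tolerance = 1e-9)
  expect_true(all(base >= 0, na.rm = TRUE))
})

test_that("stride controls window overlap", {
  set.seed(12)
  v <- rnorm(120, 1, 0.2)
  k <- 20L
  tumbling <- moving_sd(as_norm(v), msda_config(window_samples = k,
                                                stride_samples = k))
  emitted <- which(!is.na(tumbling))
  expect_equal(emitted, seq.int(k, 120L, by = k))
  expect_equal(unname(tumbling[emitted]),
               brute_moving_sd(v, k, stride = k)[emitted], tolerance = 1e-10)
})

test_that("a window longer than the series yields an empty result with a warning", {
  expect_warning(out <- moving_sd(as_norm(rnorm(10)), msda_config()), "longer")
  expect_length(out, 0)
})

test_that("the 2-second window resolves to 50 samples at 25 Hz", {
  expect_identical(resolve_window(msda_config(window_seconds = 2), 25), 50L)
  expect_identical(resolve_window(msda_config(window_samples = 32), 25), 32L)
})

test_that("minute aggregation buckets MSDA, steps and validity per slot", {
  fs <- 25
  n <- 3 * 60 * fs  # three minutes
  rec <- rec_from_values(rep(1, n), fs)
  ms <- moving_sd(acceleration_norm(rec), msda_config())
  # constant signal, two step events in minute 1
  mins <- minute_aggregate(ms, c(70, 80.5), rec, msda_config())
  expect_s3_class(mins, "minute_series")
  expect_equal(nrow(mins), 1440)
  expect_equal(mins$msda[1:3], c(0, 0, 0))
  expect_equal(mins$steps[1:3], c(0, 2, 0))
  expect_true(all(mins$valid[1:3]))
  # untouched slots are missing
  expect_false(any(mins$valid[4:1440]))
  expect_true(all(is.na(mins$msda[4:1440])))
})

test_that("minute validity threshold is inclusive at the boundary", {
  fs <- 25
  n <- 2 * 60 * fs
  valid <- rep(TRUE, n)
  valid[1:(30 * fs)] <- FALSE  # exactly half of minute 0 invalid
  rec <- rec_from_values(rep(1, n), fs, valid = valid)
  ms <- moving_sd(acceleration_norm(rec), msda_config())
  mins <- minute_aggregate(ms, numeric(0), rec, msda_config())
  expect_true(mins$valid[1])   # 0.5 >= 0.5: still measured
  expect_true(mins$valid[2])
  mins_strict <- minute_aggregate(ms, numeric(0), rec,
                                  msda_config(minute_min_valid_fraction = 0.6))
  expect_false(mins_strict$valid[1])
})

test_that("minute series marks msda missing exactly where the slot is invalid", {
  set.seed(33)
  fs <- 25
  n <- 5 * 60 * fs
  valid <- rep(TRUE, n)
  valid[(2 * 60 * fs):(3 * 60 * fs)] <- FALSE
  rec <- rec_from_values(1 + rnorm(n, 0, 0.01), fs, valid = valid)
  mins <- minute_aggregate(moving_sd(acceleration_norm(rec), msda_config()),
                           numeric(0), rec, msda_config())
  expect_identical(is.na(mins$msda), !mins$valid)
  expect_identical(is.na(mins$steps), !mins$valid)
})
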