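test_that("recordings round-trip through the delimited-text format with gaps", {
  set.seed(51)
  fs <- 25
  n <- 4 * 60 * fs
  valid <- rep(TRUE, n)
  valid[2000:2999] <- FALSE
  rec <- suppressMessages(raw_recording(
    matrix(rnorm(3 * n, c(1, 0, 0), 0.01), n, 3, byrow = FALSE),
    sampling_rate_hz = fs, subject_id = "RT01", valid = valid))
  path <- withr::local_tempfile(fileext = ".csv")
  write_recording_csv(rec, path, meta = list(seed = 99))
  back <- read_recording_csv(path)
  expect_equal(back$subject_id, "RT01")
  expect_equal(back$sampling_rate_hz, fs)
  expect_equal(back$valid, rec$valid)
  expect_equal(back$samples[valid, ], rec$samples[valid, ], tolerance = 1e-6)
  expect_true(all(is.na(back$samples[!valid, 1])))
  # header metadata preserved
  hdr <- readLines(path, n = 5)
  expect_true(any(grepl("seed=99", hdr)))
})

test_that("malformed rows are skipped up to the tolerated fraction", {
  path <- withr::local_tempfile(fileext = ".csv")
  lines <- c("# subject_id=M01", "# sampling_rate_hz=25",
             "t_s,x,y,z",
             sprintf("%g,1,0,0", (0:99) / 25))
  bad <- lines
  bad[10] <- "0.24,oops,0,0"
  writeLines(bad, path)
  expect_message(rec <- read_recording_csv(path), "malformed")
  expect_equal(sum(!rec$valid), 1)
  # too many malformed rows: reject the file
  worse <- lines
  worse[10:30] <- "0.9,oops,0,0"
  writeLines(worse, path)
  expect_error(read_recording_csv(path), "malformed")
})

test_that("minute series round-trip and the pipeline runs over a directory", {
  dir_in <- withr::local_tempdir()
  dir_out <- withr::local_tempdir()
  pr <- list(tiny_profile(n_subjects = 2))
  meta <- generate_cohort(pr, seed = 52, days = 1, dir = dir_in)
  expect_true(file.exists(file.path(dir_in, "metadata.csv")))
  summ <- suppressMessages(run_pipeline(dir_in, dir_out, seed = 52))
  expect_equal(nrow(summ), 2)
  expect_true(all(summ$retained))
  expect_true(all(is.finite(summ$daily_msda)))
  expect_true("subgroup" %in% names(summ))
  mfile <- file.path(dir_out, paste0(summ$subject_id[1], "_minutes.csv"))
  expect_true(file.exists(mfile))
  mins <- read_minute_series(mfile)
  expect_equal(nrow(mins), 1440)
  expect_identical(is.na(mins$msda), !mins$valid)
  # outputs embed the seed and a config hash
  hdr <- readLines(mfile, n = 3)
  expect_true(any(grepl("seed=52", hdr)))
  expect_true(any(grepl("config_hash=[0-9a-f]{32}", hdr)))
})

test_that("a gap-free constant recording yields zero MSDA everywhere", {
  dir_in <- withr::local_tempdir()
  dir_out <- withr::local_tempdir()
  fs <- 25
  rec <- rec_from_values(rep(1, 1440 * 60 * fs / 6), fs)  # 4 h constant
  write_recording_csv(rec, file.path(dir_in, "C01.csv"))
  summ <- run_pipeline(dir_in, dir_out, error_threshold = 1)
  expect_equal(summ$daily_msda, 0)
  expect_equal(summ$daily_steps, 0)
  expect_error(run_pipeline(withr::local_tempdir(), dir_out), "no recording")
})

test_that("validation reports serialise to JSON with schema and pairwise entries", {
  set.seed(53)
  lvl <- subgroup_levels()
  rows <- do.call(rbind, lapply(seq_along(lvl), function(i) {
    data.frame(subgroup = lvl[i],
               mobility_mode = if (grepl("WC|1-4", lvl[i])) "wheelchair" else "walking",
               daily_msda = 0.004 * i + rnorm(8, 0, 0.002),
               daily_steps = pmax(0, rnorm(8, 500 * i, 300)),
               retained = TRUE)
  }))
  rep <- build_report(rows)
  jf <- withr::local_tempfile(fileext = ".json")
  tf <- withr::local_tempfile(fileext = ".txt")
  write_validation_report(rep, jf, tf, meta = list(seed = 53))
  js <- jsonlite::read_json(jf)
  expect_equal(js$schema_version, 1)
  expect_equal(js$seed, 53)
  expect_length(js$comparisons$msda$pairwise, 15)
  expect_length(js$correlations, 3)
  txt <- readLines(tf)
  expect_true(any(grepl("Floor effect", txt)))
  # identical input produces an identical report file
  jf2 <- withr::local_tempfile(fileext = ".json")
  write_validation_report(rep, jf2, meta = list(seed = 53))
  expect_identical(readLines(jf), readLines(jf2))
})

test_that("the command-line interface simulates, computes and reports", {
  skip_on_os("windows")
  cli <- system.file("cli", "msda.R", package = "msdactivity")
  expect_true(nzchar(cli))
  dir <- withr::local_tempdir()
  rscript <- file.path(R.home("bin"), "Rscript")
  out <- system2(rscript, c(cli, "simulate", "--seed", "54", "--out",
                            file.path(dir, "raw"), "--subjects", "2",
                            "--days", "1", "--subgroup", "FIM6-walk"),
                 stdout = TRUE, stderr = TRUE)
  expect_equal(attr(out, "status") %||% 0, 0)
  expect_true(file.exists(file.path(dir, "raw", "metadata.csv")))
  out <- system2(rscript, c(cli, "compute", "--in", file.path(dir, "raw"),
                            "--out", file.path(dir, "minutes")),
                 stdout = TRUE, stderr = TRUE)
  expect_equal(attr(out, "status") %||% 0, 0)
  expect_true(file.exists(file.path(dir, "minutes", "summaries.csv")))
  # bad configuration exits non-zero
  bad <- suppressWarnings(system2(rscript, c(cli, "simulate", "--seed", "x"),
                                  stdout = TRUE, stderr = TRUE))
  expect_gt(attr(bad, "status") %||% 0, 0)
})
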