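test_that("CSV round-trip preserves samples and infers the rate", {
  lr <- syn_rec(duration = 5, seed = 31)
  tmp <- tempfile(fileext = ".csv")
  write_ecg_csv(lr$record, tmp)
  back <- read_ecg_csv(tmp)
  expect_equal(back$sampling_rate, 125)
  expect_equal(back$samples, lr$record$samples, tolerance = 1e-9)

  # (0.000, 0.008, ...) time stamps imply 125 Hz
  df <- utils::read.csv(tmp)
  expect_equal(1 / median(diff(df$time_s)), 125, tolerance = 1e-9)
})

test_that("WFDB round-trip is exact to format quantisation", {
  dir <- tempdir()
  set.seed(44)
  for (k in 1:20) {
    lr <- syn_rec(duration = 2, heart_rate = sample(50:150, 1), seed = 400 + k)
    write_wfdb(lr$record, dir, sprintf("rt%02d", k))
    back <- read_wfdb(file.path(dir, sprintf("rt%02d", k)))
    expect_equal(back$sampling_rate, 125)
    # gain 200 ADU/mV: quantisation error bounded by half a step
    expect_lte(max(abs(back$samples - lr$record$samples)), 0.5 / 200 + 1e-12)
  }
})

test_that("malformed inputs raise parse errors; off-rate input is resampled", {
  empty <- tempfile(fileext = ".csv")
  file.create(empty)
  expect_error(read_ecg_csv(empty), "parse error")

  bad <- tempfile(fileext = ".csv")
  writeLines(c("a,b", "1,2", "2,3"), bad)
  expect_error(read_ecg_csv(bad), "time_s,amplitude_mV")

  nonuni <- tempfile(fileext = ".csv")
  writeLines(c("time_s,amplitude_mV", "0,0", "0.008,1", "0.1,2"), nonuni)
  expect_error(read_ecg_csv(nonuni), "non-uniform")

  expect_error(read_record(tempfile(fileext = ".csv")), "not found")

  hi <- tempfile(fileext = ".csv")
  t250 <- seq(0, 4, by = 1 / 250)
  utils::write.csv(data.frame(time_s = t250, amplitude_mV = sin(2 * pi * 2 * t250)),
                   hi, row.names = FALSE)
  expect_message(rec <- read_ecg_csv(hi), "resampling")
  expect_equal(rec$sampling_rate, 125)
})

test_that("pipeline delegates to the stages and reports structured status", {
  lr <- syn_rec(duration = 20, heart_rate = 70, seed = 32)
  cfg <- pipeline_config(model = stub_model("SN"), seed = 7)
  res <- run_pipeline(lr$record, cfg)
  expect_equal(res$status, "ok")
  expect_equal(res$score, 100L)
  expect_equal(res$diagnosis$calls, "SN")
  expect_true(abs(res$measurements$ventricular_rate_bpm - 70) < 2)

  # byte-identical JSON on a repeated run
  expect_identical(as.character(pipeline_to_json(run_pipeline(lr$record, cfg))),
                   as.character(pipeline_to_json(run_pipeline(lr$record, cfg))))

  # empty record halts after the quality stage
  res2 <- run_pipeline(ecg_record(rep(0, 2500)), cfg)
  expect_equal(res2$status, "empty")
  expect_null(res2$score)

  # stage errors are named: a 2 s record is too short for the baseline filter
  res3 <- run_pipeline(ecg_record(lr$record$samples[1:250]), cfg)
  expect_equal(res3$status, "error")
  expect_equal(res3$stage, "clean")
  expect_match(res3$message, "too short")

  # without a model the diagnosis/score stages are skipped with a notice
  res4 <- run_pipeline(lr$record, pipeline_config())
  expect_equal(res4$status, "ok")
  expect_null(res4$score)
  expect_match(res4$notice, "skipped")
})

test_that("CLI returns distinct exit codes and chains commands", {
  tdir <- tempfile()
  dir.create(tdir)
  score_out <- file.path(tdir, "score.json")
  expect_equal(ecg_cli(c("score", "--items", "AF", "--out", score_out)), 0L)
  expect_equal(jsonlite::fromJSON(score_out)$score, 75)

  expect_equal(suppressMessages(ecg_cli(c("frobnicate"))), 2L)
  expect_equal(suppressMessages(ecg_cli(c("score"))), 2L)             # missing flag
  expect_equal(suppressMessages(ecg_cli(c("measure", "--in",
                                          file.path(tdir, "nope.csv")))), 3L)
  expect_equal(ecg_cli(character(0)), 2L)

  rec_csv <- file.path(tdir, "rec.csv")
  expect_equal(ecg_cli(c("simulate", "--out", rec_csv, "--duration", "20",
                         "--seed", "5")), 0L)
  expect_true(file.exists(rec_csv))
  expect_true(file.exists(file.path(tdir, "rec_truth.json")))

  clean_csv <- file.path(tdir, "clean.csv")
  expect_equal(ecg_cli(c("clean", "--in", rec_csv, "--out", clean_csv)), 0L)

  meas_json <- file.path(tdir, "meas.json")
  expect_equal(ecg_cli(c("measure", "--in", clean_csv, "--out", meas_json)), 0L)
  meas <- jsonlite::fromJSON(meas_json)
  expect_true(meas$ventricular_rate_bpm > 60 && meas$ventricular_rate_bpm < 90)

  hrv_json <- file.path(tdir, "hrv.json")
  expect_equal(ecg_cli(c("hrv", "--in", rec_csv, "--out", hrv_json)), 0L)
  expect_gte(jsonlite::fromJSON(hrv_json)$n_intervals, 15)

  al_json <- file.path(tdir, "alerts.json")
  expect_equal(ecg_cli(c("alerts", "--scores", "90,84,84", "--out", al_json)), 0L)
  expect_true(jsonlite::fromJSON(al_json)$triggered)

  ann_json <- file.path(tdir, "ann.json")
  expect_equal(ecg_cli(c("delineate", "--in", rec_csv, "--out", ann_json)), 0L)
  ann <- jsonlite::fromJSON(ann_json)
  expect_equal(ann$index_base, 0)

  run_json <- file.path(tdir, "run.json")
  expect_equal(ecg_cli(c("run", "--in", rec_csv, "--out", run_json)), 0L)
  expect_equal(jsonlite::fromJSON(run_json)$status, "ok")

  rep_json <- file.path(tdir, "rep.json")
  expect_equal(ecg_cli(c("report", "--items", "SN;SN;AF", "--scores",
                         "100,100,75", "--out", rep_json)), 0L)
  expect_equal(jsonlite::fromJSON(rep_json)$item_counts$SN, 2)
})

test_that("annotation JSON export uses 0-based indices", {
  lr <- syn_rec(duration = 10, heart_rate = 60, seed = 33)
  rec <- clean_record(lr$record)
  ann <- delineate_waves(rec, detect_qrs(rec))
  js <- jsonlite::fromJSON(annotations_to_json(ann))
  expect_equal(js$index_base, 0)
  expect_equal(js$beats$qrs_peak, ann$qrs_peak - 1L)
  expect_equal(js$sampling_rate, 125)
})
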