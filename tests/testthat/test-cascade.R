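cascade_cfg <- default_cascade()

test_that("interview answers encode onto the cascade scales", {
  rec <- tibble::as_tibble(interview_record())
  rec$nocturia <- "Often"
  rec$prolonged_awakenings <- "Occasionally"
  rec$unrefreshing_sleep <- "No"
  rec$snorer <- "Yes"
  rec$high_intensity_snorer <- "No"
  enc <- encode_interview(rec)
  expect_equal(enc$nocturia, 10)
  expect_equal(enc$prolonged_awakenings, 5)
  expect_equal(enc$unrefreshing_sleep, 0)
  expect_equal(enc$snorer, 2)
  expect_equal(enc$high_intensity_snorer, 0)
  expect_equal(enc$hours_of_sleep, 7)        # numeric passthrough
  # snorer: the three categories enumerate the 0-2 range
  for (ans in list(c("No", 0), c("In supine position only", 1), c("Yes", 2))) {
    rec$snorer <- ans[[1]]
    expect_equal(encode_interview(rec)$snorer, as.numeric(ans[[2]]))
  }
})

test_that("unknown labels, missing items and out-of-range values are rejected by name", {
  rec <- tibble::as_tibble(interview_record())
  rec$nocturia <- "Perhaps"
  expect_error(encode_interview(rec), "nocturia.*Perhaps")
  expect_error(encode_interview(rec[, -1]), "hours_of_sleep")
  rec2 <- tibble::as_tibble(interview_record(minutes_to_sleep = 500))
  expect_error(encode_interview(rec2), "minutes_to_sleep")
})

test_that("cascade corners behave: benign answers score low, severe answers high", {
  lo <- interview_record(hours_of_sleep = 14, minutes_to_sleep = 0)
  hi <- interview_record(hours_of_sleep = 0, minutes_to_sleep = 240,
                         prolonged_awakenings = 10, unrefreshing_sleep = 10,
                         daytime_tiredness = 10, morning_dullness = 10,
                         unjustified_multiple_awakenings = 1, nocturia = 10,
                         breathless_awakenings = 10, reported_apneas = 10,
                         snorer = 2, high_intensity_snorer = 1,
                         snore_awakenings = 10)
  res_lo <- eval_cascade(lo, cascade_cfg)
  res_hi <- eval_cascade(hi, cascade_cfg)
  expect_lt(res_lo$preliminary, 2)
  expect_gt(res_hi$preliminary, 8)
})

test_that("every cascade output lies in range and the rescaling is exact", {
  set.seed(77)
  for (i in 1:10) {
    rec <- interview_record(
      hours_of_sleep = runif(1, 0, 14), minutes_to_sleep = runif(1, 0, 240),
      prolonged_awakenings = sample(c(0, 5, 10), 1),
      unrefreshing_sleep = sample(c(0, 5, 10), 1),
      daytime_tiredness = sample(c(0, 5, 10), 1),
      morning_dullness = sample(c(0, 5, 10), 1),
      unjustified_multiple_awakenings = sample(0:1, 1),
      nocturia = sample(c(0, 5, 10), 1),
      breathless_awakenings = sample(c(0, 5, 10), 1),
      reported_apneas = sample(c(0, 5, 10), 1),
      snorer = sample(0:2, 1), high_intensity_snorer = sample(0:1, 1),
      snore_awakenings = sample(c(0, 5, 10), 1))
    res <- eval_cascade(rec, cascade_cfg)
    for (col in c("r1a", "r1b", "r2a", "r2b", "r1", "r2", "preliminary")) {
      expect_gte(res[[col]], 0); expect_lte(res[[col]], 10)
    }
    expect_identical(res$symbolic_risk, 10 * res$preliminary)
  }
  expect_equal(rescale_symbolic(6.179), 61.79)
  expect_equal(rescale_symbolic(c(0, 10)), c(0, 100))
  expect_error(rescale_symbolic(11), "\\[0, 10\\]")
})

test_that("identical inputs give identical cascade results (determinism)", {
  rec <- interview_record(nocturia = 5, reported_apneas = 10, snorer = 1)
  expect_identical(eval_cascade(rec, cascade_cfg), eval_cascade(rec, cascade_cfg))
})

test_that("level-2 and level-3 systems are monotone in their risk inputs", {
  pts <- seq(0, 10, length.out = 5)
  for (sys_name in c("level2_R1", "level2_R2", "level3")) {
    sys <- cascade_cfg[[sys_name]]
    vars <- names(sys$inputs)
    for (fixed in pts) {
      along1 <- vapply(pts, function(p) {
        fis_infer(sys, stats::setNames(list(p, fixed), vars))
      }, numeric(1))
      along2 <- vapply(pts, function(p) {
        fis_infer(sys, stats::setNames(list(fixed, p), vars))
      }, numeric(1))
      expect_true(all(diff(along1) >= -1e-4))
      expect_true(all(diff(along2) >= -1e-4))
    }
  }
})

test_that("the shipped configuration validates; broken configurations are reported", {
  v <- validate_cascade(cascade_cfg)
  expect_true(v$ok)
  expect_identical(v$issues, character(0))
  expect_equal(nrow(v$report), 7)
  expect_true(all(v$report$coverage_ok))
  expect_true(all(v$report$n_rules >= 18))

  # a complicating-factors system that never covers high nocturia
  broken <- cascade_cfg
  cf <- broken$complicating_factors
  broken$complicating_factors <- mamdani_system(
    "complicating_factors", cf$inputs, cf$output,
    list(fuzzy_rule(c(unjustified_multiple_awakenings = "No",
                      nocturia = "Never", breathless_awakenings = "Never",
                      reported_apneas = "Never"), "Very_low")))
  class(broken) <- "cascade_config"
  vb <- validate_cascade(broken)
  expect_false(vb$ok)
  expect_match(vb$issues, "complicating_factors.*coverage failure", all = FALSE)

  # mis-wired level 2
  wired <- cascade_cfg
  wired$level2_R1 <- cascade_cfg$level2_R2
  class(wired) <- "cascade_config"
  vw <- validate_cascade(wired)
  expect_false(vw$ok)
  expect_match(vw$issues, "level2_R1.*wired", all = FALSE)
})

test_that("cascade configurations round-trip through JSON losslessly", {
  path <- withr::local_tempfile(fileext = ".json")
  write_cascade(cascade_cfg, path)
  back <- read_cascade(path)
  expect_s3_class(back, "cascade_config")
  expect_identical(names(back), names(cascade_cfg))
  rec <- interview_record(nocturia = 10, reported_apneas = 5, snorer = 2,
                          daytime_tiredness = 5)
  expect_equal(eval_cascade(rec, back), eval_cascade(rec, cascade_cfg))
  expect_error(read_cascade(system.file("extdata", "case_patient.json",
                                        package = "osatriage")),
               "not a cascade configuration")
})

test_that("the case-study interview reproduces the published risk pattern", {
  res <- symbolic_risk(case_study_patient(), cascade_cfg)
  # qualitative calibration: complicating factors and snoring push R2.a/R2.b
  # high, unrefreshing-sleep stays low, overall risk lands at level 2
  expect_gt(res$r2a, 6.5)
  expect_gt(res$r2b, 6.5)
  expect_lt(res$r1b, 3.5)
  expect_gt(res$symbolic_risk, 45)
  expect_lt(res$symbolic_risk, 65)
})
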