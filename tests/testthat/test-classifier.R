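fit_small <- function(seed = 5, data = small_cohort()) {
  fit_osa_classifier(data, trees = 15, per_class = 500, seed = seed)
}

test_that("training is reproducible: same data and seed give identical metrics and predictions", {
  m1 <- fit_small()
  m2 <- fit_small()
  expect_identical(m1$cv$fold_auc, m2$cv$fold_auc)
  expect_identical(m1$cv$pooled_auc, m2$cv$pooled_auc)
  expect_identical(m1$cv$confusion, m2$cv$confusion)
  new <- objective_record(neck_circumference = 47, age = 60)
  p1 <- predict_statistical_risk(m1, new)
  p2 <- predict_statistical_risk(m2, new)
  expect_identical(p1$statistical_risk, p2$statistical_risk)
})

test_that("the statistical risk is 100 x the OSA class probability, within [0, 100]", {
  m <- fit_small()
  cohort <- small_cohort()[1:40, ]
  pred <- predict_statistical_risk(m, cohort)
  expect_equal(pred$statistical_risk, 100 * pred$statistical_prob)
  expect_true(all(pred$statistical_risk >= 0 & pred$statistical_risk <= 100))
  # monotone in the underlying probability by construction
  ord <- order(pred$statistical_prob)
  expect_identical(order(pred$statistical_risk), ord)
})

test_that("prediction refuses records encoded under a different schema", {
  m <- fit_small()
  other <- default_encoding_schema()
  other$numeric$age <- c(0, 120)
  m2 <- m
  m2$schema <- other   # model claims a schema it was not trained with
  expect_error(predict_statistical_risk(m2, objective_record()),
               "schema")
})

test_that("planted objective effects outrank pure-noise features in importance", {
  m <- fit_small()
  imp <- m$importance
  planted <- c("bmi", "neck_circumference", "age", "sex_Male")
  noise <- c("antihistamines_1", "neuroleptics_1", "morphics_1")
  expect_true(all(imp[planted] > max(imp[noise])))
})

test_that("cross-validated discrimination is strong on planted-effect data", {
  m <- fit_small()
  expect_gt(m$cv$pooled_auc, 0.75)
  expect_true(is.finite(m$cv_prebalanced$pooled_auc))
})

test_that("tidy and glance expose the CV metrics in broom shapes", {
  m <- fit_small()
  td <- tidy(m)
  expect_identical(names(td), c("fold", "auc"))
  expect_equal(nrow(td), 5)
  gl <- glance(m)
  expect_equal(nrow(gl), 1)
  expect_true(all(c("auc", "auc_prebalanced", "accuracy", "sensitivity",
                    "specificity") %in% names(gl)))
  expect_equal(gl$auc, m$cv$pooled_auc)
})

test_that("degenerate training inputs error clearly", {
  cohort <- small_cohort()
  expect_error(fit_osa_classifier(cohort[, setdiff(names(cohort), "ahi")]),
               "AHI column")
  allpos <- dplyr::mutate(cohort[1:50, ], ahi = 50)
  expect_error(fit_osa_classifier(allpos, per_class = 100, seed = 1),
               "single class")
})

test_that("models persist and load with schema-hash verification", {
  m <- fit_small()
  path <- withr::local_tempfile(fileext = ".rds")
  persist_model(m, path)
  back <- load_model(path)
  expect_identical(back$schema_hash, m$schema_hash)
  new <- objective_record(age = 44)
  expect_identical(predict_statistical_risk(back, new)$statistical_risk,
                   predict_statistical_risk(m, new)$statistical_risk)
  # tampered schema is refused
  bad <- list(format = "osatriage/model", version = 1L, model = m)
  bad$model$schema$numeric$age <- c(0, 200)
  path2 <- withr::local_tempfile(fileext = ".rds")
  saveRDS(bad, path2)
  expect_error(load_model(path2), "hash mismatch")
  expect_error(load_model(system.file("extdata", "case_patient.json",
                                      package = "osatriage")))
})
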