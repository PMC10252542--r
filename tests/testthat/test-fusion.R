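test_that("risk levels follow the closed-left/open-right threshold semantics", {
  expect_identical(risk_level(40, c(45, 60)), 1L)
  expect_identical(risk_level(61.79, c(45, 65)), 2L)
  expect_identical(risk_level(65, c(45, 65)), 3L)
  expect_identical(risk_level(45, c(45, 60)), 2L)     # L1 boundary in level 2
  expect_identical(risk_level(c(0, 44.999, 59.999, 60, 100), c(45, 60)),
                   c(1L, 1L, 2L, 3L, 3L))
  expect_error(risk_level(101, c(45, 60)), "\\[0, 100\\]")
})

test_that("levels map to utility scores level - 1", {
  expect_identical(level_score(1:3), 0:2)
  expect_error(level_score(4), "level")
  expect_error(level_score(0), "level")
})

test_that("the decision variable is the weighted score sum with constrained weights", {
  expect_equal(decision_t(0, 1), 1)
  expect_equal(decision_t(2, 2), 4)
  expect_equal(decision_t(0, 0, w_st = 1.7, w_sy = 0.3), 0)
  expect_equal(decision_t(1, 2, w_st = 1.5, w_sy = 0.5), 2.5)
  expect_error(decision_t(0, 1, w_st = 1.5, w_sy = 1.5), "w_st \\+ w_sy = 2")
  expect_error(decision_t(0, 1, w_st = 2.5, w_sy = -0.5), "\\[0, 2\\]")
  expect_error(decision_t(3, 0), "scores")
})

test_that("recommendations partition [0,4]: non-OSA below 2, doubtful in [2,3), possible OSA at 3+", {
  r <- recommend(c(0, 1, 1.99, 2, 2.5, 2.99, 3, 4))
  expect_identical(as.character(r$recommendation),
                   c("NON_OSA", "NON_OSA", "NON_OSA", "DOUBTFUL", "DOUBTFUL",
                     "DOUBTFUL", "POSSIBLE_OSA", "POSSIBLE_OSA"))
  expect_identical(r$alert_color,
                   c("green", "green", "green", "orange", "orange", "orange",
                     "red", "red"))
  expect_error(recommend(4.5), "\\[0, 4\\]")
})

test_that("every reachable T under any valid weights is covered, with no gaps", {
  scores <- expand.grid(st = 0:2, sy = 0:2)
  for (w in seq(0, 2, by = 0.125)) {
    t_vals <- decision_t(scores$st, scores$sy, w_st = w, w_sy = 2 - w)
    rec <- recommend(t_vals)
    expect_false(anyNA(rec$recommendation))
    expect_true(all(t_vals >= 0 & t_vals <= 4))
  }
})

test_that("default weights enumerate T over {0..4}, reproducing the score-grid table", {
  grid <- expand.grid(st = 0:2, sy = 0:2)
  t_vals <- decision_t(grid$st, grid$sy)
  expect_identical(sort(unique(t_vals)), c(0, 1, 2, 3, 4))
  expect_identical(t_vals, as.numeric(grid$st + grid$sy))
  # symmetry under default weights
  expect_identical(decision_t(grid$st, grid$sy), decision_t(grid$sy, grid$st))
  # colour classes along the grid
  rec <- recommend(t_vals)
  expect_identical(rec$alert_color[t_vals < 2][1], "green")
  expect_identical(unique(rec$alert_color[t_vals == 2]), "orange")
  expect_identical(unique(rec$alert_color[t_vals >= 3]), "red")
})

test_that("T and the recommendation are monotone in either risk", {
  risks <- seq(0, 100, by = 2.5)
  base <- fuse_risks(data.frame(statistical_risk = risks, symbolic_risk = 30))
  expect_true(all(diff(base$T) >= 0))
  expect_true(all(diff(as.integer(base$recommendation)) >= 0))
  base2 <- fuse_risks(data.frame(statistical_risk = 50, symbolic_risk = risks))
  expect_true(all(diff(base2$T) >= 0))
  expect_true(all(diff(as.integer(base2$recommendation)) >= 0))
})

test_that("fuse_risks assembles the complete assessment row", {
  a <- fuse_risks(data.frame(statistical_risk = c(40, 100, 0),
                             symbolic_risk = c(61.79, 100, 0)))
  expect_s3_class(a, "osa_assessment")
  expect_identical(a$statistical_level, c(1L, 3L, 1L))
  expect_identical(a$symbolic_level, c(2L, 3L, 1L))
  expect_identical(a$T, c(1, 4, 0))
  expect_identical(as.character(a$recommendation),
                   c("NON_OSA", "POSSIBLE_OSA", "NON_OSA"))
  expect_match(a$recommendation_text[1], "do not perform diagnostic studies")
  expect_error(fuse_risks(data.frame(statistical_risk = 40)), "symbolic_risk")
  bad <- default_thresholds(); bad$statistical <- c(60, 45)
  expect_error(fuse_risks(data.frame(statistical_risk = 40,
                                     symbolic_risk = 50), thresholds = bad),
               "L1 < L2")
})

test_that("assessment is branch-order independent and all-or-nothing", {
  m <- fit_osa_classifier(small_cohort(), trees = 15, per_class = 500, seed = 5)
  patient <- case_study_patient()
  a <- assess(patient, m)
  # independent branch runs reproduce the fused values
  st <- predict_statistical_risk(m, patient)$statistical_risk
  sy <- symbolic_risk(patient)$symbolic_risk
  expect_equal(a$statistical_risk, st)
  expect_equal(a$symbolic_risk, sy)
  expect_equal(a$T, decision_t(level_score(risk_level(st, c(45, 60))),
                               level_score(risk_level(sy, c(45, 65)))))
  # a failing branch aborts the assessment (no partial rows)
  broken <- patient; broken$nocturia <- "Perhaps"
  expect_error(assess(broken, m), "nocturia")
})
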