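test_that("trapezoid membership is 0 outside support, 1 on plateau, linear on ramps", {
  mf <- trapmf(0, 2, 4, 6, "t")
  expect_equal(mf_degree(mf, -1), 0)
  expect_equal(mf_degree(mf, 3), 1)
  expect_equal(mf_degree(mf, 1), 0.5)
  expect_equal(mf_degree(mf, 5), 0.5)
  expect_equal(mf_degree(mf, c(0, 2, 4, 6, 100)), c(0, 1, 1, 0, 0))
  # triangle as degenerate trapezoid shares the same evaluation path
  tri <- trimf(0, 5, 10, "tri")
  expect_equal(mf_degree(tri, c(2.5, 5, 7.5)), c(0.5, 1, 0.5))
  # degrees always within [0,1] and continuous across breakpoints
  x <- seq(-2, 8, by = 0.01)
  mu <- mf_degree(mf, x)
  expect_true(all(mu >= 0 & mu <= 1))
  expect_lt(max(abs(diff(mu))), 0.011)
})

test_that("malformed breakpoints are rejected at construction", {
  expect_error(trapmf(2, 1, 4, 6, "bad"), "a <= b <= c <= d")
  expect_error(trapmf(0, 2, 6, 4, "bad"), "a <= b <= c <= d")
})

test_that("linguistic variables enforce support, ordering and coverage", {
  expect_error(
    lingvar("v", 0, 5, list(trapmf(0, 1, 2, 7, "t1"), trapmf(2, 4, 5, 5, "t2"))),
    "outside the universe")
  expect_error(
    lingvar("v", 0, 10, list(trapmf(6, 8, 10, 10, "hi"), trapmf(0, 0, 2, 4, "lo"))),
    "ordered by centre")
  expect_error(
    lingvar("v", 0, 10, list(trapmf(0, 0, 1, 2, "lo"), trapmf(8, 9, 10, 10, "hi"))),
    "cover the universe")
})

test_that("fuzzification yields one degree per term with boundary and overlap behaviour", {
  v <- lingvar("sev", 0, 10, uniform_terms(0, 10, c("lo", "mid", "hi")))
  at_lo <- fuzzify(v, 0)
  expect_equal(unname(at_lo["lo"]), 1)
  expect_equal(unname(at_lo["hi"]), 0)
  # overlap region between adjacent terms: exactly two positive degrees
  ov <- fuzzify(v, 2.5)
  expect_equal(sum(ov > 0), 2)
  for (x in seq(0, 10, by = 0.5)) {
    d <- fuzzify(v, x)
    expect_true(all(d >= 0 & d <= 1))
    expect_gt(max(d), 0)
  }
})

test_that("out-of-universe inputs clamp within 1% of range and error beyond", {
  v <- lingvar("sev", 0, 10, uniform_terms(0, 10, c("lo", "hi")))
  expect_warning(d <- fuzzify(v, 10.05), "clamping")
  expect_equal(unname(d["hi"]), 1)
  expect_error(fuzzify(v, 10.5), "sev")
  expect_error(fuzzify(v, -1), "outside its universe")
})

test_that("rule firing strength is the minimum over antecedent degrees", {
  r <- fuzzy_rule(c(a = "x", b = "y"), "out")
  expect_equal(rule_strength(r, list(a = c(x = 0.3), b = c(y = 0.7))), 0.3)
  expect_equal(rule_strength(fuzzy_rule(c(a = "x"), "out"), list(a = c(x = 1))), 1)
  expect_equal(rule_strength(r, list(a = c(x = 0), b = c(y = 0.9))), 0)
  expect_error(rule_strength(r, list(a = c(x = 0.3))), "b")
})

test_that("adding an antecedent never increases firing strength (min-monotonicity)", {
  set.seed(401)
  for (i in 1:50) {
    degs <- list(a = c(t = runif(1)), b = c(t = runif(1)), c = c(t = runif(1)))
    s2 <- rule_strength(fuzzy_rule(c(a = "t", b = "t"), "o"), degs)
    s3 <- rule_strength(fuzzy_rule(c(a = "t", b = "t", c = "t"), "o"), degs)
    expect_lte(s3, s2)
  }
})

demo_system <- function(grid_n = 1001L) {
  v <- lingvar("x", 0, 10, uniform_terms(0, 10, c("lo", "mid", "hi")))
  out <- lingvar("y", 0, 10, uniform_terms(0, 10, c("lo", "mid", "hi")))
  mamdani_system("demo", list(v), out,
                 list(fuzzy_rule(c(x = "lo"), "lo"),
                      fuzzy_rule(c(x = "mid"), "mid"),
                      fuzzy_rule(c(x = "hi"), "hi")),
                 grid_n)
}

test_that("aggregation is the pointwise max of truncated consequents (brute-force oracle)", {
  sys <- demo_system(101L)
  strengths <- c(0.4, 0.8, 0)
  env <- aggregate_envelope(sys, strengths)
  # independent pointwise evaluation
  oracle <- vapply(sys$grid, function(y) {
    max(vapply(seq_along(sys$rules), function(i) {
      term <- sys$rules[[i]]$consequent
      mf <- sys$output$terms[[match(term, sys$output$labels)]]
      min(strengths[[i]], mf_degree(mf, y))
    }, numeric(1)))
  }, numeric(1))
  expect_equal(env, oracle)
  expect_equal(aggregate_envelope(sys, c(0, 0, 0)), numeric(length(sys$grid)))
  # a single rule at full strength reproduces its consequent on the grid
  env1 <- aggregate_envelope(sys, c(0, 1, 0))
  expect_equal(env1, mf_degree(sys$output$terms[[2]], sys$grid))
})

test_that("centroid defuzzification matches symmetry and the closed-form oracle", {
  grid <- seq(0, 10, length.out = 10001L)
  sym <- mf_degree(trapmf(3, 4, 6, 7, "s"), grid)
  expect_equal(defuzz_centroid(sym, grid), 5, tolerance = 1e-9)
  rect <- as.numeric(grid >= 2 & grid <= 4)
  expect_equal(defuzz_centroid(rect, grid), 3, tolerance = 1e-3)
  # truncated asymmetric trapezoids against the closed-form area centroid
  for (h in c(0.25, 0.6, 1)) {
    env <- pmin(h, mf_degree(trapmf(1, 2, 3, 7, "t"), grid))
    expect_equal(defuzz_centroid(env, grid),
                 trap_centroid_oracle(1, 2, 3, 7, h), tolerance = 1e-6)
  }
  expect_error(defuzz_centroid(numeric(10001), grid), "no rule fired")
})

test_that("untruncated single-term centroids match the analytic value", {
  for (t in uniform_terms(0, 10, c("a", "b", "c", "d", "e"))) {
    grid <- seq(0, 10, length.out = 10001L)
    expect_equal(defuzz_centroid(mf_degree(t, grid), grid),
                 trap_centroid_oracle(t$a, t$b, t$c, t$d, 1), tolerance = 1e-6)
  }
})

test_that("inference is deterministic, stays in the output universe, and is grid-stable", {
  sys <- demo_system()
  # one rule firing at strength 1 gives that consequent's centroid
  expect_equal(fis_infer(sys, c(x = 5)), 5, tolerance = 1e-9)
  expect_identical(fis_infer(sys, c(x = 3.3)), fis_infer(sys, c(x = 3.3)))
  for (x in seq(0, 10, length.out = 41)) {
    y <- fis_infer(sys, c(x = x))
    expect_gte(y, 0); expect_lte(y, 10)
  }
  sys2 <- demo_system(2001L)
  for (x in c(0.7, 2.9, 5.5, 8.1)) {
    expect_lt(abs(fis_infer(sys, c(x = x)) - fis_infer(sys2, c(x = x))), 0.01)
  }
  expect_error(fis_infer(sys, c(z = 1)), "missing input")
})

test_that("system construction rejects rules referencing unknown variables or terms", {
  v <- lingvar("x", 0, 10, uniform_terms(0, 10, c("lo", "hi")))
  out <- lingvar("y", 0, 10, uniform_terms(0, 10, c("lo", "hi")))
  expect_error(
    mamdani_system("s", list(v), out, list(fuzzy_rule(c(q = "lo"), "lo"))),
    "unknown input variable 'q'")
  expect_error(
    mamdani_system("s", list(v), out, list(fuzzy_rule(c(x = "huge"), "lo"))),
    "no term 'huge'")
  expect_error(
    mamdani_system("s", list(v), out, list(fuzzy_rule(c(x = "lo"), "huge"))),
    "no term 'huge'")
})
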