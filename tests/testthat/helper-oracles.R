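# Closed-form centroid of a trapezoid (a, b, c, d) truncated at height h:
# the independent oracle for centroid defuzzification. The truncated shape
# rises linearly from a to y1 = a + h (b - a), is flat at h until
# y2 = d - h (d - c), then falls linearly to d.
trap_centroid_oracle <- function(a, b, c, d, h = 1) {
  stopifnot(a <= b, b <= c, c <= d, h > 0, h <= 1)
  y1 <- a + h * (b - a)
  y2 <- d - h * (d - c)
  # moments of each piece: int mu dy and int y mu dy
  up_area <- if (b > a) (y1 - a) * h / 2 else 0
  up_mom <- if (b > a) ((y1^3 - a^3) / 3 - a * (y1^2 - a^2) / 2) / (b - a) else 0
  mid_area <- h * (y2 - y1)
  mid_mom <- h * (y2^2 - y1^2) / 2
  dn_area <- if (d > c) (d - y2) * h / 2 else 0
  dn_mom <- if (d > c) (d * (d^2 - y2^2) / 2 - (d^3 - y2^3) / 3) / (d - c) else 0
  (up_mom + mid_mom + dn_mom) / (up_area + mid_area + dn_area)
}

# Small complete interview record (encoded scales), overridable per item.
interview_record <- function(...) {
  rec <- list(hours_of_sleep = 7, minutes_to_sleep = 20,
              prolonged_awakenings = 0, unrefreshing_sleep = 0,
              daytime_tiredness = 0, morning_dullness = 0,
              unjustified_multiple_awakenings = 0, nocturia = 0,
              breathless_awakenings = 0, reported_apneas = 0,
              snorer = 0, high_intensity_snorer = 0, snore_awakenings = 0)
  utils::modifyList(rec, list(...))
}

# One complete objective record, overridable.
objective_record <- function(...) {
  flags <- as.list(stats::setNames(
    rep(0L, 18),
    c(objective_fields()$comorbidities, objective_fields()$treatments)))
  rec <- c(list(sex = "Male", age = 50, weight = 90, height = 175,
                neck_circumference = 41, smoker = "no",
                cigarettes_per_day = 0, years_smoking = 0,
                drinking = "no", grams_alcohol = 0), flags)
  tibble::as_tibble(utils::modifyList(rec, list(...)))
}

# Cached small synthetic cohort shared across tests (fast fits).
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_cohort(cohort_spec(n = 600), seed = 11)
    cache
  }
})
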