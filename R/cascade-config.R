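#' @keywords internal
risk_term_labels <- function() c("Very_low", "Low", "Medium", "High", "Very_high")

#' @keywords internal
risk_variable <- function(name) {
  lingvar(name, 0, 10, uniform_terms(0, 10, risk_term_labels()))
}

# Output-side risk variable: five congruent symmetric trapezoids centred at
# 0, 2.5, 5, 7.5, 10 on an extended defuzzification universe. Congruence
# keeps the centroid of any equal-strength union of adjacent terms at the
# midpoint of their centres regardless of the truncation level, which is
# what makes the inferred risk surfaces monotone; the edge terms' centroids
# sit exactly at 0 and 10, so inferred risks span the nominal 0-10 scale.
risk_output <- function(name) {
  terms <- lapply(seq_along(risk_term_labels()), function(i) {
    ctr <- 2.5 * (i - 1)
    trapmf(ctr - 1.875, ctr - 0.625, ctr + 0.625, ctr + 1.875,
           risk_term_labels()[[i]])
  })
  lingvar(name, -1.875, 11.875, terms, check_coverage = FALSE)
}

# Generate a complete, monotone conjunctive rule base over the full input box.
#
# Each input term carries a severity in [0, 1] (direction encoded by the
# severity vector: e.g. short sleep is the severe end of hours_of_sleep).
# For every cell of the term product, the consequent index is the weighted
# mean severity mapped onto the output term scale. Cells falling exactly
# halfway between two output terms emit BOTH rules (a bifurcated pair with
# identical antecedents), so the ambiguity is resolved by max-aggregation and
# the centroid lands between the two terms.
monotone_rules <- function(inputs, severities, weights, out_labels) {
  stopifnot(identical(names(severities), names(inputs)),
            identical(names(weights), names(inputs)))
  k_out <- length(out_labels)
  idx <- expand.grid(lapply(inputs, function(v) seq_along(v$labels)),
                     KEEP.OUT.ATTRS = FALSE)
  w <- unlist(weights)
  rules <- list()
  for (r in seq_len(nrow(idx))) {
    sev <- vapply(names(inputs), function(v) severities[[v]][[idx[[v]][[r]]]],
                  numeric(1))
    ants <- vapply(names(inputs), function(v) inputs[[v]]$labels[[idx[[v]][[r]]]],
                   character(1))
    v_out <- (k_out - 1) * sum(w * sev) / sum(w)
    lo_j <- floor(v_out + 0.5 - 1e-8)
    hi_j <- floor(v_out + 0.5 + 1e-8)
    for (j in unique(pmin(k_out - 1, pmax(0, c(lo_j, hi_j))))) {
      rules[[length(rules) + 1L]] <- fuzzy_rule(ants, out_labels[[j + 1L]])
    }
  }
  rules
}

# Append extra rules, dropping exact duplicates (same antecedents, same
# consequent); duplicated antecedents with different consequents are kept.
append_rules <- function(rules, extra) {
  key <- function(r) paste(paste(names(r$antecedents), r$antecedents,
                                 sep = "=", collapse = "&"),
                           r$consequent, sep = "->")
  seen <- vapply(rules, key, character(1))
  for (r in extra) {
    if (!key(r) %in% seen) {
      rules[[length(rules) + 1L]] <- r
      seen <- c(seen, key(r))
    }
  }
  rules
}

#' Default expert-system cascade for the sleep interview
#'
#' Builds the shipped three-level cascade of seven Mamdani systems that maps
#' the 13 sleep-interview items to the Symbolic Risk:
#'
#' * Level 1: `sleep_time` (hours of sleep, minutes to fall asleep, prolonged
#'   awakenings -> R1.a), `unrefreshing_sleep` (unrefreshing sleep, daytime
#'   tiredness, morning dullness -> R1.b), `complicating_factors` (unjustified
#'   multiple awakenings, nocturia, breathless awakenings, reported apneas ->
#'   R2.a), `snores` (snorer, high-intensity snorer, snore-related awakenings
#'   -> R2.b).
#' * Level 2: (R1.a, R1.b) -> R1 and (R2.a, R2.b) -> R2.
#' * Level 3: (R1, R2) -> preliminary Symbolic Risk on 0-10.
#'
#' Interview items use 3-term partitions and risk variables 5-term partitions
#' (Very_low ... Very_high), all symmetric normal convex trapezoids with ~50%
#' overlap ([uniform_terms()]). On the output side the five risk terms are
#' congruent trapezoids centred at 0, 2.5, 5, 7.5 and 10 on an extended
#' defuzzification universe, so the centroid of an equal-strength union of
#' terms sits exactly at the mean of their centres and inferred risks span
#' the full 0-10 scale. Rule bases are generated from a monotone
#' severity map covering the full input box, with the clinically established
#' example rules (including the single-antecedent reported-apneas and
#' non-snorer rules and the bifurcated sleep-time pair) added verbatim.
#' Severity directions: risk decreases with hours of sleep and increases with
#' every other item; reported apneas and awakenings carry extra weight.
#'
#' @param grid_n Defuzzification grid resolution per system (default 1001).
#' @return A named list of seven [mamdani_system()] objects with class
#'   `cascade_config`, keyed `sleep_time`, `unrefreshing_sleep`,
#'   `complicating_factors`, `snores`, `level2_R1`, `level2_R2`, `level3`.
#' @examples
#' cfg <- default_cascade()
#' names(cfg)
#' @export
default_cascade <- function(grid_n = 1001L) {
  rl <- risk_term_labels()
  asc3 <- c(0, 0.5, 1)

  ## --- Level 1 -------------------------------------------------------------
  st_in <- list(
    hours_of_sleep = lingvar("hours_of_sleep", 0, 14,
                             uniform_terms(0, 14, c("Few", "Normal", "Many"))),
    minutes_to_sleep = lingvar("minutes_to_sleep", 0, 240,
                               uniform_terms(0, 240, c("Few", "Normal", "Many"))),
    prolonged_awakenings = lingvar("prolonged_awakenings", 0, 10,
                                   uniform_terms(0, 10, c("Never", "Sometimes", "Often")))
  )
  st_rules <- monotone_rules(
    st_in,
    severities = list(hours_of_sleep = rev(asc3),  # short sleep is severe
                      minutes_to_sleep = asc3,
                      prolonged_awakenings = asc3),
    weights = list(hours_of_sleep = 1, minutes_to_sleep = 1,
                   prolonged_awakenings = 2),
    out_labels = rl
  )
  st_rules <- append_rules(st_rules, list(
    fuzzy_rule(c(hours_of_sleep = "Few", minutes_to_sleep = "Few",
                 prolonged_awakenings = "Never"), "Low"),
    fuzzy_rule(c(hours_of_sleep = "Few", minutes_to_sleep = "Few",
                 prolonged_awakenings = "Never"), "Medium")
  ))
  sleep_time <- mamdani_system("sleep_time", st_in, risk_output("r1a"),
                               st_rules, grid_n)

  us_in <- list(
    unrefreshing_sleep = lingvar("unrefreshing_sleep", 0, 10,
                                 uniform_terms(0, 10, c("Nothing", "Few", "Much"))),
    daytime_tiredness = lingvar("daytime_tiredness", 0, 10,
                                uniform_terms(0, 10, c("Nothing", "Few", "Much"))),
    morning_dullness = lingvar("morning_dullness", 0, 10,
                               uniform_terms(0, 10, c("Nothing", "Few", "Much")))
  )
  us_rules <- monotone_rules(
    us_in,
    severities = list(unrefreshing_sleep = asc3, daytime_tiredness = asc3,
                      morning_dullness = asc3),
    weights = list(unrefreshing_sleep = 1, daytime_tiredness = 1,
                   morning_dullness = 1),
    out_labels = rl
  )
  us_rules <- append_rules(us_rules, list(
    fuzzy_rule(c(unrefreshing_sleep = "Nothing", daytime_tiredness = "Nothing",
                 morning_dullness = "Nothing"), "Very_low"),
    fuzzy_rule(c(unrefreshing_sleep = "Nothing", daytime_tiredness = "Nothing",
                 morning_dullness = "Few"), "Very_low")
  ))
  unrefreshing <- mamdani_system("unrefreshing_sleep", us_in,
                                 risk_output("r1b"), us_rules, grid_n)

  cf_in <- list(
    unjustified_multiple_awakenings =
      lingvar("unjustified_multiple_awakenings", 0, 1,
              uniform_terms(0, 1, c("No", "Yes"))),
    nocturia = lingvar("nocturia", 0, 10,
                       uniform_terms(0, 10, c("Never", "Sometimes", "Always"))),
    breathless_awakenings = lingvar("breathless_awakenings", 0, 10,
                                    uniform_terms(0, 10, c("Never", "Sometimes", "Always"))),
    reported_apneas = lingvar("reported_apneas", 0, 10,
                              uniform_terms(0, 10, c("Never", "Sometimes", "Always")))
  )
  cf_rules <- monotone_rules(
    cf_in,
    severities = list(unjustified_multiple_awakenings = c(0, 1),
                      nocturia = asc3, breathless_awakenings = asc3,
                      reported_apneas = asc3),
    weights = list(unjustified_multiple_awakenings = 1, nocturia = 1.5,
                   breathless_awakenings = 1.5, reported_apneas = 3),
    out_labels = rl
  )
  cf_rules <- append_rules(cf_rules, list(
    fuzzy_rule(c(reported_apneas = "Always"), "Very_high"),
    fuzzy_rule(c(unjustified_multiple_awakenings = "No", nocturia = "Never",
                 breathless_awakenings = "Never", reported_apneas = "Never"),
               "Very_low")
  ))
  complicating <- mamdani_system("complicating_factors", cf_in,
                                 risk_output("r2a"), cf_rules, grid_n)

  sn_in <- list(
    snorer = lingvar("snorer", 0, 2,
                     uniform_terms(0, 2, c("No", "In_dorsal_position_only", "Yes"))),
    high_intensity_snorer = lingvar("high_intensity_snorer", 0, 1,
                                    uniform_terms(0, 1, c("No", "Yes"))),
    snore_awakenings = lingvar("snore_awakenings", 0, 10,
                               uniform_terms(0, 10, c("Never", "Sometimes", "Often")))
  )
  sn_rules <- monotone_rules(
    sn_in,
    severities = list(snorer = asc3, high_intensity_snorer = c(0, 1),
                      snore_awakenings = asc3),
    weights = list(snorer = 1, high_intensity_snorer = 1, snore_awakenings = 1),
    out_labels = rl
  )
  sn_rules <- append_rules(sn_rules, list(
    fuzzy_rule(c(snorer = "No"), "Very_low"),
    fuzzy_rule(c(snorer = "In_dorsal_position_only",
                 high_intensity_snorer = "No",
                 snore_awakenings = "Never"), "Very_low")
  ))
  snores <- mamdani_system("snores", sn_in, risk_output("r2b"),
                           sn_rules, grid_n)

  ## --- Levels 2 and 3 ------------------------------------------------------
  sev5 <- c(0, 0.25, 0.5, 0.75, 1)
  level2 <- function(name, in1, in2, out) {
    ins <- stats::setNames(list(risk_variable(in1), risk_variable(in2)),
                           c(in1, in2))
    rules <- monotone_rules(
      ins,
      severities = stats::setNames(list(sev5, sev5), c(in1, in2)),
      weights = stats::setNames(list(1, 1), c(in1, in2)),
      out_labels = rl
    )
    rules <- append_rules(rules, list(
      fuzzy_rule(stats::setNames(c("Very_low", "Very_low"), c(in1, in2)), "Very_low"),
      fuzzy_rule(stats::setNames(c("Very_low", "Low"), c(in1, in2)), "Very_low"),
      fuzzy_rule(stats::setNames(c("Very_low", "Low"), c(in1, in2)), "Low")
    ))
    mamdani_system(name, ins, risk_output(out), rules, grid_n)
  }

  cfg <- list(
    sleep_time = sleep_time,
    unrefreshing_sleep = unrefreshing,
    complicating_factors = complicating,
    snores = snores,
    level2_R1 = level2("level2_R1", "r1a", "r1b", "r1"),
    level2_R2 = level2("level2_R2", "r2a", "r2b", "r2"),
    level3 = level2("level3", "r1", "r2", "preliminary")
  )
  structure(cfg, class = "cascade_config")
}

#' @export
print.cascade_config <- function(x, ...) {
  cat("<cascade_config> three-level Mamdani cascade\n")
  for (s in x) {
    cat(sprintf("  %-22s %d rules: (%s) -> %s\n", s$name, length(s$rules),
                paste(names(s$inputs), collapse = ", "), s$output$name))
  }
  invisible(x)
}
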