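#' Specification of a synthetic sleep-unit cohort
#'
#' All parameters of the generative model in one declared block. The defaults
#' emulate the size and class balance of a referred sleep-unit population
#' (n = 4400 with 61.2% of patients at AHI >= 15) and plant clinically
#' sensible effects: AHI follows a log-linear model on BMI, neck
#' circumference, age, sex and selected comorbidities, and symptom answers
#' are sampled with probabilities increasing in AHI. The marginals are
#' declared assumptions, not estimates from any real cohort.
#'
#' @param n Number of patients.
#' @param prevalence Target fraction with AHI >= `ahi_threshold`; the model
#'   intercept is calibrated to it by bounded root-finding.
#' @param ahi_threshold AHI threshold defining the positive class.
#' @param coef Named coefficients of the log-linear AHI model (per-unit
#'   effects on `log(AHI + 1)` of centred BMI, neck, age and of male sex,
#'   hypertension, diabetes).
#' @param sigma Residual SD of `log(AHI + 1)`.
#' @param symptom_slopes Named per-item slopes of the symptom latent on the
#'   log-AHI scale (zero decouples an item from disease severity).
#' @param p_male Probability of male sex.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 4400L,
                        prevalence = 0.612,
                        ahi_threshold = 15,
                        coef = c(bmi = 0.085, neck = 0.09, age = 0.016,
                                 male = 0.45, hypertension = 0.30,
                                 diabetes = 0.25),
                        sigma = 0.75,
                        symptom_slopes = c(
                          prolonged_awakenings = 0.45,
                          unrefreshing_sleep = 0.50,
                          daytime_tiredness = 0.55,
                          morning_dullness = 0.45,
                          unjustified_multiple_awakenings = 0.40,
                          nocturia = 0.60,
                          breathless_awakenings = 0.80,
                          reported_apneas = 1.40,
                          snorer = 1.20,
                          high_intensity_snorer = 1.10,
                          snore_awakenings = 0.90,
                          hours_of_sleep = -0.20,
                          minutes_to_sleep = -0.25),
                        p_male = 0.70) {
  stopifnot(n >= 1, prevalence > 0, prevalence < 1, sigma > 0)
  structure(list(n = as.integer(n), prevalence = prevalence,
                 ahi_threshold = ahi_threshold, coef = coef, sigma = sigma,
                 symptom_slopes = symptom_slopes, p_male = p_male),
            class = "cohort_spec")
}

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  pmin(hi, pmax(lo, stats::rnorm(n, mean, sd)))
}

# linear predictor of log(AHI + 1), excluding the intercept
cohort_eta <- function(spec, covars) {
  b <- spec$coef
  b[["bmi"]] * (covars$bmi - 29) +
    b[["neck"]] * (covars$neck_circumference - 37) +
    b[["age"]] * (covars$age - 55) +
    b[["male"]] * (covars$sex == "Male") +
    b[["hypertension"]] * covars$hypertension +
    b[["diabetes"]] * covars$diabetes
}

#' Generate a synthetic cohort
#'
#' Draws `spec$n` complete patient records: objective fields from plausible
#' clinical marginals (age truncated-normal, BMI lognormal, neck
#' circumference correlated with BMI and sex, habits, comorbidity and
#' treatment flags), an AHI from the log-linear severity model (intercept
#' calibrated by root-finding so the expected prevalence of AHI >= threshold
#' matches `spec$prevalence`), and interview answers whose category
#' probabilities increase with AHI through per-item ordered-logit couplings.
#' Treatment flags are drawn independently of AHI, so they act as pure-noise
#' features for the classifier. The output is byte-identical for identical
#' `(spec, seed)`.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed (mandatory: every persisted cohort must be
#'   reproducible).
#' @return A tibble with the [objective_fields()] columns, the numeric
#'   [interview_items()] columns, and `ahi`; the calibrated model intercept
#'   is attached as attribute `"ahi_intercept"`.
#' @examples
#' cohort <- generate_cohort(cohort_spec(n = 200), seed = 7)
#' mean(cohort$ahi >= 15)
#' @export
generate_cohort <- function(spec = cohort_spec(), seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (missing(seed)) stop("a seed is mandatory for cohort generation", call. = FALSE)
  with_local_seed(seed, {
    n <- spec$n
    sex <- ifelse(stats::runif(n) < spec$p_male, "Male", "Female")
    age <- rtrunc_norm(n, 55, 13, 18, 95)
    bmi <- pmin(60, pmax(16, stats::rlnorm(n, log(29), 0.18)))
    height <- ifelse(sex == "Male", stats::rnorm(n, 175, 7), stats::rnorm(n, 162, 6.5))
    height <- pmin(210, pmax(140, height))
    weight <- round(bmi * (height / 100)^2, 1)
    height <- round(height)
    bmi <- derive_bmi(weight, height)
    neck <- 34 + 0.45 * (bmi - 29) + 3.5 * (sex == "Male") + stats::rnorm(n, 0, 1.5)
    neck <- round(pmin(60, pmax(27, neck)), 1)

    smoker <- sample(c("no", "yes", "former"), n, replace = TRUE,
                     prob = c(0.5, 0.25, 0.25))
    cpd <- ifelse(smoker == "no", 0,
                  pmin(60, pmax(1, round(stats::rlnorm(n, log(14), 0.5)))))
    yrs <- ifelse(smoker == "no", 0,
                  pmax(1, pmin(age - 16, round(stats::runif(n, 3, 40)))))
    drinking <- sample(c("no", "occasional", "daily"), n, replace = TRUE,
                       prob = c(0.5, 0.35, 0.15))
    grams <- ifelse(drinking == "no", 0,
                    round(pmin(300, stats::rlnorm(n, log(ifelse(drinking == "daily", 30, 12)), 0.6)), 1))

    z_age <- (age - 55) / 13
    z_bmi <- (bmi - 29) / 5
    flag <- function(base_logit, slope_age = 0, slope_bmi = 0) {
      as.integer(stats::runif(n) < stats::plogis(base_logit + slope_age * z_age + slope_bmi * z_bmi))
    }
    covars <- tibble::tibble(
      sex = sex, age = age, weight = weight, height = height, bmi = bmi,
      neck_circumference = neck, smoker = smoker, cigarettes_per_day = cpd,
      years_smoking = yrs, drinking = drinking, grams_alcohol = grams,
      hypertension = flag(-0.7, 0.8, 0.5),
      resistant_hypertension = flag(-3.0, 0.6, 0.4),
      acva = flag(-3.5, 0.7), acva_past_year = flag(-4.2, 0.7),
      diabetes = flag(-1.7, 0.6, 0.5),
      ischemic_heart_disease = flag(-2.6, 0.8),
      copd = flag(-2.7, 0.6), home_oxygen = flag(-3.9, 0.5),
      rhinitis = flag(-2.0, -0.3), depression = flag(-1.8, 0.1),
      atrial_fibrillation = flag(-2.9, 0.9), heart_failure = flag(-3.3, 0.9),
      benzodiazepines = flag(-2.2), antidepressants = flag(-2.0),
      neuroleptics = flag(-3.5), antihistamines = flag(-3.0),
      morphics = flag(-3.9), hypnotics = flag(-2.4)
    )

    eta <- cohort_eta(spec, covars)
    log_thr <- log(spec$ahi_threshold + 1)
    # expected prevalence as a function of the intercept; monotone increasing
    prev_fun <- function(b0) {
      mean(1 - stats::pnorm((log_thr - (b0 + eta)) / spec$sigma)) - spec$prevalence
    }
    root <- tryCatch(
      stats::uniroot(prev_fun, interval = log_thr + c(-20, 20), tol = 1e-10),
      error = function(e) stop("cannot calibrate intercept to prevalence ",
                               spec$prevalence, ": ", conditionMessage(e),
                               call. = FALSE))
    b0 <- root$root
    ahi <- pmax(0, exp(b0 + eta + stats::rnorm(n, 0, spec$sigma)) - 1)
    ahi <- round(ahi, 2)

    # symptom coupling on the standardized log-severity scale
    z <- (log(ahi + 1) - log_thr) / spec$sigma
    sl <- spec$symptom_slopes
    latent <- function(item) sl[[item]] * z + stats::rlogis(n)
    scale3 <- function(item, c_lo, c_hi) {
      l <- latent(item)
      ifelse(l > c_hi, 10, ifelse(l > c_lo, 5, 0))
    }
    binary <- function(item, c_cut) as.integer(latent(item) > c_cut)

    interview <- tibble::tibble(
      hours_of_sleep = round(rtrunc_norm(n, 6.9 + 0.35 * sl[["hours_of_sleep"]] * z, 1.1, 1, 14), 1),
      minutes_to_sleep = round(pmin(240, pmax(0, stats::rlnorm(n, log(25) + 0.3 * sl[["minutes_to_sleep"]] * z, 0.6)))),
      prolonged_awakenings = scale3("prolonged_awakenings", -0.2, 1.4),
      unrefreshing_sleep = scale3("unrefreshing_sleep", -0.1, 1.3),
      daytime_tiredness = scale3("daytime_tiredness", -0.3, 1.2),
      morning_dullness = scale3("morning_dullness", 0.0, 1.5),
      unjustified_multiple_awakenings = binary("unjustified_multiple_awakenings", 0.8),
      nocturia = scale3("nocturia", 0.0, 1.4),
      breathless_awakenings = scale3("breathless_awakenings", 0.8, 2.0),
      reported_apneas = scale3("reported_apneas", 0.6, 1.8),
      snorer = {
        l <- latent("snorer")
        ifelse(l > 0.8, 2, ifelse(l > -0.6, 1, 0))
      },
      high_intensity_snorer = binary("high_intensity_snorer", 0.9),
      snore_awakenings = scale3("snore_awakenings", 0.5, 1.8)
    )

    out <- dplyr::bind_cols(covars, interview)
    out$ahi <- ahi
    attr(out, "ahi_intercept") <- b0
    attr(out, "spec") <- spec
    out
  })
}

#' Generating-model probability of OSA
#'
#' Evaluates, for each record, the true probability that AHI >= threshold
#' under the log-linear generative model that produced the cohort -- the
#' oracle against which the Statistical Risk can be calibrated.
#'
#' @param data A cohort generated by [generate_cohort()] (or any table with
#'   the model covariates and a `bmi` column or weight/height).
#' @param spec The [cohort_spec()] used for generation; defaults to the one
#'   attached to `data`.
#' @param intercept Model intercept; defaults to the calibrated value
#'   attached to `data`.
#' @return The input tibble with a `.true_prob` column appended.
#' @export
ground_truth <- function(data, spec = attr(data, "spec"),
                         intercept = attr(data, "ahi_intercept")) {
  if (is.null(spec) || is.null(intercept)) {
    stop("spec/intercept not supplied and not attached to the data; ",
         "was this cohort generated by generate_cohort()?", call. = FALSE)
  }
  stopifnot(inherits(spec, "cohort_spec"))
  covars <- tibble::as_tibble(data)
  if (!"bmi" %in% names(covars)) {
    covars$bmi <- derive_bmi(covars$weight, covars$height)
  }
  eta <- cohort_eta(spec, covars)
  log_thr <- log(spec$ahi_threshold + 1)
  dplyr::mutate(tibble::as_tibble(data),
                .true_prob = 1 - stats::pnorm((log_thr - (intercept + eta)) / spec$sigma))
}
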