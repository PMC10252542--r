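#' Objective-data dictionary
#'
#' Column names for the objective (health-record) side of a patient record:
#' anthropometry, habits, 12 diagnosed-condition flags and 6
#' prescribed-treatment flags. Weight/height and the raw smoking quantities
#' are collected but not fed to the classifier; they are replaced by the
#' derived BMI and pack-year index.
#'
#' @return A list with elements `numeric`, `categorical`, `comorbidities`,
#'   `treatments` (character vectors of column names).
#' @export
objective_fields <- function() {
  list(
    numeric = c("age", "weight", "height", "neck_circumference",
                "cigarettes_per_day", "years_smoking", "grams_alcohol"),
    categorical = c("sex", "smoker", "drinking"),
    comorbidities = c("hypertension", "resistant_hypertension", "acva",
                      "acva_past_year", "diabetes", "ischemic_heart_disease",
                      "copd", "home_oxygen", "rhinitis", "depression",
                      "atrial_fibrillation", "heart_failure"),
    treatments = c("benzodiazepines", "antidepressants", "neuroleptics",
                   "antihistamines", "morphics", "hypnotics")
  )
}

#' Body mass index from weight and height
#'
#' @param weight Weight in kg.
#' @param height Height in cm.
#' @return BMI in kg/m^2. Vectorised.
#' @examples
#' derive_bmi(85, 186) # 24.57
#' @export
derive_bmi <- function(weight, height) {
  stopifnot(is.numeric(weight), is.numeric(height))
  if (any(height <= 0, na.rm = TRUE)) {
    stop("height must be positive to derive BMI", call. = FALSE)
  }
  if (any(weight < 0, na.rm = TRUE)) stop("weight must be non-negative", call. = FALSE)
  weight / (height / 100)^2
}

#' Pack-year smoking exposure
#'
#' Standard clinical definition: (cigarettes per day x years smoked) / 20
#' cigarettes per pack. Never-smokers may omit both quantities (NA), which
#' counts as zero exposure.
#'
#' @param cigarettes_per_day,years_smoking Non-negative numerics (NA allowed,
#'   treated as 0 for never-smokers).
#' @return Pack-years. Vectorised.
#' @examples
#' derive_pack_years(20, 10) # 10
#' @export
derive_pack_years <- function(cigarettes_per_day, years_smoking) {
  cpd <- ifelse(is.na(cigarettes_per_day), 0, cigarettes_per_day)
  yrs <- ifelse(is.na(years_smoking), 0, years_smoking)
  if (any(cpd < 0) || any(yrs < 0)) {
    stop("smoking quantities must be non-negative", call. = FALSE)
  }
  cpd * yrs / 20
}

#' Min-max normalization
#'
#' Scales `x` to `[0, 1]` as `(x - min) / (max - min)` against fixed,
#' clinician-set bounds. Values beyond the bounds are clamped with a warning
#' rather than extrapolated.
#'
#' @param x Numeric vector.
#' @param bounds Length-2 numeric `c(min, max)`, `max > min`.
#' @param name Variable name for messages.
#' @return Values in `[0, 1]`.
#' @export
minmax_normalize <- function(x, bounds, name = "x") {
  stopifnot(is.numeric(x), length(bounds) == 2L)
  if (bounds[[2]] <= bounds[[1]]) {
    stop("invalid normalization bounds for '", name, "': max <= min",
         call. = FALSE)
  }
  out <- (x - bounds[[1]]) / (bounds[[2]] - bounds[[1]])
  if (any(out < 0 | out > 1, na.rm = TRUE)) {
    warning("clamping '", name, "' values outside bounds [",
            bounds[[1]], ", ", bounds[[2]], "]", call. = FALSE)
    out <- pmin(1, pmax(0, out))
  }
  out
}

#' Default encoding schema for the objective features
#'
#' Normalization bounds are plausible clinical envelopes, declared here so
#' they can be reviewed and overridden rather than silently inferred from
#' data: age 18-100 y, BMI 10-80 kg/m^2, neck circumference 25-60 cm,
#' pack-years 0-150, alcohol 0-300 g/day. Categorical variables carry an
#' ordered category list whose first entry is the reference category (encoded
#' as all-zero dummies); every comorbidity/treatment flag is a binary
#' categorical.
#'
#' @return An object of class `encoding_schema`: list with `numeric` (named
#'   list of `c(min, max)`) and `categorical` (named list of category level
#'   vectors, reference first).
#' @export
default_encoding_schema <- function() {
  fields <- objective_fields()
  cat <- c(
    list(sex = c("Female", "Male"),
         smoker = c("no", "yes", "former"),
         drinking = c("no", "daily", "occasional")),
    stats::setNames(rep(list(c("0", "1")),
                        length(c(fields$comorbidities, fields$treatments))),
                    c(fields$comorbidities, fields$treatments))
  )
  structure(
    list(numeric = list(age = c(18, 100), bmi = c(10, 80),
                        neck_circumference = c(25, 60),
                        pack_years = c(0, 150), grams_alcohol = c(0, 300)),
         categorical = cat),
    class = "encoding_schema"
  )
}

# canonicalise free-text categorical answers onto schema levels
canon_category <- function(x, var) {
  lab <- tolower(trimws(as.character(x)))
  syn <- switch(var,
    sex = c("male" = "Male", "m" = "Male", "female" = "Female", "f" = "Female"),
    smoker = c("no" = "no", "never" = "no", "yes" = "yes", "smoker" = "yes",
               "no longer" = "former", "former" = "former",
               "ex-smoker" = "former", "ex smoker" = "former"),
    drinking = c("no" = "no", "never" = "no", "daily" = "daily",
                 "regularly" = "daily", "occasionally" = "occasional",
                 "occasional" = "occasional"),
    c("0" = "0", "no" = "0", "false" = "0", "1" = "1", "yes" = "1",
      "true" = "1")
  )
  out <- unname(syn[lab])
  bad <- is.na(out) & !is.na(x)
  if (any(bad)) {
    stop("variable '", var, "': unseen category ",
         paste(sQuote(unique(x[bad])), collapse = ", "), call. = FALSE)
  }
  out
}

#' Encode objective records into the model feature space
#'
#' Derives BMI and pack-years (replacing their raw source fields, which are
#' not fed to the learner), min-max normalizes the numeric features against
#' the schema bounds, and dummy-encodes each c-category variable into c-1
#' indicator columns (reference category = all zeros). Missing habit
#' quantities for never-smokers/non-drinkers default to 0; any other missing
#' field is an error.
#'
#' @param data Data frame with the [objective_fields()] columns (flags may be
#'   0/1, logical or yes/no).
#' @param schema An `encoding_schema`, default [default_encoding_schema()].
#' @return A tibble of numeric features in a fixed column order, with
#'   attributes `schema` and `schema_hash`.
#' @export
encode_cohort <- function(data, schema = default_encoding_schema()) {
  stopifnot(inherits(schema, "encoding_schema"))
  data <- tibble::as_tibble(data)
  fields <- objective_fields()
  need <- c("sex", "age", "weight", "height", "neck_circumference", "smoker",
            "drinking", fields$comorbidities, fields$treatments)
  missing <- setdiff(need, names(data))
  if (length(missing)) {
    stop("objective column(s) missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }

  smoker <- canon_category(data$smoker, "smoker")
  cpd <- if ("cigarettes_per_day" %in% names(data)) data$cigarettes_per_day else NA_real_
  yrs <- if ("years_smoking" %in% names(data)) data$years_smoking else NA_real_
  cpd <- ifelse(smoker == "no" & is.na(cpd), 0, cpd)
  yrs <- ifelse(smoker == "no" & is.na(yrs), 0, yrs)
  drinking <- canon_category(data$drinking, "drinking")
  grams <- if ("grams_alcohol" %in% names(data)) data$grams_alcohol else NA_real_
  grams <- ifelse(drinking == "no" & is.na(grams), 0, grams)

  raw_num <- tibble::tibble(
    age = as.numeric(data$age),
    bmi = derive_bmi(as.numeric(data$weight), as.numeric(data$height)),
    neck_circumference = as.numeric(data$neck_circumference),
    pack_years = derive_pack_years(as.numeric(cpd), as.numeric(yrs)),
    grams_alcohol = as.numeric(grams)
  )
  for (v in names(raw_num)) {
    if (anyNA(raw_num[[v]])) {
      stop("numeric variable '", v, "' has missing values; records must be complete",
           call. = FALSE)
    }
  }
  num <- purrr::imap_dfc(raw_num, function(x, v) {
    minmax_normalize(x, schema$numeric[[v]], name = v)
  })

  cats <- tibble::tibble(sex = canon_category(data$sex, "sex"),
                         smoker = smoker, drinking = drinking)
  for (f in c(fields$comorbidities, fields$treatments)) {
    cats[[f]] <- canon_category(data[[f]], f)
  }
  dummies <- purrr::imap(schema$categorical, function(levels, v) {
    x <- cats[[v]]
    bad <- !x %in% levels
    if (any(bad)) {
      stop("variable '", v, "': unseen category ",
           paste(sQuote(unique(x[bad])), collapse = ", "), call. = FALSE)
    }
    cols <- lapply(levels[-1], function(lev) as.numeric(x == lev))
    names(cols) <- paste(v, levels[-1], sep = "_")
    tibble::as_tibble(cols)
  })
  out <- dplyr::bind_cols(num, dummies)
  attr(out, "schema") <- schema
  attr(out, "schema_hash") <- rlang::hash(schema)
  out
}

#' Invert dummy encoding back to categories
#'
#' Given an encoded feature table and the schema that produced it, recovers
#' the categorical columns (the round-trip counterpart of [encode_cohort()]).
#'
#' @param features Encoded feature tibble.
#' @param schema The `encoding_schema` used for encoding.
#' @return Tibble of categorical columns.
#' @export
decode_dummies <- function(features, schema = default_encoding_schema()) {
  purrr::imap_dfc(schema$categorical, function(levels, v) {
    cols <- paste(v, levels[-1], sep = "_")
    m <- as.matrix(features[, cols, drop = FALSE])
    idx <- apply(m, 1L, function(r) {
      hit <- which(r == 1)
      if (length(hit) == 0L) 1L else hit[[1L]] + 1L
    })
    tibble::tibble(!!v := levels[idx])
  })
}

#' Label patients by apnea-hypopnea index
#'
#' Binary OSA label at a configurable AHI threshold: `OSA` for
#' `ahi >= threshold` (boundary inclusive, separating mild from
#' moderate-severe disease at the default of 15 events/hour), `non-OSA`
#' below.
#'
#' @param ahi Numeric AHI values (events/hour, non-negative).
#' @param threshold Labeling threshold, default 15.
#' @return Factor with levels `non-OSA`, `OSA`.
#' @examples
#' label_by_ahi(c(15, 11.9, 14.999))
#' @export
label_by_ahi <- function(ahi, threshold = 15) {
  stopifnot(is.numeric(ahi))
  if (any(ahi < 0, na.rm = TRUE)) stop("AHI must be non-negative", call. = FALSE)
  factor(ifelse(ahi >= threshold, "OSA", "non-OSA"),
         levels = c("non-OSA", "OSA"))
}
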