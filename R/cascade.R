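#' Sleep-interview data dictionary
#'
#' The 13 interview items feeding the symbolic branch, with their universes
#' and answer scales. Frequency items are answered No / Occasionally / Often
#' and encoded 0 / 5 / 10; yes-no items are encoded 1 / 0; the snorer item
#' distinguishes non-snorers, supine-only snorers and habitual snorers
#' (0 / 1 / 2); hours and minutes are numeric pass-through.
#'
#' @return A tibble with columns `item`, `kind`
#'   (`numeric`/`frequency`/`yesno`/`snorer`), `lo`, `hi`.
#' @export
interview_items <- function() {
  tibble::tribble(
    ~item,                             ~kind,       ~lo, ~hi,
    "hours_of_sleep",                  "numeric",     0,  14,
    "minutes_to_sleep",                "numeric",     0, 240,
    "prolonged_awakenings",            "frequency",   0,  10,
    "unrefreshing_sleep",              "frequency",   0,  10,
    "daytime_tiredness",               "frequency",   0,  10,
    "morning_dullness",                "frequency",   0,  10,
    "unjustified_multiple_awakenings", "yesno",       0,   1,
    "nocturia",                        "frequency",   0,  10,
    "breathless_awakenings",           "frequency",   0,  10,
    "reported_apneas",                 "frequency",   0,  10,
    "snorer",                          "snorer",      0,   2,
    "high_intensity_snorer",           "yesno",       0,   1,
    "snore_awakenings",                "frequency",   0,  10
  )
}

encode_one_item <- function(x, item, kind) {
  if (is.numeric(x)) return(as.numeric(x))
  lab <- tolower(trimws(gsub("[_-]", " ", as.character(x))))
  map <- switch(kind,
    frequency = c("no" = 0, "never" = 0, "nothing" = 0,
                  "occasionally" = 5, "sometimes" = 5, "few" = 5,
                  "often" = 10, "always" = 10, "much" = 10),
    yesno = c("no" = 0, "yes" = 1),
    snorer = c("no" = 0,
               "in supine position only" = 1, "in dorsal position only" = 1,
               "supine only" = 1, "yes" = 2),
    numeric = NULL
  )
  if (is.null(map)) {
    out <- suppressWarnings(as.numeric(lab))
    bad <- is.na(out) & !is.na(x)
  } else {
    out <- unname(map[lab])
    # numbers typed into a categorical field pass through if on-scale
    num <- suppressWarnings(as.numeric(lab))
    out[is.na(out) & !is.na(num)] <- num[is.na(out) & !is.na(num)]
    bad <- is.na(out) & !is.na(x)
  }
  if (any(bad)) {
    stop("item '", item, "': unknown answer label ",
         paste(sQuote(unique(x[bad])), collapse = ", "), call. = FALSE)
  }
  out
}

#' Encode sleep-interview answers to cascade inputs
#'
#' Maps categorical interview answers onto the numeric scales the fuzzy
#' cascade expects: frequency answers No -> 0, Occasionally -> 5, Often -> 10;
#' yes-no answers Yes -> 1, No -> 0; snorer No -> 0, supine-position-only -> 1,
#' Yes -> 2. Numeric answers (hours of sleep, minutes to fall asleep, or
#' already-encoded scales) pass through unchanged. Out-of-range values are
#' rejected with an error naming the item.
#'
#' @param data Data frame with one row per patient and the 13 columns listed
#'   by [interview_items()] (extra columns are kept untouched).
#' @return A tibble of the same shape with interview columns numeric.
#' @examples
#' encode_interview(data.frame(
#'   hours_of_sleep = 7, minutes_to_sleep = 20,
#'   prolonged_awakenings = "Often", unrefreshing_sleep = "No",
#'   daytime_tiredness = "No", morning_dullness = "Occasionally",
#'   unjustified_multiple_awakenings = "No", nocturia = "Often",
#'   breathless_awakenings = "No", reported_apneas = "Often",
#'   snorer = "Yes", high_intensity_snorer = "Yes",
#'   snore_awakenings = "Occasionally"
#' ))
#' @export
encode_interview <- function(data) {
  items <- interview_items()
  missing <- setdiff(items$item, names(data))
  if (length(missing)) {
    stop("interview column(s) missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::as_tibble(data)
  for (i in seq_len(nrow(items))) {
    it <- items$item[[i]]
    v <- encode_one_item(out[[it]], it, items$kind[[i]])
    oob <- !is.na(v) & (v < items$lo[[i]] | v > items$hi[[i]])
    if (any(oob)) {
      stop("item '", it, "': value ", signif(v[oob][1], 6),
           " outside its range [", items$lo[[i]], ", ", items$hi[[i]], "]",
           call. = FALSE)
    }
    out[[it]] <- v
  }
  out
}

#' Evaluate the expert-system cascade for one patient
#'
#' Runs the four level-1 systems, the two level-2 systems on their outputs
#' and the level-3 system, then rescales the preliminary 0-10 output to the
#' 0-100 Symbolic Risk.
#'
#' @param inputs Named list or one-row data frame of encoded interview values
#'   (see [encode_interview()]).
#' @param cascade A cascade configuration, by default [default_cascade()].
#' @return A one-row tibble with columns `r1a`, `r1b`, `r2a`, `r2b`, `r1`,
#'   `r2`, `preliminary` (each on 0-10) and `symbolic_risk` (0-100).
#' @export
eval_cascade <- function(inputs, cascade = default_cascade()) {
  stopifnot(inherits(cascade, "cascade_config"))
  inputs <- as.list(inputs)
  pick <- function(sys) inputs[names(cascade[[sys]]$inputs)]
  # inferred risks live on the nominal 0-10 scale; clamp away any grid-level
  # rounding at the scale ends before the next fuzzification stage
  risk10 <- function(x) min(10, max(0, x))
  r1a <- risk10(fis_infer(cascade$sleep_time, pick("sleep_time")))
  r1b <- risk10(fis_infer(cascade$unrefreshing_sleep, pick("unrefreshing_sleep")))
  r2a <- risk10(fis_infer(cascade$complicating_factors, pick("complicating_factors")))
  r2b <- risk10(fis_infer(cascade$snores, pick("snores")))
  r1 <- risk10(fis_infer(cascade$level2_R1, list(r1a = r1a, r1b = r1b)))
  r2 <- risk10(fis_infer(cascade$level2_R2, list(r2a = r2a, r2b = r2b)))
  prelim <- risk10(fis_infer(cascade$level3, list(r1 = r1, r2 = r2)))
  tibble::tibble(r1a = r1a, r1b = r1b, r2a = r2a, r2b = r2b,
                 r1 = r1, r2 = r2, preliminary = prelim,
                 symbolic_risk = rescale_symbolic(prelim))
}

#' Rescale the preliminary cascade output to a percentage risk
#'
#' The third-level system reasons on a 0-10 universe; the Symbolic Risk is
#' reported on 0-100, so the preliminary value is multiplied by 10.
#'
#' @param preliminary Numeric vector on `[0, 10]`.
#' @return `10 * preliminary`, on `[0, 100]`.
#' @examples
#' rescale_symbolic(6.179) # 61.79
#' @export
rescale_symbolic <- function(preliminary) {
  stopifnot(is.numeric(preliminary))
  if (any(preliminary < 0 | preliminary > 10, na.rm = TRUE)) {
    stop("preliminary symbolic value must lie in [0, 10]", call. = FALSE)
  }
  10 * preliminary
}

#' Symbolic Risk for a cohort
#'
#' Tidy front end to the cascade: takes a data frame with the 13 interview
#' columns (categorical answers are encoded first), evaluates the cascade per
#' row and appends the intermediate risks and the Symbolic Risk.
#'
#' @param data Data frame with the [interview_items()] columns.
#' @param cascade Cascade configuration, default [default_cascade()].
#' @return The input as a tibble with columns `r1a`, `r1b`, `r2a`, `r2b`,
#'   `r1`, `r2`, `preliminary`, `symbolic_risk` appended.
#' @examples
#' case_study_patient() |> symbolic_risk()
#' @export
symbolic_risk <- function(data, cascade = default_cascade()) {
  enc <- encode_interview(data)
  items <- interview_items()$item
  res <- purrr::map(seq_len(nrow(enc)), function(i) {
    eval_cascade(as.list(enc[i, items, drop = FALSE]), cascade)
  })
  dplyr::bind_cols(tibble::as_tibble(data), dplyr::bind_rows(res))
}

#' Validate a cascade configuration
#'
#' Structural and behavioural checks on a cascade: the seven systems are
#' present and wired (R1.a, R1.b) -> R1, (R2.a, R2.b) -> R2, (R1, R2) ->
#' preliminary; all level outputs live on 0-10; and a grid scan over each
#' system's input box (5 points per axis, corners included) verifies that no
#' reachable input leaves an all-zero aggregated envelope ("no rule fired").
#' Rule counts per system are reported.
#'
#' @param cascade A cascade configuration.
#' @param points_per_axis Grid density of the coverage scan.
#' @return A list with `ok` (logical), `report` (tibble: system, inputs,
#'   output, n_rules, coverage_ok) and `issues` (character vector of
#'   structured failure messages, empty when `ok`).
#' @export
validate_cascade <- function(cascade, points_per_axis = 5L) {
  issues <- character()
  expected <- c("sleep_time", "unrefreshing_sleep", "complicating_factors",
                "snores", "level2_R1", "level2_R2", "level3")
  if (!all(expected %in% names(cascade))) {
    issues <- c(issues, paste("missing system(s):",
                              paste(setdiff(expected, names(cascade)),
                                    collapse = ", ")))
    return(list(ok = FALSE, report = tibble::tibble(), issues = issues))
  }
  wiring <- list(level2_R1 = c("r1a", "r1b"), level2_R2 = c("r2a", "r2b"),
                 level3 = c("r1", "r2"))
  for (s in names(wiring)) {
    got <- names(cascade[[s]]$inputs)
    if (!setequal(got, wiring[[s]])) {
      issues <- c(issues, sprintf("system '%s' wired to (%s), expected (%s)",
                                  s, paste(got, collapse = ", "),
                                  paste(wiring[[s]], collapse = ", ")))
    }
  }
  rows <- purrr::map(expected, function(sname) {
    sys <- cascade[[sname]]
    if (sys$output$lo > 0 || sys$output$hi < 10) {
      issues <<- c(issues, sprintf(
        "system '%s': output universe [%g, %g] does not contain the 0-10 risk scale",
        sname, sys$output$lo, sys$output$hi))
    }
    grids <- lapply(sys$inputs, function(v) {
      seq(v$lo, v$hi, length.out = points_per_axis)
    })
    box <- expand.grid(grids, KEEP.OUT.ATTRS = FALSE)
    cover_ok <- TRUE
    for (r in seq_len(nrow(box))) {
      res <- tryCatch(fis_infer(sys, as.list(box[r, , drop = FALSE])),
                      error = function(e) e)
      if (inherits(res, "error")) {
        cover_ok <- FALSE
        issues <<- c(issues, sprintf(
          "system '%s': coverage failure at (%s): %s", sname,
          paste(sprintf("%s=%g", names(box), unlist(box[r, ])), collapse = ", "),
          conditionMessage(res)))
        break
      }
    }
    tibble::tibble(system = sname,
                   inputs = paste(names(sys$inputs), collapse = ", "),
                   output = sys$output$name,
                   n_rules = length(sys$rules),
                   coverage_ok = cover_ok)
  })
  list(ok = length(issues) == 0L, report = dplyr::bind_rows(rows),
       issues = issues)
}

## --- JSON serialization ----------------------------------------------------

lingvar_to_list <- function(v) {
  list(name = v$name, lo = v$lo, hi = v$hi,
       check_coverage = isTRUE(v$check_coverage),
       terms = lapply(v$terms, function(t) {
         list(label = t$label, a = t$a, b = t$b, c = t$c, d = t$d)
       }))
}

lingvar_from_list <- function(l) {
  lingvar(l$name, as.numeric(l$lo), as.numeric(l$hi),
          lapply(l$terms, function(t) {
            trapmf(as.numeric(t$a), as.numeric(t$b), as.numeric(t$c),
                   as.numeric(t$d), t$label)
          }),
          check_coverage = !isFALSE(l$check_coverage))
}

#' Write a cascade configuration to JSON
#'
#' Serialises variables, membership-function breakpoints and the full rule
#' bases in a human-auditable JSON document that [read_cascade()] restores
#' losslessly.
#'
#' @param cascade A cascade configuration.
#' @param path File path to write.
#' @return `path`, invisibly.
#' @export
write_cascade <- function(cascade, path) {
  stopifnot(inherits(cascade, "cascade_config"))
  doc <- list(
    format = "osatriage/cascade",
    version = 1L,
    systems = lapply(unclass(cascade), function(sys) {
      list(name = sys$name,
           grid_n = length(sys$grid),
           inputs = lapply(unname(sys$inputs), lingvar_to_list),
           output = lingvar_to_list(sys$output),
           rules = lapply(sys$rules, function(r) {
             list(antecedents = as.list(r$antecedents),
                  consequent = r$consequent)
           }))
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a cascade configuration from JSON
#'
#' @param path Path to a JSON document written by [write_cascade()].
#' @return A `cascade_config`.
#' @export
read_cascade <- function(path) {
  doc <- jsonlite::read_json(path)
  if (is.null(doc$format) || doc$format != "osatriage/cascade") {
    stop("'", path, "' is not a cascade configuration document", call. = FALSE)
  }
  systems <- lapply(doc$systems, function(s) {
    mamdani_system(
      s$name,
      inputs = lapply(s$inputs, lingvar_from_list),
      output = lingvar_from_list(s$output),
      rules = lapply(s$rules, function(r) {
        fuzzy_rule(unlist(r$antecedents), r$consequent)
      }),
      grid_n = as.integer(s$grid_n)
    )
  })
  names(systems) <- vapply(systems, `[[`, character(1), "name")
  structure(systems, class = "cascade_config")
}
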