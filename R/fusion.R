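#' Default risk-level thresholds
#'
#' Limit 1 is 45 for both branches; Limit 2 is 60 for the Statistical Risk
#' and 65 for the Symbolic Risk. Both limits are clinical policy values meant
#' to be reviewed and overridden.
#'
#' @return A list with elements `statistical` and `symbolic`, each
#'   `c(l1 = ..., l2 = ...)`.
#' @export
default_thresholds <- function() {
  list(statistical = c(l1 = 45, l2 = 60), symbolic = c(l1 = 45, l2 = 65))
}

check_thresholds <- function(thresholds) {
  for (b in c("statistical", "symbolic")) {
    l <- thresholds[[b]]
    if (is.null(l) || length(l) != 2L || !(0 < l[[1]] && l[[1]] < l[[2]] && l[[2]] < 100)) {
      stop("invalid ", b, " thresholds: need 0 < L1 < L2 < 100", call. = FALSE)
    }
  }
  invisible(thresholds)
}

#' Map a percentage risk to a level
#'
#' Level 1 below Limit 1; level 2 on `[L1, L2)` (closed left, open right);
#' level 3 at or above Limit 2.
#'
#' @param risk Numeric risk on `[0, 100]`.
#' @param limits `c(l1, l2)` with `0 < l1 < l2 < 100`.
#' @return Integer levels in `{1, 2, 3}`. Vectorised.
#' @examples
#' risk_level(c(40, 61.79, 65), c(45, 65))
#' @export
risk_level <- function(risk, limits) {
  stopifnot(is.numeric(risk), length(limits) == 2L, limits[[1]] < limits[[2]])
  if (any(risk < 0 | risk > 100, na.rm = TRUE)) {
    stop("risk must lie in [0, 100]", call. = FALSE)
  }
  1L + (risk >= limits[[1]]) + (risk >= limits[[2]])
}

#' Utility score of a risk level
#'
#' Level 1 scores 0 points, level 2 one point, level 3 two points.
#'
#' @param level Integer levels in `{1, 2, 3}`.
#' @return Integer scores in `{0, 1, 2}`. Vectorised.
#' @export
level_score <- function(level) {
  if (!all(level %in% 1:3)) {
    stop("level must be 1, 2 or 3", call. = FALSE)
  }
  as.integer(level) - 1L
}

#' Decision variable T
#'
#' Weighted sum of the two branch scores:
#' `T = w_st * statistical_score + w_sy * symbolic_score`, with the weights
#' constrained to `w_st + w_sy = 2`, each in `[0, 2]` (defaults 1 and 1, under
#' which T takes values in `{0, 1, 2, 3, 4}`).
#'
#' @param score_st,score_sy Scores in `{0, 1, 2}`.
#' @param w_st,w_sy Branch weights.
#' @return Numeric T in `[0, 4]`. Vectorised over the scores.
#' @examples
#' decision_t(0, 1) # the case-study value: T = 1
#' @export
decision_t <- function(score_st, score_sy, w_st = 1, w_sy = 1) {
  if (!all(score_st %in% 0:2) || !all(score_sy %in% 0:2)) {
    stop("scores must be 0, 1 or 2", call. = FALSE)
  }
  if (abs(w_st + w_sy - 2) > 1e-9 || w_st < 0 || w_st > 2 || w_sy < 0 || w_sy > 2) {
    stop("weights must satisfy w_st + w_sy = 2 with each in [0, 2]",
         call. = FALSE)
  }
  w_st * score_st + w_sy * score_sy
}

#' Recommendation and alert colour from T
#'
#' `T < 2` is a non-OSA case (green, no diagnostic studies); `2 <= T < 3` is
#' doubtful (orange, medical team review) -- the half-open interval extends
#' the canonical `T = 2` row so that fractional T values reachable under
#' non-unit weights remain covered, erring toward clinical review; `T >= 3`
#' is a possible OSA case (red, perform diagnostic studies).
#'
#' @param t Numeric T values in `[0, 4]`.
#' @return A tibble with columns `T`, `recommendation` (factor `NON_OSA` <
#'   `DOUBTFUL` < `POSSIBLE_OSA`) and `alert_color` (`green`/`orange`/`red`).
#' @examples
#' recommend(c(1, 2, 2.5, 3))
#' @export
recommend <- function(t) {
  stopifnot(is.numeric(t))
  if (any(t < 0 | t > 4, na.rm = TRUE)) {
    stop("T must lie in [0, 4]", call. = FALSE)
  }
  rec <- dplyr::case_when(t < 2 ~ "NON_OSA", t < 3 ~ "DOUBTFUL",
                          TRUE ~ "POSSIBLE_OSA")
  tibble::tibble(
    T = t,
    recommendation = factor(rec, levels = c("NON_OSA", "DOUBTFUL", "POSSIBLE_OSA"),
                            ordered = TRUE),
    alert_color = unname(c(NON_OSA = "green", DOUBTFUL = "orange",
                           POSSIBLE_OSA = "red")[rec])
  )
}

#' Human-readable recommendation text
#'
#' @param recommendation Factor/character as returned by [recommend()].
#' @return Character vector of clinical recommendation sentences.
#' @export
recommendation_text <- function(recommendation) {
  unname(c(
    NON_OSA = "Non-OSA case - do not perform diagnostic studies",
    DOUBTFUL = paste("Doubtful case - medical team should assess whether",
                     "further tests or a new evaluation after a period of",
                     "time is necessary"),
    POSSIBLE_OSA = "Possible OSA case - perform diagnostic studies"
  )[as.character(recommendation)])
}

#' Fuse the two branch risks into an assessment
#'
#' Stage-3 logic on a table that already carries `statistical_risk` and
#' `symbolic_risk` columns (0-100): maps each risk to a level and a score,
#' computes the decision variable T and appends the recommendation and alert
#' colour.
#'
#' @param data Data frame with numeric `statistical_risk` and `symbolic_risk`.
#' @param thresholds Threshold config, default [default_thresholds()].
#' @param w_st,w_sy Fusion weights (see [decision_t()]).
#' @return The input tibble with `statistical_level`, `symbolic_level`,
#'   `statistical_score`, `symbolic_score`, `T`, `recommendation`,
#'   `alert_color` and `recommendation_text` appended; class
#'   `osa_assessment`.
#' @examples
#' fuse_risks(data.frame(statistical_risk = 40, symbolic_risk = 61.79))
#' @export
fuse_risks <- function(data, thresholds = default_thresholds(),
                       w_st = 1, w_sy = 1) {
  stopifnot(all(c("statistical_risk", "symbolic_risk") %in% names(data)))
  check_thresholds(thresholds)
  out <- tibble::as_tibble(data)
  out$statistical_level <- risk_level(out$statistical_risk, thresholds$statistical)
  out$symbolic_level <- risk_level(out$symbolic_risk, thresholds$symbolic)
  out$statistical_score <- level_score(out$statistical_level)
  out$symbolic_score <- level_score(out$symbolic_level)
  rec <- recommend(decision_t(out$statistical_score, out$symbolic_score,
                              w_st = w_st, w_sy = w_sy))
  out$T <- rec$T
  out$recommendation <- rec$recommendation
  out$alert_color <- rec$alert_color
  out$recommendation_text <- recommendation_text(rec$recommendation)
  class(out) <- c("osa_assessment", class(out))
  out
}

#' Assess patients end to end
#'
#' Runs both branches and the fusion for each record: the Statistical Risk
#' from the trained classifier over the objective fields, the Symbolic Risk
#' from the fuzzy cascade over the interview answers, then levels, scores, T
#' and the recommendation. The two branches are independent (either order
#' gives the same assessment) and every intermediate is kept for audit;
#' branch failures abort the assessment rather than emitting partial rows.
#'
#' @param data Data frame with both the [objective_fields()] and the
#'   [interview_items()] columns.
#' @param model A fitted [fit_osa_classifier()] model.
#' @param cascade Cascade configuration, default [default_cascade()].
#' @param thresholds Threshold config, default [default_thresholds()].
#' @param w_st,w_sy Fusion weights.
#' @return An `osa_assessment` tibble: the input plus both risks, all cascade
#'   intermediates, levels, scores, T, recommendation and alert colour.
#' @export
assess <- function(data, model, cascade = default_cascade(),
                   thresholds = default_thresholds(), w_st = 1, w_sy = 1) {
  stopifnot(inherits(model, "osa_classifier"))
  out <- predict_statistical_risk(model, data)
  out <- symbolic_risk(out, cascade = cascade)
  fuse_risks(out, thresholds = thresholds, w_st = w_st, w_sy = w_sy)
}
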