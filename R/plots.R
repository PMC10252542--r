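#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the membership functions of a linguistic variable
#'
#' @param object A [lingvar()].
#' @param n Curve resolution.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lingvar <- function(object, n = 401L, ...) {
  x <- seq(object$lo, object$hi, length.out = n)
  df <- purrr::map_dfr(object$terms, function(t) {
    tibble::tibble(term = t$label, x = x, membership = mf_degree(t, x))
  })
  df$term <- factor(df$term, levels = object$labels)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$membership,
                                   colour = .data$term)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(title = object$name, x = object$name, y = "membership",
                  colour = "term") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot all variables of a Mamdani system
#'
#' Facets the membership functions of every input variable and the output.
#'
#' @param object A [mamdani_system()].
#' @param n Curve resolution.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mamdani <- function(object, n = 401L, ...) {
  vars <- c(unname(object$inputs), list(object$output))
  df <- purrr::map_dfr(vars, function(v) {
    x <- seq(v$lo, v$hi, length.out = n)
    purrr::map_dfr(v$terms, function(t) {
      tibble::tibble(variable = v$name, term = t$label, x = x,
                     membership = mf_degree(t, x))
    })
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$membership,
                                   colour = .data$term)) +
    ggplot2::geom_line(linewidth = 0.6) +
    ggplot2::facet_wrap(~variable, scales = "free_x") +
    ggplot2::labs(title = paste("Mamdani system:", object$name),
                  y = "membership") +
    ggplot2::theme_minimal()
}

#' ROC curve of the cross-validated classifier
#'
#' @param object An `osa_classifier`.
#' @param ... Unused.
#' @return A ggplot of the pooled cross-validated ROC curve with the AUC in
#'   the subtitle.
#' @export
autoplot.osa_classifier <- function(object, ...) {
  ggplot2::ggplot(object$cv$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_path(colour = "#2166ac", linewidth = 0.9) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = "Statistical Risk classifier, pooled CV ROC",
                  subtitle = sprintf("AUC = %.3f", object$cv$pooled_auc),
                  x = "false positive rate", y = "true positive rate") +
    ggplot2::theme_minimal()
}

#' Plot assessments against the decision thresholds
#'
#' Shows each patient's Statistical and Symbolic Risk with the branch limits
#' overlaid and points coloured by the triage alert.
#'
#' @param object An `osa_assessment` tibble (see [fuse_risks()]).
#' @param thresholds Thresholds to draw, default [default_thresholds()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.osa_assessment <- function(object, thresholds = default_thresholds(), ...) {
  df <- tibble::as_tibble(object)
  lim <- tibble::tibble(
    branch = rep(c("statistical", "symbolic"), each = 2),
    limit = c(thresholds$statistical, thresholds$symbolic)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$statistical_risk,
                                   y = .data$symbolic_risk,
                                   colour = .data$recommendation)) +
    ggplot2::geom_vline(xintercept = thresholds$statistical, linetype = 2,
                        colour = "grey50") +
    ggplot2::geom_hline(yintercept = thresholds$symbolic, linetype = 2,
                        colour = "grey50") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_colour_manual(values = c(NON_OSA = "#1a9850",
                                            DOUBTFUL = "#fd8d3c",
                                            POSSIBLE_OSA = "#d73027"),
                                 drop = FALSE) +
    ggplot2::lims(x = c(0, 100), y = c(0, 100)) +
    ggplot2::labs(x = "Statistical Risk", y = "Symbolic Risk",
                  colour = "recommendation") +
    ggplot2::theme_minimal()
}
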