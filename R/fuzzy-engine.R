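#' Trapezoidal membership function
#'
#' Builds a trapezoidal fuzzy set with breakpoints `a <= b <= c <= d` on the
#' variable's universe. Membership is 0 outside `[a, d]`, 1 on the plateau
#' `[b, c]`, and linear on the ramps. Triangular sets are the special case
#' `b == c`.
#'
#' @param a,b,c,d Breakpoints, in the units of the variable.
#' @param label Term name (e.g. `"Very_low"`).
#' @return An object of class `trapmf`.
#' @examples
#' mf <- trapmf(0, 2, 4, 6, "Moderate")
#' mf_degree(mf, c(-1, 1, 3, 5, 7))
#' @export
trapmf <- function(a, b, c, d, label) {
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(c), is.numeric(d))
  if (!(a <= b && b <= c && c <= d)) {
    stop("trapmf breakpoints must satisfy a <= b <= c <= d (term '",
         label, "': ", paste(signif(c(a, b, c, d), 6), collapse = ", "), ")",
         call. = FALSE)
  }
  structure(list(a = a, b = b, c = c, d = d, label = as.character(label)),
            class = "trapmf")
}

#' Triangular membership function
#'
#' Convenience wrapper: a triangle is a trapezoid with a degenerate plateau.
#'
#' @param a,peak,d Left foot, apex and right foot.
#' @inheritParams trapmf
#' @return A `trapmf` with `b == c == peak`.
#' @export
trimf <- function(a, peak, d, label) trapmf(a, peak, peak, d, label)

#' Membership degree of a crisp value
#'
#' Piecewise-linear trapezoid evaluation; vectorised over `x`. Values outside
#' the support get degree 0, so `x` may lie anywhere on the real line.
#'
#' @param mf A [trapmf()].
#' @param x Numeric vector of crisp values.
#' @return Degrees in `[0, 1]`, same length as `x`.
#' @export
mf_degree <- function(mf, x) {
  stopifnot(inherits(mf, "trapmf"), is.numeric(x))
  out <- numeric(length(x))
  # plateau (covers b == c triangles and a == b / c == d shoulders)
  out[x >= mf$b & x <= mf$c] <- 1
  up <- x > mf$a & x < mf$b
  if (any(up)) out[up] <- (x[up] - mf$a) / (mf$b - mf$a)
  dn <- x > mf$c & x < mf$d
  if (any(dn)) out[dn] <- (mf$d - x[dn]) / (mf$d - mf$c)
  pmin(1, pmax(0, out))
}

#' @export
print.trapmf <- function(x, ...) {
  cat(sprintf("<trapmf> %s: (%g, %g, %g, %g)\n", x$label, x$a, x$b, x$c, x$d))
  invisible(x)
}

#' Linguistic variable
#'
#' A named variable over a closed universe `[lo, hi]` partitioned into ordered
#' fuzzy terms. Construction enforces that every term's support lies within
#' the universe, that terms are ordered by centre, and that every point of the
#' universe is covered by at least one term (checked on a fine grid).
#'
#' @param name Variable name.
#' @param lo,hi Universe bounds.
#' @param terms List of [trapmf()] terms.
#' @param check_coverage Require every point of the universe to have positive
#'   membership in some term. Mandatory for variables that are fuzzified as
#'   inputs; output variables on an extended defuzzification universe (whose
#'   edge terms are centred on the nominal scale ends) may disable it.
#' @return An object of class `lingvar`.
#' @examples
#' v <- lingvar("risk", 0, 10, uniform_terms(0, 10, c("Low", "Medium", "High")))
#' fuzzify(v, 2.5)
#' @export
lingvar <- function(name, lo, hi, terms, check_coverage = TRUE) {
  stopifnot(is.character(name), length(name) == 1L, lo < hi, length(terms) >= 1L)
  if (!all(vapply(terms, inherits, logical(1), "trapmf"))) {
    stop("all terms must be trapmf objects", call. = FALSE)
  }
  labels <- vapply(terms, `[[`, character(1), "label")
  if (anyDuplicated(labels)) {
    stop("duplicate term labels in variable '", name, "'", call. = FALSE)
  }
  for (t in terms) {
    if (t$a < lo - 1e-9 || t$d > hi + 1e-9) {
      stop("term '", t$label, "' of variable '", name,
           "' has support outside the universe [", lo, ", ", hi, "]",
           call. = FALSE)
    }
  }
  centers <- vapply(terms, function(t) (t$b + t$c) / 2, numeric(1))
  if (is.unsorted(centers)) {
    stop("terms of variable '", name, "' must be ordered by centre", call. = FALSE)
  }
  if (check_coverage) {
    grid <- seq(lo, hi, length.out = 256L)
    cover <- Reduce(pmax, lapply(terms, mf_degree, x = grid))
    if (any(cover <= 0)) {
      stop("terms of variable '", name, "' do not cover the universe (gap near x = ",
           signif(grid[which(cover <= 0)[1L]], 4), ")", call. = FALSE)
    }
  }
  structure(list(name = name, lo = lo, hi = hi, terms = terms, labels = labels,
                 check_coverage = check_coverage),
            class = "lingvar")
}

#' @export
print.lingvar <- function(x, ...) {
  cat(sprintf("<lingvar> %s on [%g, %g], %d terms: %s\n",
              x$name, x$lo, x$hi, length(x$terms),
              paste(x$labels, collapse = ", ")))
  invisible(x)
}

#' Uniform trapezoidal partition of a universe
#'
#' Standard partition used by the shipped defaults: term centres are equally
#' spaced from `lo` to `hi`; each term has a plateau of half the inter-centre
#' spacing and ramps that give roughly 50% overlap between adjacent terms, so
#' adjacent degrees sum to 1 in the overlap and coverage never drops below
#' 0.5. Terms are symmetric, normal and convex.
#'
#' @param lo,hi Universe bounds.
#' @param labels Character vector of term names (length >= 2) in increasing
#'   order of position.
#' @return A list of [trapmf()] objects.
#' @export
uniform_terms <- function(lo, hi, labels) {
  k <- length(labels)
  stopifnot(k >= 2L, lo < hi)
  w <- (hi - lo) / (k - 1)
  lapply(seq_len(k), function(i) {
    ctr <- lo + (i - 1) * w
    trapmf(max(lo, ctr - 0.75 * w), max(lo, ctr - 0.25 * w),
           min(hi, ctr + 0.25 * w), min(hi, ctr + 0.75 * w),
           labels[[i]])
  })
}

#' Fuzzify a crisp value
#'
#' Evaluates every term of a linguistic variable at `x`, returning one degree
#' per term. Values outside the universe are clamped to it when they are
#' within 1% of the range (with a warning), to tolerate rounding in entry
#' forms; anything further out is a range error naming the variable.
#'
#' @param var A [lingvar()].
#' @param x A single crisp value.
#' @param clamp_tol Fraction of the universe range allowed for clamping.
#' @return Named numeric vector of degrees in `[0, 1]`, one per term.
#' @export
fuzzify <- function(var, x, clamp_tol = 0.01) {
  stopifnot(inherits(var, "lingvar"), is.numeric(x), length(x) == 1L)
  if (is.na(x)) stop("variable '", var$name, "' is NA", call. = FALSE)
  rng <- var$hi - var$lo
  if (x < var$lo - clamp_tol * rng || x > var$hi + clamp_tol * rng) {
    stop("value ", signif(x, 6), " for variable '", var$name,
         "' is outside its universe [", var$lo, ", ", var$hi, "]",
         call. = FALSE)
  }
  if (x < var$lo || x > var$hi) {
    warning("clamping value ", signif(x, 6), " of variable '", var$name,
            "' to its universe [", var$lo, ", ", var$hi, "]", call. = FALSE)
    x <- min(var$hi, max(var$lo, x))
  }
  degrees <- vapply(var$terms, mf_degree, numeric(1), x = x)
  names(degrees) <- var$labels
  degrees
}

#' Fuzzy IF-THEN rule
#'
#' Antecedents are (variable, term) pairs joined by AND; the consequent names
#' a term of the system's output variable. Only conjunctive rules are
#' supported (AND = minimum); OR connectives, weights and hedges are not.
#'
#' @param antecedents Named character vector: `c(variable = "term", ...)`.
#'   A rule may reference a subset of the system's input variables.
#' @param consequent Output term label.
#' @return An object of class `fuzzy_rule`.
#' @examples
#' fuzzy_rule(c(nocturia = "Often", reported_apneas = "Often"), "Very_high")
#' @export
fuzzy_rule <- function(antecedents, consequent) {
  stopifnot(is.character(antecedents), length(antecedents) >= 1L,
            is.character(consequent), length(consequent) == 1L)
  if (is.null(names(antecedents)) || any(!nzchar(names(antecedents)))) {
    stop("antecedents must be a named character vector (variable = term)",
         call. = FALSE)
  }
  structure(list(antecedents = antecedents, consequent = consequent),
            class = "fuzzy_rule")
}

#' Firing strength of one rule
#'
#' AND semantics: the strength is the minimum of the membership degrees of the
#' rule's antecedents, looked up in per-variable fuzzification results.
#'
#' @param rule A [fuzzy_rule()].
#' @param degrees Named list: for each variable, the named degree vector
#'   produced by [fuzzify()].
#' @return Strength in `[0, 1]`.
#' @export
rule_strength <- function(rule, degrees) {
  stopifnot(inherits(rule, "fuzzy_rule"))
  vars <- names(rule$antecedents)
  missing <- setdiff(vars, names(degrees))
  if (length(missing)) {
    stop("no fuzzified degrees for variable(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  min(vapply(seq_along(vars), function(i) {
    d <- degrees[[vars[[i]]]][[rule$antecedents[[i]]]]
    if (is.null(d) || is.na(d)) {
      stop("term '", rule$antecedents[[i]], "' not found for variable '",
           vars[[i]], "'", call. = FALSE)
    }
    d
  }, numeric(1)))
}

#' Mamdani fuzzy inference system
#'
#' Bundles input variables, one output variable and a conjunctive rule base.
#' The inference operators are fixed to the classical Mamdani choices:
#' minimum implication (consequent truncation), maximum aggregation, and
#' centroid defuzzification on a discretised output grid.
#'
#' @param name System name (used in error messages and validation reports).
#' @param inputs List of [lingvar()] input variables.
#' @param output A [lingvar()] output variable.
#' @param rules List of [fuzzy_rule()] objects.
#' @param grid_n Number of grid points used to discretise the output universe
#'   for defuzzification (default 1001, giving sub-0.01 centroid error on a
#'   0-10 universe).
#' @return An object of class `mamdani`.
#' @export
mamdani_system <- function(name, inputs, output, rules, grid_n = 1001L) {
  stopifnot(is.character(name), length(name) == 1L,
            all(vapply(inputs, inherits, logical(1), "lingvar")),
            inherits(output, "lingvar"),
            length(rules) >= 1L,
            all(vapply(rules, inherits, logical(1), "fuzzy_rule")),
            grid_n >= 2L)
  in_names <- vapply(inputs, `[[`, character(1), "name")
  names(inputs) <- in_names
  for (i in seq_along(rules)) {
    r <- rules[[i]]
    for (v in names(r$antecedents)) {
      if (!v %in% in_names) {
        stop("system '", name, "', rule ", i, ": unknown input variable '",
             v, "'", call. = FALSE)
      }
      if (!r$antecedents[[v]] %in% inputs[[v]]$labels) {
        stop("system '", name, "', rule ", i, ": variable '", v,
             "' has no term '", r$antecedents[[v]], "'", call. = FALSE)
      }
    }
    if (!r$consequent %in% output$labels) {
      stop("system '", name, "', rule ", i, ": output variable '",
           output$name, "' has no term '", r$consequent, "'", call. = FALSE)
    }
  }
  grid <- seq(output$lo, output$hi, length.out = as.integer(grid_n))
  # pre-sampled output term membership, one row per term: makes aggregation a
  # handful of pmin/pmax calls regardless of rule count
  term_grid <- do.call(rbind, lapply(output$terms, mf_degree, x = grid))
  rownames(term_grid) <- output$labels
  structure(list(name = name, inputs = inputs, output = output, rules = rules,
                 grid = grid, term_grid = term_grid),
            class = "mamdani")
}

#' @export
print.mamdani <- function(x, ...) {
  cat(sprintf("<mamdani> %s: %d input(s) [%s] -> %s, %d rules, grid %d\n",
              x$name, length(x$inputs), paste(names(x$inputs), collapse = ", "),
              x$output$name, length(x$rules), length(x$grid)))
  invisible(x)
}

#' Aggregated output envelope
#'
#' Truncates each rule's consequent at the rule's firing strength (minimum
#' implication) and superposes the truncated sets with the maximum operator,
#' sampled on the system's output grid.
#'
#' @param system A [mamdani_system()].
#' @param strengths Numeric vector of firing strengths, one per rule.
#' @return Numeric envelope, one value per grid point.
#' @export
aggregate_envelope <- function(system, strengths) {
  stopifnot(inherits(system, "mamdani"),
            length(strengths) == length(system$rules))
  # max strength per consequent term, then envelope over <= n_terms shapes
  per_term <- stats::setNames(numeric(nrow(system$term_grid)),
                              rownames(system$term_grid))
  for (i in seq_along(strengths)) {
    cq <- system$rules[[i]]$consequent
    if (strengths[[i]] > per_term[[cq]]) per_term[[cq]] <- strengths[[i]]
  }
  env <- numeric(length(system$grid))
  for (term in names(per_term)) {
    if (per_term[[term]] > 0) {
      env <- pmax(env, pmin(per_term[[term]], system$term_grid[term, ]))
    }
  }
  env
}

#' Centroid defuzzification
#'
#' Crisp output as the centre of gravity of the aggregated envelope:
#' `sum(y * mu) / sum(mu)` on the grid. An identically-zero envelope means no
#' rule fired, which signals an incomplete rule base and is an error.
#'
#' @param envelope Numeric membership envelope.
#' @param grid Numeric grid of output values, same length.
#' @param context Optional system name for the error message.
#' @return Crisp value within the grid's range.
#' @export
defuzz_centroid <- function(envelope, grid, context = NULL) {
  stopifnot(length(envelope) == length(grid), length(grid) >= 2L)
  n <- length(grid)
  if (max(envelope) <= 0) {
    stop("no rule fired",
         if (!is.null(context)) paste0(" in system '", context, "'") else "",
         ": the aggregated output set is empty (incomplete rule coverage?)",
         call. = FALSE)
  }
  # integrate the piecewise-linear interpolant of the sampled envelope
  # exactly on each grid cell: area = dy (mu0 + mu1) / 2,
  # first moment = dy (y0 (2 mu0 + mu1) + y1 (mu0 + 2 mu1)) / 6
  y0 <- grid[-n]; y1 <- grid[-1L]
  m0 <- envelope[-n]; m1 <- envelope[-1L]
  dy <- y1 - y0
  area <- sum(dy * (m0 + m1)) / 2
  mom <- sum(dy * (y0 * (2 * m0 + m1) + y1 * (m0 + 2 * m1))) / 6
  mom / area
}

#' Run one Mamdani inference
#'
#' Full composition: fuzzify every input, evaluate rule firing strengths
#' (AND = min), truncate consequents (min implication), aggregate (max) and
#' defuzzify (centroid). Deterministic.
#'
#' @param system A [mamdani_system()].
#' @param inputs Named numeric vector or list of crisp values, one per input
#'   variable of the system.
#' @return Crisp output value, guaranteed to lie in the output universe.
#' @examples
#' sys <- mamdani_system(
#'   "demo",
#'   inputs = list(lingvar("x", 0, 10, uniform_terms(0, 10, c("lo", "hi")))),
#'   output = lingvar("y", 0, 10, uniform_terms(0, 10, c("lo", "hi"))),
#'   rules = list(fuzzy_rule(c(x = "lo"), "lo"), fuzzy_rule(c(x = "hi"), "hi"))
#' )
#' fis_infer(sys, c(x = 2))
#' @export
fis_infer <- function(system, inputs) {
  stopifnot(inherits(system, "mamdani"))
  inputs <- as.list(inputs)
  missing <- setdiff(names(system$inputs), names(inputs))
  if (length(missing)) {
    stop("system '", system$name, "': missing input(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  degrees <- lapply(names(system$inputs), function(v) {
    fuzzify(system$inputs[[v]], as.numeric(inputs[[v]]))
  })
  names(degrees) <- names(system$inputs)
  strengths <- vapply(system$rules, rule_strength, numeric(1), degrees = degrees)
  env <- aggregate_envelope(system, strengths)
  out <- defuzz_centroid(env, system$grid, context = system$name)
  min(system$output$hi, max(system$output$lo, out))
}
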