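#' SMOTE-NC class balancing for mixed continuous/categorical features
#'
#' Oversamples *both* classes to a common per-class target by synthesizing
#' records between nearest same-class neighbours, following the
#' nominal-continuous SMOTE variant: distances are Euclidean over the
#' continuous features plus a fixed penalty per mismatching categorical
#' feature (the median of the class's continuous-feature standard
#' deviations); a synthetic record interpolates the continuous features
#' between a seed record and one of its `k` nearest neighbours and takes each
#' categorical feature by majority vote among those `k` neighbours. Original
#' rows are always retained, and the draw is fully determined by `seed`.
#'
#' @param data Data frame of features plus a class column.
#' @param class_col Name of the class column (factor or character, 2 classes).
#' @param cat_cols Character vector of categorical feature columns; all other
#'   feature columns are treated as continuous.
#' @param k Number of nearest neighbours (default 5).
#' @param per_class Target record count per class (default 4000); must be at
#'   least the largest observed class count.
#' @param seed Integer seed driving neighbour and gap draws.
#' @return A tibble with `per_class` rows per class: the original rows
#'   followed by synthetic rows, with a logical `.synthetic` column and a
#'   `.seed_row` column giving, for synthetic rows, the row index (within the
#'   output) of the seed record used.
#' @examples
#' d <- data.frame(x = rnorm(40), g = rep(c("a", "b"), 20),
#'                 cls = rep(c("p", "n"), each = 20))
#' dplyr::count(balance_smote_nc(d, "cls", cat_cols = "g",
#'                               per_class = 30, seed = 1), cls)
#' @export
balance_smote_nc <- function(data, class_col, cat_cols = character(),
                             k = 5L, per_class = 4000L, seed = 1L) {
  stopifnot(is.data.frame(data), class_col %in% names(data), k >= 1L)
  data <- tibble::as_tibble(data)
  cls <- as.character(data[[class_col]])
  classes <- sort(unique(cls))
  if (length(classes) != 2L) {
    stop("balance_smote_nc expects exactly 2 classes, got ",
         length(classes), call. = FALSE)
  }
  counts <- table(cls)
  if (per_class < max(counts)) {
    stop("per-class target (", per_class,
         ") is below the largest observed class count (", max(counts), ")",
         call. = FALSE)
  }
  feat_cols <- setdiff(names(data), class_col)
  bad_cat <- setdiff(cat_cols, feat_cols)
  if (length(bad_cat)) {
    stop("unknown categorical column(s): ", paste(bad_cat, collapse = ", "),
         call. = FALSE)
  }
  # non-numeric feature columns are categorical whether flagged or not
  auto_cat <- feat_cols[!vapply(data[feat_cols], is.numeric, logical(1))]
  cat_cols <- union(cat_cols, auto_cat)
  cont_cols <- setdiff(feat_cols, cat_cols)
  if (length(cont_cols) == 0L) {
    stop("SMOTE-NC needs at least one continuous feature", call. = FALSE)
  }

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  pieces <- lapply(classes, function(cl) {
    rows <- which(cls == cl)
    n <- length(rows)
    n_new <- per_class - n
    orig <- data[rows, , drop = FALSE]
    orig$.synthetic <- FALSE
    orig$.seed_row <- NA_integer_
    if (n_new == 0L) return(orig)
    if (n < k + 1L) {
      stop("class '", cl, "' has ", n, " members; SMOTE-NC with k = ", k,
           " needs at least k + 1", call. = FALSE)
    }
    Xc <- as.matrix(orig[, cont_cols, drop = FALSE])
    storage.mode(Xc) <- "double"
    # SMOTE-NC categorical mismatch penalty: median of the continuous
    # features' standard deviations within this class (squared inside the
    # Euclidean sum)
    med <- stats::median(apply(Xc, 2L, stats::sd))
    if (!is.finite(med) || med == 0) med <- 1
    d2 <- as.matrix(stats::dist(Xc))^2
    for (cc in cat_cols) {
      v <- as.character(orig[[cc]])
      d2 <- d2 + med^2 * outer(v, v, `!=`)
    }
    diag(d2) <- Inf
    nn <- t(apply(d2, 1L, function(r) order(r)[seq_len(k)]))

    seed_idx <- sample.int(n, n_new, replace = TRUE)
    nb_pick <- sample.int(k, n_new, replace = TRUE)
    gaps <- stats::runif(n_new)
    nb_idx <- nn[cbind(seed_idx, nb_pick)]

    syn <- orig[seed_idx, , drop = FALSE]
    for (cc in cont_cols) {
      syn[[cc]] <- Xc[seed_idx, cc] + gaps * (Xc[nb_idx, cc] - Xc[seed_idx, cc])
    }
    for (cc in cat_cols) {
      v <- as.character(orig[[cc]])
      syn[[cc]] <- vapply(seq_len(n_new), function(i) {
        votes <- v[nn[seed_idx[[i]], ]]
        tab <- table(votes)
        names(tab)[which.max(tab)]
      }, character(1))
      if (is.numeric(orig[[cc]])) syn[[cc]] <- as.numeric(syn[[cc]])
    }
    syn$.synthetic <- TRUE
    syn$.seed_row <- seed_idx
    dplyr::bind_rows(orig, syn)
  })
  dplyr::bind_rows(pieces)
}
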