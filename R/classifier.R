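#' Fit the Statistical Risk classifier
#'
#' Trains a bagged-tree ensemble (bootstrap-aggregated decision trees,
#' implemented as a random forest with no feature subsampling) on the encoded
#' objective features, with SMOTE-NC class balancing and stratified k-fold
#' cross-validation. The learner is deliberately pluggable in spirit: the
#' risk is simply 100 times the ensemble's OSA class probability, so any
#' probabilistic classifier could stand behind the same surface.
#'
#' Cross-validated performance is computed with balancing applied *inside*
#' each training fold (the default, leakage-free protocol) and, for
#' comparison, with balancing applied once before the split; both AUCs are
#' reported ([glance()] shows them side by side).
#'
#' @param data Cohort data frame with the [objective_fields()] columns and an
#'   AHI column.
#' @param ahi_col Name of the AHI column (default `"ahi"`).
#' @param threshold AHI labeling threshold (default 15).
#' @param schema Encoding schema, default [default_encoding_schema()].
#' @param trees Number of bagged trees (default 30).
#' @param folds Cross-validation folds (default 5).
#' @param k SMOTE-NC neighbour count (default 5).
#' @param per_class SMOTE-NC per-class target (default 4000).
#' @param balance One of `"fold"` (balance inside each training fold; the
#'   final model is fit on the fully balanced data), or `"none"`.
#' @param seed Integer seed controlling balancing, fold assignment and tree
#'   bootstraps; identical data + seed reproduce the fit exactly.
#' @return An object of class `osa_classifier` with the fitted ensemble, the
#'   encoding schema and its hash, CV metrics (per-fold and pooled AUC, ROC
#'   points, pooled confusion counts at probability 0.5) and permutation
#'   feature importance.
#' @seealso [predict_statistical_risk()], [tidy.osa_classifier()],
#'   [glance.osa_classifier()]
#' @export
fit_osa_classifier <- function(data, ahi_col = "ahi", threshold = 15,
                               schema = default_encoding_schema(),
                               trees = 30L, folds = 5L, k = 5L,
                               per_class = 4000L, balance = c("fold", "none"),
                               seed = 1L) {
  balance <- match.arg(balance)
  if (!ahi_col %in% names(data)) {
    stop("AHI column '", ahi_col, "' not found; it is required for training",
         call. = FALSE)
  }
  features <- encode_cohort(data, schema)
  label <- label_by_ahi(data[[ahi_col]], threshold)
  if (nlevels(droplevels(label)) < 2L) {
    stop("training data contains a single class; cannot fit a classifier",
         call. = FALSE)
  }
  cat_cols <- dummy_column_names(schema)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  fold_id <- stratified_folds(label, folds)
  fit_one <- function(x, y, s) {
    ranger::ranger(
      x = as.data.frame(x), y = y,
      num.trees = trees, mtry = ncol(x),          # bagging: all features per split
      replace = TRUE, sample.fraction = 1,
      probability = TRUE, min.node.size = 10,
      seed = s, num.threads = 1
    )
  }
  balance_xy <- function(x, y, s) {
    if (balance == "none") return(list(x = x, y = y))
    d <- dplyr::mutate(tibble::as_tibble(x), .class = y)
    target <- max(per_class, max(table(y)))
    b <- balance_smote_nc(d, ".class", cat_cols = cat_cols, k = k,
                          per_class = target, seed = s)
    list(x = b[, setdiff(names(b), c(".class", ".synthetic", ".seed_row"))],
         y = b$.class)
  }

  cv_run <- function(pre_balanced) {
    if (pre_balanced) {
      bal <- balance_xy(features, label, seed)
      x_all <- bal$x; y_all <- factor(bal$y, levels = levels(label))
      fid <- stratified_folds(y_all, folds)
    } else {
      x_all <- features; y_all <- label; fid <- fold_id
    }
    probs <- rep(NA_real_, length(y_all))
    fold_auc <- numeric(folds)
    for (f in seq_len(folds)) {
      tr <- fid != f
      if (pre_balanced) {
        xt <- x_all[tr, , drop = FALSE]; yt <- y_all[tr]
      } else {
        bal <- balance_xy(x_all[tr, , drop = FALSE], y_all[tr], seed + f)
        xt <- bal$x; yt <- factor(bal$y, levels = levels(label))
      }
      if (nlevels(droplevels(yt)) < 2L) {
        stop("fold ", f, " is degenerate (single class after split)",
             call. = FALSE)
      }
      m <- fit_one(xt, yt, seed + 100L * f)
      p <- stats::predict(m, as.data.frame(x_all[!tr, , drop = FALSE]))$predictions[, "OSA"]
      probs[!tr] <- p
      fold_auc[[f]] <- as.numeric(pROC::auc(
        pROC::roc(response = y_all[!tr], predictor = p,
                  levels = c("non-OSA", "OSA"), direction = "<", quiet = TRUE)))
    }
    roc_all <- pROC::roc(response = y_all, predictor = probs,
                         levels = c("non-OSA", "OSA"), direction = "<",
                         quiet = TRUE)
    pred_cls <- factor(ifelse(probs >= 0.5, "OSA", "non-OSA"),
                       levels = levels(label))
    list(fold_auc = fold_auc, pooled_auc = as.numeric(pROC::auc(roc_all)),
         roc = tibble::tibble(fpr = 1 - roc_all$specificities,
                              tpr = roc_all$sensitivities),
         confusion = table(truth = y_all, predicted = pred_cls))
  }

  cv <- cv_run(pre_balanced = FALSE)
  cv_pre <- if (balance == "fold") cv_run(pre_balanced = TRUE) else NULL

  final_bal <- balance_xy(features, label, seed)
  forest <- fit_one(final_bal$x, factor(final_bal$y, levels = levels(label)),
                    seed)
  imp_forest <- ranger::ranger(
    x = as.data.frame(final_bal$x), y = factor(final_bal$y, levels = levels(label)),
    num.trees = trees, mtry = ncol(final_bal$x), replace = TRUE,
    sample.fraction = 1, probability = TRUE, min.node.size = 10,
    importance = "permutation", seed = seed, num.threads = 1
  )

  structure(
    list(forest = forest,
         schema = attr(features, "schema"),
         schema_hash = attr(features, "schema_hash"),
         feature_names = names(features),
         importance = sort(ranger::importance(imp_forest), decreasing = TRUE),
         threshold = threshold, trees = trees, folds = folds,
         k = k, per_class = per_class, balance = balance, seed = seed,
         n_train = nrow(features), class_counts = table(label),
         cv = cv, cv_prebalanced = cv_pre),
    class = "osa_classifier"
  )
}

dummy_column_names <- function(schema) {
  unlist(purrr::imap(schema$categorical, function(levels, v) {
    paste(v, levels[-1], sep = "_")
  }), use.names = FALSE)
}

stratified_folds <- function(label, folds) {
  id <- integer(length(label))
  for (cl in levels(label)) {
    rows <- which(label == cl)
    id[rows] <- sample(rep_len(seq_len(folds), length(rows)))
  }
  id
}

#' @export
print.osa_classifier <- function(x, ...) {
  cat("<osa_classifier> bagged trees (", x$trees, " trees, ", x$folds,
      "-fold CV, SMOTE-NC balance='", x$balance, "')\n", sep = "")
  cat("  training: n =", x$n_train, "(",
      paste(names(x$class_counts), x$class_counts, collapse = ", "), ")\n")
  cat("  CV AUC (fold-balanced):", round(x$cv$pooled_auc, 3), "\n")
  if (!is.null(x$cv_prebalanced)) {
    cat("  CV AUC (pre-balanced): ", round(x$cv_prebalanced$pooled_auc, 3), "\n")
  }
  invisible(x)
}

#' Per-fold cross-validation metrics
#'
#' @param x An `osa_classifier`.
#' @param ... Unused.
#' @return A tibble with one row per CV fold: `fold`, `auc`.
#' @export
tidy.osa_classifier <- function(x, ...) {
  tibble::tibble(fold = seq_along(x$cv$fold_auc), auc = x$cv$fold_auc)
}

#' One-row model summary
#'
#' @param x An `osa_classifier`.
#' @param ... Unused.
#' @return A one-row tibble: pooled and mean per-fold AUC under fold-internal
#'   balancing, pooled AUC under pre-split balancing (NA if not computed),
#'   accuracy/sensitivity/specificity at probability 0.5, n, trees, folds.
#' @export
glance.osa_classifier <- function(x, ...) {
  cm <- x$cv$confusion
  tibble::tibble(
    auc = x$cv$pooled_auc,
    auc_fold_mean = mean(x$cv$fold_auc),
    auc_prebalanced = if (is.null(x$cv_prebalanced)) NA_real_ else x$cv_prebalanced$pooled_auc,
    accuracy = sum(diag(cm)) / sum(cm),
    sensitivity = cm["OSA", "OSA"] / sum(cm["OSA", ]),
    specificity = cm["non-OSA", "non-OSA"] / sum(cm["non-OSA", ]),
    n = x$n_train, trees = x$trees, folds = x$folds
  )
}

#' Predict the Statistical Risk
#'
#' Encodes new records with the model's stored schema (refusing records
#' encoded under a different schema) and returns 100 times the ensemble's
#' predicted OSA probability.
#'
#' @param model An `osa_classifier`.
#' @param data Data frame of objective records.
#' @return The input as a tibble with columns `statistical_prob` and
#'   `statistical_risk` (0-100) appended.
#' @export
predict_statistical_risk <- function(model, data) {
  stopifnot(inherits(model, "osa_classifier"))
  features <- encode_cohort(data, model$schema)
  if (!identical(attr(features, "schema_hash"), model$schema_hash)) {
    stop("encoding schema mismatch: record encoded under a different schema ",
         "than the model was trained with; refusing to predict", call. = FALSE)
  }
  if (!identical(names(features), model$feature_names)) {
    stop("feature columns do not match the training schema", call. = FALSE)
  }
  p <- stats::predict(model$forest, as.data.frame(features))$predictions[, "OSA"]
  dplyr::mutate(tibble::as_tibble(data),
                statistical_prob = p, statistical_risk = 100 * p)
}

#' Persist a trained classifier
#'
#' Writes the model (ensemble, schema, metadata) to an RDS file with an
#' embedded format tag and schema hash; [load_model()] verifies both before
#' the model can be used for prediction.
#'
#' @param model An `osa_classifier`.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
persist_model <- function(model, path) {
  stopifnot(inherits(model, "osa_classifier"))
  saveRDS(list(format = "osatriage/model", version = 1L, model = model), path)
  invisible(path)
}

#' Load a persisted classifier
#'
#' @param path Path written by [persist_model()].
#' @return An `osa_classifier`.
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$format, "osatriage/model")) {
    stop("'", path, "' is not an osatriage model file", call. = FALSE)
  }
  m <- obj$model
  if (!identical(m$schema_hash, rlang::hash(m$schema))) {
    stop("model file schema hash mismatch; refusing to load", call. = FALSE)
  }
  m
}
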