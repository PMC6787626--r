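#' Random-forest parameters
#'
#' The published model settings: `mtry = 4` predictors tried per split,
#' `ntree = 5000` trees, bootstrap sampling with replacement, and both
#' importance measures computed.
#'
#' @param mtry Predictors sampled at each node (clamped to the number of
#'   features at fit time).
#' @param ntree Number of trees (>= 1).
#' @param replace Bootstrap with replacement (`TRUE`, the default) or
#'   0.632-subsampling without replacement.
#' @param seed Integer seed making the forest (and its OOB quantities)
#'   reproducible.
#' @return An object of class `rf_params`.
#' @export
rf_params <- function(mtry = 4L, ntree = 5000L, replace = TRUE, seed = 1L) {
  if (mtry < 1) stop("mtry must be >= 1", call. = FALSE)
  if (ntree < 1) stop("ntree must be >= 1", call. = FALSE)
  structure(list(mtry = as.integer(mtry), ntree = as.integer(ntree),
                 replace = isTRUE(replace), seed = as.integer(seed)),
            class = "rf_params")
}

#' Fit the random-forest severity model with out-of-bag evaluation
#'
#' Grows a seeded forest of fully grown Gini CART trees, each on a bootstrap
#' sample with `mtry` features tried per node. Every participant is
#' evaluated out-of-bag (OOB): the trees whose bootstrap missed the case
#' vote on it, giving an internal error estimate without a held-out split.
#' Two feature rankings are computed: Gini importance (total node-weighted
#' impurity decrease per feature, averaged over trees) and permutation
#' importance (mean decrease in per-tree OOB accuracy when the feature is
#' shuffled among the OOB cases). Vote ties are broken toward the lowest
#' class index.
#'
#' @param features Data frame / matrix of numeric predictors, no missing
#'   values (impute first). The canonical panel is
#'   [default_feature_panel()].
#' @param labels Class labels (e.g. merged 3-class severity); every class
#'   present needs >= 2 cases.
#' @param params An [rf_params()].
#' @return An object of class `severity_rf` with elements
#'   `oob_predictions` (factor, `NA` if a case was never OOB),
#'   `oob_confusion` (true x predicted counts), `oob_error_overall`,
#'   `oob_error_per_class`, `class_scores` (per-case OOB vote fractions,
#'   rows summing to 1), `importance_gini`, `importance_permutation`
#'   (named numeric vectors), `ranking_gini`, `ranking_permutation`
#'   (feature names in descending importance), `labels`, `levels`, `params`.
#' @export
fit_rf <- function(features, labels, params = rf_params()) {
  chk <- check_features_labels(features, labels)
  X <- chk$X; y <- chk$y; lev <- chk$levels
  n <- nrow(X); p <- ncol(X); k <- length(lev)
  mtry <- min(params$mtry, p)
  set.seed(params$seed)

  votes <- matrix(0L, n, k, dimnames = list(NULL, lev))
  gini_imp <- numeric(p)
  perm_dec <- numeric(p)  # summed (acc_oob - acc_permuted) over trees
  perm_trees <- 0L
  n_boot <- if (params$replace) n else max(2L, round(0.632 * n))

  trees <- vector("list", params$ntree)
  for (b in seq_len(params$ntree)) {
    bs <- sample.int(n, n_boot, replace = params$replace)
    tr <- grow_cart(X[bs, , drop = FALSE], y[bs], k = k, mtry = mtry,
                    minsplit = 2L, minbucket = 1L, cp = 0, max_depth = 30L)
    trees[[b]] <- tr[c("var", "split", "left", "right", "pred")]
    gini_imp <- gini_imp + tr$gini_decrease
    oob <- which(!(seq_len(n) %in% bs))
    if (!length(oob)) next
    Xo <- X[oob, , drop = FALSE]
    pr <- predict_cart(tr, Xo)
    votes[cbind(oob, pr)] <- votes[cbind(oob, pr)] + 1L
    acc <- mean(pr == y[oob])
    for (f in seq_len(p)) {
      Xp <- Xo
      Xp[, f] <- Xp[sample.int(length(oob)), f]
      perm_dec[f] <- perm_dec[f] + (acc - mean(predict_cart(tr, Xp) == y[oob]))
    }
    perm_trees <- perm_trees + 1L
  }

  seen <- rowSums(votes) > 0
  oob_pred_idx <- rep(NA_integer_, n)
  oob_pred_idx[seen] <- max.col(votes[seen, , drop = FALSE], ties.method = "first")
  oob_predictions <- factor(lev[oob_pred_idx], levels = lev)
  truth <- factor(lev[y], levels = lev)
  confusion <- table(true = truth[seen], predicted = oob_predictions[seen])
  n_eval <- sum(seen)
  err_overall <- 1 - sum(diag(confusion)) / n_eval
  err_class <- 1 - diag(confusion) / rowSums(confusion)
  scores <- votes / pmax(1L, rowSums(votes))

  gini <- stats::setNames(gini_imp / params$ntree, colnames(X))
  perm <- stats::setNames(perm_dec / max(1L, perm_trees), colnames(X))
  structure(list(
    oob_predictions = oob_predictions,
    oob_confusion = confusion,
    oob_error_overall = err_overall,
    oob_error_per_class = err_class,
    class_scores = scores,
    importance_gini = gini,
    importance_permutation = perm,
    ranking_gini = names(sort(gini, decreasing = TRUE)),
    ranking_permutation = names(sort(perm, decreasing = TRUE)),
    labels = truth, levels = lev, n = n, params = params,
    features = colnames(X), trees = trees
  ), class = "severity_rf")
}

#' @export
print.severity_rf <- function(x, ...) {
  cat("Random-forest severity model:", x$params$ntree, "trees, mtry =",
      x$params$mtry, "\n")
  cat(sprintf("OOB error: %.2f%% overall (n = %d)\n",
              100 * x$oob_error_overall, x$n))
  print(x$oob_confusion)
  cat("Permutation importance ranking:",
      paste(x$ranking_permutation, collapse = " > "), "\n")
  cat("Gini importance ranking:       ",
      paste(x$ranking_gini, collapse = " > "), "\n")
  invisible(x)
}

#' Restrict a cohort table to correctly OOB-predicted cases
#'
#' Keeps the rows whose out-of-bag forest prediction equals their true
#' class -- the subset on which refined reference intervals are computed.
#' Per-class retained counts are reported via `message()`; a class with no
#' correct predictions is dropped with a warning.
#'
#' @param model A [fit_rf()] result fitted on the same rows as `table`.
#' @param table The cohort data frame the model was fitted on.
#' @return The subset of `table` (possibly empty) with a
#'   `"retained_per_class"` attribute.
#' @export
correctly_predicted_subset <- function(model, table) {
  if (!inherits(model, "severity_rf")) stop("model must be a severity_rf", call. = FALSE)
  if (nrow(table) != model$n) {
    stop("table does not match the rows the model was fitted on", call. = FALSE)
  }
  ok <- !is.na(model$oob_predictions) & model$oob_predictions == model$labels
  kept <- table(model$labels[ok])
  all_cls <- table(model$labels)
  empty <- names(all_cls)[!(names(all_cls) %in% names(kept)) | kept[names(all_cls)] == 0]
  empty <- empty[!is.na(empty)]
  if (length(empty)) {
    warning("class(es) with zero correct predictions dropped: ",
            paste(empty, collapse = ", "), call. = FALSE)
  }
  message("correctly_predicted_subset: retained ",
          paste(sprintf("%s=%d", names(kept), kept), collapse = ", "),
          " of ", paste(sprintf("%s=%d", names(all_cls), all_cls), collapse = ", "))
  out <- table[ok, , drop = FALSE]
  attr(out, "retained_per_class") <- kept
  out
}

#' Predict classes with a fitted severity forest
#'
#' Majority vote of the stored trees on new data; ties break toward the
#' lowest class index, as in fitting. (OOB quantities for the training rows
#' live in the model object itself and should be preferred there.)
#'
#' @param object A `severity_rf`.
#' @param newdata Data frame with the model's feature columns.
#' @param ... Unused.
#' @return Factor of predicted classes.
#' @export
predict.severity_rf <- function(object, newdata, ...) {
  Xn <- as.matrix(as.data.frame(newdata)[, object$features, drop = FALSE])
  k <- length(object$levels)
  votes <- matrix(0L, nrow(Xn), k)
  idx <- seq_len(nrow(Xn))
  for (tr in object$trees) {
    pr <- predict_cart(tr, Xn)
    votes[cbind(idx, pr)] <- votes[cbind(idx, pr)] + 1L
  }
  factor(object$levels[max.col(votes, ties.method = "first")], levels = object$levels)
}

#' Cohen's kappa from a confusion matrix
#'
#' Chance-corrected agreement \eqn{\kappa = (p_o - p_e) / (1 - p_e)} with
#' the expected agreement computed from the marginals.
#'
#' @param confusion Square matrix/table of counts (true x predicted).
#' @return Numeric kappa.
#' @export
cohen_kappa <- function(confusion) {
  m <- as.matrix(confusion)
  if (nrow(m) != ncol(m)) stop("confusion matrix must be square", call. = FALSE)
  total <- sum(m)
  if (total <= 0) stop("confusion matrix has zero total count", call. = FALSE)
  po <- sum(diag(m)) / total
  pe <- sum(rowSums(m) * colSums(m)) / total^2
  if (abs(1 - pe) < .Machine$double.eps) {
    stop("kappa undefined: expected agreement is 1 (degenerate marginals)", call. = FALSE)
  }
  (po - pe) / (1 - pe)
}
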