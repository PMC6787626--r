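#' ROC curve and AUC from scores
#'
#' Sweeps a decision threshold over the unique score values (predicting
#' positive when score >= threshold), tracing true-positive rate against
#' false-positive rate. Tied scores move the curve diagonally in one step,
#' and the AUC is the trapezoidal area, which equals the Mann-Whitney pair
#' count (ties counted half) divided by `n_pos * n_neg` -- the probability
#' that a random positive scores above a random negative.
#'
#' @param scores Finite numeric scores (higher = more positive-like).
#' @param labels Logical (or 0/1) vector: `TRUE` = positive class. Both
#'   classes must be present.
#' @return An object of class `severity_roc`: `points` (threshold, fpr,
#'   tpr; starts at (0,0), ends at (1,1)), `auc`, `n_pos`, `n_neg`,
#'   `restricted_to_correct` (set by [pairwise_class_roc()]).
#' @export
roc_curve <- function(scores, labels) {
  if (is.numeric(labels)) labels <- labels != 0
  if (!is.logical(labels)) stop("labels must be logical or 0/1", call. = FALSE)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  if (!all(is.finite(scores))) stop("scores must be finite", call. = FALSE)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    stop("both classes must be present to trace a ROC curve", call. = FALSE)
  }
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; l <- labels[o]
  # collapse tied scores into single steps
  last_of_tie <- c(s[-length(s)] != s[-1], TRUE)
  tp <- cumsum(l)[last_of_tie]
  fp <- cumsum(!l)[last_of_tie]
  points <- data.frame(threshold = c(Inf, s[last_of_tie]),
                       fpr = c(0, fp / n_neg), tpr = c(0, tp / n_pos))
  auc <- sum(diff(points$fpr) * (points$tpr[-1] + points$tpr[-nrow(points)]) / 2)
  structure(list(points = points, auc = auc, n_pos = n_pos, n_neg = n_neg,
                 restricted_to_correct = FALSE, class_pair = NULL),
            class = "severity_roc")
}

#' Pairwise severity-class ROC from forest OOB vote scores
#'
#' For a class pair (a, b), restricts the cohort to cases whose true class
#' is a or b, scores each case by its out-of-bag vote fraction for the
#' higher-severity class `b`, and traces the ROC of "discriminates class b
#' from class a". With `correct_only = TRUE` the cases are first restricted
#' to those the forest predicted correctly out-of-bag (via
#' [correctly_predicted_subset()]'s criterion), mirroring the
#' refined-reference-interval workflow.
#'
#' @param model A [fit_rf()] result.
#' @param table The cohort table the model was fitted on (same rows).
#' @param pair Length-2 vector of class labels (a, b) as they appear in the
#'   model's levels; `b` is taken as the positive (higher-severity) class.
#' @param correct_only Restrict to correctly OOB-predicted cases first.
#' @return A `severity_roc` with `class_pair` and `restricted_to_correct`
#'   filled in.
#' @export
pairwise_class_roc <- function(model, table, pair, correct_only = FALSE) {
  if (!inherits(model, "severity_rf")) stop("model must be a severity_rf", call. = FALSE)
  pair <- as.character(pair)
  if (length(pair) != 2 || !all(pair %in% model$levels)) {
    stop("pair must name two of the model's classes: ",
         paste(model$levels, collapse = ", "), call. = FALSE)
  }
  truth <- as.character(model$labels)
  keep <- truth %in% pair
  if (correct_only) {
    ok <- !is.na(model$oob_predictions) & model$oob_predictions == model$labels
    keep <- keep & ok
  }
  for (cl in pair) {
    if (!any(truth[keep] == cl)) {
      stop("class ", cl, " has no cases left",
           if (correct_only) " after restriction to correctly predicted cases",
           call. = FALSE)
    }
  }
  scores <- model$class_scores[keep, pair[2]]
  roc <- roc_curve(scores, truth[keep] == pair[2])
  roc$class_pair <- pair
  roc$restricted_to_correct <- correct_only
  roc
}

#' @export
print.severity_roc <- function(x, ...) {
  cat("ROC", if (!is.null(x$class_pair))
    paste0("(class ", x$class_pair[1], " vs ", x$class_pair[2], ")"),
    if (x$restricted_to_correct) "[correctly predicted cases only]", "\n")
  cat(sprintf("AUC = %.3f (n_pos = %d, n_neg = %d)\n", x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' @export
plot.severity_roc <- function(x, ...) {
  graphics::plot(x$points$fpr, x$points$tpr, type = "l",
                 xlab = "False positive rate", ylab = "True positive rate",
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 2, col = "grey")
  graphics::legend("bottomright", sprintf("AUC = %.3f", x$auc), bty = "n")
  invisible(x)
}
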