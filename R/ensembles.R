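# Internal light-weight learners for the cross-validated ensemble
# comparison. Each returns a closure predicting integer classes 1..k.
# These are deliberately simple stand-ins for the gbm/c5.0/SVM ensemble
# set of the original analysis: exact algorithm parity is not attempted.

train_rf_light <- function(X, y, k, ntree = 200L, mtry = min(4L, ncol(X))) {
  n <- nrow(X)
  trees <- vector("list", ntree)
  for (b in seq_len(ntree)) {
    bs <- sample.int(n, n, replace = TRUE)
    trees[[b]] <- grow_cart(X[bs, , drop = FALSE], y[bs], k = k, mtry = mtry,
                            minsplit = 2L, minbucket = 1L, cp = 0)
  }
  function(Xn) {
    votes <- matrix(0L, nrow(Xn), k)
    idx <- seq_len(nrow(Xn))
    for (tr in trees) {
      pr <- predict_cart(tr, Xn)
      votes[cbind(idx, pr)] <- votes[cbind(idx, pr)] + 1L
    }
    max.col(votes, ties.method = "first")
  }
}

# AdaBoost.SAMME with weight-proportional resampling over shallow CART trees.
train_adaboost <- function(X, y, k, rounds = 40L, depth = 2L) {
  n <- nrow(X)
  w <- rep(1 / n, n)
  trees <- list(); alphas <- numeric(0)
  for (r in seq_len(rounds)) {
    bs <- sample.int(n, n, replace = TRUE, prob = w)
    tr <- grow_cart(X[bs, , drop = FALSE], y[bs], k = k, mtry = ncol(X),
                    minsplit = 4L, minbucket = 1L, cp = 0, max_depth = depth)
    pr <- predict_cart(tr, X)
    err <- sum(w * (pr != y))
    if (err >= 1 - 1 / k) next          # worse than chance: discard round
    err <- max(err, 1e-10)
    alpha <- log((1 - err) / err) + log(k - 1)
    trees[[length(trees) + 1L]] <- tr
    alphas <- c(alphas, alpha)
    w <- w * exp(alpha * (pr != y))
    w <- w / sum(w)
    if (err <= 1e-10) break             # perfect learner: nothing left to boost
  }
  if (!length(trees)) {                  # fall back to the majority class
    maj <- which.max(tabulate(y, k))
    return(function(Xn) rep(maj, nrow(Xn)))
  }
  function(Xn) {
    score <- matrix(0, nrow(Xn), k)
    for (i in seq_along(trees)) {
      pr <- predict_cart(trees[[i]], Xn)
      score[cbind(seq_len(nrow(Xn)), pr)] <- score[cbind(seq_len(nrow(Xn)), pr)] + alphas[i]
    }
    max.col(score, ties.method = "first")
  }
}

# Best single-split regression stump (least squares) for gradient boosting.
fit_stump <- function(X, r) {
  n <- nrow(X)
  best <- list(sse = sum((r - mean(r))^2), f = 0L)
  for (f in seq_len(ncol(X))) {
    o <- order(X[, f], method = "radix")
    xs <- X[o, f]; rs <- r[o]
    csum <- cumsum(rs); tot <- csum[n]
    nl <- seq_len(n - 1L)
    ok <- xs[-n] < xs[-1L]
    if (!any(ok)) next
    ml <- csum[nl] / nl
    mr <- (tot - csum[nl]) / (n - nl)
    # SSE decomposition: total SS minus between-group SS
    ss_between <- nl * ml^2 + (n - nl) * mr^2
    sse <- sum(rs^2) - ss_between
    sse[!ok] <- Inf
    j <- which.min(sse)
    if (sse[j] < best$sse - 1e-12) {
      best <- list(sse = sse[j], f = f, cut = (xs[j] + xs[j + 1L]) / 2,
                   left = ml[j], right = mr[j])
    }
  }
  if (best$f == 0L) list(f = 0L, value = mean(r)) else best
}

predict_stump <- function(st, X) {
  if (st$f == 0L) rep(st$value, nrow(X)) else
    ifelse(X[, st$f] <= st$cut, st$left, st$right)
}

# One-vs-rest logistic gradient boosting on regression stumps.
train_gbm_stumps <- function(X, y, k, rounds = 60L, shrinkage = 0.2) {
  models <- lapply(seq_len(k), function(cl) {
    yc <- as.numeric(y == cl)
    Fv <- rep(0, nrow(X))
    stumps <- vector("list", rounds)
    for (m in seq_len(rounds)) {
      p <- 1 / (1 + exp(-Fv))
      st <- fit_stump(X, yc - p)
      stumps[[m]] <- st
      Fv <- Fv + shrinkage * predict_stump(st, X)
    }
    stumps
  })
  function(Xn) {
    score <- vapply(models, function(stumps) {
      Fv <- rep(0, nrow(Xn))
      for (st in stumps) Fv <- Fv + shrinkage * predict_stump(st, Xn)
      Fv
    }, numeric(nrow(Xn)))
    max.col(matrix(score, nrow = nrow(Xn)), ties.method = "first")
  }
}

# Linear SVM trained by the Pegasos subgradient method on standardized
# features; multiclass via one-vs-one voting (a one-vs-rest linear machine
# cannot isolate the middle class of an ordinal 1-D structure).
train_linear_svm <- function(X, y, k, lambda = 0.01, epochs = 30L) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd); sdv[sdv == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  p <- ncol(Xs)
  fit_binary <- function(Xb, yb) {  # yb in {-1, +1}
    n <- nrow(Xb)
    w <- numeric(p); b <- 0; t <- 0
    for (e in seq_len(epochs)) {
      for (i in sample.int(n)) {
        t <- t + 1
        eta <- 1 / (lambda * t)
        margin <- yb[i] * (sum(w * Xb[i, ]) + b)
        w <- (1 - eta * lambda) * w
        if (margin < 1) {
          w <- w + eta * yb[i] * Xb[i, ]
          b <- b + eta * yb[i]
        }
      }
    }
    list(w = w, b = b)
  }
  pairs <- utils::combn(k, 2, simplify = FALSE)
  machines <- lapply(pairs, function(pr) {
    idx <- y %in% pr
    fit_binary(Xs[idx, , drop = FALSE], ifelse(y[idx] == pr[1], 1, -1))
  })
  function(Xn) {
    Xns <- sweep(sweep(Xn, 2, mu), 2, sdv, "/")
    votes <- matrix(0L, nrow(Xn), k)
    for (j in seq_along(pairs)) {
      m <- machines[[j]]; pr <- pairs[[j]]
      win <- ifelse(Xns %*% m$w + m$b >= 0, pr[1], pr[2])
      votes[cbind(seq_len(nrow(Xn)), win)] <- votes[cbind(seq_len(nrow(Xn)), win)] + 1L
    }
    max.col(votes, ties.method = "first")
  }
}

#' Cross-validated comparison of classifier ensembles
#'
#' Repeated stratified k-fold cross-validation of several learners on the
#' same folds, summarised as per-fold accuracy and Cohen's kappa -- the
#' shape of the standard ensemble-comparison ("which algorithm for this
#' data") plot. Available methods: `"rf"` (in-package random forest),
#' `"tree_boosting"` (AdaBoost.SAMME over shallow CART trees),
#' `"gradient_boosting"` (one-vs-rest logistic boosting on regression
#' stumps) and `"svm"` (linear one-vs-rest Pegasos SVM). These are
#' stand-ins for the gbm/c5.0/SVM ensemble set of the original analysis.
#'
#' @param features Numeric feature data frame / matrix (no missing values).
#' @param labels Class labels; >= 2 classes.
#' @param methods Subset of the four method names above.
#' @param cv_folds Folds per repeat (default 5).
#' @param repeats Number of repeated CV rounds (default 3).
#' @param seed Integer seed (folds and learners are reproducible).
#' @param rf_ntree Trees per forest inside CV (default 200; scaled down from
#'   the production 5000 for tractable resampling).
#' @return An `ensemble_comparison`: list with `results` (method, repeat,
#'   fold, accuracy, kappa) and `summary` (per-method mean/sd).
#' @export
compare_ensembles <- function(features, labels,
                              methods = c("rf", "tree_boosting",
                                          "gradient_boosting", "svm"),
                              cv_folds = 5L, repeats = 3L, seed = 1L,
                              rf_ntree = 200L) {
  known <- c("rf", "tree_boosting", "gradient_boosting", "svm")
  bad <- setdiff(methods, known)
  if (length(bad)) {
    stop("unknown method(s): ", paste(bad, collapse = ", "),
         " (available: ", paste(known, collapse = ", "), ")", call. = FALSE)
  }
  chk <- check_features_labels(features, labels, min_class_n = 2L)
  X <- chk$X; y <- chk$y; k <- length(chk$levels)
  n <- nrow(X)
  set.seed(seed)
  rows <- list()
  for (rep_i in seq_len(repeats)) {
    fold <- integer(n)  # stratified: cycle fold ids within each class
    for (cl in seq_len(k)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(cv_folds), length(idx))
    }
    for (fd in seq_len(cv_folds)) {
      test <- fold == fd
      if (!any(test) || length(unique(y[!test])) < 2) next
      Xtr <- X[!test, , drop = FALSE]; ytr <- y[!test]
      Xte <- X[test, , drop = FALSE]; yte <- y[test]
      for (m in methods) {
        pred_fn <- switch(m,
          rf = train_rf_light(Xtr, ytr, k, ntree = rf_ntree),
          tree_boosting = train_adaboost(Xtr, ytr, k),
          gradient_boosting = train_gbm_stumps(Xtr, ytr, k),
          svm = train_linear_svm(Xtr, ytr, k))
        pr <- pred_fn(Xte)
        conf <- table(factor(yte, levels = seq_len(k)),
                      factor(pr, levels = seq_len(k)))
        kap <- tryCatch(cohen_kappa(conf), error = function(e) NA_real_)
        rows[[length(rows) + 1L]] <- data.frame(
          method = m, rep = rep_i, fold = fd,
          accuracy = mean(pr == yte), kappa = kap, stringsAsFactors = FALSE)
      }
    }
  }
  results <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(results, results$method), function(d) {
    data.frame(method = d$method[1], mean_accuracy = mean(d$accuracy),
               sd_accuracy = stats::sd(d$accuracy),
               mean_kappa = mean(d$kappa, na.rm = TRUE),
               sd_kappa = stats::sd(d$kappa, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  structure(list(results = results, summary = summary, levels = chk$levels),
            class = "ensemble_comparison")
}

#' @export
print.ensemble_comparison <- function(x, ...) {
  cat("Repeated stratified CV comparison:\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
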