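#' Decision-tree parameters
#'
#' CART settings used for marker-threshold extraction: `minsplit = 20` and a
#' complexity parameter in 0.01-0.085 for severity-class trees (0.14 for the
#' ME/CFS-vs-control comparison). `cp` here is the minimum relative
#' Gini-impurity improvement (scaled to the root impurity) a split must
#' achieve to be kept -- a pre-pruning analogue of the classical
#' cost-complexity parameter.
#'
#' @param minsplit Minimum node size eligible for splitting (>= 2).
#' @param cp Complexity parameter (> 0).
#' @param minbucket Minimum size of a child node (default `minsplit %/% 3`,
#'   at least 1).
#' @param max_depth Safety cap on tree depth.
#' @param seed Integer seed (tree growth itself is deterministic; kept for
#'   interface symmetry with the forest).
#' @return An object of class `tree_params`.
#' @export
tree_params <- function(minsplit = 20L, cp = 0.01, minbucket = max(1L, minsplit %/% 3L),
                        max_depth = 30L, seed = 1L) {
  if (minsplit < 2) stop("minsplit must be >= 2", call. = FALSE)
  if (cp <= 0) stop("cp must be > 0", call. = FALSE)
  structure(list(minsplit = as.integer(minsplit), cp = cp,
                 minbucket = as.integer(minbucket),
                 max_depth = as.integer(max_depth), seed = as.integer(seed)),
            class = "tree_params")
}

# Core CART grower: Gini impurity, axis-aligned splits at midpoints between
# distinct sorted values, optional per-node random feature subsampling
# (mtry < p turns it into a forest tree). Splits are kept when the node is
# large enough, both children meet minbucket, and the root-scaled impurity
# improvement reaches cp. Returns parallel node vectors plus per-feature
# accumulated (node-weighted) Gini decreases.
grow_cart <- function(X, y, k, mtry = ncol(X), minsplit = 2L, minbucket = 1L,
                      cp = 0, max_depth = 30L) {
  n <- nrow(X); p <- ncol(X)
  maxn <- 4L * n + 8L
  var <- integer(maxn); split <- numeric(maxn)
  left <- integer(maxn); right <- integer(maxn)
  pred <- integer(maxn); node_n <- integer(maxn); depth <- integer(maxn)
  counts <- matrix(0L, maxn, k)
  gini_dec <- numeric(p)

  tab0 <- tabulate(y, k)
  g_root <- 1 - sum((tab0 / n)^2)
  nodes <- 1L
  stack <- list(list(id = 1L, idx = seq_len(n), depth = 0L))
  while (length(stack)) {
    fr <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    idx <- fr$idx; id <- fr$id
    yy <- y[idx]; nn <- length(idx)
    tab <- tabulate(yy, k)
    counts[id, ] <- tab
    node_n[id] <- nn
    depth[id] <- fr$depth
    pred[id] <- which.max(tab)
    var[id] <- 0L
    if (nn < minsplit || max(tab) == nn || fr$depth >= max_depth || g_root == 0) next

    g_par <- 1 - sum((tab / nn)^2)
    feats <- if (mtry < p) sample.int(p, mtry) else seq_len(p)
    best_dec <- 0; best_f <- 0L; best_cut <- NA_real_
    for (f in feats) {
      xv <- X[idx, f]
      o <- order(xv, method = "radix")
      xs <- xv[o]; ys <- yy[o]
      nl <- seq_len(nn - 1L)
      cut_ok <- xs[-nn] < xs[-1L] & nl >= minbucket & (nn - nl) >= minbucket
      if (!any(cut_ok)) next
      cl <- matrix(0L, nn, k)
      cl[cbind(seq_len(nn), ys)] <- 1L
      cum <- apply(cl, 2, cumsum)
      cuml <- cum[nl, , drop = FALSE]
      gl <- 1 - rowSums((cuml / nl)^2)
      nr <- nn - nl
      cumr <- matrix(cum[nn, ], nn - 1L, k, byrow = TRUE) - cuml
      gr <- 1 - rowSums((cumr / nr)^2)
      dec <- g_par - (nl * gl + nr * gr) / nn
      dec[!cut_ok] <- -Inf
      jbest <- which.max(dec)
      if (dec[jbest] > best_dec + 1e-12) {
        best_dec <- dec[jbest]; best_f <- f
        best_cut <- (xs[jbest] + xs[jbest + 1L]) / 2
      }
    }
    # root-scaled relative improvement gate (pre-pruning analogue of cp)
    if (best_f == 0L || (nn / n) * best_dec / g_root < cp) next

    var[id] <- best_f; split[id] <- best_cut
    l <- nodes + 1L; r <- nodes + 2L; nodes <- nodes + 2L
    left[id] <- l; right[id] <- r
    gini_dec[best_f] <- gini_dec[best_f] + nn * best_dec
    go <- X[idx, best_f] <= best_cut
    stack[[length(stack) + 1L]] <- list(id = l, idx = idx[go], depth = fr$depth + 1L)
    stack[[length(stack) + 1L]] <- list(id = r, idx = idx[!go], depth = fr$depth + 1L)
  }
  keep <- seq_len(nodes)
  list(var = var[keep], split = split[keep], left = left[keep],
       right = right[keep], pred = pred[keep], n = node_n[keep],
       depth = depth[keep], counts = counts[keep, , drop = FALSE],
       gini_decrease = gini_dec, n_train = n)
}

# Vectorised tree traversal; returns leaf node ids.
cart_leaf_of <- function(tree, X) {
  node <- rep(1L, nrow(X))
  repeat {
    v <- tree$var[node]
    act <- which(v > 0L)
    if (!length(act)) break
    xv <- X[cbind(act, v[act])]
    goL <- xv <= tree$split[node[act]]
    node[act] <- ifelse(goL, tree$left[node[act]], tree$right[node[act]])
  }
  node
}

predict_cart <- function(tree, X) tree$pred[cart_leaf_of(tree, X)]

# Validate a feature table + labels for tree/forest fitting; returns a
# numeric matrix, integer labels 1..k and the class level vector.
check_features_labels <- function(features, labels, min_class_n = 2L) {
  X <- as.matrix(as.data.frame(features))
  if (!is.numeric(X)) stop("features must all be numeric", call. = FALSE)
  if (anyNA(X)) {
    stop("features contain missing values: impute before model fitting", call. = FALSE)
  }
  if (nrow(X) != length(labels)) stop("features/labels length mismatch", call. = FALSE)
  f <- factor(labels)
  lev <- levels(f)
  if (length(lev) < 2) stop("need at least 2 classes present", call. = FALSE)
  sizes <- table(f)
  if (any(sizes < min_class_n)) {
    stop("class imbalance: class(es) ",
         paste(names(sizes)[sizes < min_class_n], collapse = ", "),
         " have fewer than ", min_class_n, " cases", call. = FALSE)
  }
  list(X = X, y = as.integer(f), levels = lev)
}

#' Fit a CART decision tree for marker-threshold extraction
#'
#' Grows a Gini-impurity classification tree (all features considered at
#' every node), pre-pruned by `params$cp` and `params$minsplit`, and returns
#' human-readable split rules with per-leaf n and accuracy. Used to read off
#' clinically interpretable marker thresholds (e.g. "ALP <= 62.5 U/L").
#'
#' @param features Data frame / matrix of numeric predictors (no missing
#'   values).
#' @param labels Class labels (factor-able); every class needs >= 2 cases.
#' @param params A [tree_params()].
#' @return An object of class `severity_tree`: `frame` (node table),
#'   `rules` (one row per leaf: `rule`, `class`, `n`, `accuracy`),
#'   `splits` (one row per internal node: `feature`, `threshold`, `n`),
#'   `levels`, `params`. Warns and returns a root-only tree when no split
#'   survives the `cp` gate.
#' @export
fit_decision_tree <- function(features, labels, params = tree_params()) {
  chk <- check_features_labels(features, labels)
  set.seed(params$seed)
  tr <- grow_cart(chk$X, chk$y, k = length(chk$levels),
                  mtry = ncol(chk$X), minsplit = params$minsplit,
                  minbucket = params$minbucket, cp = params$cp,
                  max_depth = params$max_depth)
  feat_names <- colnames(chk$X)
  if (all(tr$var == 0L)) {
    warning("no split survives cp = ", params$cp, ": returning a single-leaf tree",
            call. = FALSE)
  }
  # leaf rules: walk each leaf back to the root
  parent <- integer(length(tr$var)); side <- character(length(tr$var))
  for (i in seq_along(tr$var)) {
    if (tr$var[i] > 0L) {
      parent[tr$left[i]] <- i; side[tr$left[i]] <- "<="
      parent[tr$right[i]] <- i; side[tr$right[i]] <- ">"
    }
  }
  leaves <- which(tr$var == 0L)
  rules <- lapply(leaves, function(lf) {
    conds <- character(0)
    node <- lf
    while (node != 1L) {
      pa <- parent[node]
      conds <- c(sprintf("%s %s %g", feat_names[tr$var[pa]], side[node], tr$split[pa]),
                 conds)
      node <- pa
    }
    data.frame(rule = if (length(conds)) paste(conds, collapse = " & ") else "<root>",
               class = chk$levels[tr$pred[lf]], n = tr$n[lf],
               accuracy = max(tr$counts[lf, ]) / tr$n[lf],
               stringsAsFactors = FALSE)
  })
  rules <- do.call(rbind, rules)
  internal <- which(tr$var > 0L)
  splits <- data.frame(feature = feat_names[tr$var[internal]],
                       threshold = tr$split[internal], n = tr$n[internal],
                       depth = tr$depth[internal], stringsAsFactors = FALSE)
  structure(list(tree = tr, frame = data.frame(
    node = seq_along(tr$var),
    var = ifelse(tr$var > 0L, feat_names[pmax(tr$var, 1L)], "<leaf>"),
    split = ifelse(tr$var > 0L, tr$split, NA_real_),
    n = tr$n, pred = chk$levels[tr$pred], stringsAsFactors = FALSE),
    rules = rules, splits = splits, levels = chk$levels,
    features = feat_names, params = params), class = "severity_tree")
}

#' @export
predict.severity_tree <- function(object, newdata, ...) {
  X <- as.matrix(as.data.frame(newdata)[, object$features, drop = FALSE])
  factor(object$levels[predict_cart(object$tree, X)], levels = object$levels)
}

#' @export
print.severity_tree <- function(x, ...) {
  cat("CART severity tree (minsplit =", x$params$minsplit,
      ", cp =", x$params$cp, ")\n")
  cat("Leaf rules:\n")
  for (i in seq_len(nrow(x$rules))) {
    cat(sprintf("  %s -> class %s (n = %d, accuracy = %.2f)\n",
                x$rules$rule[i], x$rules$class[i], x$rules$n[i], x$rules$accuracy[i]))
  }
  invisible(x)
}
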