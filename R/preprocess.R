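#' Kolmogorov-Smirnov normality screen
#'
#' One-sample K-S test of the values against a normal distribution with mean
#' and SD estimated from the sample, flagging the marker non-normal at
#' `p <= 0.05`. Parameter estimation makes the plain K-S p-value
#' conservative (no Lilliefors correction is applied); the screen is used,
#' as in routine practice, only to choose rank-based tests downstream.
#'
#' @param values Numeric vector, `n >= 3`, finite, non-constant.
#' @param alpha Significance cut-off (default 0.05).
#' @return List with `statistic`, `p_value`, `non_normal`.
#' @export
ks_normality_screen <- function(values, alpha = 0.05) {
  values <- values[!is.na(values)]
  if (length(values) < 3) stop("need at least 3 non-missing values", call. = FALSE)
  if (!all(is.finite(values))) stop("values must be finite", call. = FALSE)
  s <- stats::sd(values)
  if (s == 0) stop("degenerate (constant) input: K-S screen undefined", call. = FALSE)
  kt <- suppressWarnings(
    stats::ks.test(values, "pnorm", mean = mean(values), sd = s)
  )
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       non_normal = kt$p.value <= alpha)
}

#' Class-median imputation
#'
#' Replaces each missing value of the given markers by the median of the
#' observed values within the row's own severity class -- never the pooled
#' median. Observed values are untouched, so every class's observed median
#' is preserved and the operation is idempotent.
#'
#' @param table Cohort data frame.
#' @param markers Marker column names to impute (default: the 24-h urine
#'   marker allow-list, i.e. `"urinary_creatinine"`).
#' @param class_column Grouping column (default the 4-class label `class4`,
#'   since imputation precedes class merging).
#' @return The imputed table.
#' @export
impute_class_median <- function(table, markers = "urinary_creatinine",
                                class_column = "class4") {
  if (!class_column %in% names(table)) {
    stop("class column '", class_column, "' not found", call. = FALSE)
  }
  unknown <- setdiff(markers, names(table))
  if (length(unknown)) {
    stop("unknown marker column(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  cls <- table[[class_column]]
  for (m in markers) {
    x <- table[[m]]
    for (cl in unique(cls)) {
      in_cl <- cls == cl
      nas <- in_cl & is.na(x)
      if (!any(nas)) next
      obs <- x[in_cl & !is.na(x)]
      if (!length(obs)) {
        stop("cannot impute marker '", m, "': class ", cl,
             " has no observed values", call. = FALSE)
      }
      x[nas] <- stats::median(obs)
    }
    table[[m]] <- x
  }
  table
}

#' Per-group median / IQR descriptives
#'
#' Summarises values by group as n, median, and 25th/75th percentiles using
#' linear-interpolation quantiles (`type = 7`) -- the single quantile
#' convention used throughout the package. Empty groups are skipped with a
#' warning.
#'
#' @param values Numeric vector (missing values dropped per group).
#' @param group_labels Vector of group labels, same length as `values`.
#' @return Data frame with columns `group`, `n`, `median`, `q25`, `q75`.
#' @export
describe_by_group <- function(values, group_labels) {
  stopifnot(length(values) == length(group_labels))
  out <- lapply(sort(unique(group_labels)), function(g) {
    x <- values[group_labels == g & !is.na(values)]
    if (!length(x)) {
      warning("group '", g, "' has no observed values: skipped", call. = FALSE)
      return(NULL)
    }
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    data.frame(group = g, n = length(x), median = q[2], q25 = q[1], q75 = q[3])
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Marker-by-group summary table
#'
#' Applies [describe_by_group()] to each marker column, yielding the
#' median/IQR summary shape of the published per-class tables.
#'
#' @param table Cohort data frame.
#' @param markers Marker column names.
#' @param group_column Grouping column name.
#' @return Data frame with columns `marker`, `group`, `n`, `median`, `q25`, `q75`.
#' @export
marker_summaries <- function(table, markers = intersect(wst_markers()$marker, names(table)),
                             group_column = "class4") {
  out <- lapply(markers, function(m) {
    d <- describe_by_group(table[[m]], table[[group_column]])
    if (is.null(d)) return(NULL)
    cbind(marker = m, d, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
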