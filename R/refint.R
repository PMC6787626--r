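#' Median/IQR reference intervals per marker per group
#'
#' "Reference interval" here means the median with the 25th-75th percentile
#' band of a marker within a group -- deliberately narrower than the
#' clinical-chemistry 2.5-97.5% convention, and not interchangeable with
#' it. Intervals can be restricted to the cases a severity forest predicted
#' correctly out-of-bag by passing `correct_mask`.
#'
#' @param table Cohort data frame.
#' @param markers Marker column names (default: the six-marker panel).
#' @param group_column Grouping column (e.g. `"diagnosis"` or `"class3"`).
#' @param correct_mask Optional logical vector (length `nrow(table)`), e.g.
#'   the correct-OOB-prediction mask; rows where it is `FALSE` are dropped
#'   before interval calculation. An error names any group the mask empties.
#' @return Data frame of class `reference_intervals`: `marker`, `group`,
#'   `n`, `median`, `q25`, `q75`, `correct_only`.
#' @export
class_reference_intervals <- function(table, markers = default_feature_panel(),
                                      group_column = "class3",
                                      correct_mask = NULL) {
  if (!group_column %in% names(table)) {
    stop("group column '", group_column, "' not found", call. = FALSE)
  }
  groups_all <- unique(table[[group_column]])
  correct_only <- !is.null(correct_mask)
  if (correct_only) {
    stopifnot(is.logical(correct_mask), length(correct_mask) == nrow(table))
    sub <- table[correct_mask & !is.na(correct_mask), , drop = FALSE]
    gone <- setdiff(groups_all, unique(sub[[group_column]]))
    if (length(gone)) {
      stop("restriction mask empties group(s): ", paste(gone, collapse = ", "),
           call. = FALSE)
    }
    table <- sub
  }
  out <- lapply(markers, function(m) {
    d <- describe_by_group(table[[m]], table[[group_column]])
    cbind(marker = m, d, correct_only = correct_only, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("reference_intervals", "data.frame")
  out
}

#' Overlap between two reference intervals of the same marker
#'
#' Two closed (q25, q75) bands overlap unless one's lower quartile exceeds
#' the other's upper quartile; touching endpoints count as overlap. The
#' returned width is signed: the overlap length when positive, the size of
#' the gap (negated) when negative.
#'
#' @param a,b Single rows of a [class_reference_intervals()] result (or any
#'   list-likes with `marker`, `group`, `q25`, `q75`).
#' @return Data frame: `marker`, `group_a`, `group_b`, `overlap`,
#'   `width` (signed overlap/gap).
#' @export
interval_overlap <- function(a, b) {
  if (!identical(as.character(a$marker), as.character(b$marker))) {
    stop("intervals describe different markers: ", a$marker, " vs ", b$marker,
         call. = FALSE)
  }
  width <- min(a$q75, b$q75) - max(a$q25, b$q25)
  data.frame(marker = as.character(a$marker),
             group_a = as.character(a$group), group_b = as.character(b$group),
             overlap = width >= 0, width = width, stringsAsFactors = FALSE)
}

#' All pairwise interval overlaps within each marker
#'
#' Applies [interval_overlap()] to every group pair of every marker in a
#' reference-interval table, yielding the between-class separation report
#' used to nominate markers whose severity-class bands do not overlap.
#'
#' @param ri A [class_reference_intervals()] result.
#' @return Data frame with one row per marker x group pair.
#' @export
interval_overlap_report <- function(ri) {
  out <- lapply(split(seq_len(nrow(ri)), ri$marker), function(idx) {
    if (length(idx) < 2) return(NULL)
    pairs <- utils::combn(idx, 2, simplify = FALSE)
    do.call(rbind, lapply(pairs, function(pr) {
      interval_overlap(ri[pr[1], ], ri[pr[2], ])
    }))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
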