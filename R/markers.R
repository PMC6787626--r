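#' Marker panel metadata
#'
#' Names, labels and units of the marker panel carried by a cohort table.
#' `urinary_creatinine` is the 24-h urinary creatinine excretion rate, the
#' marker family affected by urine-collection non-compliance (and hence the
#' default target of missing-value injection and class-median imputation).
#'
#' @return Data frame with columns `marker`, `label`, `units`.
#' @export
wst_markers <- function() {
  data.frame(
    marker = c("mch", "lymphocytes", "neutrophils", "platelets", "sodium",
               "bicarbonate", "urea", "serum_creatinine", "alp", "pth",
               "urinary_creatinine", "activin_b", "dass_total", "epworth", "age"),
    label = c("MCH", "Lymphocytes", "Neutrophils", "Platelets", "Serum sodium",
              "Serum bicarbonate", "Serum urea", "Serum creatinine",
              "Alkaline phosphatase (ALP)", "Parathyroid hormone (PTH)",
              "24-h urinary creatinine excretion rate", "Activin B",
              "DASS total score", "Epworth sleep scale", "Age"),
    units = c("pg", "1e9/L", "1e9/L", "1e9/L", "mmol/L", "mmol/L", "mmol/L",
              "umol/L", "U/L", "pmol/L", "mmol/24 h", "pg/mL", "score",
              "score", "years"),
    stringsAsFactors = FALSE
  )
}

#' Default feature panel for the severity model
#'
#' The six-marker constellation found most predictive of merged severity
#' class: MCH, lymphocytes, serum urea, ALP, 24-h urinary creatinine
#' excretion and activin B.
#'
#' @return Character vector of column names.
#' @export
default_feature_panel <- function() {
  c("mch", "lymphocytes", "urea", "alp", "urinary_creatinine", "activin_b")
}

# Published per-class marker summaries (median, q25, q75) for the four WST
# severity classes; the basis of the default synthetic generator. Two serum
# sodium rows print a median outside its own IQR in the source table
# (presumed typos); those triples are stored here re-sorted so that
# q25 <= median <= q75 holds.
class_summary_rows <- function() {
  r <- function(marker, class_id, med, q25, q75) {
    data.frame(marker = marker, class4 = class_id, median = med,
               q25 = q25, q75 = q75, stringsAsFactors = FALSE)
  }
  rbind(
    r("mch", 0:3, c(30.8, 30.6, 30.3, 30.9), c(29.4, 30.0, 28.7, 30.2), c(31.5, 31.2, 31.0, 31.6)),
    r("lymphocytes", 0:3, c(2.3, 1.8, 2.0, 2.1), c(1.9, 1.5, 1.5, 1.8), c(2.6, 2.8, 2.3, 2.5)),
    r("neutrophils", 0:3, c(4.3, 3.6, 4.1, 3.5), c(3.4, 2.6, 2.9, 2.5), c(5.4, 4.8, 4.9, 4.5)),
    r("platelets", 0:3, c(264, 244, 258, 273), c(235, 203, 227, 251), c(297, 308, 307, 300)),
    # sodium classes 1 and 3 re-sorted (source prints 140.8 (141.5-142), 140 (141-142))
    r("sodium", 0:3, c(141, 141.5, 141, 141), c(139.5, 140.8, 141, 140), c(142, 142, 142, 142)),
    r("bicarbonate", 0:3, c(29, 30, 29, 29), c(28, 27, 28, 27), c(30.5, 32.3, 31.5, 30)),
    r("urea", 0:3, c(5.5, 5.1, 5.4, 4.5), c(4.75, 3.8, 4.0, 4.0), c(7.9, 5.6, 6.1, 5.1)),
    r("serum_creatinine", 0:3, c(76, 73.5, 76, 71), c(67.5, 68, 66.5, 65), c(82.5, 93, 85.5, 77)),
    r("alp", 0:3, c(65, 64, 72, 60), c(52, 53, 62, 45), c(77.5, 78, 84.5, 74)),
    r("pth", 0:3, c(7.7, 5.7, 5.6, 5.2), c(5.2, 3.7, 3.7, 2.9), c(8.8, 6.8, 7.5, 6.5)),
    r("urinary_creatinine", 0:3, c(13.1, 10, 9.4, 10.2), c(10.8, 7.8, 7.7, 9.2), c(17.2, 14.4, 12.2, 10.9)),
    r("activin_b", 0:3, c(114.19, 89.48, 79.97, 89.74), c(92.21, 59.97, 71.00, 70.48), c(162.24, 147.17, 106.97, 133.19)),
    r("dass_total", 0:3, c(8, 25, 28, 28), c(4, 10.3, 15.3, 16.3), c(11.5, 36.3, 47.3, 54.5)),
    r("epworth", 0:3, c(4, 4, 7, 6.5), c(3, 1.5, 3, 3.3), c(6.5, 5.8, 12, 10.8)),
    r("age", 0:3, c(41, 45, 55, 42), c(29, 39, 43, 36), c(51, 50, 61.5, 53))
  )
}

#' Default per-class marker distribution specifications
#'
#' One row per (marker, severity class): the published median and 25th-75th
#' IQR of each marker within each 4-class WST severity group. These
#' summaries parameterise the log-normal marginals of [generate_cohort()].
#'
#' @return Data frame with columns `marker`, `class4`, `median`, `q25`, `q75`.
#' @export
class_marker_specs <- function() {
  specs <- class_summary_rows()
  stopifnot(all(specs$q25 <= specs$median), all(specs$median <= specs$q75),
            all(specs$q25 > 0))
  specs
}

#' Published class sizes of the study cohort
#'
#' 17 healthy controls and 19/38/23 mild/moderate/severe ME/CFS cases
#' (97 participants in total; 36 in the merged class 0).
#'
#' @return Named integer vector (names `"0"`-`"3"`).
#' @export
default_class_sizes <- function() {
  c(`0` = 17L, `1` = 19L, `2` = 38L, `3` = 23L)
}
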