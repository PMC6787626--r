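#' Configuration of the synthetic cohort generator
#'
#' Bundles everything [generate_cohort()] needs: per-class sizes, per-class
#' marker quantile specifications, the missingness rate of the 24-h urine
#' markers, per-class POTS prevalence, and the seed.
#'
#' @param class_sizes Named integer vector of participants per 4-class
#'   severity class (names `"0"`-`"3"`); zero-size classes are allowed.
#' @param marker_specs Data frame with columns `marker`, `class4`, `median`,
#'   `q25`, `q75`; one row per (marker, class) pair for every non-empty class.
#' @param urine_missing_rate Fraction in `[0, 1)` of values of
#'   `missing_markers` set missing, emulating urine-collection
#'   non-compliance (reported as 15-20%; default 0.175).
#' @param missing_markers Markers subject to missingness injection.
#' @param pots_rate Named numeric vector of POTS prevalence per class.
#'   Defaults to 0 for healthy controls and 0.30 for ME/CFS classes.
#' @param seed Integer seed; identical configs and seeds give
#'   byte-identical cohorts.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(class_sizes = default_class_sizes(),
                          marker_specs = class_marker_specs(),
                          urine_missing_rate = 0.175,
                          missing_markers = "urinary_creatinine",
                          pots_rate = c(`0` = 0, `1` = 0.3, `2` = 0.3, `3` = 0.3),
                          seed = 1L) {
  class_sizes <- as.integer(class_sizes)
  if (is.null(names(class_sizes)) || !all(names(class_sizes) %in% as.character(0:3))) {
    names(class_sizes) <- as.character(seq_along(class_sizes) - 1L)
  }
  if (any(class_sizes < 0)) stop("class sizes must be non-negative", call. = FALSE)
  if (urine_missing_rate < 0 || urine_missing_rate >= 1) {
    stop("urine_missing_rate must be in [0, 1)", call. = FALSE)
  }
  need <- c("marker", "class4", "median", "q25", "q75")
  if (!all(need %in% names(marker_specs))) {
    stop("marker_specs must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (!all(missing_markers %in% unique(marker_specs$marker))) {
    stop("missing_markers must name markers present in marker_specs", call. = FALSE)
  }
  structure(list(class_sizes = class_sizes, marker_specs = marker_specs,
                 urine_missing_rate = urine_missing_rate,
                 missing_markers = missing_markers,
                 pots_rate = pots_rate, seed = as.integer(seed)),
            class = "cohort_config")
}

# Draw a Table-1a-consistent (standing_time, difficulty) pair per class.
draw_standing_test <- function(class_id, n) {
  if (n == 0L) return(data.frame(standing_time = numeric(0), difficulty = integer(0)))
  if (class_id == 0L) {
    data.frame(standing_time = rep(20, n), difficulty = sample(1:4, n, replace = TRUE))
  } else if (class_id == 1L) {
    data.frame(standing_time = rep(20, n), difficulty = sample(1:3, n, replace = TRUE))
  } else if (class_id == 2L) {
    data.frame(standing_time = rep(20, n), difficulty = sample(4:10, n, replace = TRUE))
  } else {
    t3 <- sample(seq(0, 18, by = 2), n, replace = TRUE)
    data.frame(standing_time = t3, difficulty = ifelse(t3 < 10, 14L, 12L))
  }
}

#' Generate a seeded synthetic cohort
#'
#' Emulates the structure the severity analysis assumes: per-class sizes, a
#' (standing time, difficulty) pair drawn uniformly from each class's
#' definition, supine/standing heart rates with configurable POTS
#' prevalence, and one independent log-normal draw per marker from that
#' class's (median, q25, q75) specification (median matched exactly,
#' quartiles in ratio; see [fit_lognormal_from_quantiles()]). Markers are
#' generated independently within class -- no within-class correlation
#' structure is imposed. Missingness at `config$urine_missing_rate` is then
#' injected into `config$missing_markers`.
#'
#' @param config A [cohort_config()].
#' @return Data frame with one row per participant: `participant_id`,
#'   `diagnosis` (`"HC"` for class 0, else `"ME/CFS"`), `standing_time`,
#'   `difficulty`, `hr_supine`, `hr_standing_max`, and one column per marker.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) stop("config must be a cohort_config", call. = FALSE)
  set.seed(config$seed)
  specs <- config$marker_specs
  markers <- unique(specs$marker)
  rows <- list()
  for (cl in names(config$class_sizes)) {
    n <- config$class_sizes[[cl]]
    if (n == 0L) next
    cli <- as.integer(cl)
    st <- draw_standing_test(cli, n)
    hr_supine <- pmax(45, round(stats::rnorm(n, mean = 70, sd = 8)))
    p_pots <- if (cl %in% names(config$pots_rate)) config$pots_rate[[cl]] else 0
    is_pots <- stats::runif(n) < p_pots
    delta <- ifelse(is_pots, stats::runif(n, 30, 55), stats::runif(n, 5, 25))
    df <- data.frame(
      diagnosis = if (cli == 0L) "HC" else "ME/CFS",
      standing_time = st$standing_time, difficulty = st$difficulty,
      hr_supine = hr_supine, hr_standing_max = round(hr_supine + delta),
      stringsAsFactors = FALSE
    )
    for (m in markers) {
      row <- specs[specs$marker == m & specs$class4 == cli, ]
      if (nrow(row) != 1L) {
        stop("marker spec missing for marker '", m, "' in class ", cl, call. = FALSE)
      }
      par <- fit_lognormal_from_quantiles(row$median, row$q25, row$q75)
      df[[m]] <- if (par$sdlog == 0) rep(row$median, n) else
        stats::rlnorm(n, meanlog = par$meanlog, sdlog = par$sdlog)
    }
    rows[[cl]] <- df
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- cbind(participant_id = sprintf("P%03d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  if (config$urine_missing_rate > 0) {
    out <- inject_missingness(out, config$missing_markers,
                              rate = config$urine_missing_rate,
                              seed = config$seed + 1L)
  }
  out
}

#' Inject missing values into named marker columns
#'
#' Each value of each named marker is independently set to `NA` with
#' probability `rate`; other columns are untouched. Seeded and reproducible.
#'
#' @param table Cohort data frame.
#' @param markers Character vector of marker column names.
#' @param rate Missingness probability in `[0, 1)`.
#' @param seed Integer seed.
#' @return The table with missing values injected.
#' @export
inject_missingness <- function(table, markers, rate, seed = 1L) {
  if (rate < 0 || rate >= 1) stop("rate must be in [0, 1)", call. = FALSE)
  unknown <- setdiff(markers, names(table))
  if (length(unknown)) {
    stop("unknown marker column(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (rate == 0) return(table)
  set.seed(seed)
  for (m in markers) {
    drop <- stats::runif(nrow(table)) < rate
    table[[m]][drop] <- NA
  }
  table
}

#' Write / read a cohort CSV
#'
#' The on-disk format is a plain CSV with one header row, one row per
#' participant, and empty fields for missing values. `read_cohort()`
#' validates the schema (required identity/standing-test columns plus at
#' least one numeric marker), coerces marker columns to numeric, and logs
#' row counts and per-column missingness via `message()`.
#'
#' @param table Cohort data frame.
#' @param path File path; `read_cohort()` treats `.tsv`/`.txt` as
#'   tab-separated, anything else as comma-separated.
#' @return `read_cohort()` returns the validated data frame;
#'   `write_cohort()` returns `path` invisibly.
#' @export
write_cohort <- function(table, path) {
  utils::write.table(table, path, sep = if (grepl("\\.(tsv|txt)$", path)) "\t" else ",",
                     row.names = FALSE, na = "", qmethod = "double")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  sep <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep, na.strings = "",
                           stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("diagnosis", "standing_time", "difficulty", "hr_supine", "hr_standing_max")
  miss <- setdiff(required, names(tab))
  if (length(miss)) {
    stop("cohort file lacks required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  marker_cols <- setdiff(names(tab), c("participant_id", "diagnosis"))
  for (m in marker_cols) {
    if (!is.numeric(tab[[m]])) {
      coerced <- suppressWarnings(as.numeric(tab[[m]]))
      bad <- which(is.na(coerced) & !is.na(tab[[m]]))
      if (length(bad)) {
        stop("non-numeric value in column '", m, "' at row ", bad[1], call. = FALSE)
      }
      tab[[m]] <- coerced
    }
  }
  n_miss <- vapply(tab, function(x) sum(is.na(x)), integer(1))
  message(sprintf("read_cohort: %d rows, %d columns; missing values: %s",
                  nrow(tab), ncol(tab),
                  if (sum(n_miss) == 0) "none" else
                    paste(sprintf("%s=%d", names(n_miss)[n_miss > 0], n_miss[n_miss > 0]),
                          collapse = ", ")))
  tab
}
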