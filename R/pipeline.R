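# Derive a reproducible per-stage seed from the global seed, so stages can
# be re-run in isolation with the same stream they had inside the pipeline.
stage_seed <- function(seed, stage) {
  u <- utf8ToInt(stage)
  h <- sum(u * seq_along(u)) %% 100000
  as.integer((abs(as.numeric(seed)) %% 1e6 * 131 + h) %% 2147483647)
}

#' Pipeline configuration
#'
#' Bundles the end-to-end analysis settings. Exactly one input source is
#' used: a cohort CSV/TSV (`input_path`) or a synthetic [cohort_config()]
#' (`cohort`; the default when both are `NULL`). One global `seed` fans out
#' to per-stage derived seeds (stable hash of the stage name), so the
#' synthetic cohort, the forest and the ensemble comparison are individually
#' reproducible.
#'
#' @param input_path Optional path to a cohort file (see [read_cohort()]).
#' @param cohort Optional [cohort_config()]; its seed is overridden by the
#'   pipeline's derived stage seed.
#' @param feature_panel Marker columns fed to the severity model.
#' @param alpha Significance level for the test batteries (default 0.05).
#' @param rf An [rf_params()]; the seed is overridden per stage.
#' @param tree A [tree_params()].
#' @param impute_markers Markers imputed by class median (default the 24-h
#'   urine allow-list).
#' @param correct_only Also compute correct-prediction-restricted ROC
#'   curves and reference intervals (default `TRUE`).
#' @param output_dir Directory for artefacts (`NULL` = return-only).
#' @param seed Global integer seed.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(input_path = NULL, cohort = NULL,
                            feature_panel = default_feature_panel(),
                            alpha = 0.05, rf = rf_params(), tree = tree_params(),
                            impute_markers = "urinary_creatinine",
                            correct_only = TRUE, output_dir = NULL, seed = 1L) {
  if (!is.null(input_path) && !is.null(cohort)) {
    stop("give exactly one of input_path or cohort", call. = FALSE)
  }
  if (is.null(input_path) && is.null(cohort)) cohort <- cohort_config()
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  structure(list(input_path = input_path, cohort = cohort,
                 feature_panel = feature_panel, alpha = alpha, rf = rf,
                 tree = tree, impute_markers = impute_markers,
                 correct_only = correct_only, output_dir = output_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

fmt_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE, na = "")
}

md_table <- function(df, digits = 3) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, digits))
  header <- paste("|", paste(names(df), collapse = " | "), "|")
  sep <- paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|")
  body <- apply(df, 1, function(r) paste("|", paste(r, collapse = " | "), "|"))
  c(header, sep, body)
}

#' Run the end-to-end severity analysis pipeline
#'
#' Executes, in order: cohort synthesis or ingest; WST scoring and class
#' assignment; class-median imputation; normality screening and median/IQR
#' descriptives; the Mann-Whitney / Kruskal-Wallis / Jonckheere-Terpstra
#' test batteries; the random-forest severity model with OOB evaluation;
#' a pruned decision tree for marker thresholds; pairwise severity-class
#' ROC/AUC (all cases and, optionally, correctly predicted cases only); and
#' reference intervals with between-class overlap assessment. With an
#' `output_dir`, per-stage TSV/JSON artefacts and a markdown summary report
#' are written; identical config + seed gives byte-identical artefacts.
#'
#' @param config A [pipeline_config()].
#' @return (Invisibly) the report bundle: `cohort` (scored + imputed),
#'   `summaries`, `diagnosis_tests`, `class_tests`, `model`, `tree`,
#'   `rocs` (named list), `auc` (data frame), `intervals`, `overlaps`,
#'   `report` (character lines), `paths` (written files).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    stop("config must be a pipeline_config", call. = FALSE)
  }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  # -- ingest / synthesise ---------------------------------------------------
  cohort <- run_stage("cohort", {
    if (!is.null(config$input_path)) {
      read_cohort(config$input_path)
    } else {
      cc <- config$cohort
      cc$seed <- stage_seed(config$seed, "synth")
      generate_cohort(cc)
    }
  })
  n_missing <- vapply(cohort, function(x) sum(is.na(x)), integer(1))

  # -- score + impute --------------------------------------------------------
  cohort <- run_stage("score", score_standing_tests(cohort))
  cohort <- run_stage("impute", impute_class_median(
    cohort, markers = intersect(config$impute_markers, names(cohort)),
    class_column = "class4"))

  panel <- config$feature_panel
  miss_panel <- setdiff(panel, names(cohort))
  if (length(miss_panel)) {
    stop("pipeline stage 'model' failed: panel column(s) absent: ",
         paste(miss_panel, collapse = ", "), call. = FALSE)
  }

  # -- descriptives + tests --------------------------------------------------
  summaries <- run_stage("describe", marker_summaries(cohort, panel, "class3"))
  diagnosis_tests <- run_stage("tests", diagnosis_test_battery(cohort, panel,
                                                               alpha = config$alpha))
  class_tests <- run_stage("tests", marker_test_battery(cohort, panel,
                                                        group_column = "class3",
                                                        alpha = config$alpha))

  # -- severity model --------------------------------------------------------
  rf <- config$rf
  rf$seed <- stage_seed(config$seed, "model")
  model <- run_stage("model", fit_rf(cohort[, panel], cohort$class3, rf))
  kappa <- cohen_kappa(model$oob_confusion)

  tree_par <- config$tree
  tree_par$seed <- stage_seed(config$seed, "tree")
  tree <- run_stage("tree", fit_decision_tree(cohort[, panel], cohort$class3, tree_par))

  # -- ROC -------------------------------------------------------------------
  pairs <- list(c("0", "1"), c("0", "2"), c("1", "2"))
  restrictions <- if (config$correct_only) c(FALSE, TRUE) else FALSE
  rocs <- list()
  for (pr in pairs) {
    for (co in restrictions) {
      key <- paste0(pr[1], "v", pr[2], if (co) "_correct" else "_all")
      rocs[[key]] <- run_stage("roc", pairwise_class_roc(model, cohort, pr,
                                                         correct_only = co))
    }
  }
  auc <- do.call(rbind, lapply(names(rocs), function(k) {
    r <- rocs[[k]]
    data.frame(comparison = k, class_a = r$class_pair[1], class_b = r$class_pair[2],
               correct_only = r$restricted_to_correct, auc = r$auc,
               n_pos = r$n_pos, n_neg = r$n_neg, stringsAsFactors = FALSE)
  }))

  # -- reference intervals ---------------------------------------------------
  mask <- !is.na(model$oob_predictions) & model$oob_predictions == model$labels
  intervals <- run_stage("ri", {
    ri <- rbind(
      cbind(criterion = "diagnosis",
            class_reference_intervals(cohort, panel, "diagnosis")),
      cbind(criterion = "class3",
            class_reference_intervals(cohort, panel, "class3"))
    )
    if (config$correct_only) {
      ri <- rbind(ri,
        cbind(criterion = "diagnosis",
              class_reference_intervals(cohort, panel, "diagnosis", correct_mask = mask)),
        cbind(criterion = "class3",
              class_reference_intervals(cohort, panel, "class3", correct_mask = mask)))
    }
    ri
  })
  ri_class <- intervals[intervals$criterion == "class3" &
                          intervals$correct_only == config$correct_only, ]
  class(ri_class) <- c("reference_intervals", "data.frame")
  overlaps <- run_stage("ri", interval_overlap_report(ri_class))

  # -- report ----------------------------------------------------------------
  cls4 <- table(cohort$class4); cls3 <- table(cohort$class3)
  report <- c(
    "# Severity analysis report", "",
    sprintf("Cohort: %d participants (%s).", nrow(cohort),
            if (is.null(config$input_path)) "synthetic" else config$input_path),
    sprintf("4-class sizes: %s; merged 3-class sizes: %s.",
            paste(sprintf("%s=%d", names(cls4), cls4), collapse = ", "),
            paste(sprintf("%s=%d", names(cls3), cls3), collapse = ", ")),
    sprintf("Missing values before imputation: %s.",
            if (sum(n_missing) == 0) "none" else
              paste(sprintf("%s=%d", names(n_missing)[n_missing > 0],
                            n_missing[n_missing > 0]), collapse = ", ")),
    "", "## Marker summaries (median, 25th-75th IQR) by merged class", "",
    md_table(summaries),
    "", "## ME/CFS vs healthy controls (Mann-Whitney U, K-S screen)", "",
    md_table(diagnosis_tests),
    "", "## Severity-class battery (Kruskal-Wallis + Jonckheere-Terpstra)", "",
    md_table(class_tests),
    "", "## Random-forest severity model", "",
    sprintf("OOB error: %.2f%% overall; Cohen's kappa %.3f.",
            100 * model$oob_error_overall, kappa),
    sprintf("Permutation-importance ranking: %s.",
            paste(model$ranking_permutation, collapse = " > ")),
    sprintf("Gini-importance ranking: %s.",
            paste(model$ranking_gini, collapse = " > ")),
    "", "### Decision-tree threshold rules", "",
    sprintf("- %s -> class %s (n = %d, accuracy = %.2f)",
            tree$rules$rule, tree$rules$class, tree$rules$n, tree$rules$accuracy),
    "", "## Pairwise ROC/AUC between severity classes", "",
    md_table(auc),
    "", "## Reference intervals (median, 25th-75th IQR)", "",
    md_table(intervals),
    "", "### Between-class interval separations (merged classes)", "",
    md_table(overlaps)
  )

  paths <- character(0)
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    out <- function(name) file.path(config$output_dir, name)
    write_cohort(cohort, out("cohort_scored.csv"))
    fmt_tsv(summaries, out("marker_summaries.tsv"))
    fmt_tsv(diagnosis_tests, out("tests_diagnosis.tsv"))
    fmt_tsv(class_tests, out("tests_classes.tsv"))
    fmt_tsv(auc, out("roc_auc.tsv"))
    for (k in names(rocs)) fmt_tsv(rocs[[k]]$points, out(paste0("roc_points_", k, ".tsv")))
    fmt_tsv(intervals, out("reference_intervals.tsv"))
    fmt_tsv(overlaps, out("interval_overlaps.tsv"))
    model_json <- list(
      params = unclass(model$params),
      oob_error_overall = model$oob_error_overall,
      oob_error_per_class = as.list(model$oob_error_per_class),
      kappa = kappa,
      confusion = as.data.frame(model$oob_confusion),
      importance_gini = as.list(model$importance_gini),
      importance_permutation = as.list(model$importance_permutation),
      oob_predictions = as.character(model$oob_predictions)
    )
    jsonlite::write_json(model_json, out("model.json"), auto_unbox = TRUE,
                         digits = 10, pretty = TRUE)
    writeLines(report, out("report.md"))
    paths <- c(out("cohort_scored.csv"), out("marker_summaries.tsv"),
               out("tests_diagnosis.tsv"), out("tests_classes.tsv"),
               out("roc_auc.tsv"), out("reference_intervals.tsv"),
               out("interval_overlaps.tsv"), out("model.json"), out("report.md"))
  }

  invisible(list(cohort = cohort, summaries = summaries,
                 diagnosis_tests = diagnosis_tests, class_tests = class_tests,
                 model = model, kappa = kappa, tree = tree, rocs = rocs,
                 auc = auc, intervals = intervals, overlaps = overlaps,
                 report = report, paths = paths))
}
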