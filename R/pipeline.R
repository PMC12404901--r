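## End-to-end orchestration: simulate / analyze / roc. These functions are
## the tested pipeline surface; inst/cli/ipss-cli.R is a thin shell wrapper
## over them. All outputs are plain CSV (or text) with a leading provenance
## comment so runs diff cleanly.

.provLine <- function(...) {
  paste0("ipss ", as.character(utils::packageVersion("ipss")), " ", ...)
}

.ruleMethodColumn <- function(rule) {
  ## which score column an adjusted rule consumes
  if (grepl("concurrent", rule$name)) "concurrent_peak" else "basal_peak"
}

#' Simulate a cohort and write it to disk
#'
#' Writes `measurements.csv` and `metadata.csv` in the package CSV dialect
#' plus `truth.csv` (`procedure_id,true_label,dominant_side,dilution_left,
#' dilution_right`). Identical inputs and seed produce identical files.
#'
#' @param outDir Output directory (created if needed).
#' @param preset Name of a [scenarioPresets()] entry, ignored when `config`
#'   is given.
#' @param n Number of procedures (overrides the config).
#' @param seed Root seed (overrides the config).
#' @param config Optional explicit [ipssConfig()].
#' @return Invisibly, the list from [simulateCohort()].
#' @export
runSimulate <- function(outDir, preset = "dilution", n = NULL, seed = NULL,
                        config = NULL) {
  if (is.null(config)) {
    presets <- scenarioPresets()
    if (!preset %in% names(presets))
      stop("unknown preset '", preset, "'; available: ",
           paste(names(presets), collapse = ", "))
    config <- presets[[preset]]
  }
  if (!is.null(n)) {
    if (n < 1) stop("n must be positive")
    config$nProcedures <- n
  }
  if (!is.null(seed)) config$seed <- seed
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulateCohort(config)
  prov <- .provLine("simulate preset=", preset, " n=", config$nProcedures,
                    " seed=", config$seed)
  writeCohortCsv(sim$cohort,
                 file.path(outDir, "measurements.csv"),
                 file.path(outDir, "metadata.csv"),
                 comment = prov)
  truth <- sim$truth
  names(truth) <- c("procedure_id", "true_label", "dominant_side",
                    "dilution_left", "dilution_right",
                    "gradient_left", "gradient_right")
  con <- file(file.path(outDir, "truth.csv"), "wt")
  writeLines(paste0("# ", prov), con)
  utils::write.csv(truth, con, row.names = FALSE, quote = FALSE)
  close(con)
  invisible(sim)
}

#' Analyze a cohort: scores, calls and an evaluation summary
#'
#' Reads a cohort, writes the per-procedure score table (`scores.csv`), one
#' calls file per rule (`calls_<rule>.csv`), and — when reference labels are
#' present — an evaluation summary (`summary.txt`) with contingency counts,
#' sensitivity and specificity per rule. Unlabeled cohorts get scores and
#' calls only.
#'
#' @param measurementsPath,metadataPath Input CSV paths
#'   (see [readCohortCsv()]).
#' @param outDir Output directory.
#' @param rules Character vector of rule names from [builtinRules()].
#' @param basalTime Basal sample selection, see [peakActhRatio()].
#' @return Invisibly, a list with `scores`, `calls` (named by rule) and
#'   `summary` (named list of [sensSpec()] results, or NULL).
#' @export
runAnalyze <- function(measurementsPath, metadataPath, outDir,
                       rules = c("standard_unadjusted", "basal_optimal",
                                 "concurrent_optimal"),
                       basalTime = "t0") {
  allRules <- builtinRules()
  unknown <- setdiff(rules, names(allRules))
  if (length(unknown))
    stop("unknown rule name(s): ", paste(unknown, collapse = ", "))
  cohort <- readCohortCsv(measurementsPath, metadataPath)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  scores <- cohortScores(cohort, basalTime = basalTime)
  prov <- .provLine("analyze rules=", paste(rules, collapse = "+"))
  writeScores <- function(df, path) {
    con <- file(path, "wt")
    writeLines(paste0("# ", prov), con)
    utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
    close(con)
  }
  writeScores(scores, file.path(outDir, "scores.csv"))

  labels <- referenceLabels(cohort)
  labeled <- any(labels %in% c("CD", "EAS"))
  calls <- list()
  summaries <- if (labeled) list() else NULL
  for (rn in rules) {
    rule <- allRules[[rn]]
    cc <- classifyCohort(scores, rule, method = .ruleMethodColumn(rule))
    calls[[rn]] <- cc
    writeScores(cc, file.path(outDir, paste0("calls_", rn, ".csv")))
    if (labeled)
      summaries[[rn]] <- sensSpec(contingency(cc$call, unname(labels)))
  }
  if (labeled) {
    lines <- c(paste0("# ", prov))
    for (rn in rules) {
      cnt <- contingency(calls[[rn]]$call, unname(labels))
      ss <- summaries[[rn]]
      lines <- c(lines, sprintf(
        "%s: TP %d FP %d FN %d TN %d indeterminate %d | sensitivity %.1f%% specificity %.1f%%",
        rn, cnt$TP, cnt$FP, cnt$FN, cnt$TN, cnt$nIndeterminate,
        ss$sensitivity, ss$specificity))
    }
    writeLines(lines, file.path(outDir, "summary.txt"))
  } else {
    message("no reference labels present; evaluation skipped")
  }
  invisible(list(scores = scores, calls = calls, summary = summaries))
}

#' ROC analysis of the adjusted scores of a labeled cohort
#'
#' Computes the ROC curve of each adjustment method's scores against the
#' reference labels, writes per-method point files
#' (`roc_<method>.csv`: `threshold,fpr,tpr`) and a summary with AUC and the
#' Youden-optimal cut-off.
#'
#' @inheritParams runAnalyze
#' @param methods Score columns to analyze.
#' @return Invisibly, a named list of `ipssRoc` objects.
#' @export
runRoc <- function(measurementsPath, metadataPath, outDir,
                   methods = c("basal_peak", "concurrent_peak"),
                   basalTime = "t0") {
  cohort <- readCohortCsv(measurementsPath, metadataPath)
  labels <- referenceLabels(cohort)
  if (!all(c("CD", "EAS") %in% labels))
    stop("ROC analysis needs both CD and EAS reference labels")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  scores <- cohortScores(cohort, basalTime = basalTime)
  prov <- .provLine("roc methods=", paste(methods, collapse = "+"))
  rocs <- list()
  lines <- paste0("# ", prov)
  for (m in methods) {
    roc <- rocCurve(scores[[m]], unname(labels))
    rocs[[m]] <- roc
    con <- file(file.path(outDir, paste0("roc_", m, ".csv")), "wt")
    writeLines(paste0("# ", prov), con)
    utils::write.csv(roc$points, con, row.names = FALSE, quote = FALSE)
    close(con)
    lines <- c(lines, sprintf("%s: AUC %.3f optimal_cutoff %.3g", m,
                              roc$auc, roc$optimalCutoff))
  }
  writeLines(lines, file.path(outDir, "roc_summary.txt"))
  invisible(rocs)
}
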