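## Diagnostic-performance statistics. CD is the positive class throughout;
## denominators count procedures, not patients. Indeterminate calls are
## bookkept separately and reduce denominators rather than counting as
## errors.

#' Contingency counts against reference labels
#'
#' @param calls Character vector of calls (`"CD"`, `"EAS"`,
#'   `"indeterminate"`; NA calls are dropped with their labels), or the
#'   data.frame from [classifyCohort()] (its `call` column is used).
#' @param labels Character vector of reference labels aligned with `calls`;
#'   `"unknown"` labels are excluded.
#' @return List of class `ipssCounts`: `TP`, `FP`, `FN`, `TN`,
#'   `nIndeterminate`.
#' @export
contingency <- function(calls, labels) {
  if (is.data.frame(calls)) calls <- calls$call
  if (length(calls) != length(labels))
    stop("calls and labels must be aligned")
  keep <- labels %in% c("CD", "EAS") & !is.na(calls)
  calls <- calls[keep]; labels <- labels[keep]
  if (!length(calls)) stop("no labeled procedures to evaluate")
  structure(list(
    TP = sum(calls == "CD" & labels == "CD"),
    FP = sum(calls == "CD" & labels == "EAS"),
    FN = sum(calls == "EAS" & labels == "CD"),
    TN = sum(calls == "EAS" & labels == "EAS"),
    nIndeterminate = sum(calls == "indeterminate")),
    class = "ipssCounts")
}

#' Build contingency counts directly
#'
#' @param TP,FP,FN,TN,nIndeterminate Non-negative integer counts.
#' @return List of class `ipssCounts`.
#' @export
ipssCounts <- function(TP, FP, FN, TN, nIndeterminate = 0) {
  counts <- list(TP = TP, FP = FP, FN = FN, TN = TN,
                 nIndeterminate = nIndeterminate)
  if (any(unlist(counts) < 0)) stop("counts must be non-negative")
  structure(counts, class = "ipssCounts")
}

#' @export
print.ipssCounts <- function(x, ...) {
  cat(sprintf("TP %d, FP %d, FN %d, TN %d", x$TP, x$FP, x$FN, x$TN))
  if (x$nIndeterminate > 0) cat(",", x$nIndeterminate, "indeterminate")
  cat("\n")
  invisible(x)
}

#' Sensitivity, specificity and accuracy from contingency counts
#'
#' Percentages; a zero denominator yields NA (undefined), never 0.
#' Indeterminate calls are excluded from all denominators.
#'
#' @param counts An `ipssCounts` object (from [contingency()] or
#'   [ipssCounts()]).
#' @return List: `sensitivity`, `specificity`, `accuracy` (all in percent).
#' @export
sensSpec <- function(counts) {
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  list(sensitivity = pct(counts$TP, counts$TP + counts$FN),
       specificity = pct(counts$TN, counts$TN + counts$FP),
       accuracy = pct(counts$TP + counts$TN,
                      counts$TP + counts$FP + counts$FN + counts$TN))
}

#' Sensitivity/specificity for a published contingency row
#'
#' Convenience wrapper over [sensSpec()] for scoring literature contingency
#' counts.
#'
#' @inheritParams sensSpec
#' @return List: `sensitivity`, `specificity` (percent; NA when undefined).
#' @export
evaluatePublishedRow <- function(counts) {
  sensSpec(counts)[c("sensitivity", "specificity")]
}

#' ROC curve over a score vector
#'
#' Thresholds are swept over the distinct score values (call positive iff
#' score >= threshold), so tied scores move jointly. The curve runs from
#' (0,0) to (1,1); AUC is the trapezoidal integral. When the classes
#' separate perfectly the open interval between the highest EAS score and
#' the lowest CD score is reported as `separationGap`.
#'
#' @param scores Numeric scores (higher = more CD-like).
#' @param labels `"CD"`/`"EAS"` labels aligned with `scores`.
#' @return List of class `ipssRoc`: `points` (data.frame
#'   `threshold,fpr,tpr`), `auc`, `youdenJ`, `optimalCutoff`,
#'   `separationGap` (length-2 numeric or NULL).
#' @export
rocCurve <- function(scores, labels) {
  if (length(scores) != length(labels))
    stop("scores and labels must be aligned")
  keep <- !is.na(scores) & labels %in% c("CD", "EAS")
  scores <- scores[keep]; labels <- labels[keep]
  pos <- scores[labels == "CD"]; neg <- scores[labels == "EAS"]
  if (!length(pos) || !length(neg))
    stop("both classes must be present for ROC analysis")

  thresholds <- c(Inf, sort(unique(scores), decreasing = TRUE))
  pts <- data.frame(
    threshold = thresholds,
    fpr = vapply(thresholds, function(t) mean(neg >= t), numeric(1)),
    tpr = vapply(thresholds, function(t) mean(pos >= t), numeric(1)))
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  j <- pts$tpr - pts$fpr
  youdenJ <- max(j)
  gap <- if (max(neg) < min(pos)) c(max(neg), min(pos)) else NULL
  roc <- structure(list(points = pts, auc = auc, youdenJ = youdenJ,
                        separationGap = gap, optimalCutoff = NA_real_),
                   class = "ipssRoc")
  roc$optimalCutoff <- optimalCutoff(roc)
  roc
}

#' ROC-optimal cut-off (Youden's J)
#'
#' Returns the threshold maximizing J = TPR - FPR. Under perfect separation
#' every threshold in the separation gap attains J = 1; the midpoint of the
#' gap is returned as the canonical cut-off.
#'
#' @param roc An `ipssRoc` object from [rocCurve()].
#' @return The optimal cut-off value.
#' @export
optimalCutoff <- function(roc) {
  if (!is.null(roc$separationGap)) return(mean(roc$separationGap))
  j <- roc$points$tpr - roc$points$fpr
  best <- which(j == max(j))
  ## deterministic among ties: the lowest finite maximizing threshold
  cand <- roc$points$threshold[best]
  min(cand[is.finite(cand)])
}

#' @export
print.ipssRoc <- function(x, ...) {
  cat(sprintf("ROC: AUC %.3f, Youden J %.3f, optimal cutoff %.3g\n",
              x$auc, x$youdenJ, x$optimalCutoff))
  if (!is.null(x$separationGap))
    cat(sprintf("  perfect separation, gap (%.3g, %.3g)\n",
                x$separationGap[1], x$separationGap[2]))
  invisible(x)
}

#' Single-time-point diagnostic accuracy
#'
#' Restricted to procedures with reference label CD: the fraction whose
#' maximum side ratio at `time` meets the phase-appropriate standard
#' threshold (>= 2.0 for pre-stimulation times, >= 3.0 post-stimulation).
#' Quantifies how much diagnostic power a single sampling time retains.
#'
#' @param cohort An [IpssCohort-class].
#' @param time One grid time point.
#' @param basalCutoff,postCutoff Phase thresholds, defaults 2.0 and 3.0.
#' @return Accuracy in percent.
#' @export
singleTimepointAccuracy <- function(cohort, time, basalCutoff = 2.0,
                                    postCutoff = 3.0) {
  if (!time %in% timeGrid()) stop("time point off the sampling grid: ", time)
  cutoff <- if (time <= 0) basalCutoff else postCutoff
  cd <- Filter(function(p) referenceLabel(p) == "CD", procedures(cohort))
  ratioAt <- function(p) {
    r <- sinusRatios(p, "ACTH")[, as.character(time)]
    if (all(is.na(r))) NA_real_ else max(r, na.rm = TRUE)
  }
  r <- vapply(cd, ratioAt, numeric(1))
  r <- r[!is.na(r)]
  if (!length(r)) stop("no CD procedure has a ratio at time ", time)
  100 * mean(r >= cutoff)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by the sum-of-small-probabilities convention: the sum
#' of hypergeometric probabilities (at fixed margins) no larger than that of
#' the observed table. Used for confounding checks of subgroup splits
#' against the diagnostic outcome. Degenerate tables (any zero margin)
#' return p = 1 with attribute `degenerate = TRUE`.
#'
#' @param a,b,c,d Cell counts, row-wise.
#' @return The two-sided p-value in (0, 1].
#' @export
fisherExact2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (sum(counts) == 0) stop("empty table")
  tab <- matrix(counts, nrow = 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(structure(1, degenerate = TRUE))
  stats::fisher.test(tab)$p.value
}
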