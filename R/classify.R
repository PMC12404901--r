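## Rule-based pituitary (CD) vs ectopic (EAS) classification.
##
## Three rule kinds:
##  * unadjusted_standard — the classic dual-window criterion on unadjusted
##    peak ratios (>= basalCutoff pre-stimulation OR >= postCutoff
##    post-stimulation implies CD);
##  * adjusted_single_cutoff — one threshold on an adjusted score
##    (>= cdThreshold implies CD, else EAS);
##  * adjusted_dual_cutoff — published gray-zone rules (>= cdThreshold CD,
##    <= easThreshold EAS, in between indeterminate).

#' Construct a classification rule set
#'
#' @param name Rule name (used in outputs).
#' @param kind `"unadjusted_standard"`, `"adjusted_single_cutoff"` or
#'   `"adjusted_dual_cutoff"`.
#' @param basalCutoff,postCutoff Thresholds on the pre-/post-stimulation peak
#'   ratios (unadjusted rule only; both inclusive).
#' @param cdThreshold Score at or above which CD is called (adjusted rules).
#' @param easThreshold Score at or below which EAS is called (dual rules
#'   only); must be < `cdThreshold`.
#' @return A list of class `ipssRule`.
#' @export
ipssRule <- function(name,
                     kind = c("unadjusted_standard", "adjusted_single_cutoff",
                              "adjusted_dual_cutoff"),
                     basalCutoff = NA_real_, postCutoff = NA_real_,
                     cdThreshold = NA_real_, easThreshold = NA_real_) {
  kind <- match.arg(kind)
  if (kind == "unadjusted_standard" &&
      (is.na(basalCutoff) || is.na(postCutoff)))
    stop("unadjusted_standard rules need basalCutoff and postCutoff")
  if (kind != "unadjusted_standard" && is.na(cdThreshold))
    stop("adjusted rules need cdThreshold")
  if (kind == "adjusted_dual_cutoff") {
    if (is.na(easThreshold)) stop("dual rules need easThreshold")
    if (!(easThreshold < cdThreshold))
      stop("dual rules require easThreshold < cdThreshold")
  }
  structure(list(name = name, kind = kind, basalCutoff = basalCutoff,
                 postCutoff = postCutoff, cdThreshold = cdThreshold,
                 easThreshold = easThreshold),
            class = "ipssRule")
}

#' @export
print.ipssRule <- function(x, ...) {
  cat("ipssRule", x$name, paste0("(", x$kind, "):"),
      switch(x$kind,
             unadjusted_standard =
               sprintf("CD iff peak >= %.1f pre or >= %.1f post",
                       x$basalCutoff, x$postCutoff),
             adjusted_single_cutoff =
               sprintf("CD iff score >= %.1f", x$cdThreshold),
             adjusted_dual_cutoff =
               sprintf("CD iff score >= %.1f, EAS iff score <= %.1f",
                       x$cdThreshold, x$easThreshold)), "\n")
  invisible(x)
}

#' Built-in classification rule sets
#'
#' * `standard_unadjusted`: peak ratio >= 2.0 pre-stimulation or >= 3.0
#'   post-stimulation indicates CD (the classic criterion).
#' * `basal_optimal`: single cut-off 1.0 on the basal prolactin-adjusted peak
#'   ratio (ROC-optimal on the packaged reference cohort).
#' * `concurrent_optimal`: single cut-off 0.7 on the concurrent
#'   prolactin-adjusted peak ratio.
#' * `findling_basal`: dual cut-offs 0.8 (CD) / 0.6 (EAS) on the basal
#'   adjusted ratio, with a gray zone.
#' * `sharma_basal`: dual cut-offs 1.3 (CD) / 0.7 (EAS).
#'
#' @return Named list of [ipssRule()] objects.
#' @export
builtinRules <- function() {
  rules <- list(
    ipssRule("standard_unadjusted", "unadjusted_standard",
             basalCutoff = 2.0, postCutoff = 3.0),
    ipssRule("basal_optimal", "adjusted_single_cutoff", cdThreshold = 1.0),
    ipssRule("concurrent_optimal", "adjusted_single_cutoff", cdThreshold = 0.7),
    ipssRule("findling_basal", "adjusted_dual_cutoff",
             cdThreshold = 0.8, easThreshold = 0.6),
    ipssRule("sharma_basal", "adjusted_dual_cutoff",
             cdThreshold = 1.3, easThreshold = 0.7))
  stats::setNames(rules, vapply(rules, `[[`, character(1), "name"))
}

.call <- function(call, rule, score) {
  data.frame(call = call, rule = rule, scoreUsed = score)
}

#' Classify with the standard unadjusted criterion
#'
#' CD iff the pre-stimulation peak ratio meets `basalCutoff` (inclusive) OR
#' the post-stimulation peak ratio meets `postCutoff` (inclusive); EAS
#' otherwise. Either peak may be NA (partial procedure) but not both.
#'
#' @param peakBasal Peak unadjusted ratio over the pre-stimulation window.
#' @param peakPost Peak unadjusted ratio over the post-stimulation window.
#' @param rule An `unadjusted_standard` [ipssRule()]; default the built-in
#'   2.0/3.0 criterion.
#' @return One-row data.frame: `call` (`"CD"`/`"EAS"`), `rule`, `scoreUsed`
#'   (the larger margin-defining peak).
#' @export
classifyStandard <- function(peakBasal, peakPost,
                             rule = builtinRules()[["standard_unadjusted"]]) {
  if (rule$kind != "unadjusted_standard")
    stop("classifyStandard needs an unadjusted_standard rule")
  if (is.na(peakBasal) && is.na(peakPost))
    stop("both peaks undefined")
  cd <- (!is.na(peakBasal) && peakBasal >= rule$basalCutoff) ||
        (!is.na(peakPost) && peakPost >= rule$postCutoff)
  .call(if (cd) "CD" else "EAS", rule$name,
        max(peakBasal, peakPost, na.rm = TRUE))
}

#' Classify a prolactin-adjusted score
#'
#' Single-cutoff rules call CD iff score >= `cdThreshold`, else EAS.
#' Dual-cutoff rules additionally call EAS iff score <= `easThreshold` and
#' return `"indeterminate"` inside the gray zone.
#'
#' @param score Numeric adjusted score (or a one-row score data.frame from
#'   one of the adjustment methods, whose `value` is used).
#' @param rule An adjusted [ipssRule()].
#' @return One-row data.frame: `call` (`"CD"`/`"EAS"`/`"indeterminate"`),
#'   `rule`, `scoreUsed`.
#' @export
classifyAdjusted <- function(score, rule) {
  if (is.data.frame(score)) score <- score$value
  if (!rule$kind %in% c("adjusted_single_cutoff", "adjusted_dual_cutoff"))
    stop("classifyAdjusted needs an adjusted rule, got '", rule$kind, "'")
  if (is.na(score)) stop("score undefined")
  call <- if (score >= rule$cdThreshold) "CD"
          else if (rule$kind == "adjusted_single_cutoff") "EAS"
          else if (score <= rule$easThreshold) "EAS"
          else "indeterminate"
  .call(call, rule$name, score)
}

#' Classify every procedure of a score table under a rule
#'
#' Applies one rule to the per-procedure score table of [cohortScores()].
#' For the unadjusted standard rule the pre-/post-stimulation peak columns
#' are used; adjusted rules are applied to the requested method column.
#' Procedures whose required score is NA yield an NA call.
#'
#' @param scores data.frame from [cohortScores()].
#' @param rule An [ipssRule()].
#' @param method Score column for adjusted rules: `"basal_peak"`,
#'   `"concurrent_peak"`, `"basal_all"`, or `"concurrent_all"`.
#' @return data.frame: `procedureId`, `rule`, `call`, `scoreUsed`.
#' @export
classifyCohort <- function(scores, rule, method = "basal_peak") {
  one <- function(i) {
    res <- tryCatch(
      if (rule$kind == "unadjusted_standard")
        classifyStandard(scores$peakBasal[i], scores$peakPost[i], rule)
      else
        classifyAdjusted(scores[[method]][i], rule),
      error = function(e) .call(NA_character_, rule$name, NA_real_))
    cbind(procedureId = scores$procedureId[i], res)
  }
  do.call(rbind, lapply(seq_len(nrow(scores)), one))
}
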