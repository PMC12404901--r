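## Core S4 containers for IPSS procedures and cohorts.
##
## A procedure holds two 3 x 7 concentration matrices (sites x time points),
## one per analyte, plus parallel quality-flag matrices. Missing cells are NA
## with flag "missing". The time grid is fixed by the sampling protocol.

#' Sampling time grid (minutes relative to secretagogue injection)
#'
#' IPSS samples are drawn simultaneously from both inferior petrosal sinuses
#' and a peripheral vein at -5 and 0 minutes (pre-stimulation) and at +1.5,
#' +5, +10, +15 and +20 minutes after CRH/DDAVP injection. No other time
#' points are admitted anywhere in the package.
#'
#' @return Numeric vector of the seven grid times, in order.
#' @export
timeGrid <- function() c(-5, 0, 1.5, 5, 10, 15, 20)

#' Sampling sites
#' @return Character vector: left and right petrosal sinus, peripheral vein.
#' @export
ipssSites <- function() c("left", "right", "peripheral")

#' Analytes measured during IPSS
#' @return Character vector: ACTH (pmol/L) and prolactin (uIU/mL).
#' @export
ipssAnalytes <- function() c("ACTH", "prolactin")

#' Assay measuring ranges used for quality flagging
#'
#' Electrochemiluminescence immunoassay measuring ranges: values outside the
#' range are retained at their reported value but flagged `below_range` /
#' `above_range` (no imputation, no truncation of the stored value).
#'
#' @return Named list with `ACTH` and `prolactin` elements, each `c(lower, upper)`.
#' @export
assayRanges <- function() {
  list(ACTH = c(0.33, 440), prolactin = c(2, 10000))
}

#' Pre- versus post-stimulation phase of a grid time point
#'
#' @param minutes Numeric vector of grid times.
#' @return Character vector, `"pre"` for minutes <= 0, `"post"` otherwise.
#' @export
timePhase <- function(minutes) {
  if (!all(minutes %in% timeGrid()))
    stop("time point(s) off the sampling grid: ",
         paste(setdiff(minutes, timeGrid()), collapse = ", "))
  ifelse(minutes <= 0, "pre", "post")
}

.QC_LEVELS <- c("ok", "below_range", "above_range", "missing")

.emptyAssayMatrix <- function() {
  matrix(NA_real_, nrow = 3, ncol = 7,
         dimnames = list(ipssSites(), as.character(timeGrid())))
}

.flagFromValue <- function(values, analyte) {
  rng <- assayRanges()[[analyte]]
  flags <- ifelse(is.na(values), "missing",
           ifelse(values < rng[1], "below_range",
           ifelse(values > rng[2], "above_range", "ok")))
  dim(flags) <- dim(values)
  dimnames(flags) <- dimnames(values)
  flags
}

.checkAssayMatrix <- function(m, what) {
  msg <- character(0)
  if (!is.matrix(m) || !is.numeric(m))
    return(paste0(what, " must be a numeric matrix"))
  if (!identical(dim(m), c(3L, 7L)))
    msg <- c(msg, paste0(what, " must be 3 sites x 7 time points"))
  if (!identical(rownames(m), ipssSites()))
    msg <- c(msg, paste0(what, " rows must be ", paste(ipssSites(), collapse = "/")))
  if (!identical(colnames(m), as.character(timeGrid())))
    msg <- c(msg, paste0(what, " columns must be the time grid"))
  msg
}

#' @importFrom methods setClass new validObject is slot
NULL

#' IpssProcedure: one bilateral simultaneous sampling procedure
#'
#' Holds the ACTH and prolactin concentration matrices (sites x time grid,
#' NA = sample not obtained), parallel quality-flag matrices derived from the
#' assay measuring ranges, and procedure metadata including the reference
#' diagnosis used for evaluation.
#'
#' @slot procedureId Unique identifier of the procedure.
#' @slot patientId Patient identifier (a patient may own several procedures).
#' @slot stimulant `"CRH"` or `"DDAVP"` (pass-through label).
#' @slot referenceLabel `"CD"`, `"EAS"` or `"unknown"`.
#' @slot acth,prolactin 3 x 7 numeric matrices (pmol/L and uIU/mL).
#' @slot acthFlag,prolactinFlag 3 x 7 character matrices with levels
#'   `ok`, `below_range`, `above_range`, `missing`.
#' @export
setClass("IpssProcedure",
  representation(
    procedureId = "character",
    patientId = "character",
    stimulant = "character",
    referenceLabel = "character",
    acth = "matrix",
    prolactin = "matrix",
    acthFlag = "matrix",
    prolactinFlag = "matrix"
  )
)

setValidity("IpssProcedure", function(object) {
  msg <- character(0)
  if (length(object@procedureId) != 1L || !nzchar(object@procedureId))
    msg <- c(msg, "procedureId must be a single non-empty string")
  if (!object@stimulant %in% c("CRH", "DDAVP"))
    msg <- c(msg, "stimulant must be CRH or DDAVP")
  if (!object@referenceLabel %in% c("CD", "EAS", "unknown"))
    msg <- c(msg, "referenceLabel must be CD, EAS or unknown")
  msg <- c(msg,
           .checkAssayMatrix(object@acth, "acth"),
           .checkAssayMatrix(object@prolactin, "prolactin"))
  for (analyte in ipssAnalytes()) {
    vals <- if (analyte == "ACTH") object@acth else object@prolactin
    flags <- if (analyte == "ACTH") object@acthFlag else object@prolactinFlag
    if (!all(flags %in% .QC_LEVELS)) {
      msg <- c(msg, paste0(analyte, " flags outside allowed levels"))
      next
    }
    if (any(is.na(vals) != (flags == "missing")))
      msg <- c(msg, paste0(analyte, ": NA values and 'missing' flags disagree"))
    ok <- !is.na(vals) & flags == "ok"
    if (any(vals[ok] <= 0))
      msg <- c(msg, paste0(analyte, ": non-positive value flagged ok"))
  }
  if (length(msg)) msg else TRUE
})

#' Construct an IpssProcedure
#'
#' Quality flags are derived from the assay measuring ranges
#' ([assayRanges()]): values below/above the range keep their reported value
#' and are flagged; NA cells are flagged `missing`.
#'
#' @param procedureId Unique procedure identifier.
#' @param acth,prolactin 3 x 7 numeric matrices with rows
#'   `left`/`right`/`peripheral` and columns the time grid. Partial matrices
#'   are accepted via named rows/columns of a full matrix with NAs.
#' @param patientId Patient identifier, defaults to `procedureId`.
#' @param stimulant `"CRH"` (default) or `"DDAVP"`.
#' @param referenceLabel `"CD"`, `"EAS"` or `"unknown"` (default).
#' @return An [IpssProcedure-class] object.
#' @examples
#' m <- matrix(10, 3, 7, dimnames = list(ipssSites(), as.character(timeGrid())))
#' p <- IpssProcedure("proc1", acth = m, prolactin = m * 20)
#' sidesAvailable(p)
#' @export
IpssProcedure <- function(procedureId, acth, prolactin,
                          patientId = procedureId,
                          stimulant = "CRH",
                          referenceLabel = "unknown") {
  new("IpssProcedure",
      procedureId = as.character(procedureId),
      patientId = as.character(patientId),
      stimulant = stimulant,
      referenceLabel = referenceLabel,
      acth = acth,
      prolactin = prolactin,
      acthFlag = .flagFromValue(acth, "ACTH"),
      prolactinFlag = .flagFromValue(prolactin, "prolactin"))
}

#' IpssCohort: an ordered collection of procedures
#'
#' @slot procedures List of [IpssProcedure-class] objects with unique
#'   procedure ids (one patient may own several procedures).
#' @slot provenance Free-text source tag.
#' @export
setClass("IpssCohort",
  representation(procedures = "list", provenance = "character"))

setValidity("IpssCohort", function(object) {
  msg <- character(0)
  if (!all(vapply(object@procedures, is, logical(1), class2 = "IpssProcedure")))
    msg <- c(msg, "all elements must be IpssProcedure objects")
  else {
    ids <- vapply(object@procedures, function(p) p@procedureId, character(1))
    if (anyDuplicated(ids))
      msg <- c(msg, paste0("duplicate procedure ids: ",
                           paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  if (length(object@provenance) != 1L)
    msg <- c(msg, "provenance must be a single string")
  if (length(msg)) msg else TRUE
})

#' Construct an IpssCohort
#'
#' @param procedures List of [IpssProcedure-class] objects.
#' @param provenance Free-text source tag.
#' @return An [IpssCohort-class] object.
#' @export
IpssCohort <- function(procedures = list(), provenance = "unspecified") {
  new("IpssCohort", procedures = procedures, provenance = provenance)
}
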