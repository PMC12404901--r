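## Generics, accessors and show methods.

#' @importFrom methods setGeneric setMethod signature
NULL

#' @rdname IpssProcedure-class
#' @param object,x An `IpssProcedure` or `IpssCohort`.
#' @export
setGeneric("procedureId", function(object) standardGeneric("procedureId"))
#' @rdname IpssProcedure-class
#' @export
setGeneric("patientId", function(object) standardGeneric("patientId"))
#' @rdname IpssProcedure-class
#' @export
setGeneric("stimulant", function(object) standardGeneric("stimulant"))
#' @rdname IpssProcedure-class
#' @export
setGeneric("referenceLabel", function(object) standardGeneric("referenceLabel"))
#' @rdname IpssProcedure-class
#' @param analyte `"ACTH"` or `"prolactin"`.
#' @export
setGeneric("assayValues", function(object, analyte) standardGeneric("assayValues"))
#' @rdname IpssProcedure-class
#' @export
setGeneric("assayFlags", function(object, analyte) standardGeneric("assayFlags"))
#' @rdname IpssProcedure-class
#' @export
setGeneric("sidesAvailable", function(object) standardGeneric("sidesAvailable"))

#' @rdname IpssProcedure-class
setMethod("procedureId", "IpssProcedure", function(object) object@procedureId)
#' @rdname IpssProcedure-class
setMethod("patientId", "IpssProcedure", function(object) object@patientId)
#' @rdname IpssProcedure-class
setMethod("stimulant", "IpssProcedure", function(object) object@stimulant)
#' @rdname IpssProcedure-class
setMethod("referenceLabel", "IpssProcedure", function(object) object@referenceLabel)

.matchAnalyte <- function(analyte) match.arg(analyte, ipssAnalytes())

#' @rdname IpssProcedure-class
setMethod("assayValues", "IpssProcedure", function(object, analyte) {
  if (.matchAnalyte(analyte) == "ACTH") object@acth else object@prolactin
})
#' @rdname IpssProcedure-class
setMethod("assayFlags", "IpssProcedure", function(object, analyte) {
  if (.matchAnalyte(analyte) == "ACTH") object@acthFlag else object@prolactinFlag
})

#' @rdname IpssProcedure-class
setMethod("sidesAvailable", "IpssProcedure", function(object) {
  ## A side is analyzable when at least one of its ACTH samples can be paired
  ## with a peripheral ACTH sample drawn at the same time.
  peri <- !is.na(object@acth["peripheral", ])
  sides <- c("left", "right")
  sides[vapply(sides, function(s) any(!is.na(object@acth[s, ]) & peri),
               logical(1))]
})

setMethod("show", "IpssProcedure", function(object) {
  nA <- sum(!is.na(object@acth))
  nP <- sum(!is.na(object@prolactin))
  cat("IpssProcedure", object@procedureId,
      sprintf("(patient %s, %s-stimulated, reference %s)\n",
              object@patientId, object@stimulant, object@referenceLabel))
  cat(sprintf("  %d/21 ACTH and %d/21 prolactin cells present; sides: %s\n",
              nA, nP,
              if (length(sidesAvailable(object)))
                paste(sidesAvailable(object), collapse = ", ") else "none"))
})

#' @rdname IpssCohort-class
#' @param object An `IpssCohort`.
#' @export
setGeneric("procedures", function(object) standardGeneric("procedures"))
#' @rdname IpssCohort-class
#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))

#' @rdname IpssCohort-class
setMethod("procedures", "IpssCohort", function(object) object@procedures)
#' @rdname IpssCohort-class
setMethod("provenance", "IpssCohort", function(object) object@provenance)

#' @rdname IpssCohort-class
#' @param x An `IpssCohort`.
#' @export
setMethod("length", "IpssCohort", function(x) length(x@procedures))

#' @rdname IpssCohort-class
#' @param i Index or procedure id.
#' @export
setMethod("[[", "IpssCohort", function(x, i) {
  if (is.character(i)) {
    ids <- vapply(x@procedures, procedureId, character(1))
    j <- match(i, ids)
    if (is.na(j)) stop("no procedure with id '", i, "'")
    x@procedures[[j]]
  } else x@procedures[[i]]
})

setMethod("show", "IpssCohort", function(object) {
  labs <- vapply(object@procedures, referenceLabel, character(1))
  cat(sprintf("IpssCohort of %d procedures (%d CD, %d EAS, %d unknown)\n",
              length(object@procedures),
              sum(labs == "CD"), sum(labs == "EAS"), sum(labs == "unknown")))
  cat("  provenance:", object@provenance, "\n")
})

#' Reference diagnoses of a cohort
#'
#' @param cohort An [IpssCohort-class].
#' @return Named character vector of reference labels, one per procedure.
#' @export
referenceLabels <- function(cohort) {
  stats::setNames(vapply(procedures(cohort), referenceLabel, character(1)),
                  vapply(procedures(cohort), procedureId, character(1)))
}
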