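## Cohort-level CSV reading/writing and per-procedure validation.
##
## File dialect (long format, one row per measurement):
##   measurements: procedure_id,time_min,site,analyte,value
##   metadata:     procedure_id,patient_id,stimulant,reference_label
## UTF-8, comma separator, dot decimal. Lines starting with '#' are treated
## as provenance comments and skipped.

.MEAS_HEADER <- c("procedure_id", "time_min", "site", "analyte", "value")
.META_HEADER <- c("procedure_id", "patient_id", "stimulant", "reference_label")

.readCsvChecked <- function(path, header) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                        colClasses = "character")
  if (!identical(names(df), header))
    stop("unexpected header in ", path, ": expected ",
         paste(header, collapse = ","))
  df
}

#' Read an IPSS cohort from long-format CSV files
#'
#' Builds one [IpssProcedure-class] per metadata row and joins measurement
#' rows by `procedure_id`. Quality flags are assigned from the assay
#' measuring ranges at parse time; below/above-range values keep their
#' reported value. Partial procedures (missing cells, missing sides) are
#' accepted; structural problems are hard errors.
#'
#' @param measurementsPath Path to the measurements CSV
#'   (`procedure_id,time_min,site,analyte,value`).
#' @param metadataPath Path to the metadata CSV
#'   (`procedure_id,patient_id,stimulant,reference_label`).
#' @param provenance Source tag stored on the cohort; defaults to the
#'   measurements path.
#' @return An [IpssCohort-class].
#' @export
readCohortCsv <- function(measurementsPath, metadataPath,
                          provenance = measurementsPath) {
  meas <- .readCsvChecked(measurementsPath, .MEAS_HEADER)
  meta <- .readCsvChecked(metadataPath, .META_HEADER)

  if (anyDuplicated(meta$procedure_id))
    stop("duplicate procedure_id in metadata: ",
         paste(unique(meta$procedure_id[duplicated(meta$procedure_id)]),
               collapse = ", "))
  badSite <- setdiff(unique(meas$site), ipssSites())
  if (length(badSite)) stop("unknown site token: ", paste(badSite, collapse = ", "))
  badAnalyte <- setdiff(unique(meas$analyte), ipssAnalytes())
  if (length(badAnalyte))
    stop("unknown analyte token: ", paste(badAnalyte, collapse = ", "))
  badStim <- setdiff(unique(meta$stimulant), c("CRH", "DDAVP"))
  if (length(badStim)) stop("unknown stimulant token: ", paste(badStim, collapse = ", "))
  badLab <- setdiff(unique(meta$reference_label), c("CD", "EAS", "unknown"))
  if (length(badLab))
    stop("unknown reference_label token: ", paste(badLab, collapse = ", "))

  if (nrow(meas)) {
    tm <- suppressWarnings(as.numeric(meas$time_min))
    if (any(is.na(tm)) || !all(tm %in% timeGrid()))
      stop("time_min off the sampling grid: ",
           paste(unique(meas$time_min[is.na(tm) | !tm %in% timeGrid()]),
                 collapse = ", "))
    meas$time_min <- tm
    val <- suppressWarnings(as.numeric(meas$value))
    if (any(is.na(val))) stop("non-numeric value in measurements file")
    meas$value <- val

    key <- paste(meas$procedure_id, meas$site, meas$analyte, meas$time_min)
    if (anyDuplicated(key))
      stop("duplicate measurement for key (procedure_id, site, analyte, time): ",
           key[duplicated(key)][1])
    orphan <- setdiff(unique(meas$procedure_id), meta$procedure_id)
    if (length(orphan))
      stop("measurement rows without metadata row: ",
           paste(orphan, collapse = ", "))
  }

  procs <- lapply(seq_len(nrow(meta)), function(i) {
    id <- meta$procedure_id[i]
    acth <- .emptyAssayMatrix()
    prl <- .emptyAssayMatrix()
    rows <- meas[meas$procedure_id == id, , drop = FALSE]
    for (j in seq_len(nrow(rows))) {
      tgt <- if (rows$analyte[j] == "ACTH") "acth" else "prl"
      m <- get(tgt)
      m[rows$site[j], as.character(rows$time_min[j])] <- rows$value[j]
      assign(tgt, m)
    }
    IpssProcedure(id, acth = acth, prolactin = prl,
                  patientId = meta$patient_id[i],
                  stimulant = meta$stimulant[i],
                  referenceLabel = meta$reference_label[i])
  })
  IpssCohort(procs, provenance = provenance)
}

#' Write an IPSS cohort to long-format CSV files
#'
#' Inverse of [readCohortCsv()]: reading the written files reproduces the
#' cohort exactly (values, flags, ordering). Only present cells are written,
#' in a fixed (procedure, time, site, analyte) order; values are formatted at
#' full double precision so the round trip is bitwise exact.
#'
#' @param cohort An [IpssCohort-class].
#' @param measurementsPath,metadataPath Output file paths.
#' @param comment Optional provenance line(s) written as leading `#` comments.
#' @return Invisibly, the two paths.
#' @export
writeCohortCsv <- function(cohort, measurementsPath, metadataPath,
                           comment = NULL) {
  rows <- list()
  meta <- data.frame(procedure_id = character(0), patient_id = character(0),
                     stimulant = character(0), reference_label = character(0))
  for (p in procedures(cohort)) {
    meta <- rbind(meta, data.frame(
      procedure_id = procedureId(p), patient_id = patientId(p),
      stimulant = stimulant(p), reference_label = referenceLabel(p)))
    for (tm in timeGrid()) for (site in ipssSites()) for (an in ipssAnalytes()) {
      v <- assayValues(p, an)[site, as.character(tm)]
      if (!is.na(v))
        rows[[length(rows) + 1L]] <- data.frame(
          procedure_id = procedureId(p), time_min = tm, site = site,
          analyte = an, value = v)
    }
  }
  meas <- if (length(rows)) do.call(rbind, rows) else
    data.frame(procedure_id = character(0), time_min = numeric(0),
               site = character(0), analyte = character(0), value = numeric(0))
  meas$value <- sprintf("%.17g", meas$value)
  meas$time_min <- vapply(meas$time_min, format, character(1))

  .writeWithComment <- function(df, path) {
    con <- file(path, open = "wt", encoding = "UTF-8")
    on.exit(close(con))
    if (!is.null(comment)) writeLines(paste0("# ", comment), con)
    utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  }
  .writeWithComment(meas, measurementsPath)
  .writeWithComment(meta, metadataPath)
  invisible(c(measurementsPath, metadataPath))
}

#' Validate a procedure for downstream analysis
#'
#' Produces a deterministic report rather than raising errors. A procedure
#' with an empty error list is analyzable by every downstream operation its
#' available sides permit.
#'
#' @param proc An [IpssProcedure-class].
#' @return A list of class `ipssValidation`: `procedureId`, `errors`
#'   (character vector of structured issues) and `completeness` (fraction of
#'   the 42 possible site x analyte x time cells present).
#' @export
validateProcedure <- function(proc) {
  errors <- character(0)
  acth <- assayValues(proc, "ACTH")
  prl <- assayValues(proc, "prolactin")
  completeness <- (sum(!is.na(acth)) + sum(!is.na(prl))) / 42

  ## A sinus sample without a concurrent peripheral sample cannot form a ratio.
  for (tm in as.character(timeGrid())) {
    sinusPresent <- any(!is.na(acth[c("left", "right"), tm]))
    if (sinusPresent && is.na(acth["peripheral", tm]))
      errors <- c(errors, sprintf("missing peripheral sample at %+g", as.numeric(tm)))
  }
  if (length(sidesAvailable(proc)) == 0L)
    errors <- c(errors, "no analyzable side")
  for (an in ipssAnalytes()) {
    v <- assayValues(proc, an)
    if (any(v <= 0, na.rm = TRUE))
      errors <- c(errors, paste0("non-positive ", an, " value"))
  }
  structure(list(procedureId = procedureId(proc), errors = errors,
                 completeness = completeness),
            class = "ipssValidation")
}

#' @export
print.ipssValidation <- function(x, ...) {
  cat(sprintf("Validation of %s: completeness %.2f, %d issue(s)\n",
              x$procedureId, x$completeness, length(x$errors)))
  for (e in x$errors) cat("  -", e, "\n")
  invisible(x)
}
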