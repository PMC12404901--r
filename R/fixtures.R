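## Packaged reference data: per-procedure peak ratios and reference
## diagnoses of a published 20-procedure CRH-stimulated IPSS cohort
## (19 patients; one patient underwent the procedure twice). Raw
## per-time-point hormone values for this cohort are not public, so the
## record carries the two printed peak unadjusted ACTH ratios per procedure.

#' Reference cohort peak ACTH ratios
#'
#' Per-procedure peak unadjusted ACTH ratios and reference diagnoses from a
#' published 20-procedure CRH-stimulated IPSS case series (16 CD patients, 3
#' EAS patients; one CD patient contributes two procedures). `peakBasal` is
#' the peak sinus/peripheral ACTH ratio at the basal (t0) sample; `peakPost`
#' is the peak over the post-stimulation time points.
#'
#' @return A data.frame with columns `procedureId`, `patientId`, `peakBasal`,
#'   `peakPost`, `referenceLabel` (20 rows).
#' @examples
#' peaks <- referenceCohortPeaks()
#' table(peaks$referenceLabel)
#' @export
referenceCohortPeaks <- function() {
  df <- data.frame(
    patientId = c(1:12, 13, 13, 14:19),
    peakBasal = c(4.9, 49.2, 8.4, 5.9, 25.0, 5.0, 18.2, 14.8, 37.7, 26.5,
                  33.1, 0.8, 1.1, 10.4, 15.8, 23.0, 1.2, 2.2, 1.3, 1.3),
    peakPost = c(7.3, 117.1, 33.4, 19.7, 71.2, 141.1, 282.2, 577.5, 186.4,
                 526.7, 367.0, 2.6, 1.7, 21.6, 87.3, 106.7, 4.3, 10.2, 2.4,
                 1.8),
    referenceLabel = c(rep("CD", 17), rep("EAS", 3))
  )
  occ <- stats::ave(df$patientId, df$patientId, FUN = seq_along)
  df$procedureId <- ifelse(df$patientId %in% df$patientId[duplicated(df$patientId)],
                           sprintf("p%02d%s", df$patientId, letters[occ]),
                           sprintf("p%02d", df$patientId))
  df$patientId <- sprintf("p%02d", df$patientId)
  df[, c("procedureId", "patientId", "peakBasal", "peakPost", "referenceLabel")]
}
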