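## Sinus-to-peripheral ratios, peak ratios over configurable windows, and
## the four prolactin-adjustment methods.
##
## All ratios are unitless: petrosal sinus concentration divided by the
## concurrent peripheral concentration of the same analyte. The "dominant"
## side is the side on which the peak ACTH ratio is achieved; "ipsilateral"
## denominators are taken from that side, never silently from the other.

.SIDES <- c("left", "right")

.windowTimes <- function(window = c("all", "post_stimulation", "basal"),
                         basalTime = c("t0", "tminus5", "both")) {
  window <- match.arg(window)
  basalTime <- match.arg(basalTime)
  switch(window,
         all = timeGrid(),
         post_stimulation = timeGrid()[timeGrid() > 0],
         basal = switch(basalTime, t0 = 0, tminus5 = -5, both = c(-5, 0)))
}

#' Sinus-to-peripheral ratio matrix
#'
#' Computes the left and right sinus/peripheral concentration ratio at every
#' grid time. A cell is NA whenever the sinus or the peripheral sample at
#' that time is absent.
#'
#' @param proc An [IpssProcedure-class].
#' @param analyte `"ACTH"` or `"prolactin"`.
#' @return 2 x 7 numeric matrix (`left`/`right` by time grid).
#' @export
sinusRatios <- function(proc, analyte = c("ACTH", "prolactin")) {
  analyte <- match.arg(analyte)
  vals <- assayValues(proc, analyte)
  peri <- vals["peripheral", ]
  usedZero <- !is.na(peri) & peri == 0 &
    colSums(!is.na(vals[.SIDES, , drop = FALSE])) > 0
  if (any(usedZero))
    stop("degenerate input: peripheral ", analyte, " value of 0 at time ",
         paste(names(peri)[usedZero], collapse = ", "))
  sweep(vals[.SIDES, , drop = FALSE], 2, peri, "/")
}

#' Single sinus-to-peripheral ratio
#'
#' @param proc An [IpssProcedure-class].
#' @param analyte `"ACTH"` or `"prolactin"`.
#' @param side `"left"` or `"right"`.
#' @param time One of the grid time points.
#' @return The ratio, or NA if either cell is absent.
#' @export
sinusPeripheralRatio <- function(proc, analyte, side, time) {
  side <- match.arg(side, .SIDES)
  if (!time %in% timeGrid()) stop("time point off the sampling grid: ", time)
  sinusRatios(proc, analyte)[side, as.character(time)]
}

.ratioQcFlagged <- function(proc, analyte, side, time) {
  flags <- assayFlags(proc, analyte)
  any(flags[c(side, "peripheral"), as.character(time)] != "ok")
}

#' Peak ACTH ratio over a time window
#'
#' The peak is the maximum defined ACTH ratio across the available sides and
#' the requested window. Ties are broken deterministically: earlier time
#' point first, then left side. `qcFlagged` marks peaks built from any
#' below/above-range value.
#'
#' @param proc An [IpssProcedure-class].
#' @param window `"all"` (default), `"post_stimulation"`, or `"basal"`.
#' @param basalTime Basal sample selection for `window = "basal"`: `"t0"`
#'   (default), `"tminus5"`, or `"both"` (peak over -5 and 0 min). Interpretation
#'   is insensitive to this choice on well-behaved data.
#' @return One-row data.frame: `value`, `side`, `time`, `window`, `qcFlagged`.
#' @export
peakActhRatio <- function(proc, window = c("all", "post_stimulation", "basal"),
                          basalTime = c("t0", "tminus5", "both")) {
  window <- match.arg(window)
  times <- .windowTimes(window, basalTime)
  ratios <- sinusRatios(proc, "ACTH")[, as.character(times), drop = FALSE]
  if (all(is.na(ratios)))
    stop("window empty: no defined ACTH ratio in window '", window, "'")
  best <- NULL
  for (tm in as.character(times)) for (side in .SIDES) {
    v <- ratios[side, tm]
    if (!is.na(v) && (is.null(best) || v > best$value))
      best <- list(value = v, side = side, time = as.numeric(tm))
  }
  data.frame(value = best$value, side = best$side, time = best$time,
             window = window,
             qcFlagged = .ratioQcFlagged(proc, "ACTH", best$side, best$time))
}

.basalProlactinRatio <- function(proc, side, basalTime) {
  ## basal denominator: prolactin ratio at t0 (or -5 min / max of both)
  times <- .windowTimes("basal", basalTime)
  r <- sinusRatios(proc, "prolactin")[side, as.character(times)]
  if (all(is.na(r))) return(NA_real_)
  max(r, na.rm = TRUE)
}

.basalProlactinTime <- function(basalTime) {
  switch(basalTime, t0 = 0, tminus5 = -5, both = 0)
}

.adjScore <- function(method, value, side, acthTime, prolactinTime, qcFlagged) {
  data.frame(method = method, value = value, side = side,
             acthTime = acthTime, prolactinTime = prolactinTime,
             qcFlagged = qcFlagged)
}

#' Method 1: basal prolactin-adjusted peak ACTH ratio
#'
#' The peak post-stimulation ACTH ratio divided by the ipsilateral basal
#' prolactin ratio. Because catheter dilution multiplies ACTH and prolactin
#' alike on a given side, the prolactin denominator cancels placement and
#' venous-efflux effects out of the ACTH gradient.
#'
#' @param proc An [IpssProcedure-class].
#' @param basalTime Basal sample used for the denominator: `"t0"` (default),
#'   `"tminus5"`, or `"both"`.
#' @return One-row data.frame: `method`, `value`, `side`, `acthTime`,
#'   `prolactinTime`, `qcFlagged`.
#' @export
basalAdjustedPeak <- function(proc, basalTime = c("t0", "tminus5", "both")) {
  basalTime <- match.arg(basalTime)
  peak <- peakActhRatio(proc, "post_stimulation")
  prl <- .basalProlactinRatio(proc, peak$side, basalTime)
  if (is.na(prl))
    stop("ipsilateral basal prolactin unavailable on side '", peak$side, "'")
  prlTime <- .basalProlactinTime(basalTime)
  .adjScore("basal_peak", peak$value / prl, peak$side, peak$time, prlTime,
            peak$qcFlagged ||
              .ratioQcFlagged(proc, "prolactin", peak$side, prlTime))
}

#' Method 2: concurrent prolactin-adjusted peak ACTH ratio
#'
#' The peak ACTH ratio over all time points divided by the prolactin ratio
#' at the same side and the same time point.
#'
#' @inheritParams basalAdjustedPeak
#' @return One-row data.frame as in [basalAdjustedPeak()].
#' @export
concurrentAdjustedPeak <- function(proc) {
  peak <- peakActhRatio(proc, "all")
  prl <- sinusRatios(proc, "prolactin")[peak$side, as.character(peak$time)]
  if (is.na(prl))
    stop("concurrent prolactin unavailable at (", peak$side, ", ",
         peak$time, ")")
  .adjScore("concurrent_peak", peak$value / prl, peak$side, peak$time,
            peak$time,
            peak$qcFlagged ||
              .ratioQcFlagged(proc, "prolactin", peak$side, peak$time))
}

#' Method 3: basal prolactin adjustment of every ACTH ratio
#'
#' Every available ACTH ratio (up to 14: seven time points on each side) is
#' divided by its side's basal prolactin ratio; the maximum adjusted ratio is
#' returned. Every side contributing ACTH ratios must have a basal prolactin
#' ratio.
#'
#' @inheritParams basalAdjustedPeak
#' @return One-row data.frame as in [basalAdjustedPeak()].
#' @export
basalAdjustedAll <- function(proc, basalTime = c("t0", "tminus5", "both")) {
  basalTime <- match.arg(basalTime)
  acth <- sinusRatios(proc, "ACTH")
  prlTime <- .basalProlactinTime(basalTime)
  denom <- vapply(.SIDES, function(side) {
    if (all(is.na(acth[side, ]))) return(NA_real_)
    prl <- .basalProlactinRatio(proc, side, basalTime)
    if (is.na(prl))
      stop("ipsilateral basal prolactin unavailable on side '", side, "'")
    prl
  }, numeric(1))
  best <- NULL
  ## scan order (time-major, left first) implements the tie-break:
  ## earlier time point, then left side
  for (tm in as.character(timeGrid())) for (side in .SIDES) {
    if (is.na(acth[side, tm]) || is.na(denom[side])) next
    v <- acth[side, tm] / denom[side]
    if (is.null(best) || v > best$value)
      best <- list(value = v, side = side, time = as.numeric(tm))
  }
  if (is.null(best)) stop("window empty: no defined ACTH ratio")
  .adjScore("basal_all", best$value, best$side, best$time, prlTime,
            .ratioQcFlagged(proc, "ACTH", best$side, best$time) ||
              .ratioQcFlagged(proc, "prolactin", best$side, prlTime))
}

#' Method 4: concurrent prolactin adjustment of every ACTH ratio
#'
#' Every available ACTH ratio is divided by the prolactin ratio at the same
#' side and time; the maximum adjusted ratio is returned. Cells lacking the
#' concurrent prolactin ratio are skipped with a warning.
#'
#' @inheritParams basalAdjustedPeak
#' @return One-row data.frame as in [basalAdjustedPeak()].
#' @export
concurrentAdjustedAll <- function(proc) {
  acth <- sinusRatios(proc, "ACTH")
  prl <- sinusRatios(proc, "prolactin")
  best <- NULL
  skipped <- 0L
  for (tm in as.character(timeGrid())) for (side in .SIDES) {
    a <- acth[side, tm]
    if (is.na(a)) next
    p <- prl[side, tm]
    if (is.na(p)) { skipped <- skipped + 1L; next }
    v <- a / p
    if (is.null(best) || v > best$value)
      best <- list(value = v, side = side, time = as.numeric(tm))
  }
  if (skipped > 0L)
    warning(skipped, " ACTH ratio cell(s) lacked a concurrent prolactin ",
            "ratio and were skipped")
  if (is.null(best))
    stop("no cell has both an ACTH and a concurrent prolactin ratio")
  .adjScore("concurrent_all", best$value, best$side, best$time, best$time,
            .ratioQcFlagged(proc, "ACTH", best$side, best$time) ||
              .ratioQcFlagged(proc, "prolactin", best$side, best$time))
}

#' All four prolactin-adjusted scores of a procedure
#'
#' @inheritParams basalAdjustedPeak
#' @return Four-row data.frame, one row per method (`basal_peak`,
#'   `concurrent_peak`, `basal_all`, `concurrent_all`).
#' @export
adjustedScores <- function(proc, basalTime = c("t0", "tminus5", "both")) {
  basalTime <- match.arg(basalTime)
  rbind(basalAdjustedPeak(proc, basalTime),
        concurrentAdjustedPeak(proc),
        basalAdjustedAll(proc, basalTime),
        concurrentAdjustedAll(proc))
}

#' Post-stimulation prolactin rise on the ACTH-dominant side
#'
#' Percent change from the basal (t0) sinus prolactin to the maximum
#' post-stimulation sinus prolactin on the side of the overall peak ACTH
#' ratio. A consistent rise on the dominant side is a CRH effect on
#' lactotrophs and feeds into the concurrent-adjustment denominator.
#'
#' @param proc An [IpssProcedure-class].
#' @return Percent change (100 * (post max - basal) / basal).
#' @export
prolactinRiseDominant <- function(proc) {
  dominant <- peakActhRatio(proc, "all")$side
  prl <- assayValues(proc, "prolactin")
  basal <- prl[dominant, "0"]
  if (is.na(basal)) stop("missing basal prolactin on dominant side")
  post <- prl[dominant, as.character(timeGrid()[timeGrid() > 0])]
  if (all(is.na(post))) stop("no post-stimulation prolactin on dominant side")
  100 * (max(post, na.rm = TRUE) - basal) / basal
}

#' Per-procedure score table for a cohort
#'
#' Computes unadjusted peak ratios (basal window, post-stimulation window,
#' overall) and the four adjusted scores for every procedure. Procedures on
#' which a quantity is uncomputable (e.g. missing ipsilateral prolactin) get
#' NA for that column.
#'
#' @param cohort An [IpssCohort-class].
#' @param basalTime Basal sample selection, see [peakActhRatio()]. The
#'   pre-stimulation window of the standard unadjusted criterion is always
#'   the peak over \{-5, 0\} min.
#' @return data.frame with one row per procedure: `procedureId`,
#'   `referenceLabel`, `peakBasal`, `peakPost`, `peakAll`, `basal_peak`,
#'   `concurrent_peak`, `basal_all`, `concurrent_all`.
#' @export
cohortScores <- function(cohort, basalTime = c("t0", "tminus5", "both")) {
  basalTime <- match.arg(basalTime)
  one <- function(p) {
    grab <- function(expr) tryCatch(suppressWarnings(expr)$value,
                                    error = function(e) NA_real_)
    data.frame(
      procedureId = procedureId(p),
      referenceLabel = referenceLabel(p),
      peakBasal = grab(peakActhRatio(p, "basal", basalTime = "both")),
      peakPost = grab(peakActhRatio(p, "post_stimulation")),
      peakAll = grab(peakActhRatio(p, "all")),
      basal_peak = grab(basalAdjustedPeak(p, basalTime)),
      concurrent_peak = grab(concurrentAdjustedPeak(p)),
      basal_all = grab(basalAdjustedAll(p, basalTime)),
      concurrent_all = grab(concurrentAdjustedAll(p)))
  }
  do.call(rbind, lapply(procedures(cohort), one))
}
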