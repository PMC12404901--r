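# Fixture builders and independent oracles used across the suite.

gridChr <- as.character(timeGrid())

# Full assay matrix from per-site vectors (scalar recycled over the grid).
mkMat <- function(left = NA_real_, right = NA_real_, peripheral = NA_real_) {
  m <- matrix(NA_real_, 3, 7, dimnames = list(ipssSites(), gridChr))
  m["left", ] <- left
  m["right", ] <- right
  m["peripheral", ] <- peripheral
  m
}

# Procedure whose ACTH/prolactin ratio matrices equal the given per-side
# vectors (peripheral fixed), the easiest way to express ratio fixtures.
mkRatioProc <- function(id = "t1", acthLeft = NA_real_, acthRight = NA_real_,
                        prlLeft = NA_real_, prlRight = NA_real_,
                        acthPeripheral = 10, prlPeripheral = 100,
                        referenceLabel = "unknown") {
  IpssProcedure(id,
    acth = mkMat(acthLeft * acthPeripheral, acthRight * acthPeripheral,
                 acthPeripheral),
    prolactin = mkMat(prlLeft * prlPeripheral, prlRight * prlPeripheral,
                      prlPeripheral),
    referenceLabel = referenceLabel)
}

# Complete well-behaved bilateral procedure for plumbing tests.
mkCompleteProc <- function(id = "c1", label = "CD") {
  mkRatioProc(id,
              acthLeft = c(3, 3.2, 12, 10, 8, 6, 5),
              acthRight = c(1.5, 1.4, 2, 1.8, 1.7, 1.6, 1.5),
              prlLeft = c(2, 2.1, 3, 2.8, 2.5, 2.3, 2.2),
              prlRight = c(1.8, 1.9, 2.0, 2.0, 1.9, 1.8, 1.8),
              referenceLabel = label)
}

# Rescale every value of one analyte (sinus AND peripheral) by a constant.
scaleAnalyte <- function(proc, analyte, factor) {
  acth <- assayValues(proc, "ACTH")
  prl <- assayValues(proc, "prolactin")
  if (analyte == "ACTH") acth <- acth * factor else prl <- prl * factor
  IpssProcedure(procedureId(proc), acth = acth, prolactin = prl,
                patientId = patientId(proc), stimulant = stimulant(proc),
                referenceLabel = referenceLabel(proc))
}

# Multiply one side's sinus values of both analytes by d at the given times
# (a synthetic catheter-dilution event).
diluteSide <- function(proc, side, d, times = timeGrid()) {
  acth <- assayValues(proc, "ACTH")
  prl <- assayValues(proc, "prolactin")
  acth[side, as.character(times)] <- acth[side, as.character(times)] * d
  prl[side, as.character(times)] <- prl[side, as.character(times)] * d
  IpssProcedure(procedureId(proc), acth = acth, prolactin = prl,
                patientId = patientId(proc), stimulant = stimulant(proc),
                referenceLabel = referenceLabel(proc))
}

# Independent AUC oracle: Mann-Whitney count of correctly ordered
# (CD, EAS) pairs, ties counting one half.
aucByPairEnumeration <- function(scores, labels) {
  pos <- scores[labels == "CD"]
  neg <- scores[labels == "EAS"]
  total <- 0
  for (p in pos) for (n in neg)
    total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
  total / (length(pos) * length(neg))
}

# Independent two-sided Fisher oracle: full hypergeometric enumeration over
# all tables with the observed margins, summing probabilities no larger
# than the observed table's.
fisherByEnumeration <- function(a, b, c, d) {
  m <- a + b          # row 1 total
  n <- c + d          # row 2 total
  k <- a + c          # column 1 total
  xs <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(xs, m, n, k)
  pObs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# Classify a full synthetic cohort with one adjusted method and cutoff;
# returns the per-procedure call vector.
adjustedCalls <- function(scores, column, cutoff) {
  ifelse(scores[[column]] >= cutoff, "CD", "EAS")
}
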