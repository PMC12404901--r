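## Seedable synthetic IPSS cohort generator.
##
## Mechanistic premises made literal:
##  * CD: one sinus side drains the adenoma and carries a large ACTH gradient
##    that is amplified by CRH along a fixed kinetic shape; the contralateral
##    side carries a mild gradient. EAS: sinus/peripheral ACTH gradients near
##    1, and the (small) CRH response is systemic so it cancels in ratios.
##  * Every subject carries a pituitary prolactin gradient on both sides.
##  * Catheter placement / venous efflux is a per-side dilution factor plus
##    per-time multiplicative jitter that multiplies ACTH and prolactin
##    IDENTICALLY at a given (side, time) — the premise that makes prolactin
##    adjustment work.
##  * Sinus concentrations are built from the basal peripheral level times
##    the gradient response; the peripheral ACTH series has its own mild,
##    lagged CRH response, so unadjusted post-stimulation ratios are
##    gradient x stimulation / peripheral-rise.
##  * Assay noise per cell; values outside the assay measuring ranges keep
##    their value but are flagged.

.cvToSdlog <- function(cv) if (cv <= 0) 0 else sqrt(log(1 + cv^2))

.rlnormMedian <- function(n, median, sdlog) {
  stats::rlnorm(n, meanlog = log(median), sdlog = sdlog)
}

.noiseFactor <- function(n, cv) {
  if (cv <= 0) rep(1, n) else stats::rlnorm(n, 0, .cvToSdlog(cv))
}

#' Generator configuration for synthetic IPSS cohorts
#'
#' Defaults encode the cohort structure the analysis assumes; distribution
#' parameters are `c(median, sdlog)` for lognormals and `c(min, max)` for
#' uniforms.
#'
#' @param nProcedures Number of procedures.
#' @param easFraction Probability that a procedure is EAS (default 0.15,
#'   matching a 3/20 case mix).
#' @param peripheralActhMedian,peripheralProlactinMedian Basal peripheral
#'   medians (pmol/L, uIU/mL). Ratios are invariant to these.
#' @param cdDominantGradient,cdContralateralGradient,easGradient Lognormal
#'   `c(median, sdlog)` of the sinus/peripheral ACTH gradient per side class.
#' @param crhActhFoldCd,crhActhFoldEas Uniform range of the CRH-driven ACTH
#'   fold (dominant-side amplification for CD; systemic for EAS).
#' @param responseShape Named multipliers at the post-stimulation grid times
#'   scaling (fold - 1): peak at +1.5 min, decaying to +20 min.
#' @param prolactinGradient Lognormal `c(median, sdlog)` of the per-side
#'   prolactin gradient (all subjects — the pituitary secretes prolactin
#'   regardless of diagnosis).
#' @param crhProlactinRise Uniform range of the fractional post-stimulation
#'   prolactin rise on the CD dominant side (default 0.135-3.0, i.e.
#'   13.5%-300% at the shape peak).
#' @param peripheralCrhFoldCd Uniform range of the mild peripheral ACTH CRH
#'   response in CD, applied with a one-grid-point lag. Zero response for
#'   EAS beyond the systemic fold.
#' @param dilutionLow Per-side dilution factor is uniform on
#'   `[dilutionLow, 1]`; 1 disables the confound.
#' @param dilutionJitterCv CV of the per-(side, time) multiplicative jitter
#'   shared by both analytes.
#' @param assayCv Per-cell measurement noise CV.
#' @param missingSideProb Probability that one sinus side is lost entirely
#'   (failed catheterization).
#' @param seed Default root seed used by [simulateCohort()].
#' @return A list of class `ipssConfig`.
#' @export
ipssConfig <- function(nProcedures = 20,
                       easFraction = 0.15,
                       peripheralActhMedian = 20,
                       peripheralProlactinMedian = 200,
                       cdDominantGradient = c(10, 0.7),
                       cdContralateralGradient = c(2, 0.4),
                       easGradient = c(1, 0.1),
                       crhActhFoldCd = c(2, 10),
                       crhActhFoldEas = c(1, 1.3),
                       responseShape = c("1.5" = 1.0, "5" = 0.9, "10" = 0.7,
                                         "15" = 0.5, "20" = 0.4),
                       prolactinGradient = c(3, 0.4),
                       crhProlactinRise = c(0.135, 3.0),
                       peripheralCrhFoldCd = c(1, 1.5),
                       dilutionLow = 0.2,
                       dilutionJitterCv = 0.10,
                       assayCv = 0.05,
                       missingSideProb = 0,
                       seed = 1) {
  cfg <- as.list(environment())
  if (cfg$nProcedures < 1) stop("nProcedures must be positive")
  if (cfg$easFraction < 0 || cfg$easFraction > 1)
    stop("easFraction must be in [0, 1]")
  if (cfg$dilutionLow <= 0 || cfg$dilutionLow > 1)
    stop("dilutionLow must be in (0, 1]")
  for (nm in c("peripheralActhMedian", "peripheralProlactinMedian"))
    if (cfg[[nm]] <= 0) stop(nm, " must be positive")
  for (nm in c("cdDominantGradient", "cdContralateralGradient", "easGradient",
               "prolactinGradient"))
    if (cfg[[nm]][1] <= 0 || cfg[[nm]][2] < 0)
      stop(nm, " must be c(median > 0, sdlog >= 0)")
  if (!identical(names(cfg$responseShape),
                 as.character(timeGrid()[timeGrid() > 0])))
    stop("responseShape must be named by the post-stimulation grid times")
  structure(cfg, class = "ipssConfig")
}

#' Named generator scenario presets
#'
#' * `clean`: no dilution confound (`dilutionLow = 1`, jitter 0).
#' * `dilution`: the defaults — per-side dilution uniform on \[0.2, 1\].
#' * `noisy_timepoints`: per-time jitter CV 0.30; exposes the failure mode of
#'   the adjust-every-time-point methods, whose max picks up noise maxima.
#' * `partial`: 15% of procedures lose one sinus side.
#'
#' @return Named list of [ipssConfig()] objects.
#' @export
scenarioPresets <- function() {
  list(clean = ipssConfig(dilutionLow = 1, dilutionJitterCv = 0),
       dilution = ipssConfig(),
       noisy_timepoints = ipssConfig(dilutionJitterCv = 0.30),
       partial = ipssConfig(missingSideProb = 0.15))
}

#' Simulate one IPSS procedure
#'
#' @param config An [ipssConfig()].
#' @param trueLabel `"CD"`, `"EAS"`, or NULL to draw from
#'   `config$easFraction`.
#' @param procedureId Identifier for the generated procedure.
#' @param seed Optional integer seed for this procedure's random stream.
#' @return List with elements `procedure` ([IpssProcedure-class], whose
#'   `referenceLabel` is the true label) and `truth` (one-row data.frame:
#'   `procedureId`, `trueLabel`, `dominantSide`, `dilutionLeft`,
#'   `dilutionRight`, `gradientLeft`, `gradientRight`). The truth record is
#'   for parameter-recovery checks only and is never consumed by analysis
#'   operations.
#' @export
simulateProcedure <- function(config, trueLabel = NULL, procedureId = "sim1",
                              seed = NULL) {
  stopifnot(inherits(config, "ipssConfig"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(trueLabel))
    trueLabel <- if (stats::runif(1) < config$easFraction) "EAS" else "CD"
  trueLabel <- match.arg(trueLabel, c("CD", "EAS"))

  grid <- timeGrid()
  post <- grid > 0
  shape <- c(0, 0, unname(config$responseShape))        # aligned to grid
  lagShape <- c(0, 0, 0, unname(config$responseShape)[-5]) # one-point lag

  P0a <- .rlnormMedian(1, config$peripheralActhMedian, 0.5)
  P0p <- .rlnormMedian(1, config$peripheralProlactinMedian, 0.4)
  gradPrl <- stats::setNames(.rlnormMedian(2, config$prolactinGradient[1],
                                           config$prolactinGradient[2]),
                             .SIDES)

  if (trueLabel == "CD") {
    dominant <- sample(.SIDES, 1)
    other <- setdiff(.SIDES, dominant)
    grads <- numeric(2); names(grads) <- .SIDES
    grads[dominant] <- .rlnormMedian(1, config$cdDominantGradient[1],
                                     config$cdDominantGradient[2])
    grads[other] <- .rlnormMedian(1, config$cdContralateralGradient[1],
                                  config$cdContralateralGradient[2])
    foldA <- stats::runif(1, config$crhActhFoldCd[1], config$crhActhFoldCd[2])
    pfold <- stats::runif(1, config$peripheralCrhFoldCd[1],
                          config$peripheralCrhFoldCd[2])
    rise <- stats::runif(1, config$crhProlactinRise[1],
                         config$crhProlactinRise[2])

    periAc <- P0a * (1 + (pfold - 1) * lagShape)
    stimDom <- 1 + (foldA - 1) * shape
    sinusAc <- rbind(left = P0a * grads["left"] *
                       (if (dominant == "left") stimDom else 1),
                     right = P0a * grads["right"] *
                       (if (dominant == "right") stimDom else 1))
    riseDom <- 1 + rise * shape
    sinusPr <- rbind(left = P0p * gradPrl["left"] *
                       (if (dominant == "left") riseDom else 1),
                     right = P0p * gradPrl["right"] *
                       (if (dominant == "right") riseDom else 1))
    periPr <- rep(P0p, 7)
  } else {
    dominant <- NA_character_
    grads <- stats::setNames(.rlnormMedian(2, config$easGradient[1],
                                           config$easGradient[2]), .SIDES)
    foldE <- stats::runif(1, config$crhActhFoldEas[1], config$crhActhFoldEas[2])
    systemic <- 1 + (foldE - 1) * shape  # shared by sinus and periphery
    periAc <- P0a * systemic
    sinusAc <- rbind(left = P0a * grads["left"] * systemic,
                     right = P0a * grads["right"] * systemic)
    sinusPr <- rbind(left = P0p * gradPrl["left"] * rep(1, 7),
                     right = P0p * gradPrl["right"] * rep(1, 7))
    periPr <- rep(P0p, 7)
  }

  ## catheter confound: per-side dilution, per-(side,time) jitter shared by
  ## both analytes
  dil <- stats::setNames(stats::runif(2, config$dilutionLow, 1), .SIDES)
  jitter <- matrix(.noiseFactor(14, config$dilutionJitterCv), nrow = 2,
                   dimnames = list(.SIDES, as.character(grid)))
  for (s in .SIDES) {
    sinusAc[s, ] <- sinusAc[s, ] * dil[s] * jitter[s, ]
    sinusPr[s, ] <- sinusPr[s, ] * dil[s] * jitter[s, ]
  }

  acth <- .emptyAssayMatrix()
  prl <- .emptyAssayMatrix()
  acth[c("left", "right"), ] <- sinusAc
  acth["peripheral", ] <- periAc
  prl[c("left", "right"), ] <- sinusPr
  prl["peripheral", ] <- periPr
  acth[] <- acth * .noiseFactor(21, config$assayCv)
  prl[] <- prl * .noiseFactor(21, config$assayCv)

  if (stats::runif(1) < config$missingSideProb) {
    lost <- sample(.SIDES, 1)
    acth[lost, ] <- NA_real_
    prl[lost, ] <- NA_real_
  }

  proc <- IpssProcedure(procedureId, acth = acth, prolactin = prl,
                        referenceLabel = trueLabel)
  truth <- data.frame(procedureId = procedureId, trueLabel = trueLabel,
                      dominantSide = dominant,
                      dilutionLeft = unname(dil["left"]),
                      dilutionRight = unname(dil["right"]),
                      gradientLeft = unname(grads["left"]),
                      gradientRight = unname(grads["right"]))
  list(procedure = proc, truth = truth)
}

#' Simulate a full IPSS cohort
#'
#' Fully reproducible: the same root seed yields a byte-identical cohort.
#' Each procedure draws from its own substream keyed by (root seed, index),
#' so changing `nProcedures` does not perturb earlier procedures.
#'
#' @param config An [ipssConfig()].
#' @param seed Root seed; defaults to `config$seed`. Kept below 2^31.
#' @return List: `cohort` ([IpssCohort-class]) and `truth` (data.frame with
#'   one row per procedure).
#' @export
simulateCohort <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "ipssConfig"))
  n <- config$nProcedures
  procSeed <- function(i) ((as.double(seed) %% 2147483647) * 100003 +
                             i * 7919) %% 2147483629 + 1
  sims <- lapply(seq_len(n), function(i)
    simulateProcedure(config, procedureId = sprintf("sim%04d", i),
                      seed = procSeed(i)))
  cohort <- IpssCohort(lapply(sims, `[[`, "procedure"),
                       provenance = sprintf("synthetic (seed %s)", seed))
  truth <- do.call(rbind, lapply(sims, `[[`, "truth"))
  list(cohort = cohort, truth = truth)
}
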