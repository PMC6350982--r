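## Chou-Talalay constant-ratio combination analysis.

#' Assemble a constant-ratio design
#'
#' Fits the median-effect model to the two single-agent series and the
#' fixed-ratio mixture series, and records the mixture weights (fractions of
#' the total mixture dose; wA + wB = 1).  Weights default to the mixture's
#' own \code{mixtureRatio}.  The ratio is also expressed in the conventional
#' "1 : x" notation (x = wB / wA).
#'
#' @param drA,drB single-agent \linkS4class{DoseResponse} series.
#' @param drMix the mixture series (doses = total concentration).
#' @param weights length-2 positive weights, or NULL to take them from
#'   \code{drMix}.
#' @param rThreshold r requirement passed to \code{\link{fitMedianEffect}}.
#' @return a \linkS4class{ConstantRatioDesign}.
#' @export
constantRatioDesign <- function(drA, drB, drMix, weights = NULL,
                                rThreshold = 0.85) {
  if (is.null(weights)) {
    mr <- mixtureRatio(drMix)
    if (is.null(mr))
      stop("no weights given and the mixture series carries no mixtureRatio")
    weights <- mr$weights
  }
  weights <- weights / sum(weights)
  new("ConstantRatioDesign",
      drA = drA, drB = drB, drMix = drMix,
      fitA = fitMedianEffect(drA, rThreshold),
      fitB = fitMedianEffect(drB, rThreshold),
      fitMix = fitMedianEffect(drMix, rThreshold),
      weights = setNames(weights, c(drA@compoundId, drB@compoundId)),
      ratioLabel = sprintf("1 : %.3g", weights[2] / weights[1]))
}

.design_fa_range <- function(design) {
  rng <- rbind(design@fitA@faRange, design@fitB@faRange, design@fitMix@faRange)
  c(max(rng[, 1]), min(rng[, 2]))
}

.ci_core <- function(fitA, fitB, fitMix, wA, wB, fa, force = FALSE) {
  Dmix <- doseForEffect(fitMix, fa, force = force)
  dA <- wA * Dmix
  dB <- wB * Dmix
  DxA <- doseForEffect(fitA, fa, force = force)
  DxB <- doseForEffect(fitB, fa, force = force)
  list(ci = dA / DxA + dB / DxB, dA = dA, dB = dB, DxA = DxA, DxB = DxB)
}

#' Combination index at effect levels
#'
#' The two-term (mutually exclusive) combination index at effect level fa:
#' CI = d_A / Dx_A + d_B / Dx_B, where D_mix is the total mixture dose
#' producing fa (from the mixture fit), d_i = w_i D_mix are the component
#' doses actually present, and Dx_i the single-agent doses producing the same
#' fa.  CI < 1 synergism, CI = 1 additivity, CI > 1 antagonism.  Levels
#' outside the observed fa range of any of the three series are flagged
#' \code{extrapolated}.
#'
#' @param design a \linkS4class{ConstantRatioDesign}.
#' @param fa effect level(s) in (0, 1).
#' @param force use invalid fits anyway.
#' @return data.frame: \code{fa}, \code{ci}, \code{extrapolated}.
#' @export
computeCI <- function(design, fa, force = FALSE) {
  w <- design@weights
  cc <- .ci_core(design@fitA, design@fitB, design@fitMix, w[1], w[2], fa,
                 force = force)
  rng <- .design_fa_range(design)
  data.frame(fa = fa, ci = unname(cc$ci),
             extrapolated = fa < rng[1] | fa > rng[2])
}

#' Dose-reduction index
#'
#' DRI_i = Dx_i / d_i: the fold by which drug i's dose in the combination is
#' reduced relative to its single-agent dose for the same effect.  The
#' algebraic identity CI = 1/DRI_A + 1/DRI_B holds at every level.
#'
#' @inheritParams computeCI
#' @return data.frame: \code{fa}, \code{dri_a}, \code{dri_b}.
#' @export
dri <- function(design, fa, force = FALSE) {
  w <- design@weights
  cc <- .ci_core(design@fitA, design@fitB, design@fitMix, w[1], w[2], fa,
                 force = force)
  data.frame(fa = fa, dri_a = unname(cc$DxA / cc$dA),
             dri_b = unname(cc$DxB / cc$dB))
}

#' Sequential-deletion confidence intervals for CI
#'
#' Variability of CI by sequential deletion analysis: one concentration level
#' of one series (drug A, drug B, or the mixture) is deleted at a time, that
#' series is refitted, and CI is recomputed at each requested effect level.
#' Over the deletion set the mean CI and a 95\% half-width are reported.  The
#' half-width uses the delete-one jackknife standard error,
#' sqrt((n-1)/n * sum (CI_i - mean)^2), with the t quantile on n - 1 degrees
#' of freedom; deletion replicates are strongly correlated (each shares all
#' but one point with the full data), and the jackknife inflation accounts
#' for this where the naive sd/sqrt(n) would not.  Deletions that produce an
#' invalid or inestimable refit are dropped and counted out of n.
#'
#' @param design a \linkS4class{ConstantRatioDesign}; every series needs at
#'   least 3 dose levels so a deletion leaves a fittable series.
#' @param faLevels effect levels at which to evaluate CI.
#' @param force use invalid (full-data or refitted) fits anyway.
#' @return data.frame: \code{fa}, \code{mean}, \code{halfwidth},
#'   \code{n_deletions}.
#' @export
sdaConfidence <- function(design, faLevels = c(0.5, 0.75, 0.9, 0.95),
                          force = FALSE) {
  series <- list(A = design@drA, B = design@drB, mix = design@drMix)
  if (any(vapply(series, function(s) length(doses(s)), 1L) < 3L))
    stop("insufficient data: sequential deletion needs >= 3 doses per series")
  fits <- list(A = design@fitA, B = design@fitB, mix = design@fitMix)
  w <- design@weights
  rThr <- design@fitA@rThreshold
  ci_rows <- list()
  for (who in names(series)) {
    dr <- series[[who]]
    p <- faValues(dr)
    for (dose_del in doses(dr)) {
      keep <- p$dose != dose_del
      sub <- DoseResponse(dr@compoundId, dose = p$dose[keep],
                          fa = p$fa[keep], replicate = p$replicate[keep],
                          mixtureRatio = mixtureRatio(dr))
      refit <- tryCatch(fitMedianEffect(sub, rThreshold = rThr),
                        error = function(e) NULL)
      if (is.null(refit) || (!refit@valid && !force)) next
      f <- fits
      f[[who]] <- refit
      ci <- tryCatch(
        .ci_core(f$A, f$B, f$mix, w[1], w[2], faLevels, force = force)$ci,
        error = function(e) NULL)
      if (!is.null(ci)) ci_rows[[length(ci_rows) + 1L]] <- ci
    }
  }
  if (length(ci_rows) < 2L)
    stop("sequential deletion produced fewer than 2 usable refits")
  mat <- do.call(rbind, ci_rows)
  n <- nrow(mat)
  mu <- colMeans(mat)
  se_jack <- sqrt((n - 1) / n * colSums(sweep(mat, 2, mu)^2))
  data.frame(fa = faLevels, mean = unname(mu),
             halfwidth = unname(qt(0.975, n - 1) * se_jack),
             n_deletions = n)
}

#' Weighted combination index
#'
#' CI_wt = (CI_50 + 2 CI_75 + 3 CI_90 + 4 CI_95) / 10: a weighted average
#' over the 50/75/90/95\% effect levels emphasizing the high effect levels of
#' higher therapeutic relevance.
#'
#' @param ci50,ci75,ci90,ci95 positive CI values at the four levels.
#' @return CI_wt.
#' @examples
#' ciWeighted(0.5, 0.4, 0.3, 0.2)  # 0.30
#' @export
ciWeighted <- function(ci50, ci75, ci90, ci95) {
  stopifnot(all(c(ci50, ci75, ci90, ci95) > 0))
  (ci50 + 2 * ci75 + 3 * ci90 + 4 * ci95) / 10
}

.GRADE_BREAKS <- c(0, 0.1, 0.3, 0.7, 0.85, 0.90, 1.10, 1.20, 1.45, 3.3, Inf)
.GRADE_SYMBOLS <- c("+++++", "++++", "+++", "++", "+", "\u00b1",
                    "-", "--", "---", "----")

#' Synergy grade symbol from CI_wt
#'
#' Maps the weighted combination index to the conventional symbol scale:
#' CI_wt < 0.1 very strong synergism "+++++", [0.1, 0.3) strong "++++",
#' [0.3, 0.7) synergism "+++", [0.7, 0.85) moderate "++", [0.85, 0.90)
#' slight "+", [0.90, 1.10] near-additive (+/-), (1.10, 1.20] slight
#' antagonism "-", (1.20, 1.45] "--", (1.45, 3.3] "---", above 3.3 "----".
#' The grade is a non-increasing step function of CI_wt.
#'
#' @param ci_wt positive CI_wt value(s).
#' @return grade symbol(s).
#' @examples
#' gradeCI(c(0.077, 0.340, 1.0, 1.349))
#' @export
gradeCI <- function(ci_wt) {
  stopifnot(all(ci_wt > 0))
  ## synergy bands are closed on the lower end; the near-additive band is
  ## closed on both ends ([0.90, 1.10]), so antagonism bands are (lo, hi]
  idx <- ifelse(ci_wt < 1.10,
                findInterval(ci_wt, .GRADE_BREAKS, left.open = FALSE),
                findInterval(ci_wt, .GRADE_BREAKS, left.open = TRUE))
  .GRADE_SYMBOLS[idx]
}

#' Isobologram points
#'
#' For each effect level: the additivity-line axis intercepts (Dx_A, 0) and
#' (0, Dx_B) from the single-agent fits, and the actual combination point
#' (w_A D_mix, w_B D_mix).  The point lies below the additivity line exactly
#' when CI < 1 at that level.
#'
#' @inheritParams computeCI
#' @param levels effect levels (default the classical 0.5, 0.75, 0.9).
#' @return data.frame: \code{level}, \code{dx_a}, \code{dx_b}, \code{d_a},
#'   \code{d_b}.
#' @export
isobologramPoints <- function(design, levels = c(0.5, 0.75, 0.9),
                              force = FALSE) {
  w <- design@weights
  cc <- .ci_core(design@fitA, design@fitB, design@fitMix, w[1], w[2], levels,
                 force = force)
  data.frame(level = levels, dx_a = unname(cc$DxA), dx_b = unname(cc$DxB),
             d_a = unname(cc$dA), d_b = unname(cc$dB))
}

#' Fa-CI curve
#'
#' CI sampled over a grid of effect levels, with per-point extrapolation
#' flags, for the Fa-CI plot.
#'
#' @inheritParams computeCI
#' @param faGrid grid of effect levels.
#' @return data.frame as \code{\link{computeCI}}.
#' @export
faCiCurve <- function(design, faGrid = seq(0.05, 0.95, by = 0.05),
                      force = FALSE) {
  computeCI(design, faGrid, force = force)
}

#' Full combination analysis
#'
#' One-call analysis of a constant-ratio design: CI at the reporting effect
#' levels (0.5, 0.75, 0.90, 0.95 by default, as needed for CI_wt) with
#' sequential-deletion intervals, CI_wt and its grade symbol, dose-reduction
#' indices, isobologram points and the Fa-CI curve.
#'
#' @param drA,drB,drMix the three \linkS4class{DoseResponse} series (or pass
#'   a ready \linkS4class{ConstantRatioDesign} as \code{drA}).
#' @param weights,rThreshold see \code{\link{constantRatioDesign}}.
#' @param effectLevels levels reported (must include 0.5, 0.75, 0.9, 0.95
#'   for CI_wt).
#' @param isoLevels isobologram levels.
#' @param faGrid Fa-CI curve grid.
#' @param sda compute sequential-deletion intervals (needs >= 3 doses per
#'   series).
#' @param force use invalid fits anyway.
#' @return a \linkS4class{CombinationResult}.
#' @examples
#' a <- AgentModel("drugA", Dm = 10, m = 1.5)
#' b <- AgentModel("drugB", Dm = 40, m = 1.5)
#' sim <- simulateConstantRatio(a, b, interactionSpec("fixed_ci", 0.5),
#'                              cv = 0, seed = 7)
#' res <- analyzeCombination(sim$drA, sim$drB, sim$drMix)
#' gradeSymbol(res)
#' @export
analyzeCombination <- function(drA, drB = NULL, drMix = NULL, weights = NULL,
                               rThreshold = 0.85,
                               effectLevels = c(0.5, 0.75, 0.9, 0.95),
                               isoLevels = c(0.5, 0.75, 0.9),
                               faGrid = seq(0.05, 0.95, by = 0.05),
                               sda = TRUE, force = FALSE) {
  design <- if (is(drA, "ConstantRatioDesign")) drA else
    constantRatioDesign(drA, drB, drMix, weights, rThreshold)
  ciAt <- computeCI(design, effectLevels, force = force)
  need <- c(0.5, 0.75, 0.9, 0.95)
  idx <- match(need, ciAt$fa)
  if (anyNA(idx))
    stop("effectLevels must include 0.5, 0.75, 0.9 and 0.95 for CI_wt")
  wt <- ciWeighted(ciAt$ci[idx[1]], ciAt$ci[idx[2]], ciAt$ci[idx[3]],
                   ciAt$ci[idx[4]])
  sda_df <- if (sda)
    sdaConfidence(design, effectLevels, force = force)
  else
    data.frame(fa = numeric(), mean = numeric(), halfwidth = numeric(),
               n_deletions = integer())
  new("CombinationResult", design = design, effectLevels = effectLevels,
      ciAt = ciAt, sda = sda_df, ciWt = wt, grade = gradeCI(wt),
      driAt = dri(design, effectLevels, force = force),
      isobologram = isobologramPoints(design, isoLevels, force = force),
      faCiCurve = faCiCurve(design, faGrid, force = force))
}
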