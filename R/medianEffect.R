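## Median-effect model fitting and inversion.

#' Fit the median-effect model
#'
#' Linear regression of the logarithmic form of the median-effect equation:
#' log10(fa/fu) = m log10(D) - m log10(Dm), with fu = 1 - fa.  Replicates are
#' averaged per dose before regression (the CompuSyn convention;
#' \code{perReplicate = TRUE} regresses individual replicates instead).
#' Dose levels whose (mean) fa is <= 0 or >= 1 leave log10(fa/fu) undefined;
#' they are excluded and recorded.  r is the Pearson correlation of the
#' regressed pairs, reported as a positive number; a fit is \code{valid} when
#' r exceeds \code{rThreshold} (default 0.85) and the slope is positive (a
#' cytotoxic dose-response must have m > 0).
#'
#' @param dr a \linkS4class{DoseResponse}.
#' @param rThreshold goodness-of-fit requirement on r.
#' @param perReplicate regress individual replicates instead of dose means.
#' @return a \linkS4class{MedianEffectFit}.
#' @examples
#' a <- AgentModel("a", Dm = 10, m = 2)
#' dr <- simulateDoseResponse(a, 10 * 2^(-2:2), nRep = 1, cv = 0)
#' fitMedianEffect(dr)  # recovers Dm = 10, m = 2, r = 1
#' @export
fitMedianEffect <- function(dr, rThreshold = 0.85, perReplicate = FALSE) {
  p <- faValues(dr)
  if (perReplicate) {
    d <- p$dose
    fa <- p$fa
  } else {
    d <- unique(p$dose)
    fa <- vapply(split(p$fa, factor(p$dose, levels = d)), mean, numeric(1))
  }
  usable <- fa > 0 & fa < 1
  excluded <- data.frame(dose = d[!usable],
                         reason = ifelse(fa[!usable] <= 0, "fa <= 0", "fa >= 1"))
  d <- d[usable]
  fa <- fa[usable]
  if (length(unique(d)) < 2L)
    stop("insufficient data: fewer than 2 usable dose levels after exclusion")
  y <- log10(fa / (1 - fa))
  x <- log10(d)
  if (sd(y) == 0)
    stop("degenerate fit: all fa values identical")
  fit <- lm(y ~ x)
  m <- unname(coef(fit)[2])
  b <- unname(coef(fit)[1])
  r <- abs(cor(x, y))
  new("MedianEffectFit", compoundId = dr@compoundId,
      Dm = 10^(-b / m), m = m, r = r,
      nPoints = length(unique(d)),
      valid = (r > rThreshold) && (m > 0),
      rThreshold = rThreshold, excluded = excluded,
      faRange = range(fa))
}

.check_fit <- function(fit, force) {
  if (!fit@valid && !force)
    stop(sprintf(paste0("fit for '%s' is invalid (r = %.3f, threshold %.2f, ",
                        "m = %.3f); pass force = TRUE to use it anyway"),
                 fit@compoundId, fit@r, fit@rThreshold, fit@m))
}

#' Dose required for a given effect level
#'
#' Inverts the median-effect equation: Dx = Dm (fa / (1 - fa))^(1/m).
#' \code{doseForEffect(fit, 0.5)} is exactly Dm.
#'
#' @param fit a \linkS4class{MedianEffectFit} (or \linkS4class{AgentModel}).
#' @param fa effect level(s), strictly inside (0, 1).
#' @param force use an invalid fit anyway.
#' @return dose(s) in uM.
#' @export
doseForEffect <- function(fit, fa, force = FALSE) {
  if (any(fa <= 0 | fa >= 1))
    stop("boundary error: effect level must be strictly inside (0, 1)")
  if (is(fit, "MedianEffectFit")) .check_fit(fit, force)
  fit@Dm * (fa / (1 - fa))^(1 / fit@m)
}

#' Effect at a given dose
#'
#' The forward median-effect curve for a fitted series:
#' fa = D^m / (D^m + Dm^m); the exact inverse of
#' \code{\link{doseForEffect}}.
#'
#' @inheritParams doseForEffect
#' @param D dose(s) >= 0, uM.
#' @return fraction affected.
#' @export
effectAtDose <- function(fit, D, force = FALSE) {
  stopifnot(all(D >= 0))
  if (is(fit, "MedianEffectFit")) .check_fit(fit, force)
  .me_fa(D, fit@Dm, fit@m)
}
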