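## Webb fractional-product (Bliss independence) classification, for
## fixed-concentration designs and for agents whose flat dose-response
## precludes a median-effect fit.

#' Expected additive survival (fractional product)
#'
#' fu_calc = fu_A x fu_B: the Bliss-independence expectation for the
#' surviving fraction under the combination, from the single-agent survival
#' fractions.
#'
#' @param fuA,fuB survival fractions in [0, 1] (fu = 1 - fa).
#' @return the product, in [0, 1].
#' @export
expectedAdditive <- function(fuA, fuB) {
  if (any(fuA < 0 | fuA > 1 | fuB < 0 | fuB > 1))
    stop("validation error: survival fractions must lie in [0, 1]")
  fuA * fuB
}

.WEBB_SYMBOLS <- c(strong_synergy = "**S", synergy = "*S", additive = "",
                   antagonism = "*A", strong_antagonism = "**A")

#' Classify a combination by the fractional-product criteria
#'
#' Compares the observed combination survival replicates fu_det against the
#' expected additive survival fu_calc.  Strong synergy when
#' 0.7 fu_calc - mean(fu_det) >= 3 SD(fu_det); (weak) synergy when the same
#' margin reaches 1 SD; strong antagonism when
#' mean(fu_det) - 1.3 fu_calc >= 3 SD; (weak) antagonism at 1 SD; otherwise
#' additive.  SD is the sample standard deviation (n - 1 denominator).
#'
#' @param fuCalc expected additive survival (see
#'   \code{\link{expectedAdditive}}).
#' @param fuDet numeric vector of >= 2 observed combination survival
#'   replicates.
#' @return one-row data.frame: \code{fu_calc}, \code{fu_det_mean},
#'   \code{fu_det_sd}, \code{n_rep}, \code{verdict}, \code{symbol}.
#' @examples
#' classifyWebb(0.5, c(0.18, 0.20, 0.22))  # strong_synergy
#' @export
classifyWebb <- function(fuCalc, fuDet) {
  if (length(fuDet) < 2L)
    stop("insufficient data: SD needs >= 2 replicates")
  if (any(fuDet < 0 | fuDet > 1) || fuCalc < 0 || fuCalc > 1)
    stop("validation error: survival fractions must lie in [0, 1]")
  mu <- mean(fuDet)
  s <- sd(fuDet)
  syn <- 0.7 * fuCalc - mu
  ant <- mu - 1.3 * fuCalc
  verdict <- if (syn >= 3 * s) "strong_synergy"
    else if (syn >= s) "synergy"
    else if (ant >= 3 * s) "strong_antagonism"
    else if (ant >= s) "antagonism"
    else "additive"
  data.frame(fu_calc = fuCalc, fu_det_mean = mu, fu_det_sd = s,
             n_rep = length(fuDet), verdict = verdict,
             symbol = unname(.WEBB_SYMBOLS[verdict]))
}

#' Fractional-product classification along a dose grid
#'
#' Applies \code{\link{classifyWebb}} at each position of matched dose grids:
#' single-agent survivals \code{fuA[i]}, \code{fuB[i]} give the expectation,
#' the replicate combination survivals \code{fuDet[[i]]} the observation.
#'
#' @param fuA,fuB single-agent survival fractions, one per dose.
#' @param fuDet list (one element per dose) of replicate combination
#'   survival vectors, or a matrix with one row per dose.
#' @param dose optional dose annotation column.
#' @return data.frame with one row per dose and a \code{"verdict_counts"}
#'   attribute summarizing the verdicts.
#' @export
webbOverCurve <- function(fuA, fuB, fuDet, dose = seq_along(fuA)) {
  if (is.matrix(fuDet)) fuDet <- asplit(fuDet, 1)
  if (length(fuA) != length(fuB) || length(fuA) != length(fuDet))
    stop("pairing error: fuA, fuB and fuDet must share one dose grid")
  out <- do.call(rbind, Map(function(a, b, det, d)
    cbind(data.frame(dose = d, fu_a = a, fu_b = b),
          classifyWebb(expectedAdditive(a, b), det)),
    fuA, fuB, fuDet, dose))
  rownames(out) <- NULL
  counts <- table(factor(out$verdict, levels = names(.WEBB_SYMBOLS)))
  attr(out, "verdict_counts") <- counts
  out
}
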