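## Synthetic-data generators with known ground truth. All generators are
## deterministic given `seed` and leave the caller's RNG state untouched.

.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

## multiplicative lognormal noise with unit mean and coefficient of variation cv
.ln_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}

#' Median-effect fraction affected
#'
#' Evaluates the median-effect equation fa/fu = (D/Dm)^m, i.e.
#' fa = D^m / (D^m + Dm^m): the ground-truth response of an agent at a dose.
#' Strictly increasing in dose, fa(0) = 0, fa(Dm) = 0.5.
#'
#' @param agent an \linkS4class{AgentModel}.
#' @param dose dose(s) in uM, >= 0.
#' @return fraction affected in [0, 1).
#' @examples
#' a <- AgentModel("a", Dm = 10, m = 1)
#' medianEffectFa(a, c(0, 10, 90))  # 0, 0.5, 0.9
#' @export
medianEffectFa <- function(agent, dose) {
  stopifnot(is(agent, "AgentModel"), all(dose >= 0))
  .me_fa(dose, agent@Dm, agent@m)
}

.me_fa <- function(dose, Dm, m) {
  r <- (dose / Dm)^m
  r / (1 + r)
}

#' Interaction specification for simulated combinations
#'
#' Encodes the ground-truth interaction of a simulated two-drug mixture.
#' \code{"loewe_additive"}: the mixture's underlying curve satisfies the
#' Loewe sum exactly, so the combination index is 1 at every effect level.
#' \code{"fixed_ci"}: the additive mixture's Dm is scaled by \code{targetCI},
#' pinning CI at the 50\% effect level to \code{targetCI} (with the additive
#' mixture's m; when the two agents share one m, CI equals \code{targetCI} at
#' every level).
#'
#' @param mode "loewe_additive" or "fixed_ci".
#' @param targetCI ground-truth CI at fa = 0.5 (used for "fixed_ci").
#' @param ratio length-2 positive weights of the components in the total
#'   mixture dose, or NULL for the equipotent (Dm_A : Dm_B) ratio.
#' @return a list of class "InteractionSpec".
#' @export
interactionSpec <- function(mode = c("loewe_additive", "fixed_ci"),
                            targetCI = 1, ratio = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.finite(targetCI), targetCI > 0)
  if (!is.null(ratio)) {
    stopifnot(length(ratio) == 2L, all(ratio > 0))
    ratio <- ratio / sum(ratio)
  }
  structure(list(mode = mode, targetCI = targetCI, ratio = ratio),
            class = "InteractionSpec")
}

## Loewe-additive fa of a mixture at total dose D (weights wA, wB).
## Exact when mA == mB; otherwise the unique root of the Loewe sum.
.loewe_fa <- function(D, A, B, wA, wB) {
  vapply(D, function(d) {
    if (d == 0) return(0)
    g <- function(fa) {
      q <- (fa / (1 - fa))
      wA * d / (A@Dm * q^(1 / A@m)) + wB * d / (B@Dm * q^(1 / B@m)) - 1
    }
    uniroot(g, c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  }, numeric(1))
}

## Additive-mixture median-effect parameters: Dm_add is the exact total dose
## with Loewe sum 1 at fa = 0.5; m_add is the shared m (equal-m case) or the
## log-linear slope of the exact additive curve over the design doses.
.additive_params <- function(A, B, wA, wB, doses) {
  Dm_add <- 1 / (wA / A@Dm + wB / B@Dm)
  if (isTRUE(all.equal(A@m, B@m))) {
    m_add <- A@m
  } else {
    fa <- .loewe_fa(doses, A, B, wA, wB)
    fit <- lm(log10(fa / (1 - fa)) ~ log10(doses))
    m_add <- unname(coef(fit)[2])
  }
  list(Dm = Dm_add, m = m_add)
}

#' Simulate a dose-response series
#'
#' Generates replicate fa measurements at the given doses from a
#' median-effect ground truth, with multiplicative lognormal noise of
#' coefficient of variation \code{cv} applied to fa and the result clamped to
#' [0, 1].  With \code{agentB} and an \code{\link{interactionSpec}}, the
#' series is the fixed-ratio mixture (doses are total concentrations).
#'
#' @param agentA an \linkS4class{AgentModel}.
#' @param doses positive doses, uM (two-fold series around Dm by default
#'   elsewhere; here explicit).
#' @param nRep replicates per dose (>= 1), default 4 as in the constant-ratio
#'   assay design.
#' @param cv coefficient of variation of the noise (default 0.05).
#' @param seed integer seed or NULL.
#' @param agentB optional second \linkS4class{AgentModel}.
#' @param interaction an \code{\link{interactionSpec}} (required with
#'   \code{agentB}).
#' @return a \linkS4class{DoseResponse}.
#' @export
simulateDoseResponse <- function(agentA, doses, nRep = 4L, cv = 0.05,
                                 seed = NULL, agentB = NULL,
                                 interaction = NULL) {
  stopifnot(all(doses > 0))
  if (nRep < 1L) stop("nRep must be at least 1")
  doses <- sort(unique(doses))
  if (is.null(agentB)) {
    fa_true <- medianEffectFa(agentA, doses)
    id <- agentA@compoundId
    mr <- NULL
  } else {
    if (is.null(interaction)) stop("a mixture needs an interactionSpec")
    w <- interaction$ratio
    if (is.null(w)) w <- c(agentA@Dm, agentB@Dm) / (agentA@Dm + agentB@Dm)
    if (interaction$mode == "loewe_additive") {
      fa_true <- .loewe_fa(doses, agentA, agentB, w[1], w[2])
    } else {
      ap <- .additive_params(agentA, agentB, w[1], w[2], doses)
      fa_true <- .me_fa(doses, interaction$targetCI * ap$Dm, ap$m)
    }
    id <- paste(agentA@compoundId, agentB@compoundId, sep = "+")
    mr <- list(components = c(agentA@compoundId, agentB@compoundId),
               weights = w)
  }
  fa <- .with_seed(seed, {
    noise <- .ln_noise(length(doses) * nRep, cv)
    pmin(pmax(rep(fa_true, each = nRep) * noise, 0), 1)
  })
  DoseResponse(id, dose = rep(doses, each = nRep), fa = fa, mixtureRatio = mr)
}

#' Simulate the three series of a constant-ratio design
#'
#' Convenience wrapper producing drug A alone, drug B alone, and their
#' fixed-ratio mixture, each as a two-fold dilution series of \code{nDoses}
#' concentrations centred on the series' own Dm (from 1/4 x to 4 x Dm for the
#' default 5 doses, the standard design).
#'
#' @inheritParams simulateDoseResponse
#' @param interaction an \code{\link{interactionSpec}}.
#' @param nDoses doses per series (default 5).
#' @return list with elements \code{drA}, \code{drB}, \code{drMix},
#'   \code{weights}.
#' @export
simulateConstantRatio <- function(agentA, agentB, interaction, nDoses = 5L,
                                  nRep = 4L, cv = 0.05, seed = NULL) {
  w <- interaction$ratio
  if (is.null(w)) w <- c(agentA@Dm, agentB@Dm) / (agentA@Dm + agentB@Dm)
  series_doses <- function(Dm)
    Dm * 2^(seq_len(nDoses) - (nDoses + 1) / 2)
  dosesA <- series_doses(agentA@Dm)
  dosesB <- series_doses(agentB@Dm)
  ap <- .additive_params(agentA, agentB, w[1], w[2],
                         series_doses(1 / (w[1] / agentA@Dm + w[2] / agentB@Dm)))
  mix_centre <- if (interaction$mode == "fixed_ci")
    interaction$targetCI * ap$Dm else ap$Dm
  seeds <- if (is.null(seed)) list(NULL, NULL, NULL) else
    as.list(seed + 0:2)
  interaction$ratio <- w
  list(drA = simulateDoseResponse(agentA, dosesA, nRep, cv, seeds[[1]]),
       drB = simulateDoseResponse(agentB, dosesB, nRep, cv, seeds[[2]]),
       drMix = simulateDoseResponse(agentA, series_doses(mix_centre), nRep,
                                    cv, seeds[[3]], agentB = agentB,
                                    interaction = interaction),
       weights = setNames(w, c(agentA@compoundId, agentB@compoundId)))
}

#' Simulate a raw screen-plate read
#'
#' Raw-signal model: expected signal = floor + (ctrl - floor) x (1 - score),
#' where ctrl is the negative-control level, the background floor defaults to
#' 2\% of ctrl, and score is the well's true HTS score (0 for negative
#' controls, 1 for positive controls, the entry of \code{effects} for library
#' and combination wells).  Multiplicative lognormal noise with coefficient
#' of variation \code{cv} is applied per well.  At cv = 0,
#' \code{\link{normalizePlate}} recovers every true score exactly.
#'
#' @param layout a \linkS4class{PlateLayout}.
#' @param effects named numeric vector: true score in [0, 1] (or beyond) per
#'   \code{compound_id}; required for every library/combination well.
#' @param ctrlSignal expected negative-control signal (arbitrary units).
#' @param cv noise coefficient of variation.
#' @param seed integer seed or NULL.
#' @param floorFrac background floor as a fraction of \code{ctrlSignal}.
#' @param replicateId replicate label.
#' @return a \linkS4class{PlateRead} covering every non-empty well.
#' @export
simulateScreenPlate <- function(layout, effects, ctrlSignal = 1e4, cv = 0.05,
                                seed = NULL, floorFrac = 0.02,
                                replicateId = "r1") {
  w <- wells(layout)
  w <- w[w$role != "empty", , drop = FALSE]
  lib <- w$role %in% c("library", "combination")
  if (any(lib & !(w$compound_id %in% names(effects))))
    stop("missing effect for library compound(s): ",
         paste(setdiff(w$compound_id[lib], names(effects)), collapse = ", "))
  score <- numeric(nrow(w))
  score[w$role == "negative_control"] <- 0
  score[w$role == "positive_control"] <- 1
  score[lib] <- effects[w$compound_id[lib]]
  floor_sig <- floorFrac * ctrlSignal
  mu <- floor_sig + (ctrlSignal - floor_sig) * (1 - score)
  sig <- .with_seed(seed, mu * .ln_noise(length(mu), cv))
  PlateRead(plateId(layout),
            data.frame(row = w$row, col = w$col, signal = pmax(sig, 0)),
            replicateId = replicateId)
}

#' Simulate a high-content object table
#'
#' Draws \code{nLive} live and \code{nDead} dead nuclei.  Live objects have
#' low PI and high Calcein; dead objects have high PI correlated with their
#' Hoechst intensity (PI is proportional to Hoechst up to lognormal scatter)
#' and low Calcein.  Intensity scales are arbitrary units chosen to mimic the
#' order of magnitude of segmented-nucleus mean intensities.
#'
#' @param nLive,nDead object counts (>= 0).
#' @param seed integer seed or NULL.
#' @param well,timepoint annotation for the resulting table.
#' @param params optional list overriding the intensity parameters
#'   (\code{hoechstMean}, \code{livePiMean}, \code{deadPiGain},
#'   \code{liveCalceinMean}, \code{deadCalceinMean}, \code{sdlog}).
#' @return an \linkS4class{HCAObjectTable} with nLive + nDead rows.
#' @export
simulateHCAObjects <- function(nLive, nDead, seed = NULL, well = "A1",
                               timepoint = 72, params = list()) {
  stopifnot(nLive >= 0, nDead >= 0)
  p <- utils::modifyList(list(hoechstMean = 1000, livePiMean = 40,
                              deadPiGain = 0.8, liveCalceinMean = 800,
                              deadCalceinMean = 40, sdlog = 0.25), params)
  obj <- .with_seed(seed, {
    ho <- rlnorm(nLive + nDead, log(p$hoechstMean), p$sdlog)
    pi_live <- rlnorm(nLive, log(p$livePiMean), p$sdlog)
    ## dead: PI tracks Hoechst (correlated channels), plus the live baseline
    pi_dead <- p$deadPiGain * ho[seq_len(nDead) + nLive] *
      rlnorm(nDead, 0, p$sdlog / 2) + p$livePiMean
    ca <- c(rlnorm(nLive, log(p$liveCalceinMean), p$sdlog),
            rlnorm(nDead, log(p$deadCalceinMean), p$sdlog))
    data.frame(hoechst = ho, pi = c(pi_live, pi_dead), calcein = ca)
  })
  HCAObjectTable(well, timepoint, obj)
}
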