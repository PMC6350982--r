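setClassUnion("listOrNULL", c("list", "NULL"))

.WELL_ROLES <- c("negative_control", "positive_control", "library",
                 "combination", "empty")

## ---------------------------------------------------------------------------
## PlateLayout
## ---------------------------------------------------------------------------

#' Plate layout: geometry and well roles of a screen plate
#'
#' A \code{PlateLayout} describes the geometry (default 16 x 24, i.e. a
#' 384-well plate) and the role of each well: negative control (cells +
#' vehicle), positive control (cells + a fully cytotoxic reference drug),
#' library well (one test compound), combination well, or empty.  For
#' combination plates a platinum ("Pt") drug at fixed concentration is present
#' in every non-empty well, controls included, and is recorded in
#' \code{pt_drug_id} / \code{pt_concentration}; normalization against the
#' in-plate controls then scores each library compound relative to the effect
#' of the Pt drug alone.
#'
#' @slot plateId character plate identifier.
#' @slot nRows,nCols integer plate dimensions.
#' @slot wells data.frame with columns \code{row}, \code{col} (1-based
#'   integers), \code{role}, \code{compound_id}, \code{concentration} (uM),
#'   \code{pt_drug_id}, \code{pt_concentration} (uM).
#'
#' @section Validity:
#' Every (row, col) pair appears at most once and lies inside the plate;
#' roles are restricted to the set above; control wells carry no library
#' compound; empty wells carry nothing; on a combination plate all non-empty
#' wells share one \code{pt_drug_id} and one \code{pt_concentration}.
#'
#' @examples
#' lay <- primaryScreenLayout("P1", paste0("cmpd", 1:10))
#' table(wells(lay)$role)
#' @export
setClass("PlateLayout",
  slots = c(plateId = "character", nRows = "integer", nCols = "integer",
            wells = "data.frame"))

.validPlateLayout <- function(object) {
  w <- object@wells
  msg <- character()
  need <- c("row", "col", "role", "compound_id", "concentration",
            "pt_drug_id", "pt_concentration")
  if (!all(need %in% names(w)))
    return(paste("wells lacks columns:",
                 paste(setdiff(need, names(w)), collapse = ", ")))
  if (anyDuplicated(w[, c("row", "col")]))
    msg <- c(msg, "duplicate well address in layout")
  if (any(w$row < 1L | w$row > object@nRows | w$col < 1L | w$col > object@nCols))
    msg <- c(msg, "well address outside plate geometry")
  if (!all(w$role %in% .WELL_ROLES))
    msg <- c(msg, paste("unknown well role:",
                        paste(unique(setdiff(w$role, .WELL_ROLES)), collapse = ", ")))
  ctrl <- w$role %in% c("negative_control", "positive_control")
  if (any(ctrl & !is.na(w$compound_id)))
    msg <- c(msg, "control wells must not carry a library compound")
  emp <- w$role == "empty"
  if (any(emp & (!is.na(w$compound_id) | !is.na(w$pt_drug_id))))
    msg <- c(msg, "empty wells must carry nothing")
  ## combination-plate consistency: any Pt annotation must be plate-wide
  nonempty <- !emp
  if (any(!is.na(w$pt_drug_id[nonempty]))) {
    ids <- unique(w$pt_drug_id[nonempty])
    conc <- unique(w$pt_concentration[nonempty])
    if (length(ids) != 1L || anyNA(ids))
      msg <- c(msg, "combination plate with mixed or partial pt_drug_id")
    if (length(conc) != 1L || anyNA(conc))
      msg <- c(msg, "combination plate with mixed or partial pt_concentration")
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
}
setValidity("PlateLayout", .validPlateLayout)

#' Construct a PlateLayout
#'
#' @param plateId plate identifier.
#' @param wells data.frame as documented in \linkS4class{PlateLayout}.
#' @param nRows,nCols plate geometry (defaults 16 x 24).
#' @return a validated \linkS4class{PlateLayout}.
#' @export
PlateLayout <- function(plateId, wells, nRows = 16L, nCols = 24L) {
  wells$row <- as.integer(wells$row)
  wells$col <- as.integer(wells$col)
  for (col in c("compound_id", "pt_drug_id"))
    wells[[col]] <- as.character(wells[[col]])
  for (col in c("concentration", "pt_concentration"))
    wells[[col]] <- as.numeric(wells[[col]])
  rownames(wells) <- NULL
  new("PlateLayout", plateId = as.character(plateId),
      nRows = as.integer(nRows), nCols = as.integer(nCols),
      wells = as.data.frame(wells, stringsAsFactors = FALSE))
}

#' @rdname accessors
#' @export
setMethod("plateId", "PlateLayout", function(object) object@plateId)

#' @rdname accessors
#' @export
setMethod("wells", "PlateLayout", function(object) object@wells)

setMethod("show", "PlateLayout", function(object) {
  cat(sprintf("PlateLayout '%s' (%d x %d)\n", object@plateId,
              object@nRows, object@nCols))
  print(table(role = object@wells$role))
  pt <- unique(stats::na.omit(object@wells$pt_drug_id))
  if (length(pt))
    cat(sprintf("combination plate: %s at %g uM\n", pt,
                unique(stats::na.omit(object@wells$pt_concentration))[1]))
})

## ---------------------------------------------------------------------------
## PlateRead
## ---------------------------------------------------------------------------

#' Raw fluorescence read of one plate
#'
#' Bottom-read fluorescence intensities (arbitrary units, one value per
#' measured well) for a single replicate of a plate.
#'
#' @slot plateId,replicateId character identifiers.
#' @slot signal data.frame with columns \code{row}, \code{col}, \code{signal}.
#' @export
setClass("PlateRead",
  slots = c(plateId = "character", replicateId = "character",
            signal = "data.frame"))

setValidity("PlateRead", function(object) {
  s <- object@signal
  if (!all(c("row", "col", "signal") %in% names(s)))
    return("signal needs columns row, col, signal")
  if (anyDuplicated(s[, c("row", "col")]))
    return("duplicate well address in signal")
  if (any(!is.finite(s$signal)) || any(s$signal < 0))
    return("signals must be finite and non-negative")
  TRUE
})

#' Construct a PlateRead
#'
#' @param plateId,replicateId identifiers.
#' @param signal data.frame with columns \code{row}, \code{col}, \code{signal}.
#' @return a validated \linkS4class{PlateRead}.
#' @export
PlateRead <- function(plateId, signal, replicateId = "r1") {
  signal$row <- as.integer(signal$row)
  signal$col <- as.integer(signal$col)
  signal$signal <- as.numeric(signal$signal)
  new("PlateRead", plateId = as.character(plateId),
      replicateId = as.character(replicateId),
      signal = as.data.frame(signal, stringsAsFactors = FALSE))
}

#' @rdname accessors
#' @export
setMethod("plateId", "PlateRead", function(object) object@plateId)

#' @rdname accessors
#' @export
setMethod("signals", "PlateRead", function(object) object@signal)

setMethod("show", "PlateRead", function(object) {
  cat(sprintf("PlateRead '%s' replicate '%s': %d wells, signal range [%g, %g]\n",
              object@plateId, object@replicateId, nrow(object@signal),
              min(object@signal$signal), max(object@signal$signal)))
})

## ---------------------------------------------------------------------------
## DoseResponse
## ---------------------------------------------------------------------------

#' Dose-response series on the fraction-affected scale
#'
#' A series of (dose, fa) measurements for a single agent or a fixed-ratio
#' mixture treated as one agent (the constant-ratio "diagonal" design).  fa is
#' the fraction of cells affected, fu = 1 - fa the surviving fraction.  For a
#' mixture, doses are total concentrations (sum of the components) and
#' \code{mixtureRatio} records the component ids and their weight in the
#' total.
#'
#' @slot compoundId character.
#' @slot points data.frame with columns \code{dose} (uM, > 0),
#'   \code{replicate}, \code{fa} (in [0, 1]).
#' @slot mixtureRatio \code{NULL} for a single agent, else
#'   \code{list(components = c(idA, idB), weights = c(wA, wB))} with positive
#'   weights summing to 1.
#' @export
setClass("DoseResponse",
  slots = c(compoundId = "character", points = "data.frame",
            mixtureRatio = "listOrNULL"))

setValidity("DoseResponse", function(object) {
  p <- object@points
  if (!all(c("dose", "replicate", "fa") %in% names(p)))
    return("points needs columns dose, replicate, fa")
  if (any(!is.finite(p$dose)) || any(p$dose <= 0))
    return("doses must be finite and strictly positive")
  bad <- which(!is.finite(p$fa) | p$fa < 0 | p$fa > 1)
  if (length(bad))
    return(sprintf("fa outside [0, 1] at row(s) %s",
                   paste(bad, collapse = ", ")))
  if (is.unsorted(unique(p$dose), strictly = TRUE))
    return("dose levels must be strictly increasing")
  mr <- object@mixtureRatio
  if (!is.null(mr)) {
    if (!all(c("components", "weights") %in% names(mr)))
      return("mixtureRatio needs elements 'components' and 'weights'")
    if (length(mr$weights) != length(mr$components) || any(mr$weights <= 0))
      return("mixture ratio weights must be positive, one per component")
  }
  TRUE
})

#' Construct a DoseResponse
#'
#' @param compoundId agent (or mixture) identifier.
#' @param dose numeric vector of doses (uM), one per measurement.
#' @param fa numeric vector of fraction-affected values in [0, 1].
#' @param replicate optional replicate labels (default: numbered within dose).
#' @param mixtureRatio \code{NULL} or \code{list(components=, weights=)}; the
#'   weights are normalized to sum to 1.
#' @return a validated \linkS4class{DoseResponse}, points ordered by dose.
#' @export
DoseResponse <- function(compoundId, dose, fa, replicate = NULL,
                         mixtureRatio = NULL) {
  if (length(dose) != length(fa))
    stop("dose and fa must have equal length")
  if (is.null(replicate))
    replicate <- stats::ave(seq_along(dose), dose, FUN = seq_along)
  p <- data.frame(dose = as.numeric(dose), replicate = as.character(replicate),
                  fa = as.numeric(fa), stringsAsFactors = FALSE)
  p <- p[order(p$dose, p$replicate), , drop = FALSE]
  rownames(p) <- NULL
  if (!is.null(mixtureRatio))
    mixtureRatio$weights <- mixtureRatio$weights / sum(mixtureRatio$weights)
  new("DoseResponse", compoundId = as.character(compoundId), points = p,
      mixtureRatio = mixtureRatio)
}

#' @rdname accessors
#' @export
setMethod("doses", "DoseResponse", function(object) unique(object@points$dose))

#' @rdname accessors
#' @export
setMethod("faValues", "DoseResponse", function(object) object@points)

#' @rdname accessors
#' @export
setMethod("mixtureRatio", "DoseResponse", function(object) object@mixtureRatio)

setMethod("show", "DoseResponse", function(object) {
  cat(sprintf("DoseResponse '%s': %d doses x up to %d replicates\n",
              object@compoundId, length(doses(object)),
              max(table(object@points$dose))))
  if (!is.null(object@mixtureRatio))
    cat(sprintf("mixture of %s (weights %s)\n",
                paste(object@mixtureRatio$components, collapse = " + "),
                paste(signif(object@mixtureRatio$weights, 3), collapse = " : ")))
})

## ---------------------------------------------------------------------------
## HCAObjectTable
## ---------------------------------------------------------------------------

#' Per-object high-content measurements for one well
#'
#' One row per segmented nucleus with Hoechst (nuclear), PI (dead-cell) and
#' Calcein (live-cell) mean intensities, as exported by image-segmentation
#' software.  Segmentation itself is upstream of this package.
#'
#' @slot well character well name ("B3").
#' @slot timepoint numeric exposure time in hours.
#' @slot objects data.frame with columns \code{hoechst}, \code{pi},
#'   \code{calcein} (arbitrary units, finite and non-negative).
#' @export
setClass("HCAObjectTable",
  slots = c(well = "character", timepoint = "numeric", objects = "data.frame"))

setValidity("HCAObjectTable", function(object) {
  o <- object@objects
  if (!all(c("hoechst", "pi", "calcein") %in% names(o)))
    return("objects needs columns hoechst, pi, calcein")
  v <- unlist(o[, c("hoechst", "pi", "calcein")], use.names = FALSE)
  if (length(v) && (any(!is.finite(v)) || any(v < 0)))
    return("intensities must be finite and non-negative")
  TRUE
})

#' Construct an HCAObjectTable
#'
#' @param well well name, e.g. "B3".
#' @param timepoint hours of exposure.
#' @param objects data.frame with columns \code{hoechst}, \code{pi},
#'   \code{calcein}.
#' @return a validated \linkS4class{HCAObjectTable}.
#' @export
HCAObjectTable <- function(well, timepoint, objects) {
  new("HCAObjectTable", well = as.character(well),
      timepoint = as.numeric(timepoint),
      objects = as.data.frame(objects, stringsAsFactors = FALSE))
}

setMethod("show", "HCAObjectTable", function(object) {
  cat(sprintf("HCAObjectTable well %s, t = %g h: %d objects\n",
              object@well, object@timepoint, nrow(object@objects)))
})

## ---------------------------------------------------------------------------
## AgentModel (synthetic ground truth)
## ---------------------------------------------------------------------------

#' Median-effect agent model
#'
#' Ground-truth dose-response model of one agent for the synthetic-data
#' generator: fa/fu = (D/Dm)^m, so fa(D) = D^m / (D^m + Dm^m).  Dm is the
#' median-effect dose (the IC50) and m the sigmoidicity (shape) of the curve.
#'
#' @slot compoundId character.
#' @slot Dm numeric median-effect dose, uM, > 0.
#' @slot m numeric sigmoidicity, > 0.
#' @export
setClass("AgentModel",
  slots = c(compoundId = "character", Dm = "numeric", m = "numeric"))

setValidity("AgentModel", function(object) {
  if (length(object@Dm) != 1L || !is.finite(object@Dm) || object@Dm <= 0)
    return("Dm must be a single positive number")
  if (length(object@m) != 1L || !is.finite(object@m) || object@m <= 0)
    return("m must be a single positive number")
  TRUE
})

#' Construct an AgentModel
#'
#' @param compoundId agent identifier.
#' @param Dm median-effect dose (IC50), uM.
#' @param m sigmoidicity, unitless.
#' @return an \linkS4class{AgentModel}.
#' @examples
#' cis <- AgentModel("cisplatin", Dm = 15, m = 1.5)  # PANC-1 IC50
#' medianEffectFa(cis, 15)  # 0.5 by definition
#' @export
AgentModel <- function(compoundId, Dm, m) {
  new("AgentModel", compoundId = as.character(compoundId),
      Dm = as.numeric(Dm), m = as.numeric(m))
}

#' @rdname accessors
#' @export
setMethod("Dm", "AgentModel", function(object) object@Dm)

#' @rdname accessors
#' @export
setMethod("mCoef", "AgentModel", function(object) object@m)

setMethod("show", "AgentModel", function(object) {
  cat(sprintf("AgentModel '%s': Dm = %g uM, m = %g\n",
              object@compoundId, object@Dm, object@m))
})

## ---------------------------------------------------------------------------
## ScoreTable
## ---------------------------------------------------------------------------

#' Normalized HTS scores of one plate
#'
#' Per-well HTS scores anchored at the in-plate controls: a well at the
#' negative-control mean signal scores exactly 0, one at the positive-control
#' mean scores exactly 1.  Scores are deliberately not clipped to [0, 1];
#' clipping happens only when scores are converted to fa (\code{\link{scoreToFa}}).
#' The plate noise floor is the mean negative-control score (0 by
#' construction) plus three negative-control score standard deviations.
#'
#' @slot plateId,replicateId character.
#' @slot scores data.frame: \code{row}, \code{col}, \code{role},
#'   \code{compound_id}, \code{signal}, \code{score}.
#' @slot negMean,negSD,posMean,posSD raw-signal control statistics.
#' @slot noiseFloor numeric, on the score scale.
#' @export
setClass("ScoreTable",
  slots = c(plateId = "character", replicateId = "character",
            scores = "data.frame", negMean = "numeric", negSD = "numeric",
            posMean = "numeric", posSD = "numeric", noiseFloor = "numeric"))

#' @rdname accessors
#' @export
setMethod("plateId", "ScoreTable", function(object) object@plateId)

#' @rdname accessors
#' @export
setMethod("scores", "ScoreTable", function(object) object@scores)

setMethod("show", "ScoreTable", function(object) {
  cat(sprintf(paste0("ScoreTable '%s' (%s): %d wells\n",
                     "controls %g +/- %g (neg) vs %g +/- %g (pos); ",
                     "noise floor %.4f (score scale)\n"),
              object@plateId, object@replicateId, nrow(object@scores),
              signif(object@negMean, 4), signif(object@negSD, 3),
              signif(object@posMean, 4), signif(object@posSD, 3),
              object@noiseFloor))
})

## ---------------------------------------------------------------------------
## MedianEffectFit
## ---------------------------------------------------------------------------

#' Median-effect fit of a dose-response series
#'
#' Result of the log-linear median-effect regression: log10(fa/fu) on
#' log10(D) gives slope m and intercept -m log10(Dm).  r is the linear
#' correlation coefficient of the regressed pairs (reported positive); a fit
#' is valid when r exceeds the threshold (default 0.85) and the slope is
#' positive.
#'
#' @slot compoundId character.
#' @slot Dm,m,r numeric fit parameters.
#' @slot nPoints integer number of dose levels used.
#' @slot valid logical.
#' @slot rThreshold numeric threshold used.
#' @slot excluded data.frame (\code{dose}, \code{reason}) of dropped points.
#' @slot faRange numeric(2), observed mean-fa range (for extrapolation flags).
#' @export
setClass("MedianEffectFit",
  slots = c(compoundId = "character", Dm = "numeric", m = "numeric",
            r = "numeric", nPoints = "integer", valid = "logical",
            rThreshold = "numeric", excluded = "data.frame",
            faRange = "numeric"))

setValidity("MedianEffectFit", function(object) {
  if (object@Dm <= 0) return("Dm must be positive")
  if (object@nPoints < 2L) return("a fit needs at least 2 points")
  if (object@valid && object@r <= object@rThreshold)
    return("valid fit requires r above threshold")
  TRUE
})

#' @rdname accessors
#' @export
setMethod("Dm", "MedianEffectFit", function(object) object@Dm)

#' @rdname accessors
#' @export
setMethod("mCoef", "MedianEffectFit", function(object) object@m)

#' @rdname accessors
#' @export
setMethod("rCoef", "MedianEffectFit", function(object) object@r)

#' @rdname accessors
#' @export
setMethod("isValidFit", "MedianEffectFit", function(object) object@valid)

setMethod("show", "MedianEffectFit", function(object) {
  cat(sprintf("MedianEffectFit '%s': Dm = %.4g uM, m = %.4g, r = %.4f (%s, %d points)\n",
              object@compoundId, object@Dm, object@m, object@r,
              if (object@valid) "valid" else
                sprintf("INVALID, r threshold %.2f", object@rThreshold),
              object@nPoints))
  if (nrow(object@excluded))
    cat(sprintf("excluded doses: %s\n",
                paste(signif(object@excluded$dose, 4), collapse = ", ")))
})

## ---------------------------------------------------------------------------
## ConstantRatioDesign / CombinationResult
## ---------------------------------------------------------------------------

#' Constant-ratio combination design
#'
#' The diagonal constant-ratio design: dose-response series for drug A alone,
#' drug B alone, and their fixed-ratio mixture (treated as one agent in total
#' dose), together with the three median-effect fits and the mixture weights
#' (wA + wB = 1 of the total dose).
#'
#' @slot drA,drB,drMix \linkS4class{DoseResponse} series.
#' @slot fitA,fitB,fitMix \linkS4class{MedianEffectFit} fits.
#' @slot weights named numeric(2), fractions of total mixture dose.
#' @slot ratioLabel character, the "1 : x" notation.
#' @export
setClass("ConstantRatioDesign",
  slots = c(drA = "DoseResponse", drB = "DoseResponse", drMix = "DoseResponse",
            fitA = "MedianEffectFit", fitB = "MedianEffectFit",
            fitMix = "MedianEffectFit", weights = "numeric",
            ratioLabel = "character"))

setValidity("ConstantRatioDesign", function(object) {
  if (length(object@weights) != 2L || any(object@weights <= 0))
    return("weights must be two positive numbers")
  if (abs(sum(object@weights) - 1) > 1e-8)
    return("weights must sum to 1")
  TRUE
})

#' @rdname accessors
#' @export
setMethod("ratioWeights", "ConstantRatioDesign", function(object) object@weights)

setMethod("show", "ConstantRatioDesign", function(object) {
  cat(sprintf("ConstantRatioDesign %s + %s (ratio %s)\n",
              object@fitA@compoundId, object@fitB@compoundId,
              object@ratioLabel))
  for (f in list(object@fitA, object@fitB, object@fitMix)) show(f)
})

#' Full combination-index analysis result
#'
#' Combination index CI(fa) with sequential-deletion confidence intervals,
#' dose-reduction indices, the weighted combination index CI_wt, its synergy
#' grade symbol, isobologram points and the Fa-CI curve.  CI < 1 indicates
#' synergism, CI = 1 additivity, CI > 1 antagonism.
#'
#' @slot design the \linkS4class{ConstantRatioDesign} analysed.
#' @slot effectLevels numeric effect levels (fa) reported.
#' @slot ciAt data.frame: \code{fa}, \code{ci}, \code{extrapolated}.
#' @slot sda data.frame: \code{fa}, \code{mean}, \code{halfwidth},
#'   \code{n_deletions}.
#' @slot ciWt numeric weighted CI.
#' @slot grade character symbol ("+++", "-", ...).
#' @slot driAt data.frame: \code{fa}, \code{dri_a}, \code{dri_b}.
#' @slot isobologram data.frame: \code{level}, \code{dx_a}, \code{dx_b},
#'   \code{d_a}, \code{d_b}.
#' @slot faCiCurve data.frame: \code{fa}, \code{ci}, \code{extrapolated}.
#' @export
setClass("CombinationResult",
  slots = c(design = "ConstantRatioDesign", effectLevels = "numeric",
            ciAt = "data.frame", sda = "data.frame", ciWt = "numeric",
            grade = "character", driAt = "data.frame",
            isobologram = "data.frame", faCiCurve = "data.frame"))

#' @rdname accessors
#' @export
setMethod("ciWt", "CombinationResult", function(object) object@ciWt)

#' @rdname accessors
#' @export
setMethod("gradeSymbol", "CombinationResult", function(object) object@grade)

setMethod("show", "CombinationResult", function(object) {
  cat(sprintf("CombinationResult %s + %s (ratio %s)\n",
              object@design@fitA@compoundId, object@design@fitB@compoundId,
              object@design@ratioLabel))
  ci <- object@ciAt
  sda <- object@sda
  for (i in seq_len(nrow(ci))) {
    hw <- sda$halfwidth[match(ci$fa[i], sda$fa)]
    cat(sprintf("  CI at fa = %.2f: %.3f%s%s\n", ci$fa[i], ci$ci[i],
                if (length(hw) && is.finite(hw))
                  sprintf(" (S.D.A. %.3f +/- %.3f)",
                          sda$mean[match(ci$fa[i], sda$fa)], hw) else "",
                if (ci$extrapolated[i]) " [extrapolated]" else ""))
  }
  cat(sprintf("  CI_wt = %.3f  grade %s\n", object@ciWt, object@grade))
})
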