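## Plate normalization, Z'-factor QC and hit calling.

.control_stats <- function(read, layout) {
  w <- wells(layout)
  s <- signals(read)
  m <- merge(w, s, by = c("row", "col"))
  neg <- m$signal[m$role == "negative_control"]
  pos <- m$signal[m$role == "positive_control"]
  if (length(neg) < 2L || length(pos) < 2L)
    stop("need at least 2 negative and 2 positive control wells with signal")
  list(m = m, negMean = mean(neg), negSD = sd(neg),
       posMean = mean(pos), posSD = sd(pos))
}

#' Normalize a plate read to HTS scores
#'
#' score(w) = (Av_neg - signal(w)) / (Av_neg - Av_pos), anchoring a score of
#' 0 at the average negative-control fluorescence and 1 at the average
#' positive-control fluorescence of the same plate.  On a combination plate
#' the in-plate controls themselves contain the Pt drug, so this same formula
#' normalizes every well to the effect of the Pt drug alone.  Scores are not
#' clipped: values above 1 or below 0 are informative for QC.
#'
#' The plate noise floor is returned on the score scale as the mean
#' negative-control score (0 by construction) plus 3 negative-control score
#' standard deviations; compound scores at or below it are indistinguishable
#' from untreated wells.
#'
#' @param read a \linkS4class{PlateRead}.
#' @param layout the matching \linkS4class{PlateLayout}.
#' @return a \linkS4class{ScoreTable}.
#' @examples
#' lay <- primaryScreenLayout("P1", paste0("c", 1:4))
#' rd <- simulateScreenPlate(lay, setNames(c(.1, .2, .5, .9), paste0("c", 1:4)),
#'                           cv = 0, seed = 1)
#' st <- normalizePlate(rd, lay)
#' head(scores(st))
#' @export
normalizePlate <- function(read, layout) {
  cs <- .control_stats(read, layout)
  if (isTRUE(all.equal(cs$negMean, cs$posMean)))
    stop("degenerate plate: negative and positive control means are equal")
  span <- cs$negMean - cs$posMean
  m <- cs$m
  m$score <- (cs$negMean - m$signal) / span
  m <- m[order(m$row, m$col),
         c("row", "col", "role", "compound_id", "signal", "score")]
  rownames(m) <- NULL
  neg_scores <- m$score[m$role == "negative_control"]
  new("ScoreTable", plateId = plateId(read), replicateId = read@replicateId,
      scores = m, negMean = cs$negMean, negSD = cs$negSD,
      posMean = cs$posMean, posSD = cs$posSD,
      noiseFloor = mean(neg_scores) + 3 * sd(neg_scores))
}

#' Z'-factor plate QC
#'
#' Screening-window coefficient computed on the raw control signals:
#' Z' = 1 - 3 (SD_pos + SD_neg) / |Av_pos - Av_neg|.  Z' <= 1 always; a plate
#' passes when Z' exceeds the threshold (default 0.4, the lower end of the
#' commonly used 0.4-0.5 band).
#'
#' @param read a \linkS4class{PlateRead}.
#' @param layout the matching \linkS4class{PlateLayout}.
#' @param threshold pass threshold on Z'.
#' @return one-row data.frame: \code{plate_id}, \code{replicate_id},
#'   \code{z_prime}, \code{pass}, \code{threshold}.
#' @export
zPrime <- function(read, layout, threshold = 0.4) {
  cs <- .control_stats(read, layout)
  if (isTRUE(all.equal(cs$negMean, cs$posMean)))
    stop("degenerate plate: negative and positive control means are equal")
  z <- 1 - 3 * (cs$posSD + cs$negSD) / abs(cs$posMean - cs$negMean)
  data.frame(plate_id = plateId(read), replicate_id = read@replicateId,
             z_prime = z, pass = z > threshold, threshold = threshold)
}

#' Replicate statistics of compound scores
#'
#' Pools the library/combination wells of replicate score tables of the same
#' condition and returns per-compound mean and SD over replicates, together
#' with the plate noise floor (averaged over replicates) and whether the mean
#' score clears it.
#'
#' @param scoreTables a \linkS4class{ScoreTable} or list of them (replicates
#'   of one condition).
#' @return data.frame: \code{compound_id}, \code{mean}, \code{sd}, \code{n},
#'   \code{noise_floor}, \code{above_noise_floor}.
#' @export
compoundScores <- function(scoreTables) {
  if (is(scoreTables, "ScoreTable")) scoreTables <- list(scoreTables)
  floor <- mean(vapply(scoreTables, function(x) x@noiseFloor, numeric(1)))
  df <- do.call(rbind, lapply(scoreTables, function(x) {
    s <- scores(x)
    s[s$role %in% c("library", "combination"), c("compound_id", "score")]
  }))
  agg <- do.call(rbind, lapply(split(df$score, df$compound_id), function(v)
    data.frame(mean = mean(v), sd = sd(v), n = length(v))))
  out <- data.frame(compound_id = rownames(agg), agg,
                    noise_floor = floor, row.names = NULL)
  out$above_noise_floor <- out$mean > out$noise_floor
  out[order(out$compound_id), , drop = FALSE]
}

#' Call hit combinations
#'
#' Compares each compound's score in combination with a Pt drug against its
#' score alone.  A combination is only considered when its mean score clears
#' the combination plate's noise floor (negative-control mean + 3 SD).  Rule
#' variants: \code{"as_printed"} calls a hit when
#' Mean_combo + SD_combo > Mean_alone - SD_alone and additionally
#' Mean_combo > Mean_alone (the higher-mean requirement stated with the
#' rule); \code{"strict"} requires Mean_combo - SD_combo >
#' Mean_alone + SD_alone.  A strict hit is always an as-printed hit.
#'
#' @param alone,combo outputs of \code{\link{compoundScores}} for the
#'   compound-alone and compound-plus-Pt conditions (matching compound sets).
#' @param ruleVariant "as_printed" (default) or "strict".
#' @param ptDrugId,ptConcentration annotation carried into the result.
#' @return data.frame with one row per compound: means/SDs alone and in
#'   combination, \code{above_noise_floor}, \code{is_hit},
#'   \code{rule_variant}.
#' @export
callHits <- function(alone, combo, ruleVariant = c("as_printed", "strict"),
                     ptDrugId = NA_character_, ptConcentration = NA_real_) {
  ruleVariant <- match.arg(ruleVariant)
  if (!setequal(alone$compound_id, combo$compound_id))
    stop("pairing error: compound sets of 'alone' and 'combo' differ")
  combo <- combo[match(alone$compound_id, combo$compound_id), , drop = FALSE]
  if (any(alone$n < 2L) || any(combo$n < 2L))
    stop("hit calling needs >= 2 replicates per condition")
  considered <- combo$above_noise_floor
  rule <- if (ruleVariant == "strict")
    combo$mean - combo$sd > alone$mean + alone$sd
  else
    (combo$mean + combo$sd > alone$mean - alone$sd) & (combo$mean > alone$mean)
  data.frame(compound_id = alone$compound_id, pt_drug_id = ptDrugId,
             pt_concentration = ptConcentration,
             mean_alone = alone$mean, sd_alone = alone$sd,
             mean_combo = combo$mean, sd_combo = combo$sd,
             noise_floor = combo$noise_floor,
             above_noise_floor = considered,
             is_hit = considered & rule, rule_variant = ruleVariant)
}

#' Convert HTS scores to fraction affected
#'
#' fa is the clipped score: values are clamped into [clip[1], clip[2]]
#' (default [0.001, 0.999]) so that downstream log-linearization
#' (log10(fa/fu)) stays defined.  fu = 1 - fa.
#'
#' @param score numeric scores.
#' @param clip length-2 clamp interval inside (0, 1), or NULL for no
#'   clipping.
#' @return fa values.
#' @export
scoreToFa <- function(score, clip = c(0.001, 0.999)) {
  if (is.null(clip)) return(score)
  stopifnot(length(clip) == 2L, clip[1] > 0, clip[2] < 1, clip[1] < clip[2])
  pmin(pmax(score, clip[1]), clip[2])
}
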