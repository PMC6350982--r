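## Well-level high-content metrics from per-object tables.

#' Well-level metrics from a high-content object table
#'
#' The three headline metrics per well and timepoint: N_cells (object count),
#' the mean PI intensity over nuclei, and Q_PI/Ho, the Pearson correlation of
#' Hoechst and PI intensities across the objects of the well.  Q_PI/Ho is
#' computed object-level (not pixel-level; pixel data is out of scope) and
#' only when the well holds at least 3 objects with variance in both
#' channels; otherwise it is recorded as NA.  Calcein intensities are carried
#' by the object table but unused by these metrics.
#'
#' @param objects an \linkS4class{HCAObjectTable} or a list of them.
#' @return data.frame, one row per table: \code{well}, \code{timepoint},
#'   \code{n_cells}, \code{mean_pi}, \code{q_pi_ho}.
#' @export
wellMetrics <- function(objects) {
  if (is(objects, "HCAObjectTable")) objects <- list(objects)
  out <- do.call(rbind, lapply(objects, function(x) {
    o <- x@objects
    n <- nrow(o)
    q <- NA_real_
    if (n >= 3L && sd(o$hoechst) > 0 && sd(o$pi) > 0)
      q <- cor(o$hoechst, o$pi)
    data.frame(well = x@well, timepoint = x@timepoint, n_cells = n,
               mean_pi = if (n) mean(o$pi) else NA_real_, q_pi_ho = q)
  }))
  rownames(out) <- NULL
  out
}

#' Normalize well metrics to the negative control
#'
#' Adds the control-normalized forms at matching timepoints:
#' \code{pct_n_cells} = 100 x N_cells / N_cells(neg. ctrl) and
#' \code{n_i_pi} = mean PI / mean PI(neg. ctrl).
#'
#' @param metrics data.frame from \code{\link{wellMetrics}}.
#' @param control \code{\link{wellMetrics}} rows of the negative-control
#'   well(s); one row per timepoint (pool replicate control wells upstream if
#'   needed).
#' @return \code{metrics} with columns \code{pct_n_cells} and \code{n_i_pi}
#'   appended.
#' @export
normalizeToControl <- function(metrics, control) {
  idx <- match(metrics$timepoint, control$timepoint)
  if (anyNA(idx))
    stop("pairing error: no control metrics for timepoint(s) ",
         paste(unique(metrics$timepoint[is.na(idx)]), collapse = ", "))
  ctrl_n <- control$n_cells[idx]
  ctrl_pi <- control$mean_pi[idx]
  if (any(ctrl_n <= 0) || any(!is.finite(ctrl_pi)) || any(ctrl_pi <= 0))
    stop("degenerate control: zero cell count or non-positive mean PI")
  metrics$pct_n_cells <- 100 * metrics$n_cells / ctrl_n
  metrics$n_i_pi <- metrics$mean_pi / ctrl_pi
  metrics
}

#' Qualitative combination flags from HCA metrics
#'
#' Per matched timepoint: \code{cytostatic} when the cell count falls below
#' \code{pctThreshold} percent of control while the PI ratio stays below
#' \code{piElevation} (growth arrest without the death marker);
#' \code{cytotoxic} when the PI ratio is elevated; \code{supra_single_agent}
#' when both the combination's Q_PI/Ho and PI ratio exceed those of both
#' single agents.
#'
#' @param metricsA,metricsB,metricsCombo normalized metrics
#'   (\code{\link{normalizeToControl}}) of drug A, drug B, and the
#'   combination, with matching timepoints.
#' @param pctThreshold \%N_cells threshold (default 50).
#' @param piElevation n_I(PI) elevation threshold (default 1.2).
#' @return data.frame: \code{timepoint}, \code{cytostatic},
#'   \code{cytotoxic}, \code{supra_single_agent}.
#' @export
combinationFlags <- function(metricsA, metricsB, metricsCombo,
                             pctThreshold = 50, piElevation = 1.2) {
  tp <- metricsCombo$timepoint
  ia <- match(tp, metricsA$timepoint)
  ib <- match(tp, metricsB$timepoint)
  if (anyNA(ia) || anyNA(ib))
    stop("pairing error: single-agent metrics lack matching timepoints")
  data.frame(
    timepoint = tp,
    cytostatic = metricsCombo$pct_n_cells < pctThreshold &
      metricsCombo$n_i_pi < piElevation,
    cytotoxic = metricsCombo$n_i_pi >= piElevation,
    supra_single_agent =
      metricsCombo$q_pi_ho > pmax(metricsA$q_pi_ho[ia], metricsB$q_pi_ho[ib]) &
      metricsCombo$n_i_pi > pmax(metricsA$n_i_pi[ia], metricsB$n_i_pi[ib]))
}
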