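## CSV I/O. One canonical dialect: comma-separated, UTF-8, "." decimal,
## header row; wells as "A1" names. Round-trip fidelity read(write(x)) == x
## is a tested contract for every pair.

.read_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("format error: empty file: ", path)
  df
}

.need_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("format error: %s file lacks column(s): %s",
                 what, paste(miss, collapse = ", ")))
}

#' Read / write a plate layout
#'
#' Layout files are CSV with columns \code{plate_id}, \code{well} ("A1"),
#' \code{role}, \code{compound_id}, \code{concentration}, \code{pt_drug_id},
#' \code{pt_concentration}; empty strings mean NA.  Duplicate wells, unknown
#' roles, and inconsistent combination-plate Pt annotation are rejected.
#'
#' @param path file path.
#' @param nRows,nCols plate geometry (default 16 x 24).
#' @return \code{readPlateLayout}: a \linkS4class{PlateLayout}.
#' @export
readPlateLayout <- function(path, nRows = 16L, nCols = 24L) {
  df <- .read_csv(path)
  .need_cols(df, c("plate_id", "well", "role"), "layout")
  for (col in c("compound_id", "concentration", "pt_drug_id",
                "pt_concentration"))
    if (is.null(df[[col]])) df[[col]] <- NA
  df$compound_id[!is.na(df$compound_id) & df$compound_id == ""] <- NA
  df$pt_drug_id[!is.na(df$pt_drug_id) & df$pt_drug_id == ""] <- NA
  rc <- parseWellName(df$well)
  if (anyDuplicated(rc))
    stop("format error: duplicate well in layout file: ",
         paste(unique(df$well[duplicated(rc)]), collapse = ", "))
  w <- data.frame(row = rc$row, col = rc$col, role = df$role,
                  compound_id = as.character(df$compound_id),
                  concentration = as.numeric(df$concentration),
                  pt_drug_id = as.character(df$pt_drug_id),
                  pt_concentration = as.numeric(df$pt_concentration),
                  stringsAsFactors = FALSE)
  PlateLayout(df$plate_id[1], w, nRows = nRows, nCols = nCols)
}

#' @rdname readPlateLayout
#' @param layout a \linkS4class{PlateLayout}.
#' @export
writePlateLayout <- function(layout, path) {
  w <- wells(layout)
  out <- data.frame(plate_id = plateId(layout),
                    well = wellName(w$row, w$col),
                    role = w$role, compound_id = w$compound_id,
                    concentration = w$concentration,
                    pt_drug_id = w$pt_drug_id,
                    pt_concentration = w$pt_concentration)
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read / write a raw plate read
#'
#' CSV columns: \code{plate_id}, \code{replicate_id}, \code{well},
#' \code{signal}.  Negative or non-finite signals are rejected.
#'
#' @param path file path.
#' @return \code{readPlateRead}: a \linkS4class{PlateRead}.
#' @export
readPlateRead <- function(path) {
  df <- .read_csv(path)
  .need_cols(df, c("plate_id", "replicate_id", "well", "signal"), "plate-read")
  if (any(!is.finite(df$signal) | df$signal < 0))
    stop(sprintf("validation error: negative or non-finite signal at row(s) %s",
                 paste(which(!is.finite(df$signal) | df$signal < 0),
                       collapse = ", ")))
  rc <- parseWellName(df$well)
  PlateRead(df$plate_id[1],
            data.frame(row = rc$row, col = rc$col, signal = df$signal),
            replicateId = df$replicate_id[1])
}

#' @rdname readPlateRead
#' @param read a \linkS4class{PlateRead}.
#' @export
writePlateRead <- function(read, path) {
  s <- signals(read)
  out <- data.frame(plate_id = plateId(read), replicate_id = read@replicateId,
                    well = wellName(s$row, s$col), signal = s$signal)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read / write a dose-response series
#'
#' Long format CSV: \code{compound_id}, \code{dose} (uM), \code{replicate},
#' \code{fa}.  Mixtures carry four extra constant columns
#' \code{component_a}, \code{component_b}, \code{weight_a}, \code{weight_b}.
#' Rows with fa outside [0, 1] or non-positive doses are rejected with their
#' row index.
#'
#' @param path file path.
#' @return \code{readDoseResponse}: a \linkS4class{DoseResponse}.
#' @export
readDoseResponse <- function(path) {
  df <- .read_csv(path)
  .need_cols(df, c("compound_id", "dose", "replicate", "fa"), "dose-response")
  bad <- which(!is.finite(df$dose) | df$dose <= 0)
  if (length(bad))
    stop(sprintf("validation error: non-positive dose at row(s) %s",
                 paste(bad, collapse = ", ")))
  bad <- which(!is.finite(df$fa) | df$fa < 0 | df$fa > 1)
  if (length(bad))
    stop(sprintf("validation error: fa outside [0, 1] at row(s) %s",
                 paste(bad, collapse = ", ")))
  mr <- NULL
  if (all(c("component_a", "component_b", "weight_a", "weight_b") %in%
          names(df)) && !anyNA(df$weight_a))
    mr <- list(components = c(df$component_a[1], df$component_b[1]),
               weights = c(df$weight_a[1], df$weight_b[1]))
  DoseResponse(df$compound_id[1], dose = df$dose, fa = df$fa,
               replicate = df$replicate, mixtureRatio = mr)
}

#' @rdname readDoseResponse
#' @param dr a \linkS4class{DoseResponse}.
#' @export
writeDoseResponse <- function(dr, path) {
  p <- faValues(dr)
  out <- data.frame(compound_id = dr@compoundId, dose = p$dose,
                    replicate = p$replicate, fa = p$fa)
  mr <- mixtureRatio(dr)
  if (!is.null(mr)) {
    out$component_a <- mr$components[1]
    out$component_b <- mr$components[2]
    out$weight_a <- mr$weights[1]
    out$weight_b <- mr$weights[2]
  }
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read / write high-content object tables
#'
#' CSV with one row per segmented object: \code{well}, \code{timepoint}
#' (hours), \code{hoechst}, \code{pi}, \code{calcein}.  A file may hold many
#' wells and timepoints; the reader returns one \linkS4class{HCAObjectTable}
#' per (well, timepoint).
#'
#' @param path file path.
#' @return \code{readHCAObjects}: a list of \linkS4class{HCAObjectTable}.
#' @export
readHCAObjects <- function(path) {
  df <- .read_csv(path)
  .need_cols(df, c("well", "timepoint", "hoechst", "pi", "calcein"), "HCA")
  v <- c(df$hoechst, df$pi, df$calcein)
  if (any(!is.finite(v) | v < 0))
    stop("validation error: negative or non-finite intensity in HCA file")
  key <- paste(df$well, df$timepoint, sep = "@")
  lapply(split(df, factor(key, levels = unique(key))), function(d)
    HCAObjectTable(d$well[1], d$timepoint[1],
                   d[, c("hoechst", "pi", "calcein")]))
}

#' @rdname readHCAObjects
#' @param tables a single \linkS4class{HCAObjectTable} or a list of them.
#' @export
writeHCAObjects <- function(tables, path) {
  if (is(tables, "HCAObjectTable")) tables <- list(tables)
  out <- do.call(rbind, lapply(tables, function(x)
    cbind(data.frame(well = x@well, timepoint = x@timepoint), x@objects)))
  rownames(out) <- NULL
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write a score table to CSV
#'
#' One row per well with the raw signal and the normalized HTS score, plus
#' plate-level control statistics and the noise floor repeated per row so the
#' file is self-contained.
#'
#' @param st a \linkS4class{ScoreTable}.
#' @param path file path.
#' @export
writeScoreTable <- function(st, path) {
  s <- scores(st)
  out <- data.frame(plate_id = plateId(st), replicate_id = st@replicateId,
                    well = wellName(s$row, s$col), role = s$role,
                    compound_id = s$compound_id, signal = s$signal,
                    score = s$score, neg_mean = st@negMean, neg_sd = st@negSD,
                    pos_mean = st@posMean, pos_sd = st@posSD,
                    noise_floor = st@noiseFloor)
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}
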