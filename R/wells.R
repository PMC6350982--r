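#' Well-name conversion
#'
#' Files use the letter+number convention ("A1" .. "P24"); internally wells
#' are 1-based (row, col) integer pairs.  Rows beyond "Z" are not supported
#' (the largest plate handled is 16 x 24).
#'
#' @param row,col 1-based integer indices (vectorized).
#' @return \code{wellName} returns character names; \code{parseWellName}
#'   returns a data.frame with integer columns \code{row}, \code{col}.
#' @examples
#' wellName(1, 1)          # "A1"
#' parseWellName("P24")    # row 16, col 24
#' @export
wellName <- function(row, col) {
  stopifnot(all(row >= 1L), all(row <= 26L), all(col >= 1L))
  paste0(LETTERS[row], col)
}

#' @rdname wellName
#' @param name character well names like "A1".
#' @export
parseWellName <- function(name) {
  m <- regmatches(name, regexec("^([A-Z])([0-9]+)$", name))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad))
    stop("malformed well name(s): ", paste(name[bad], collapse = ", "))
  data.frame(row = match(vapply(m, `[`, "", 2L), LETTERS),
             col = as.integer(vapply(m, `[`, "", 3L)))
}
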