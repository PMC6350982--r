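#' @import methods
#' @importFrom stats lm coef cor sd qt rlnorm rnorm runif uniroot setNames complete.cases
#' @importFrom utils read.csv write.csv packageVersion
NULL

#' Accessor generics
#'
#' Small accessor family for the screening / synergy S4 classes.
#'
#' @param object an object of one of the package's S4 classes.
#' @name accessors
#' @aliases plateId wells signals doses faValues Dm mCoef rCoef isValidFit
#'   scores mixtureRatio ratioWeights ciWt gradeSymbol
NULL

#' @rdname accessors
#' @export
setGeneric("plateId", function(object) standardGeneric("plateId"))

#' @rdname accessors
#' @export
setGeneric("wells", function(object) standardGeneric("wells"))

#' @rdname accessors
#' @export
setGeneric("signals", function(object) standardGeneric("signals"))

#' @rdname accessors
#' @export
setGeneric("doses", function(object) standardGeneric("doses"))

#' @rdname accessors
#' @export
setGeneric("faValues", function(object) standardGeneric("faValues"))

#' @rdname accessors
#' @export
setGeneric("mixtureRatio", function(object) standardGeneric("mixtureRatio"))

#' @rdname accessors
#' @export
setGeneric("Dm", function(object) standardGeneric("Dm"))

#' @rdname accessors
#' @export
setGeneric("mCoef", function(object) standardGeneric("mCoef"))

#' @rdname accessors
#' @export
setGeneric("rCoef", function(object) standardGeneric("rCoef"))

#' @rdname accessors
#' @export
setGeneric("isValidFit", function(object) standardGeneric("isValidFit"))

#' @rdname accessors
#' @export
setGeneric("scores", function(object) standardGeneric("scores"))

#' @rdname accessors
#' @export
setGeneric("ratioWeights", function(object) standardGeneric("ratioWeights"))

#' @rdname accessors
#' @export
setGeneric("ciWt", function(object) standardGeneric("ciWt"))

#' @rdname accessors
#' @export
setGeneric("gradeSymbol", function(object) standardGeneric("gradeSymbol"))
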