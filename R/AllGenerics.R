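#' Accessor generics
#'
#' Small accessor generics for the package's S4 result containers.
#'
#' @param object an S4 object from this package.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("exposureLabels", function(object) standardGeneric("exposureLabels"))

#' @rdname accessors
#' @export
setGeneric("highVsRest", function(object) standardGeneric("highVsRest"))

#' @rdname accessors
#' @export
setGeneric("bwExtremes", function(object) standardGeneric("bwExtremes"))

#' @rdname accessors
#' @export
setGeneric("screenTable", function(object) standardGeneric("screenTable"))

#' @rdname accessors
#' @export
setGeneric("candidates", function(object) standardGeneric("candidates"))

#' @rdname accessors
#' @export
setGeneric("verdict", function(object) standardGeneric("verdict"))

#' @rdname accessors
#' @export
setGeneric("mediationTable", function(object) standardGeneric("mediationTable"))

#' @rdname accessors
#' @export
setGeneric("requirementsMet", function(object) standardGeneric("requirementsMet"))
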