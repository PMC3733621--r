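#' @rdname MetabolicNetwork-accessors
#' @export
setGeneric("metabolites", function(x) standardGeneric("metabolites"))

#' @rdname MetabolicNetwork-accessors
#' @export
setGeneric("reactions", function(x) standardGeneric("reactions"))

#' @rdname MetabolicNetwork-accessors
#' @export
setGeneric("stoichMatrix", function(x, internal = TRUE)
  standardGeneric("stoichMatrix"))

#' @rdname MetabolicNetwork-accessors
#' @export
setGeneric("metaboliteIds", function(x) standardGeneric("metaboliteIds"))

#' @rdname MetabolicNetwork-accessors
#' @export
setGeneric("reactionIds", function(x) standardGeneric("reactionIds"))

#' @rdname MetabolicNetwork-accessors
#' @export
setGeneric("internalMetabolites", function(x)
  standardGeneric("internalMetabolites"))

#' @rdname referenceFluxes
#' @export
setGeneric("referenceFluxes", function(x) standardGeneric("referenceFluxes"))

#' @rdname expressionRatios
#' @export
setGeneric("expressionRatios", function(x) standardGeneric("expressionRatios"))

#' @rdname rateParameters
#' @export
setGeneric("rateParams", function(x) standardGeneric("rateParams"))
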