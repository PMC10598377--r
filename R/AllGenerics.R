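#' @rdname accessors
#' @export
setGeneric("viewId", function(x) standardGeneric("viewId"))

#' @rdname accessors
#' @export
setGeneric("viewData", function(x) standardGeneric("viewData"))

#' @rdname accessors
#' @export
setGeneric("caseId", function(x) standardGeneric("caseId"))

#' @rdname accessors
#' @export
setGeneric("caseLabel", function(x) standardGeneric("caseLabel"))

#' @rdname accessors
#' @export
setGeneric("caseViews", function(x) standardGeneric("caseViews"))

#' @rdname accessors
#' @export
setGeneric("nViews", function(x) standardGeneric("nViews"))

#' @rdname accessors
#' @export
setGeneric("viewIds", function(x) standardGeneric("viewIds"))

#' @rdname accessors
#' @export
setGeneric("trainCases", function(x) standardGeneric("trainCases"))

#' @rdname accessors
#' @export
setGeneric("valCases", function(x) standardGeneric("valCases"))

#' @rdname accessors
#' @export
setGeneric("testCases", function(x) standardGeneric("testCases"))

#' @rdname accessors
#' @export
setGeneric("auc", function(x) standardGeneric("auc"))

#' @rdname accessors
#' @export
setGeneric("operatingPoint", function(x) standardGeneric("operatingPoint"))

#' @rdname accessors
#' @export
setGeneric("probabilities", function(x) standardGeneric("probabilities"))

#' @rdname accessors
#' @export
setGeneric("trainLog", function(x) standardGeneric("trainLog"))

#' @rdname accessors
#' @export
setGeneric("fusionStrategy", function(x) standardGeneric("fusionStrategy"))
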