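#' @rdname LocusAlignment-class
#' @param x a \code{LocusAlignment}
#' @export
setGeneric("locusId", function(x) standardGeneric("locusId"))

#' @rdname LocusAlignment-class
#' @export
setGeneric("popLabels", function(x) standardGeneric("popLabels"))

#' @rdname LocusAlignment-class
#' @export
setGeneric("fragmentLength", function(x) standardGeneric("fragmentLength"))

#' @rdname LocusAlignment-class
#' @export
setGeneric("ploidyFactor", function(x) standardGeneric("ploidyFactor"))

#' @rdname DemographicModel-class
#' @param x a \code{DemographicModel}
#' @export
setGeneric("thetaSite", function(x) standardGeneric("thetaSite"))

#' @rdname HistorySet-class
#' @param x a \code{HistorySet}
#' @export
setGeneric("nHistories", function(x) standardGeneric("nHistories"))

#' @rdname HistorySet-class
#' @export
setGeneric("modelType", function(x) standardGeneric("modelType"))
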