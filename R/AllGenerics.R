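#' @rdname MRCohort-accessors
#' @export
setGeneric("caseStatus", function(x) standardGeneric("caseStatus"))

#' @rdname MRCohort-accessors
#' @export
setGeneric("exposureValues", function(x) standardGeneric("exposureValues"))

#' @rdname MRCohort-accessors
#' @export
setGeneric("genotypeMatrix", function(x) standardGeneric("genotypeMatrix"))

#' @rdname MRCohort-accessors
#' @export
setGeneric("covariateData", function(x) standardGeneric("covariateData"))

#' @rdname MRCohort-accessors
#' @export
setGeneric("snpInfo", function(x) standardGeneric("snpInfo"))

#' @rdname NonlinearMR-accessors
#' @export
setGeneric("laceTable", function(x) standardGeneric("laceTable"))

#' @rdname NonlinearMR-accessors
#' @export
setGeneric("nonlinearityTests", function(x) standardGeneric("nonlinearityTests"))

#' @rdname NonlinearMR-accessors
#' @export
setGeneric("causalCurves", function(x) standardGeneric("causalCurves"))
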