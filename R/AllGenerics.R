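#' @rdname CountTable-class
#' @param object,x a \code{CountTable}, \code{DistanceMatrix},
#'   \code{SourceSet}, \code{Attribution} or \code{GeneratedCohort}.
#' @export
setGeneric("counts", function(object, ...) standardGeneric("counts"))

#' @rdname CountTable-class
#' @export
setGeneric("taxonIds", function(object) standardGeneric("taxonIds"))

#' @rdname CountTable-class
#' @export
setGeneric("sampleIds", function(object) standardGeneric("sampleIds"))

#' @rdname SourceSet-class
#' @export
setGeneric("phaseLabels", function(object) standardGeneric("phaseLabels"))

#' @rdname SourceSet-class
#' @export
setGeneric("sourceCounts", function(object) standardGeneric("sourceCounts"))

#' @rdname Attribution-class
#' @export
setGeneric("proportions", function(object) standardGeneric("proportions"))

#' @rdname Attribution-class
#' @export
setGeneric("restartSD", function(object) standardGeneric("restartSD"))

#' @rdname GeneratedCohort-class
#' @export
setGeneric("cohortTable", function(object) standardGeneric("cohortTable"))

#' @rdname GeneratedCohort-class
#' @export
setGeneric("cohortMetadata", function(object) standardGeneric("cohortMetadata"))

#' @rdname GeneratedCohort-class
#' @export
setGeneric("cohortTree", function(object) standardGeneric("cohortTree"))

#' @rdname GeneratedCohort-class
#' @export
setGeneric("cohortTruth", function(object) standardGeneric("cohortTruth"))
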