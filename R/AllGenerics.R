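#' @include utils.R
NULL

#' Subject identifiers of an object
#'
#' @param x an object carrying per-subject data, such as a
#'   [BiomarkerTable-class] or [VariablePair-class].
#' @return Character vector of subject identifiers.
#' @export
setGeneric("subjectIDs", function(x) standardGeneric("subjectIDs"))

#' Variable names of a measurement container
#'
#' @param x a [BiomarkerTable-class].
#' @return Character vector of variable names.
#' @export
setGeneric("variableNames", function(x) standardGeneric("variableNames"))

#' Measurement matrix
#'
#' @param x a [BiomarkerTable-class].
#' @return Numeric matrix (subjects x variables), `NA` for missing cells.
#' @export
setGeneric("measurements", function(x) standardGeneric("measurements"))

#' Measurement units
#'
#' @param x a [BiomarkerTable-class].
#' @return Named character vector of unit strings, one per variable.
#' @export
setGeneric("measurementUnits", function(x) standardGeneric("measurementUnits"))

#' Number of subjects
#'
#' @param x a per-subject container.
#' @return Integer count.
#' @export
setGeneric("nSubjects", function(x) standardGeneric("nSubjects"))

#' Member identifiers of a fitted linear axis or subject set
#'
#' @param x a [LinearAxis-class] or [SubjectSet-class].
#' @return Character vector of subject identifiers.
#' @export
setGeneric("memberIDs", function(x) standardGeneric("memberIDs"))

#' Fitted axes of a cluster solution
#'
#' @param x a [ClusterSolution-class].
#' @return List of [LinearAxis-class] objects.
#' @export
setGeneric("axes", function(x) standardGeneric("axes"))

#' Final subject set of a search trace
#'
#' @param x a [SearchTrace-class].
#' @return A [SubjectSet-class].
#' @export
setGeneric("finalSet", function(x) standardGeneric("finalSet"))

#' Per-step record of a search trace
#'
#' @param x a [SearchTrace-class].
#' @return `data.frame` with columns `step`, `subject`, `size`, `rho`.
#' @export
setGeneric("traceSteps", function(x) standardGeneric("traceSteps"))
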