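#' @include AllGenerics.R
NULL

#' BiomarkerTable: per-subject biochemical measurement matrix
#'
#' Holds a subjects x variables matrix of biochemical measurements (enzyme
#' activities in nmol/min*mg protein, coenzyme Q10 content in nmol/g protein,
#' derived ratios) together with unit bookkeeping. Any cell may be missing
#' (`NA`); non-missing cells must be finite. Negative values are physically
#' implausible for concentrations/activities and are flagged at load time by
#' [readBiomarkerTable()], but do not invalidate the object.
#'
#' @slot values numeric matrix; rownames are unique subject identifiers,
#'   colnames are unique variable names.
#' @slot units named character vector of unit strings, one per variable
#'   (empty string when unknown).
#' @seealso [BiomarkerTable()], [readBiomarkerTable()], [pairwiseComplete()]
#' @exportClass BiomarkerTable
setClass("BiomarkerTable",
  representation(values = "matrix", units = "character"))

setValidity("BiomarkerTable", function(object) {
  v <- object@values
  msg <- character()
  if (!is.numeric(v)) msg <- c(msg, "'values' must be a numeric matrix")
  if (is.null(rownames(v)) && nrow(v) > 0)
    msg <- c(msg, "'values' must have subject identifiers as rownames")
  if (anyDuplicated(rownames(v)))
    msg <- c(msg, "subject identifiers must be unique")
  if (is.null(colnames(v)) && ncol(v) > 0)
    msg <- c(msg, "'values' must have variable names as colnames")
  if (anyDuplicated(colnames(v)))
    msg <- c(msg, "variable names must be unique")
  if (any(is.infinite(v)))
    msg <- c(msg, "non-missing values must be finite")
  if (length(object@units) != ncol(v))
    msg <- c(msg, "'units' must have one entry per variable")
  if (length(msg)) msg else TRUE
})

#' VariablePair: a pairwise-complete (X, Y) extraction
#'
#' The two-variable view on which correlations and subpopulation searches
#' operate: equal-length vectors with no missing entries, indexed by subject
#' identifier, in the source table's row order.
#'
#' @slot xName,yName names of the extracted variables.
#' @slot subjects character vector of subject identifiers.
#' @slot x,y numeric vectors aligned with `subjects`, all finite.
#' @seealso [pairwiseComplete()], [pearsonCorrelation()], [divisiveSearch()]
#' @exportClass VariablePair
setClass("VariablePair",
  representation(xName = "character", yName = "character",
                 subjects = "character", x = "numeric", y = "numeric"))

setValidity("VariablePair", function(object) {
  msg <- character()
  n <- length(object@subjects)
  if (length(object@x) != n || length(object@y) != n)
    msg <- c(msg, "'x', 'y' and 'subjects' must have equal length")
  if (anyDuplicated(object@subjects))
    msg <- c(msg, "subject identifiers must be unique")
  if (n && (!all(is.finite(object@x)) || !all(is.finite(object@y))))
    msg <- c(msg, "all pair values must be finite (no missing entries)")
  if (length(object@xName) != 1L || length(object@yName) != 1L)
    msg <- c(msg, "'xName' and 'yName' must be single strings")
  if (length(msg)) msg else TRUE
})

#' LinearAxis: a fitted line with member residuals
#'
#' One candidate linear cluster: an OLS line y = beta0 + beta1 * x over its
#' member subjects, with per-member vertical residuals. Produced by
#' [robustLinearClusters()] and consumed by [seedTriple()].
#'
#' @slot beta0,beta1 intercept and slope of the fitted line.
#' @slot memberIDs subject identifiers assigned to this axis.
#' @slot x,y member coordinates.
#' @slot residuals per-member vertical residuals `y - (beta0 + beta1 * x)`.
#' @exportClass LinearAxis
setClass("LinearAxis",
  representation(beta0 = "numeric", beta1 = "numeric",
                 memberIDs = "character", x = "numeric", y = "numeric",
                 residuals = "numeric"))

setValidity("LinearAxis", function(object) {
  msg <- character()
  n <- length(object@memberIDs)
  if (length(object@x) != n || length(object@y) != n ||
      length(object@residuals) != n)
    msg <- c(msg, "member vectors must have equal length")
  if (n) {
    expected <- object@y - (object@beta0 + object@beta1 * object@x)
    if (max(abs(expected - object@residuals)) > 1e-8)
      msg <- c(msg, "residuals inconsistent with fitted line")
  }
  if (length(msg)) msg else TRUE
})

#' ClusterSolution: output of the trimmed k-lines initializer
#'
#' A partition of the input subjects into `k` linear axes plus a trimmed
#' ("unassigned") noise set, with the per-iteration objective trace of the
#' winning restart for convergence diagnostics.
#'
#' @slot axes list of [LinearAxis-class] objects.
#' @slot unassignedIDs subjects trimmed as noise.
#' @slot seed RNG seed the solution was computed under.
#' @slot objective total squared vertical residual over untrimmed members.
#' @slot objectiveTrace numeric vector, objective after each iteration of the
#'   winning restart (non-increasing).
#' @slot xName,yName variable names of the underlying pair.
#' @exportClass ClusterSolution
setClass("ClusterSolution",
  representation(axes = "list", unassignedIDs = "character",
                 seed = "integer", objective = "numeric",
                 objectiveTrace = "numeric",
                 xName = "character", yName = "character"))

setValidity("ClusterSolution", function(object) {
  msg <- character()
  if (!all(vapply(object@axes, is, logical(1), "LinearAxis")))
    msg <- c(msg, "'axes' must be a list of LinearAxis objects")
  ids <- c(unlist(lapply(object@axes, slot, "memberIDs")),
           object@unassignedIDs)
  if (anyDuplicated(ids))
    msg <- c(msg, "axes and unassigned set must partition the subjects")
  if (length(msg)) msg else TRUE
})

#' SubjectSet: an ordered set of subjects under growth or pruning
#'
#' The evolving membership set of either search procedure, bound to the
#' [VariablePair-class] it indexes so that correlation measures are always
#' well defined.
#'
#' @slot ids unique subject identifiers, a subset of the pair's subjects.
#' @slot pair the indexed [VariablePair-class].
#' @seealso [correlationLoss()], [correlationGain()], [agglomerativeSearch()]
#' @exportClass SubjectSet
setClass("SubjectSet",
  representation(ids = "character", pair = "VariablePair"))

setValidity("SubjectSet", function(object) {
  msg <- character()
  if (anyDuplicated(object@ids))
    msg <- c(msg, "subject identifiers must be unique")
  if (!all(object@ids %in% object@pair@subjects))
    msg <- c(msg, "all ids must belong to the underlying pair")
  if (length(msg)) msg else TRUE
})

#' SearchConfig: target threshold and stopping controls
#'
#' @slot rStar target Pearson correlation in (0, 1) that a returned
#'   subpopulation must satisfy (default 0.95).
#' @slot maxSteps cap on greedy steps (default `Inf`).
#' @slot mode `"agglomerative"` or `"divisive"`.
#' @exportClass SearchConfig
setClass("SearchConfig",
  representation(rStar = "numeric", maxSteps = "numeric", mode = "character"))

setValidity("SearchConfig", function(object) {
  msg <- character()
  if (length(object@rStar) != 1L || is.na(object@rStar) ||
      object@rStar <= 0 || object@rStar >= 1)
    msg <- c(msg, "'rStar' must lie strictly between 0 and 1")
  if (!object@mode %in% c("agglomerative", "divisive"))
    msg <- c(msg, "'mode' must be \"agglomerative\" or \"divisive\"")
  if (length(object@maxSteps) != 1L || is.na(object@maxSteps) ||
      object@maxSteps < 0)
    msg <- c(msg, "'maxSteps' must be a non-negative number")
  if (length(msg)) msg else TRUE
})

#' SearchTrace: full per-step record of a greedy search
#'
#' @slot steps `data.frame` with one row per accepted step: `step` (1-based
#'   index), `subject` (the chosen individual), `size` (set size after the
#'   step), `rho` (Pearson correlation of the resulting set).
#' @slot finalSet the returned [SubjectSet-class].
#' @slot finalR Pearson correlation of the final set.
#' @slot terminatedBy one of `"threshold"`, `"exhausted"`, `"max_steps"`.
#' @slot mode `"agglomerative"` or `"divisive"`.
#' @exportClass SearchTrace
setClass("SearchTrace",
  representation(steps = "data.frame", finalSet = "SubjectSet",
                 finalR = "numeric", terminatedBy = "character",
                 mode = "character"))

setValidity("SearchTrace", function(object) {
  msg <- character()
  need <- c("step", "subject", "size", "rho")
  if (!all(need %in% names(object@steps)))
    msg <- c(msg, "steps must have columns step, subject, size, rho")
  if (!object@terminatedBy %in% c("threshold", "exhausted", "max_steps"))
    msg <- c(msg, "unknown termination reason")
  if (nrow(object@steps) > 1) {
    d <- diff(object@steps$size)
    if (object@mode == "agglomerative" && any(d <= 0))
      msg <- c(msg, "agglomerative set sizes must be strictly increasing")
    if (object@mode == "divisive" && any(d >= 0))
      msg <- c(msg, "divisive set sizes must be strictly decreasing")
  }
  if (length(msg)) msg else TRUE
})

#' AgreementReport: agglomerative vs divisive solution comparison
#'
#' @slot pairLabel label of the variable pair, e.g. `"CIII vs CoQ"`.
#' @slot nAgglomerative size of the agglomerative solution (`NA` when that
#'   procedure produced no sensible result for the pair).
#' @slot nDivisive size of the divisive solution.
#' @slot nCommon size of the intersection.
#' @slot agreementPct 100 * |A .. D| / max(|A|, |D|); `NA` when the
#'   agglomerative run failed.
#' @slot reportedN the headline subpopulation size (divisive by convention).
#' @exportClass AgreementReport
setClass("AgreementReport",
  representation(pairLabel = "character", nAgglomerative = "integer",
                 nDivisive = "integer", nCommon = "integer",
                 agreementPct = "numeric", reportedN = "integer"))

setValidity("AgreementReport", function(object) {
  msg <- character()
  if (!is.na(object@agreementPct) &&
      (object@agreementPct < 0 || object@agreementPct > 100))
    msg <- c(msg, "'agreementPct' must lie in [0, 100]")
  if (!is.na(object@nAgglomerative) &&
      object@nCommon > min(object@nAgglomerative, object@nDivisive))
    msg <- c(msg, "'nCommon' cannot exceed either solution size")
  if (length(msg)) msg else TRUE
})
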