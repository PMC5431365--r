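#' @include AllClasses.R
NULL

#' Construct a BiomarkerTable
#'
#' @param values numeric matrix (subjects x variables) with subject
#'   identifiers as rownames and variable names as colnames; `NA` marks a
#'   missing cell. A data.frame of numeric columns is accepted and coerced.
#' @param units optional character vector of unit strings, one per variable
#'   (recycled empty when omitted). Typical values are
#'   `"nmol/min*mg protein"` for respiratory-chain activities,
#'   `"nmol/g protein"` for coenzyme Q10 content.
#' @param subjectIDs optional subject identifiers overriding rownames.
#' @return A [BiomarkerTable-class].
#' @examples
#' m <- matrix(c(185, 90, 310, 132, 75, 201), ncol = 2,
#'             dimnames = list(c("P01", "P02", "P03"), c("CoQ", "CS")))
#' bt <- BiomarkerTable(m, units = c("nmol/g protein", "nmol/min*mg protein"))
#' nSubjects(bt)
#' @export
BiomarkerTable <- function(values, units = NULL, subjectIDs = NULL) {
  if (is.data.frame(values)) values <- as.matrix(values)
  if (!is.numeric(values)) {
    stop("'values' must be numeric", call. = FALSE)
  }
  if (!is.null(subjectIDs)) rownames(values) <- as.character(subjectIDs)
  if (is.null(rownames(values)) && nrow(values) > 0) {
    rownames(values) <- sprintf("S%0*d", nchar(nrow(values)),
                                seq_len(nrow(values)))
  }
  units <- as.character(units %||% rep("", ncol(values)))
  if (length(units) == 1L && ncol(values) > 1L)
    units <- rep(units, ncol(values))
  names(units) <- colnames(values)
  new("BiomarkerTable", values = values, units = units)
}

#' @rdname subjectIDs
#' @export
setMethod("subjectIDs", "BiomarkerTable", function(x) rownames(x@values))

#' @rdname variableNames
#' @export
setMethod("variableNames", "BiomarkerTable", function(x) colnames(x@values))

#' @rdname measurements
#' @export
setMethod("measurements", "BiomarkerTable", function(x) x@values)

#' @rdname measurementUnits
#' @export
setMethod("measurementUnits", "BiomarkerTable", function(x) x@units)

#' @rdname nSubjects
#' @export
setMethod("nSubjects", "BiomarkerTable", function(x) nrow(x@values))

#' Subset a BiomarkerTable by subjects and/or variables
#'
#' @param x a [BiomarkerTable-class].
#' @param i subject selector (identifiers, indices or logical).
#' @param j variable selector.
#' @param ... ignored.
#' @param drop ignored; the result is always a BiomarkerTable.
#' @return A [BiomarkerTable-class].
#' @export
setMethod("[", "BiomarkerTable", function(x, i, j, ..., drop = FALSE) {
  v <- x@values
  if (missing(i)) i <- seq_len(nrow(v))
  if (missing(j)) j <- seq_len(ncol(v))
  new("BiomarkerTable", values = v[i, j, drop = FALSE], units = x@units[j])
})

setMethod("show", "BiomarkerTable", function(object) {
  cat(sprintf("BiomarkerTable: %d subjects x %d variables\n",
              nrow(object@values), ncol(object@values)))
  nm <- colnames(object@values)
  for (k in seq_along(nm)) {
    col <- object@values[, k]
    u <- object@units[[k]]
    cat(sprintf("  %-14s %s n=%d, missing=%d\n", nm[k],
                if (nzchar(u)) sprintf("[%s] ", u) else "",
                sum(!is.na(col)), sum(is.na(col))))
  }
  invisible(NULL)
})

#' @rdname subjectIDs
#' @export
setMethod("subjectIDs", "VariablePair", function(x) x@subjects)

#' @rdname nSubjects
#' @export
setMethod("nSubjects", "VariablePair", function(x) length(x@subjects))

setMethod("show", "VariablePair", function(object) {
  cat(sprintf("VariablePair: %s vs %s, n = %d pairwise-complete subjects\n",
              object@yName, object@xName, length(object@subjects)))
  invisible(NULL)
})

#' Coordinates of a variable pair
#'
#' @param pair a [VariablePair-class].
#' @return `data.frame` with columns `subject`, `x`, `y`.
#' @export
pairData <- function(pair) {
  stopifnot(is(pair, "VariablePair"))
  data.frame(subject = pair@subjects, x = pair@x, y = pair@y,
             stringsAsFactors = FALSE)
}

#' Construct a SubjectSet
#'
#' @param ids character vector of subject identifiers.
#' @param pair the [VariablePair-class] the set indexes.
#' @return A [SubjectSet-class].
#' @export
SubjectSet <- function(ids, pair) {
  new("SubjectSet", ids = as.character(ids), pair = pair)
}

#' @rdname memberIDs
#' @export
setMethod("memberIDs", "SubjectSet", function(x) x@ids)

#' @rdname nSubjects
#' @export
setMethod("nSubjects", "SubjectSet", function(x) length(x@ids))

setMethod("show", "SubjectSet", function(object) {
  cat(sprintf("SubjectSet: %d of %d subjects (%s vs %s)\n",
              length(object@ids), length(object@pair@subjects),
              object@pair@yName, object@pair@xName))
  invisible(NULL)
})

#' Construct a SearchConfig
#'
#' @param rStar target correlation threshold in (0, 1); the default 0.95 is
#'   a deliberately demanding bar for biological variables.
#' @param maxSteps cap on greedy steps.
#' @param mode `"agglomerative"` or `"divisive"`.
#' @return A [SearchConfig-class].
#' @export
SearchConfig <- function(rStar = 0.95, maxSteps = Inf,
                         mode = c("divisive", "agglomerative")) {
  new("SearchConfig", rStar = as.numeric(rStar),
      maxSteps = as.numeric(maxSteps), mode = match.arg(mode))
}

#' @rdname memberIDs
#' @export
setMethod("memberIDs", "LinearAxis", function(x) x@memberIDs)

setMethod("show", "LinearAxis", function(object) {
  cat(sprintf("LinearAxis: y = %.4g + %.4g x, %d members\n",
              object@beta0, object@beta1, length(object@memberIDs)))
  invisible(NULL)
})

#' @rdname axes
#' @export
setMethod("axes", "ClusterSolution", function(x) x@axes)

setMethod("show", "ClusterSolution", function(object) {
  sizes <- vapply(object@axes, function(a) length(a@memberIDs), integer(1))
  cat(sprintf("ClusterSolution: %d axes (sizes %s), %d trimmed, seed %d\n",
              length(object@axes), paste(sizes, collapse = "/"),
              length(object@unassignedIDs), object@seed))
  cat(sprintf("  objective (total squared residual): %.6g\n",
              object@objective))
  invisible(NULL)
})

#' @rdname finalSet
#' @export
setMethod("finalSet", "SearchTrace", function(x) x@finalSet)

#' @rdname traceSteps
#' @export
setMethod("traceSteps", "SearchTrace", function(x) x@steps)

setMethod("show", "SearchTrace", function(object) {
  cat(sprintf("SearchTrace (%s): %d steps, final n = %d, final r = %.4f (%s)\n",
              object@mode, nrow(object@steps),
              length(object@finalSet@ids), object@finalR,
              object@terminatedBy))
  invisible(NULL)
})

setMethod("show", "AgreementReport", function(object) {
  agg <- if (is.na(object@nAgglomerative)) "-"
         else as.character(object@nAgglomerative)
  pct <- if (is.na(object@agreementPct)) "-"
         else sprintf("%.1f%%", object@agreementPct)
  cat(sprintf("AgreementReport [%s]: agglomerative n = %s, divisive n = %d, common = %d, agreement = %s\n",
              object@pairLabel, agg, object@nDivisive, object@nCommon, pct))
  invisible(NULL)
})

#' Flatten an AgreementReport to a one-row data.frame
#'
#' @param x an [AgreementReport-class].
#' @param row.names,optional,... passed for generic compatibility, unused.
#' @return One-row `data.frame` with columns `pair`, `n_agglomerative`,
#'   `n_divisive`, `n_common`, `agreement_pct`, `reported_n`.
#' @export
as.data.frame.AgreementReport <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  data.frame(pair = x@pairLabel,
             n_agglomerative = x@nAgglomerative,
             n_divisive = x@nDivisive,
             n_common = x@nCommon,
             agreement_pct = x@agreementPct,
             reported_n = x@reportedN,
             stringsAsFactors = FALSE)
}
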