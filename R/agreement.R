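#' @include search.R
NULL

#' Agreement between agglomerative and divisive solutions
#'
#' Scores how far the two procedures identified the same subpopulation for
#' one variable pair: `agreement = 100 * |A intersect D| / max(|A|, |D|)`,
#' the conservative denominator (an agreement of 98\% on sets of ~214 means
#' at least 210 shared individuals). Pass `a = NULL` when the agglomerative
#' procedure produced no sensible result; the report then carries `NA` in
#' the agglomerative columns, mirroring the cases where only the divisive
#' method applies.
#'
#' @param a agglomerative [SubjectSet-class], or `NULL` on failure.
#' @param d divisive [SubjectSet-class].
#' @param denominator `"max"` (default), `"min"` or `"union"` -- alternative
#'   agreement denominators for sensitivity analysis.
#' @return An [AgreementReport-class]; `reportedN` is the divisive size, the
#'   method available for every pair.
#' @export
compareSolutions <- function(a, d, denominator = c("max", "min", "union")) {
  stopifnot(is(d, "SubjectSet"))
  denominator <- match.arg(denominator)
  label <- sprintf("%s vs %s", d@pair@yName, d@pair@xName)
  if (is.null(a)) {
    return(new("AgreementReport", pairLabel = label,
               nAgglomerative = NA_integer_,
               nDivisive = length(d@ids), nCommon = NA_integer_,
               agreementPct = NA_real_,
               reportedN = length(d@ids)))
  }
  stopifnot(is(a, "SubjectSet"))
  if (!identical(a@pair@xName, d@pair@xName) ||
      !identical(a@pair@yName, d@pair@yName) ||
      !identical(a@pair@subjects, d@pair@subjects))
    stop("solutions index different variable pairs", call. = FALSE)
  common <- length(intersect(a@ids, d@ids))
  den <- switch(denominator,
                max = max(length(a@ids), length(d@ids)),
                min = min(length(a@ids), length(d@ids)),
                union = length(union(a@ids, d@ids)))
  pct <- if (den == 0) 100 else 100 * common / den
  new("AgreementReport", pairLabel = label,
      nAgglomerative = length(a@ids), nDivisive = length(d@ids),
      nCommon = as.integer(common), agreementPct = pct,
      reportedN = length(d@ids))
}

#' Subpopulation counts and method agreement over many pairs
#'
#' For each (anchor, target) combination: extract the pairwise-complete
#' subjects, screen outliers, run the divisive search and the full
#' agglomerative pipeline, and score the agreement. Per-pair failures are
#' recorded in the row (message in `error`, `NA` cells) without aborting
#' the report -- the agglomerative method legitimately fails for some enzyme
#' pairs.
#'
#' @param table a [BiomarkerTable-class].
#' @param anchorVars variables used as X (e.g. `c("CoQ", "CS")`).
#' @param targetVars variables used as Y (the enzyme activities).
#' @param config a [SearchConfig-class].
#' @param seed RNG seed for the axis detection.
#' @param k,trim,restarts passed to [robustLinearClusters()].
#' @param outlierMethod,outlierThreshold passed to [screenOutliers()].
#' @return `data.frame`, one row per target x anchor combination, columns
#'   `target`, `anchor`, `n_pairwise`, `n_removed`, `n_agglomerative`,
#'   `n_divisive`, `n_common`, `agreement_pct`, `reported_n`, `error`.
#' @export
agreementTable <- function(table, anchorVars, targetVars,
                           config = SearchConfig(), seed = 1L,
                           k = 3L, trim = 0.10, restarts = 50L,
                           outlierMethod = "mad", outlierThreshold = 4.0) {
  stopifnot(is(table, "BiomarkerTable"))
  rows <- list()
  for (target in targetVars) {
    for (anchor in anchorVars) {
      row <- data.frame(target = target, anchor = anchor,
                        n_pairwise = NA_integer_, n_removed = NA_integer_,
                        n_agglomerative = NA_integer_,
                        n_divisive = NA_integer_, n_common = NA_integer_,
                        agreement_pct = NA_real_, reported_n = NA_integer_,
                        error = NA_character_, stringsAsFactors = FALSE)
      res <- tryCatch({
        pair <- pairwiseComplete(table, anchor, target)
        row$n_pairwise <- nSubjects(pair)
        screened <- screenOutliers(pair, method = outlierMethod,
                                   threshold = outlierThreshold)
        row$n_removed <- length(screened$removed)
        pair <- screened$pair
        div <- divisiveSearch(pair, config)
        agg <- agglomerativePipeline(pair, config, k = k, trim = trim,
                                     restarts = restarts, seed = seed)
        aSet <- if (is.null(agg$best)) NULL else agg$best@finalSet
        rep <- compareSolutions(aSet, div@finalSet)
        row$n_agglomerative <- rep@nAgglomerative
        row$n_divisive <- rep@nDivisive
        row$n_common <- rep@nCommon
        row$agreement_pct <- rep@agreementPct
        row$reported_n <- rep@reportedN
        if (is.null(agg$best))
          row$error <- "agglomerative: no axis produced a sensible result"
        row
      }, error = function(e) {
        row$error <- conditionMessage(e)
        row
      })
      rows[[length(rows) + 1L]] <- res
    }
  }
  do.call(rbind, rows)
}
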