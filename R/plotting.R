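#' @include reference-cohort.R
NULL

#' Scatter plot of a pair with a selected subpopulation highlighted
#'
#' Base-graphics scatter of the full pair with the members of the selected
#' subpopulation drawn in colour -- the standard visual check that the
#' search picked out a coherent linear cluster rather than an arbitrary
#' subset.
#'
#' @param pair a [VariablePair-class].
#' @param set a [SubjectSet-class] over the same pair (e.g.
#'   `finalSet(trace)`); `NULL` plots the pair alone.
#' @param main plot title.
#' @param ... further arguments to [graphics::plot()].
#' @return Invisibly, `NULL`.
#' @export
plotSubpopulation <- function(pair, set = NULL, main = NULL, ...) {
  stopifnot(is(pair, "VariablePair"))
  inSet <- if (is.null(set)) {
    rep(FALSE, nSubjects(pair))
  } else {
    pair@subjects %in% set@ids
  }
  graphics::plot(pair@x, pair@y, col = ifelse(inSet, "#2166ac", "grey60"),
                 pch = ifelse(inSet, 19, 1), xlab = pair@xName,
                 ylab = pair@yName,
                 main = main %||% sprintf("%s vs %s", pair@yName,
                                          pair@xName), ...)
  if (!is.null(set) && sum(inSet) >= 2L) {
    fit <- .olsFit(pair@x[inSet], pair@y[inSet])
    if (!is.null(fit)) graphics::abline(fit[1L], fit[2L], col = "#2166ac")
  }
  invisible(NULL)
}
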