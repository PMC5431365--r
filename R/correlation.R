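#' @include preprocessing.R
NULL

#' Pearson correlation with significance for a variable pair
#'
#' Computes Pearson's r over the pair's subjects and a two-sided p-value from
#' the exact t reference distribution, `t = r * sqrt((n - 2) / (1 - r^2))`
#' with n - 2 degrees of freedom. An exactly collinear pair maps to p = 0.
#' Significance is flagged at p < 0.01, the screening level used for
#' correlation tables in this package.
#'
#' @param pair a [VariablePair-class] with at least 3 subjects and nonzero
#'   variance on both coordinates.
#' @param alpha significance level for the flag (default 0.01).
#' @return A [CorrelationResult-class].
#' @examples
#' p <- new("VariablePair", xName = "X", yName = "Y",
#'          subjects = paste0("s", 1:4),
#'          x = c(0, 1, 2, 3), y = c(0, 2, 1, 3))
#' pearsonCorrelation(p)  # r = 0.8
#' @export
pearsonCorrelation <- function(pair, alpha = 0.01) {
  stopifnot(is(pair, "VariablePair"))
  n <- nSubjects(pair)
  if (n < 3L) stop("need at least 3 pairwise-complete subjects", call. = FALSE)
  for (side in c("x", "y")) {
    if (stats::var(slot(pair, side)) == 0) {
      nm <- if (side == "x") pair@xName else pair@yName
      stop("variable has zero variance: ", nm, call. = FALSE)
    }
  }
  r <- stats::cor(pair@x, pair@y)
  if (abs(r) >= 1 - 1e-15) {
    p <- 0
    r <- sign(r)
  } else {
    p <- stats::cor.test(pair@x, pair@y, method = "pearson")$p.value
  }
  new("CorrelationResult", xName = pair@xName, yName = pair@yName,
      r = r, n = as.integer(n), p = p, significant = p < alpha)
}

#' Build a correlation table over many variable pairs
#'
#' One row per requested pair, each computed on its own pairwise-complete
#' subject subset, so sample sizes differ across rows when missingness does.
#' Degenerate pairs (too few subjects, zero variance) become failure rows
#' rather than aborting the table.
#'
#' @param table a [BiomarkerTable-class].
#' @param pairs list of length-2 character vectors `c(xName, yName)`, or a
#'   2-column character matrix.
#' @param alpha significance level for the flag (default 0.01).
#' @return `data.frame` with columns `x`, `y`, `r`, `n`, `p`, `significant`,
#'   `error` (`NA` for clean rows).
#' @export
correlationTable <- function(table, pairs, alpha = 0.01) {
  stopifnot(is(table, "BiomarkerTable"))
  if (is.matrix(pairs)) pairs <- asplit(pairs, 1L)
  if (length(pairs) == 0L) {
    return(data.frame(x = character(), y = character(), r = numeric(),
                      n = integer(), p = numeric(), significant = logical(),
                      error = character(), stringsAsFactors = FALSE))
  }
  rows <- lapply(pairs, function(pr) {
    pr <- as.character(pr)
    res <- tryCatch({
      cr <- pearsonCorrelation(pairwiseComplete(table, pr[1L], pr[2L]),
                               alpha = alpha)
      data.frame(x = pr[1L], y = pr[2L], r = cr@r, n = cr@n, p = cr@p,
                 significant = cr@significant, error = NA_character_,
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(x = pr[1L], y = pr[2L], r = NA_real_, n = NA_integer_,
                 p = NA_real_, significant = NA, error = conditionMessage(e),
                 stringsAsFactors = FALSE)
    })
    res
  })
  do.call(rbind, rows)
}

#' Summary statistics for one variable
#'
#' @param table a [BiomarkerTable-class].
#' @param variable a variable name with at least one non-missing value.
#' @return One-row `data.frame` with columns `variable`, `n`, `min`, `max`,
#'   `mean`, `sd` (sample SD, n - 1 denominator, as clinical laboratories
#'   report; `NA` when n = 1).
#' @export
summarizeVariable <- function(table, variable) {
  stopifnot(is(table, "BiomarkerTable"))
  v <- measurements(table)
  if (!variable %in% colnames(v))
    stop("unknown variable: ", variable, call. = FALSE)
  col <- v[, variable]
  col <- col[!is.na(col)]
  if (length(col) == 0L)
    stop("variable is entirely missing: ", variable, call. = FALSE)
  data.frame(variable = variable, n = length(col),
             min = min(col), max = max(col),
             mean = mean(col), sd = stats::sd(col),
             stringsAsFactors = FALSE)
}

#' Summary statistics for every variable in a table
#'
#' @param table a [BiomarkerTable-class].
#' @return `data.frame`, one row per variable (see [summarizeVariable()]);
#'   all-missing variables are skipped with a warning.
#' @export
summaryTable <- function(table) {
  vars <- variableNames(table)
  rows <- lapply(vars, function(nm) {
    tryCatch(summarizeVariable(table, nm), error = function(e) {
      warning(conditionMessage(e), call. = FALSE)
      NULL
    })
  })
  do.call(rbind, rows)
}

#' CorrelationResult: Pearson r with sample size and significance
#'
#' @slot xName,yName variable names.
#' @slot r Pearson coefficient in `[-1, 1]`.
#' @slot n number of pairwise-complete subjects.
#' @slot p two-sided p-value from the t reference distribution.
#' @slot significant logical flag at the screening level (default p < 0.01).
#' @exportClass CorrelationResult
setClass("CorrelationResult",
  representation(xName = "character", yName = "character", r = "numeric",
                 n = "integer", p = "numeric", significant = "logical"))

setValidity("CorrelationResult", function(object) {
  msg <- character()
  if (abs(object@r) > 1 + 1e-12) msg <- c(msg, "|r| must not exceed 1")
  if (object@n < 3L) msg <- c(msg, "n must be at least 3")
  if (object@p < 0 || object@p > 1) msg <- c(msg, "p must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CorrelationResult", function(object) {
  cat(sprintf("Pearson %s vs %s: r = %.3f (N = %d); p = %.3g%s\n",
              object@yName, object@xName, object@r, object@n, object@p,
              if (object@significant) " *" else ""))
  invisible(NULL)
})
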