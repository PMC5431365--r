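#' @include biomarker-table.R
NULL

#' Extract the pairwise-complete subjects for two variables
#'
#' Retains exactly the subjects with non-missing values for both variables,
#' preserving row order. Correlations over many variable pairs therefore use
#' per-pair sample sizes, as is standard for clinical tables with scattered
#' missingness.
#'
#' @param table a [BiomarkerTable-class].
#' @param xName,yName variable names present in `table`.
#' @return A [VariablePair-class].
#' @examples
#' m <- matrix(c(1, NA, 3, 4, 10, 20, NA, 40), ncol = 2,
#'             dimnames = list(paste0("P", 1:4), c("A", "B")))
#' nSubjects(pairwiseComplete(BiomarkerTable(m), "A", "B"))  # 2
#' @export
pairwiseComplete <- function(table, xName, yName) {
  stopifnot(is(table, "BiomarkerTable"))
  .assertString(xName, "xName"); .assertString(yName, "yName")
  v <- measurements(table)
  for (nm in c(xName, yName)) {
    if (!nm %in% colnames(v))
      stop("unknown variable: ", nm, call. = FALSE)
  }
  keep <- !is.na(v[, xName]) & !is.na(v[, yName])
  new("VariablePair", xName = xName, yName = yName,
      subjects = rownames(v)[keep],
      x = unname(v[keep, xName]), y = unname(v[keep, yName]))
}

# unit convention: activity/activity ratios are reported as mUnits per unit
# of the denominator enzyme (x1000); content/activity ratios stay plain
.ratioScale <- function(numUnit, denUnit) {
  isActivity <- function(u) grepl("nmol/min", u, fixed = TRUE)
  if (isActivity(numUnit) && isActivity(denUnit)) 1000 else 1
}

#' Append a normalization ratio variable
#'
#' Adds `"<numerator>/<denominator>"` to the table, computed per subject and
#' missing wherever either operand is missing or the denominator is zero.
#' When both variables are enzyme activities (units in nmol/min*mg protein),
#' the ratio is multiplied by 1000 and reported as mUnits per denominator
#' unit -- the convention used for respiratory-chain activities normalized to
#' citrate synthase (e.g. CIV/CS reference range 503-1300 mUnits/CS Units).
#' Content/activity ratios such as CoQ/CS stay unscaled (nmol per CS Unit).
#'
#' @param table a [BiomarkerTable-class].
#' @param numerator,denominator distinct variable names.
#' @param scaleFactor override for the unit scale; `NULL` (default) applies
#'   the convention above based on the variables' unit strings.
#' @return The input table with one extra variable.
#' @export
normalizeRatio <- function(table, numerator, denominator,
                           scaleFactor = NULL) {
  stopifnot(is(table, "BiomarkerTable"))
  v <- measurements(table)
  for (nm in c(numerator, denominator)) {
    if (!nm %in% colnames(v))
      stop("unknown variable: ", nm, call. = FALSE)
  }
  if (identical(numerator, denominator))
    stop("numerator and denominator must differ (ratio would be constant)",
         call. = FALSE)
  units <- measurementUnits(table)
  scale <- scaleFactor %||% .ratioScale(units[[numerator]],
                                        units[[denominator]])
  den <- v[, denominator]
  zero <- !is.na(den) & den == 0
  if (any(zero)) {
    warning(sprintf("zero denominator for %d subject(s); ratio set missing",
                    sum(zero)), call. = FALSE)
    den[zero] <- NA_real_
  }
  ratio <- scale * v[, numerator] / den
  newName <- paste0(numerator, "/", denominator)
  out <- cbind(v, ratio)
  colnames(out)[ncol(out)] <- newName
  newUnit <- if (scale == 1000) {
    sprintf("mUnits/%s Units", denominator)
  } else if (nzchar(units[[numerator]])) {
    sprintf("(%s)/(%s)", units[[numerator]], units[[denominator]])
  } else ""
  BiomarkerTable(out, units = c(units, newUnit))
}

.robustScale <- function(z) {
  # 1.4826 * MAD estimates the SD under normality; IQR/1.349 is the fallback
  s <- stats::mad(z)
  if (s > 0) return(s)
  s <- stats::IQR(z) / 1.349
  if (s > 0) return(s)
  0
}

#' Screen gross outliers from a variable pair
#'
#' Single-pass univariate robust-z screen: a subject is removed when either
#' coordinate lies more than `threshold` robust standard deviations
#' (1.4826 * MAD) from that coordinate's median. The screen is applied
#' exactly once -- re-screening survivors could remove further points, so
#' one pass keeps the rule reproducible and conservative. With a zero MAD
#' the scale falls back to IQR/1.349; if that is also zero the coordinate is
#' skipped with a warning.
#'
#' @param pair a non-empty [VariablePair-class].
#' @param method `"mad"` (default) or `"none"` (identity).
#' @param threshold robust-z cutoff; the default 4.0 removes only gross
#'   outliers (a handful of points in a cohort of several hundred).
#' @return List with elements `pair` (survivors, a [VariablePair-class]) and
#'   `removed` (character vector of removed subject identifiers).
#' @export
screenOutliers <- function(pair, method = c("mad", "none"), threshold = 4.0) {
  stopifnot(is(pair, "VariablePair"))
  method <- match.arg(method)
  if (nSubjects(pair) == 0L) stop("empty pair", call. = FALSE)
  if (method == "none") {
    return(list(pair = pair, removed = character()))
  }
  flag <- rep(FALSE, nSubjects(pair))
  for (coord in list(pair@x, pair@y)) {
    s <- .robustScale(coord)
    if (s == 0) {
      warning("degenerate robust scale; coordinate not screened",
              call. = FALSE)
      next
    }
    flag <- flag | abs(coord - stats::median(coord)) / s > threshold
  }
  keep <- !flag
  survivors <- new("VariablePair", xName = pair@xName, yName = pair@yName,
                   subjects = pair@subjects[keep],
                   x = pair@x[keep], y = pair@y[keep])
  list(pair = survivors, removed = pair@subjects[flag])
}
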