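#' @include correlation.R
NULL

# closed-form OLS of y on x; returns c(beta0, beta1) or NULL when degenerate
.olsFit <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(NULL)
  vx <- sum((x - mean(x))^2)
  if (vx == 0) return(NULL)
  b1 <- sum((x - mean(x)) * (y - mean(y))) / vx
  c(mean(y) - b1 * mean(x), b1)
}

# one restart of trimmed k-lines; returns list(assign, betas, objective,
# trace) with assign = 0 for trimmed points
.kLinesOnce <- function(x, y, k, nTrim, maxIter = 100L) {
  n <- length(x)
  betas <- matrix(NA_real_, nrow = k, ncol = 2L)
  for (j in seq_len(k)) {
    repeat {
      idx <- sample.int(n, 2L)
      fit <- .olsFit(x[idx], y[idx])
      if (!is.null(fit)) break
    }
    betas[j, ] <- fit
  }
  assign <- rep(-1L, n)
  trace <- numeric()
  for (iter in seq_len(maxIter)) {
    res2 <- vapply(seq_len(k), function(j) {
      (y - (betas[j, 1L] + betas[j, 2L] * x))^2
    }, numeric(n))
    res2 <- matrix(res2, nrow = n)
    best <- max.col(-res2, ties.method = "first")
    bestRes <- res2[cbind(seq_len(n), best)]
    newAssign <- best
    if (nTrim > 0L) {
      cut <- order(bestRes, decreasing = TRUE)[seq_len(nTrim)]
      newAssign[cut] <- 0L
    }
    # re-seed an emptied axis from the worst-fitting untrimmed points
    for (j in seq_len(k)) {
      if (sum(newAssign == j) >= 2L) next
      pool <- which(newAssign > 0L)
      worst <- pool[order(bestRes[pool], decreasing = TRUE)[seq_len(2L)]]
      newAssign[worst] <- j
    }
    obj <- sum(bestRes[newAssign > 0L])
    trace <- c(trace, obj)
    for (j in seq_len(k)) {
      mem <- newAssign == j
      fit <- .olsFit(x[mem], y[mem])
      if (!is.null(fit)) betas[j, ] <- fit
    }
    if (identical(newAssign, assign)) break
    assign <- newAssign
  }
  list(assign = assign, betas = betas, objective = obj, trace = trace)
}

#' Detect candidate linear clusters by trimmed k-lines
#'
#' Robust linear grouping for scatter that contains one or more linear
#' structures inside diffuse background: each of `k` axes is seeded from a
#' random 2-point sample, every point is assigned to the axis minimising its
#' squared vertical residual, the `ceiling(trim * n)` worst-fitting points
#' are trimmed as noise, and each axis is refit by OLS on its untrimmed
#' members; assignment/trim/refit iterates to a fixed point. The best of
#' `restarts` random restarts (smallest total trimmed squared residual) is
#' returned. Vertical (y-on-x) residuals are used throughout because the
#' downstream seeding rule is defined via an OLS regression of Y on X.
#'
#' @param pair a [VariablePair-class] with at least `3 * k` subjects.
#' @param k number of axes (default 3, the number of linear directions
#'   explored before growing clusters).
#' @param trim fraction of points trimmed as noise, in `[0, 0.5)`
#'   (default 0.10).
#' @param seed RNG seed; required for reproducible restarts.
#' @param restarts number of random restarts (default 50).
#' @return A [ClusterSolution-class]; axes are ordered by decreasing member
#'   count.
#' @examples
#' pr <- new("VariablePair", xName = "X", yName = "Y",
#'           subjects = sprintf("s%02d", 1:20),
#'           x = seq(0, 1, length.out = 20),
#'           y = 2 + 3 * seq(0, 1, length.out = 20))
#' sol <- robustLinearClusters(pr, k = 1, trim = 0, seed = 1)
#' axes(sol)[[1]]
#' @export
robustLinearClusters <- function(pair, k = 3L, trim = 0.10, seed,
                                 restarts = 50L) {
  stopifnot(is(pair, "VariablePair"))
  k <- .assertCount(k, "k", min = 1L)
  .assertFraction(trim, "trim", maxExclusive = 0.5)
  restarts <- .assertCount(restarts, "restarts", min = 1L)
  seed <- .assertCount(seed, "seed")
  n <- nSubjects(pair)
  if (n < 3L * k) stop("need at least 3*k subjects", call. = FALSE)
  nTrim <- as.integer(ceiling(trim * n))
  if (n - nTrim < 2L * k) stop("trim leaves too few points", call. = FALSE)
  x <- pair@x; y <- pair@y
  best <- NULL
  .withSeed(seed, {
    for (r in seq_len(restarts)) {
      cand <- .kLinesOnce(x, y, k, nTrim)
      if (is.null(best) || cand$objective < best$objective) best <- cand
    }
  })
  ord <- order(vapply(seq_len(k), function(j) sum(best$assign == j),
                      integer(1)), decreasing = TRUE)
  axesList <- lapply(ord, function(j) {
    mem <- best$assign == j
    fit <- .olsFit(x[mem], y[mem])
    if (is.null(fit)) fit <- c(best$betas[j, 1L], best$betas[j, 2L])
    new("LinearAxis", beta0 = fit[1L], beta1 = fit[2L],
        memberIDs = pair@subjects[mem], x = x[mem], y = y[mem],
        residuals = y[mem] - (fit[1L] + fit[2L] * x[mem]))
  })
  new("ClusterSolution", axes = axesList,
      unassignedIDs = pair@subjects[best$assign == 0L],
      seed = seed, objective = best$objective,
      objectiveTrace = best$trace,
      xName = pair@xName, yName = pair@yName)
}

#' Seed triple: the three members closest to their axis
#'
#' Selects the three member subjects with the smallest absolute vertical
#' residual to the axis line -- the starting set M(0) of the agglomerative
#' search. Ties are broken by ascending subject identifier so reruns are
#' bit-identical.
#'
#' @param axis a [LinearAxis-class] with at least 3 members.
#' @param pair the [VariablePair-class] the axis was fitted on.
#' @return A [SubjectSet-class] of size 3.
#' @export
seedTriple <- function(axis, pair) {
  stopifnot(is(axis, "LinearAxis"), is(pair, "VariablePair"))
  if (length(axis@memberIDs) < 3L)
    stop("axis has fewer than 3 members", call. = FALSE)
  ord <- order(abs(axis@residuals), axis@memberIDs, method = "radix")
  SubjectSet(axis@memberIDs[ord[1:3]], pair)
}
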