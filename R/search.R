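#' @include cluster-init.R
NULL

# ---- incremental Pearson engine -------------------------------------------
#
# Both greedy searches must evaluate, at every step, the correlation of the
# current set with one subject added (or removed) for every candidate.  The
# engine keeps the five running sums (n, Sx, Sy, Sxx, Syy, Sxy) so that each
# candidate costs O(1) and each step O(n); a full run is O(n^2), which keeps
# cohorts of ~450 subjects interactive.  Sums are refreshed from scratch
# every 64 accepted steps to bound floating-point drift.

.sumsOf <- function(x, y) {
  list(n = length(x), sx = sum(x), sy = sum(y),
       sxx = sum(x * x), syy = sum(y * y), sxy = sum(x * y))
}

# vectorized Pearson r from sums; NaN where a coordinate is degenerate
.rFromSums <- function(n, sx, sy, sxx, syy, sxy) {
  vx <- sxx - sx * sx / n
  vy <- syy - sy * sy / n
  num <- sxy - sx * sy / n
  den <- vx * vy
  r <- ifelse(den > 0, num / sqrt(pmax(den, 0)), NaN)
  pmin(1, pmax(-1, r))
}

.rOfSums <- function(s) .rFromSums(s$n, s$sx, s$sy, s$sxx, s$syy, s$sxy)

# r of the current set with each (xc, yc) added, vectorized over candidates
.rWithAdded <- function(s, xc, yc) {
  .rFromSums(s$n + 1, s$sx + xc, s$sy + yc,
             s$sxx + xc * xc, s$syy + yc * yc, s$sxy + xc * yc)
}

# r of the current set with each member (xm, ym) removed, vectorized
.rWithRemoved <- function(s, xm, ym) {
  .rFromSums(s$n - 1, s$sx - xm, s$sy - ym,
             s$sxx - xm * xm, s$syy - ym * ym, s$sxy - xm * ym)
}

.pairIndex <- function(pair, ids) {
  idx <- match(ids, pair@subjects)
  if (anyNA(idx)) {
    stop("subject(s) not in pair: ",
         paste(ids[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  idx
}

# ---- correlation loss / gain ----------------------------------------------

#' Correlation loss from adding one individual
#'
#' The correlation loss measure CLM(M, i) = rho(M) - rho(M + {i}): the drop
#' in within-set Pearson correlation caused by adjoining subject `i` to the
#' set M. Negative values mean the candidate *increases* the correlation.
#' When adjoining the candidate makes a coordinate constant (degenerate
#' correlation), `+Inf` is returned so the candidate can never be selected.
#'
#' @param current a [SubjectSet-class] with at least 3 members and
#'   non-degenerate correlation.
#' @param candidate a subject identifier in the pair but not in `current`.
#' @return Signed loss (scalar).
#' @seealso [correlationGain()], [agglomerativeSearch()]
#' @export
correlationLoss <- function(current, candidate) {
  stopifnot(is(current, "SubjectSet"))
  .assertString(candidate, "candidate")
  if (candidate %in% current@ids)
    stop("candidate already in the set", call. = FALSE)
  if (length(current@ids) < 3L)
    stop("current set must have at least 3 members", call. = FALSE)
  pair <- current@pair
  mi <- .pairIndex(pair, current@ids)
  ci <- .pairIndex(pair, candidate)
  s <- .sumsOf(pair@x[mi], pair@y[mi])
  rCur <- .rOfSums(s)
  if (is.nan(rCur))
    stop("current set has a constant coordinate", call. = FALSE)
  rNew <- .rWithAdded(s, pair@x[ci], pair@y[ci])
  if (is.nan(rNew)) return(Inf)
  rCur - rNew
}

#' Correlation gain from deleting one individual
#'
#' The correlation gain measure CGM(M, i) = rho(M - {i}) - rho(M): the rise
#' in within-set Pearson correlation caused by deleting subject `i`.
#' Satisfies the identity CGM(M, i) = CLM(M - {i}, i). When the deletion
#' makes a coordinate constant, `-Inf` is returned so the candidate can
#' never be selected.
#'
#' @param current a [SubjectSet-class] with at least 4 members.
#' @param candidate a subject identifier inside `current`.
#' @return Signed gain (scalar).
#' @seealso [correlationLoss()], [divisiveSearch()]
#' @export
correlationGain <- function(current, candidate) {
  stopifnot(is(current, "SubjectSet"))
  .assertString(candidate, "candidate")
  if (!candidate %in% current@ids)
    stop("candidate not in the set", call. = FALSE)
  if (length(current@ids) < 4L)
    stop("current set must have at least 4 members", call. = FALSE)
  pair <- current@pair
  mi <- .pairIndex(pair, current@ids)
  ci <- .pairIndex(pair, candidate)
  s <- .sumsOf(pair@x[mi], pair@y[mi])
  rCur <- .rOfSums(s)
  if (is.nan(rCur))
    stop("current set has a constant coordinate", call. = FALSE)
  rWo <- .rWithRemoved(s, pair@x[ci], pair@y[ci])
  if (is.nan(rWo)) return(-Inf)
  rWo - rCur
}

# ---- searches -------------------------------------------------------------

.makeTrace <- function(steps, ids, pair, finalR, terminatedBy, mode) {
  steps <- if (length(steps)) {
    do.call(rbind, steps)
  } else {
    data.frame(step = integer(), subject = character(), size = integer(),
               rho = numeric(), stringsAsFactors = FALSE)
  }
  new("SearchTrace", steps = steps, finalSet = SubjectSet(ids, pair),
      finalR = finalR, terminatedBy = terminatedBy, mode = mode)
}

#' Agglomerative subpopulation search (correlation-loss minimisation)
#'
#' Grows a seed set one subject at a time. At each step every non-member is
#' scored by its correlation loss; the subject with the smallest loss
#' (equivalently, the largest resulting correlation) is the greedy choice.
#' If even that best addition would drop the set's correlation below the
#' target `rStar`, the addition is rejected and the search stops, so the
#' returned set always satisfies `rho >= rStar`. Candidate ties are broken
#' by ascending subject identifier.
#'
#' @param pair a [VariablePair-class].
#' @param seedSet the starting [SubjectSet-class], typically the three
#'   smallest-residual members of a detected linear axis ([seedTriple()]);
#'   its correlation must already satisfy `rStar`, otherwise the axis is not
#'   a sensible starting direction and an error is raised.
#' @param config a [SearchConfig-class]; `rStar` and `maxSteps` are used.
#' @return A [SearchTrace-class] with `terminatedBy` one of `"threshold"`
#'   (best addition rejected), `"exhausted"` (every subject absorbed) or
#'   `"max_steps"`.
#' @export
agglomerativeSearch <- function(pair, seedSet, config = SearchConfig()) {
  stopifnot(is(pair, "VariablePair"), is(seedSet, "SubjectSet"),
            is(config, "SearchConfig"))
  rStar <- config@rStar
  ids <- .sortIDs(seedSet@ids)
  if (length(ids) < 3L) stop("seed set needs >= 3 members", call. = FALSE)
  memberIdx <- .pairIndex(pair, ids)
  s <- .sumsOf(pair@x[memberIdx], pair@y[memberIdx])
  rCur <- .rOfSums(s)
  if (is.nan(rCur) || rCur < rStar)
    stop(sprintf("seed below threshold: rho(seed) = %.4f < r* = %.4f",
                 rCur, rStar), call. = FALSE)
  # candidates kept sorted by id so which.max resolves ties deterministically
  candIdx <- setdiff(seq_along(pair@subjects), memberIdx)
  candIdx <- candIdx[.idOrder(pair@subjects[candIdx])]
  steps <- list()
  k <- 0L
  terminated <- NULL
  while (is.null(terminated)) {
    if (length(candIdx) == 0L) { terminated <- "exhausted"; break }
    if (k >= config@maxSteps) { terminated <- "max_steps"; break }
    rAdd <- .rWithAdded(s, pair@x[candIdx], pair@y[candIdx])
    rAdd[is.nan(rAdd)] <- -Inf
    best <- which.max(rAdd)
    if (!is.finite(rAdd[best]) || rAdd[best] < rStar) {
      terminated <- "threshold"
      break
    }
    i <- candIdx[best]
    memberIdx <- c(memberIdx, i)
    candIdx <- candIdx[-best]
    k <- k + 1L
    if (k %% 64L == 0L) {
      s <- .sumsOf(pair@x[memberIdx], pair@y[memberIdx])
    } else {
      s <- list(n = s$n + 1L, sx = s$sx + pair@x[i], sy = s$sy + pair@y[i],
                sxx = s$sxx + pair@x[i]^2, syy = s$syy + pair@y[i]^2,
                sxy = s$sxy + pair@x[i] * pair@y[i])
    }
    rCur <- .rOfSums(s)
    steps[[k]] <- data.frame(step = k, subject = pair@subjects[i],
                             size = length(memberIdx), rho = rCur,
                             stringsAsFactors = FALSE)
  }
  .makeTrace(steps, pair@subjects[memberIdx], pair, rCur, terminated,
             "agglomerative")
}

#' Divisive subpopulation search (correlation-gain maximisation)
#'
#' Starts from the whole cohort and deletes one subject per step: the one
#' whose removal raises the set's correlation the most (largest correlation
#' gain). Deletion stops as soon as the correlation reaches the target
#' `rStar`, so the first -- and therefore largest -- satisfying set is
#' returned. Fully deterministic; ties are broken by ascending subject
#' identifier.
#'
#' @param pair a [VariablePair-class] with at least 4 subjects.
#' @param config a [SearchConfig-class]; `rStar` and `maxSteps` are used.
#' @return A [SearchTrace-class]; `terminatedBy = "exhausted"` flags the
#'   diagnostic case where the set shrank to 3 subjects without reaching
#'   `rStar` (no high-correlation subpopulation).
#' @examples
#' pr <- new("VariablePair", xName = "X", yName = "Y",
#'           subjects = paste0("s", 1:4),
#'           x = c(0, 1, 2, 3), y = c(0, 1, 2, 0))
#' tr <- divisiveSearch(pr)
#' traceSteps(tr)  # one deletion: the off-line subject s4
#' @export
divisiveSearch <- function(pair, config = SearchConfig()) {
  stopifnot(is(pair, "VariablePair"), is(config, "SearchConfig"))
  rStar <- config@rStar
  if (nSubjects(pair) < 4L)
    stop("need at least 4 subjects", call. = FALSE)
  ord <- .idOrder(pair@subjects)
  memberIdx <- seq_along(pair@subjects)[ord]  # id-sorted for tie-breaking
  s <- .sumsOf(pair@x, pair@y)
  rCur <- .rOfSums(s)
  if (is.nan(rCur))
    stop("a coordinate is constant over the whole cohort", call. = FALSE)
  steps <- list()
  k <- 0L
  terminated <- NULL
  while (rCur < rStar) {
    if (length(memberIdx) <= 3L) { terminated <- "exhausted"; break }
    if (k >= config@maxSteps) { terminated <- "max_steps"; break }
    rLoo <- .rWithRemoved(s, pair@x[memberIdx], pair@y[memberIdx])
    rLoo[is.nan(rLoo)] <- -Inf
    best <- which.max(rLoo)
    i <- memberIdx[best]
    memberIdx <- memberIdx[-best]
    k <- k + 1L
    if (k %% 64L == 0L) {
      s <- .sumsOf(pair@x[memberIdx], pair@y[memberIdx])
    } else {
      s <- list(n = s$n - 1L, sx = s$sx - pair@x[i], sy = s$sy - pair@y[i],
                sxx = s$sxx - pair@x[i]^2, syy = s$syy - pair@y[i]^2,
                sxy = s$sxy - pair@x[i] * pair@y[i])
    }
    rCur <- .rOfSums(s)
    steps[[k]] <- data.frame(step = k, subject = pair@subjects[i],
                             size = length(memberIdx), rho = rCur,
                             stringsAsFactors = FALSE)
  }
  if (is.null(terminated)) terminated <- "threshold"
  # report members in original pair order
  memberIdx <- sort(memberIdx)
  .makeTrace(steps, pair@subjects[memberIdx], pair, rCur, terminated,
             "divisive")
}

#' Grow every detected axis and keep the largest subpopulation
#'
#' The full agglomerative pipeline for one variable pair: detect `k`
#' candidate linear axes, seed each with its three closest members, grow
#' each seed by [agglomerativeSearch()], and select the grown cluster with
#' the most individuals. Axes whose seed already violates the threshold are
#' reported as failures rather than silently dropped -- for some enzyme
#' pairs no linear axis yields a sensible start and only the divisive method
#' applies.
#'
#' @param pair a [VariablePair-class].
#' @param config a [SearchConfig-class].
#' @param k,trim,restarts,seed passed to [robustLinearClusters()].
#' @return List with `best` (the winning [SearchTrace-class], or `NULL` when
#'   every axis failed), `traces` (one per axis, `NULL` where failed),
#'   `failures` (character, per-axis failure messages, `NA` where grown),
#'   and `clusters` (the [ClusterSolution-class]).
#' @export
agglomerativePipeline <- function(pair, config = SearchConfig(),
                                  k = 3L, trim = 0.10, restarts = 50L,
                                  seed) {
  clusters <- robustLinearClusters(pair, k = k, trim = trim, seed = seed,
                                   restarts = restarts)
  traces <- vector("list", length(clusters@axes))
  failures <- rep(NA_character_, length(clusters@axes))
  for (j in seq_along(clusters@axes)) {
    axis <- clusters@axes[[j]]
    traces[[j]] <- tryCatch({
      agglomerativeSearch(pair, seedTriple(axis, pair), config)
    }, error = function(e) {
      failures[j] <<- conditionMessage(e)
      NULL
    })
  }
  grown <- Filter(Negate(is.null), traces)
  best <- NULL
  if (length(grown)) {
    sizes <- vapply(grown, function(tr) length(tr@finalSet@ids), integer(1))
    best <- grown[[which.max(sizes)]]
  }
  list(best = best, traces = traces, failures = failures,
       clusters = clusters)
}

#' Serialize a search trace to CSV
#'
#' @param trace a [SearchTrace-class].
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
writeSearchTrace <- function(trace, path) {
  stopifnot(is(trace, "SearchTrace"))
  df <- trace@steps
  df$action <- rep(if (trace@mode == "agglomerative") "add" else "remove",
                   nrow(df))
  df <- df[, c("step", "action", "subject", "size", "rho")]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
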