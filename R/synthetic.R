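#' @include agreement.R
NULL

#' Specification for a synthetic two-variable cohort
#'
#' Describes the statistical structure the generator plants: weakly
#' correlated background scatter, one or more linear clusters with distinct
#' slopes and controllable vertical noise, a small fraction of gross
#' outliers, and uniformly scattered missing cells. This is the structure
#' the subpopulation searches are designed to resolve -- a dominant tight
#' linear cluster embedded in diffuse scatter -- not a biochemical
#' simulation.
#'
#' @param nBackground number of background subjects.
#' @param backgroundR target Pearson correlation of the background scatter
#'   (weak by design; default 0.2).
#' @param backgroundMean,backgroundSd length-2 numeric: mean and SD of the
#'   background marginals (x then y).
#' @param clusters `data.frame` with one row per planted linear cluster and
#'   columns `size`, `beta0`, `beta1`, `xmin`, `xmax`, `noiseSd`: cluster x
#'   is uniform on `[xmin, xmax]` and `y = beta0 + beta1 * x + N(0,
#'   noiseSd)`. `NULL` for no clusters.
#' @param missingFrac fraction of cells masked missing, in `[0, 1)`.
#' @param outlierCount number of gross outliers, scattered uniformly over a
#'   bounding box inflated 1.5x beyond the data range.
#' @param seed RNG seed (recorded in the output).
#' @param xName,yName variable names for the generated table.
#' @return A validated list of class `"SyntheticSpec"`.
#' @export
syntheticSpec <- function(nBackground = 100L, backgroundR = 0.2,
                          backgroundMean = c(0, 0), backgroundSd = c(1, 1),
                          clusters = NULL, missingFrac = 0,
                          outlierCount = 0L, seed = 1L,
                          xName = "X", yName = "Y") {
  nBackground <- .assertCount(nBackground, "nBackground")
  outlierCount <- .assertCount(outlierCount, "outlierCount")
  seed <- .assertCount(seed, "seed")
  .assertFraction(missingFrac, "missingFrac")
  if (abs(backgroundR) > 1) stop("'backgroundR' must lie in [-1, 1]",
                                 call. = FALSE)
  if (!is.null(clusters)) {
    clusters <- as.data.frame(clusters)
    need <- c("size", "beta0", "beta1", "xmin", "xmax", "noiseSd")
    if (!all(need %in% names(clusters)))
      stop("clusters needs columns: ", paste(need, collapse = ", "),
           call. = FALSE)
    if (any(clusters$size < 0) || any(clusters$noiseSd < 0) ||
        any(clusters$xmax <= clusters$xmin))
      stop("invalid cluster row (size/noiseSd >= 0, xmax > xmin)",
           call. = FALSE)
  }
  structure(list(nBackground = nBackground, backgroundR = backgroundR,
                 backgroundMean = backgroundMean, backgroundSd = backgroundSd,
                 clusters = clusters, missingFrac = missingFrac,
                 outlierCount = outlierCount, seed = seed,
                 xName = xName, yName = yName),
            class = "SyntheticSpec")
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws the cohort described by a [syntheticSpec()]: background from a
#' bivariate normal with the requested correlation, each planted cluster
#' along its line with vertical Gaussian noise, outliers uniform over an
#' inflated bounding box, then uniform missingness. Fully reproducible from
#' the spec's seed; the caller's RNG state is untouched.
#'
#' @param spec a `"SyntheticSpec"` (see [syntheticSpec()]).
#' @return List with `table` (a [BiomarkerTable-class]) and `truth`
#'   (`data.frame` with columns `subject`, `label`; labels are
#'   `"background"`, `"cluster1"`, `"cluster2"`, ..., `"outlier"`).
#' @examples
#' spec <- syntheticSpec(nBackground = 50,
#'                       clusters = data.frame(size = 30, beta0 = 1,
#'                                             beta1 = 2, xmin = -1,
#'                                             xmax = 1, noiseSd = 0),
#'                       seed = 7)
#' cohort <- generateCohort(spec)
#' table(cohort$truth$label)
#' @export
generateCohort <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  nc <- if (is.null(spec$clusters)) 0L else nrow(spec$clusters)
  nTotal <- spec$nBackground +
    (if (nc) sum(spec$clusters$size) else 0L) + spec$outlierCount
  .withSeed(spec$seed, {
    xs <- numeric(0); ys <- numeric(0); labels <- character(0)
    if (spec$nBackground > 0L) {
      z1 <- stats::rnorm(spec$nBackground)
      z2 <- spec$backgroundR * z1 +
        sqrt(1 - spec$backgroundR^2) * stats::rnorm(spec$nBackground)
      xs <- c(xs, spec$backgroundMean[1] + spec$backgroundSd[1] * z1)
      ys <- c(ys, spec$backgroundMean[2] + spec$backgroundSd[2] * z2)
      labels <- c(labels, rep("background", spec$nBackground))
    }
    if (nc) {
      for (j in seq_len(nc)) {
        cl <- spec$clusters[j, ]
        if (cl$size == 0L) next
        cx <- stats::runif(cl$size, cl$xmin, cl$xmax)
        cy <- cl$beta0 + cl$beta1 * cx +
          stats::rnorm(cl$size, sd = cl$noiseSd)
        xs <- c(xs, cx); ys <- c(ys, cy)
        labels <- c(labels, rep(sprintf("cluster%d", j), cl$size))
      }
    }
    if (spec$outlierCount > 0L) {
      rngX <- range(xs); rngY <- range(ys)
      padX <- 0.5 * diff(rngX); padY <- 0.5 * diff(rngY)
      xs <- c(xs, stats::runif(spec$outlierCount,
                               rngX[1] - padX, rngX[2] + padX))
      ys <- c(ys, stats::runif(spec$outlierCount,
                               rngY[1] - padY, rngY[2] + padY))
      labels <- c(labels, rep("outlier", spec$outlierCount))
    }
    ids <- sprintf("S%0*d", max(3L, nchar(nTotal)), seq_len(nTotal))
    values <- cbind(xs, ys)
    dimnames(values) <- list(ids, c(spec$xName, spec$yName))
    if (spec$missingFrac > 0) {
      mask <- stats::runif(length(values)) < spec$missingFrac
      values[mask] <- NA_real_
    }
    list(table = BiomarkerTable(values),
         truth = data.frame(subject = ids, label = labels,
                            stringsAsFactors = FALSE))
  })
}

#' Write a generated cohort to disk
#'
#' @param cohort output of [generateCohort()].
#' @param path CSV path for the measurement table; truth labels go to a
#'   sidecar `<path>.truth.csv`.
#' @return Invisibly, `path`.
#' @export
writeCohort <- function(cohort, path) {
  writeBiomarkerTable(cohort$table, path)
  utils::write.csv(cohort$truth, paste0(path, ".truth.csv"),
                   row.names = FALSE)
  invisible(path)
}
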