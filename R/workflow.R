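#' @include plotting.R
NULL

.writeManifest <- function(outDir, command, inputs, config, outputs) {
  manifest <- list(command = command, inputs = inputs, config = config,
                   outputs = outputs,
                   tool = list(package = "corrsubpop",
                               version = as.character(
                                 utils::packageVersion("corrsubpop"))),
                   timestamp = format(Sys.time(), tz = "UTC",
                                      "%Y-%m-%dT%H:%M:%SZ"))
  path <- file.path(outDir, paste0(command, ".manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

.ensureDir <- function(outDir) {
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  invisible(outDir)
}

#' Run the correlation stage: summary statistics and correlation tables
#'
#' Writes per-variable summary statistics and Pearson correlation tables for
#' all requested variable pairs under three normalizations: the raw
#' (per-protein) variables, activities normalized to CS, and activities
#' normalized to CoQ (each applied only when the corresponding normalizer
#' column is present).
#'
#' @param input path to a subject-level CSV/TSV (see
#'   [readBiomarkerTable()]), or a [BiomarkerTable-class].
#' @param outDir output directory (created if needed).
#' @param anchorVars normalizer/anchor variables present in the table
#'   (default `c("CoQ", "CS")`).
#' @param alpha significance level for the flag (default 0.01).
#' @param ... passed to [readBiomarkerTable()] when `input` is a path.
#' @return Invisibly, named character vector of output paths.
#' @export
runCorrelate <- function(input, outDir, anchorVars = c("CoQ", "CS"),
                         alpha = 0.01, ...) {
  .ensureDir(outDir)
  table <- if (is(input, "BiomarkerTable")) input
           else readBiomarkerTable(input, ...)
  vars <- variableNames(table)
  anchors <- intersect(anchorVars, vars)
  targets <- setdiff(vars, anchors)
  outputs <- c(summary = file.path(outDir, "summary_stats.csv"))
  utils::write.csv(summaryTable(table), outputs[["summary"]],
                   row.names = FALSE)
  # raw variables, pairwise against each anchor
  pairs <- c(if (length(anchors) == 2L) list(anchors),
             unlist(lapply(anchors, function(a) {
               lapply(targets, function(t) c(a, t))
             }), recursive = FALSE))
  rawPath <- file.path(outDir, "correlations_raw.csv")
  utils::write.csv(correlationTable(table, pairs, alpha = alpha), rawPath,
                   row.names = FALSE)
  outputs <- c(outputs, raw = rawPath)
  # activities normalized to each anchor, correlated with the other anchor
  for (norm in anchors) {
    other <- setdiff(anchors, norm)
    if (length(other) != 1L) next
    tab <- table
    ratioVars <- character()
    for (t in targets) {
      tab <- normalizeRatio(tab, t, norm)
      ratioVars <- c(ratioVars, paste0(t, "/", norm))
    }
    normPairs <- lapply(ratioVars, function(rv) c(other, rv))
    p <- file.path(outDir, sprintf("correlations_per_%s.csv", norm))
    utils::write.csv(correlationTable(tab, normPairs, alpha = alpha), p,
                     row.names = FALSE)
    outputs <- c(outputs, stats::setNames(p, paste0("per_", norm)))
  }
  .writeManifest(outDir, "correlate",
                 inputs = if (is.character(input)) input else "<in-memory>",
                 config = list(anchorVars = anchorVars, alpha = alpha),
                 outputs = as.list(outputs))
  invisible(outputs)
}

#' Run one subpopulation search end to end
#'
#' Extracts the pairwise-complete subjects for one variable pair, screens
#' outliers, runs the requested search (divisive, or the full agglomerative
#' pipeline over all detected axes with the largest grown cluster selected),
#' and writes the step trace, the final membership list, the removed-subject
#' sidecar and a reproducibility manifest. Optionally draws the selected
#' subpopulation over the scatter.
#'
#' @param input path to a subject-level CSV, or a [BiomarkerTable-class].
#' @param outDir output directory.
#' @param xName,yName the variable pair to search.
#' @param mode `"divisive"` or `"agglomerative"`.
#' @param rStar target correlation (default 0.95).
#' @param k,trim,restarts axis-detection controls (agglomerative mode).
#' @param seed RNG seed; required in agglomerative mode.
#' @param outlierMethod,outlierThreshold see [screenOutliers()].
#' @param plot when `TRUE`, writes `search_plot.pdf` with the selected
#'   subpopulation highlighted.
#' @param ... passed to [readBiomarkerTable()] when `input` is a path.
#' @return Invisibly, the winning [SearchTrace-class].
#' @export
runSearch <- function(input, outDir, xName, yName,
                      mode = c("divisive", "agglomerative"), rStar = 0.95,
                      k = 3L, trim = 0.10, restarts = 50L, seed = NULL,
                      outlierMethod = "mad", outlierThreshold = 4.0,
                      plot = FALSE, ...) {
  mode <- match.arg(mode)
  .ensureDir(outDir)
  table <- if (is(input, "BiomarkerTable")) input
           else readBiomarkerTable(input, ...)
  pair <- pairwiseComplete(table, xName, yName)
  screened <- screenOutliers(pair, method = outlierMethod,
                             threshold = outlierThreshold)
  pair <- screened$pair
  if (length(screened$removed)) {
    utils::write.csv(
      data.frame(subject_id = screened$removed,
                 variable_pair = sprintf("%s~%s", xName, yName),
                 reason = sprintf("robust z > %g", outlierThreshold)),
      file.path(outDir, "removed_subjects.csv"), row.names = FALSE)
  }
  config <- SearchConfig(rStar = rStar, mode = mode)
  failures <- character()
  if (mode == "divisive") {
    best <- divisiveSearch(pair, config)
  } else {
    if (is.null(seed))
      stop("agglomerative mode requires a seed", call. = FALSE)
    res <- agglomerativePipeline(pair, config, k = k, trim = trim,
                                 restarts = restarts, seed = seed)
    failures <- res$failures[!is.na(res$failures)]
    if (is.null(res$best))
      stop("agglomerative search failed on every axis: ",
           paste(failures, collapse = "; "), call. = FALSE)
    best <- res$best
    for (j in seq_along(res$traces)) {
      if (is.null(res$traces[[j]])) next
      writeSearchTrace(res$traces[[j]],
                       file.path(outDir, sprintf("trace_axis%d.csv", j)))
    }
  }
  writeSearchTrace(best, file.path(outDir, "search_trace.csv"))
  writeLines(memberIDs(finalSet(best)),
             file.path(outDir, "membership.txt"))
  if (plot) {
    grDevices::pdf(file.path(outDir, "search_plot.pdf"), width = 6,
                   height = 5)
    plotSubpopulation(pair, finalSet(best),
                      main = sprintf("%s vs %s (n = %d, r = %.3f)", yName,
                                     xName, nSubjects(finalSet(best)),
                                     best@finalR))
    grDevices::dev.off()
  }
  .writeManifest(outDir, "search",
                 inputs = if (is.character(input)) input else "<in-memory>",
                 config = list(xName = xName, yName = yName, mode = mode,
                               rStar = rStar, k = k, trim = trim,
                               restarts = restarts, seed = seed,
                               outlierMethod = outlierMethod,
                               outlierThreshold = outlierThreshold,
                               failures = failures),
                 outputs = list(trace = "search_trace.csv",
                                membership = "membership.txt"))
  invisible(best)
}

#' Run the method-agreement report
#'
#' @param input path to a subject-level CSV, or a [BiomarkerTable-class].
#' @param outDir output directory.
#' @param anchorVars,targetVars variable sets for [agreementTable()];
#'   `targetVars = NULL` uses every non-anchor variable.
#' @param rStar target correlation.
#' @param seed RNG seed for axis detection.
#' @param ... further arguments to [agreementTable()].
#' @return Invisibly, the report `data.frame`.
#' @export
runCompare <- function(input, outDir, anchorVars = c("CoQ", "CS"),
                       targetVars = NULL, rStar = 0.95, seed = 1L, ...) {
  .ensureDir(outDir)
  table <- if (is(input, "BiomarkerTable")) input
           else readBiomarkerTable(input)
  targetVars <- targetVars %||% setdiff(variableNames(table), anchorVars)
  report <- agreementTable(table, anchorVars, targetVars,
                         config = SearchConfig(rStar = rStar), seed = seed,
                         ...)
  utils::write.csv(report, file.path(outDir, "agreement_report.csv"),
                   row.names = FALSE)
  .writeManifest(outDir, "compare",
                 inputs = if (is.character(input)) input else "<in-memory>",
                 config = list(anchorVars = anchorVars,
                               targetVars = targetVars, rStar = rStar,
                               seed = seed),
                 outputs = list(report = "agreement_report.csv"))
  invisible(report)
}

#' Generate and write a synthetic cohort
#'
#' @param outDir output directory; the table goes to `synthetic_cohort.csv`
#'   with truth labels in a sidecar.
#' @param spec a [syntheticSpec()]; the default spec plants one dominant
#'   tight cluster inside weakly correlated background.
#' @return Invisibly, the generated cohort list.
#' @export
runSimulate <- function(outDir,
                        spec = syntheticSpec(
                          nBackground = 100L,
                          clusters = data.frame(size = 100, beta0 = 0.5,
                                                beta1 = 1.5, xmin = -2,
                                                xmax = 2, noiseSd = 0.04),
                          seed = 1L)) {
  .ensureDir(outDir)
  cohort <- generateCohort(spec)
  path <- file.path(outDir, "synthetic_cohort.csv")
  writeCohort(cohort, path)
  .writeManifest(outDir, "simulate", inputs = list(),
                 config = unclass(spec),
                 outputs = list(table = "synthetic_cohort.csv",
                                truth = "synthetic_cohort.csv.truth.csv"))
  invisible(cohort)
}
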