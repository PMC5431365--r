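test_that("runCorrelate writes summary and correlation tables", {
  co <- plantedCohort(seed = 2, nPlanted = 20, nBackground = 20)
  v <- measurements(co$table)
  colnames(v) <- c("CoQ", "CS")
  tab <- BiomarkerTable(v + 10, units = c("nmol/g protein",
                                          "nmol/min*mg protein"))
  out <- withr::local_tempdir()
  paths <- runCorrelate(tab, out)
  expect_true(file.exists(file.path(out, "summary_stats.csv")))
  expect_true(file.exists(file.path(out, "correlations_raw.csv")))
  expect_true(file.exists(file.path(out, "correlate.manifest.json")))
  raw <- read.csv(file.path(out, "correlations_raw.csv"))
  expect_equal(raw$n[1], 40L)
})

test_that("runSearch on a collinear table keeps every subject", {
  x <- seq(1, 5, length.out = 12)
  v <- cbind(X = x, Y = 1 + 2 * x)
  rownames(v) <- sprintf("P%02d", 1:12)
  out <- withr::local_tempdir()
  tr <- runSearch(BiomarkerTable(v), out, "X", "Y", mode = "divisive",
                  outlierMethod = "none")
  expect_setequal(readLines(file.path(out, "membership.txt")),
                  sprintf("P%02d", 1:12))
  expect_true(file.exists(file.path(out, "search_trace.csv")))
  expect_true(file.exists(file.path(out, "search.manifest.json")))
})

test_that("agglomerative runSearch reports per-axis traces and the winner", {
  co <- plantedCohort(seed = 6)
  out <- withr::local_tempdir()
  tr <- runSearch(co$table, out, "X", "Y", mode = "agglomerative",
                  seed = 3, outlierMethod = "none")
  expect_gte(nSubjects(finalSet(tr)), 90L)
  expect_true(file.exists(file.path(out, "trace_axis1.csv")))
  expect_error(runSearch(co$table, withr::local_tempdir(), "X", "Y",
                         mode = "agglomerative", outlierMethod = "none"),
               "requires a seed")
})

test_that("reruns with identical inputs are byte-identical", {
  co <- plantedCohort(seed = 4, nPlanted = 30, nBackground = 30)
  out1 <- withr::local_tempdir(); out2 <- withr::local_tempdir()
  runSearch(co$table, out1, "X", "Y", mode = "divisive",
            outlierMethod = "none")
  runSearch(co$table, out2, "X", "Y", mode = "divisive",
            outlierMethod = "none")
  for (f in c("search_trace.csv", "membership.txt")) {
    expect_identical(unname(tools::md5sum(file.path(out1, f))),
                     unname(tools::md5sum(file.path(out2, f))))
  }
})

test_that("runSimulate writes the cohort, truth labels and manifest", {
  out <- withr::local_tempdir()
  co <- runSimulate(out)
  expect_true(file.exists(file.path(out, "synthetic_cohort.csv")))
  expect_true(file.exists(file.path(out,
                                    "synthetic_cohort.csv.truth.csv")))
  # the default spec scatters around the origin, so the physiological
  # negativity flag is expected here
  back <- suppressWarnings(
    readBiomarkerTable(file.path(out, "synthetic_cohort.csv")))
  expect_equal(nSubjects(back), 200L)
  # same seed, same files
  out2 <- withr::local_tempdir()
  runSimulate(out2)
  expect_identical(
    unname(tools::md5sum(file.path(out, "synthetic_cohort.csv"))),
    unname(tools::md5sum(file.path(out2, "synthetic_cohort.csv"))))
})

test_that("the command-line script runs the simulate and search commands", {
  skip_if_not_installed("optparse")
  script <- system.file("scripts", "corrsubpop.R", package = "corrsubpop")
  skip_if(script == "")
  out <- file.path(withr::local_tempdir(), "cli")
  res <- system2("Rscript", c(script, "simulate", "--seed", "7",
                              "--out-dir", shQuote(out), "--quiet"),
                 stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(file.path(out, "synthetic_cohort.csv")))
  res2 <- system2("Rscript",
                  c(script, "search", "--input",
                    shQuote(file.path(out, "synthetic_cohort.csv")),
                    "--x", "X", "--y", "Y", "--mode", "divisive",
                    "--no-outlier-screen",
                    "--out-dir", shQuote(out), "--quiet"),
                  stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(file.path(out, "membership.txt")))
})
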