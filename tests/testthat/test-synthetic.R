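test_that("generated cohorts have the specified composition", {
  spec <- syntheticSpec(nBackground = 50,
                        clusters = data.frame(size = c(30, 20),
                                              beta0 = c(0, 5),
                                              beta1 = c(1, -2),
                                              xmin = -1, xmax = 1,
                                              noiseSd = c(0, 0.1)),
                        outlierCount = 5, missingFrac = 0.05, seed = 3)
  co <- generateCohort(spec)
  expect_equal(nSubjects(co$table), 105L)
  counts <- table(co$truth$label)
  expect_equal(unname(counts[c("background", "cluster1", "cluster2",
                               "outlier")]),
               c(50L, 30L, 20L, 5L), ignore_attr = TRUE)
  # zero-noise cluster members are exactly collinear (where observed)
  v <- measurements(co$table)
  m <- co$truth$label == "cluster1"
  ok <- m & !is.na(v[, "X"]) & !is.na(v[, "Y"])
  expect_equal(max(abs(v[ok, "Y"] - (0 + 1 * v[ok, "X"]))), 0,
               tolerance = 1e-12)
})

test_that("generation is deterministic and leaves the RNG state alone", {
  spec <- syntheticSpec(nBackground = 40, seed = 9, missingFrac = 0.1)
  set.seed(1); before <- runif(1)
  set.seed(1)
  a <- generateCohort(spec)
  after <- runif(1)
  b <- generateCohort(spec)
  expect_identical(measurements(a$table), measurements(b$table))
  expect_identical(a$truth, b$truth)
  expect_identical(before, after)  # caller's stream undisturbed
})

test_that("planted clusters reach their nominal tightness across seeds", {
  rins <- vapply(1:20, function(s) {
    co <- plantedCohort(seed = s)
    v <- measurements(co$table)
    m <- co$truth$label == "cluster1"
    cor(v[m, "X"], v[m, "Y"])
  }, numeric(1))
  expect_true(all(rins >= 0.99))
})

test_that("background correlation lands near its target for large n", {
  rbg <- vapply(1:10, function(s) {
    co <- generateCohort(syntheticSpec(nBackground = 1000,
                                       backgroundR = 0.2, seed = s))
    v <- measurements(co$table)
    cor(v[, "X"], v[, "Y"])
  }, numeric(1))
  expect_true(all(abs(rbg - 0.2) < 0.1))
  expect_equal(mean(rbg), 0.2, tolerance = 0.15)
})

test_that("missingness fraction is honoured on average", {
  fracs <- vapply(1:10, function(s) {
    co <- generateCohort(syntheticSpec(nBackground = 200,
                                       missingFrac = 0.1, seed = s))
    mean(is.na(measurements(co$table)))
  }, numeric(1))
  expect_equal(mean(fracs), 0.1, tolerance = 0.02)
})

test_that("the synthetic reference cohort reproduces its calibrated marginals", {
  ref <- syntheticReferenceCohort(seed = 11)
  t <- ref$table
  v <- measurements(t)
  # assay availability pattern: CoQ 447, CS 448, CIII 305; pairwise overlaps
  expect_equal(sum(!is.na(v[, "CoQ"])), 447L)
  expect_equal(sum(!is.na(v[, "CS"])), 448L)
  expect_equal(sum(!is.na(v[, "CIII"])), 305L)
  expect_equal(nSubjects(pairwiseComplete(t, "CoQ", "CS")), 447L)
  expect_equal(nSubjects(pairwiseComplete(t, "CoQ", "CIII")), 304L)
  expect_equal(nSubjects(pairwiseComplete(t, "CS", "CIII")), 305L)
  # calibrated marginal moments (exact up to the assay floor)
  s <- summaryTable(t)
  expect_equal(s$mean[s$variable == "CoQ"], 185, tolerance = 0.005)
  expect_equal(s$sd[s$variable == "CoQ"], 114, tolerance = 0.01)
  expect_equal(s$mean[s$variable == "CS"], 132, tolerance = 0.005)
  expect_equal(s$mean[s$variable == "CIII"], 75, tolerance = 0.05)
  expect_true(all(v >= 0, na.rm = TRUE))
  # planted subpopulations have the documented sizes and tightness
  cs <- ref$truth$subject[ref$truth$cs_cluster]
  expect_length(cs, 214L)
  m <- match(cs, rownames(v))
  expect_gt(cor(v[m, "CoQ"], v[m, "CS"]), 0.98)
  c3 <- ref$truth$subject[ref$truth$ciii_cluster]
  expect_length(c3, 126L)
  expect_true(all(c3 %in% cs))
  # deterministic in the seed
  again <- syntheticReferenceCohort(seed = 11)
  expect_identical(measurements(again$table), v)
})
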