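test_that("a single exact line is recovered with zero residuals", {
  x <- seq(0, 5, length.out = 25)
  pr <- makePair(x, 2 + 3 * x)
  sol <- robustLinearClusters(pr, k = 1, trim = 0, seed = 1, restarts = 5)
  ax <- axes(sol)[[1]]
  expect_equal(ax@beta0, 2, tolerance = 1e-9)
  expect_equal(ax@beta1, 3, tolerance = 1e-9)
  expect_equal(max(abs(ax@residuals)), 0, tolerance = 1e-9)
  expect_length(sol@unassignedIDs, 0L)
})

test_that("k=1, trim=0 degenerates to ordinary least squares", {
  set.seed(21)
  x <- rnorm(40); y <- 1.5 - 0.7 * x + rnorm(40, sd = 0.5)
  sol <- robustLinearClusters(makePair(x, y), k = 1, trim = 0, seed = 3,
                              restarts = 3)
  fit <- lm(y ~ x)
  expect_equal(axes(sol)[[1]]@beta0, unname(coef(fit)[1]), tolerance = 1e-9)
  expect_equal(axes(sol)[[1]]@beta1, unname(coef(fit)[2]), tolerance = 1e-9)
})

test_that("two noiseless planted lines are recovered exactly", {
  x <- seq(0, 10, length.out = 50)
  pr <- makePair(c(x, x), c(x, -x + 10),
                 ids = c(sprintf("a%02d", 1:50), sprintf("b%02d", 1:50)))
  sol <- robustLinearClusters(pr, k = 2, trim = 0, seed = 5, restarts = 40)
  mems <- lapply(axes(sol), memberIDs)
  planted <- list(sprintf("a%02d", 1:50), sprintf("b%02d", 1:50))
  # membership must match the planted partition up to the shared point
  # x = 5 (on both lines); allow it on either axis
  shared <- c("a25", "b25")  # nearest to the crossing
  matched <- all(vapply(planted, function(p) {
    any(vapply(mems, function(m) {
      length(setdiff(setdiff(p, shared), m)) == 0
    }, logical(1)))
  }, logical(1)))
  expect_true(matched)
  slopes <- sort(vapply(axes(sol), slot, numeric(1), "beta1"))
  expect_equal(slopes, c(-1, 1), tolerance = 1e-6)
})

test_that("the objective trace is non-increasing", {
  set.seed(9)
  x <- c(rnorm(60), seq(-2, 2, length.out = 40))
  y <- c(rnorm(60), 1 + 2 * seq(-2, 2, length.out = 40) +
           rnorm(40, sd = 0.05))
  sol <- robustLinearClusters(makePair(x, y), k = 2, trim = 0.1, seed = 2,
                              restarts = 10)
  expect_true(all(diff(sol@objectiveTrace) <= 1e-9))
  expect_equal(sol@objective, sol@objectiveTrace[length(sol@objectiveTrace)])
})

test_that("planted members are recovered under modest noise across seeds", {
  hits <- vapply(1:20, function(seed) {
    set.seed(seed + 100)
    x <- runif(60, 0, 10)
    y1 <- 2 + 1 * x[1:30] + rnorm(30, sd = 0.15)
    y2 <- 30 - 2 * x[31:60] + rnorm(30, sd = 0.15)
    pr <- makePair(x, c(y1, y2),
                   ids = c(sprintf("p%02d", 1:30), sprintf("q%02d", 1:30)))
    sol <- robustLinearClusters(pr, k = 2, trim = 0, seed = seed,
                                restarts = 30)
    mems <- lapply(axes(sol), memberIDs)
    best <- max(vapply(mems, function(m) {
      sum(startsWith(m, "p")) / 30
    }, numeric(1)))
    best
  }, numeric(1))
  expect_gte(mean(hits), 0.95)
})

test_that("seedTriple picks the three smallest residuals, ties by id", {
  # collinear members: all residuals zero, tie-break on ascending id
  x <- 1:5
  pr <- makePair(x, 2 * x, ids = c("e", "d", "c", "b", "a"))
  sol <- robustLinearClusters(pr, k = 1, trim = 0, seed = 1, restarts = 2)
  expect_identical(sort(memberIDs(seedTriple(axes(sol)[[1]], pr))),
                   c("a", "b", "c"))
  # explicit residual ordering
  ax <- new("LinearAxis", beta0 = 0, beta1 = 0,
            memberIDs = c("v", "w", "x", "y", "z"),
            x = rep(0, 5), y = c(0.5, 0.1, 0.9, 0.2, 0.3),
            residuals = c(0.5, 0.1, 0.9, 0.2, 0.3))
  pr2 <- makePair(rep(0, 5), c(0.5, 0.1, 0.9, 0.2, 0.3),
                  ids = c("v", "w", "x", "y", "z"))
  expect_identical(sort(memberIDs(seedTriple(ax, pr2))), c("w", "y", "z"))
  # exactly three members: identity
  ax3 <- new("LinearAxis", beta0 = 0, beta1 = 1, memberIDs = c("a", "b", "c"),
             x = 1:3, y = 1:3, residuals = rep(0, 3))
  expect_identical(sort(memberIDs(seedTriple(ax3, makePair(1:3, 1:3,
                                                           ids = c("a", "b", "c"))))),
                   c("a", "b", "c"))
  ax2 <- new("LinearAxis", beta0 = 0, beta1 = 1, memberIDs = c("a", "b"),
             x = 1:2, y = 1:2, residuals = rep(0, 2))
  expect_error(seedTriple(ax2, makePair(1:2, 1:2, ids = c("a", "b"))),
               "fewer than 3")
})

test_that("identical seeds reproduce identical solutions", {
  set.seed(33)
  pr <- makePair(rnorm(50), rnorm(50))
  s1 <- robustLinearClusters(pr, k = 2, trim = 0.1, seed = 42, restarts = 10)
  s2 <- robustLinearClusters(pr, k = 2, trim = 0.1, seed = 42, restarts = 10)
  expect_identical(lapply(axes(s1), memberIDs), lapply(axes(s2), memberIDs))
  expect_identical(s1@objective, s2@objective)
})
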