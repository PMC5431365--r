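# Independent oracles and fixture builders shared by the suite.
# Oracles deliberately avoid the package's incremental-sums engine: they use
# the naive two-pass Pearson formula or stats::cor on materialized subsets.

makePair <- function(x, y, ids = NULL, xName = "X", yName = "Y") {
  ids <- ids %||% sprintf("s%02d", seq_along(x))
  new("VariablePair", xName = xName, yName = yName,
      subjects = as.character(ids), x = as.numeric(x), y = as.numeric(y))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# naive two-pass Pearson formula, written directly from the definition
naivePearson <- function(x, y) {
  xb <- mean(x); yb <- mean(y)
  sum((x - xb) * (y - yb)) / sqrt(sum((x - xb)^2) * sum((y - yb)^2))
}

# direct-formula correlation loss: rho(M) - rho(M + {i})
naiveCLM <- function(pair, memberIds, candidateId) {
  m <- match(memberIds, pair@subjects)
  ci <- match(candidateId, pair@subjects)
  naivePearson(pair@x[m], pair@y[m]) -
    naivePearson(pair@x[c(m, ci)], pair@y[c(m, ci)])
}

# direct-formula correlation gain: rho(M - {i}) - rho(M)
naiveCGM <- function(pair, memberIds, candidateId) {
  m <- match(memberIds, pair@subjects)
  keep <- m[memberIds != candidateId]
  naivePearson(pair@x[keep], pair@y[keep]) -
    naivePearson(pair@x[m], pair@y[m])
}

# random instance with a loose linear trend plus scatter; ids shuffled so
# identifier order differs from coordinate order
randomInstance <- function(n, seed) {
  set.seed(seed)
  x <- rnorm(n)
  y <- 0.5 * x + rnorm(n)
  ids <- sample(sprintf("r%03d", seq_len(n)))
  makePair(x, y, ids = ids)
}

# planted-subpopulation cohort used by the recovery checks: members along a
# line with weak background scatter around them
plantedCohort <- function(seed, nPlanted = 100L, nBackground = 100L,
                          noiseSd = 0.04) {
  spec <- syntheticSpec(
    nBackground = nBackground, backgroundR = 0.2,
    clusters = data.frame(size = nPlanted, beta0 = 0.5, beta1 = 1.5,
                          xmin = -2, xmax = 2, noiseSd = noiseSd),
    seed = seed)
  generateCohort(spec)
}
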