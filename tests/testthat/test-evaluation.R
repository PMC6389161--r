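test_that("ROC AUC matches the pairwise Mann-Whitney oracle", {
  expect_equal(rocAUC(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(rocAUC(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0)), 0)
  expect_error(rocAUC(runif(5), rep(1, 5)), "both classes")
  set.seed(51)
  for (i in 1:20) {
    scores <- sample(round(runif(50), 2))  # ties included
    labels <- rbinom(50, 1, 0.5)
    if (length(unique(labels)) < 2) next
    expect_equal(rocAUC(scores, labels), bruteForceAUC(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("negating tie-free scores complements the AUC", {
  set.seed(52)
  scores <- rnorm(60)
  labels <- rbinom(60, 1, 0.4)
  expect_equal(rocAUC(scores, labels) + rocAUC(-scores, labels), 1,
               tolerance = 1e-12)
})

test_that("MCC matches its closed form and symmetries", {
  expect_equal(mcc(50, 0, 50, 0), 1)
  expect_equal(mcc(25, 25, 25, 25), 0)
  expect_equal(mcc(40, 20, 30, 10), 1000 / sqrt(60 * 50 * 50 * 40),
               tolerance = 1e-12)
  expect_equal(mcc(0, 5, 0, 5), -1)  # complete disagreement
  expect_equal(mcc(0, 0, 50, 50), 0)  # empty marginal convention
  set.seed(53)
  for (i in 1:20) {
    cc <- rpois(4, 20) + 1
    m <- mcc(cc[1], cc[2], cc[3], cc[4])
    expect_equal(m, mcc(cc[3], cc[4], cc[1], cc[2]), tolerance = 1e-12)
    # class-label flip swaps tp<->fn and tn<->fp, negating the coefficient
    expect_equal(mcc(cc[4], cc[3], cc[2], cc[1]), -m, tolerance = 1e-12)
  }
})

test_that("accuracy from counts", {
  expect_equal(accuracyFromCounts(75, 0, 25, 0), 1)
  expect_equal(accuracyFromCounts(0, 50, 0, 50), 0)
  expect_equal(accuracyFromCounts(30, 20, 30, 20), 0.6)
  expect_error(accuracyFromCounts(0, 0, 0, 0), "empty")
})

test_that("bootstrap subsampling is seeded, consistent, and degenerate-safe", {
  set.seed(54)
  n <- 200
  labels <- rbinom(n, 1, 0.5)
  scores <- labels + rnorm(n, sd = 0.7)
  r1 <- bootstrapEvaluate(scores, labels, nBootstrap = 50, seed = 9)
  r2 <- bootstrapEvaluate(scores, labels, nBootstrap = 50, seed = 9)
  expect_identical(r1$replicates, r2$replicates)
  r3 <- bootstrapEvaluate(scores, labels, nBootstrap = 50, seed = 10)
  expect_false(identical(r1$replicates, r3$replicates))
  # bootstrap mean AUC close to the full-sample AUC
  full <- rocAUC(scores, labels)
  auc_row <- r1$summary[r1$summary$metric == "auc", ]
  expect_lt(abs(auc_row$mean - full), 3 * max(auc_row$sd, 1e-3))
  # perfectly separated scores: AUC constant across replicates
  sep <- bootstrapEvaluate(labels * 2 - 1, labels, nBootstrap = 20, seed = 1)
  expect_equal(sep$summary$sd[sep$summary$metric == "auc"], 0)
})

test_that("paired t-test matches the textbook formula", {
  b <- rep(0, 4)
  a <- c(1, 2, 3, 4)
  res <- pairedTTest(a, b)
  d <- a - b
  t_oracle <- mean(d) / (sd(d) / sqrt(4))
  expect_equal(res$statistic, t_oracle, tolerance = 1e-12)
  expect_equal(res$statistic, 3.873, tolerance = 1e-3)
  expect_equal(res$p.value, 2 * pt(-abs(t_oracle), df = 3),
               tolerance = 1e-12)
  expect_equal(res$p.value, 0.030466, tolerance = 1e-4)
  swapped <- pairedTTest(b, a)
  expect_equal(swapped$statistic, -res$statistic)
  expect_equal(swapped$p.value, res$p.value)
  expect_error(pairedTTest(a, a), "zero variance")
})

test_that("Anderson-Darling check: nonnegative, powered, roughly calibrated", {
  set.seed(55)
  res <- andersonDarlingNormal(rnorm(1000))
  expect_gte(res$statistic, 0)
  bimodal <- c(rnorm(250, -4), rnorm(250, 4))
  expect_true(andersonDarlingNormal(bimodal)$reject)
  expect_error(andersonDarlingNormal(rnorm(5)), "at least 8")
  # type-I rate near alpha over repeated normal samples
  rejects <- vapply(1:200, function(i)
    andersonDarlingNormal(rnorm(100))$reject, logical(1))
  expect_lt(abs(mean(rejects) - 0.05), 0.05)
})

test_that("Pearson correlation: limits and direct-formula oracle", {
  x <- rnorm(30)
  expect_equal(pearsonCorrelation(x, x), 1)
  expect_equal(pearsonCorrelation(x, -x), -1)
  expect_error(pearsonCorrelation(rep(1, 10), x[1:10]), "constant")
  set.seed(56)
  for (i in 1:10) {
    a <- rnorm(25)
    b <- rnorm(25)
    expect_equal(pearsonCorrelation(a, b), bruteForcePearson(a, b),
                 tolerance = 1e-12)
  }
})

test_that("evaluation tables export one row per outcome and metric", {
  set.seed(57)
  labels <- rbinom(100, 1, 0.5)
  scores <- labels + rnorm(100)
  reports <- list(MF = bootstrapEvaluate(scores, labels, 10, seed = 1),
                  CR = bootstrapEvaluate(scores, labels, 10, seed = 2))
  path <- tempfile(fileext = ".tsv")
  writeEvaluationTable(reports, path)
  tab <- read.delim(path)
  expect_equal(nrow(tab), 6L)
  expect_setequal(unique(tab$outcome), c("MF", "CR"))
})
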