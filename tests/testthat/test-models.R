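test_that("a near-separating feature yields near-0/1 training propensities", {
  set.seed(41)
  n <- 1000
  y <- rbinom(n, 1, 0.5)
  x <- matrix(y + rnorm(n, sd = 0.05), ncol = 1)
  m <- suppressMessages(trainOutcomeModel(x, y))
  p <- predictPropensity(m, x)
  expect_true(all(p[y == 1] >= 0.9))
  expect_true(all(p[y == 0] <= 0.1))
})

test_that("labels independent of features give a null model", {
  set.seed(42)
  n <- 2000
  X <- matrix(rnorm(n * 3), n, 3)
  y <- rbinom(n, 1, 0.3)
  m <- trainOutcomeModel(X, y)
  expect_true(all(abs(m@weights) < 0.1))
  p <- predictPropensity(m, X)
  expect_equal(mean(p), 0.3, tolerance = 0.03)
})

test_that("the IRLS fit agrees with glm on the standardized scale", {
  set.seed(43)
  n <- 500
  X <- matrix(rnorm(n * 4), n, 4)
  y <- rbinom(n, 1, plogis(X[, 1] - 0.5 * X[, 3]))
  m <- trainOutcomeModel(X, y)
  Z <- scale(X)
  ref <- glm(y ~ Z, family = binomial,
             control = glm.control(epsilon = 1e-12))
  # glm standardizes with the same sample sd, so coefficients are comparable
  expect_equal(unname(m@weights),
               unname(coef(ref)[-1]) * apply(Z, 2, sd), tolerance = 1e-6)
  expect_equal(unname(m@intercept), unname(coef(ref)[1]), tolerance = 1e-6)
})

test_that("separated data trigger a ridge-stabilized fit, not an explosion", {
  y <- rep(c(0, 1), each = 25)
  x <- matrix(seq_len(50), ncol = 1)  # perfectly separable
  expect_message(m <- trainOutcomeModel(x, y), "separation")
  expect_true(m@ridged)
  expect_true(all(is.finite(m@weights)))
  p <- predictPropensity(m, x)
  expect_gt(rocAUC(p, y), 0.99)
})

test_that("propensity prediction follows the sigmoid contract", {
  m <- constantModel("MF", 0.5)
  expect_equal(unname(predictPropensity(m, matrix(3.7))), 0.5)
  # a positively weighted feature strictly increases the output
  m2 <- new("OutcomeModel", outcome = "PF", featureIndices = 1L,
            featureNamesUsed = "f1", weights = 1.5, intercept = 0,
            center = 0, scale = 1, confidence = c(0.2, 0.8), ridged = FALSE)
  grid <- matrix(seq(-3, 3, length.out = 7), ncol = 1)
  p <- predictPropensity(m2, grid)
  expect_true(all(diff(p) > 0))
  expect_true(all(p > 0 & p < 1))
  expect_error(predictPropensity(m2, matrix(NaN)), "f1")
})

test_that("confidence tiers split at the 20th/80th training percentiles", {
  props <- seq(0.01, 1.00, by = 0.01)
  thr <- unname(quantile(props, c(0.2, 0.8), type = 7))
  m <- new("OutcomeModel", outcome = "CR", featureIndices = 1L,
           featureNamesUsed = "f1", weights = 0, intercept = 0,
           center = 0, scale = 1, confidence = thr, ridged = FALSE)
  expect_equal(assignConfidence(m, 0.10), "low")
  expect_equal(assignConfidence(m, 0.50), "medium")
  expect_equal(assignConfidence(m, 0.95), "high")
  # boundary values are medium (strict inequalities)
  expect_equal(assignConfidence(m, thr[1]), "medium")
  expect_equal(assignConfidence(m, thr[2]), "medium")
  # degenerate calibration: identical thresholds make everything medium
  md <- new("OutcomeModel", outcome = "CR", featureIndices = 1L,
            featureNamesUsed = "f1", weights = 0, intercept = 0,
            center = 0, scale = 1, confidence = c(0.5, 0.5), ridged = FALSE)
  expect_equal(assignConfidence(md, 0.5), "medium")
  expect_equal(assignConfidence(md, 0.49), "low")
})

test_that("training-set propensities reproduce the calibration exactly", {
  set.seed(44)
  n <- 400
  X <- matrix(rnorm(n * 2), n, 2)
  y <- rbinom(n, 1, plogis(X[, 1]))
  m <- trainOutcomeModel(X, y)
  p <- predictPropensity(m, X)
  expect_equal(unname(quantile(p, c(0.2, 0.8), type = 7)), m@confidence,
               tolerance = 1e-15)
})

test_that("the overall call is the argmax with later-stage tie-breaking", {
  mk <- function(oc, p) constantModel(oc, p)
  set1 <- new("OutcomeModelSet", models = list(
    MF = mk("MF", 0.1), PF = mk("PF", 0.2),
    CF = mk("CF", 0.3), CR = mk("CR", 0.9)), selection = list())
  feats <- matrix(0, 1, 1, dimnames = list("q", "f1"))
  rep1 <- predictOutcomes(set1, feats)
  expect_equal(rep1$overall, "CR")
  set2 <- new("OutcomeModelSet", models = list(
    MF = mk("MF", 0.4), PF = mk("PF", 0.4),
    CF = mk("CF", 0.1), CR = mk("CR", 0.1)), selection = list())
  rep2 <- predictOutcomes(set2, feats)
  expect_equal(rep2$overall, "PF")  # tie resolved toward the later stage
  expect_length(grep("^p_", colnames(rep2)), 4L)
  expect_length(grep("^conf_", colnames(rep2)), 4L)
})

test_that("a model bundle round-trips through its plain-text format", {
  set.seed(45)
  d <- syntheticProteinSet(c(MF = 15, PF = 15, CF = 15, CR = 15),
                           effectSize = 0.6, seed = 46)
  feats <- extractFeatures(d$sequences)
  set <- suppressMessages(
    trainOutcomeModels(feats, d$labels$outcome, seed = 5, minRetained = 3L))
  dir <- tempfile()
  writeModelBundle(set, dir)
  back <- readModelBundle(dir)
  p1 <- predictOutcomes(set, feats)
  p2 <- predictOutcomes(back, feats)
  expect_equal(p1, p2, tolerance = 1e-14)
  expect_error(readModelBundle(tempfile()), "MANIFEST")
})
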