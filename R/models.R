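# Logistic outcome models: IRLS fit on standardized features, percentile
# confidence calibration, per-protein prediction reports.

# iteratively reweighted least squares for binary logistic regression;
# X1 carries the intercept column first.  ridge penalizes the non-intercept
# coefficients on the standardized scale.
.irls <- function(X1, y, ridge = 0, tol = 1e-8, maxit = 100L) {
  p <- ncol(X1)
  beta <- numeric(p)
  pen <- diag(c(0, rep(ridge, p - 1L)), p)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- drop(X1 %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    A <- crossprod(X1, X1 * w) + pen
    bnew <- tryCatch(drop(solve(A, crossprod(X1, w * z))),
                     error = function(e) NULL)
    if (is.null(bnew)) break
    delta <- max(abs(bnew - beta))
    beta <- bnew
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  list(beta = beta, converged = converged)
}

# standardize + fit; falls back to a tiny ridge when the data are
# (quasi-)separated, signalled by non-convergence or diverging coefficients
.fitStandardizedLogistic <- function(X, y) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  center <- colMeans(X)
  scale <- apply(X, 2L, stats::sd)
  scale[scale == 0 | !is.finite(scale)] <- 1
  Z <- sweep(sweep(X, 2L, center), 2L, scale, "/")
  X1 <- cbind(1, Z)
  fit <- .irls(X1, y)
  ridged <- FALSE
  if (!fit$converged || max(abs(fit$beta[-1L])) > 30) {
    fit <- .irls(X1, y, ridge = 1e-4)
    ridged <- TRUE
  }
  list(intercept = fit$beta[1L], weights = fit$beta[-1L],
       center = center, scale = scale, ridged = ridged)
}

.predictStandardizedLogistic <- function(fit, X) {
  Z <- sweep(sweep(as.matrix(X), 2L, fit$center), 2L, fit$scale, "/")
  stats::plogis(drop(fit$intercept + Z %*% fit$weights))
}

#' Train one logistic outcome model
#'
#' Standardizes the features to zero mean / unit variance (constant features
#' keep scale 1), fits a maximum-likelihood logistic regression by
#' iteratively reweighted least squares (convergence when the largest
#' coefficient change drops below 1e-8, at most 100 iterations; separated
#' data trigger a ridge-stabilized refit with penalty 1e-4 on the
#' standardized weights), and calibrates the confidence tiers as the
#' empirical 20th and 80th percentiles of the fitted training propensities
#' (linear-interpolation percentile definition).
#'
#' @param X n x k numeric feature matrix (column names become the model's
#'   feature names).
#' @param y binary labels (logical or 0/1), both classes present.
#' @param outcome outcome tag, e.g. one of [outcomeLevels()].
#' @param featureIndices catalog indices of the columns of \code{X}
#'   (defaults to 1..k for standalone fits).
#' @return An [OutcomeModel-class].
#' @export
trainOutcomeModel <- function(X, y, outcome = "outcome",
                              featureIndices = seq_len(ncol(as.matrix(X)))) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (length(unique(y)) < 2L) stop("training labels contain a single class")
  if (anyNA(X)) stop("feature matrix contains missing values")
  stopifnot(ncol(X) >= 1L, length(featureIndices) == ncol(X))
  fit <- .fitStandardizedLogistic(X, y)
  if (fit$ridged)
    message("outcome ", outcome,
            ": separation detected, using ridge-stabilized fit")
  prop <- .predictStandardizedLogistic(fit, X)
  conf <- unname(stats::quantile(prop, c(0.2, 0.8), type = 7))
  nms <- colnames(X)
  if (is.null(nms)) nms <- paste0("f", featureIndices)
  new("OutcomeModel", outcome = outcome,
      featureIndices = as.integer(featureIndices),
      featureNamesUsed = nms,
      weights = unname(fit$weights), intercept = unname(fit$intercept),
      center = unname(fit$center), scale = unname(fit$scale),
      confidence = conf, ridged = fit$ridged)
}

#' Propensity of one outcome for new proteins
#'
#' \code{sigmoid(intercept + sum w_j z_j)} on the model's standardized
#' feature scale.
#'
#' @param model an [OutcomeModel-class].
#' @param x either a full-catalog feature matrix/vector (columns are looked
#'   up by the model's \code{featureIndices}) or a matrix/vector with
#'   exactly the model's k features.
#' @return Numeric propensities in (0, 1), one per row.
#' @export
predictPropensity <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L,
                                   dimnames = list(NULL, names(x)))
  k <- length(model@weights)
  if (ncol(x) != k) {
    if (max(model@featureIndices) > ncol(x))
      stop("feature matrix has ", ncol(x),
           " columns; model expects catalog index up to ",
           max(model@featureIndices))
    x <- x[, model@featureIndices, drop = FALSE]
  }
  bad <- which(!is.finite(x), arr.ind = TRUE)
  if (nrow(bad <- as.matrix(bad)) > 0L)
    stop("non-finite value in feature '",
         model@featureNamesUsed[bad[1L, 2L]], "'")
  fit <- list(intercept = model@intercept, weights = model@weights,
              center = model@center, scale = model@scale)
  .predictStandardizedLogistic(fit, x)
}

#' Confidence tier of a propensity
#'
#' \code{low} when the propensity is strictly below the model's 20th
#' training percentile, \code{high} strictly above the 80th, otherwise
#' \code{medium} (values exactly at a threshold are medium).
#'
#' @param model an [OutcomeModel-class].
#' @param propensity numeric vector of propensities.
#' @return Character vector over \code{c("low", "medium", "high")}.
#' @export
assignConfidence <- function(model, propensity) {
  ifelse(propensity < model@confidence[1L], "low",
         ifelse(propensity > model@confidence[2L], "high", "medium"))
}

#' Train the four outcome models with per-outcome feature selection
#'
#' For each outcome in [outcomeLevels()], forms the one-vs-rest binary label,
#' runs the three-stage selection ([selectFeatures()]) and fits the logistic
#' model on the selected subset.  Sub-seeds are derived deterministically
#' from \code{seed}.
#'
#' @param features n x 1276 feature matrix from [extractFeatures()].
#' @param labels character/factor vector of outcome labels over
#'   [outcomeLevels()], one per row.
#' @param seed integer master seed for fold assignment.
#' @param cvFolds,relevanceMultiplier,redundancyThreshold,minRetained
#'   selection parameters, see [selectFeatures()].
#' @return An [OutcomeModelSet-class].
#' @export
trainOutcomeModels <- function(features, labels, seed = 1L, cvFolds = 5L,
                               relevanceMultiplier = 2,
                               redundancyThreshold = 0.7, minRetained = 10L) {
  labels <- as.character(labels)
  stopifnot(nrow(features) == length(labels))
  if (!all(labels %in% outcomeLevels()))
    stop("labels must be in {", paste(outcomeLevels(), collapse = ", "), "}")
  models <- list()
  selections <- list()
  for (i in seq_along(outcomeLevels())) {
    oc <- outcomeLevels()[i]
    y <- as.numeric(labels == oc)
    if (length(unique(y)) < 2L)
      stop("outcome ", oc, " is absent (or universal) in the training labels")
    sel <- selectFeatures(features, y, outcome = oc,
                          relevanceMultiplier = relevanceMultiplier,
                          redundancyThreshold = redundancyThreshold,
                          cvFolds = cvFolds, minRetained = minRetained,
                          seed = seed + i)
    models[[oc]] <- trainOutcomeModel(
      features[, sel@selected, drop = FALSE], y, outcome = oc,
      featureIndices = sel@selected)
    selections[[oc]] <- sel
  }
  new("OutcomeModelSet", models = models, selection = selections)
}

#' Predict all four outcomes for a batch of proteins
#'
#' Extracts the features once, applies the four models, sets the overall
#' call to the outcome with the highest propensity (ties broken toward the
#' later pipeline stage), and assigns the four confidence tiers.
#'
#' @param modelSet an [OutcomeModelSet-class].
#' @param x a [ProteinBatch-class], [Biostrings::AAStringSet-class], named
#'   character vector of sequences, or a precomputed full-catalog feature
#'   matrix.
#' @param catalog the [FeatureCatalog-class] used at training time.
#' @return data.frame with columns \code{id}, \code{p_MF}..\code{p_CR},
#'   \code{overall}, \code{conf_MF}..\code{conf_CR}.
#' @export
predictOutcomes <- function(modelSet, x, catalog = featureCatalog()) {
  stopifnot(is(modelSet, "OutcomeModelSet"))
  feats <- if (is.matrix(x)) x else extractFeatures(x, catalog)
  ids <- rownames(feats)
  if (is.null(ids)) ids <- paste0("seq", seq_len(nrow(feats)))
  P <- sapply(outcomeLevels(), function(oc)
    predictPropensity(modelSet[[oc]], feats))
  P <- matrix(P, ncol = 4L, dimnames = list(ids, outcomeLevels()))
  overall <- apply(P, 1L, function(p)
    outcomeLevels()[max(which(p == max(p)))])
  out <- data.frame(id = ids, stringsAsFactors = FALSE)
  for (oc in outcomeLevels()) out[[paste0("p_", oc)]] <- unname(P[, oc])
  out$overall <- unname(overall)
  for (oc in outcomeLevels())
    out[[paste0("conf_", oc)]] <-
      unname(assignConfidence(modelSet[[oc]], P[, oc]))
  rownames(out) <- NULL
  out
}

.fmt <- function(x) sprintf("%.17g", x)

#' Write / read a plain-text model bundle
#'
#' Serializes an [OutcomeModelSet-class] as one versioned text file per
#' outcome plus a manifest, so a trained bundle is portable and diffable.
#'
#' @param modelSet an [OutcomeModelSet-class].
#' @param dir bundle directory (created if needed).
#' @return Invisibly, the directory.
#' @export
writeModelBundle <- function(modelSet, dir) {
  stopifnot(is(modelSet, "OutcomeModelSet"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(c("crystalprop-model-bundle", "version: 1",
               paste0("outcomes: ", paste(outcomeLevels(), collapse = ","))),
             file.path(dir, "MANIFEST"))
  for (oc in outcomeLevels()) {
    m <- modelSet[[oc]]
    con <- file(file.path(dir, paste0(oc, ".model.txt")), "w")
    writeLines(c(paste0("outcome: ", m@outcome),
                 paste0("intercept: ", .fmt(m@intercept)),
                 paste0("conf_low: ", .fmt(m@confidence[1L])),
                 paste0("conf_high: ", .fmt(m@confidence[2L])),
                 paste0("ridged: ", as.integer(m@ridged)),
                 "index\tname\tcenter\tscale\tweight"), con)
    writeLines(paste(m@featureIndices, m@featureNamesUsed, .fmt(m@center),
                     .fmt(m@scale), .fmt(m@weights), sep = "\t"), con)
    close(con)
  }
  invisible(dir)
}

#' @rdname writeModelBundle
#' @return \code{readModelBundle} returns the [OutcomeModelSet-class].
#' @export
readModelBundle <- function(dir) {
  man <- file.path(dir, "MANIFEST")
  if (!file.exists(man)) stop("not a model bundle (no MANIFEST): ", dir)
  models <- list()
  for (oc in outcomeLevels()) {
    lines <- readLines(file.path(dir, paste0(oc, ".model.txt")))
    kv <- function(key) sub(paste0("^", key, ": "), "",
                            grep(paste0("^", key, ": "), lines, value = TRUE))
    tab <- utils::read.delim(text = lines[-(1:5)], stringsAsFactors = FALSE)
    models[[oc]] <- new("OutcomeModel", outcome = kv("outcome"),
      featureIndices = as.integer(tab$index),
      featureNamesUsed = as.character(tab$name),
      weights = as.numeric(tab$weight),
      intercept = as.numeric(kv("intercept")),
      center = as.numeric(tab$center), scale = as.numeric(tab$scale),
      confidence = c(as.numeric(kv("conf_low")), as.numeric(kv("conf_high"))),
      ridged = as.logical(as.integer(kv("ridged"))))
  }
  new("OutcomeModelSet", models = models, selection = list())
}
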