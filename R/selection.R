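# Per-outcome feature selection: biserial relevance filter, Pearson
# redundancy pruning, greedy forward wrapper maximizing cross-validated AUC.

#' Point-biserial correlation
#'
#' Correlation between a continuous feature and a binary (0/1) label,
#' computed as the Pearson correlation against the 0/1 vector.  A constant
#' feature returns 0 by convention.
#'
#' @param x numeric feature values.
#' @param y binary labels (logical or 0/1), both classes present.
#' @return A value in [-1, 1].
#' @export
#' @examples
#' pointBiserial(c(1, 2, 3, 4), c(0, 0, 1, 1))
pointBiserial <- function(x, y) {
  y <- as.numeric(y)
  if (length(x) != length(y) || length(x) < 2L)
    stop("x and y must have equal length >= 2")
  if (length(unique(y)) < 2L)
    stop("correlation with a single-class label is undefined")
  if (stats::sd(x) == 0) return(0)
  stats::cor(x, y)
}

# |point-biserial| for every column; constant columns get 0
.biserialAll <- function(X, y) {
  y <- as.numeric(y)
  r <- suppressWarnings(as.vector(stats::cor(X, y)))
  r[!is.finite(r)] <- 0
  abs(r)
}

#' Relevance filter on absolute biserial correlation
#'
#' Keeps feature j iff |r_j| >= \code{relevanceMultiplier} times the mean
#' absolute point-biserial correlation over all features.  If fewer than
#' \code{minRetained} features survive (the rule can empty the set when
#' correlations are homogeneous), the top \code{min(minRetained, p)}
#' features by |r| are kept instead.
#'
#' @param X n x p numeric feature matrix.
#' @param y binary labels.
#' @param relevanceMultiplier multiplier on the mean |r| (default 2).
#' @param minRetained fallback size (default 10).
#' @return Integer feature indices in ascending order, with the ranking by
#'   |r| attached as attribute \code{"relevance"} (per-feature |r| vector
#'   over all p features).
#' @export
relevanceFilter <- function(X, y, relevanceMultiplier = 2, minRetained = 10L) {
  stopifnot(relevanceMultiplier > 0, ncol(X) >= 1L)
  if (length(unique(as.numeric(y))) < 2L)
    stop("relevance filter needs both label classes")
  r <- .biserialAll(X, y)
  keep <- which(r >= relevanceMultiplier * mean(r))
  if (length(keep) < minRetained)
    keep <- sort(order(-r, seq_along(r))[seq_len(min(minRetained, ncol(X)))])
  structure(keep, relevance = r)
}

#' Redundancy pruning at a Pearson correlation cap
#'
#' Scans the surviving features in descending relevance (|r|; ties broken by
#' catalog order) and accepts a feature iff its absolute Pearson correlation
#' with every already-accepted feature is at most \code{threshold}, so the
#' more relevant member of a correlated pair is kept.
#'
#' @param X n x p feature matrix.
#' @param survivors integer indices to prune.
#' @param relevance per-feature |r| over all p features.
#' @param threshold Pearson cap (default 0.7).
#' @return Integer indices in descending-relevance order (the wrapper's
#'   candidate ranking).
#' @export
redundancyFilter <- function(X, survivors, relevance, threshold = 0.7) {
  stopifnot(length(survivors) >= 1L, threshold > 0, threshold <= 1)
  ord <- survivors[order(-relevance[survivors], survivors)]
  accepted <- ord[1L]
  for (j in ord[-1L]) {
    cors <- suppressWarnings(
      abs(as.vector(stats::cor(X[, j], X[, accepted, drop = FALSE]))))
    cors[!is.finite(cors)] <- 0
    if (all(cors <= threshold)) accepted <- c(accepted, j)
  }
  accepted
}

# stratified k-fold assignment; retry shifts the seed deterministically
.stratifiedFolds <- function(y, k, seed, retry = 0L) {
  y <- as.integer(as.numeric(y) > 0)
  fold <- integer(length(y))
  set.seed(seed + 104729L * retry)
  for (cls in c(0L, 1L)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# mean out-of-fold AUC of a logistic fit on the given feature columns
.cvAUC <- function(X, y, cols, folds) {
  k <- max(folds)
  aucs <- numeric(0)
  for (f in seq_len(k)) {
    tr <- folds != f
    if (length(unique(y[tr])) < 2L || length(unique(y[!tr])) < 2L)
      return(NA_real_)
    fit <- .fitStandardizedLogistic(X[tr, cols, drop = FALSE], y[tr])
    sc <- .predictStandardizedLogistic(fit, X[!tr, cols, drop = FALSE])
    aucs <- c(aucs, rocAUC(sc, y[!tr]))
  }
  mean(aucs)
}

#' Greedy forward wrapper selection by cross-validated AUC
#'
#' Initializes the selected set with the top-ranked candidate, then scans
#' the remaining candidates once in rank order; each candidate is accepted
#' iff adding it strictly improves the mean AUC of a logistic regression
#' under stratified k-fold cross-validation (fold assignment seeded by
#' \code{seed}).  Ties reject, biasing toward smaller subsets.
#'
#' @param X n x p feature matrix.
#' @param y binary labels.
#' @param candidates integer indices ranked by descending relevance.
#' @param cvFolds number of folds (default 5).
#' @param seed fold-assignment seed.
#' @param outcome tag stored in the result.
#' @return A [SelectionResult-class] with the full audit trace (the
#'   relevance/redundancy slots are set to the candidate set when the
#'   wrapper is called standalone).
#' @export
wrapperSelect <- function(X, y, candidates, cvFolds = 5L, seed = 1L,
                          outcome = "outcome") {
  stopifnot(length(candidates) >= 1L, cvFolds >= 2L)
  folds <- .stratifiedFolds(y, cvFolds, seed)
  retry <- 0L
  repeat {
    auc0 <- .cvAUC(X, y, candidates[1L], folds)
    if (!is.na(auc0) || retry >= 5L) break
    retry <- retry + 1L
    folds <- .stratifiedFolds(y, cvFolds, seed, retry)
  }
  if (is.na(auc0))
    stop("could not form cross-validation folds with both classes")
  selected <- candidates[1L]
  trace <- data.frame(candidate = candidates[1L], auc_before = NA_real_,
                      auc_after = auc0, accepted = TRUE)
  cur <- auc0
  for (j in candidates[-1L]) {
    auc_new <- .cvAUC(X, y, c(selected, j), folds)
    ok <- !is.na(auc_new) && auc_new > cur
    trace <- rbind(trace, data.frame(candidate = j, auc_before = cur,
                                     auc_after = auc_new, accepted = ok))
    if (ok) {
      selected <- c(selected, j)
      cur <- auc_new
    }
  }
  new("SelectionResult", outcome = outcome,
      relevanceSurvivors = as.integer(sort(candidates)),
      redundancySurvivors = as.integer(candidates),
      selected = as.integer(selected), trace = trace)
}

#' Full three-stage feature selection for one outcome
#'
#' Runs [relevanceFilter()], [redundancyFilter()] and [wrapperSelect()] in
#' sequence and returns the combined [SelectionResult-class].  With a fixed
#' seed the whole pipeline is deterministic.
#'
#' @inheritParams wrapperSelect
#' @param relevanceMultiplier,minRetained see [relevanceFilter()].
#' @param redundancyThreshold see [redundancyFilter()].
#' @return A [SelectionResult-class].
#' @export
selectFeatures <- function(X, y, outcome = "outcome",
                           relevanceMultiplier = 2, redundancyThreshold = 0.7,
                           cvFolds = 5L, minRetained = 10L, seed = 1L) {
  rel <- relevanceFilter(X, y, relevanceMultiplier, minRetained)
  r <- attr(rel, "relevance")
  red <- redundancyFilter(X, rel, r, redundancyThreshold)
  res <- wrapperSelect(X, y, red, cvFolds, seed, outcome)
  res@relevanceSurvivors <- as.integer(sort(rel))
  methods::validObject(res)
  res
}

#' Serialize a selection trace to a text report
#'
#' One line per wrapper step for auditing which candidates were tried, the
#' AUC before and after, and whether they were accepted.
#'
#' @param result a [SelectionResult-class].
#' @param path output path.
#' @return Invisibly, the path.
#' @export
writeSelectionReport <- function(result, path) {
  hdr <- c(paste0("# outcome: ", result@outcome),
           paste0("# relevance survivors: ",
                  length(result@relevanceSurvivors)),
           paste0("# redundancy survivors: ",
                  length(result@redundancySurvivors)),
           paste0("# selected: ", paste(result@selected, collapse = ",")))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(result@trace, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
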