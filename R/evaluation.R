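# Evaluation protocol: ROC AUC, MCC, accuracy, bootstrap subsampling with
# mean +/- sd, paired t-test, Anderson-Darling normality check, Pearson
# correlation of score vectors.

#' Area under the ROC curve
#'
#' Computed via midranks as the Mann-Whitney statistic:
#' (concordant pairs + 0.5 * tied pairs) / (n_pos * n_neg).
#'
#' @param scores numeric scores, higher = more positive.
#' @param labels binary labels (logical or 0/1), both classes present.
#' @return AUC in [0, 1].
#' @export
#' @examples
#' rocAUC(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
rocAUC <- function(scores, labels) {
  y <- as.numeric(labels)
  stopifnot(length(scores) == length(y))
  npos <- sum(y == 1)
  nneg <- sum(y == 0)
  if (npos == 0L || nneg == 0L)
    stop("AUC needs both classes present")
  r <- rank(scores)
  (sum(r[y == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Matthews correlation coefficient
#'
#' \code{(tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))}; 0 when any
#' marginal of the confusion table is empty.
#'
#' @param tp,fp,tn,fn non-negative confusion counts.
#' @return MCC in [-1, 1].
#' @export
mcc <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

#' Classification accuracy from confusion counts
#'
#' @inheritParams mcc
#' @return \code{(tp + tn) / (tp + fp + tn + fn)}.
#' @export
accuracyFromCounts <- function(tp, fp, tn, fn) {
  total <- tp + fp + tn + fn
  if (total == 0) stop("empty confusion table")
  (tp + tn) / total
}

#' Confusion counts at a decision threshold
#'
#' @param scores numeric scores.
#' @param labels binary labels.
#' @param threshold scores >= threshold are called positive (default 0.5).
#' @return Named numeric vector \code{c(tp, fp, tn, fn)}.
#' @export
confusionCounts <- function(scores, labels, threshold = 0.5) {
  y <- as.numeric(labels)
  pred <- as.numeric(scores >= threshold)
  c(tp = sum(pred == 1 & y == 1), fp = sum(pred == 1 & y == 0),
    tn = sum(pred == 0 & y == 0), fn = sum(pred == 0 & y == 1))
}

#' Bootstrap evaluation on random subsets
#'
#' Draws \code{nBootstrap} subsets of size \code{round(fraction * n)}
#' without replacement (subsampling), recomputes AUC and, at the decision
#' threshold, MCC and accuracy on each subset, and reports their mean and
#' standard deviation.  Subsets containing a single class are redrawn
#' (at most 100 retries per replicate).
#'
#' @param scores numeric scores.
#' @param labels binary labels, both classes present.
#' @param nBootstrap number of replicates (default 100).
#' @param fraction subset fraction (default 0.25).
#' @param threshold decision threshold for MCC/accuracy (default 0.5).
#' @param seed RNG seed; the whole report is reproducible given the seed.
#' @return List with \code{summary} (data.frame metric/mean/sd) and
#'   \code{replicates} (nBootstrap x 3 matrix of auc, mcc, accuracy).
#' @export
bootstrapEvaluate <- function(scores, labels, nBootstrap = 100L,
                              fraction = 0.25, threshold = 0.5, seed = 1L) {
  y <- as.numeric(labels)
  n <- length(scores)
  stopifnot(length(y) == n, fraction > 0, fraction <= 1, nBootstrap >= 1L)
  if (length(unique(y)) < 2L) stop("labels contain a single class")
  m <- max(2L, round(fraction * n))
  set.seed(seed)
  reps <- matrix(NA_real_, nBootstrap, 3L,
                 dimnames = list(NULL, c("auc", "mcc", "accuracy")))
  for (b in seq_len(nBootstrap)) {
    for (try in seq_len(100L)) {
      idx <- sample.int(n, m)
      if (length(unique(y[idx])) == 2L) break
      if (try == 100L)
        stop("could not draw a two-class subset at fraction ", fraction)
    }
    cc <- confusionCounts(scores[idx], y[idx], threshold)
    reps[b, ] <- c(rocAUC(scores[idx], y[idx]),
                   mcc(cc["tp"], cc["fp"], cc["tn"], cc["fn"]),
                   accuracyFromCounts(cc["tp"], cc["fp"], cc["tn"], cc["fn"]))
  }
  summary <- data.frame(metric = colnames(reps),
                        mean = colMeans(reps),
                        sd = apply(reps, 2L, stats::sd),
                        row.names = NULL)
  list(summary = summary, replicates = reps)
}

#' Paired t-test
#'
#' Classical paired t on the differences, df = n - 1, two-sided.
#'
#' @param a,b equal-length numeric vectors (n >= 2).
#' @return List with \code{statistic} and \code{p.value}.
#' @export
pairedTTest <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2L)
  d <- a - b
  if (stats::sd(d) == 0)
    stop("paired t-test is degenerate: differences have zero variance")
  ht <- stats::t.test(a, b, paired = TRUE)
  list(statistic = unname(ht$statistic), p.value = ht$p.value)
}

#' Anderson-Darling normality check
#'
#' A-squared statistic against the normal family with estimated mean and
#' variance (small-sample corrected); the rejection decision compares the
#' test's p-value with \code{alpha}.
#'
#' @param sample numeric vector, n >= 8.
#' @param alpha significance level (default 0.05).
#' @return List with \code{statistic}, \code{p.value} and \code{reject}.
#' @export
andersonDarlingNormal <- function(sample, alpha = 0.05) {
  if (length(sample) < 8L)
    stop("Anderson-Darling check needs at least 8 observations")
  ht <- nortest::ad.test(sample)
  list(statistic = unname(ht$statistic), p.value = ht$p.value,
       reject = ht$p.value < alpha)
}

#' Pearson correlation of two score vectors
#'
#' @param x,y equal-length numeric vectors, both non-constant.
#' @return Product-moment correlation in [-1, 1].
#' @export
pearsonCorrelation <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation of a constant vector is undefined")
  stats::cor(x, y)
}

#' Export a per-outcome bootstrap evaluation table
#'
#' Writes a TSV with one row per outcome x metric: mean, sd, and (when two
#' score sets are compared) the paired t-test p-value.
#'
#' @param reports named list (by outcome) of [bootstrapEvaluate()] results.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
writeEvaluationTable <- function(reports, path) {
  rows <- do.call(rbind, lapply(names(reports), function(oc) {
    s <- reports[[oc]]$summary
    cbind(outcome = oc, s)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
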