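# Shared fixtures and independent oracles used across the suite.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

randSeq <- function(L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(AA20, L, replace = TRUE), collapse = "")
}

writeTempFasta <- function(records) {
  path <- tempfile(fileext = ".fasta")
  lines <- unlist(lapply(names(records), function(id)
    c(paste0(">", id), records[[id]])))
  writeLines(lines, path)
  path
}

# brute-force pairwise AUC: (concordant + 0.5 * tied) / (npos * nneg)
bruteForceAUC <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# direct-formula Pearson correlation (no call into stats::cor)
bruteForcePearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# columns with an exact prescribed sample correlation matrix: center and
# orthonormalize a random basis, then impose the Cholesky factor
exactCorColumns <- function(n, R, seed = 1) {
  set.seed(seed)
  k <- nrow(R)
  Z <- matrix(rnorm(n * k), n, k)
  Z <- scale(Z, center = TRUE, scale = FALSE)
  Q <- qr.Q(qr(Z))
  Q %*% chol(R)
}

# tiny trained model with prescribed constant propensity (no features used)
constantModel <- function(outcome, propensity) {
  new("OutcomeModel", outcome = outcome, featureIndices = 1L,
      featureNamesUsed = "f1", weights = 0, intercept = qlogis(propensity),
      center = 0, scale = 1, confidence = c(0.2, 0.8), ridged = FALSE)
}
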