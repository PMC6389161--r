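# Synthetic data: labeled sequence sets with class-dependent compositional
# structure, and feature tables with a known logistic generative model.
# These make the full pipeline (extraction -> selection -> training ->
# evaluation) testable without any external dataset.

# Fixed per-class composition direction vectors (sum zero).  Loosely
# motivated by published crystallization-propensity residue trends: CR
# enriched in small/ordered residues, MF in hydrophobic/aromatic, PF in
# charged, CF in repeat-prone residues.  No claim of realism; they exist to
# make the four outcomes learnable in a controlled way.
.classDirections <- function() {
  up <- list(MF = c("F", "W", "Y", "L", "I", "V", "M"),
             PF = c("D", "E", "K", "R"),
             CF = c("Q", "N", "S", "G"),
             CR = c("A", "G", "S", "T", "D"))
  out <- sapply(up, function(res) {
    d <- numeric(20L)
    d[match(res, .AA20)] <- 0.10
    d - mean(d)
  })
  rownames(out) <- .AA20
  out
}

#' Generate a labeled synthetic protein set
#'
#' Draws each sequence residue-by-residue from a class-specific residue
#' composition: the uniform composition (1/20 per residue) perturbed by
#' \code{effectSize} along a fixed per-class direction vector.  Negative
#' probabilities arising at extreme effect sizes are clipped to zero and the
#' composition renormalized (with a message).  Sequence lengths follow a
#' log-normal distribution (median \code{medianLength}, dispersion
#' \code{sdlog}) clipped to [30, 2000], so every generated sequence passes
#' validation.  Fully reproducible given \code{seed}.
#'
#' @param nPerClass named integer vector of sequence counts per outcome
#'   (names in [outcomeLevels()]); at least two positive classes.
#' @param effectSize non-negative scale of the class-specific composition
#'   shift; 0 means all classes share the uniform composition.
#' @param medianLength median sequence length in residues (default 300).
#' @param sdlog log-scale dispersion of the length distribution
#'   (default 0.45).
#' @param seed RNG seed.
#' @return List with \code{sequences} (a named
#'   [Biostrings::AAStringSet-class]) and \code{labels} (data.frame
#'   \code{id}, \code{outcome}).
#' @export
#' @examples
#' d <- syntheticProteinSet(c(MF = 5, PF = 5, CF = 5, CR = 5),
#'                          effectSize = 0.3, seed = 7)
#' table(d$labels$outcome)
syntheticProteinSet <- function(nPerClass, effectSize = 0.3,
                                medianLength = 300, sdlog = 0.45,
                                seed = 1L) {
  stopifnot(effectSize >= 0, all(nPerClass >= 0))
  if (is.null(names(nPerClass)))
    names(nPerClass) <- outcomeLevels()[seq_along(nPerClass)]
  stopifnot(all(names(nPerClass) %in% outcomeLevels()))
  if (sum(nPerClass > 0) < 2L)
    stop("need at least two classes with positive counts")
  dirs <- .classDirections()
  set.seed(seed)
  seqs <- character(0)
  ids <- character(0)
  outcomes <- character(0)
  for (oc in outcomeLevels()) {
    n <- if (oc %in% names(nPerClass)) nPerClass[[oc]] else 0L
    if (n == 0L) next
    p <- 1 / 20 + effectSize * dirs[, oc]
    if (any(p < 0)) {
      message("effect size ", effectSize,
              " drives probabilities negative for ", oc,
              "; clipping and renormalizing")
      p <- pmax(p, 0)
    }
    p <- p / sum(p)
    lens <- pmin(pmax(round(stats::rlnorm(n, log(medianLength), sdlog)),
                      30L), 2000L)
    cls_seqs <- vapply(lens, function(L)
      paste(sample(.AA20, L, replace = TRUE, prob = p), collapse = ""),
      character(1))
    seqs <- c(seqs, cls_seqs)
    ids <- c(ids, sprintf("%s_%04d", oc, seq_len(n)))
    outcomes <- c(outcomes, rep(oc, n))
  }
  ss <- Biostrings::AAStringSet(seqs)
  names(ss) <- ids
  list(sequences = ss,
       labels = data.frame(id = ids, outcome = outcomes,
                           stringsAsFactors = FALSE))
}

#' Generate a feature table with a known logistic generative model
#'
#' The first \code{kInformative} columns are standard normal and enter a
#' logistic label model with the given weights (zero intercept); the
#' remaining columns are independent standard-normal noise.  Used for
#' selection-recovery and parameter-recovery checks.
#'
#' @param n number of rows.
#' @param p number of columns.
#' @param kInformative number of informative columns (<= p).
#' @param weights numeric weights of length \code{kInformative}.
#' @param seed RNG seed.
#' @return List with \code{x} (n x p matrix), \code{labels} (0/1 vector) and
#'   \code{informative} (the informative column indices).
#' @export
syntheticFeatureTable <- function(n, p, kInformative, weights, seed = 1L) {
  stopifnot(kInformative <= p, length(weights) == kInformative)
  set.seed(seed)
  x <- matrix(stats::rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  eta <- if (kInformative > 0L)
    drop(x[, seq_len(kInformative), drop = FALSE] %*% weights) else
    numeric(n)
  labels <- stats::rbinom(n, 1L, stats::plogis(eta))
  list(x = x, labels = labels, informative = seq_len(kInformative))
}
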