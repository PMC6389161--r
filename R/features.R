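# Feature extraction: a validated sequence -> the ordered 1276-feature
# vector.  Five groups: AAC 420 (20 residues + 400 dipeptides), CLUSTER 336
# (7 properties x 48 grouped C/T/D + segment statistics), AAPHYS 448 (64
# residue indices x 7 windowed summaries), PROTPHYS 4 (pI, aliphatic index,
# instability index, net charge), CXDIS 68 (34-number profile summary of the
# disorder score and of the low-complexity mask).

.asSeqChar <- function(x) {
  if (is(x, "AAString") || is(x, "AAStringSet")) x <- as.character(x)
  if (!is.character(x) || length(x) != 1L)
    stop("expected a single sequence")
  toupper(x)
}

.seqCodes <- function(sequence) {
  codes <- match(strsplit(sequence, "")[[1]], .AA20)
  if (anyNA(codes))
    stop("sequence contains non-standard residues")
  codes
}

# min and max of means over all contiguous windows of length min(w, L)
.windowMinMax <- function(v, w) {
  L <- length(v)
  w <- min(w, L)
  cs <- c(0, cumsum(v))
  means <- (cs[(w + 1L):(L + 1L)] - cs[1L:(L - w + 1L)]) / w
  c(min(means), max(means))
}

#' Amino-acid composition (20 features)
#'
#' Fraction of each of the 20 standard residues, in alphabetical one-letter
#' order; the values sum to 1.
#'
#' @param sequence a validated sequence (character scalar or
#'   [Biostrings::AAString-class]).
#' @return Named numeric vector of length 20.
#' @export
#' @examples
#' aaComposition(strrep("A", 40))[["AAC.A"]]
aaComposition <- function(sequence) {
  codes <- .seqCodes(.asSeqChar(sequence))
  out <- tabulate(codes, 20L) / length(codes)
  names(out) <- paste0("AAC.", .AA20)
  out
}

#' Dipeptide composition (400 features)
#'
#' Frequency of each ordered residue pair among the L - 1 adjacent pairs;
#' ordered by first residue (alphabetical), then second.  Sums to 1.
#'
#' @inheritParams aaComposition
#' @return Named numeric vector of length 400.
#' @export
dipeptideComposition <- function(sequence) {
  codes <- .seqCodes(.asSeqChar(sequence))
  L <- length(codes)
  if (L < 2L) stop("dipeptide composition needs at least 2 residues")
  idx <- (codes[-L] - 1L) * 20L + codes[-1L]
  out <- tabulate(idx, 400L) / (L - 1L)
  names(out) <- paste0("DPC.", rep(.AA20, each = 20L), rep(.AA20, 20L))
  out
}

.ctdNames <- function(prop) {
  key <- paste0("ctdnames.", prop)
  if (is.null(.pkg_cache[[key]]))
    .pkg_cache[[key]] <- paste0("CTD.", prop, ".", c(
      paste0("comp.c", 1:3),
      c("trans.c1c2", "trans.c1c3", "trans.c2c3"),
      paste0("dist.c", rep(1:3, each = 5L), ".",
             rep(c("first", "q25", "q50", "q75", "last"), 3L)),
      paste0("seg.c", rep(1:3, each = 9L), ".",
             rep(c("count", "longest", "shortest", "meanlen", "coverage",
                   "ge2", "ge3", "first", "last"), 3L))))
  .pkg_cache[[key]]
}

# 48 features for one three-class property alphabet
.ctdOne <- function(cls, L, prop) {
  comp <- tabulate(cls, 3L) / L
  a <- cls[-L]; b <- cls[-1L]
  trans <- c(sum((a == 1L & b == 2L) | (a == 2L & b == 1L)),
             sum((a == 1L & b == 3L) | (a == 3L & b == 1L)),
             sum((a == 2L & b == 3L) | (a == 3L & b == 2L))) /
    max(L - 1L, 1L)
  dist <- numeric(15L)
  seg <- numeric(27L)
  for (k in 1:3) {
    pos <- which(cls == k)
    n <- length(pos)
    if (n > 0L) {
      qpos <- pos[pmax(1L, ceiling(c(0.25, 0.5, 0.75) * n))]
      dist[(k - 1L) * 5L + 1:5] <- c(pos[1L], qpos, pos[n]) / L
      r <- rle(cls == k)
      lens <- r$lengths[r$values]
      seg[(k - 1L) * 9L + 1:9] <- c(
        length(lens) / L, max(lens) / L, min(lens) / L, mean(lens) / L,
        n / L, sum(lens >= 2L) / L, sum(lens >= 3L) / L,
        pos[1L] / L, pos[n] / L)
    }
  }
  stats::setNames(c(comp, trans, dist, seg), .ctdNames(prop))
}

# residue (1..20) -> class (1..3) lookup per property, cached for the
# default alphabets
.ctdClassMaps <- function(alphabets) {
  if (identical(alphabets, .PROPERTY_ALPHABETS) &&
      !is.null(.pkg_cache$clsmaps)) return(.pkg_cache$clsmaps)
  maps <- lapply(seq_along(alphabets), function(i) {
    alpha <- alphabets[[i]]
    .checkAlphabet(alpha, names(alphabets)[i])
    clsmap <- integer(20L)
    for (k in 1:3) clsmap[match(alpha[[k]], .AA20)] <- k
    clsmap
  })
  names(maps) <- names(alphabets)
  if (identical(alphabets, .PROPERTY_ALPHABETS)) .pkg_cache$clsmaps <- maps
  maps
}

#' Grouped composition/transition/distribution features (336)
#'
#' Recodes the sequence into three classes under each of the seven
#' physicochemical property alphabets and computes, per property (48
#' features): class composition (3), normalized transition frequencies
#' between unordered class pairs (3), distribution of the 1st/25\%/50\%/
#' 75\%/100\% occurrence of each class as a fraction of the length (15, 0
#' for an absent class), and nine segment statistics per class (27): run
#' count / L, longest, shortest and mean run / L, residue coverage, runs of
#' length >= 2 and >= 3 / L, and first/last occurrence / L.
#'
#' @inheritParams aaComposition
#' @param alphabets list of 7 three-class alphabets, see
#'   [propertyAlphabets()].
#' @return Named numeric vector of length 336.
#' @export
ctdFeatures <- function(sequence, alphabets = propertyAlphabets()) {
  codes <- .seqCodes(.asSeqChar(sequence))
  L <- length(codes)
  maps <- .ctdClassMaps(alphabets)
  out <- vector("list", length(alphabets))
  for (i in seq_along(alphabets))
    out[[i]] <- .ctdOne(maps[[i]][codes], L, names(alphabets)[i])
  unlist(out)
}

#' Windowed residue-index features (448)
#'
#' For each of the 64 bundled residue index tables: the whole-sequence mean
#' of the per-residue values, and for each window length in \code{windows}
#' (clipped to the sequence length) the minimum and maximum of the means
#' over all contiguous windows.
#'
#' @inheritParams aaComposition
#' @param tables 20 x m numeric matrix of per-residue scales (rows in
#'   alphabetical one-letter order), default the bundled 64.
#' @param windows integer window lengths; default \code{c(5, 15, 31)}.
#' @return Named numeric vector of length \code{7 * ncol(tables)} (448 for
#'   the bundled tables).
#' @export
aaindexFeatures <- function(sequence, tables = residueIndexTables(),
                            windows = c(5L, 15L, 31L)) {
  codes <- .seqCodes(.asSeqChar(sequence))
  if (nrow(tables) != 20L || anyNA(tables))
    stop("each index table must map all 20 residues to finite values")
  L <- length(codes)
  V <- tables[codes, , drop = FALSE]            # L x m profile matrix
  m <- ncol(tables)
  cs <- rbind(0, apply(V, 2L, cumsum))          # (L+1) x m
  out <- matrix(0, nrow = 1L + 2L * length(windows), ncol = m)
  out[1L, ] <- cs[L + 1L, ] / L
  for (wi in seq_along(windows)) {
    w <- min(windows[wi], L)
    wm <- (cs[(w + 1L):(L + 1L), , drop = FALSE] -
           cs[1L:(L - w + 1L), , drop = FALSE]) / w
    out[2L * wi, ]      <- apply(wm, 2L, min)
    out[2L * wi + 1L, ] <- apply(wm, 2L, max)
  }
  stat <- c("mean", paste0(rep(c("min", "max"), length(windows)), ".w",
                           rep(windows, each = 2L)))
  v <- as.vector(out)  # column-major: the 7 stats of an index stay contiguous
  key <- paste0("aaidxnames.", paste(windows, collapse = "."), ".",
                paste(colnames(tables), collapse = ""))
  if (is.null(.pkg_cache[[key]]))
    .pkg_cache[[key]] <- paste0(
      "AAIDX.", rep(colnames(tables), each = length(stat)), ".",
      rep(stat, m))
  names(v) <- .pkg_cache[[key]]
  v
}

.netChargeFromCounts <- function(counts, pH, pka = titrationPKa()) {
  pos <- c("Nterm", "H", "K", "R")
  neg <- c("Cterm", "C", "D", "E", "Y")
  sum(counts[pos] / (1 + 10^(pH - pka[pos]))) -
    sum(counts[neg] / (1 + 10^(pka[neg] - pH)))
}

#' Whole-chain physicochemical indices (4 features)
#'
#' Isoelectric point (bisection on pH 0..14 of the Henderson-Hasselbalch
#' net charge, tolerance 1e-3), aliphatic index
#' (mole\% A + 2.9 mole\% V + 3.9 (mole\% I + mole\% L)), instability index
#' ((10 / L) sum of dipeptide instability weights over adjacent pairs), and
#' net charge at pH 7 (elementary charges, free termini included).
#'
#' @inheritParams aaComposition
#' @return Named numeric vector \code{c(PHYS.pI, PHYS.aliphatic,
#'   PHYS.instability, PHYS.charge)}.
#' @export
#' @examples
#' globalPhyschem(strrep("A", 40))[["PHYS.aliphatic"]]  # 100
globalPhyschem <- function(sequence) {
  sequence <- .asSeqChar(sequence)
  codes <- .seqCodes(sequence)
  L <- length(codes)
  cnt <- tabulate(codes, 20L)
  names(cnt) <- .AA20
  molepct <- 100 * cnt / L

  aliphatic <- molepct[["A"]] + 2.9 * molepct[["V"]] +
    3.9 * (molepct[["I"]] + molepct[["L"]])

  diwv <- dipeptideInstabilityTable()
  instability <- if (L >= 2L)
    10 / L * sum(diwv[cbind(codes[-L], codes[-1L])]) else 0

  counts <- c(Nterm = 1, Cterm = 1, cnt[c("C", "D", "E", "H", "K", "R", "Y")])
  charge7 <- .netChargeFromCounts(counts, 7.0)

  lo <- 0; hi <- 14
  qlo <- .netChargeFromCounts(counts, lo)   # > 0
  while (hi - lo > 1e-3) {
    mid <- (lo + hi) / 2
    if (.netChargeFromCounts(counts, mid) > 0) lo <- mid else hi <- mid
  }
  pI <- (lo + hi) / 2

  c(PHYS.pI = pI, PHYS.aliphatic = unname(aliphatic),
    PHYS.instability = instability, PHYS.charge = charge7)
}

#' Built-in per-residue disorder propensity
#'
#' A deterministic windowed hydropathy-charge score in [0, 1]: residues in
#' windows that are depleted in hydropathy and enriched in charged residues
#' (D, E, K, R) score high, the classical signature of intrinsic disorder.
#' The score for residue i is \code{clamp(0.5 - 0.5 h_i + 0.5 c_i)} where
#' h_i is the windowed Kyte-Doolittle mean rescaled to [0, 1] and c_i the
#' windowed fraction of charged residues.  An externally computed score can
#' be supplied instead via \code{scoreFile} (two whitespace-separated
#' columns: position, score), used verbatim after clipping to [0, 1].
#'
#' @inheritParams aaComposition
#' @param window centred smoothing window (default 21), truncated at the
#'   chain ends.
#' @param scoreFile optional path to a per-residue score file overriding the
#'   built-in score; must have exactly one row per residue.
#' @return Numeric vector, one value in [0, 1] per residue.
#' @export
disorderProfile <- function(sequence, window = 21L, scoreFile = NULL) {
  sequence <- .asSeqChar(sequence)
  codes <- .seqCodes(sequence)
  L <- length(codes)
  if (!is.null(scoreFile)) {
    tab <- utils::read.table(scoreFile)
    if (nrow(tab) != L)
      stop("score file has ", nrow(tab), " rows but the sequence has ",
           L, " residues")
    return(pmin(1, pmax(0, as.numeric(tab[[2L]]))))
  }
  kd <- .KD_HYDROPATHY[.AA20][codes]
  chg <- as.numeric(.AA20[codes] %in% c("D", "E", "K", "R"))
  half <- (min(window, L) - 1L) %/% 2L
  cs_kd <- c(0, cumsum(kd)); cs_ch <- c(0, cumsum(chg))
  i <- seq_len(L)
  lo <- pmax(i - half, 1L); hi <- pmin(i + half, L)
  n <- hi - lo + 1L
  hmean <- (cs_kd[hi + 1L] - cs_kd[lo]) / n
  cmean <- (cs_ch[hi + 1L] - cs_ch[lo]) / n
  hnorm <- (hmean + 4.5) / 9
  pmin(1, pmax(0, 0.5 - 0.5 * hnorm + 0.5 * cmean))
}

#' Low-complexity residue mask
#'
#' Marks a residue as low-complexity when the Shannon entropy (bits) of the
#' residue composition of at least one window covering it falls below the
#' threshold.  A window longer than the sequence degrades to a single
#' whole-sequence window.
#'
#' @inheritParams aaComposition
#' @param window window length in residues (default 12).
#' @param entropyThreshold threshold in bits (default 2.2).
#' @return Integer 0/1 vector, one value per residue (1 = low-complexity).
#' @export
lowComplexityMask <- function(sequence, window = 12L,
                              entropyThreshold = 2.2) {
  codes <- .seqCodes(.asSeqChar(sequence))
  L <- length(codes)
  w <- min(window, L)
  nwin <- L - w + 1L
  ent <- numeric(nwin)
  cnt <- tabulate(codes[seq_len(w)], 20L)
  entOf <- function(cnt) {
    p <- cnt[cnt > 0L] / w
    -sum(p * log2(p))
  }
  ent[1L] <- entOf(cnt)
  if (nwin > 1L) for (s in 2:nwin) {
    cnt[codes[s - 1L]] <- cnt[codes[s - 1L]] - 1L
    cnt[codes[s + w - 1L]] <- cnt[codes[s + w - 1L]] + 1L
    ent[s] <- entOf(cnt)
  }
  low <- which(ent < entropyThreshold)
  mask <- integer(L)
  for (s in low) mask[s:(s + w - 1L)] <- 1L
  mask
}

.PROFILE_STAT_NAMES <- c(
  "mean", "median", "sd", "min", "max",
  "min.w5", "max.w5", "min.w15", "max.w15", "min.w31", "max.w31",
  "frac.above",
  paste0(rep(c("runcount", "longest", "meanlen", "coverage"), 3L), ".m",
         rep(c(1L, 4L, 10L), each = 4L)),
  "pos.first", "pos.q25", "pos.q50", "pos.q75", "pos.last",
  "crossings", "mean.first30", "mean.last30", "mean.above", "mean.below")

#' 34-number summary of a per-residue signal
#'
#' Collapses a per-residue signal in [0, 1] (e.g. a disorder propensity
#' profile or a 0/1 low-complexity mask) into 34 fixed-order statistics:
#' mean/median/sd/min/max (5); min and max of window means for windows 5,
#' 15, 31 (6); fraction of residues above 0.5 (1); for minimum run lengths
#' 1, 4 and 10 over the thresholded (> 0.5) signal the run count / L,
#' longest run / L, mean run length / L and coverage (12); positions of the
#' 1st/25\%/50\%/75\%/last above-threshold residue / L, 0 if none (5);
#' threshold crossings / L (1); mean over the first and last 30 residues
#' (2); mean of above- and of below-threshold values, 0 when empty (2).
#'
#' @param signal numeric vector of per-residue values in [0, 1].
#' @param prefix name prefix for the returned statistics.
#' @return Named numeric vector of length 34.
#' @export
profileSummary <- function(signal, prefix = "PROF") {
  L <- length(signal)
  stopifnot(L >= 1L, all(is.finite(signal)))
  sdv <- if (L > 1L) stats::sd(signal) else 0
  basic <- c(mean(signal), stats::median(signal), sdv,
             min(signal), max(signal))
  wins <- unlist(lapply(c(5L, 15L, 31L),
                        function(w) .windowMinMax(signal, w)))
  b <- signal > 0.5
  frac <- mean(b)
  runstats <- numeric(12L)
  r <- rle(b)
  lens <- r$lengths[r$values]
  for (mi in seq_along(c(1L, 4L, 10L))) {
    m <- c(1L, 4L, 10L)[mi]
    ok <- lens[lens >= m]
    if (length(ok))
      runstats[(mi - 1L) * 4L + 1:4] <-
        c(length(ok), max(ok), mean(ok), sum(ok)) / L
  }
  pos <- which(b)
  posstats <- numeric(5L)
  if (length(pos)) {
    n <- length(pos)
    q <- pos[pmax(1L, ceiling(c(0.25, 0.5, 0.75) * n))]
    posstats <- c(pos[1L], q, pos[n]) / L
  }
  crossings <- if (L > 1L) sum(b[-1L] != b[-L]) / L else 0
  edge <- c(mean(signal[seq_len(min(30L, L))]),
            mean(signal[seq.int(max(1L, L - 29L), L)]))
  ab <- if (any(b)) mean(signal[b]) else 0
  be <- if (any(!b)) mean(signal[!b]) else 0
  out <- c(basic, wins, frac, runstats, posstats, crossings, edge, ab, be)
  names(out) <- paste0(prefix, ".", .PROFILE_STAT_NAMES)
  out
}

#' Build the 1276-entry feature catalog
#'
#' @return A [FeatureCatalog-class]; construction asserts the group sizes
#'   420/336/448/4/68 and the total of 1276.
#' @export
#' @examples
#' length(featureCatalog())
featureCatalog <- function() {
  if (!is.null(.pkg_cache$catalog)) return(.pkg_cache$catalog)
  probe <- strrep(paste(.AA20, collapse = ""), 2L)
  nm_aac <- c(names(aaComposition(probe)), names(dipeptideComposition(probe)))
  nm_ctd <- names(ctdFeatures(probe))
  nm_idx <- names(aaindexFeatures(probe))
  nm_phys <- names(globalPhyschem(probe))
  nm_prof <- c(paste0("DIS.", .PROFILE_STAT_NAMES),
               paste0("LCR.", .PROFILE_STAT_NAMES))
  entries <- data.frame(
    name = c(nm_aac, nm_ctd, nm_idx, nm_phys, nm_prof),
    group = rep(names(.CATALOG_GROUP_SIZES), .CATALOG_GROUP_SIZES),
    stringsAsFactors = FALSE)
  cat <- new("FeatureCatalog", entries = entries)
  .pkg_cache$catalog <- cat
  cat
}

#' Export the feature catalog as a two-column text file
#'
#' @param catalog a [FeatureCatalog-class].
#' @param path output path (tab-separated: name, group).
#' @return Invisibly, the path.
#' @export
writeFeatureCatalog <- function(catalog = featureCatalog(), path) {
  utils::write.table(catalog@entries, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

.extractOne <- function(sequence, tables) {
  c(aaComposition(sequence),
    dipeptideComposition(sequence),
    ctdFeatures(sequence),
    aaindexFeatures(sequence, tables),
    globalPhyschem(sequence),
    profileSummary(disorderProfile(sequence), "DIS"),
    profileSummary(as.numeric(lowComplexityMask(sequence)), "LCR"))
}

#' Extract the full 1276-feature matrix for a batch
#'
#' Concatenates, in catalog order: amino-acid + dipeptide composition (420),
#' grouped C/T/D features (336), windowed residue-index features (448),
#' whole-chain physicochemical indices (4), and the 34-number summaries of
#' the disorder profile and the low-complexity mask (68).  Deterministic:
#' identical input gives identical output, independent of batch order.
#'
#' @param x a [ProteinBatch-class], [Biostrings::AAStringSet-class], or a
#'   named character vector of validated sequences.
#' @param catalog the [FeatureCatalog-class] to align to.
#' @return Numeric matrix, one row per protein (rownames = ids), 1276
#'   columns named per the catalog.
#' @export
extractFeatures <- function(x, catalog = featureCatalog()) {
  if (is(x, "ProteinBatch")) x <- proteinSequences(x)
  if (is(x, "AAStringSet")) {
    ids <- names(x)
    seqs <- as.character(x)
  } else {
    ids <- names(x)
    seqs <- as.character(x)
  }
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  tables <- residueIndexTables()
  out <- matrix(NA_real_, nrow = length(seqs), ncol = length(catalog),
                dimnames = list(ids, featureNames(catalog)))
  for (i in seq_along(seqs)) {
    v <- .extractOne(seqs[i], tables)
    if (length(v) != length(catalog))
      stop("extractor produced ", length(v), " features, expected ",
           length(catalog))
    out[i, ] <- v
  }
  stopifnot(all(is.finite(out)))
  out
}
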