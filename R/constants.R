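# Shared constant tables: residue alphabet, three-class physicochemical
# alphabets, titration pKa set, hydropathy scale, and loaders for the
# bundled plain-text tables (64 residue indices, dipeptide instability).

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Three-class partitions of the 20 residues for the grouped
# composition/transition/distribution features.  Standard groupings for the
# seven properties; each is asserted to be a disjoint cover of the alphabet.
.PROPERTY_ALPHABETS <- list(
  hydrophobicity = list(
    polar       = c("R", "K", "E", "D", "Q", "N"),
    neutral     = c("G", "A", "S", "T", "P", "H", "Y"),
    hydrophobic = c("C", "L", "V", "I", "M", "F", "W")),
  vdw_volume = list(
    small  = c("G", "A", "S", "T", "P", "D", "C"),
    medium = c("N", "V", "E", "Q", "I", "L"),
    large  = c("M", "H", "K", "F", "R", "Y", "W")),
  polarity = list(
    low    = c("L", "I", "F", "W", "C", "M", "V", "Y"),
    medium = c("P", "A", "T", "G", "S"),
    high   = c("H", "Q", "R", "K", "N", "E", "D")),
  polarizability = list(
    low    = c("G", "A", "S", "D", "T"),
    medium = c("C", "P", "N", "V", "E", "Q", "I", "L"),
    high   = c("K", "M", "H", "F", "R", "Y", "W")),
  charge = list(
    positive = c("K", "R"),
    neutral  = c("A", "N", "C", "Q", "G", "H", "I", "L", "M", "F",
                 "P", "S", "T", "W", "Y", "V"),
    negative = c("D", "E")),
  secondary_structure = list(
    helix  = c("E", "A", "L", "M", "Q", "K", "R", "H"),
    strand = c("V", "I", "Y", "C", "W", "F", "T"),
    coil   = c("G", "N", "P", "S", "D")),
  solvent_accessibility = list(
    buried       = c("A", "L", "F", "C", "G", "I", "V", "W"),
    exposed      = c("R", "K", "Q", "E", "N", "D"),
    intermediate = c("M", "S", "P", "T", "H", "Y")))

# Side-chain and terminal pKa values for the Henderson-Hasselbalch net
# charge and the bisection pI.
.PKA <- c(Nterm = 8.6, Cterm = 3.6, C = 8.5, D = 3.9, E = 4.1,
          H = 6.5, K = 10.8, R = 12.5, Y = 10.1)

# Kyte-Doolittle hydropathy, used by the built-in disorder score.
.KD_HYDROPATHY <- c(A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8,
                    G = -0.4, H = -3.2, I = 4.5, K = -3.9, L = 3.8,
                    M = 1.9, N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
                    S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3)

.pkg_cache <- new.env(parent = emptyenv())

#' Three-class physicochemical residue alphabets
#'
#' The seven property alphabets (hydrophobicity, van der Waals volume,
#' polarity, polarizability, charge, secondary structure, solvent
#' accessibility), each a partition of the 20 standard residues into three
#' disjoint covering classes.  These drive the 336 grouped
#' composition/transition/distribution features.
#'
#' @return Named list of 7 alphabets; each alphabet is a named list of 3
#'   character vectors.
#' @export
#' @examples
#' names(propertyAlphabets())
#' propertyAlphabets()$charge$positive
propertyAlphabets <- function() .PROPERTY_ALPHABETS

.checkAlphabet <- function(alpha, name = "alphabet") {
  all_aa <- sort(unlist(alpha, use.names = FALSE))
  if (length(alpha) != 3L || length(all_aa) != 20L ||
      !identical(all_aa, .AA20))
    stop(name, " must partition the 20 standard residues into 3 classes")
  invisible(TRUE)
}

#' Bundled residue index tables
#'
#' The 64 hydrophobicity- and energy-themed per-residue numeric scales
#' (AAindex accessions) shipped with the package as a plain-text table; they
#' feed the 448 windowed residue-index features.
#'
#' @return A 20 x 64 numeric matrix; rows are residues in alphabetical
#'   one-letter order, columns are index accessions.
#' @export
residueIndexTables <- function() {
  if (is.null(.pkg_cache$aaidx)) {
    path <- system.file("extdata", "aaindex_hydro_energy64.tsv",
                        package = "crystalprop", mustWork = TRUE)
    tab <- utils::read.delim(path, check.names = FALSE)
    m <- t(as.matrix(tab[, .AA20]))
    colnames(m) <- tab$accession
    stopifnot(ncol(m) == 64L, nrow(m) == 20L, all(is.finite(m)))
    .pkg_cache$aaidx <- m
  }
  .pkg_cache$aaidx
}

#' Bundled dipeptide instability weights
#'
#' The 20 x 20 dipeptide instability weight values (DIWV) used by the
#' classical instability index: for adjacent residues x, y the table entry
#' \code{[x, y]} contributes to \code{(10 / L) * sum DIWV(x_i, x_{i+1})}.
#'
#' @return A 20 x 20 numeric matrix indexed by one-letter codes
#'   (first residue = row, second = column).
#' @export
dipeptideInstabilityTable <- function() {
  if (is.null(.pkg_cache$diwv)) {
    path <- system.file("extdata", "diwv_instability.tsv",
                        package = "crystalprop", mustWork = TRUE)
    tab <- utils::read.delim(path, row.names = 1, check.names = FALSE)
    m <- as.matrix(tab)
    stopifnot(identical(rownames(m), .AA20), identical(colnames(m), .AA20))
    .pkg_cache$diwv <- m
  }
  .pkg_cache$diwv
}

#' Titration pKa set
#'
#' pKa values used for the Henderson-Hasselbalch net charge and the
#' isoelectric point: free N/C termini plus the ionizable side chains
#' C, D, E, H, K, R, Y.
#'
#' @return Named numeric vector.
#' @export
titrationPKa <- function() .PKA
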