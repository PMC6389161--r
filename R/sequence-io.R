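#' Read and validate protein sequences from FASTA
#'
#' Parses a (possibly line-wrapped, multi-record) FASTA file, upper-cases
#' the sequences, and validates each record: minimum length, the 20-letter
#' standard residue alphabet, non-empty sequence, and identifier uniqueness
#' within the batch.  The identifier is the header text up to the first
#' whitespace.  Records failing validation are rejected individually with a
#' machine-readable reason (\code{too-short}, \code{non-standard-residue},
#' \code{duplicate-id}, \code{empty-sequence}); with
#' \code{onInvalid = "reject-batch"} any invalid record aborts the read.
#'
#' @param path path to a FASTA file.
#' @param minLength minimum sequence length kept (default 30; shorter chains
#'   are peptides outside the predictor's domain).
#' @param onInvalid \code{"reject-record"} (default) drops invalid records;
#'   \code{"reject-batch"} raises an error if any record is invalid.
#' @return A [ProteinBatch-class] holding the validated sequences and the
#'   rejection table.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1 test", paste(rep("MKVL", 10), collapse = "")), fa)
#' batch <- readProteinFasta(fa)
#' length(batch)
readProteinFasta <- function(path, minLength = 30,
                             onInvalid = c("reject-record", "reject-batch")) {
  onInvalid <- match.arg(onInvalid)
  stopifnot(minLength >= 1)
  if (!file.exists(path)) stop("cannot read FASTA file: ", path)
  seqs <- tryCatch(Biostrings::readAAStringSet(path),
                   error = function(e) stop("failed to parse FASTA '", path,
                                            "': ", conditionMessage(e)))
  if (length(seqs) == 0L)
    stop("empty batch: no FASTA records found in ", path)
  ids <- sub("\\s.*$", "", names(seqs))
  chars <- toupper(as.character(seqs))

  reason <- rep(NA_character_, length(seqs))
  reason[nchar(chars) == 0L] <- "empty-sequence"
  bad_alpha <- grepl(paste0("[^", paste(.AA20, collapse = ""), "]"), chars)
  reason[is.na(reason) & bad_alpha] <- "non-standard-residue"
  reason[is.na(reason) & nchar(chars) < minLength] <- "too-short"
  reason[is.na(reason) & duplicated(ids)] <- "duplicate-id"

  rejected <- data.frame(id = ids[!is.na(reason)],
                         reason = reason[!is.na(reason)],
                         stringsAsFactors = FALSE)
  if (onInvalid == "reject-batch" && nrow(rejected) > 0L)
    stop("invalid records in batch: ",
         paste(rejected$id, rejected$reason, sep = " (", collapse = "), "), ")")
  keep <- is.na(reason)
  if (!any(keep))
    stop("empty batch: no valid records after validation in ", path)
  out <- Biostrings::AAStringSet(chars[keep])
  names(out) <- ids[keep]
  new("ProteinBatch", sequences = out, rejected = rejected)
}

#' Write a prediction report to a tab-separated file
#'
#' Writes one row per protein with the four outcome propensities (six
#' decimal places), the overall call, and the four confidence tiers.
#' [readPredictions()] reverses the operation to the printed precision.
#'
#' @param reports data.frame as returned by [predictOutcomes()]: columns
#'   \code{id}, \code{p_MF}, \code{p_PF}, \code{p_CF}, \code{p_CR},
#'   \code{overall}, \code{conf_MF}, \code{conf_PF}, \code{conf_CF},
#'   \code{conf_CR}.
#' @param path output path.
#' @return Invisibly, the path written.
#' @export
writePredictions <- function(reports, path) {
  cols <- c("id", paste0("p_", outcomeLevels()), "overall",
            paste0("conf_", outcomeLevels()))
  if (!is.data.frame(reports) || nrow(reports) == 0L)
    stop("reports must be a non-empty data.frame")
  if (!all(cols %in% colnames(reports)))
    stop("reports is missing columns: ",
         paste(setdiff(cols, colnames(reports)), collapse = ", "))
  out <- reports[, cols]
  for (p in paste0("p_", outcomeLevels()))
    out[[p]] <- sprintf("%.6f", out[[p]])
  con <- file(path, "w")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writePredictions
#' @return \code{readPredictions} returns the prediction data.frame with
#'   propensities as numerics.
#' @export
readPredictions <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  for (p in paste0("p_", outcomeLevels())) df[[p]] <- as.numeric(df[[p]])
  df
}

#' Write a ProteinBatch (or AAStringSet) to FASTA
#'
#' @param x a [ProteinBatch-class] or [Biostrings::AAStringSet-class].
#' @param path output FASTA path.
#' @return Invisibly, the path.
#' @export
writeProteinFasta <- function(x, path) {
  if (is(x, "ProteinBatch")) x <- proteinSequences(x)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
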