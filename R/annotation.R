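# Trial-status annotation: map registry stop/current status strings to the
# four pipeline outcomes and resolve multi-trial sequences to the farthest
# stage reached.

# canonical status -> outcome table; matching is by normalized exact string.
# The CR duplicate-target spellings vary across registry eras, so all known
# synonyms are listed here rather than hard-coded in the matcher.
.STATUS_MAP <- data.frame(
  kind = c(rep("stop", 10L), rep("current", 2L)),
  status = c("sequencing failed", "cloning failed", "expression failed",
             "purification failed",
             "crystallization failed", "poor diffraction",
             "structure successful", "pdb duplication found",
             "targetdb duplicate target found", "pdb duplicate found",
             "crystal structure", "in pdb"),
  outcome = c("MF", "MF", "MF", "PF", "CF", "CF",
              "CR", "CR", "CR", "CR", "CR", "CR"),
  stringsAsFactors = FALSE)

.normStatus <- function(x) tolower(gsub("\\s+", " ", trimws(x)))

#' Status-to-outcome mapping table
#'
#' @return data.frame with columns \code{kind} (\code{stop} or
#'   \code{current}), \code{status} (normalized) and \code{outcome}.
#' @export
statusMap <- function() .STATUS_MAP

#' Map a trial status string to an outcome
#'
#' Case-insensitive exact match after trimming and collapsing internal
#' whitespace.  Stop statuses map to MF (sequencing/cloning/expression
#' failed), PF (purification failed), CF (crystallization failed, poor
#' diffraction) or CR (structure successful and the duplicate-target
#' synonyms); the current statuses "crystal structure" and "in PDB" map to
#' CR.  Anything else is unmapped (\code{NA}), never an error.
#'
#' @param status character vector of status strings.
#' @param kind \code{"stop"} or \code{"current"} (recycled).
#' @return Character vector of outcome labels, \code{NA} where unmapped.
#' @export
#' @examples
#' mapStatus("purification failed", "stop")    # "PF"
#' mapStatus("work stopped", "stop")           # NA
mapStatus <- function(status, kind = "stop") {
  kind <- rep_len(as.character(kind), length(status))
  key <- paste(kind, .normStatus(status), sep = "\r")
  tab <- paste(.STATUS_MAP$kind, .STATUS_MAP$status, sep = "\r")
  .STATUS_MAP$outcome[match(key, tab)]
}

#' Resolve multiple trials of one sequence to the farthest pipeline stage
#'
#' Maps each status, drops the unmapped, and keeps the outcome with the
#' highest pipeline rank (MF < PF < CF < CR): a later-stage record proves
#' the earlier stages succeeded.  Order-independent and idempotent.
#'
#' @param status character vector of status strings for one sequence.
#' @param kind parallel vector of status kinds.
#' @return A single outcome label, or \code{NA} if nothing maps.
#' @export
#' @examples
#' resolveFarthest(c("expression failed", "purification failed"))  # "PF"
resolveFarthest <- function(status, kind = "stop") {
  oc <- mapStatus(status, kind)
  oc <- oc[!is.na(oc)]
  if (!length(oc)) return(NA_character_)
  outcomeLevels()[max(outcomeRank(oc))]
}

#' Read a trial-status table
#'
#' @param path 3-column TSV: \code{sequence_id}, \code{status_kind}
#'   (\code{stop}/\code{current}), \code{status}.
#' @return data.frame with those columns.
#' @export
readStatusTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("sequence_id", "status_kind", "status")
  if (!all(need %in% colnames(df)))
    stop("status table must have columns: ", paste(need, collapse = ", "))
  df
}

#' Annotate sequences with their farthest-stage outcome
#'
#' Groups the status records by sequence id and applies [resolveFarthest()]
#' per sequence.
#'
#' @param statusTable data.frame as from [readStatusTable()].
#' @return data.frame with columns \code{sequence_id} and \code{outcome}
#'   (\code{NA} where no status maps), one row per unique id, in first-seen
#'   order.
#' @export
annotateOutcomes <- function(statusTable) {
  ids <- unique(statusTable$sequence_id)
  outcome <- vapply(ids, function(id) {
    sel <- statusTable$sequence_id == id
    resolveFarthest(statusTable$status[sel], statusTable$status_kind[sel])
  }, character(1))
  data.frame(sequence_id = ids, outcome = unname(outcome),
             stringsAsFactors = FALSE)
}
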