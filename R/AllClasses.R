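#' @import methods
NULL

#' The four pipeline outcomes, in pipeline order
#'
#' Protein production and crystallization trials are annotated with one of
#' four terminal outcomes: failure of material production (\code{MF}),
#' failure to purify (\code{PF}), failure to crystallize (\code{CF}), and
#' success of diffraction-quality crystallization (\code{CR}).  The order is
#' the order of the experimental pipeline; \code{MF} is the earliest stage a
#' target can fail at and \code{CR} is full success.
#'
#' @return Character vector \code{c("MF", "PF", "CF", "CR")}.
#' @export
#' @examples
#' outcomeLevels()
outcomeLevels <- function() c("MF", "PF", "CF", "CR")

#' Pipeline rank of an outcome label
#'
#' @param x character vector of outcome labels.
#' @return Integer rank (MF = 1 < PF = 2 < CF = 3 < CR = 4); \code{NA} for
#'   anything that is not one of the four labels.
#' @export
outcomeRank <- function(x) match(x, outcomeLevels())

#' Validated protein sequence batch
#'
#' A \code{ProteinBatch} holds the sequences that passed validation (length
#' and alphabet filters, unique identifiers) together with a table of the
#' records that were rejected and why.  Created by [readProteinFasta()].
#'
#' @slot sequences An [Biostrings::AAStringSet-class] of validated,
#'   upper-case sequences over the 20 standard residues, named by FASTA id.
#' @slot rejected A data.frame with columns \code{id} and \code{reason}
#'   (one of \code{too-short}, \code{non-standard-residue},
#'   \code{duplicate-id}, \code{empty-sequence}).
#'
#' @export
setClass("ProteinBatch",
  representation(sequences = "AAStringSet", rejected = "data.frame"))

setValidity("ProteinBatch", function(object) {
  seqs <- object@sequences
  msgs <- character()
  if (length(seqs) && anyDuplicated(names(seqs)))
    msgs <- c(msgs, "sequence ids must be unique")
  if (length(seqs) && (is.null(names(seqs)) || any(!nzchar(names(seqs)))))
    msgs <- c(msgs, "all sequences must be named")
  if (!all(c("id", "reason") %in% colnames(object@rejected)))
    msgs <- c(msgs, "rejected table needs columns 'id' and 'reason'")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn ProteinBatch-class number of validated sequences
#' @param x,object a \code{ProteinBatch}.
#' @export
setMethod("length", "ProteinBatch", function(x) length(x@sequences))

#' Accessors for ProteinBatch
#'
#' @param x a [ProteinBatch-class].
#' @return \code{proteinSequences} returns the validated
#'   [Biostrings::AAStringSet-class]; \code{rejectedRecords} the data.frame
#'   of rejected entries.
#' @export
proteinSequences <- function(x) {
  stopifnot(is(x, "ProteinBatch"))
  x@sequences
}

#' @rdname proteinSequences
#' @export
rejectedRecords <- function(x) {
  stopifnot(is(x, "ProteinBatch"))
  x@rejected
}

setMethod("show", "ProteinBatch", function(object) {
  cat("ProteinBatch with", length(object@sequences), "validated sequence(s),",
      nrow(object@rejected), "rejected record(s)\n")
  if (length(object@sequences)) {
    w <- Biostrings::width(object@sequences)
    cat("  length range:", min(w), "-", max(w), "residues\n")
  }
})

#' The ordered 1276-feature catalog
#'
#' Names and group memberships of every feature the extractor emits, in the
#' fixed order used by [extractFeatures()].  Group sizes are part of the
#' class contract: AAC (amino-acid + dipeptide composition) 420, CLUSTER
#' (grouped composition/transition/distribution) 336, AAPHYS (windowed
#' residue-index profiles) 448, PROTPHYS (whole-chain physicochemical
#' indices) 4, CXDIS (sequence-complexity and disorder summaries) 68;
#' 1276 in total.
#'
#' @slot entries data.frame with columns \code{name} (unique) and
#'   \code{group}.
#' @export
setClass("FeatureCatalog", representation(entries = "data.frame"))

.CATALOG_GROUP_SIZES <- c(AAC = 420L, CLUSTER = 336L, AAPHYS = 448L,
                          PROTPHYS = 4L, CXDIS = 68L)

setValidity("FeatureCatalog", function(object) {
  e <- object@entries
  msgs <- character()
  if (!all(c("name", "group") %in% colnames(e)))
    msgs <- c(msgs, "entries needs columns 'name' and 'group'")
  else {
    if (nrow(e) != sum(.CATALOG_GROUP_SIZES))
      msgs <- c(msgs, sprintf("catalog must have %d entries, got %d",
                              sum(.CATALOG_GROUP_SIZES), nrow(e)))
    if (anyDuplicated(e$name)) msgs <- c(msgs, "feature names must be unique")
    got <- table(factor(e$group, levels = names(.CATALOG_GROUP_SIZES)))
    if (!all(as.integer(got) == as.integer(.CATALOG_GROUP_SIZES)))
      msgs <- c(msgs, paste0("group sizes must be ",
        paste(names(.CATALOG_GROUP_SIZES), .CATALOG_GROUP_SIZES,
              sep = "=", collapse = ", ")))
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn FeatureCatalog-class number of features (always 1276)
#' @param x,object a \code{FeatureCatalog}.
#' @export
setMethod("length", "FeatureCatalog", function(x) nrow(x@entries))

#' Catalog accessors
#'
#' @param x a [FeatureCatalog-class].
#' @return \code{featureNames} the ordered feature names; \code{featureGroups}
#'   the parallel group labels.
#' @export
featureNames <- function(x) {
  stopifnot(is(x, "FeatureCatalog"))
  x@entries$name
}

#' @rdname featureNames
#' @export
featureGroups <- function(x) {
  stopifnot(is(x, "FeatureCatalog"))
  x@entries$group
}

setMethod("show", "FeatureCatalog", function(object) {
  tab <- table(factor(object@entries$group, names(.CATALOG_GROUP_SIZES)))
  cat("FeatureCatalog with", nrow(object@entries), "features\n")
  for (g in names(tab)) cat(sprintf("  %-9s %4d\n", g, tab[[g]]))
})

#' Trace of the per-outcome feature-selection pipeline
#'
#' Records the three selection stages for one outcome: relevance filtering
#' by absolute point-biserial correlation, redundancy pruning at a Pearson
#' correlation cap, and the greedy forward wrapper that accepts a candidate
#' only when it strictly improves cross-validated AUC.
#'
#' @slot outcome one of \code{MF}, \code{PF}, \code{CF}, \code{CR} (or
#'   another binary-task tag).
#' @slot relevanceSurvivors integer catalog indices passing the relevance
#'   filter.
#' @slot redundancySurvivors integer indices surviving redundancy pruning,
#'   in descending relevance order (the wrapper's candidate ranking).
#' @slot selected integer indices of the final subset, in acceptance order.
#' @slot trace data.frame, one row per wrapper step: \code{candidate},
#'   \code{auc_before}, \code{auc_after}, \code{accepted}.
#' @export
setClass("SelectionResult",
  representation(outcome = "character",
                 relevanceSurvivors = "integer",
                 redundancySurvivors = "integer",
                 selected = "integer",
                 trace = "data.frame"))

setValidity("SelectionResult", function(object) {
  msgs <- character()
  if (!all(object@selected %in% object@redundancySurvivors))
    msgs <- c(msgs, "selected must be a subset of redundancySurvivors")
  if (!all(object@redundancySurvivors %in% object@relevanceSurvivors))
    msgs <- c(msgs, "redundancySurvivors must be a subset of relevanceSurvivors")
  acc <- object@trace$auc_after[object@trace$accepted]
  if (length(acc) > 1 && any(diff(acc) <= 0))
    msgs <- c(msgs, "accepted AUC sequence must be strictly increasing")
  if (length(msgs)) msgs else TRUE
})

#' @rdname selectedFeatures
#' @export
setGeneric("selectionTrace", function(x) standardGeneric("selectionTrace"))

#' Selection accessors
#'
#' @param x a [SelectionResult-class].
#' @return \code{selectedFeatures}: integer catalog indices of the final
#'   subset; \code{selectionTrace}: the wrapper audit trail.
#' @export
setGeneric("selectedFeatures", function(x) standardGeneric("selectedFeatures"))

#' @rdname selectedFeatures
#' @export
setMethod("selectedFeatures", "SelectionResult", function(x) x@selected)

#' @rdname selectedFeatures
#' @export
setMethod("selectionTrace", "SelectionResult", function(x) x@trace)

setMethod("show", "SelectionResult", function(object) {
  cat("SelectionResult [", object@outcome, "]\n", sep = "")
  cat("  relevance survivors :", length(object@relevanceSurvivors), "\n")
  cat("  redundancy survivors:", length(object@redundancySurvivors), "\n")
  cat("  selected            :", length(object@selected),
      paste0("(", paste(object@selected, collapse = ", "), ")"), "\n")
})

#' One fitted logistic outcome model
#'
#' A binary logistic regression for one pipeline outcome, fitted on
#' standardized features, plus the percentile calibration used for the
#' low/medium/high confidence tiers (20th and 80th percentiles of the
#' training propensities).
#'
#' @slot outcome outcome tag (usually one of MF/PF/CF/CR).
#' @slot featureIndices integer indices into the feature catalog (or the
#'   training matrix columns for standalone fits).
#' @slot featureNamesUsed character names of the selected features.
#' @slot weights numeric coefficients on the standardized scale.
#' @slot intercept numeric intercept.
#' @slot center,scale per-feature standardization parameters learned on the
#'   training data (constant features get scale 1).
#' @slot confidence numeric \code{c(low, high)}: 20th/80th percentile of the
#'   training propensities (linear-interpolation percentile definition).
#' @slot ridged logical; TRUE when a tiny ridge penalty was used to
#'   stabilize a (quasi-)separated fit.
#' @export
setClass("OutcomeModel",
  representation(outcome = "character",
                 featureIndices = "integer",
                 featureNamesUsed = "character",
                 weights = "numeric",
                 intercept = "numeric",
                 center = "numeric",
                 scale = "numeric",
                 confidence = "numeric",
                 ridged = "logical"))

setValidity("OutcomeModel", function(object) {
  msgs <- character()
  k <- length(object@featureIndices)
  if (length(object@weights) != k || length(object@center) != k ||
      length(object@scale) != k)
    msgs <- c(msgs, "weights/center/scale must match featureIndices in length")
  if (length(object@confidence) != 2 ||
      object@confidence[1] > object@confidence[2] ||
      any(object@confidence < 0) || any(object@confidence > 1))
    msgs <- c(msgs, "confidence must be c(low, high) in [0,1] with low <= high")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "OutcomeModel", function(object) {
  cat("OutcomeModel [", object@outcome, "] with ",
      length(object@weights), " feature(s)", sep = "")
  if (object@ridged) cat(" (ridge-stabilized)")
  cat("\n  confidence tiers: low < ", signif(object@confidence[1], 4),
      " <= medium <= ", signif(object@confidence[2], 4), " < high\n", sep = "")
})

#' A bundle of the four outcome models
#'
#' @slot models named list of [OutcomeModel-class], one per outcome in
#'   [outcomeLevels()] order.
#' @slot selection named list of [SelectionResult-class] (may be empty when
#'   models were trained on pre-chosen features).
#' @export
setClass("OutcomeModelSet",
  representation(models = "list", selection = "list"))

setValidity("OutcomeModelSet", function(object) {
  msgs <- character()
  if (!identical(names(object@models), outcomeLevels()))
    msgs <- c(msgs, "models must be named MF, PF, CF, CR in that order")
  if (!all(vapply(object@models, is, TRUE, "OutcomeModel")))
    msgs <- c(msgs, "all elements must be OutcomeModel objects")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn OutcomeModelSet-class extract one outcome model by label
#' @param x an \code{OutcomeModelSet}; \code{i} an outcome label or index.
#' @param i,j,... index (outcome label or position); further args ignored.
#' @export
setMethod("[[", "OutcomeModelSet", function(x, i, j, ...) x@models[[i]])

setMethod("show", "OutcomeModelSet", function(object) {
  cat("OutcomeModelSet (MF, PF, CF, CR)\n")
  for (m in object@models)
    cat(sprintf("  %s: %d feature(s)%s\n", m@outcome, length(m@weights),
                if (m@ridged) " [ridged]" else ""))
})
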