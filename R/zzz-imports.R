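#' @importFrom Biostrings readAAStringSet writeXStringSet AAStringSet width
#' @importFrom methods new is validObject
#' @importFrom stats cor sd median quantile plogis rlnorm rnorm rbinom t.test setNames
#' @importFrom nortest ad.test
#' @importFrom utils read.delim read.table write.table
NULL
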