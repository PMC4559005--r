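#' Transcriptome segmentation index
#'
#' Precomputed partition of a transcriptome into mappability-defined
#' segments. A *virtual read* is a read-length substring of a transcript
#' (for paired-end data, a pair of such substrings spanning a fragment
#' size); the multiset of (transcript, number of positions) a virtual read
#' maps to is its *alignment class*, and all distinct virtual reads with
#' the same alignment class form one *segment*. The number of distinct
#' virtual reads in a segment at a given fragment size is its
#' fragment-size-specific length. Transcripts connected (transitively) by
#' shared segments form *sequence-sharing sets*, the independent units of
#' joint likelihood estimation.
#'
#' Slots are internal; use the accessors [txIds()], [geneIds()],
#' [segmentTable()], [sharingSets()], [readLength()].
#'
#' @slot txId,geneId,txLength per-transcript id, gene id, length (bases).
#' @slot segClassKey canonical class key per segment (`"i:m;j:m"` over
#'   transcript indices).
#' @slot segMembers,segMult parsed class: transcript indices and their
#'   multiplicities, one list element per segment.
#' @slot perSizeLength integer matrix, segments x indexed fragment sizes;
#'   entry = number of distinct virtual reads of that class at that size.
#' @slot weightedLength numeric, the fragment-size-distribution-weighted
#'   segment length (uniform over indexed sizes until a dataset is seen).
#' @slot segSet integer, sequence-sharing-set id per segment.
#' @slot sets list of integer vectors: transcript indices per set.
#' @slot droppedClassKey class keys of segments removed by pruning; reads
#'   falling in these classes are discarded at counting time.
#' @slot readLength read length (bases) the index was built for.
#' @slot fragRange integer(2) indexed fragment-size range (paired-end), or
#'   integer(0) for single-end.
#' @slot stranded logical; FALSE merges reverse-complement substrings.
#' @slot formatVersion serialization format version.
#' @seealso [buildIndex()], [writeIndex()], [countReads()], [fitAbundance()]
#' @export
setClass("TranscriptomeIndex",
  representation(
    txId = "character", geneId = "character", txLength = "integer",
    segClassKey = "character", segMembers = "list", segMult = "list",
    perSizeLength = "matrix", weightedLength = "numeric",
    segSet = "integer", sets = "list", droppedClassKey = "character",
    readLength = "integer", fragRange = "integer", stranded = "logical",
    formatVersion = "integer"
  )
)

setValidity("TranscriptomeIndex", function(object) {
  msg <- character()
  nt <- length(object@txId)
  ns <- length(object@segClassKey)
  if (length(object@geneId) != nt || length(object@txLength) != nt)
    msg <- c(msg, "transcript slots have unequal lengths")
  if (length(object@segMembers) != ns || length(object@segMult) != ns ||
      nrow(object@perSizeLength) != ns || length(object@weightedLength) != ns ||
      length(object@segSet) != ns)
    msg <- c(msg, "segment slots have unequal lengths")
  if (ns && anyDuplicated(object@segClassKey))
    msg <- c(msg, "segment class keys are not unique")
  covered <- sort(unlist(object@sets, use.names = FALSE))
  if (!identical(covered, seq_len(nt)))
    msg <- c(msg, "sequence-sharing sets must partition the transcripts")
  if (ns) {
    inSet <- vapply(seq_len(ns), function(i) {
      all(object@segMembers[[i]] %in% object@sets[[object@segSet[i]]])
    }, logical(1))
    if (!all(inSet))
      msg <- c(msg, "a segment references a transcript outside its set")
  }
  if (length(msg)) msg else TRUE
})

#' Per-segment read counts for one dataset
#'
#' Result of streaming a best-mismatch-filtered alignment set against a
#' [TranscriptomeIndex-class]: the observed read count per segment, the
#' per-reason discard breakdown, and the empirical fragment-size
#' distribution (paired-end).
#'
#' @slot counts numeric, one observed read count per index segment.
#' @slot classKey class keys, parallel to `counts` (sanity link to the
#'   index used).
#' @slot totalCounted,totalDiscarded totals; their sum is the number of
#'   reads (or read pairs) seen.
#' @slot discarded named numeric, per-reason discard counts.
#' @slot fragDist named numeric, empirical fragment-size distribution of
#'   counted reads, truncated and renormalized to the indexed range
#'   (single-end: point mass at the read length).
#' @seealso [countReads()], [fitAbundance()]
#' @export
setClass("SegmentCounts",
  representation(
    counts = "numeric", classKey = "character",
    totalCounted = "numeric", totalDiscarded = "numeric",
    discarded = "numeric", fragDist = "numeric"
  )
)

setValidity("SegmentCounts", function(object) {
  msg <- character()
  if (length(object@counts) != length(object@classKey))
    msg <- c(msg, "counts and classKey lengths differ")
  if (any(object@counts < 0)) msg <- c(msg, "negative segment count")
  if (abs(sum(object@counts) - object@totalCounted) > 1e-8)
    msg <- c(msg, "counts do not sum to totalCounted")
  if (abs(sum(object@discarded) - object@totalDiscarded) > 1e-8)
    msg <- c(msg, "discard reasons do not sum to totalDiscarded")
  if (length(object@fragDist) &&
      abs(sum(object@fragDist) - 1) > 1e-6)
    msg <- c(msg, "fragment-size distribution must sum to 1")
  if (length(msg)) msg else TRUE
})

#' Transcript abundance estimates
#'
#' Per-transcript expression from the joint Poisson maximum-likelihood
#' fit: the per-virtual-length-unit rate `e`, FPKM, TPM, effective length
#' (sum of lengths of all segments containing the transcript), and the
#' inferred read count. `solvable` is FALSE when the restart optima
#' disagreed, i.e. the data constrain only a sum of transcript rates.
#'
#' Use [as.data.frame()] for the transcript table and [geneAbundance()]
#' for gene-level aggregates.
#'
#' @slot table data.frame with columns `transcript_id`, `gene_id`,
#'   `effective_length`, `est_count`, `FPKM`, `TPM`, `e`, `solvable`,
#'   in input transcriptome order.
#' @slot totalCounted number of counted reads behind the fit.
#' @seealso [fitAbundance()], [writeAbundance()]
#' @export
setClass("AbundanceTable",
  representation(table = "data.frame", totalCounted = "numeric")
)

setValidity("AbundanceTable", function(object) {
  need <- c("transcript_id", "gene_id", "effective_length", "est_count",
            "FPKM", "TPM", "e", "solvable")
  if (!all(need %in% names(object@table)))
    return("missing abundance columns")
  num <- object@table[c("effective_length", "est_count", "FPKM", "TPM", "e")]
  if (any(unlist(num) < 0, na.rm = TRUE))
    return("abundance quantities must be non-negative")
  tpm <- sum(object@table$TPM)
  if (tpm > 0 && abs(tpm - 1e6) > 1e-6 * 1e6)
    return("TPM must sum to 1e6")
  TRUE
})
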