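#' Accessors for segquant objects
#'
#' @param x a [TranscriptomeIndex-class], [SegmentCounts-class] or
#'   [AbundanceTable-class] object.
#' @name accessors
NULL

#' @describeIn accessors transcript ids, in input order.
#' @export
setGeneric("txIds", function(x) standardGeneric("txIds"))
#' @describeIn accessors gene ids, parallel to [txIds()].
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
#' @describeIn accessors segment table: class key, member transcripts,
#'   per-size lengths and the current weighted length.
#' @export
setGeneric("segmentTable", function(x) standardGeneric("segmentTable"))
#' @describeIn accessors sequence-sharing sets as a list of transcript-id
#'   vectors.
#' @export
setGeneric("sharingSets", function(x) standardGeneric("sharingSets"))
#' @describeIn accessors read length the index was built for.
#' @export
setGeneric("readLength", function(x) standardGeneric("readLength"))
#' @describeIn accessors per-reason discard counts of a counting run.
#' @export
setGeneric("discardSummary", function(x) standardGeneric("discardSummary"))
#' @describeIn accessors empirical fragment-size distribution.
#' @export
setGeneric("fragmentSizeDistribution",
           function(x) standardGeneric("fragmentSizeDistribution"))
#' @describeIn accessors gene-level abundance aggregates.
#' @export
setGeneric("geneAbundance", function(x) standardGeneric("geneAbundance"))

#' @rdname accessors
#' @export
setMethod("txIds", "TranscriptomeIndex", function(x) x@txId)
#' @rdname accessors
#' @export
setMethod("geneIds", "TranscriptomeIndex", function(x)
  setNames(x@geneId, x@txId))
#' @rdname accessors
#' @export
setMethod("readLength", "TranscriptomeIndex", function(x) x@readLength)

#' @rdname accessors
#' @export
setMethod("segmentTable", "TranscriptomeIndex", function(x) {
  data.frame(
    class_key = x@segClassKey,
    members = vapply(x@segMembers, function(m)
      paste(x@txId[m], collapse = ","), character(1)),
    multiplicities = vapply(x@segMult, paste, character(1), collapse = ","),
    weighted_length = x@weightedLength,
    set = x@segSet,
    x@perSizeLength,
    check.names = FALSE, stringsAsFactors = FALSE
  )
})

#' @rdname accessors
#' @export
setMethod("sharingSets", "TranscriptomeIndex", function(x)
  lapply(x@sets, function(i) x@txId[i]))

#' @describeIn accessors observed read count per segment (named by class
#'   key), from `BiocGenerics::counts`.
#' @importFrom BiocGenerics counts
#' @param object a [SegmentCounts-class] object.
#' @export
setMethod("counts", "SegmentCounts", function(object)
  setNames(object@counts, object@classKey))

#' @rdname accessors
#' @export
setMethod("discardSummary", "SegmentCounts", function(x) x@discarded)
#' @rdname accessors
#' @export
setMethod("fragmentSizeDistribution", "SegmentCounts", function(x) x@fragDist)

#' @rdname accessors
#' @export
setMethod("geneAbundance", "AbundanceTable", function(x) {
  tab <- x@table
  agg <- stats::aggregate(
    tab[c("est_count", "FPKM", "TPM")],
    by = list(gene_id = tab$gene_id), FUN = sum)
  # keep first-appearance gene order
  agg[match(unique(tab$gene_id), agg$gene_id), , drop = FALSE]
})

#' @param row.names,optional,... passed on as in [base::as.data.frame()].
#' @rdname accessors
#' @export
as.data.frame.AbundanceTable <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  x@table
}

setMethod("show", "TranscriptomeIndex", function(object) {
  nt <- length(object@txId)
  ns <- length(object@segClassKey)
  setSizes <- lengths(object@sets)
  cat("TranscriptomeIndex:", nt, "transcripts,", ns, "segments,",
      length(object@sets), "sequence-sharing sets\n")
  cat("  read length:", object@readLength,
      if (length(object@fragRange))
        paste0("| fragment sizes: ", object@fragRange[1], "-",
               object@fragRange[2])
      else "| single-end",
      "|", if (object@stranded) "stranded" else "unstranded", "\n")
  cat("  largest set:", if (length(setSizes)) max(setSizes) else 0,
      "transcripts |", length(object@droppedClassKey),
      "segments pruned\n")
})

setMethod("show", "SegmentCounts", function(object) {
  cat("SegmentCounts:", object@totalCounted, "reads counted over",
      sum(object@counts > 0), "of", length(object@counts), "segments;",
      object@totalDiscarded, "discarded\n")
  if (length(object@discarded)) {
    d <- object@discarded[object@discarded > 0]
    if (length(d))
      cat("  discards:", paste(names(d), d, sep = "=", collapse = ", "), "\n")
  }
})

setMethod("show", "AbundanceTable", function(object) {
  cat("AbundanceTable:", nrow(object@table), "transcripts,",
      length(unique(object@table$gene_id)), "genes;",
      sum(object@table$TPM > 0), "with TPM > 0\n")
  print(utils::head(object@table, 5))
  if (nrow(object@table) > 5) cat("  ...\n")
})
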