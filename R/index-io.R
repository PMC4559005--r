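# Versioned on-disk container for the transcriptome index.
# Format: a single JSON object, format_version first; portable text,
# adequate for the index sizes this package targets.

.INDEX_FORMAT_VERSION <- 1L

#' Write a transcriptome index to disk
#'
#' Serializes a [TranscriptomeIndex-class] as a versioned JSON container
#' (atomically: written to a temporary file and renamed into place).
#' [readIndex()] refuses files whose `format_version` it does not know.
#'
#' @param index a [TranscriptomeIndex-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeIndex <- function(index, path) {
  stopifnot(is(index, "TranscriptomeIndex"))
  obj <- list(
    format_version = .INDEX_FORMAT_VERSION,
    tool = "segquant",
    read_length = index@readLength,
    frag_range = index@fragRange,
    stranded = index@stranded,
    tx_id = index@txId,
    gene_id = index@geneId,
    tx_length = index@txLength,
    seg_class_key = index@segClassKey,
    per_size_length = index@perSizeLength,
    size_labels = colnames(index@perSizeLength),
    weighted_length = index@weightedLength,
    seg_set = index@segSet,
    sets = index@sets,
    dropped_class_key = index@droppedClassKey
  )
  .atomicWrite(path, function(p)
    jsonlite::write_json(obj, p, auto_unbox = FALSE, digits = NA))
  invisible(path)
}

#' Read a transcriptome index from disk
#'
#' @param path a file written by [writeIndex()].
#' @return a [TranscriptomeIndex-class].
#' @export
readIndex <- function(path) {
  if (!file.exists(path)) stop("index file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format_version) ||
      obj$format_version != .INDEX_FORMAT_VERSION)
    stop("unsupported index format_version: ",
         if (is.null(obj$format_version)) "missing" else obj$format_version,
         " (this build reads version ", .INDEX_FORMAT_VERSION, ")")
  psl <- obj$per_size_length
  if (is.null(dim(psl)))
    psl <- matrix(psl, ncol = max(1L, length(obj$size_labels)))
  colnames(psl) <- obj$size_labels
  parsed <- .parseClassKeys(as.character(obj$seg_class_key))
  # jsonlite may simplify a list of equal-length sets to a matrix/vector
  rawSets <- obj$sets
  sets <- if (is.matrix(rawSets)) {
    lapply(seq_len(nrow(rawSets)), function(i) as.integer(rawSets[i, ]))
  } else if (is.list(rawSets)) {
    lapply(rawSets, as.integer)
  } else {
    as.list(as.integer(rawSets))
  }
  new("TranscriptomeIndex",
      txId = as.character(obj$tx_id),
      geneId = as.character(obj$gene_id),
      txLength = as.integer(obj$tx_length),
      segClassKey = as.character(obj$seg_class_key),
      segMembers = lapply(parsed, `[[`, "members"),
      segMult = lapply(parsed, `[[`, "mult"),
      perSizeLength = psl,
      weightedLength = as.numeric(obj$weighted_length),
      segSet = as.integer(obj$seg_set),
      sets = unname(sets),
      droppedClassKey = as.character(obj$dropped_class_key),
      readLength = as.integer(obj$read_length),
      fragRange = as.integer(obj$frag_range),
      stranded = as.logical(obj$stranded),
      formatVersion = as.integer(obj$format_version))
}
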