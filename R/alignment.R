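# Alignment streaming, best-mismatch filtering and segment counting.
#
# The in-memory alignment representation is a data.frame with one row per
# alignment record: qname, tx (transcript id), pos (0-based leftmost),
# strand ("+"/"-"), nm (mismatches), and for paired data mate (1/2) and
# mpos (0-based mate position); optional cigarOK marks ungapped
# full-length alignments. readAlignments() produces it from SAM/BAM.

# mismatches from an MD tag: letters outside ^-deletion runs
.mdMismatches <- function(md) {
  stripped <- gsub("\\^[A-Z]+", "", md)
  nchar(gsub("[^A-Z]", "", stripped))
}

#' Read a SAM/BAM alignment file into the alignment table
#'
#' Reads all records (including secondary alignments) of a
#' transcriptome-aligned SAM or BAM file via Rsamtools. Mismatch counts
#' come from the `NM` tag, falling back to parsing `MD`. SAM input is
#' converted with [Rsamtools::asBam()] behind the scenes.
#'
#' @param file path to a SAM or BAM file.
#' @return a `data.table` with columns `qname`, `tx`, `pos` (0-based),
#'   `strand`, `nm`, `mate` (0 single-end, 1/2 paired), `mpos` (0-based,
#'   NA when single-end), `cigarOK`, `mapped`.
#' @seealso [countReads()]
#' @export
readAlignments <- function(file) {
  if (!file.exists(file)) stop("alignment file not found: ", file)
  bam <- file
  if (!grepl("\\.bam$", file, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- suppressMessages(
      Rsamtools::asBam(file, destination = dest, overwrite = TRUE,
                       indexDestination = FALSE))
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "mpos"),
    tag = c("NM", "MD"))
  res <- Rsamtools::scanBam(bam, param = param)[[1L]]
  if (!length(res$qname))
    return(data.table(qname = character(), tx = character(),
                      pos = integer(), strand = character(),
                      nm = integer(), mate = integer(), mpos = integer(),
                      cigarOK = logical(), mapped = logical()))
  flag <- res$flag
  mapped <- bitwAnd(flag, 4L) == 0L
  nm <- res$tag$NM
  if (is.null(nm)) nm <- rep(NA_integer_, length(flag))
  md <- res$tag$MD
  needMD <- mapped & is.na(nm)
  if (any(needMD)) {
    if (is.null(md) || anyNA(md[needMD]))
      stop("mapped records lack both NM and MD tags; ",
           "cannot determine mismatch counts")
    nm[needMD] <- .mdMismatches(md[needMD])
  }
  paired <- bitwAnd(flag, 1L) != 0L
  dt <- data.table(
    qname = res$qname,
    tx = as.character(res$rname),
    pos = res$pos - 1L,
    strand = ifelse(bitwAnd(flag, 16L) != 0L, "-", "+"),
    nm = as.integer(nm),
    mate = ifelse(!paired, 0L, ifelse(bitwAnd(flag, 64L) != 0L, 1L, 2L)),
    mpos = res$mpos - 1L,
    cigarOK = grepl("^[0-9]+M$", res$cigar),
    mapped = mapped)
  dt
}

#' Keep only each read's minimum-mismatch alignments
#'
#' Implements "n mismatches, best" filtering: within every read (or read
#' pair) group, exactly the alignments whose mismatch count equals the
#' group minimum are retained; ties are all kept.
#'
#' @param alignments alignment table with columns `qname` and `nm` (for
#'   paired units, `nm` should already be the pair's summed mismatches).
#' @return the filtered table.
#' @export
filterBestAlignments <- function(alignments) {
  dt <- as.data.table(alignments)
  if (!nrow(dt)) return(dt)
  dt[, .keep := nm == min(nm), by = qname]
  out <- dt[.keep == TRUE][, .keep := NULL]
  out[]
}

#' Fragment size of a paired alignment
#'
#' End-to-end span of the two mates on one transcript:
#' `max(end) - min(start)`.
#'
#' @param start1,end1 half-open 0-based interval of mate 1.
#' @param start2,end2 half-open 0-based interval of mate 2.
#' @return the fragment size(s) in bases.
#' @examples
#' inferFragmentSize(100, 200, 250, 350)  # 250
#' @export
inferFragmentSize <- function(start1, end1, start2, end2) {
  pmax(end1, end2) - pmin(start1, start2)
}

#' Resolve a read's alignment class against the index
#'
#' The multiset of (transcript, number of retained positions) is looked
#' up among the index segments. Classes absent from the perfect-match
#' index (pruned segments, or mismatch-tolerant alignments that created
#' a class no virtual read has) are rejected.
#'
#' @param txs character vector of transcript ids of a read's retained
#'   alignments, one entry per mapped position (repeats encode
#'   multiplicity).
#' @param index a [TranscriptomeIndex-class].
#' @return list with `segment` (index of the matching segment, or `NA`),
#'   `key` (the canonical class key) and `reason` (`NA` or
#'   `"unindexed_class"`).
#' @export
resolveAlignmentClass <- function(txs, index) {
  idx <- match(txs, index@txId)
  if (anyNA(idx))
    stop("unknown transcript id(s): ",
         paste(unique(txs[is.na(idx)]), collapse = ", "),
         " (index/alignment mismatch)")
  tab <- table(idx)
  key <- .makeClassKey(as.integer(names(tab)), as.integer(tab))
  seg <- match(key, index@segClassKey)
  list(segment = seg, key = key,
       reason = if (is.na(seg)) "unindexed_class" else NA_character_)
}

# empty discard tally
.discardReasons <- c("unmapped", "clipped_or_gapped", "wrong_strand",
                     "unpaired_mate", "too_many_alignments",
                     "ambiguous_fragment_size", "unindexed_class")

#' Count reads per segment
#'
#' The quantification counting stage: groups alignments by read, applies
#' best-mismatch filtering ([filterBestAlignments()]), enforces the
#' per-read alignment cap, resolves each read's alignment class against
#' the index and increments the matching segment. Identical reads
#' occurring multiple times in the data are counted each time. For
#' paired data, mates are paired into alignment units, reads whose
#' retained alignments imply more than one fragment size are discarded,
#' and the empirical fragment-size distribution of the counted reads is
#' recorded (truncated and renormalized to the indexed range). Counting
#' is order-independent and every read is accounted for: counted plus
#' per-reason discards equals reads seen.
#'
#' @param x alignments: a SAM/BAM path (see [readAlignments()]) or an
#'   alignment data.frame with columns `qname`, `tx`, `pos`, `strand`,
#'   `nm` (and `mate`, `mpos` for paired data).
#' @param index a [TranscriptomeIndex-class].
#' @param maxAlignments discard reads with more retained alignments than
#'   this (default 100; applied after best filtering).
#' @return a [SegmentCounts-class].
#' @export
setGeneric("countReads", function(x, index, maxAlignments = 100)
  standardGeneric("countReads"))

#' @rdname countReads
#' @export
setMethod("countReads", "character", function(x, index,
                                              maxAlignments = 100) {
  countReads(readAlignments(x), index, maxAlignments)
})

#' @rdname countReads
#' @export
setMethod("countReads", "data.frame", function(x, index,
                                               maxAlignments = 100) {
  stopifnot(is(index, "TranscriptomeIndex"))
  dt <- as.data.table(x)
  need <- c("qname", "tx", "pos", "strand", "nm")
  if (!all(need %in% names(dt)))
    stop("alignment table needs columns: ", paste(need, collapse = ", "))
  if (!"mate" %in% names(dt)) dt[, mate := 0L]
  if (!"mpos" %in% names(dt)) dt[, mpos := NA_integer_]
  if (!"mapped" %in% names(dt)) dt[, mapped := !is.na(tx)]
  if (!"cigarOK" %in% names(dt)) dt[, cigarOK := TRUE]

  # fully duplicated records are distinct physical reads, not extra
  # alignments of one read: split them into their own groups
  dt[, .dup := seq_len(.N), by = .(qname, tx, pos, strand, mate, mpos)]
  if (any(dt$.dup > 1L)) {
    warning("duplicate read ids with identical alignments; ",
            "treated as distinct reads")
    dt[.dup > 1L, qname := paste0(qname, "#dup", .dup)]
  }
  dt[, .dup := NULL]

  discarded <- setNames(numeric(length(.discardReasons)), .discardReasons)
  seen <- uniqueN(dt$qname)
  dropStage <- function(keepRows, reason) {
    before <- unique(dt$qname)
    dt <<- dt[keepRows]
    gone <- setdiff(before, unique(dt$qname))
    discarded[reason] <<- discarded[reason] + length(gone)
  }

  dropStage(dt$mapped & !is.na(dt$tx), "unmapped")
  if (nrow(dt)) {
    unknown <- setdiff(unique(dt$tx), index@txId)
    if (length(unknown))
      stop("alignments reference transcripts absent from the index: ",
           paste(head(unknown, 5), collapse = ", "))
  }
  dropStage(dt$cigarOK, "clipped_or_gapped")
  if (index@stranded && nrow(dt)) {
    if (any(dt$mate > 0L)) {
      # stranded FR pair: mate 1 forward, mate 2 reverse
      dropStage((dt$mate == 1L & dt$strand == "+") |
                (dt$mate == 2L & dt$strand == "-") |
                dt$mate == 0L, "wrong_strand")
    } else {
      dropStage(dt$strand == "+", "wrong_strand")
    }
  }

  paired <- nrow(dt) && any(dt$mate > 0L)
  rl <- index@readLength
  if (paired) {
    m1 <- dt[mate == 1L]
    m2 <- dt[mate == 2L, .(qname, tx, pos2 = pos, mpos2 = mpos, nm2 = nm)]
    before <- unique(dt$qname)
    units <- merge(m1, m2,
                   by.x = c("qname", "tx", "pos", "mpos"),
                   by.y = c("qname", "tx", "mpos2", "pos2"),
                   allow.cartesian = TRUE)
    units[, nm := nm + nm2]
    units[, frag := inferFragmentSize(pos, pos + rl, mpos, mpos + rl)]
    dt <- units[, .(qname, tx, pos, strand, nm, frag)]
    gone <- setdiff(before, unique(dt$qname))
    discarded["unpaired_mate"] <- discarded["unpaired_mate"] + length(gone)
  } else {
    dt[, frag := rl]
  }

  if (!nrow(dt)) {
    return(new("SegmentCounts",
      counts = numeric(length(index@segClassKey)),
      classKey = index@segClassKey, totalCounted = 0,
      totalDiscarded = sum(discarded), discarded = discarded,
      fragDist = if (length(index@fragRange)) numeric(0)
                 else setNames(1, as.character(rl))))
  }

  dt <- filterBestAlignments(dt)
  dt[, .n := .N, by = qname]
  dropStage(dt$.n <= maxAlignments, "too_many_alignments")
  dt[, .n := NULL]
  if (paired && nrow(dt)) {
    dt[, .nf := uniqueN(frag), by = qname]
    dropStage(dt$.nf == 1L, "ambiguous_fragment_size")
    if (".nf" %in% names(dt)) dt[, .nf := NULL]
  }

  if (!nrow(dt)) {
    classKeys <- character(0)
  } else {
    dt[, txIdx := match(tx, index@txId)]
    byTx <- dt[, .N, by = .(qname, txIdx)]
    setorder(byTx, qname, txIdx)
    keys <- byTx[, .(key = paste(paste0(txIdx, ":", N), collapse = ";"),
                     frag = NA_integer_), by = qname]
    keys[, seg := match(key, index@segClassKey)]
    fragByRead <- dt[, .(frag = frag[1L]), by = qname]
    keys[, frag := fragByRead$frag[match(qname, fragByRead$qname)]]
    bad <- keys[is.na(seg)]
    discarded["unindexed_class"] <- discarded["unindexed_class"] + nrow(bad)
    keys <- keys[!is.na(seg)]
  }

  countsVec <- numeric(length(index@segClassKey))
  fragDist <- numeric(0)
  totalCounted <- 0
  if (nrow(dt) && nrow(keys)) {
    tabSeg <- keys[, .N, by = seg]
    countsVec[tabSeg$seg] <- tabSeg$N
    totalCounted <- as.numeric(nrow(keys))
    if (length(index@fragRange)) {
      h <- table(keys$frag)
      sizes <- as.integer(names(h))
      inRange <- sizes >= index@fragRange[1] & sizes <= index@fragRange[2]
      h <- h[inRange]
      if (sum(h) > 0)
        fragDist <- setNames(as.numeric(h) / sum(h), names(h))
    } else {
      fragDist <- setNames(1, as.character(rl))
    }
  } else if (!length(index@fragRange)) {
    fragDist <- setNames(1, as.character(rl))
  }

  new("SegmentCounts",
      counts = countsVec, classKey = index@segClassKey,
      totalCounted = totalCounted,
      totalDiscarded = as.numeric(seen) - totalCounted,
      discarded = discarded, fragDist = fragDist)
})
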