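#' Cluster identical read-length substrings across a transcriptome
#'
#' Enumerates every length-`k` substring (virtual read) of every
#' transcript and groups positions whose substrings are identical; in
#' unstranded mode a substring and its reverse complement share the
#' lexicographically smaller representative. Substrings containing a
#' non-ACGT base produce no virtual read and are excluded.
#'
#' @param transcripts a `DNAStringSet`, FASTA path, or named character
#'   vector of transcript sequences.
#' @param k substring length in bases (the read length).
#' @param stranded logical; if `FALSE`, reverse-complement substrings are
#'   merged into one cluster.
#' @param keepKmer keep the substring itself as a column (used by the
#'   exact-match aligner; roughly doubles memory).
#' @return a `data.table` with columns `cluster` (integer id; two rows
#'   share an id iff their substrings are identical, up to reverse
#'   complement when unstranded), `tx` (transcript index), `offset`
#'   (0-based start). Empty (with a warning) when `k` exceeds every
#'   transcript length.
#' @seealso [deriveSegmentsSingleEnd()], [buildIndex()]
#' @export
clusterSubstrings <- function(transcripts, k, stranded = TRUE,
                              keepKmer = FALSE) {
  stopifnot(k >= 1)
  seqs <- .asTranscripts(transcripts)
  if (length(seqs) == 0L) stop("empty transcriptome")
  chars <- as.character(seqs)
  widths <- nchar(chars)
  usable <- which(widths >= k)
  if (!length(usable)) {
    warning("k = ", k, " exceeds every transcript length; no clusters")
    return(data.table(cluster = integer(), tx = integer(),
                      offset = integer()))
  }
  pieces <- lapply(usable, function(i) {
    n <- widths[i] - k + 1L
    starts <- seq_len(n)
    data.table(tx = i, offset = starts - 1L,
               kmer = substring(chars[i], starts, starts + k - 1L))
  })
  dt <- rbindlist(pieces)
  dt <- dt[!grepl("[^ACGT]", kmer)]
  if (!nrow(dt)) {
    warning("all length-", k, " substrings contain non-ACGT bases")
    return(data.table(cluster = integer(), tx = integer(),
                      offset = integer()))
  }
  if (!stranded) dt[, kmer := .canonicalKmer(kmer)]
  dt[, cluster := match(kmer, unique(kmer))]
  if (!keepKmer) dt[, kmer := NULL]
  setcolorder(dt, intersect(c("cluster", "tx", "offset", "kmer"), names(dt)))
  setorder(dt, cluster, tx, offset)
  dt[]
}

# shared: turn a (cluster, tx) table into segments.
# each cluster is one distinct virtual read; clusters with the same
# alignment class (multiset of transcript positions) merge into a segment
# whose length is the number of merged clusters.
.segmentsFromClusters <- function(clusters, sizeLabel) {
  agg <- clusters[, .N, by = .(cluster, tx)]
  setorder(agg, cluster, tx)
  keys <- agg[, .(key = paste(paste0(tx, ":", N), collapse = ";")),
              by = cluster]
  tab <- keys[, .(len = .N), by = key]
  parsed <- .parseClassKeys(tab$key)
  psl <- matrix(as.integer(tab$len), ncol = 1L,
                dimnames = list(NULL, as.character(sizeLabel)))
  list(classKey = tab$key,
       members = lapply(parsed, `[[`, "members"),
       mult = lapply(parsed, `[[`, "mult"),
       perSizeLength = psl)
}

#' Derive single-end segments from substring clusters
#'
#' Each cluster from [clusterSubstrings()] is one distinct virtual read;
#' its alignment class is the multiset of (transcript, number of cluster
#' positions on that transcript). Clusters with equal classes merge into
#' one segment whose length at the read length is the number of merged
#' clusters.
#'
#' @param clusters output of [clusterSubstrings()] with `k` equal to the
#'   read length.
#' @param readLength the read length used for clustering.
#' @return a segment table: list with `classKey`, `members`, `mult`,
#'   `perSizeLength` (one column named by the read length).
#' @export
deriveSegmentsSingleEnd <- function(clusters, readLength) {
  if (!nrow(clusters)) {
    return(list(classKey = character(), members = list(), mult = list(),
                perSizeLength = matrix(integer(), ncol = 1L,
                  dimnames = list(NULL, as.character(readLength)))))
  }
  .segmentsFromClusters(clusters, readLength)
}

#' Derive paired-end segments with fragment-size-specific lengths
#'
#' For each fragment size `F` in the indexed range, every transcript
#' position pair `(p, p + F - readLength)` (0-based) defines a virtual
#' paired read: two read-length mates whose end-to-end span is `F`.
#' Identical mate-sequence pairs cluster into alignment classes; in
#' unstranded mode a pair and its opposite-orientation reverse complement
#' are identified. `perSizeLength[, F]` counts the distinct virtual pairs
#' of each class at size `F`.
#'
#' @inheritParams clusterSubstrings
#' @param readLength mate length in bases.
#' @param fragRange integer(2), inclusive fragment-size range; the
#'   minimum must be at least `readLength`.
#' @return a segment table as in [deriveSegmentsSingleEnd()], with one
#'   `perSizeLength` column per fragment size.
#' @export
deriveSegmentsPairedEnd <- function(transcripts, readLength, fragRange,
                                    stranded = TRUE) {
  if (length(fragRange) != 2L || anyNA(fragRange) ||
      fragRange[1] > fragRange[2])
    stop("fragRange must be c(min, max) with min <= max")
  if (fragRange[1] < readLength)
    stop("minimum fragment size must be >= the read length")
  seqs <- .asTranscripts(transcripts)
  chars <- as.character(seqs)
  widths <- nchar(chars)
  k <- as.integer(readLength)
  sizes <- seq.int(fragRange[1], fragRange[2])
  perSize <- vector("list", length(sizes))
  allKeys <- character()
  for (si in seq_along(sizes)) {
    F <- sizes[si]
    usable <- which(widths >= F)
    if (!length(usable)) next
    pieces <- lapply(usable, function(i) {
      n <- widths[i] - F + 1L
      p <- seq_len(n)   # 1-based start of mate 1
      m1 <- substring(chars[i], p, p + k - 1L)
      m2 <- substring(chars[i], p + F - k, p + F - 1L)
      data.table(tx = i, m1 = m1, m2 = m2)
    })
    dt <- rbindlist(pieces)
    dt <- dt[!grepl("[^ACGT]", m1) & !grepl("[^ACGT]", m2)]
    if (!nrow(dt)) next
    if (stranded) {
      dt[, pair := paste0(m1, "|", m2)]
    } else {
      # swapped-mate opposite-strand orientation reads the same fragment
      rc1 <- .revComp(dt$m1); rc2 <- .revComp(dt$m2)
      fwd <- paste0(dt$m1, "|", dt$m2)
      rev <- paste0(rc2, "|", rc1)
      dt[, pair := ifelse(fwd <= rev, fwd, rev)]
    }
    dt[, cluster := match(pair, unique(pair))]
    seg <- .segmentsFromClusters(dt[, .(cluster, tx)], F)
    perSize[[si]] <- setNames(as.integer(seg$perSizeLength[, 1L]),
                              seg$classKey)
    allKeys <- union(allKeys, seg$classKey)
  }
  if (!length(allKeys))
    stop("no virtual paired reads in the given fragment-size range")
  psl <- matrix(0L, nrow = length(allKeys), ncol = length(sizes),
                dimnames = list(NULL, as.character(sizes)))
  for (si in seq_along(sizes)) {
    v <- perSize[[si]]
    if (!is.null(v)) psl[match(names(v), allKeys), si] <- v
  }
  parsed <- .parseClassKeys(allKeys)
  list(classKey = allKeys,
       members = lapply(parsed, `[[`, "members"),
       mult = lapply(parsed, `[[`, "mult"),
       perSizeLength = psl)
}

#' Weight segment lengths by a fragment-size distribution
#'
#' Sets each segment's overall length to the average of its
#' fragment-size-specific lengths weighted by the probability of each
#' size: `L_C = sum_F P(F) * perSizeLength_C(F)`. The distribution is
#' truncated to the indexed sizes and renormalized; for single-end
#' fixed-length data the point mass at the read length leaves the
#' per-size value unchanged.
#'
#' @param index a [TranscriptomeIndex-class].
#' @param fragDist named numeric: probabilities named by fragment size
#'   (e.g. [fragmentSizeDistribution()] of a [SegmentCounts-class]).
#' @return the index with `weightedLength` updated.
#' @export
weightSegmentLengths <- function(index, fragDist) {
  stopifnot(is(index, "TranscriptomeIndex"))
  sizes <- colnames(index@perSizeLength)
  p <- fragDist[names(fragDist) %in% sizes]
  if (!length(p) || sum(p) <= 0)
    stop("fragment-size distribution lies entirely outside the indexed range")
  p <- p / sum(p)
  w <- as.numeric(index@perSizeLength[, names(p), drop = FALSE] %*% p)
  index@weightedLength <- w
  index
}

# union-find with path halving; members is a list of integer vectors
.connectedSets <- function(membersList, nTx) {
  parent <- seq_len(nTx)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (m in membersList) {
    u <- unique(m)
    if (length(u) > 1L) {
      r <- find(u[1L])
      for (j in u[-1L]) {
        rj <- find(j)
        if (rj != r) parent[rj] <- r
      }
    }
  }
  root <- vapply(seq_len(nTx), find, integer(1))
  # renumber sets by first transcript appearance for determinism
  ids <- match(root, unique(root))
  list(setId = ids, sets = unname(split(seq_len(nTx), ids)))
}

#' Partition transcripts into sequence-sharing sets
#'
#' Computes the transitive closure of "shares a segment": the minimal
#' partition in which any two transcripts appearing in one alignment
#' class are in the same set. Equivalent to connected components of the
#' transcript-segment incidence graph; transcripts in no shared segment
#' form singleton sets.
#'
#' @param segments a segment table ([deriveSegmentsSingleEnd()] /
#'   [deriveSegmentsPairedEnd()]).
#' @param nTranscripts number of transcripts in the transcriptome.
#' @return list with `setId` (set per segment), `sets` (list of
#'   transcript-index vectors), `txSetId` (set per transcript).
#' @export
buildSharingSets <- function(segments, nTranscripts) {
  if (length(segments$members) &&
      max(unlist(segments$members)) > nTranscripts)
    stop("segments reference unknown transcripts")
  cc <- .connectedSets(segments$members, nTranscripts)
  segSet <- vapply(segments$members, function(m) cc$setId[m[1L]], integer(1))
  list(setId = segSet, sets = cc$sets, txSetId = cc$setId)
}

#' Prune segments until every sequence-sharing set is small enough
#'
#' Very large sets (joint estimation over thousands of transcripts) are
#' broken up by iteratively dropping segments whose weighted length is
#' below a threshold and rebuilding the sets, doubling the threshold
#' until the largest set has at most `maxSetSize` transcripts. Short
#' shared segments carry little information; their reads are discarded at
#' counting time (the dropped class keys are recorded on the index).
#'
#' @param index a [TranscriptomeIndex-class].
#' @param maxSetSize largest permitted set (default 5000 transcripts).
#' @param initialThreshold starting segment-length threshold.
#' @param growthFactor multiplicative threshold schedule.
#' @return the pruned index.
#' @export
pruneLargeSets <- function(index, maxSetSize = 5000,
                           initialThreshold = 2, growthFactor = 2) {
  stopifnot(is(index, "TranscriptomeIndex"), maxSetSize >= 1,
            growthFactor > 1)
  threshold <- initialThreshold
  repeat {
    sizes <- lengths(index@sets)
    if (!length(sizes) || max(sizes) <= maxSetSize) break
    bigSets <- which(sizes > maxSetSize)
    inBig <- index@segSet %in% bigSets
    multi <- lengths(index@segMembers) > 1L
    if (!any(inBig & multi))
      stop("cannot reduce sets below ", maxSetSize,
           " transcripts: degenerate transcriptome")
    drop <- inBig & multi & index@weightedLength < threshold
    if (any(drop)) {
      index@droppedClassKey <- c(index@droppedClassKey,
                                 index@segClassKey[drop])
      keep <- !drop
      index@segClassKey <- index@segClassKey[keep]
      index@segMembers <- index@segMembers[keep]
      index@segMult <- index@segMult[keep]
      index@perSizeLength <- index@perSizeLength[keep, , drop = FALSE]
      index@weightedLength <- index@weightedLength[keep]
      ss <- buildSharingSets(
        list(members = index@segMembers), length(index@txId))
      index@segSet <- ss$setId
      index@sets <- ss$sets
    }
    threshold <- threshold * growthFactor
  }
  validObject(index)
  index
}

#' Build a transcriptome segmentation index
#'
#' Runs the full indexing pipeline: enumerate virtual reads, cluster
#' identical substrings ([clusterSubstrings()] /
#' [deriveSegmentsPairedEnd()]), merge clusters into segments, partition
#' transcripts into sequence-sharing sets ([buildSharingSets()]) and
#' prune oversized sets ([pruneLargeSets()]). Until a dataset supplies an
#' empirical fragment-size distribution, weighted segment lengths are the
#' uniform average over the indexed sizes (for single-end data this *is*
#' the final length).
#'
#' @inheritParams clusterSubstrings
#' @param readLength read length in bases.
#' @param paired index virtual read pairs over `fragRange`.
#' @param fragRange integer(2) fragment-size range (paired only).
#' @param geneMap transcript-to-gene mapping: `NULL` (second FASTA header
#'   token when present, else gene = transcript), a named character
#'   vector, a two-column data.frame, or a TSV path.
#' @param maxSetSize,initialThreshold,growthFactor see [pruneLargeSets()].
#' @return a [TranscriptomeIndex-class].
#' @examples
#' txs <- Biostrings::DNAStringSet(c(t1 = "ACGTACGTGG", t2 = "TTACGTACGA"))
#' idx <- buildIndex(txs, readLength = 4)
#' idx
#' @export
buildIndex <- function(transcripts, readLength, paired = FALSE,
                       fragRange = NULL, stranded = TRUE, geneMap = NULL,
                       maxSetSize = 5000, initialThreshold = 2,
                       growthFactor = 2) {
  stopifnot(readLength >= 1)
  seqs <- .asTranscripts(transcripts)
  genes <- .resolveGeneMap(seqs, geneMap)
  if (paired) {
    if (is.null(fragRange)) stop("paired indexing needs fragRange")
    seg <- deriveSegmentsPairedEnd(seqs, readLength, fragRange, stranded)
    fr <- as.integer(fragRange)
  } else {
    cl <- clusterSubstrings(seqs, readLength, stranded)
    seg <- deriveSegmentsSingleEnd(cl, readLength)
    fr <- integer(0)
  }
  ss <- buildSharingSets(seg, length(seqs))
  idx <- new("TranscriptomeIndex",
    txId = names(seqs), geneId = unname(genes),
    txLength = Biostrings::width(seqs),
    segClassKey = seg$classKey, segMembers = seg$members,
    segMult = seg$mult, perSizeLength = seg$perSizeLength,
    weightedLength = rowMeans(seg$perSizeLength),
    segSet = ss$setId, sets = ss$sets,
    droppedClassKey = character(0),
    readLength = as.integer(readLength), fragRange = fr,
    stranded = stranded, formatVersion = 1L)
  pruneLargeSets(idx, maxSetSize, initialThreshold, growthFactor)
}
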