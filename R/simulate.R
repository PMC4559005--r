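# Synthetic transcriptomes, ground-truth abundances and error-bearing
# reads, so every stage is testable without external data.

#' Specify a simulation
#'
#' Defines a synthetic study: a random transcriptome with paralogous
#' gene pairs, log-normal true abundances, and substitution-error reads.
#' Defaults describe a small but realistic bulk RNA-seq experiment: 200
#' transcripts of 400-2000 bp, 20 paralog pairs differing at 5 positions
#' (close paralogs, ~99.5 % identity at 1 kb), log-normal expression with
#' sdlog 1.5, and 100,000 fixed-length 50 bp single-end reads.
#'
#' @param nTranscripts number of transcripts.
#' @param lengthRange integer(2), uniform transcript-length range (bp).
#' @param paralogPairs number of paralogous pairs (each pair occupies two
#'   consecutive transcripts and two distinct genes).
#' @param paralogDiff number of differing nucleotide positions per pair;
#'   recycled across pairs; 0 makes sequence-identical duplicates.
#' @param abundanceMeanlog,abundanceSdlog log-normal parameters of the
#'   true expression levels (normalized to TPM).
#' @param nReads total reads (or read pairs).
#' @param readLength read length (bp).
#' @param paired simulate read pairs.
#' @param fragMean,fragSd,fragRange normal fragment-size model, truncated
#'   to `fragRange` (paired only).
#' @param errorRate per-base substitution probability in `[0, 1]`.
#' @param stranded reads drawn from the sense strand only.
#' @param seed integer seed; everything downstream is reproducible from it.
#' @return a `SimulationSpec` (validated list).
#' @export
simulationSpec <- function(nTranscripts = 200L, lengthRange = c(400L, 2000L),
                           paralogPairs = 20L, paralogDiff = 5L,
                           abundanceMeanlog = 0, abundanceSdlog = 1.5,
                           nReads = 1e5L, readLength = 50L, paired = FALSE,
                           fragMean = 200, fragSd = 40,
                           fragRange = c(100L, 300L),
                           errorRate = 0, stranded = TRUE, seed = 1L) {
  spec <- list(nTranscripts = as.integer(nTranscripts),
               lengthRange = as.integer(lengthRange),
               paralogPairs = as.integer(paralogPairs),
               paralogDiff = as.integer(paralogDiff),
               abundanceMeanlog = abundanceMeanlog,
               abundanceSdlog = abundanceSdlog,
               nReads = as.integer(nReads),
               readLength = as.integer(readLength),
               paired = isTRUE(paired),
               fragMean = fragMean, fragSd = fragSd,
               fragRange = as.integer(fragRange),
               errorRate = errorRate, stranded = isTRUE(stranded),
               seed = as.integer(seed))
  stopifnot(spec$nTranscripts >= 1, spec$nReads >= 0,
            spec$readLength >= 1,
            spec$errorRate >= 0, spec$errorRate <= 1,
            spec$paralogPairs >= 0,
            2L * spec$paralogPairs <= spec$nTranscripts,
            all(spec$paralogDiff >= 0))
  class(spec) <- "SimulationSpec"
  spec
}

.randomSeq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substitute exactly `at` positions of a sequence with a different base
.substitutePositions <- function(seq, at) {
  ch <- strsplit(seq, "")[[1L]]
  for (p in at) {
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  }
  paste(ch, collapse = "")
}

#' Generate a synthetic transcriptome with ground truth
#'
#' Draws random transcript sequences, turns the first `2 * paralogPairs`
#' of them into paralogous pairs differing at exactly the specified
#' number of positions (0 gives identical duplicates), assigns every
#' transcript its own gene, and draws true expression levels from a
#' log-normal distribution, normalized to TPM. Byte-identical given the
#' same spec (seeded).
#'
#' @param spec a [simulationSpec()].
#' @return list with `transcripts` (named `DNAStringSet`), `geneMap`
#'   (named character), and `truth` (data.frame: `transcript_id`,
#'   `gene_id`, `length`, `tpm`).
#' @export
makeTranscriptome <- function(spec) {
  stopifnot(inherits(spec, "SimulationSpec"))
  .withSeed(spec$seed, {
    n <- spec$nTranscripts
    lens <- as.integer(round(runif(n, spec$lengthRange[1],
                                   spec$lengthRange[2])))
    diffs <- rep_len(spec$paralogDiff, max(spec$paralogPairs, 1L))
    seqs <- character(n)
    for (i in seq_len(n)) seqs[i] <- .randomSeq(lens[i])
    if (spec$paralogPairs > 0) {
      for (p in seq_len(spec$paralogPairs)) {
        a <- 2L * p - 1L; b <- 2L * p
        d <- diffs[p]
        if (d > lens[a]) stop("paralogDiff exceeds transcript length")
        lens[b] <- lens[a]
        seqs[b] <- if (d == 0L) seqs[a] else
          .substitutePositions(seqs[a], sample.int(lens[a], d))
      }
    }
    ids <- sprintf("tx%04d", seq_len(n))
    genes <- sprintf("g%04d", seq_len(n))
    expr <- rlnorm(n, spec$abundanceMeanlog, spec$abundanceSdlog)
    tpm <- expr / sum(expr) * 1e6
    list(transcripts = setNames(Biostrings::DNAStringSet(seqs), ids),
         geneMap = setNames(genes, ids),
         truth = data.frame(transcript_id = ids, gene_id = genes,
                            length = lens, tpm = tpm,
                            stringsAsFactors = FALSE))
  })
}

# apply iid per-base substitution errors; returns list(seq, nErr)
.addErrors <- function(seqs, rate) {
  if (rate <= 0) return(list(seq = seqs, nErr = integer(length(seqs))))
  nErr <- rbinom(length(seqs), nchar(seqs), rate)
  idx <- which(nErr > 0)
  for (i in idx) {
    at <- sample.int(nchar(seqs[i]), nErr[i])
    seqs[i] <- .substitutePositions(seqs[i], at)
  }
  list(seq = seqs, nErr = nErr)
}

#' Simulate reads with known origins
#'
#' Draws reads from transcripts with probability proportional to true
#' abundance times virtual length (the number of distinct start
#' positions at the sampled fragment size), start positions uniform,
#' substitution errors i.i.d. per base. Transcripts shorter than the
#' read (or sampled fragment) yield no reads. The true origin of every
#' read is returned for round-trip tests.
#'
#' @param txome output of [makeTranscriptome()] (or a compatible list
#'   with `transcripts` and `truth`).
#' @param spec the [simulationSpec()] controlling reads, errors and seed
#'   (the read-generation stream is offset from the transcriptome
#'   stream, so the same spec gives a reproducible full experiment).
#' @return a data.frame with one row per read: `qname`, `tx`, `pos`
#'   (0-based), `frag` (fragment size; read length for single-end),
#'   `seq`, `nErr` (and `seq2`, `nErr2` for pairs).
#' @seealso [writeReadsFastq()], [writeAlignmentsSam()]
#' @export
simulateReads <- function(txome, spec) {
  stopifnot(inherits(spec, "SimulationSpec"))
  chars <- as.character(txome$transcripts)
  lens <- nchar(chars)
  tpm <- txome$truth$tpm
  rl <- spec$readLength
  .withSeed(spec$seed + 104729L, {
    if (spec$paired) {
      fragSizes <- pmin(pmax(round(rnorm(spec$nReads, spec$fragMean,
                                         spec$fragSd)),
                             spec$fragRange[1]), spec$fragRange[2])
      fragSizes <- pmax(fragSizes, rl)
      # weight at the mean fragment size; reject-and-redraw transcripts
      # too short for the drawn fragment
      w <- tpm * pmax(0, lens - round(spec$fragMean) + 1)
    } else {
      fragSizes <- rep(rl, spec$nReads)
      w <- tpm * pmax(0, lens - rl + 1)
    }
    if (all(w == 0)) stop("no transcript long enough to emit reads")
    if (any(tpm > 0 & pmax(0, lens - rl + 1) == 0))
      warning("some expressed transcripts are shorter than the read ",
              "length and yield no reads")
    tx <- sample.int(length(lens), spec$nReads, replace = TRUE,
                     prob = w / sum(w))
    # redraw fragment sizes that do not fit their transcript
    bad <- which(fragSizes > lens[tx])
    while (length(bad)) {
      fragSizes[bad] <- pmax(pmin(round(rnorm(length(bad), spec$fragMean,
                                              spec$fragSd)),
                                  spec$fragRange[2], lens[tx[bad]]),
                             rl)
      bad <- bad[fragSizes[bad] > lens[tx[bad]]]
    }
    maxStart <- lens[tx] - fragSizes + 1L
    pos <- as.integer(floor(runif(spec$nReads) * maxStart))  # 0-based
    m1 <- substring(chars[tx], pos + 1L, pos + rl)
    e1 <- .addErrors(m1, spec$errorRate)
    out <- data.frame(qname = sprintf("read%07d", seq_len(spec$nReads)),
                      tx = names(txome$transcripts)[tx],
                      pos = pos, frag = fragSizes,
                      seq = e1$seq, nErr = e1$nErr,
                      stringsAsFactors = FALSE)
    if (spec$paired) {
      m2 <- substring(chars[tx], pos + fragSizes - rl + 1L,
                      pos + fragSizes)
      m2 <- .revComp(m2)  # FR orientation: mate 2 on the reverse strand
      e2 <- .addErrors(m2, spec$errorRate)
      out$seq2 <- e2$seq
      out$nErr2 <- e2$nErr
    }
    out
  })
}

#' Write simulated reads as FASTQ
#'
#' Constant quality `'I'` (the simulator does not model qualities).
#' Paired reads go to `<prefix>_1.fastq` / `<prefix>_2.fastq`, single-end
#' to `<prefix>.fastq`.
#'
#' @param reads output of [simulateReads()].
#' @param prefix output path prefix.
#' @return written paths, invisibly.
#' @export
writeReadsFastq <- function(reads, prefix) {
  writeOne <- function(seqs, names, path) {
    x <- Biostrings::DNAStringSet(setNames(seqs, names))
    .atomicWrite(path, function(p)
      Biostrings::writeXStringSet(
        x, p, format = "fastq",
        qualities = Biostrings::BStringSet(strrep("I", nchar(seqs)))))
  }
  if (!is.null(reads$seq2)) {
    p1 <- paste0(prefix, "_1.fastq"); p2 <- paste0(prefix, "_2.fastq")
    writeOne(reads$seq, reads$qname, p1)
    writeOne(reads$seq2, reads$qname, p2)
    invisible(c(p1, p2))
  } else {
    p <- paste0(prefix, ".fastq")
    writeOne(reads$seq, reads$qname, p)
    invisible(p)
  }
}

#' Write an alignment table as SAM
#'
#' Serializes alignments (e.g. the simulator's true origins, or
#' [alignPerfect()] output) as a SAM file with proper `@SQ` headers, `NM`
#' tags and `<readLength>M` CIGARs, so the counting stage can consume it
#' through the standard SAM/BAM path. Multiple alignments of one read are
#' written as one primary plus secondary records.
#'
#' @param alignments data.frame with `qname`, `tx`, `pos` (0-based),
#'   `strand`, `nm`, optional `seq`.
#' @param transcripts the reference `DNAStringSet` (for header lengths).
#' @param path output SAM path.
#' @param readLength read length (CIGAR).
#' @return `path`, invisibly.
#' @export
writeAlignmentsSam <- function(alignments, transcripts, path, readLength) {
  al <- as.data.table(alignments)
  setorder(al, qname, tx, pos)
  al[, .rank := seq_len(.N), by = qname]
  flag <- ifelse(al$strand == "-", 16L, 0L) +
    ifelse(al$.rank > 1L, 256L, 0L)
  seqField <- if ("seq" %in% names(al)) al$seq else rep("*", nrow(al))
  qualField <- ifelse(seqField == "*", "*", strrep("I", nchar(seqField)))
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(transcripts),
                      Biostrings::width(transcripts)),
              "@PG\tID:segquant\tPN:segquant")
  body <- sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t%s\tNM:i:%d",
                  al$qname, flag, al$tx, al$pos + 1L, readLength,
                  seqField, qualField, al$nm)
  .atomicWrite(path, function(p) writeLines(c(header, body), p))
  invisible(path)
}

#' Exhaustive perfect-match alignment of fixed-length reads
#'
#' Reports every position in the transcriptome whose substring equals
#' the read exactly (unstranded: or its reverse complement) -- all
#' alignments, zero mismatches. Used to exercise the counting and
#' estimation stages on error-free simulations without an external
#' aligner.
#'
#' @param reads data.frame with `qname` and `seq` (all the same length).
#' @param transcripts reference `DNAStringSet` (or FASTA path).
#' @param stranded match the forward strand only.
#' @return alignment data.frame (`qname`, `tx`, `pos`, `strand`, `nm`,
#'   `seq`) suitable for [countReads()] / [writeAlignmentsSam()]; reads
#'   with no perfect match are absent.
#' @export
alignPerfect <- function(reads, transcripts, stranded = TRUE) {
  seqs <- .asTranscripts(transcripts)
  rl <- unique(nchar(reads$seq))
  if (length(rl) != 1L)
    stop("alignPerfect requires fixed-length reads")
  km <- clusterSubstrings(seqs, rl, stranded = stranded, keepKmer = TRUE)
  rdt <- data.table(qname = reads$qname, seq = reads$seq)
  rdt[, key := if (stranded) seq else .canonicalKmer(seq)]
  hits <- km[rdt, on = .(kmer = key), allow.cartesian = TRUE, nomatch = NULL]
  if (!nrow(hits))
    return(data.frame(qname = character(), tx = character(),
                      pos = integer(), strand = character(),
                      nm = integer(), seq = character(),
                      stringsAsFactors = FALSE))
  out <- data.frame(qname = hits$qname, tx = names(seqs)[hits$tx],
                    pos = hits$offset,
                    strand = "+", nm = 0L, seq = hits$seq,
                    stringsAsFactors = FALSE)
  if (!stranded) {
    # orientation of the hit: "-" when the read matches the reverse strand
    ref <- substring(as.character(seqs)[hits$tx], hits$offset + 1L,
                     hits$offset + rl)
    out$strand <- ifelse(ref == hits$seq, "+", "-")
  }
  out
}

#' The two-gene worked example
#'
#' The canonical small instance motivating joint estimation: two
#' single-isoform genes of total (virtual) lengths 10 and 20 sharing a
#' multiply-alignable region of length 3, leaving uniquely mappable
#' lengths 7 and 17; 70 and 340 reads map uniquely to each gene and 90
#' map to both. Three segments, three Poisson equations, two unknowns;
#' the MLE is (10, 20) reads per unit and the 90 shared reads split
#' 30:60.
#'
#' @return list with `A` (3 x 2 class matrix), `lengths` (7, 17, 3),
#'   `counts` (70, 340, 90), `fullLength` (10, 20), `txId`.
#' @seealso [multireadStrategies()], [twoGeneTranscriptome()]
#' @export
twoGeneExample <- function() {
  list(A = matrix(c(1, 0, 1,
                    0, 1, 1), ncol = 2L,
                  dimnames = list(NULL, c("gene1", "gene2"))),
       lengths = c(7, 17, 3),
       counts = c(70, 340, 90),
       fullLength = c(10, 20),
       txId = c("gene1", "gene2"))
}

#' Sequences realizing the two-gene worked example
#'
#' Builds two transcripts that segment exactly as [twoGeneExample()]:
#' with read length `k`, transcript 1 has 10 virtual reads (7 unique),
#' transcript 2 has 20 (17 unique), and they share a common suffix
#' contributing 3 shared virtual reads. Sequences are drawn under the
#' seed and redrawn until all substrings are collision-free, so the
#' segment structure is exact by construction.
#'
#' @param readLength virtual read length `k` (>= 4).
#' @param seed integer seed.
#' @return list with `transcripts` (named `DNAStringSet`) and `geneMap`.
#' @export
twoGeneTranscriptome <- function(readLength = 20L, seed = 7L) {
  k <- as.integer(readLength)
  stopifnot(k >= 4)
  .withSeed(seed, {
    for (attempt in 1:100) {
      shared <- .randomSeq(k + 2L)          # 3 shared virtual reads
      u1 <- .randomSeq(7L)                  # 7 unique positions on tx1
      u2 <- .randomSeq(17L)                 # 17 unique positions on tx2
      t1 <- paste0(u1, shared)
      t2 <- paste0(u2, shared)
      km <- c(substring(t1, 1:(nchar(t1) - k + 1L), k:nchar(t1)),
              substring(t2, 1:(nchar(t2) - k + 1L), k:nchar(t2)))
      # the only repeats must be the 3 shared suffix substrings
      if (sum(duplicated(km)) == 3L) {
        return(list(
          transcripts = setNames(Biostrings::DNAStringSet(c(t1, t2)),
                                 c("tx1", "tx2")),
          geneMap = c(tx1 = "gene1", tx2 = "gene2")))
      }
    }
  })
  stop("could not build a collision-free two-gene transcriptome")
}

# hamming distance between equal-length strings, vectorized over x
.hamming <- function(x, ref) {
  refCh <- strsplit(ref, "")[[1L]]
  m <- matrix(unlist(strsplit(x, "")), nrow = nchar(ref))
  colSums(m != refCh)
}

#' Alignment-strategy experiment on three similar short genes
#'
#' Reproduces the design probing how mismatch-tolerant alignment biases
#' unique-read counts: three 56-bp genes, two identical except at two
#' positions and one dissimilar, 1000 full-length reads per gene with
#' i.i.d. substitution errors, aligned by exhaustive Hamming comparison
#' against all three references (no external aligner). Strategies:
#' `perfect_match` keeps 0-mismatch alignments, `all_k_mismatches` all
#' alignments with at most `maxMismatch`, `best_k_mismatches` each
#' read's minimum-mismatch alignments. Only uniquely mapped reads are
#' kept; reported per gene as fractions of the uniquely mapped reads,
#' together with the mapping percentage.
#'
#' @param errorRates per-base substitution rates to simulate.
#' @param nReadsPerGene reads per gene (default 1000).
#' @param maxMismatch mismatch allowance `k` (default 2).
#' @param strategies subset of the three strategies.
#' @param geneLength gene/read length (default 56).
#' @param seed integer seed.
#' @return data.frame with one row per (errorRate, strategy, gene):
#'   `fraction` (of uniquely mapped reads) and `mappedPct` (uniquely
#'   mapped reads as a percentage of all reads for that strategy).
#' @export
mismatchStrategyExperiment <- function(errorRates = c(0.001, 0.005, 0.01, 0.05),
                                       nReadsPerGene = 1000L,
                                       maxMismatch = 2L,
                                       strategies = c("perfect_match",
                                                      "all_k_mismatches",
                                                      "best_k_mismatches"),
                                       geneLength = 56L, seed = 1L) {
  strategies <- match.arg(strategies, several.ok = TRUE)
  .withSeed(seed, {
    # two near-identical genes plus one dissimilar gene
    g1 <- .randomSeq(geneLength)
    g2 <- .substitutePositions(g1, sample.int(geneLength, 2L))
    repeat {
      g3 <- .randomSeq(geneLength)
      if (.hamming(g3, g1) > 10 && .hamming(g3, g2) > 10) break
    }
    refs <- c(g1, g2, g3)
    out <- list()
    for (rate in errorRates) {
      true <- rep(1:3, each = nReadsPerGene)
      reads <- .addErrors(refs[true], rate)$seq
      d <- vapply(refs, function(r) .hamming(reads, r),
                  numeric(length(reads)))  # reads x 3 genes
      for (strat in strategies) {
        keep <- switch(strat,
          perfect_match = d == 0,
          all_k_mismatches = d <= maxMismatch,
          best_k_mismatches = {
            mins <- apply(d, 1L, min)
            d == mins & mins <= maxMismatch
          })
        nAlign <- rowSums(keep)
        uniq <- nAlign == 1L
        mappedGene <- max.col(keep, ties.method = "first")
        tab <- tabulate(mappedGene[uniq], nbins = 3L)
        frac <- if (sum(uniq)) tab / sum(uniq) else rep(NA_real_, 3L)
        out[[length(out) + 1L]] <- data.frame(
          errorRate = rate, strategy = strat, gene = 1:3,
          fraction = frac,
          mappedPct = 100 * sum(uniq) / length(uniq),
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, out)
  })
}
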