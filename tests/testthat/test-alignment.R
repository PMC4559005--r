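test_that("best filtering keeps exactly the minimum-mismatch alignments", {
  df <- data.frame(qname = "r1", tx = c("a", "b", "c"), pos = 0:2,
                   strand = "+", nm = c(0L, 0L, 2L))
  out <- filterBestAlignments(df)
  expect_identical(sort(out$tx), c("a", "b"))
  expect_true(all(out$nm == 0))

  # random mismatch vectors: retained set equals an independent argmin
  set.seed(101)
  for (i in 1:20) {
    n <- sample(1:8, 1)
    nm <- sample(0:4, n, replace = TRUE)
    df <- data.frame(qname = "r", tx = paste0("t", seq_len(n)),
                     pos = seq_len(n), strand = "+", nm = nm)
    out <- filterBestAlignments(df)
    expect_setequal(out$tx, df$tx[nm == min(nm)])
  }
})

test_that("fragment size is the end-to-end mate span", {
  expect_identical(inferFragmentSize(100, 200, 250, 350), 250)
  expect_identical(inferFragmentSize(250, 350, 100, 200), 250)  # swapped
})

test_that("alignment classes resolve by transcript position multiset", {
  tg <- twoGeneTranscriptome(readLength = 20)
  idx <- buildIndex(tg$transcripts, 20, geneMap = tg$geneMap)
  hit <- resolveAlignmentClass(c("tx1", "tx2"), idx)
  expect_false(is.na(hit$segment))
  expect_identical(hit$key, "1:1;2:1")
  # multiplicity matters: {tx1:2, tx2:1} is a different (absent) class
  miss <- resolveAlignmentClass(c("tx1", "tx1", "tx2"), idx)
  expect_true(is.na(miss$segment))
  expect_identical(miss$reason, "unindexed_class")
  expect_error(resolveAlignmentClass("nope", idx), "unknown transcript")
})

test_that("the two-gene read configuration counts into its three segments", {
  tg <- twoGeneTranscriptome(readLength = 20)
  idx <- buildIndex(tg$transcripts, 20, geneMap = tg$geneMap)
  aln <- twoGeneAlignments(tg, readLength = 20)
  sc <- countReads(aln, idx)
  got <- counts(sc)
  expect_identical(unname(got[c("1:1", "2:1", "1:1;2:1")]),
                   c(70, 340, 90))
  expect_identical(sc@totalCounted, 500)
  expect_identical(sc@totalDiscarded, 0)

  # order independence: a shuffled stream gives identical counts
  set.seed(5)
  sc2 <- countReads(aln[sample(nrow(aln)), ], idx)
  expect_identical(counts(sc2), got)
})

test_that("empty input yields zero counts and totals", {
  tg <- twoGeneTranscriptome(readLength = 20)
  idx <- buildIndex(tg$transcripts, 20)
  sc <- countReads(data.frame(qname = character(), tx = character(),
                              pos = integer(), strand = character(),
                              nm = integer()), idx)
  expect_identical(sc@totalCounted, 0)
  expect_true(all(counts(sc) == 0))
})

test_that("every read is accounted for across discard reasons", {
  tg <- twoGeneTranscriptome(readLength = 20)
  idx <- buildIndex(tg$transcripts, 20)
  aln <- rbind(
    data.frame(qname = "ok", tx = "tx1", pos = 0, strand = "+", nm = 0,
               cigarOK = TRUE, mapped = TRUE),
    data.frame(qname = "clip", tx = "tx1", pos = 1, strand = "+", nm = 0,
               cigarOK = FALSE, mapped = TRUE),
    data.frame(qname = "anti", tx = "tx1", pos = 2, strand = "-", nm = 0,
               cigarOK = TRUE, mapped = TRUE),
    data.frame(qname = "lost", tx = NA, pos = NA, strand = "+", nm = NA,
               cigarOK = TRUE, mapped = FALSE),
    data.frame(qname = "odd", tx = c("tx1", "tx1"), pos = c(0, 3),
               strand = "+", nm = 0, cigarOK = TRUE, mapped = TRUE))
  sc <- countReads(aln, idx)
  d <- discardSummary(sc)
  expect_identical(sc@totalCounted, 1)             # "ok" only
  expect_identical(unname(d["clipped_or_gapped"]), 1)
  expect_identical(unname(d["wrong_strand"]), 1)
  expect_identical(unname(d["unmapped"]), 1)
  expect_identical(unname(d["unindexed_class"]), 1)  # {tx1:2} not indexed
  expect_identical(sc@totalCounted + sc@totalDiscarded, 5)
})

test_that("the per-read alignment cap and duplicates are enforced", {
  tg <- twoGeneTranscriptome(readLength = 20)
  idx <- buildIndex(tg$transcripts, 20)
  many <- data.frame(qname = "r", tx = "tx2", pos = 0:9, strand = "+",
                     nm = 0)
  sc <- countReads(many, idx, maxAlignments = 5)
  expect_identical(unname(discardSummary(sc)["too_many_alignments"]), 1)

  dup <- data.frame(qname = c("r", "r"), tx = "tx1", pos = 0,
                    strand = "+", nm = 0)
  expect_warning(sc <- countReads(dup, idx), "distinct reads")
  expect_identical(sc@totalCounted, 2)   # counted each time
})

test_that("paired counting infers sizes and discards ambiguity", {
  set.seed(31)
  seqs <- setNames(Biostrings::DNAStringSet(paste(
    sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")), "t1")
  idx <- buildIndex(seqs, 50, paired = TRUE, fragRange = c(150, 250))
  mk <- function(qname, p1, p2, nm1 = 0, nm2 = 0) {
    rbind(data.frame(qname = qname, tx = "t1", pos = p1, strand = "+",
                     nm = nm1, mate = 1L, mpos = p2, mapped = TRUE),
          data.frame(qname = qname, tx = "t1", pos = p2, strand = "-",
                     nm = nm2, mate = 2L, mpos = p1, mapped = TRUE))
  }
  aln <- rbind(mk("a", 0, 150),        # fragment 200
               mk("b", 10, 110),       # fragment 150
               mk("amb", 0, 150), mk("amb", 0, 100))  # sizes 200 and 150
  sc <- countReads(aln, idx)
  expect_identical(sc@totalCounted, 2)
  expect_identical(unname(discardSummary(sc)["ambiguous_fragment_size"]), 1)
  expect_equal(sum(fragmentSizeDistribution(sc)), 1)
  expect_setequal(names(fragmentSizeDistribution(sc)), c("150", "200"))

  # best filtering acts on the pair's summed mismatches
  aln2 <- rbind(mk("c", 0, 150, 0, 0), mk("c", 20, 170, 1, 1))
  sc2 <- countReads(aln2, idx)
  expect_identical(sc2@totalCounted, 1)
  expect_identical(unname(fragmentSizeDistribution(sc2)["200"]), 1)
})

test_that("error-free simulated reads all land in indexed classes", {
  spec <- simulationSpec(nTranscripts = 20, paralogPairs = 4,
                         nReads = 2000, readLength = 30,
                         lengthRange = c(150, 400), seed = 17)
  txome <- makeTranscriptome(spec)
  idx <- buildIndex(txome$transcripts, 30, geneMap = txome$geneMap)
  reads <- simulateReads(txome, spec)
  aln <- alignPerfect(reads, txome$transcripts)
  sc <- countReads(aln, idx)
  expect_identical(unname(discardSummary(sc)["unindexed_class"]), 0)
  expect_identical(sc@totalCounted, 2000)

  # per-read brute-force classification agrees with the counted totals
  classOf <- vapply(split(aln$tx, aln$qname), function(txs) {
    t <- table(match(txs, txIds(idx)))
    paste(paste0(names(t), ":", as.integer(t)), collapse = ";")
  }, character(1))
  brute <- table(classOf)
  got <- counts(sc)
  expect_identical(unname(got[names(brute)]), as.numeric(brute))
})

test_that("SAM files round-trip through the counting stage", {
  spec <- simulationSpec(nTranscripts = 8, paralogPairs = 2, nReads = 300,
                         readLength = 30, lengthRange = c(100, 250),
                         seed = 23)
  txome <- makeTranscriptome(spec)
  idx <- buildIndex(txome$transcripts, 30, geneMap = txome$geneMap)
  reads <- simulateReads(txome, spec)
  aln <- alignPerfect(reads, txome$transcripts)
  sam <- file.path(tempdir(), "roundtrip.sam")
  writeAlignmentsSam(aln, txome$transcripts, sam, 30)
  scFile <- countReads(sam, idx)
  scDf <- countReads(aln, idx)
  expect_identical(counts(scFile), counts(scDf))
  expect_identical(scFile@totalCounted, scDf@totalCounted)
})

test_that("mismatch counts fall back to the MD tag", {
  tg <- twoGeneTranscriptome(readLength = 20)
  w <- Biostrings::width(tg$transcripts)
  sam <- file.path(tempdir(), "md.sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", names(tg$transcripts), w),
    # r1: 0 mismatches on tx1; 2 mismatches on tx2 (MD only)
    sprintf("r1\t0\ttx1\t1\t255\t20M\t*\t0\t0\t%s\t%s\tMD:Z:20",
            strrep("A", 20), strrep("I", 20)),
    sprintf("r1\t256\ttx2\t1\t255\t20M\t*\t0\t0\t%s\t%s\tMD:Z:5A4C9",
            strrep("A", 20), strrep("I", 20))), sam)
  a <- readAlignments(sam)
  expect_identical(a$nm, c(0L, 2L))
  idx <- buildIndex(tg$transcripts, 20)
  sc <- countReads(sam, idx)  # best filtering leaves the tx1 alignment
  expect_identical(unname(counts(sc)["1:1"]), 1)
})
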