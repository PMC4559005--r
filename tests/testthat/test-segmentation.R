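test_that("substring clustering groups identical k-mers exactly", {
  # one transcript with a repeated 4-mer at offsets 0 and 4
  cl <- clusterSubstrings(c(t1 = "ACGTACGT"), k = 4, stranded = TRUE)
  part <- clusterTableToPartition(cl)
  expect_length(part, 4)  # ACGT (x2), CGTA, GTAC, TACG
  sizes <- sort(lengths(part))
  expect_identical(sizes, c(1L, 1L, 1L, 2L))
  rep4 <- part[lengths(part) == 2][[1]]
  expect_setequal(rep4, c("1:0", "1:4"))
})

test_that("clustering matches a brute-force k-mer dictionary", {
  set.seed(401)
  for (stranded in c(TRUE, FALSE)) {
    seqs <- randomSharedTranscriptome(nTx = 4, minLen = 100, maxLen = 160)
    cl <- clusterSubstrings(seqs, k = 30, stranded = stranded)
    expect_true(samePartition(
      clusterTableToPartition(cl),
      bruteKmerPartition(seqs, 30, stranded = stranded)))
  }
})

test_that("N-containing substrings are excluded; oversized k warns", {
  cl <- clusterSubstrings(c(a = "ACGTNACGT"), k = 4)
  # positions 1..4 (0-based) all overlap the N: only offsets 0 and 5 stay
  expect_setequal(unlist(clusterTableToPartition(cl)), c("1:0", "1:5"))
  expect_warning(out <- clusterSubstrings(c(a = "ACGT"), k = 10),
                 "exceeds every transcript")
  expect_identical(nrow(out), 0L)
})

test_that("three near-identical 56-bp genes give three singleton segments", {
  set.seed(11)
  g1 <- paste(sample(c("A", "C", "G", "T"), 56, TRUE), collapse = "")
  ch <- strsplit(g1, "")[[1]]
  at <- sample(56, 2)
  for (p in at) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  g2 <- paste(ch, collapse = "")
  g3 <- paste(sample(c("A", "C", "G", "T"), 56, TRUE), collapse = "")
  seg <- deriveSegmentsSingleEnd(
    clusterSubstrings(c(g1 = g1, g2 = g2, g3 = g3), 56), 56)
  expect_length(seg$classKey, 3)
  expect_true(all(lengths(seg$members) == 1))
  expect_true(all(seg$perSizeLength[, 1] == 1))
})

test_that("single-end segment derivation handles sharing and repeats", {
  # single transcript, no repeats: one segment of length L - k + 1
  seg <- deriveSegmentsSingleEnd(
    clusterSubstrings(c(t = "ACGGTCAGTTCAGG"), 5), 5)
  expect_identical(seg$classKey, "1:1")
  expect_identical(as.integer(seg$perSizeLength[, "5"]), 10L)

  # internal repeat shared with a second transcript: class {A:2, B:1}
  set.seed(7)
  S <- paste(sample(c("A", "C", "G", "T"), 6, TRUE), collapse = "")
  mid <- "TTTTTTTT"
  A <- paste0(S, mid, S)
  B <- paste0("CCCCCCCC", S, "GGGGGGGG")
  seg <- deriveSegmentsSingleEnd(
    clusterSubstrings(c(A = A, B = B), 6), 6)
  expect_true("1:2;2:1" %in% seg$classKey)
})

test_that("weighted segment lengths average per-size lengths", {
  idx <- new("TranscriptomeIndex",
    txId = "t", geneId = "t", txLength = 300L,
    segClassKey = "1:1", segMembers = list(1L), segMult = list(1L),
    perSizeLength = matrix(c(101L, 51L), 1, 2,
                           dimnames = list(NULL, c("200", "250"))),
    weightedLength = 76, segSet = 1L, sets = list(1L),
    droppedClassKey = character(0), readLength = 100L,
    fragRange = c(200L, 250L), stranded = TRUE, formatVersion = 1L)
  w <- weightSegmentLengths(idx, c("200" = 0.5, "250" = 0.5))
  expect_equal(w@weightedLength, 76)
  w <- weightSegmentLengths(idx, c("200" = 1.0))
  expect_equal(w@weightedLength, 101)
  # empirical distribution = plain dot product after renormalization
  p <- c("200" = 0.3, "250" = 0.6, "999" = 0.1)
  w <- weightSegmentLengths(idx, p)
  expect_equal(w@weightedLength, (0.3 * 101 + 0.6 * 51) / 0.9)
  expect_error(weightSegmentLengths(idx, c("400" = 1)), "outside")
})

test_that("paired-end virtual pairs are enumerated per fragment size", {
  set.seed(21)
  one <- setNames(Biostrings::DNAStringSet(paste(
    sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")), "t1")
  seg <- deriveSegmentsPairedEnd(one, 100, c(200, 200))
  expect_identical(seg$classKey, "1:1")
  expect_identical(as.integer(seg$perSizeLength[, "200"]), 101L)

  # duplicate transcripts share every virtual pair
  two <- setNames(Biostrings::DNAStringSet(rep(as.character(one), 2)),
                  c("a", "b"))
  seg <- deriveSegmentsPairedEnd(two, 100, c(150, 155))
  expect_identical(seg$classKey, "1:1;2:1")
  expect_identical(as.integer(seg$perSizeLength[, "150"]), 151L)

  expect_error(deriveSegmentsPairedEnd(one, 100, c(90, 120)),
               "read length")
})

test_that("paired-end lengths match exhaustive mate-pair enumeration", {
  set.seed(33)
  base <- paste(sample(c("A", "C", "G", "T"), 220, TRUE), collapse = "")
  shared <- substr(base, 50, 170)  # shared internal exon
  t2 <- paste0(paste(sample(c("A", "C", "G", "T"), 40, TRUE),
                     collapse = ""), shared,
               paste(sample(c("A", "C", "G", "T"), 30, TRUE),
                     collapse = ""))
  t3 <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
  seqs <- setNames(Biostrings::DNAStringSet(c(base, t2, t3)),
                   c("t1", "t2", "t3"))
  for (stranded in c(TRUE, FALSE)) {
    seg <- deriveSegmentsPairedEnd(seqs, 30, c(150, 153),
                                   stranded = stranded)
    brute <- bruteMatePairLengths(seqs, 30, 150:153,
                                  stranded = stranded)
    got <- list()
    for (i in seq_along(seg$classKey)) {
      for (F in colnames(seg$perSizeLength)) {
        v <- seg$perSizeLength[i, F]
        if (v > 0) got[[paste0(seg$classKey[i], "@", F)]] <- as.numeric(v)
      }
    }
    expect_identical(got[order(names(got))],
                     brute[order(names(brute))])
  }
})

test_that("sequence-sharing sets are the transitive closure of sharing", {
  # {A,B}, {B,C}, {D} -> sets {A,B,C} and {D}
  seg <- list(members = list(c(1L, 2L), c(2L, 3L), 4L))
  ss <- buildSharingSets(seg, 4)
  expect_identical(ss$sets, list(c(1L, 2L, 3L), 4L))
  expect_identical(ss$setId, c(1L, 1L, 2L))

  # two genes (3 + 1 isoforms) linked by one shared segment: one set of 4
  seg <- list(members = list(c(1L, 2L), c(2L, 3L), c(3L, 4L), 1L, 4L))
  ss <- buildSharingSets(seg, 4)
  expect_length(ss$sets, 1)
  expect_identical(ss$sets[[1]], 1:4)
})

test_that("set partition matches an igraph connected-components oracle", {
  skip_if_not_installed("igraph")
  set.seed(55)
  for (rep in 1:10) {
    nTx <- sample(5:15, 1)
    nSeg <- sample(3:12, 1)
    members <- lapply(seq_len(nSeg), function(i)
      sort(sample(seq_len(nTx), sample(1:3, 1))))
    ss <- buildSharingSets(list(members = members), nTx)
    edges <- unlist(lapply(members, function(m)
      if (length(m) > 1) as.vector(rbind(m[-length(m)], m[-1]))))
    g <- igraph::make_empty_graph(nTx, directed = FALSE)
    if (length(edges)) g <- igraph::add_edges(g, edges)
    comp <- igraph::components(g)$membership
    # same partition: the label pairing is a bijection
    mine <- integer(nTx)
    for (s in seq_along(ss$sets)) mine[ss$sets[[s]]] <- s
    pairs <- unique(paste(mine, comp))
    expect_length(pairs, length(unique(mine)))
    expect_length(pairs, length(unique(comp)))
  }
})

test_that("pruning drops short bridges until sets are small enough", {
  idx <- chainIndex()
  expect_length(idx@sets, 1)
  pruned <- pruneLargeSets(idx, maxSetSize = 2)
  expect_identical(lengths(pruned@sets), rep(1L, 4))
  expect_setequal(pruned@droppedClassKey,
                  c("1:1;2:1", "2:1;3:1", "3:1;4:1"))
  # already small enough: untouched
  same <- pruneLargeSets(idx, maxSetSize = 4)
  expect_identical(same@segClassKey, idx@segClassKey)
  expect_length(same@droppedClassKey, 0)
})

test_that("single-end conservation: segment lengths tile every transcript", {
  set.seed(77)
  rl <- 25
  seqs <- randomSharedTranscriptome(nTx = 5, minLen = 60, maxLen = 200)
  idx <- buildIndex(seqs, rl)
  covered <- numeric(length(seqs))
  for (i in seq_along(idx@segMembers)) {
    m <- idx@segMembers[[i]]
    covered[m] <- covered[m] + idx@segMult[[i]] * idx@perSizeLength[i, 1]
  }
  expect_equal(covered, pmax(Biostrings::width(seqs) - rl + 1, 0))
})

test_that("unstranded segment lengths survive reverse-complementing inputs", {
  set.seed(88)
  seqs <- randomSharedTranscriptome(nTx = 4, minLen = 80, maxLen = 150)
  rc <- Biostrings::reverseComplement(seqs)
  names(rc) <- names(seqs)
  a <- buildIndex(seqs, 30, stranded = FALSE)
  b <- buildIndex(rc, 30, stranded = FALSE)
  expect_identical(sort(a@weightedLength), sort(b@weightedLength))
  expect_identical(sort(a@segClassKey), sort(b@segClassKey))
})

test_that("index building is deterministic", {
  seqs <- randomSharedTranscriptome(nTx = 4)
  a <- buildIndex(seqs, 30)
  b <- buildIndex(seqs, 30)
  expect_identical(a@segClassKey, b@segClassKey)
  expect_identical(a@perSizeLength, b@perSizeLength)
  expect_identical(a@sets, b@sets)
})
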