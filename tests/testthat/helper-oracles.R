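# Independent oracles and fixture builders used across the suite.

# --- brute-force k-mer dictionary oracle for substring clustering ------
# groups every valid position by its literal k-mer (canonicalized by
# reverse complement when unstranded) using a plain named split.
bruteKmerPartition <- function(seqs, k, stranded = TRUE) {
  chars <- as.character(seqs)
  pos <- list()
  for (i in seq_along(chars)) {
    n <- nchar(chars[i]) - k + 1
    if (n < 1) next
    for (p in seq_len(n)) {
      km <- substr(chars[i], p, p + k - 1)
      if (grepl("[^ACGT]", km)) next
      if (!stranded) {
        rc <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(km)))
        if (rc < km) km <- rc
      }
      pos[[km]] <- c(pos[[km]], paste0(i, ":", p - 1))
    }
  }
  unname(lapply(pos, sort))
}

# normalize a clusterSubstrings() table to the same comparable form
clusterTableToPartition <- function(cl) {
  groups <- split(paste0(cl$tx, ":", cl$offset), cl$cluster)
  unname(lapply(groups, sort))
}

samePartition <- function(a, b) {
  setequal(vapply(a, paste, character(1), collapse = ","),
           vapply(b, paste, character(1), collapse = ","))
}

# --- independent joint-Poisson likelihood and maximizers --------------
# (written from the model definition, not calling package internals)
oracleLogLik <- function(e, A, L, X) {
  lam <- as.vector(A %*% e) * L
  if (any(X > 0 & lam <= 0)) return(-Inf)
  ok <- X > 0
  sum(X[ok] * log(lam[ok])) - sum(lam)
}

# dense log-grid search refined with stats::optim (L-BFGS-B, box >= 0)
oracleGridMLE <- function(A, L, X) {
  nt <- ncol(A)
  scale <- sum(X) / max(sum(L * rowSums(A)), 1e-12)
  axis <- c(0, exp(seq(log(1e-4), log(1e4), length.out = 40)) * scale)
  grid <- as.matrix(expand.grid(rep(list(axis), nt)))
  S <- grid %*% t(A)
  lam <- sweep(S, 2, L, `*`)
  term <- matrix(0, nrow(lam), ncol(lam))
  pos <- which(X > 0)
  term[, pos] <- sweep(log(pmax(lam[, pos, drop = FALSE], 1e-300)), 2,
                       X[pos], `*`)
  ll <- rowSums(term) - rowSums(lam)
  best <- grid[which.max(ll), ]
  fit <- stats::optim(pmax(best, 1e-9 * scale),
                      fn = function(e) -oracleLogLik(e, A, L, X),
                      method = "L-BFGS-B", lower = 0,
                      control = list(factr = 1e4, maxit = 2000))
  fit$par
}

# brute-force multinomial MLE: the segment-probability vector that
# maximizes sum X_C log p_C with p_C = (A e)_C L_C / sum
oracleMultinomProbs <- function(A, L, X, start = NULL) {
  nt <- ncol(A)
  probs <- function(loge) {
    lam <- as.vector(A %*% exp(loge)) * L
    lam / sum(lam)
  }
  nll <- function(loge) {
    p <- probs(loge)
    if (any(X > 0 & p <= 0)) return(1e18)
    -sum(X[X > 0] * log(p[X > 0]))
  }
  if (nt == 1) return(probs(0))  # scale cancels: p is fixed
  st <- if (is.null(start)) rep(0, nt) else log(pmax(start, 1e-9))
  fit <- stats::optim(st, nll, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-12))
  probs(fit$par)
}

# --- random small estimation instances --------------------------------
# every transcript gets a unique segment (identifiable), plus random
# shared segments, occasionally with multiplicity 2
randomInstance <- function(nt = sample(1:3, 1), maxSeg = 5) {
  nShared <- sample(0:max(0, maxSeg - nt), 1)
  classes <- lapply(seq_len(nt), function(i) {
    m <- integer(nt); m[i] <- 1L; m
  })
  if (nShared > 0 && nt > 1) {
    for (s in seq_len(nShared)) {
      mem <- sample(seq_len(nt), sample(2:nt, 1))
      m <- integer(nt)
      m[mem] <- sample(1:2, length(mem), replace = TRUE, prob = c(.85, .15))
      classes <- c(classes, list(m))
    }
  }
  A <- do.call(rbind, classes)
  L <- sample(3:50, nrow(A), replace = TRUE)
  eTrue <- stats::rlnorm(nt, meanlog = 1, sdlog = 1)
  X <- stats::rpois(nrow(A), as.vector(A %*% eTrue) * L)
  list(A = A, L = L, X = X, eTrue = eTrue)
}

# --- brute-force enumeration of virtual mate pairs --------------------
# groups all (p, p + F - k) pairs by the multiset of transcripts whose
# literal pair sequence is identical; returns per-class per-size counts
bruteMatePairLengths <- function(seqs, k, sizes, stranded = TRUE) {
  chars <- as.character(seqs)
  out <- list()
  for (F in sizes) {
    dict <- list()
    for (i in seq_along(chars)) {
      n <- nchar(chars[i]) - F + 1
      if (n < 1) next
      for (p in seq_len(n)) {
        m1 <- substr(chars[i], p, p + k - 1)
        m2 <- substr(chars[i], p + F - k, p + F - 1)
        if (grepl("[^ACGT]", m1) || grepl("[^ACGT]", m2)) next
        pr <- paste0(m1, "|", m2)
        if (!stranded) {
          rc <- function(s) as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(s)))
          alt <- paste0(rc(m2), "|", rc(m1))
          if (alt < pr) pr <- alt
        }
        dict[[pr]] <- c(dict[[pr]], i)
      }
    }
    for (pr in names(dict)) {
      tab <- table(dict[[pr]])
      cls <- paste(paste0(names(tab), ":", as.integer(tab)),
                   collapse = ";")
      keyF <- paste0(cls, "@", F)
      out[[keyF]] <- (if (is.null(out[[keyF]])) 0 else out[[keyF]]) + 1
    }
  }
  out
}

# random transcriptome with sequence sharing, for conservation checks
randomSharedTranscriptome <- function(nTx = 6, minLen = 80, maxLen = 250) {
  lens <- sample(minLen:maxLen, nTx, replace = TRUE)
  seqs <- vapply(lens, function(n)
    paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = ""),
    character(1))
  # splice a shared block from tx1 into tx2 to force multi-mapping
  if (nTx >= 2) {
    block <- substr(seqs[1], 1, min(60, lens[1]))
    seqs[2] <- paste0(block, substr(seqs[2], nchar(block) + 1, lens[2]))
  }
  setNames(Biostrings::DNAStringSet(seqs),
           sprintf("rt%02d", seq_len(nTx)))
}

# hand-built index: 4 transcripts chained A-B-C-D by length-1 bridges
chainIndex <- function() {
  keys <- c("1:1", "2:1", "3:1", "4:1", "1:1;2:1", "2:1;3:1", "3:1;4:1")
  parsed <- lapply(strsplit(keys, ";"), function(p) {
    mm <- matrix(as.integer(unlist(strsplit(p, ":"))), nrow = 2)
    list(members = mm[1, ], mult = mm[2, ])
  })
  lens <- c(10, 10, 10, 10, 1, 1, 1)
  psl <- matrix(as.integer(lens), ncol = 1,
                dimnames = list(NULL, "30"))
  ss <- buildSharingSets(list(members = lapply(parsed, `[[`, "members")), 4)
  methods::new("TranscriptomeIndex",
    txId = c("A", "B", "C", "D"), geneId = c("A", "B", "C", "D"),
    txLength = rep(100L, 4), segClassKey = keys,
    segMembers = lapply(parsed, `[[`, "members"),
    segMult = lapply(parsed, `[[`, "mult"),
    perSizeLength = psl, weightedLength = lens,
    segSet = ss$setId, sets = ss$sets,
    droppedClassKey = character(0), readLength = 30L,
    fragRange = integer(0), stranded = TRUE, formatVersion = 1L)
}

# alignment table for the two-gene worked example: 70 + 340 unique
# reads and 90 shared reads placed on the realized two-gene sequences
twoGeneAlignments <- function(tg, readLength = 20) {
  w <- Biostrings::width(tg$transcripts)
  uniq1 <- data.frame(qname = sprintf("u1_%03d", 1:70), tx = "tx1",
                      pos = rep(0:6, length.out = 70))
  uniq2 <- data.frame(qname = sprintf("u2_%03d", 1:340), tx = "tx2",
                      pos = rep(0:16, length.out = 340))
  # shared suffix: the last 3 virtual-read positions on each transcript
  sh1 <- data.frame(qname = sprintf("sh_%03d", 1:90), tx = "tx1",
                    pos = rep((w[1] - readLength - 2):(w[1] - readLength),
                              length.out = 90))
  sh2 <- data.frame(qname = sh1$qname, tx = "tx2",
                    pos = sh1$pos + (w[2] - w[1]))
  out <- rbind(uniq1, uniq2, sh1, sh2)
  out$strand <- "+"
  out$nm <- 0L
  out
}
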