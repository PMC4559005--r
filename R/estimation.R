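#' Joint Poisson log-likelihood of a sequence-sharing set
#'
#' Each segment's read count is Poisson with mean
#' `lambda_C = (sum_j A[C, j] * e_j) * L_C`, the multiplicity-weighted sum
#' of the member transcripts' per-unit rates times the weighted segment
#' length. Constant terms (`log X!`) are dropped, so the value is
#' `sum_C [X_C log(lambda_C) - lambda_C]`; a segment with `X_C = 0` and
#' `lambda_C = 0` contributes 0, and `X_C > 0` with `lambda_C = 0` gives
#' `-Inf`.
#'
#' @param e non-negative abundance vector (reads per virtual-length
#'   unit), one entry per transcript of the set.
#' @param A segments x transcripts multiplicity matrix (the alignment
#'   classes).
#' @param lengths weighted segment lengths `L_C`.
#' @param counts observed segment read counts `X_C`.
#' @return the log-likelihood (a scalar, possibly `-Inf`).
#' @examples
#' ex <- twoGeneExample()
#' poissonLogLik(c(10, 20), ex$A, ex$lengths, ex$counts)
#' @export
poissonLogLik <- function(e, A, lengths, counts) {
  if (any(e < 0)) stop("abundances must be non-negative")
  lam <- as.vector(A %*% e) * lengths
  pos <- counts > 0
  if (any(pos & lam <= 0)) return(-Inf)
  sum(counts[pos] * log(lam[pos])) - sum(lam)
}

# gradient of poissonLogLik: d/de_j = sum_C A[C,j] (X_C / s_C - L_C),
# with s_C = sum_j A[C,j] e_j
.poissonGrad <- function(e, A, lengths, counts) {
  s <- as.vector(A %*% e)
  r <- counts / pmax(s, 1e-300) - lengths
  r[counts == 0] <- -lengths[counts == 0]
  as.vector(crossprod(A, r))
}

#' Maximize the joint Poisson likelihood by restart-averaged hill climbing
#'
#' Monotone projected gradient ascent with an adaptive step (doubled
#' after an accepted move, halved on rejection), clamped at zero,
#' stopping when the relative change of every coordinate stays below
#' `precision` for three consecutive accepted steps. The climb is run
#' `restarts` times from random initial points (a log-uniform scalar over
#' six decades around the mean-rate scale, applied to all coordinates so
#' that transcripts the data cannot distinguish are treated
#' symmetrically) and the coordinate-wise mean of the converged points is
#' returned. For an identifiable set all restarts agree (the likelihood
#' is concave); when only a sum of rates is determined, the symmetric
#' dynamics put each member at the same level.
#'
#' @inheritParams poissonLogLik
#' @param precision relative convergence tolerance per coordinate.
#' @param restarts number of random restarts (default 4).
#' @param seed integer seed for the restart initial points.
#' @param maxIterations iteration cap per restart; hitting it warns and
#'   returns the best point found.
#' @return the abundance vector (restart mean), with attributes
#'   `restarts` (matrix of per-restart optima), `converged`, and
#'   `logLik`.
#' @examples
#' ex <- twoGeneExample()
#' hillClimb(ex$A, ex$lengths, ex$counts)  # ~ (10, 20)
#' @export
hillClimb <- function(A, lengths, counts, precision = 1e-3, restarts = 4L,
                      seed = 1L, maxIterations = 1e5L) {
  stopifnot(precision > 0, restarts >= 1)
  A <- as.matrix(A)
  nt <- ncol(A)
  if (length(lengths) != nrow(A) || length(counts) != nrow(A))
    stop("lengths and counts must have one entry per segment row of A")
  if (sum(counts) == 0)
    return(structure(rep(0, nt),
                     restarts = matrix(0, restarts, nt),
                     converged = TRUE, logLik = 0))
  scale <- sum(counts) / max(sum(lengths * rowSums(A)), 1e-12)
  finals <- matrix(NA_real_, restarts, nt)
  convAll <- TRUE
  .withSeed(seed, {
    for (r in seq_len(restarts)) {
      e <- rep(10^runif(1, -3, 3) * scale, nt)
      ll <- poissonLogLik(e, A, lengths, counts)
      if (!is.finite(ll)) { e <- rep(scale, nt)
                            ll <- poissonLogLik(e, A, lengths, counts) }
      t <- scale
      streak <- 0L
      it <- 0L
      while (it < maxIterations) {
        it <- it + 1L
        g <- .poissonGrad(e, A, lengths, counts)
        accepted <- FALSE
        for (h in 1:80) {
          e2 <- pmax(0, e + t * g)
          ll2 <- poissonLogLik(e2, A, lengths, counts)
          if (is.finite(ll2) && ll2 > ll) { accepted <- TRUE; break }
          t <- t / 2
        }
        if (!accepted) break  # no ascent direction left: at the optimum
        rel <- max(abs(e2 - e) / pmax(abs(e), scale * 1e-9))
        e <- e2; ll <- ll2; t <- t * 2
        streak <- if (rel < precision) streak + 1L else 0L
        if (streak >= 3L) break
      }
      if (it >= maxIterations) {
        convAll <- FALSE
        warning("hill climb hit maxIterations; returning best point")
      }
      finals[r, ] <- e
    }
  })
  e <- colMeans(finals)
  structure(e, restarts = finals, converged = convAll,
            logLik = poissonLogLik(e, A, lengths, counts))
}

#' Apportion multi-mapped segment counts among class members
#'
#' Diagnostic allocation of each segment's observed reads to its member
#' transcripts in proportion to the multiplicity-weighted estimated
#' rates (the estimator itself never assigns individual reads). In the
#' two-gene worked example the 90 shared reads split 30:60 at rates
#' (10, 20).
#'
#' @inheritParams poissonLogLik
#' @param e estimated abundance vector (from [hillClimb()]).
#' @return a segments x transcripts matrix of expected read shares; rows
#'   sum to the segment counts. Segments with a positive count but all
#'   member rates zero are split equally and flagged in attribute
#'   `flagged`.
#' @export
allocateMultireads <- function(e, A, counts) {
  A <- as.matrix(A)
  w <- sweep(A, 2L, e, `*`)
  rs <- rowSums(w)
  shares <- w * ifelse(rs > 0, counts / pmax(rs, 1e-300), 0)
  flagged <- which(rs == 0 & counts > 0)
  for (i in flagged) {
    m <- A[i, ] > 0
    shares[i, m] <- counts[i] / sum(m)
  }
  structure(shares, flagged = flagged)
}

# assemble the per-set design (A, L, X) for estimation
.setInstances <- function(index, segCounts) {
  lapply(seq_along(index@sets), function(s) {
    segIdx <- which(index@segSet == s)
    txs <- index@sets[[s]]
    A <- matrix(0, length(segIdx), length(txs))
    for (i in seq_along(segIdx)) {
      m <- index@segMembers[[segIdx[i]]]
      A[i, match(m, txs)] <- index@segMult[[segIdx[i]]]
    }
    list(tx = txs, A = A,
         lengths = index@weightedLength[segIdx],
         counts = segCounts[segIdx],
         segIdx = segIdx)
  })
}

#' Estimate transcript abundances from segment counts
#'
#' The central fit: for every sequence-sharing set, maximizes the joint
#' Poisson likelihood of its segment counts ([hillClimb()]; single-
#' transcript sets use the closed form `sum(X) / sum(m * L)`), then
#' converts the per-unit rates to FPKM
#' (`e_i * 1e9 / totalCounted`), TPM (FPKM renormalized to sum to 1e6),
#' effective length (sum of the lengths of all segments containing the
#' transcript), and the inferred read count
#' `totalCounted * FPKM_i * effLen_i / 1e9`. Sets with no observed reads
#' are reported at zero without invoking the optimizer; estimates are
#' reported for all transcripts in input order.
#'
#' Segment lengths are first reweighted by the dataset's empirical
#' fragment-size distribution ([weightSegmentLengths()]) when one was
#' observed.
#'
#' @param index a [TranscriptomeIndex-class].
#' @param segCounts a [SegmentCounts-class] from [countReads()].
#' @inheritParams hillClimb
#' @return an [AbundanceTable-class].
#' @seealso [geneAbundance()], [writeAbundance()]
#' @export
fitAbundance <- function(index, segCounts, precision = 1e-3,
                         restarts = 4L, seed = 1L, maxIterations = 1e5L) {
  stopifnot(is(index, "TranscriptomeIndex"), is(segCounts, "SegmentCounts"))
  if (!identical(segCounts@classKey, index@segClassKey))
    stop("segment counts were produced against a different index")
  if (segCounts@totalCounted == 0)
    stop("no counted reads: nothing to estimate")
  if (length(segCounts@fragDist))
    index <- weightSegmentLengths(index, segCounts@fragDist)
  nt <- length(index@txId)
  e <- numeric(nt)
  solvable <- rep(TRUE, nt)
  for (inst in .setInstances(index, segCounts@counts)) {
    if (sum(inst$counts) == 0) next  # zero-count set: e stays 0
    if (length(inst$tx) == 1L) {
      denom <- sum(inst$A[, 1L] * inst$lengths)
      e[inst$tx] <- if (denom > 0) sum(inst$counts) / denom else 0
    } else {
      fit <- hillClimb(inst$A, inst$lengths, inst$counts,
                       precision = precision, restarts = restarts,
                       seed = seed + inst$tx[1L], maxIterations = maxIterations)
      e[inst$tx] <- fit
      spread <- apply(attr(fit, "restarts"), 2L, function(v)
        diff(range(v)) / max(mean(v), 1e-12))
      ok <- spread <= 10 * precision
      # transcripts with identical alignment-class columns are mutually
      # indistinguishable: only their sum is determined by the data
      colSig <- apply(inst$A, 2L, paste, collapse = ",")
      ok[colSig %in% colSig[duplicated(colSig)]] <- FALSE
      solvable[inst$tx] <- ok
    }
  }
  total <- segCounts@totalCounted
  fpkm <- e * 1e9 / total
  tpm <- if (sum(fpkm) > 0) fpkm / sum(fpkm) * 1e6 else fpkm
  effLen <- numeric(nt)
  for (i in seq_along(index@segMembers)) {
    m <- unique(index@segMembers[[i]])
    effLen[m] <- effLen[m] + index@weightedLength[i]
  }
  estCount <- total * fpkm * effLen / 1e9
  tab <- data.frame(
    transcript_id = index@txId, gene_id = index@geneId,
    effective_length = effLen, est_count = estCount,
    FPKM = fpkm, TPM = tpm, e = e, solvable = solvable,
    stringsAsFactors = FALSE)
  new("AbundanceTable", table = tab, totalCounted = total)
}

#' Write abundance tables to TSV
#'
#' Writes the transcript-level table
#' (`<prefix>.transcripts.tsv`: `transcript_id`, `gene_id`,
#' `effective_length`, `est_count`, `FPKM`, `TPM`) and a gene-level
#' companion (`<prefix>.genes.tsv`) aggregated by `gene_id`, atomically.
#'
#' @param x an [AbundanceTable-class].
#' @param prefix output path prefix.
#' @return the two file paths, invisibly.
#' @export
writeAbundance <- function(x, prefix) {
  stopifnot(is(x, "AbundanceTable"))
  txPath <- paste0(prefix, ".transcripts.tsv")
  genePath <- paste0(prefix, ".genes.tsv")
  txTab <- x@table[c("transcript_id", "gene_id", "effective_length",
                     "est_count", "FPKM", "TPM")]
  .atomicWrite(txPath, function(p)
    write.table(txTab, p, sep = "\t", quote = FALSE, row.names = FALSE))
  .atomicWrite(genePath, function(p)
    write.table(geneAbundance(x), p, sep = "\t", quote = FALSE,
                row.names = FALSE))
  invisible(c(txPath, genePath))
}

#' Reference multi-read handling strategies on the two-gene example
#'
#' Computes, for the worked two-gene instance of [twoGeneExample()], the
#' classic length-correction strategies used to motivate joint
#' estimation: `full_length` (unique counts divided by full gene
#' lengths: 7 and 17), `equal_split` (the shared reads split equally:
#' 45 and 45), `unique_region` (unique counts divided by uniquely
#' mappable lengths: 10 and 20), and `joint_poisson` (the joint Poisson
#' MLE over all three segments: 10 and 20).
#'
#' @param example an instance as returned by [twoGeneExample()].
#' @param precision,seed passed to [hillClimb()] for the joint fit.
#' @return named list of two-element vectors (one value per gene);
#'   `equal_split` reports the allocated shared reads, the others report
#'   abundance estimates.
#' @export
multireadStrategies <- function(example = twoGeneExample(),
                                precision = 1e-3, seed = 1L) {
  uc <- example$counts[1:2]           # unique counts per gene
  shared <- example$counts[3]
  ul <- example$lengths[1:2]          # unique segment lengths
  fl <- example$fullLength
  fit <- hillClimb(example$A, example$lengths, example$counts,
                   precision = precision, seed = seed)
  list(
    full_length = setNames(uc / fl, example$txId),
    equal_split = setNames(rep(shared / 2, 2), example$txId),
    unique_region = setNames(uc / ul, example$txId),
    joint_poisson = setNames(as.numeric(fit), example$txId)
  )
}
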