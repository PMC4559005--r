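# Internal helpers shared across modules.

#' @import data.table
#' @importFrom methods new validObject is slot
#' @importFrom stats runif rpois rlnorm rnorm rbinom setNames
#' @importFrom utils write.table head
NULL

# canonical class key: "i:m" pairs (transcript index, multiplicity),
# sorted by transcript index, joined by ";"
.makeClassKey <- function(members, mult) {
  o <- order(members)
  paste(paste0(members[o], ":", mult[o]), collapse = ";")
}

# vectorized inverse of .makeClassKey
.parseClassKeys <- function(keys) {
  lapply(strsplit(keys, ";", fixed = TRUE), function(p) {
    mm <- matrix(as.integer(unlist(strsplit(p, ":", fixed = TRUE))), nrow = 2L)
    list(members = mm[1L, ], mult = mm[2L, ])
  })
}

.revComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# canonical representative of a substring under reverse complement:
# the lexicographically smaller of the two (unstranded clustering)
.canonicalKmer <- function(x) {
  rc <- .revComp(x)
  ifelse(x <= rc, x, rc)
}

# run code under a temporary RNG state; restores the caller's stream
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# write a file atomically: writer(tmp) then rename into place
.atomicWrite <- function(path, writer) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  ok <- FALSE
  on.exit(if (!ok && file.exists(tmp)) unlink(tmp))
  writer(tmp)
  if (!file.rename(tmp, path)) {
    # rename across filesystems can fail; fall back to copy + remove
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  ok <- TRUE
  invisible(path)
}

# coerce FASTA path / character vector / DNAStringSet to a named DNAStringSet
.asTranscripts <- function(x) {
  if (is(x, "DNAStringSet")) {
    seqs <- x
  } else if (is.character(x) && length(x) == 1L && file.exists(x)) {
    seqs <- Biostrings::readDNAStringSet(x)
  } else if (is.character(x)) {
    seqs <- Biostrings::DNAStringSet(x)
  } else {
    stop("transcripts must be a DNAStringSet, a FASTA path, ",
         "or a character vector of sequences")
  }
  if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == ""))
    stop("every transcript needs a name (FASTA header)")
  # keep only the first whitespace token as the transcript id
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids))
    stop("duplicate transcript ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  full <- names(seqs)
  names(seqs) <- ids
  attr(seqs, "fullHeaders") <- full
  seqs
}

# resolve the transcript -> gene mapping.
# geneMap may be NULL (parse from header second token, else gene == tx),
# a named character vector, a 2-column data.frame, or a TSV path.
.resolveGeneMap <- function(seqs, geneMap = NULL) {
  ids <- names(seqs)
  if (is.null(geneMap)) {
    full <- attr(seqs, "fullHeaders")
    if (is.null(full)) full <- ids
    tok2 <- sub("^\\S+\\s+(\\S+).*$", "\\1", full)
    gene <- ifelse(grepl("\\s", full), sub("^gene[=:]", "", tok2), ids)
    return(setNames(gene, ids))
  }
  if (is.character(geneMap) && length(geneMap) == 1L && file.exists(geneMap)) {
    tab <- utils::read.table(geneMap, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)
    geneMap <- setNames(as.character(tab[[2L]]), as.character(tab[[1L]]))
  } else if (is.data.frame(geneMap)) {
    geneMap <- setNames(as.character(geneMap[[2L]]), as.character(geneMap[[1L]]))
  }
  if (is.null(names(geneMap)))
    stop("geneMap must map transcript ids to gene ids")
  missing <- setdiff(ids, names(geneMap))
  if (length(missing))
    stop("geneMap lacks entries for: ", paste(head(missing, 5), collapse = ", "))
  setNames(unname(geneMap[ids]), ids)
}
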