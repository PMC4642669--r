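# Internal helpers shared across modules.

# Reverse complement for plain character vectors (delegates to Biostrings).
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Deterministic 31-bit seed derived from a base seed and a label, so that
# every cell of an experiment gets its own reproducible stream without
# coupling to the order in which cells are run.
derive_seed <- function(seed, ...) {
  label <- paste(c(...), collapse = "/")
  h <- 0
  for (cc in utf8ToInt(label)) h <- (h * 131 + cc) %% 2147483647
  as.integer((h + as.numeric(seed)) %% 2147483647)
}

# Pull the sequences out of whatever reference container is passed around:
# a named character vector, a toy_genome, or a degraded_reference.
reference_sequences <- function(reference) {
  if (inherits(reference, "toy_genome")) return(reference$chromosomes)
  if (inherits(reference, "degraded_reference")) return(reference$contigs)
  if (is.character(reference)) {
    if (is.null(names(reference)) || anyNA(names(reference)))
      abort("reference sequences must be named")
    return(reference)
  }
  abort("unsupported reference container")
}

random_dna <- function(n, gc = 0.36) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Point-mutate a sequence: each base substituted with probability `rate`
# by one of the three other bases.
mutate_sequence <- function(seq, rate) {
  if (rate <= 0) return(seq)
  bases <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(bases)) < rate)
  if (length(hit) > 0) {
    alts <- c("A", "C", "G", "T")
    bases[hit] <- vapply(bases[hit], function(b) {
      sample(setdiff(alts, b), 1)
    }, character(1))
  }
  paste(bases, collapse = "")
}

#' Write sequences to a FASTA file
#'
#' Accepts a toy genome, a degraded reference or a named character vector.
#'
#' @param x sequences to write.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  seqs <- reference_sequences(x)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}
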