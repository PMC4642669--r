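#' Map reads with the naive seed-and-extend mapper
#'
#' A desk-scale, substitution-only read mapper: exact k-mer seeds anchor
#' candidate placements, which are scored by Hamming distance on both
#' strands. For a read of length `L` with budget `m = floor(rate * L)`,
#' `m + 1` block seeds of length `min(31, floor(L / (m + 1)))` are spread
#' across the read, so every placement within the budget is anchored by at
#' least one exact seed (pigeonhole) and the reported placement is the true
#' minimal-Hamming one. Ties on the minimum are broken toward the lowest
#' (sequence, coordinate) with forward strand first, and are flagged with
#' MAPQ 0; unique best placements get MAPQ 60.
#'
#' @param reads tibble with at least `name`, `mate`, `seq` (e.g. from
#'   [simulate_read_pairs()]).
#' @param reference reference container (named character vector,
#'   `toy_genome`, or `degraded_reference`).
#' @param stringency a [stringency_config()] giving the mismatch rate.
#' @return tibble of alignment records: `name`, `mate`, `seq`, `chrom`
#'   (NA when unmapped), `pos` (0-based), `strand`, `mismatches`, `mapq`,
#'   `n_best`.
#' @export
map_reads_naive <- function(reads, reference,
                            stringency = stringency_config("strict")) {
  stopifnot(is.data.frame(reads), all(c("name", "mate", "seq") %in% names(reads)),
            inherits(stringency, "stringency_config"))
  seqs <- reference_sequences(reference)
  hit <- cpp_map_reads(unname(seqs), reads$seq, stringency$rate)
  tibble(
    name = reads$name,
    mate = reads$mate,
    seq = reads$seq,
    chrom = names(seqs)[hit$ref],
    pos = hit$pos,
    strand = hit$strand,
    mismatches = hit$mismatches,
    mapq = ifelse(is.na(hit$n_best), NA_integer_,
                  ifelse(hit$n_best > 1L, 0L, 60L)),
    n_best = hit$n_best
  )
}

#' Filter alignments by mapping quality
#'
#' Read-level exclusion applied before pileup and calling, matching how
#' variant callers consume their MAPQ threshold. A threshold of 0 retains
#' every mapped read; ambiguous (tied-best) placements carry MAPQ 0 and are
#' removed by any positive threshold. Unmapped records are always dropped.
#'
#' @param alignments alignment tibble from [map_reads_naive()] or
#'   [read_sam_alignments()].
#' @param mapq_threshold minimum MAPQ retained.
#' @return the retained alignment rows.
#' @export
read_mapq_filter <- function(alignments, mapq_threshold = 0) {
  stopifnot(mapq_threshold >= 0)
  alignments %>% filter(!is.na(.data$chrom), .data$mapq >= mapq_threshold)
}

#' Write alignments as SAM
#'
#' Emits a coordinate-convertible SAM file (1-based POS, ungapped CIGAR,
#' NM tag) whose SEQ field is in reference orientation, as the format
#' requires. Unmapped reads are written with flag 0x4.
#'
#' @param alignments alignment tibble.
#' @param reference reference container used to emit `@SQ` header lines.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, reference, path) {
  seqs <- reference_sequences(reference)
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           paste0("@SQ\tSN:", names(seqs), "\tLN:", nchar(seqs)))
  a <- alignments
  mapped <- !is.na(a$chrom)
  rev <- mapped & a$strand == "-"
  flag <- 1L + ifelse(a$mate == 1L, 64L, 128L) +
    ifelse(mapped, 0L, 4L) + ifelse(rev, 16L, 0L)
  seq_out <- a$seq
  seq_out[rev] <- revcomp(seq_out[rev])
  body <- paste(a$name, flag,
                ifelse(mapped, a$chrom, "*"),
                ifelse(mapped, a$pos + 1L, 0L),
                ifelse(mapped, a$mapq, 0L),
                ifelse(mapped, paste0(nchar(a$seq), "M"), "*"),
                "*", 0L, 0L, seq_out, "*",
                ifelse(mapped, paste0("NM:i:", a$mismatches), ""),
                sep = "\t")
  body[!mapped] <- sub("\t$", "", body[!mapped])
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read alignments from a SAM or BAM file
#'
#' Uses Rsamtools; SAM input is converted to BAM in a temporary location
#' first. Sequences are returned in sequenced orientation (reverse-strand
#' records are reverse complemented back) so the result matches what
#' [map_reads_naive()] produces.
#'
#' @param path SAM or BAM file.
#' @return alignment tibble with `name`, `mate`, `seq`, `chrom`, `pos`
#'   (0-based), `strand`, `mismatches`, `mapq`.
#' @export
read_sam_alignments <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path,
                            destination = tempfile(fileext = ""),
                            overwrite = TRUE, indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "seq"),
    tag = "NM")
  res <- Rsamtools::scanBam(bam, param = p)[[1]]
  flag <- res$flag
  mapped <- bitwAnd(flag, 4L) == 0L
  rev <- bitwAnd(flag, 16L) != 0L
  seqs <- as.character(res$seq)
  seqs[mapped & rev] <- revcomp(seqs[mapped & rev])
  tibble(
    name = res$qname,
    mate = ifelse(bitwAnd(flag, 128L) != 0L, 2L, 1L),
    seq = seqs,
    chrom = ifelse(mapped, as.character(res$rname), NA_character_),
    pos = ifelse(mapped, res$pos - 1L, NA_integer_),
    strand = ifelse(mapped, ifelse(rev, "-", "+"), NA_character_),
    mismatches = if (is.null(res$tag$NM)) NA_integer_ else res$tag$NM,
    mapq = ifelse(mapped, res$mapq, NA_integer_)
  )
}
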