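#' Naive variant caller settings
#'
#' A haploid pileup caller: a site becomes a SNP candidate when some
#' alternate base is carried by at least `min_alt_count` reads making up at
#' least `min_alt_fraction` of the site depth. QUAL is the documentedly
#' arbitrary monotone score `min(qual_cap, qual_per_alt_read * alt count)`,
#' which is enough to exercise a QUAL >= 20 site filter.
#'
#' @param min_alt_count minimum alternate-allele read count.
#' @param min_alt_fraction minimum alternate-allele fraction of site depth.
#' @param qual_per_alt_read QUAL contributed per alternate read.
#' @param qual_cap QUAL ceiling.
#' @return a `caller_config` list.
#' @export
caller_config <- function(min_alt_count = 2L, min_alt_fraction = 0.08,
                          qual_per_alt_read = 10, qual_cap = 60) {
  stopifnot(min_alt_count >= 1, min_alt_fraction >= 0, min_alt_fraction <= 1)
  structure(list(min_alt_count = as.integer(min_alt_count),
                 min_alt_fraction = min_alt_fraction,
                 qual_per_alt_read = qual_per_alt_read,
                 qual_cap = qual_cap), class = "caller_config")
}

#' Call SNPs from aligned reads by naive pileup
#'
#' Only substitutions are considered (the mapper is ungapped). Sites where
#' two or more alternate alleles pass the thresholds are emitted as a single
#' multiallelic record (ALT alleles comma-separated), which the downstream
#' filter chain removes.
#'
#' @param alignments alignment tibble (mapped rows are used).
#' @param reference reference container the reads were mapped to.
#' @param cfg a [caller_config()].
#' @return variant tibble: `chrom`, `pos` (1-based), `ref`, `alt`, `qual`,
#'   `dp` (site read depth), `n_alt` (reads carrying the strongest
#'   alternate allele).
#' @export
call_variants_naive <- function(alignments, reference, cfg = caller_config()) {
  stopifnot(inherits(cfg, "caller_config"))
  seqs <- reference_sequences(reference)
  aln <- alignments %>% filter(!is.na(.data$chrom))
  empty <- tibble(chrom = character(), pos = integer(), ref = character(),
                  alt = character(), qual = numeric(), dp = integer(),
                  n_alt = integer())
  if (nrow(aln) == 0) return(empty)
  bad <- setdiff(unique(aln$chrom), names(seqs))
  if (length(bad) > 0)
    abort(paste0("alignments refer to sequences absent from the reference: ",
                 paste(bad, collapse = ", ")))

  ev <- mismatch_events(aln, seqs)
  if (nrow(ev) == 0) return(empty)

  depth <- site_depth(aln, seqs, ev$chrom, ev$pos)
  ev$dp <- depth

  calls <- ev %>%
    group_by(.data$chrom, .data$pos, .data$ref_base, .data$read_base) %>%
    summarise(n_alt = dplyr::n_distinct(paste0(.data$name, "/", .data$mate)),
              dp = first(.data$dp), .groups = "drop") %>%
    filter(.data$n_alt >= cfg$min_alt_count,
           .data$n_alt / .data$dp >= cfg$min_alt_fraction) %>%
    group_by(.data$chrom, .data$pos, .data$ref_base) %>%
    summarise(alt = paste(.data$read_base[order(-.data$n_alt, .data$read_base)],
                          collapse = ","),
              n_alt = max(.data$n_alt), dp = first(.data$dp),
              .groups = "drop") %>%
    mutate(pos = .data$pos + 1L,
           qual = pmin(cfg$qual_cap, cfg$qual_per_alt_read * .data$n_alt)) %>%
    select(chrom = "chrom", pos = "pos", ref = "ref_base", alt = "alt",
           qual = "qual", dp = "dp", n_alt = "n_alt") %>%
    arrange(.data$chrom, .data$pos)
  calls
}

# Per-base mismatch events of mapped alignments against the reference.
# Returns one row per (alignment, mismatched site): name, mate, chrom,
# pos (0-based), ref_base, read_base.
mismatch_events <- function(aln, seqs) {
  idx <- match(aln$chrom, names(seqs))
  ev <- cpp_mismatch_events(unname(seqs), aln$seq, idx,
                            as.integer(aln$pos), aln$strand)
  tibble(name = aln$name[ev$aln], mate = aln$mate[ev$aln],
         chrom = names(seqs)[ev$ref], pos = ev$pos,
         ref_base = ev$ref_base, read_base = ev$read_base)
}

# Read depth (number of covering alignments) at the queried 0-based sites.
site_depth <- function(aln, seqs, chrom, pos) {
  lens <- nchar(seqs)
  out <- integer(length(chrom))
  for (cn in unique(chrom)) {
    sub <- aln %>% filter(.data$chrom == cn)
    cov <- IRanges::coverage(
      IRanges::IRanges(start = sub$pos + 1L, width = nchar(sub$seq)),
      width = lens[[cn]])
    sel <- chrom == cn
    out[sel] <- as.integer(cov[pos[sel] + 1L])
  }
  out
}
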