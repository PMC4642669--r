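# Shared fixtures. Everything is generated in code; the one expensive
# object (the end-to-end toy experiment) is memoised for the whole run.

# Small repeat-free reference for constructed-alignment tests.
flat_reference <- function(n = 2, len = 3000, seed = 99) {
  set.seed(seed)
  stats::setNames(
    vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
            collapse = ""), character(1)),
    paste0("chr", seq_len(n)))
}

# Reduced-copy-number genome for unit tests on small chromosomes; keeps the
# teA/teB/teC family structure the degradation presets expect.
tiny_genome_config <- function(seed, chromosome_length = 6000,
                               n_chromosomes = 3) {
  genome_config(
    n_chromosomes = n_chromosomes,
    chromosome_length = chromosome_length,
    repeat_families = list(
      repeat_family("teA", monomer_length = 300, n_copies = 4,
                    divergence = 0.01),
      repeat_family("teB", monomer_length = 300, n_copies = 3,
                    divergence = 0.01, ancestor = "teA"),
      repeat_family("teC", monomer_length = 300, n_copies = 2,
                    divergence = 0.01)),
    seed = seed)
}

# Alignment-tibble constructor with sensible defaults.
make_aln <- function(name, seq, chrom, pos, strand = "+", mate = 1L,
                     mismatches = 0L, mapq = 60L) {
  tibble::tibble(name = name, mate = mate, seq = seq, chrom = chrom,
                 pos = as.integer(pos), strand = strand,
                 mismatches = as.integer(mismatches),
                 mapq = as.integer(mapq))
}

# Plant `n_alt` alt-carrying reads and `n_ref` reference reads over a site.
# Reads are L bp, all covering `site` (0-based) of `chrom`.
pileup_fixture <- function(seqs, chrom, site, alt, n_alt, n_ref, L = 30,
                           name_prefix = "rd", origin_chrom = NULL,
                           origin_start = NULL) {
  start <- max(0L, site - L %/% 2L)
  ref_read <- substr(seqs[[chrom]], start + 1L, start + L)
  alt_read <- ref_read
  substr(alt_read, site - start + 1L, site - start + 1L) <- alt
  oc <- if (is.null(origin_chrom)) chrom else origin_chrom
  os <- if (is.null(origin_start)) start else origin_start
  nm <- function(i) encode_origin(paste0(name_prefix, "_", i),
                                  oc, os, "+", oc, os, "-")
  n <- n_alt + n_ref
  make_aln(
    name = vapply(seq_len(n), nm, character(1)),
    seq = c(rep(alt_read, n_alt), rep(ref_read, n_ref)),
    chrom = chrom, pos = start,
    mismatches = c(rep(1L, n_alt), rep(0L, n_ref)))
}

# The shared end-to-end toy experiment (about a minute of compute),
# memoised across test files.
small_experiment_config <- function() {
  experiment_config(
    genome = default_genome_config(seed = 1, chromosome_length = 20000),
    coverage = 10, seed = 101)
}

small_experiment <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- run_experiment(small_experiment_config())
    cache
  }
})
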