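test_that("error-free self-mapping yields zero variant records", {
  g <- simulate_genome(tiny_genome_config(18, chromosome_length = 6000))
  rd <- simulate_read_pairs(g, read_sim_config(read_length = 50,
                                               coverage = 4, seed = 6))
  aln <- map_reads_naive(rd, g, stringency_config("strict"))
  v <- call_variants_naive(aln, g)
  expect_equal(nrow(v), 0)
})

test_that("a 10 ref / 10 alt site is called as one biallelic SNP, matching a brute-force pileup", {
  seqs <- flat_reference(n = 1, len = 2000, seed = 61)
  site <- 900L
  ref_base <- substr(seqs[[1]], site + 1L, site + 1L)
  alt <- setdiff(c("A", "C", "G", "T"), ref_base)[1]
  aln <- pileup_fixture(seqs, "chr1", site, alt, n_alt = 10, n_ref = 10)
  v <- call_variants_naive(aln, seqs,
                           caller_config(min_alt_count = 2,
                                         min_alt_fraction = 0.2))
  expect_equal(nrow(v), 1)
  expect_equal(v$chrom, "chr1")
  expect_equal(v$pos, site + 1L)
  expect_equal(v$ref, ref_base)
  expect_equal(v$alt, alt)
  expect_equal(v$n_alt, 10L)
  expect_equal(v$dp, 20L)
  pile <- bf_pileup(aln, seqs)
  at <- pile[pile$pos == site & pile$base == alt, ]
  expect_equal(v$n_alt, at$n)
  expect_equal(v$dp, at$depth)
})

test_that("two alternate alleles above threshold give one multiallelic record", {
  seqs <- flat_reference(n = 1, len = 2000, seed = 62)
  site <- 700L
  ref_base <- substr(seqs[[1]], site + 1L, site + 1L)
  alts <- setdiff(c("A", "C", "G", "T"), ref_base)[1:2]
  aln <- dplyr::bind_rows(
    pileup_fixture(seqs, "chr1", site, alts[1], n_alt = 5, n_ref = 5,
                   name_prefix = "a"),
    pileup_fixture(seqs, "chr1", site, alts[2], n_alt = 5, n_ref = 0,
                   name_prefix = "b"))
  v <- call_variants_naive(aln, seqs,
                           caller_config(min_alt_count = 2,
                                         min_alt_fraction = 0.1))
  expect_equal(nrow(v), 1)
  expect_true(grepl(",", v$alt, fixed = TRUE))
  expect_setequal(strsplit(v$alt, ",")[[1]], alts)
  # removed by the biallelic filter downstream
  expect_equal(nrow(basic_site_filter(v)), 0)
})

test_that("QUAL grows monotonically with alternate count and is capped", {
  seqs <- flat_reference(n = 1, len = 3000, seed = 63)
  quals <- vapply(c(2, 4, 6, 9), function(k) {
    site <- 400L + 250L * k
    ref_base <- substr(seqs[[1]], site + 1L, site + 1L)
    alt <- setdiff(c("A", "C", "G", "T"), ref_base)[1]
    aln <- pileup_fixture(seqs, "chr1", site, alt, n_alt = k, n_ref = 3,
                          name_prefix = paste0("q", k))
    call_variants_naive(aln, seqs,
                        caller_config(min_alt_count = 2,
                                      min_alt_fraction = 0.1))$qual
  }, numeric(1))
  expect_equal(quals, c(20, 40, 60, 60))
})

test_that("alignments on unknown contigs are an error", {
  seqs <- flat_reference(n = 1, len = 1000, seed = 64)
  aln <- make_aln("x|chrZ:0:+|chrZ:0:-", substr(seqs[[1]], 1, 30),
                  "chrZ", 0)
  expect_error(call_variants_naive(aln, seqs), "absent from the reference")
})

test_that("duplicate read presentations do not inflate allele counts", {
  seqs <- flat_reference(n = 1, len = 2000, seed = 65)
  site <- 600L
  ref_base <- substr(seqs[[1]], site + 1L, site + 1L)
  alt <- setdiff(c("A", "C", "G", "T"), ref_base)[1]
  aln <- pileup_fixture(seqs, "chr1", site, alt, n_alt = 3, n_ref = 3)
  twice <- dplyr::bind_rows(aln, aln)
  v1 <- call_variants_naive(aln, seqs,
                            caller_config(min_alt_count = 2,
                                          min_alt_fraction = 0.1))
  v2 <- call_variants_naive(twice, seqs,
                            caller_config(min_alt_count = 2,
                                          min_alt_fraction = 0.1))
  expect_equal(v1$n_alt, v2$n_alt)
})
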