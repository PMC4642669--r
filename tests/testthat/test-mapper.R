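test_that("self-mapping an intact reference recovers every origin", {
  g <- simulate_genome(tiny_genome_config(14, chromosome_length = 8000))
  rd <- simulate_read_pairs(g, read_sim_config(read_length = 50,
                                               coverage = 3, seed = 5))
  for (lab in c("strict", "relaxed")) {
    aln <- map_reads_naive(rd, g, stringency_config(lab))
    expect_true(all(!is.na(aln$chrom)))
    expect_true(all(aln$mismatches == 0))
    unique_best <- aln$n_best == 1
    expect_identical(aln$chrom[unique_best], rd$chrom[unique_best])
    expect_identical(aln$pos[unique_best], rd$start[unique_best])
    expect_identical(aln$strand[unique_best], rd$strand[unique_best])
    # ambiguous placements only ever happen inside repeat copies
    expect_lt(mean(!unique_best), 0.1)
    expect_true(all(aln$mapq[!unique_best] == 0))
  }
})

test_that("naive mapper equals the brute-force minimal-Hamming oracle", {
  g <- simulate_genome(tiny_genome_config(15, chromosome_length = 15000))
  d <- degrade_reference(g, degrade_preset("severe", seed = 6))
  expect_lt(sum(nchar(d$contigs)), 100000)
  rd <- simulate_read_pairs(g, read_sim_config(read_length = 50,
                                               coverage = 0.2, seed = 8))
  rd <- rd[seq_len(min(nrow(rd), 60)), ]
  for (lab in c("strict", "relaxed")) {
    rate <- stringency_config(lab)$rate
    aln <- map_reads_naive(rd, d, stringency_config(lab))
    for (i in seq_len(nrow(rd))) {
      oracle <- bf_map(rd$seq[i], d$contigs, rate)
      if (is.null(oracle)) {
        expect_true(is.na(aln$chrom[i]))
      } else {
        expect_identical(aln$chrom[i], oracle$chrom)
        expect_equal(aln$pos[i], oracle$pos)
        expect_identical(aln$strand[i], oracle$strand)
        expect_equal(aln$mismatches[i], oracle$mismatches)
        expect_equal(aln$n_best[i], oracle$n_best)
      }
    }
  }
})

test_that("reads beyond the mismatch budget everywhere stay unmapped", {
  set.seed(77)
  ref <- flat_reference(n = 1, len = 5000, seed = 78)
  # a read sampled from a different random universe: ~37 mismatches expected
  junk <- paste(sample(c("A", "C", "G", "T"), 50, TRUE), collapse = "")
  oracle <- bf_map(junk, ref, 0.02)
  expect_null(oracle)
  aln <- map_reads_naive(make_aln("x|chr1:0:+|chr1:0:-", junk, NA, NA),
                         ref, stringency_config("strict"))
  expect_true(is.na(aln$chrom))
})

test_that("tied best hits in an exact two-copy repeat get MAPQ 0 at the lowest coordinate", {
  set.seed(55)
  block <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  left <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  mid <- paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = "")
  right <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  ref <- c(chrA = paste0(left, block, mid, block, right))
  read <- substr(block, 101, 150) # 50 bp wholly inside the repeated block
  aln <- map_reads_naive(
    make_aln("t|chrA:0:+|chrA:0:-", read, NA, NA), ref,
    stringency_config("strict"))
  expect_equal(aln$n_best, 2L)
  expect_equal(aln$mapq, 0L)
  expect_equal(aln$pos, 300 + 100) # first copy
  # a positive MAPQ threshold removes it
  expect_equal(nrow(read_mapq_filter(aln, 20)), 0)
  expect_equal(nrow(read_mapq_filter(aln, 0)), 1)
})

test_that("SAM export and Rsamtools re-import preserve the alignment payload", {
  g <- simulate_genome(tiny_genome_config(16, chromosome_length = 6000))
  d <- degrade_reference(g, degrade_preset("moderate", seed = 2))
  rd <- simulate_read_pairs(g, read_sim_config(read_length = 50,
                                               coverage = 1, seed = 4))
  aln <- map_reads_naive(rd, d, stringency_config("relaxed"))
  path <- withr::local_tempfile(fileext = ".sam")
  write_sam(aln, d, path)
  back <- read_sam_alignments(path)
  x <- dplyr::arrange(dplyr::filter(aln, !is.na(chrom)), name, mate)
  y <- dplyr::arrange(dplyr::filter(back, !is.na(chrom)), name, mate)
  expect_equal(nrow(x), nrow(y))
  for (col in c("name", "mate", "seq", "chrom", "pos", "strand",
                "mismatches", "mapq"))
    expect_true(all(x[[col]] == y[[col]]), label = paste("column", col))
  # unmapped records survive with the unmapped flag
  expect_equal(sum(is.na(back$chrom)), sum(is.na(aln$chrom)))
})
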