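test_that("default paired-end fragment is 1.8x the read length", {
  for (L in c(50, 100, 150, 300, 500, 1000)) {
    cfg <- read_sim_config(read_length = L)
    expect_equal(cfg$fragment_length, round(1.8 * L))
  }
  expect_equal(read_sim_config(read_length = 50)$fragment_length, 90L)
  expect_equal(read_sim_config(read_length = 1000)$fragment_length, 1800L)
  mp <- read_sim_config(read_length = 150, mode = "mate_pair")
  expect_equal(mp$fragment_length, 3000L)
  expect_equal(mp$coverage, 50)
})

test_that("pair count and realized depth follow coverage arithmetic", {
  seqs <- flat_reference(n = 1, len = 100000, seed = 31)
  rd <- simulate_read_pairs(seqs, read_sim_config(read_length = 100,
                                                  coverage = 100, seed = 1))
  expect_equal(nrow(rd), 2 * 50000) # 50,000 pairs
  realized <- sum(nchar(rd$seq)) / nchar(seqs[[1]])
  expect_lt(abs(realized - 100) / 100, 0.02)
})

test_that("every read is the strand-adjusted source substring at its origin", {
  g <- simulate_genome(tiny_genome_config(13, chromosome_length = 6000))
  rd <- simulate_read_pairs(g, read_sim_config(read_length = 60,
                                               coverage = 2, seed = 7))
  L <- 60L
  truth <- substring(g$chromosomes[rd$chrom], rd$start + 1L, rd$start + L)
  rev <- rd$strand == "-"
  truth[rev] <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(truth[rev])))
  expect_identical(rd$seq, unname(truth))
  expect_true(all(rd$start + L <= nchar(g$chromosomes[rd$chrom])))
})

test_that("origin encoding round-trips losslessly", {
  set.seed(17)
  n <- 1000
  chrom <- sample(paste0("scaffold", 1:20), n, replace = TRUE)
  start1 <- sample.int(1e7, n) - 1L
  start2 <- sample.int(1e7, n) - 1L
  s1 <- sample(c("+", "-"), n, TRUE)
  s2 <- sample(c("+", "-"), n, TRUE)
  names <- encode_origin(paste0("p", 1:n), chrom, start1, s1,
                         chrom, start2, s2)
  d1 <- decode_origin(names, 1L)
  d2 <- decode_origin(names, 2L)
  expect_identical(d1$chrom, chrom)
  expect_identical(d1$start, start1)
  expect_identical(d1$strand, s1)
  expect_identical(d2$start, start2)
  expect_identical(d2$strand, s2)
})

test_that("malformed names raise a parse error, or are counted when tolerated", {
  expect_error(decode_origin("no_delimiters_here"), "origin-encoded")
  mixed <- c(encode_origin("a", "chr1", 5, "+", "chr1", 99, "-"),
             "garbage", "also|bad")
  out <- decode_origin(mixed, 1L, strict = FALSE)
  expect_equal(attr(out, "n_failed"), 2)
  expect_equal(sum(is.na(out$chrom)), 2)
  expect_equal(out$start[1], 5L)
})

test_that("reserved delimiters in names are rejected", {
  expect_error(encode_origin("a|b", "chr1", 1, "+", "chr1", 2, "-"),
               "reserved")
  expect_error(simulate_read_pairs(c("bad:name" = "ACGTACGTACGT"),
                                   read_sim_config(read_length = 4,
                                                   fragment_length = 8)),
               "reserved")
})

test_that("mate-pair mode produces outward-facing pairs at the set fragment", {
  seqs <- flat_reference(n = 1, len = 20000, seed = 41)
  rd <- simulate_read_pairs(seqs, read_sim_config(
    read_length = 150, mode = "mate_pair", coverage = 5, seed = 2))
  pair <- dplyr::group_by(rd, name)
  span <- dplyr::summarise(pair, w = max(start) + 150 - min(start),
                           opposite = dplyr::n_distinct(strand) == 2)
  expect_true(all(span$w == 3000))
  expect_true(all(span$opposite))
})

test_that("FASTQ export interleaves mates with origin-encoded names", {
  g <- simulate_genome(tiny_genome_config(2, chromosome_length = 5000))
  rd <- simulate_read_pairs(g, read_sim_config(read_length = 50,
                                               coverage = 1, seed = 3))
  path <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(rd, path)
  fq <- Biostrings::readDNAStringSet(path, format = "fastq")
  expect_equal(length(fq), nrow(rd))
  expect_identical(unname(as.character(fq)), rd$seq)
})
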