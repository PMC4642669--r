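test_that("classification boundary sits exactly at the position tolerance", {
  seqs <- flat_reference(n = 2, len = 4000, seed = 71)
  L <- 40L
  tol <- 100L
  cfg <- mismap_config(position_tolerance = tol)
  origin <- 1000L
  mk <- function(offset, chrom = "chr1") {
    pos <- origin + offset
    make_aln(encode_origin("r", "chr1", origin, "+", "chr1", origin, "-"),
             substr(seqs[[chrom]], pos + 1L, pos + L), chrom, pos)
  }
  expect_false(classify_mismapped(mk(0L), seqs, cfg)$mismapped)
  expect_false(classify_mismapped(mk(tol), seqs, cfg)$mismapped)
  expect_true(classify_mismapped(mk(tol + 1L), seqs, cfg)$mismapped)
  expect_true(classify_mismapped(mk(-(tol + 1L)), seqs, cfg)$mismapped)
  expect_true(classify_mismapped(mk(0L, chrom = "chr2"), seqs,
                                 cfg)$mismapped)
})

test_that("mismap percentage is monotone non-increasing in the tolerance", {
  seqs <- flat_reference(n = 1, len = 6000, seed = 72)
  set.seed(4)
  offsets <- sample(0:1500, 40, replace = TRUE)
  aln <- dplyr::bind_rows(lapply(seq_along(offsets), function(i) {
    pos <- 2000L + offsets[i]
    make_aln(encode_origin(paste0("r", i), "chr1", 2000L, "+",
                           "chr1", 2000L, "-"),
             substr(seqs[[1]], pos + 1L, pos + 30L), "chr1", pos)
  }))
  pcts <- vapply(c(0L, 50L, 300L, 1000L, 2000L), function(tol) {
    mean(classify_mismapped(aln, seqs,
                            mismap_config(position_tolerance = tol))$mismapped)
  }, numeric(1))
  expect_true(all(diff(pcts) <= 0))
  expect_equal(pcts[length(pcts)], 0) # tolerance beyond any offset
})

test_that("per-SNP assessment counts unique alt-carrying reads and their mismaps", {
  seqs <- flat_reference(n = 2, len = 3000, seed = 73)
  site <- 1500L
  ref_base <- substr(seqs[["chr1"]], site + 1L, site + 1L)
  alt <- setdiff(c("A", "C", "G", "T"), ref_base)[1]
  # 3 alt reads claiming an origin on chr2 (mismapped), 1 alt read with the
  # correct origin, 4 reference reads
  mis <- pileup_fixture(seqs, "chr1", site, alt, n_alt = 3, n_ref = 0,
                        name_prefix = "mm", origin_chrom = "chr2",
                        origin_start = 100L)
  good <- pileup_fixture(seqs, "chr1", site, alt, n_alt = 1, n_ref = 4,
                         name_prefix = "ok")
  aln <- dplyr::bind_rows(mis, good)
  snp <- tibble::tibble(chrom = "chr1", pos = site + 1L, ref = ref_base,
                        alt = alt, qual = 40, dp = 8L)
  out <- assess_mismapping(snp, aln, seqs)
  expect_equal(out$n_alt_reads, 4L)
  expect_equal(out$n_mismapped, 3L)
  expect_equal(out$pct_mismapped, 75)
  expect_true(out$defined)
  # duplicating the alignments changes nothing
  out2 <- assess_mismapping(snp, dplyr::bind_rows(aln, aln), seqs)
  expect_equal(out2$n_alt_reads, 4L)
  expect_equal(out2$pct_mismapped, 75)
})

test_that("sites whose covering reads all carry the reference are undefined", {
  seqs <- flat_reference(n = 1, len = 2000, seed = 74)
  site <- 800L
  ref_base <- substr(seqs[[1]], site + 1L, site + 1L)
  alt <- setdiff(c("A", "C", "G", "T"), ref_base)[1]
  aln <- pileup_fixture(seqs, "chr1", site, alt, n_alt = 0, n_ref = 6)
  snp <- tibble::tibble(chrom = "chr1", pos = site + 1L, ref = ref_base,
                        alt = alt, qual = 40, dp = 6L)
  out <- assess_mismapping(snp, aln, seqs)
  expect_false(out$defined)
  expect_equal(out$n_alt_reads, 0L)
  expect_true(is.na(out$pct_mismapped))
})

test_that("call-set summaries average defined sites and exclude FP-free sets", {
  a <- tibble::tibble(
    set = c("s1", "s1", "s2", "s2", "s3"),
    chrom = "c", pos = 1:5, alt = "A",
    n_alt_reads = c(5L, 5L, 4L, 4L, 0L),
    n_mismapped = c(4L, 4L, 4L, 4L, 0L),
    pct_mismapped = c(70, 90, 100, 100, NA),
    defined = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  out <- summarize_mismapping(a, set = "set")
  expect_equal(nrow(out$per_set), 2) # s3 has no FP SNPs
  expect_equal(sort(out$per_set$mean_pct), c(80, 100))
  expect_equal(out$grand_mean, 90)
  none <- summarize_mismapping(a[!a$defined, ], set = "set")
  expect_true(is.na(none$grand_mean))
})

test_that("undecodable read names are excluded and counted", {
  seqs <- flat_reference(n = 1, len = 2000, seed = 75)
  aln <- dplyr::bind_rows(
    make_aln(encode_origin("ok", "chr1", 500L, "+", "chr1", 500L, "-"),
             substr(seqs[[1]], 501L, 530L), "chr1", 500L),
    make_aln("external_read_1", substr(seqs[[1]], 601L, 630L), "chr1", 600L))
  out <- classify_mismapped(aln, seqs)
  expect_equal(nrow(out), 1)
  expect_equal(attr(out, "n_undecodable"), 1)
})
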