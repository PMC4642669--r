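# Independent oracles used to cross-check the implementation.

# Brute-force minimal-Hamming placement over every position and strand of
# every reference sequence. Tie-break identical to the mapper's contract:
# lowest (sequence-in-order, coordinate), forward strand before reverse.
bf_map <- function(read, seqs, rate) {
  L <- nchar(read)
  m <- floor(rate * L + 1e-9)
  rows <- list()
  for (cn in names(seqs)) {
    n <- nchar(seqs[[cn]])
    if (n < L) next
    subj <- Biostrings::DNAString(seqs[[cn]])
    starts <- seq_len(n - L + 1L)
    for (st in c("+", "-")) {
      pat <- if (st == "+") read else
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(read)))
      d <- Biostrings::neditStartingAt(Biostrings::DNAString(pat), subj,
                                       starting.at = starts,
                                       with.indels = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = cn, pos = starts - 1L, strand = st, d = d,
        chrom_rank = match(cn, names(seqs)))
    }
  }
  all <- do.call(rbind, rows)
  all <- all[order(all$chrom_rank, all$pos, all$strand), ]
  md <- min(all$d)
  if (md > m) return(NULL)
  hit <- all[all$d == md, ]
  list(chrom = hit$chrom[1], pos = hit$pos[1], strand = hit$strand[1],
       mismatches = md, n_best = nrow(hit))
}

# Brute-force pileup: per-site base counts from an alignment tibble,
# counting each (name, mate) once. Returns base counts and site depth.
bf_pileup <- function(alignments, seqs) {
  aln <- alignments[!is.na(alignments$chrom), ]
  recs <- list()
  for (i in seq_len(nrow(aln))) {
    s <- aln$seq[i]
    if (aln$strand[i] == "-")
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    bases <- strsplit(s, "", fixed = TRUE)[[1]]
    recs[[i]] <- data.frame(
      chrom = aln$chrom[i], pos = aln$pos[i] + seq_along(bases) - 1L,
      base = bases, read = paste0(aln$name[i], "/", aln$mate[i]))
  }
  df <- do.call(rbind, recs)
  df <- unique(df)
  depth <- stats::aggregate(read ~ chrom + pos, df,
                            function(x) length(unique(x)))
  names(depth)[3] <- "depth"
  counts <- stats::aggregate(read ~ chrom + pos + base, df,
                             function(x) length(unique(x)))
  names(counts)[4] <- "n"
  merge(counts, depth, by = c("chrom", "pos"))
}

# Two-sided exact binomial p-value by direct summation of the density.
bf_binom_two_sided <- function(k, n, p) {
  d <- dbinom(0:n, n, p)
  sum(d[d <= dbinom(k, n, p) * (1 + 1e-7)])
}

# aov-based oracle for the balanced decomposition: named treatment SS,
# residual SS and replicate-stratum SS.
aov_oracle <- function(data, response = "n_fp", replicate = "replicate") {
  factors <- setdiff(names(data), c(response, replicate))
  y <- log_fp_transform(data[[response]])
  d2 <- data
  d2$.y <- y
  d2$.rep <- factor(d2[[replicate]])
  form <- stats::as.formula(paste(".y ~", paste(factors, collapse = " * "),
                                  "+ Error(.rep)"))
  fit <- summary(stats::aov(form, data = d2))
  within <- fit[["Error: Within"]][[1]]
  ss <- stats::setNames(within[["Sum Sq"]], trimws(rownames(within)))
  list(terms = ss[names(ss) != "Residuals"],
       residual = unname(ss[["Residuals"]]),
       stratum = fit[["Error: .rep"]][[1]][["Sum Sq"]])
}
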