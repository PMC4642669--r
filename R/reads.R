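#' Configuration for error-free read simulation
#'
#' Reads are sampled error-free and haploid, so any SNP later called from
#' their mappings is a false positive by construction. Paired-end fragments
#' default to 1.8 times the read length (90/180/270/540/900/1800 bp for the
#' six standard lengths); mate pairs use a 3000 bp fragment at 50-fold
#' coverage. Fragment lengths are fixed, not jittered, which keeps the
#' coverage arithmetic exact.
#'
#' @param read_length read length L in bp.
#' @param coverage fold coverage; defaults to 100 for paired-end and 50 for
#'   mate-pair mode.
#' @param mode `"paired_end"` (innie FR pairs) or `"mate_pair"`
#'   (outward-facing RF pairs).
#' @param fragment_length fragment size in bp; defaults to `1.8 * L` for
#'   paired-end and 3000 for mate-pair mode.
#' @param name_prefix prefix for origin-encoded read names.
#' @param seed integer seed.
#' @return a `read_sim_config` list.
#' @export
read_sim_config <- function(read_length = 100,
                            coverage = NULL,
                            mode = c("paired_end", "mate_pair"),
                            fragment_length = NULL,
                            name_prefix = "sim",
                            seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(coverage)) coverage <- if (mode == "paired_end") 100 else 50
  if (is.null(fragment_length))
    fragment_length <- if (mode == "paired_end")
      round(1.8 * read_length) else 3000L
  if (fragment_length < read_length)
    abort("fragment_length must be at least the read length")
  stopifnot(read_length >= 1, coverage > 0)
  structure(list(read_length = as.integer(read_length),
                 coverage = coverage, mode = mode,
                 fragment_length = as.integer(fragment_length),
                 name_prefix = name_prefix, seed = as.integer(seed)),
            class = "read_sim_config")
}

#' Simulate error-free read pairs with provenance-encoded names
#'
#' Fragment start positions are uniform over each sequence (weighted by
#' sequence length); the number of pairs is `round(coverage * G / (2 * L))`.
#' Every read equals the strand-adjusted substring of its source at the
#' origin encoded in its name, so origins can be recovered downstream with
#' [decode_origin()] even from externally produced alignments.
#'
#' @param source a `toy_genome`, `degraded_reference` or named character
#'   vector of sequences.
#' @param cfg a [read_sim_config()].
#' @return tibble with one row per read (two per pair): `name`, `mate`,
#'   `seq`, and the true origin columns `chrom`, `start` (0-based),
#'   `strand`.
#' @export
simulate_read_pairs <- function(source, cfg = read_sim_config()) {
  stopifnot(inherits(cfg, "read_sim_config"))
  seqs <- reference_sequences(source)
  if (any(grepl("[|:]", names(seqs))))
    abort("sequence names must not contain '|' or ':' (reserved by the origin encoding)")
  lens <- nchar(seqs)
  usable <- lens >= cfg$fragment_length
  if (!any(usable))
    abort("no source sequence is at least one fragment long")
  seqs <- seqs[usable]
  lens <- lens[usable]
  set.seed(cfg$seed)

  G <- sum(lens)
  L <- cfg$read_length
  FL <- cfg$fragment_length
  n_pairs <- round(cfg$coverage * G / (2 * L))
  if (n_pairs < 1) abort("coverage too low: zero pairs requested")

  chrom <- sample(names(seqs), n_pairs, replace = TRUE,
                  prob = lens - FL + 1)
  max_start <- lens[chrom] - FL
  fs <- as.integer(floor(runif(n_pairs) * (max_start + 1)))
  flip <- runif(n_pairs) < 0.5 # fragment sampled from the reverse strand

  # left/right read windows of the fragment, in forward coordinates
  left_s <- fs
  right_s <- fs + FL - L
  if (cfg$mode == "paired_end") {
    # innie: one mate forward off the left end, the other reverse off the right
    m1_start <- ifelse(flip, right_s, left_s)
    m1_strand <- ifelse(flip, "-", "+")
    m2_start <- ifelse(flip, left_s, right_s)
    m2_strand <- ifelse(flip, "+", "-")
  } else {
    # outie mate pairs: reverse off the left end, forward off the right
    m1_start <- ifelse(flip, right_s, left_s)
    m1_strand <- ifelse(flip, "+", "-")
    m2_start <- ifelse(flip, left_s, right_s)
    m2_strand <- ifelse(flip, "-", "+")
  }

  name <- paste0(cfg$name_prefix, "_", seq_len(n_pairs),
                 "|", chrom, ":", m1_start, ":", m1_strand,
                 "|", chrom, ":", m2_start, ":", m2_strand)

  grab <- function(starts, strands) {
    out <- substring(seqs[chrom], starts + 1L, starts + L)
    rev <- strands == "-"
    if (any(rev)) out[rev] <- revcomp(out[rev])
    unname(out)
  }

  tibble(
    name = rep(name, 2),
    mate = rep(c(1L, 2L), each = n_pairs),
    seq = c(grab(m1_start, m1_strand), grab(m2_start, m2_strand)),
    chrom = rep(chrom, 2),
    start = c(m1_start, m2_start),
    strand = c(m1_strand, m2_strand)
  ) %>% arrange(.data$name, .data$mate)
}

#' Encode read-pair origins into a read name
#'
#' The name format is `prefix|chrom:start:strand|chrom:start:strand`, with
#' the two origin tokens belonging to mates 1 and 2. This is the provenance
#' contract every downstream stage relies on.
#'
#' @param prefix pair identifier (must not contain `|` or `:`).
#' @param chrom1,start1,strand1 origin of mate 1 (0-based start).
#' @param chrom2,start2,strand2 origin of mate 2.
#' @return character vector of encoded names.
#' @export
encode_origin <- function(prefix, chrom1, start1, strand1,
                          chrom2, start2, strand2) {
  if (any(grepl("[|:]", c(prefix, chrom1, chrom2))))
    abort("'|' and ':' are reserved delimiters in origin-encoded names")
  stopifnot(all(strand1 %in% c("+", "-")), all(strand2 %in% c("+", "-")))
  paste0(prefix, "|", chrom1, ":", as.integer(start1), ":", strand1,
         "|", chrom2, ":", as.integer(start2), ":", strand2)
}

#' Decode the true origin of reads from their names
#'
#' @param name character vector of origin-encoded names.
#' @param mate mate index (1 or 2), recycled against `name`.
#' @param strict error on the first malformed name (default) or return NA
#'   rows for malformed names, with the number of failures in the
#'   `n_failed` attribute.
#' @return tibble with `chrom`, `start`, `strand`, `mate`; one row per input.
#' @export
decode_origin <- function(name, mate = 1L, strict = TRUE) {
  n <- length(name)
  mate <- rep_len(as.integer(mate), n)
  parts <- stringr::str_split_fixed(name, stringr::fixed("|"), 4)
  tok <- ifelse(mate == 1L, parts[, 2], parts[, 3])
  f <- stringr::str_split_fixed(tok, stringr::fixed(":"), 4)
  ok <- parts[, 2] != "" & parts[, 3] != "" & parts[, 4] == "" &
    f[, 1] != "" & grepl("^[0-9]+$", f[, 2]) & f[, 3] %in% c("+", "-") &
    f[, 4] == "" & mate %in% c(1L, 2L)
  if (strict && !all(ok)) {
    bad <- which(!ok)[1]
    abort(paste0("read name is not origin-encoded: '", name[bad],
                 "' (reads must come from this package's simulator)"))
  }
  out <- tibble(chrom = ifelse(ok, f[, 1], NA_character_),
                start = ifelse(ok, suppressWarnings(as.integer(f[, 2])),
                               NA_integer_),
                strand = ifelse(ok, f[, 3], NA_character_),
                mate = mate)
  attr(out, "n_failed") <- sum(!ok)
  out
}

#' Write reads to FASTQ
#'
#' Mates are interleaved with `/1` and `/2` suffixes; base qualities are
#' constant `I` (the reads are error-free).
#'
#' @param reads a [simulate_read_pairs()] tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual <- vapply(nchar(reads$seq), function(n)
    paste(rep("I", n), collapse = ""), character(1))
  lines <- as.vector(rbind(paste0("@", reads$name, "/", reads$mate),
                           reads$seq, "+", qual))
  writeLines(lines, path)
  invisible(path)
}
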