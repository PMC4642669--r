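#' SNP filter-chain settings
#'
#' The standard post-calling chain: keep biallelic records only, remove
#' records with QUAL below 20, and optionally cap site depth (records with
#' DP above the cap are removed; the boundary value itself is kept). MAPQ
#' filtering is a read-level operation applied before calling (see
#' [read_mapq_filter()]); its threshold is carried here so a single config
#' describes a call set.
#'
#' @param min_qual minimum QUAL retained (default 20; QUAL < 20 removed).
#' @param max_depth depth cap (default 150).
#' @param depth_enabled apply the depth filter at all?
#' @param mapq_threshold read-level MAPQ threshold (0 = off, 20 = on).
#' @param biallelic_only drop multiallelic records?
#' @return a `filter_config` list.
#' @export
filter_config <- function(min_qual = 20, max_depth = 150,
                          depth_enabled = TRUE, mapq_threshold = 0,
                          biallelic_only = TRUE) {
  stopifnot(min_qual >= 0, max_depth >= 0, mapq_threshold >= 0)
  structure(list(min_qual = min_qual, max_depth = max_depth,
                 depth_enabled = isTRUE(depth_enabled),
                 mapq_threshold = mapq_threshold,
                 biallelic_only = isTRUE(biallelic_only)),
            class = "filter_config")
}

#' Biallelic and quality site filter
#'
#' Retains records with exactly one ALT allele and `QUAL >= min_qual`
#' (records at exactly the threshold are kept). Records with a missing QUAL
#' are rejected with a warning. Order is preserved.
#'
#' @param records variant tibble with `alt` and `qual` columns.
#' @param cfg a [filter_config()].
#' @return the retained records.
#' @export
basic_site_filter <- function(records, cfg = filter_config()) {
  stopifnot(inherits(cfg, "filter_config"))
  if (nrow(records) == 0) return(records)
  no_qual <- is.na(records$qual)
  if (any(no_qual)) {
    warn(paste0(sum(no_qual), " record(s) without QUAL rejected"))
    records <- records[!no_qual, , drop = FALSE]
  }
  keep <- records$qual >= cfg$min_qual
  if (cfg$biallelic_only)
    keep <- keep & !grepl(",", records$alt, fixed = TRUE)
  records[keep, , drop = FALSE]
}

#' Maximum-depth site filter
#'
#' Retains records with `DP <= max_depth`, targeting the read pileups that
#' collapsed repeats attract. Disabled mode returns the input unchanged.
#'
#' @param records variant tibble with a `dp` column.
#' @param cfg a [filter_config()]; `cfg$depth_enabled` switches the filter.
#' @return the retained records.
#' @export
depth_filter <- function(records, cfg = filter_config()) {
  stopifnot(inherits(cfg, "filter_config"))
  if (!cfg$depth_enabled || nrow(records) == 0) return(records)
  records[records$dp <= cfg$max_depth, , drop = FALSE]
}

#' Apply the full site filter chain
#'
#' [basic_site_filter()] followed by [depth_filter()]. The two site filters
#' are order-independent and idempotent.
#'
#' @inheritParams basic_site_filter
#' @return the retained records.
#' @export
apply_filter_chain <- function(records, cfg = filter_config()) {
  records %>% basic_site_filter(cfg) %>% depth_filter(cfg)
}

#' Annotate rather than drop failing records
#'
#' Audit variant of the chain: adds a `filter` column with `PASS` or a
#' semicolon-joined list of `multiallelic`, `lowqual`, `highdepth`.
#'
#' @inheritParams basic_site_filter
#' @return `records` with a `filter` column added.
#' @export
flag_filter_chain <- function(records, cfg = filter_config()) {
  stopifnot(inherits(cfg, "filter_config"))
  tags <- lapply(seq_len(nrow(records)), function(i) {
    t <- character(0)
    if (cfg$biallelic_only && grepl(",", records$alt[i], fixed = TRUE))
      t <- c(t, "multiallelic")
    if (!is.na(records$qual[i]) && records$qual[i] < cfg$min_qual)
      t <- c(t, "lowqual")
    if (cfg$depth_enabled && records$dp[i] > cfg$max_depth)
      t <- c(t, "highdepth")
    if (length(t) == 0) "PASS" else paste(t, collapse = ";")
  })
  records$filter <- unlist(tags, use.names = FALSE)
  records
}

#' Write variant records as VCF
#'
#' Sites-only VCF v4.2 with DP in INFO. Readable back with any VCF parser;
#' [read_vcf_records()] round-trips it.
#'
#' @param records variant tibble (`chrom`, `pos`, `ref`, `alt`, `qual`,
#'   `dp`, optional `filter`).
#' @param reference reference container for `##contig` header lines.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(records, reference, path) {
  seqs <- reference_sequences(reference)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=fpsnp",
           paste0("##contig=<ID=", names(seqs), ",length=", nchar(seqs), ">"),
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Site read depth\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- character(0)
  if (nrow(records) > 0) {
    filt <- if ("filter" %in% names(records)) records$filter else
      rep(".", nrow(records))
    body <- paste(records$chrom, records$pos, ".", records$ref, records$alt,
                  records$qual, filt, paste0("DP=", records$dp), sep = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read variant records from a VCF file
#'
#' Parses with vcfR and returns the tibble layout used throughout the
#' package. DP is taken from INFO when present.
#'
#' @param path VCF file (plain or gzipped).
#' @return variant tibble: `chrom`, `pos`, `ref`, `alt`, `qual`, `dp`.
#' @export
read_vcf_records <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0)
    return(tibble(chrom = character(), pos = integer(), ref = character(),
                  alt = character(), qual = numeric(), dp = integer()))
  dp <- suppressWarnings(as.integer(
    stringr::str_match(fix$INFO, "(?:^|;)DP=([0-9]+)")[, 2]))
  tibble(chrom = fix$CHROM, pos = as.integer(fix$POS), ref = fix$REF,
         alt = fix$ALT, qual = suppressWarnings(as.numeric(fix$QUAL)),
         dp = dp)
}
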