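#' Mismapping-classification settings
#'
#' A read is mismapped when its placement, traced back to source-genome
#' coordinates, lies on a different chromosome than its encoded origin or
#' more than `position_tolerance` bp away on the same chromosome. The
#' tolerance defaults to one read length — the smallest scale at which a
#' placement can still overlap its true locus.
#'
#' @param position_tolerance same-chromosome tolerance in bp, or `NULL` to
#'   use each read's own length.
#' @param dedupe_by_name count each (name, mate) only once per SNP.
#' @return a `mismap_config` list.
#' @export
mismap_config <- function(position_tolerance = NULL, dedupe_by_name = TRUE) {
  if (!is.null(position_tolerance)) stopifnot(position_tolerance >= 0)
  structure(list(position_tolerance = position_tolerance,
                 dedupe_by_name = isTRUE(dedupe_by_name)),
            class = "mismap_config")
}

#' Classify mapped reads as correctly mapped or mismapped
#'
#' Decodes each read's true origin from its name, traces the mapped
#' coordinates back to the source genome (identity for an intact reference,
#' provenance lookup for a degraded one) and applies the positional rule.
#' Reads with undecodable names are excluded and counted in the
#' `n_undecodable` attribute.
#'
#' @param alignments mapped alignment tibble.
#' @param reference the reference the reads were mapped to.
#' @param cfg a [mismap_config()].
#' @return `alignments` with `src_chrom`, `src_pos` and logical `mismapped`
#'   columns added.
#' @export
classify_mismapped <- function(alignments, reference, cfg = mismap_config()) {
  stopifnot(inherits(cfg, "mismap_config"))
  aln <- alignments %>% filter(!is.na(.data$chrom))
  org <- decode_origin(aln$name, aln$mate, strict = FALSE)
  n_bad <- attr(org, "n_failed")
  ok <- !is.na(org$chrom)
  aln <- aln[ok, , drop = FALSE]
  org <- org[ok, , drop = FALSE]
  src <- map_to_source(reference, aln$chrom, aln$pos)
  tol <- if (is.null(cfg$position_tolerance)) nchar(aln$seq) else
    rep_len(cfg$position_tolerance, nrow(aln))
  aln$src_chrom <- src$src_chrom
  aln$src_pos <- src$src_pos
  aln$mismapped <- is.na(src$src_chrom) | src$src_chrom != org$chrom |
    abs(src$src_pos - org$start) > tol
  attr(aln, "n_undecodable") <- n_bad
  aln
}

#' Per-SNP mismapping assessment
#'
#' For each retained SNP, takes the unique covering reads that carry the
#' alternate allele and reports what percentage of them are mismapped.
#' Sites with no alternate-carrying covering reads are returned with
#' `defined = FALSE`.
#'
#' @param variants filtered variant tibble (biallelic records).
#' @param alignments alignment tibble for the same call set (after any
#'   read-level MAPQ filtering, i.e. the reads the caller actually saw).
#' @param reference the reference mapped against.
#' @param cfg a [mismap_config()].
#' @return tibble with one row per SNP: `chrom`, `pos`, `alt`,
#'   `n_alt_reads`, `n_mismapped`, `pct_mismapped`, `defined`.
#' @export
assess_mismapping <- function(variants, alignments, reference,
                              cfg = mismap_config()) {
  base <- variants %>%
    select("chrom", "pos", "alt") %>%
    mutate(n_alt_reads = 0L, n_mismapped = 0L,
           pct_mismapped = NA_real_, defined = FALSE)
  if (nrow(variants) == 0) return(base)
  aln <- classify_mismapped(alignments, reference, cfg)
  if (nrow(aln) == 0) return(base)
  seqs <- reference_sequences(reference)
  ev <- mismatch_events(aln, seqs) %>%
    mutate(pos = .data$pos + 1L) # to VCF coordinates
  aln_keys <- aln %>%
    distinct(.data$name, .data$mate, .keep_all = TRUE) %>%
    select("name", "mate", "mismapped")

  counted <- ev %>%
    inner_join(variants %>% select("chrom", "pos", "alt"),
               by = c("chrom", "pos")) %>%
    filter(.data$read_base == .data$alt)
  if (cfg$dedupe_by_name)
    counted <- counted %>%
      distinct(.data$chrom, .data$pos, .data$name, .data$mate,
               .keep_all = TRUE)
  got <- counted %>%
    left_join(aln_keys, by = c("name", "mate")) %>%
    group_by(.data$chrom, .data$pos, .data$alt) %>%
    summarise(n_alt_reads = n(), n_mismapped = sum(.data$mismapped),
              .groups = "drop")

  base %>%
    select("chrom", "pos", "alt") %>%
    left_join(got, by = c("chrom", "pos", "alt")) %>%
    mutate(n_alt_reads = dplyr::coalesce(.data$n_alt_reads, 0L),
           n_mismapped = dplyr::coalesce(.data$n_mismapped, 0L),
           defined = .data$n_alt_reads > 0L,
           pct_mismapped = ifelse(.data$defined,
                                  100 * .data$n_mismapped / .data$n_alt_reads,
                                  NA_real_))
}

#' Summarise mismapping across call sets
#'
#' Means are taken over defined assessments only; call sets with no
#' false-positive SNPs are excluded from the grand mean, which is the mean
#' of per-set means over the remaining sets.
#'
#' @param assessments an [assess_mismapping()] tibble, optionally with a
#'   grouping column naming the call set each row belongs to.
#' @param set name of the call-set column; `NULL` treats all rows as one
#'   set.
#' @return list with `per_set` (tibble of per-set `n_snps` and `mean_pct`)
#'   and `grand_mean` (NA when no set contains FP SNPs).
#' @export
summarize_mismapping <- function(assessments, set = NULL) {
  a <- assessments %>% filter(.data$defined)
  if (is.null(set)) {
    a$`..set` <- "all"
    set <- "..set"
  }
  per_set <- a %>%
    group_by(dplyr::across(dplyr::all_of(set))) %>%
    summarise(n_snps = n(), mean_pct = mean(.data$pct_mismapped),
              .groups = "drop")
  grand <- if (nrow(per_set) == 0) NA_real_ else mean(per_set$mean_pct)
  list(per_set = per_set, grand_mean = grand)
}
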