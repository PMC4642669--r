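#' Annotation settings
#'
#' @param flank flanking bases either side of a SNP site extracted into its
#'   manifest sequence (default 120).
#' @param feature_precedence label order used to resolve sites covered by
#'   more than one feature interval.
#' @param density_window window size in bp for positional density tracks.
#' @return an `annotate_config` list.
#' @export
annotate_config <- function(flank = 120L,
                            feature_precedence = c("TE", "pseudogene",
                                                   "CDS", "intergenic"),
                            density_window = 2000L) {
  stopifnot(flank >= 0, density_window > 0)
  structure(list(flank = as.integer(flank),
                 feature_precedence = feature_precedence,
                 density_window = as.integer(density_window)),
            class = "annotate_config")
}

#' Extract SNP manifest sequences
#'
#' A manifest is the SNP site base plus up to `flank` bases either side,
#' truncated at sequence ends (truncation is flagged). Manifests can be
#' exported as FASTA for external BLAST-style annotation workflows.
#'
#' @param reference reference container holding the sequences the SNPs were
#'   called on.
#' @param chrom,pos vectors of sequence name and 1-based SNP position.
#' @param flank flank size in bp.
#' @return tibble with `chrom`, `pos`, `start`, `end` (1-based inclusive
#'   extracted window), `seq` and `truncated`.
#' @export
extract_manifest <- function(reference, chrom, pos, flank = 120L) {
  seqs <- reference_sequences(reference)
  stopifnot(flank >= 0)
  lens <- nchar(seqs)
  if (any(!chrom %in% names(seqs)))
    abort("manifest requested on a sequence absent from the reference")
  L <- lens[chrom]
  if (any(pos < 1 | pos > L))
    abort("manifest position outside its sequence")
  s <- pmax(1L, as.integer(pos) - as.integer(flank))
  e <- pmin(as.integer(L), as.integer(pos) + as.integer(flank))
  tibble(chrom = as.character(chrom), pos = as.integer(pos),
         start = s, end = e,
         seq = unname(substring(seqs[chrom], s, e)),
         truncated = (e - s) < 2L * as.integer(flank))
}

#' Write manifest sequences as FASTA
#'
#' @param manifests an [extract_manifest()] tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_manifest_fasta <- function(manifests, path) {
  ss <- Biostrings::DNAStringSet(manifests$seq)
  names(ss) <- paste0(manifests$chrom, "_", manifests$pos)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Assign a feature label to each SNP site
#'
#' Classification is by interval overlap at the site position against the
#' ground-truth annotation, with ties resolved by precedence (TE over
#' pseudogene over CDS over intergenic by default). Sites on sequences
#' absent from the annotation, or covered by no interval, are labelled
#' `unannotated`.
#'
#' @param snps tibble with `chrom` and `pos` (1-based) columns; for SNPs on
#'   a degraded reference, map coordinates to the source genome first with
#'   [map_to_source()].
#' @param features feature tibble (`chrom`, `start`, `end` 0-based
#'   half-open, `label`), e.g. `genome$features`.
#' @param cfg an [annotate_config()].
#' @return `snps` with a `label` column added.
#' @export
classify_positions <- function(snps, features, cfg = annotate_config()) {
  stopifnot(inherits(cfg, "annotate_config"))
  if (nrow(snps) == 0) {
    snps$label <- character(0)
    return(snps)
  }
  prec <- cfg$feature_precedence
  q <- snps %>% mutate(.row = row_number(), p0 = .data$pos - 1L)
  hits <- q %>%
    select(".row", "chrom", "p0") %>%
    left_join(features, by = "chrom", relationship = "many-to-many") %>%
    filter(!is.na(.data$start), .data$p0 >= .data$start,
           .data$p0 < .data$end) %>%
    mutate(rank = match(.data$label, prec)) %>%
    arrange(.data$.row, .data$rank) %>%
    distinct(.data$.row, .keep_all = TRUE) %>%
    select(".row", "label")
  out <- q %>% left_join(hits, by = ".row")
  snps$label <- dplyr::coalesce(out$label, "unannotated")
  snps
}

#' Feature-composition enrichment of SNP sites
#'
#' Compares the label composition of SNP sites against the genome baseline
#' with a two-sided exact binomial test per label, reporting enrichment
#' ratios (observed / baseline proportion).
#'
#' @param labels character vector of per-SNP labels (one per SNP), or a
#'   tibble with a `label` column.
#' @param baseline tibble with `label` and `prop` columns, e.g. from
#'   [feature_base_fraction()].
#' @return tibble with one row per label in either set: `label`,
#'   `n_snps`, `observed_prop`, `baseline_prop`, `enrichment_ratio`,
#'   `p_value`.
#' @export
composition_enrichment <- function(labels, baseline) {
  if (is.data.frame(labels)) labels <- labels$label
  if (length(labels) == 0) abort("no labelled SNPs to test")
  obs <- tibble(label = labels) %>% count(.data$label, name = "n_snps")
  n_total <- sum(obs$n_snps)
  out <- baseline %>%
    select("label", baseline_prop = "prop") %>%
    dplyr::full_join(obs, by = "label") %>%
    mutate(n_snps = dplyr::coalesce(.data$n_snps, 0L),
           baseline_prop = dplyr::coalesce(.data$baseline_prop, 0),
           observed_prop = .data$n_snps / n_total,
           enrichment_ratio = ifelse(.data$baseline_prop > 0,
                                     .data$observed_prop / .data$baseline_prop,
                                     NA_real_))
  out$p_value <- vapply(seq_len(nrow(out)), function(i) {
    p <- out$baseline_prop[i]
    if (p <= 0 || p >= 1) return(NA_real_)
    stats::binom.test(out$n_snps[i], n_total, p)$p.value
  }, numeric(1))
  out %>% arrange(dplyr::desc(.data$enrichment_ratio))
}

#' Positional density of SNPs along chromosomes
#'
#' Counts SNPs in fixed windows along each chromosome; the output covers
#' every window of every chromosome (zero counts included), ready for
#' plotting with [plot_positional_density()].
#'
#' @param snps tibble with `chrom` and `pos` (1-based) columns.
#' @param chrom_lengths named vector of chromosome lengths.
#' @param window window size in bp.
#' @return tibble with `chrom`, `window_start` (0-based), `window_end`,
#'   `n_snps`.
#' @export
positional_density <- function(snps, chrom_lengths, window = 2000L) {
  stopifnot(window > 0)
  grid <- purrr::map_dfr(names(chrom_lengths), function(cn) {
    ws <- seq(0L, max(0L, chrom_lengths[[cn]] - 1L), by = window)
    tibble(chrom = cn, window_start = as.integer(ws),
           window_end = as.integer(pmin(ws + window, chrom_lengths[[cn]])))
  })
  if (nrow(snps) == 0) {
    grid$n_snps <- 0L
    return(grid)
  }
  cnt <- snps %>%
    mutate(window_start = as.integer((.data$pos - 1L) %/% window * window)) %>%
    count(.data$chrom, .data$window_start, name = "n_snps")
  grid %>%
    left_join(cnt, by = c("chrom", "window_start")) %>%
    mutate(n_snps = dplyr::coalesce(.data$n_snps, 0L))
}
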