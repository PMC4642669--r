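#' Configuration for a simulated toy genome
#'
#' The simulated genome is a scaled-down analogue of a small eukaryote
#' chromosome set: each chromosome carries a central, repeat-rich
#' "pericentromeric" block into which transposable-element (TE) repeat family
#' copies are placed preferentially, with the chromosome arms tiled by coding
#' sequence (CDS), pseudogene and intergenic blocks. All coordinates are
#' 0-based, half-open.
#'
#' @param n_chromosomes number of chromosomes.
#' @param chromosome_length length of each chromosome in bp.
#' @param repeat_families list of family specs from [repeat_family()].
#' @param pericentromere_fraction fraction of each chromosome forming the
#'   central repeat-rich block, in `[0, 1]`.
#' @param pericentromere_bias probability that a repeat copy is placed inside
#'   the pericentromeric block rather than in an arm.
#' @param gc_content background GC fraction.
#' @param cds_fraction,pseudogene_fraction sampling weights for labelling the
#'   non-TE background; the remainder is intergenic.
#' @param seed integer seed making the genome reproducible.
#' @return a `genome_config` list.
#' @export
genome_config <- function(n_chromosomes = 3,
                          chromosome_length = 40000,
                          repeat_families = list(),
                          pericentromere_fraction = 0.3,
                          pericentromere_bias = 0.9,
                          gc_content = 0.36,
                          cds_fraction = 0.30,
                          pseudogene_fraction = 0.03,
                          seed = 1L) {
  stopifnot(n_chromosomes >= 1, chromosome_length >= 100,
            pericentromere_fraction >= 0, pericentromere_fraction <= 1,
            pericentromere_bias >= 0, pericentromere_bias <= 1,
            gc_content > 0, gc_content < 1)
  for (f in repeat_families) {
    stopifnot(inherits(f, "repeat_family"), f$divergence >= 0,
              f$divergence < 1, f$monomer_length >= 1, f$n_copies >= 0)
  }
  structure(list(n_chromosomes = as.integer(n_chromosomes),
                 chromosome_length = as.integer(chromosome_length),
                 repeat_families = repeat_families,
                 pericentromere_fraction = pericentromere_fraction,
                 pericentromere_bias = pericentromere_bias,
                 gc_content = gc_content,
                 cds_fraction = cds_fraction,
                 pseudogene_fraction = pseudogene_fraction,
                 seed = as.integer(seed)),
            class = "genome_config")
}

#' Specify a transposable-element repeat family
#'
#' @param name family identifier.
#' @param monomer_length monomer length in bp.
#' @param n_copies number of copies placed genome-wide.
#' @param divergence per-copy substitution fraction relative to the family
#'   monomer, in `[0, 1)`.
#' @param ancestor optional name of an earlier family; when set, this family's
#'   monomer is derived from that family's monomer rather than drawn fresh,
#'   producing "sister" families whose copies are mutual near-matches.
#' @param ancestor_divergence substitution fraction applied when deriving the
#'   monomer from `ancestor`.
#' @return a `repeat_family` list.
#' @export
repeat_family <- function(name, monomer_length = 300, n_copies = 6,
                          divergence = 0.01, ancestor = NULL,
                          ancestor_divergence = 0.015) {
  structure(list(name = name, monomer_length = as.integer(monomer_length),
                 n_copies = as.integer(n_copies), divergence = divergence,
                 ancestor = ancestor,
                 ancestor_divergence = ancestor_divergence),
            class = "repeat_family")
}

#' Default toy genome: 120 kb across 3 chromosomes, ~6% TE
#'
#' A 1000x-scaled analogue of a 120 Mbp plant genome: three 40 kb chromosomes
#' with ~6% of bases in TE families concentrated in the central 30% of each
#' chromosome. Family `teA` is high-copy; `teB` is a sister lineage of `teA`
#' (so collapsed copies of either compete for the same reads); `teC` is a
#' low-copy independent family; `teD` is background TE content that is never
#' collapsed by the bundled degradation presets.
#'
#' @param seed integer seed.
#' @inheritParams genome_config
#' @return a `genome_config`.
#' @export
default_genome_config <- function(seed = 1L, n_chromosomes = 3,
                                  chromosome_length = 40000) {
  genome_config(
    n_chromosomes = n_chromosomes,
    chromosome_length = chromosome_length,
    repeat_families = list(
      repeat_family("teA", monomer_length = 300, n_copies = 9,
                    divergence = 0.01),
      repeat_family("teB", monomer_length = 300, n_copies = 6,
                    divergence = 0.01, ancestor = "teA",
                    ancestor_divergence = 0.015),
      repeat_family("teC", monomer_length = 300, n_copies = 2,
                    divergence = 0.01),
      repeat_family("teD", monomer_length = 300, n_copies = 7,
                    divergence = 0.02)
    ),
    seed = seed
  )
}

#' Simulate a toy genome with annotated features
#'
#' Deterministic for a fixed seed. Repeat copies are placed without overlap,
#' preferentially inside the pericentromeric block; every base receives
#' exactly one primary feature label (TE, CDS, pseudogene or intergenic).
#'
#' @param cfg a [genome_config()].
#' @return a `toy_genome`: list with `chromosomes` (named character vector),
#'   `features` (tibble `chrom,start,end,label,family`, 0-based half-open)
#'   and the `config`.
#' @export
simulate_genome <- function(cfg = default_genome_config()) {
  stopifnot(inherits(cfg, "genome_config"))
  set.seed(cfg$seed)
  chrom_names <- paste0("chr", seq_len(cfg$n_chromosomes))
  len <- cfg$chromosome_length

  te_total <- sum(vapply(cfg$repeat_families,
                         function(f) f$monomer_length * f$n_copies, 0))
  peri_len <- round(len * cfg$pericentromere_fraction)
  if (te_total > 0.8 * cfg$n_chromosomes * max(peri_len, 1))
    abort("repeat content exceeds pericentromeric capacity; enlarge the genome or reduce copies")

  chroms <- setNames(vapply(chrom_names, function(nm)
    random_dna(len, cfg$gc_content), character(1)), chrom_names)

  peri_start <- round(len * (1 - cfg$pericentromere_fraction) / 2)
  peri_end <- peri_start + peri_len

  # family monomers, honouring ancestor links
  monomers <- list()
  for (f in cfg$repeat_families) {
    if (!is.null(f$ancestor)) {
      if (is.null(monomers[[f$ancestor]]))
        abort(paste0("ancestor family '", f$ancestor, "' must be defined first"))
      monomers[[f$name]] <- mutate_sequence(monomers[[f$ancestor]],
                                            f$ancestor_divergence)
    } else {
      monomers[[f$name]] <- random_dna(f$monomer_length, 0.5)
    }
  }

  occupied <- lapply(chrom_names, function(x) integer(0)) # flat occupied bases
  names(occupied) <- chrom_names
  te_rows <- list()
  for (f in cfg$repeat_families) {
    if (f$n_copies == 0) next
    for (k in seq_len(f$n_copies)) {
      chrom <- sample(chrom_names, 1)
      placed <- FALSE
      for (try in seq_len(500)) {
        inside <- runif(1) < cfg$pericentromere_bias
        if (inside && peri_len > f$monomer_length) {
          s <- sample.int(peri_end - peri_start - f$monomer_length, 1) +
            peri_start - 1L
        } else {
          s <- sample.int(len - f$monomer_length, 1) - 1L
        }
        span <- seq.int(s, s + f$monomer_length - 1L)
        if (!any(span %in% occupied[[chrom]])) {
          occupied[[chrom]] <- c(occupied[[chrom]], span)
          copy_seq <- mutate_sequence(monomers[[f$name]], f$divergence)
          substr(chroms[[chrom]], s + 1L, s + f$monomer_length) <- copy_seq
          te_rows[[length(te_rows) + 1L]] <-
            tibble(chrom = chrom, start = s, end = s + f$monomer_length,
                   label = "TE", family = f$name)
          placed <- TRUE
          break
        }
      }
      if (!placed) abort("could not place a repeat copy without overlap; genome too crowded")
    }
  }
  te <- if (length(te_rows)) dplyr::bind_rows(te_rows) else
    tibble(chrom = character(), start = integer(), end = integer(),
           label = character(), family = character())

  # label the non-TE background with CDS / pseudogene / intergenic blocks
  bg_rows <- list()
  p_lab <- c(CDS = cfg$cds_fraction, pseudogene = cfg$pseudogene_fraction,
             intergenic = 1 - cfg$cds_fraction - cfg$pseudogene_fraction)
  mean_len <- c(CDS = 600, pseudogene = 400, intergenic = 1200)
  for (chrom in chrom_names) {
    tes <- te %>% filter(.data$chrom == !!chrom) %>% arrange(.data$start)
    bounds <- c(0L, rbind(tes$start, tes$end), len)
    gaps <- matrix(bounds, ncol = 2, byrow = TRUE) # gap start/end pairs
    for (g in seq_len(nrow(gaps))) {
      at <- gaps[g, 1]
      while (at < gaps[g, 2]) {
        lab <- sample(names(p_lab), 1, prob = p_lab)
        blk <- max(50L, round(rexp(1, 1 / mean_len[[lab]])))
        e <- min(at + blk, gaps[g, 2])
        bg_rows[[length(bg_rows) + 1L]] <-
          tibble(chrom = chrom, start = as.integer(at), end = as.integer(e),
                 label = lab, family = NA_character_)
        at <- e
      }
    }
  }
  features <- dplyr::bind_rows(te, dplyr::bind_rows(bg_rows)) %>%
    arrange(.data$chrom, .data$start)

  structure(list(chromosomes = chroms, features = features,
                 pericentromere = tibble(chrom = chrom_names,
                                         start = peri_start, end = peri_end),
                 config = cfg),
            class = "toy_genome")
}

#' @export
print.toy_genome <- function(x, ...) {
  cat("<toy_genome> ", length(x$chromosomes), " chromosomes, ",
      sum(nchar(x$chromosomes)), " bp total\n", sep = "")
  comp <- feature_base_fraction(x)
  for (i in seq_len(nrow(comp)))
    cat(sprintf("  %-11s %6.2f%%\n", comp$label[i], 100 * comp$prop[i]))
  invisible(x)
}

#' Per-label base composition of a toy genome
#'
#' @param genome a `toy_genome`.
#' @return tibble with `label`, `bases` and `prop` (proportions sum to 1).
#' @export
feature_base_fraction <- function(genome) {
  stopifnot(inherits(genome, "toy_genome"))
  genome$features %>%
    mutate(w = .data$end - .data$start) %>%
    group_by(.data$label) %>%
    summarise(bases = sum(.data$w), .groups = "drop") %>%
    mutate(prop = .data$bases / sum(.data$bases))
}

#' Export toy-genome feature intervals as GFF3
#'
#' @param genome a `toy_genome`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_features_gff3 <- function(genome, path) {
  stopifnot(inherits(genome, "toy_genome"))
  f <- genome$features
  gr <- GenomicRanges::GRanges(
    seqnames = f$chrom,
    ranges = IRanges::IRanges(start = f$start + 1L, end = f$end),
    type = f$label,
    ID = paste0(f$label, "_", seq_len(nrow(f))))
  gr$family <- f$family
  # the CDS intervals are plain feature blocks, not gene models: no phase
  suppressWarnings(rtracklayer::export(gr, path, format = "GFF3"))
  invisible(path)
}
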