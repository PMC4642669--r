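#' Configuration for the end-to-end toy factorial experiment
#'
#' Sweeps a crossed design over read length, reference degradation preset
#' ("assembly"), mapping stringency, read-level MAPQ filtering and depth
#' filtering, in replicate. Reads are error-free and haploid, so every SNP
#' surviving the filter chain is a false positive; the per-cell FP counts
#' form a balanced factor table for [balanced_factorial_anova()].
#'
#' The depth cap defaults to 2.5 times the coverage: with Poisson-like
#' depth at honest single-copy loci this sits beyond the 99.99th percentile
#' of the depth distribution, so (like a cap of 150 on 100-fold data) it
#' only removes the pileups that collapsed repeats attract.
#'
#' @param genome a [genome_config()].
#' @param lengths read lengths swept.
#' @param assemblies degradation presets swept (see [degrade_preset()]).
#' @param stringencies stringency labels swept.
#' @param mapq_levels read-level MAPQ thresholds swept.
#' @param depth_levels depth-filter settings swept (`"no"`/`"yes"`).
#' @param replicates number of replicate runs.
#' @param coverage fold coverage of the simulated paired-end reads.
#' @param depth_cap depth-filter cap; default `ceiling(2.5 * coverage)`.
#' @param caller a [caller_config()].
#' @param mismap a [mismap_config()].
#' @param min_qual QUAL threshold for the site filter.
#' @param seed global seed; every cell derives its own stream from it.
#' @return an `experiment_config` list.
#' @export
experiment_config <- function(genome = default_genome_config(),
                              lengths = c(50L, 100L),
                              assemblies = c("control", "moderate", "severe"),
                              stringencies = c("strict", "relaxed"),
                              mapq_levels = c(0L, 20L),
                              depth_levels = c("no", "yes"),
                              replicates = 2L,
                              coverage = 12,
                              depth_cap = NULL,
                              caller = caller_config(),
                              mismap = mismap_config(),
                              min_qual = 20,
                              seed = 1L) {
  if (is.null(depth_cap)) depth_cap <- ceiling(2.5 * coverage)
  structure(list(genome = genome, lengths = as.integer(lengths),
                 assemblies = assemblies, stringencies = stringencies,
                 mapq_levels = as.integer(mapq_levels),
                 depth_levels = depth_levels,
                 replicates = as.integer(replicates), coverage = coverage,
                 depth_cap = depth_cap, caller = caller, mismap = mismap,
                 min_qual = min_qual, seed = as.integer(seed)),
            class = "experiment_config")
}

#' Run the toy factorial experiment end to end
#'
#' For every cell of the design: simulate error-free reads, map them with
#' the naive mapper against the cell's reference, apply the read-level MAPQ
#' filter, call SNPs, apply the site filter chain, count the (by
#' construction false-positive) SNPs, and assess read mismapping at the
#' retained sites. Reads and mappings are shared between cells that only
#' differ in caller-side factors, so the design stays internally
#' consistent. Everything derives deterministically from the global seed.
#'
#' @param cfg an [experiment_config()].
#' @param keep_variants keep the per-cell variant tables (list column)?
#' @return an `fp_experiment`: list with `genome`, `references`, `counts`
#'   (the balanced factor table with `n_fp` per cell), `cells` (per-cell
#'   detail incl. variants and mismapping), `mismap` (per-cell mismapping
#'   summary) and `config`.
#' @export
run_experiment <- function(cfg = experiment_config(), keep_variants = TRUE) {
  stopifnot(inherits(cfg, "experiment_config"))
  genome_cfg <- cfg$genome
  genome_cfg$seed <- derive_seed(cfg$seed, "genome")
  genome <- simulate_genome(genome_cfg)

  # references: one control + a fresh degradation per (preset, replicate),
  # mirroring the re-assembly of each replicate run
  refs <- list()
  for (a in cfg$assemblies) {
    for (r in seq_len(cfg$replicates)) {
      key <- paste(a, r, sep = "/")
      refs[[key]] <- if (a == "control") genome else
        degrade_reference(genome, degrade_preset(
          a, seed = derive_seed(cfg$seed, "degrade", a, r)))
    }
  }

  reads_cache <- list()
  aln_cache <- list()
  cells <- list()
  for (L in cfg$lengths) for (r in seq_len(cfg$replicates)) {
    rkey <- paste(L, r, sep = "/")
    reads_cache[[rkey]] <- simulate_read_pairs(
      genome, read_sim_config(read_length = L, coverage = cfg$coverage,
                              seed = derive_seed(cfg$seed, "reads", L, r)))
    for (a in cfg$assemblies) for (s in cfg$stringencies) {
      akey <- paste(L, r, a, s, sep = "/")
      aln_cache[[akey]] <- map_reads_naive(
        reads_cache[[rkey]], refs[[paste(a, r, sep = "/")]],
        stringency_config(s))
    }
  }

  for (L in cfg$lengths) for (a in cfg$assemblies)
    for (s in cfg$stringencies) for (mq in cfg$mapq_levels)
      for (d in cfg$depth_levels) for (r in seq_len(cfg$replicates)) {
        ref <- refs[[paste(a, r, sep = "/")]]
        aln <- read_mapq_filter(aln_cache[[paste(L, r, a, s, sep = "/")]],
                                mq)
        fcfg <- filter_config(min_qual = cfg$min_qual,
                              max_depth = cfg$depth_cap,
                              depth_enabled = (d == "yes"),
                              mapq_threshold = mq)
        variants <- call_variants_naive(aln, ref, cfg$caller) %>%
          apply_filter_chain(fcfg)
        assess <- assess_mismapping(variants, aln, ref, cfg$mismap)
        cells[[length(cells) + 1L]] <- tibble(
          length = L, assembly = a, stringency = s, mapq = mq,
          depth_filter = d, replicate = r, n_fp = nrow(variants),
          mean_mismap_pct = if (any(assess$defined))
            mean(assess$pct_mismapped[assess$defined]) else NA_real_,
          variants = if (keep_variants) list(variants) else list(NULL),
          assessments = if (keep_variants) list(assess) else list(NULL))
      }
  cells <- bind_rows(cells)
  counts <- cells %>%
    select("length", "assembly", "stringency", "mapq", "depth_filter",
           "replicate", "n_fp")

  structure(list(genome = genome, references = refs, counts = counts,
                 cells = cells, config = cfg),
            class = "fp_experiment")
}

#' @export
print.fp_experiment <- function(x, ...) {
  cat("<fp_experiment> ", nrow(x$counts), " cells (",
      nrow(dplyr::distinct(x$counts %>% select(-"replicate", -"n_fp"))),
      " combinations x ", x$config$replicates, " replicates)\n", sep = "")
  cat("  FP counts: min ", min(x$counts$n_fp), ", max ", max(x$counts$n_fp),
      "\n", sep = "")
  invisible(x)
}

#' Pool and annotate the FP SNP sites of an experiment
#'
#' Maps every retained FP SNP of the selected cells back to source-genome
#' coordinates, labels it against the ground-truth annotation, and returns
#' the pooled site table (deduplicated per source site and assembly).
#'
#' @param exp an [run_experiment()] result (with `keep_variants = TRUE`).
#' @param assemblies which assembly levels to pool (default: all degraded).
#' @param cfg an [annotate_config()].
#' @return tibble of distinct FP sites: `assembly`, `src_chrom`, `src_pos`
#'   (1-based), `label`.
#' @export
annotate_experiment_sites <- function(exp, assemblies = NULL,
                                      cfg = annotate_config()) {
  stopifnot(inherits(exp, "fp_experiment"))
  if (is.null(assemblies))
    assemblies <- setdiff(exp$config$assemblies, "control")
  rows <- exp$cells %>% filter(.data$assembly %in% assemblies)
  sites <- purrr::map_dfr(seq_len(nrow(rows)), function(i) {
    v <- rows$variants[[i]]
    if (is.null(v) || nrow(v) == 0) return(tibble())
    ref <- exp$references[[paste(rows$assembly[i], rows$replicate[i],
                                 sep = "/")]]
    src <- map_to_source(ref, v$chrom, v$pos - 1L)
    tibble(assembly = rows$assembly[i], src_chrom = src$src_chrom,
           src_pos = src$src_pos + 1L)
  })
  if (nrow(sites) == 0)
    return(tibble(assembly = character(), src_chrom = character(),
                  src_pos = integer(), label = character()))
  sites %>%
    distinct() %>%
    rename(chrom = "src_chrom", pos = "src_pos") %>%
    classify_positions(exp$genome$features, cfg) %>%
    rename(src_chrom = "chrom", src_pos = "pos")
}
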