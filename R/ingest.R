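#' Ingest externally produced alignments and calls
#'
#' Bridges real mapper/caller output into the pipeline: reads a SAM/BAM of
#' provenance-named reads and a VCF of SNP candidates, applies the site
#' filter chain, and quantifies read mismapping at the retained sites —
#' identical downstream treatment to the in-process naive stages.
#'
#' @param sam_path SAM or BAM file of the mapping.
#' @param vcf_path VCF of the call set.
#' @param reference the reference container mapped against (needed for
#'   provenance tracing and depth-independent checks).
#' @param filter_cfg a [filter_config()]; the MAPQ threshold is applied to
#'   the ingested alignments before mismapping assessment (external callers
#'   apply theirs internally).
#' @param mismap_cfg a [mismap_config()].
#' @param max_undecodable_fraction abort when more than this fraction of
#'   mapped reads lack decodable origin-encoded names.
#' @return list with `counts` (`n_candidates`, `n_fp` after filtering),
#'   `variants` (retained records), `assessments` and `mismap_summary`.
#' @export
ingest_external <- function(sam_path, vcf_path, reference,
                            filter_cfg = filter_config(),
                            mismap_cfg = mismap_config(),
                            max_undecodable_fraction = 0.05) {
  aln <- read_sam_alignments(sam_path)
  records <- read_vcf_records(vcf_path)
  seqs <- reference_sequences(reference)
  bad <- setdiff(unique(records$chrom), names(seqs))
  if (length(bad) > 0)
    abort(paste0("VCF records on contig(s) absent from the reference: ",
                 paste(bad, collapse = ", ")))
  bad_aln <- setdiff(unique(aln$chrom[!is.na(aln$chrom)]), names(seqs))
  if (length(bad_aln) > 0)
    abort(paste0("alignments on contig(s) absent from the reference: ",
                 paste(bad_aln, collapse = ", ")))

  mapped <- aln %>% filter(!is.na(.data$chrom))
  org <- decode_origin(mapped$name, mapped$mate, strict = FALSE)
  frac_bad <- if (nrow(mapped) == 0) 0 else
    attr(org, "n_failed") / nrow(mapped)
  if (frac_bad > max_undecodable_fraction)
    abort(sprintf(paste0("%.1f%% of mapped reads lack origin-encoded ",
                         "names; these reads were not produced by this ",
                         "package's simulator"), 100 * frac_bad))

  aln <- read_mapq_filter(aln, filter_cfg$mapq_threshold)
  variants <- apply_filter_chain(records, filter_cfg)
  assessments <- assess_mismapping(variants, aln, reference, mismap_cfg)
  list(counts = tibble(n_candidates = nrow(records),
                       n_fp = nrow(variants)),
       variants = variants,
       assessments = assessments,
       mismap_summary = summarize_mismapping(assessments))
}
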