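# fpsnp

Diagnosing the causes of **false-positive SNP calls** in mapping-based
variant discovery.

## The problem

When sequencing reads are mapped to an imperfect reference — fragmented,
incompletely assembled, with repeat families collapsed onto single copies
— reads whose true locus is missing still map somewhere, usually to a
paralogous copy. The substitution differences they carry masquerade as
SNPs. These false positives look unremarkable in every VCF field and are
hard to remove by filtering alone.

`fpsnp` is a desk-scale laboratory for this failure mode, aimed at anyone
designing or sanity-checking a SNP discovery pipeline for a non-model
organism. It provides, as composable tibble-in/tibble-out functions:

* a **toy genome simulator** with TE repeat families concentrated in
  pericentromeric blocks, and a **reference degrader** (repeat collapse,
  sequence loss, fragmentation) with full per-base provenance;
* an **error-free, haploid read simulator** whose read names encode each
  read's true origin (`pair|chrom:start:strand|…`) — so every SNP called
  downstream is a false positive by construction, and every alt-carrying
  read can be classified as correctly mapped or mismapped;
* a naive but **provably complete seed-and-extend mapper** (per-read
  mismatch budget `floor(r·L)`; strict `r = 0.02`, relaxed `r = 0.14`)
  and a haploid pileup caller, plus ingestion of external SAM/VCF;
* the standard **SNP filter chain** (biallelic, QUAL ≥ 20, DP ≤ cap,
  read-level MAPQ);
* per-SNP **read-mismapping quantification** and feature
  **annotation/enrichment** of FP sites;
* a balanced **factorial ANOVA** on `log10(N+1)`-transformed FP counts
  with a replicate stratum, percentage sums of squares, a
  within-replicate permutation test, and cell-mean tables with
  `sed = sqrt(2·MS_residual/m)`.

## Worked example

Run the full toy factorial experiment — read length × reference quality ×
mapping stringency × MAPQ filter × depth filter, in duplicate, on a
120 kb genome at 12× coverage (about two minutes on one core):

```r
library(fpsnp)
library(dplyr)

ex <- run_experiment(experiment_config(seed = 1))
ex$counts %>%
  group_by(assembly, stringency) %>%
  summarise(mean_fp = mean(n_fp), .groups = "drop")
#> # A tibble: 6 × 3
#>   assembly stringency mean_fp
#> 1 control  relaxed       0
#> 2 control  strict        0
#> 3 moderate relaxed      53.7
#> 4 moderate strict        6.69
#> 5 severe   relaxed     165
#> 6 severe   strict       16.2
```

The intact control yields zero false positives; degraded references yield
up to hundreds per cell, an order of magnitude fewer under strict
mapping. The factorial decomposition ranks the causes:

```r
an <- permutation_test(balanced_factorial_anova(ex$counts), seed = 1)
tidy(an) %>% filter(!grepl(":", term))
#>   term          df     ss     vr   f_prob perm_prob pct_ss
#> 1 length         1  0.191   60.4  5.5e-10     0.001  0.29
#> 2 assembly       2 50.8   8028.   2.7e-60     0.001 77.3
#> 3 stringency     1  9.16  2896.   7.0e-44     0.001 14.0
#> 4 mapq           1  0.041   12.9  7.8e-04     0.001  0.06
#> 5 depth_filter   1  0.122   38.5  1.3e-07     0.001  0.19
```

Reference quality dominates (77% of the total sum of squares), mapping
stringency comes second (14%), and every factor is significant by both F
and permutation probabilities. Mismapping and annotation close the loop —
at FP sites, ~80% of alt-carrying reads are mismapped, and FP sites are
TE-enriched (ratio ≈ 3.4 over the 6% genome baseline) and concentrated in
the pericentromeric blocks:

```r
mm <- filter(ex$cells, !is.na(mean_mismap_pct))
mean(mm$mean_mismap_pct)
#> [1] 80.4

sites <- annotate_experiment_sites(ex)
composition_enrichment(sites$label, feature_base_fraction(ex$genome))
#>   label      baseline_prop observed_prop enrichment_ratio  p_value
#> 1 TE                 0.06          0.205             3.41  1.4e-30
#> ...
```

`plot_mismatch_budget()`, `plot_positional_density()`,
`plot_composition()` and `autoplot()` on an ANOVA give ggplot views of
each result type. See the methods vignette
(`vignettes/false-positive-snp-diagnosis.Rmd`) for the models,
parameter choices and limitations.

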