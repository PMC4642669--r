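---
title: "Diagnosing false-positive SNPs from read mismapping: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnosing false-positive SNPs from read mismapping: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Mapping-based SNP discovery calls a site polymorphic when enough mapped
reads disagree with the reference. When the reference is a fragmented,
incompletely assembled draft — the normal situation for non-model organisms
— reads whose true locus is missing or collapsed in the assembly still map
*somewhere*, usually to a paralogous repeat copy. The substitution
differences they carry then look exactly like SNPs. `fpsnp` is a desk-scale
laboratory for this failure mode: it builds genomes where the truth is
known, produces reads that are error-free and haploid so that **every**
called SNP is a false positive by construction, and measures how seven
factors of a variant-calling pipeline (reference quality, read length,
mapping stringency, mapper, caller, MAPQ filtering, depth filtering) drive
FP SNP counts.

## The simulated system

`simulate_genome()` draws a small multi-chromosome genome in which each
chromosome has a central "pericentromeric" block (default 30% of its
length) that receives most copies of a set of transposable-element (TE)
repeat families; the arms are tiled with CDS, pseudogene and intergenic
blocks so that every base carries exactly one primary label. The default
genome is 3 × 40 kb = 120 kb with ~6% TE content — a deliberate
1000×-scaled analogue of a small plant genome of ~120 Mbp with its
repeat-poor arms and repeat-dense pericentromeres.

Three structural choices matter for what the pipeline can show:

* **Family structure.** The default families are a high-copy family
  (`teA`, 9 copies), a *sister* family derived from `teA`'s monomer
  (`teB`, 6 copies), a low-copy family (`teC`, 2 copies), and background
  TE content (`teD`) that degradation never touches. Sister lineages exist
  so that, once both families are collapsed, reads from deleted copies
  have two competing near-equal targets — that is what produces tied best
  hits, and hence MAPQ-0 mismaps, the ambiguity that MAPQ filtering is
  supposed to remove. Copy divergence defaults to 1% per copy, low enough
  that reads from a deleted copy still map to the surviving representative
  under a 2% per-read mismatch budget.
* **Degradation** (`degrade_reference()`) applies the three pathologies of
  draft assemblies: *collapse* (all copies of a family merged into the
  first copy in coordinate order, with all merged sources recorded),
  *sequence loss* (random blocks dropped until a target fraction is
  reached, flanks joined at the junction — a misjoin), and *fragmentation*
  (contig breaks, with short contigs discarded). Full provenance is kept:
  every contig base traces to a source interval, which is what lets the
  pipeline translate positions on the degraded reference back to truth
  coordinates.
* **Reads** (`simulate_read_pairs()`) are error-free, haploid, fixed-length
  fragments: paired-end at 100× with fragment = 1.8 × read length (90, 180,
  270, 540, 900, 1800 bp for the six standard lengths) and outward-facing
  mate pairs at 50× with a 3000 bp fragment. Fragments are fixed-length
  (no jitter) so coverage arithmetic stays exact and oracles stay simple.
  Each read name carries `pair|chrom:start:strand|chrom:start:strand`; this
  encoding is the provenance contract that the mismapping stage — and any
  external mapping fed back through `ingest_external()` — relies on.

What the generator does **not** emulate: sequencing errors and quality
profiles (reads are error-free by design), indels and structural variants
(the naive mapper is substitution-only), GC or positional coverage bias,
diploidy, and the internal behaviour of real assemblers (degradation
presets stand in for assemblies of different quality, not for any
particular assembler). Conclusions from passing tests are therefore about
the mismapping mechanism itself, not about any specific tool's error
model.

## Mapping, stringency, and calling

The stringency model applies a mismatch *rate* uniformly across read
lengths: the per-read budget is `floor(r * L)`. The strict default of 2%
is the smallest rate that allows one mismatch in a 50 bp read; the relaxed
default of 14% characterises the default behaviour of a popular
Burrows–Wheeler mapper. `min_score_threshold()` translates a rate into a
linear alignment-score bound whose pass/fail decision is provably the same
as the mismatch-count decision.

`map_reads_naive()` is an exact-seed, Hamming-extension mapper. For budget
`m` it uses `m + 1` block seeds of length `min(31, floor(L / (m + 1)))`
spread evenly across the read, so by pigeonhole every placement within the
budget is anchored by at least one exact seed — the search is therefore
*complete*, and a brute-force minimal-Hamming scan is an exact oracle for
it (this equivalence is asserted in the tests on sub-100 kb references).
Ties on the minimal mismatch count are broken toward the lowest (sequence,
coordinate) with forward strand first and are flagged with MAPQ 0; unique
best placements get MAPQ 60. There are no gapped alignments: the FP
mechanism of interest is substitution mismatches from mismapping.

`call_variants_naive()` is a haploid pileup caller: a site is emitted when
an alternate base is carried by at least 2 unique reads making up at least
8% of the site depth. The 8% floor is set below the ~1/(copy number)
allele fraction that a collapsed high-copy family produces (a 9-copy
collapse dilutes each deleted copy's private alleles to ~11% of the
pile), so the caller can see collapse-induced FPs; the 2-read floor keeps
isolated singletons out. QUAL is the documentedly arbitrary monotone score
`min(60, 10 × alt count)` — enough to exercise a QUAL ≥ 20 filter, with no
probabilistic interpretation.

## The filter chain

`basic_site_filter()` keeps biallelic records with QUAL ≥ 20 (a record at
exactly 20 is kept — "less than 20" is removed). `depth_filter()` keeps
records with DP ≤ cap, reading the cap as inclusive. MAPQ filtering is
read-level and applied *before* calling, matching how variant callers
consume their MAPQ threshold, rather than as a post-hoc site filter. At
100× the canonical cap is 150 ≈ 1.5× coverage; at the toy experiment's
12× the default cap is `ceiling(2.5 × coverage)` = 30, chosen as the
>99.99th percentile of Poisson(12) depth at honest single-copy loci — the
scaled-down analogue of the same idea: only collapsed-repeat pileups
should exceed it. SNPs removed by any site filter are also excluded from
mismapping assessment, keeping "retained SNP" consistent across stages.

## Quantifying mismapping

For each retained SNP, `assess_mismapping()` takes the unique covering
reads (keyed by name and mate) that carry the alternate allele, decodes
each read's true origin from its name, traces its mapped position back to
source coordinates through the provenance table, and classifies it as
mismapped when it sits on a different chromosome or more than one read
length away on the same chromosome. One read length is the default
same-chromosome tolerance because it is the smallest scale at which a
placement can still overlap its true locus; it is exposed as
`mismap_config(position_tolerance=)`, and the mismap percentage is
monotone non-increasing in it. Mates are classified independently;
pairing information is deliberately not used. Call-set summaries average
over defined sites only, and call sets without FP SNPs are excluded from
the grand mean.

## Annotation

SNP sites are labelled by interval overlap at the site position against
the ground-truth annotation, with ties resolved TE > pseudogene > CDS >
intergenic. Classification against the known truth replaces a BLAST-based
annotation of manifest sequences: on a simulated genome the truth is
available, and a sequence-similarity search would add an external
dependency without adding information. Manifests (site ± 120 bp) are
still extracted and exportable as FASTA for external workflows. Per-label
enrichment uses a two-sided exact binomial test against the genome's base
composition — the simplest test consistent with reporting an enrichment
ratio; site-position classification (rather than manifest-majority) is
the simplest defensible rule and the alternative is available by
classifying manifest midpoints.

## The factorial analysis

FP counts are analysed after a `log10(N + 1)` transform. For a complete,
balanced design, `balanced_factorial_anova()` decomposes the response
into a replicate blocking stratum (replicates are the random effect), all
main effects and interactions up to full order (fixed effects), and a
residual that is exactly the replicate-by-treatment stratum. Sums of
squares come from marginal cell means with inclusion–exclusion (Möbius)
correction, which on balanced data reproduces the classical orthogonal
projection — the test suite asserts equality with `aov()`'s
`Error()`-stratum decomposition to 1e-10 — but costs only a handful of
`rowsum()` passes, so the permutation test can refit hundreds of times in
seconds. Variance ratios use the residual mean square; F probabilities
are upper-tail; `percent_ss()` reports each row's share of the total SS
*including* the replicate stratum in the denominator (a toggle excludes
it, since published tables are ambiguous on this point).

The permutation test (999 permutations by default) permutes responses
within replicate strata — respecting the blocking — and recomputes every
term's variance ratio; `p = (1 + #{F* ≥ F}) / (n_perm + 1)`, so the
smallest attainable value is 0.001 at 999 permutations. Whole-table
permutation is available as an alternative scheme. Type-I error
calibration under the null is part of the test suite.

Cell-mean tables carry `sed = sqrt(2 × MS_residual / m)` with `m` the
observations averaged per cell; mean squares are kept at full precision
and rounded only for display, which is required to reproduce published
sed values to five decimals (e.g. m = 8 → 0.02191, m = 288 → 0.00365,
m = 192 → 0.00447 from a residual row of SS 1.10452 on 575 df).
"Zero-FP combination" means zero in *every* replicate, the stricter of
the two readings of a mean-based summary; `zero_fp_summary()` reports the
overall and per-assembly counts.

## The toy experiment

`run_experiment()` sweeps read length × reference (intact control plus
"moderate" and "severe" degradation presets) × stringency × MAPQ × depth
filter, in duplicate, with a fresh degradation per replicate. Reads and
mappings are shared between cells that differ only in caller-side
factors. Every cell's random stream derives from the global seed and the
cell's labels, so runs are reproducible and cells are uncoupled. The
default problem size — 120 kb genome, 12× coverage, read lengths 50 and
100, 96 cells — was chosen so a full factorial run takes about two
minutes on one core; the test suite uses a 60 kb variant of the same
design. The mapper and caller factors of the full-size published design
are represented by the single naive stand-in pair; the two degradation
presets stand in for the two draft assemblies.

Expected directional behaviour, asserted end-to-end in the tests:
degraded references yield more FPs than the control in (essentially)
every paired cell; relaxed mapping never beats strict; MAPQ-20 and depth
filtering both reduce totals; most alternate-allele reads at FP sites are
mismapped; FP sites are TE-enriched and concentrated in the
pericentromeric blocks.

## Numerical conventions and edge cases

* Coordinates are 0-based half-open internally; VCF/SAM/GFF emission is
  1-based. SAM SEQ is emitted in reference orientation and converted back
  on ingestion.
* Mapper tie-break: lowest (sequence index, coordinate), forward strand
  before reverse; ties ⇒ MAPQ 0. Deterministic by construction.
* Reads whose names cannot be decoded are excluded from mismapping with a
  count attached (`n_undecodable`); ingestion aborts when more than 5% of
  mapped reads are undecodable.
* Degenerate inputs: empty variant sets flow through every stage; a
  constant response yields zero SS everywhere and `percent_ss()` refuses
  the 0/0; selecting the full design for cell means leaves m = 1 and sed
  undefined, which is an error.
* All simulation parameters are integer-seeded; seeds derived per cell
  use a 31-bit polynomial hash of the cell labels.

## Known limitations

The naive mapper is ungapped and exhaustive-within-budget, so its MAPQ is
binary (0 or 60) rather than a calibrated probability; depth is the only
INFO field the naive caller emits; the degradation model breaks and
deletes but never duplicates or inverts; and the toy scale (tens of FP
sites per degraded cell, not tens of thousands) means count magnitudes
are not comparable to any full-genome experiment — only directions,
ratios and the analytic design quantities are.
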