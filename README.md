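# rrftools

Profiling of ribosomal-RNA-derived fragments (rRFs) in short RNA-seq data.

Short RNA-seq libraries contain, alongside miRNAs/isomiRs and tRNA-derived
fragments, large numbers of 16–33 nt fragments that map back to the six
human rRNAs — 5S, 5.8S, 18S and 28S from the nuclear genome, 12S and 16S
from the mitochondrial genome. These rRFs arise from recurrent "hotspots"
with preferred 5′ and 3′ endpoints, sometimes straddle the annotated rRNA
termini, and their abundances can differ systematically between groups of
samples (e.g. by sex or population of origin). Telling genuine rRFs apart
from the background is delicate because rRNA sequence is scattered across
the genome in full and partial copies.

`rrftools` implements a complete, desk-scale pipeline for this analysis:

1. **rRNA space** — reference rRNAs are loaded from annotated FASTA,
   padded with genomic flanks so terminus-straddling fragments are
   mappable, and the "rRNA space" is assembled as the merged union of
   full-length rRNA loci, annotated rRNA repeats (BED), and partial rRNA
   copies found by a built-in seed-and-extend local aligner
   (+1/−2 match/mismatch, affine gaps, Karlin–Altschul E-values,
   cutoff 1e−8, minimum aligned span 16 nt).
2. **Mapping** — reads are quality- and adapter-trimmed (cutadapt-like
   semantics; inserts < 16 nt discarded) and mapped onto the padded
   references by exhaustive exact matching; every occurrence of every
   distinct read is reported, with flank-aware coordinates (position 0 is
   the first base upstream of the rRNA 5′ end).
3. **Filtering** — three tiers: a per-sample adaptive raw-count
   threshold (knee of the species-survival curve), a reads-per-million
   floor (RPM = count / total trimmed reads × 10⁶, keep ≥ 10 RPM), and
   per-rRNA minimum fragment lengths from a genomic signal-to-noise
   criterion: S/N(rRNA, length) = Σ instances inside rRNA space / Σ
   instances outside, computed by brute-force both-strand genome search;
   lengths with S/N < 50 (more than ~2% of instances outside) are
   discarded.
4. **Annotation** — fragments are typed 5′-rRF / i-rRF / 3′-rRF / x-rRF
   by position relative to the parental rRNA and labelled with
   reversible, sequence-derived "license plates"
   (`rRF-<length>-<code>`, a base-4 → 32-symbol block code; decoding
   recovers the sequence exactly).
5. **Differential abundance** — a SAM-style moderated d-statistic
   (`d = (x̄A − x̄B)/(s + s0)`, Tusher exchangeability constant,
   permutation-based q-values, FDR ≤ 0.01) and PLS-DA with VIP scoring
   (VIP ≥ 1.5; mean VIP² = 1 by construction), intersected into
   **iDARs** over a population- or sex-comparison grid; Jaccard indices
   quantify method agreement.
6. **Synthetic cohorts** — a generator for mini-genomes (rRNA cassettes
   with flanks, partial copies, decoy plantings) and FASTQ cohorts
   (hotspots with preferred endpoints, negative-binomial hotspot
   activity, group-specific fold changes, adapter contamination,
   sequencing noise) with ground-truth manifests, so every stage is
   testable end to end.

## Worked example

```r
library(rrftools)

cfg    <- sim_config(seed = 42, n_per_cell = 2, populations = c("CEU", "YRI"))
sim    <- generate_mini_genome(cfg)
space  <- truth_rrna_space(sim)
cohort <- generate_cohort(cfg, sim, dir = tempdir())

samples <- lapply(seq_len(nrow(cohort$samples)), function(i)
  trim_reads(cohort$samples$fastq[i], cfg$adapter,
             sample_id  = cohort$samples$sample_id[i],
             population = cohort$samples$population[i],
             sex        = cohort$samples$sex[i]))

pipe <- run_rrf_pipeline(samples, sim$refs, sim$genome, space)
pipe
#> <rrf_pipeline> 79 retained rRF record(s) across 8 sample(s)
#> <length_cutoff_table> S/N >= 50 minimum lengths:
#>   5S 5.8S  18S  28S  12S  16S
#>   16   17   16   18   20   17
```

The minimum-length row says, e.g., that 28S fragments shorter than 18 nt
were discarded: the generator planted exact decoy copies of the 16/17-nt
28S fragments outside the rRNA regions, so their S/N fell below 50 —
exactly the situation the filter exists for. The master table lists each
retained fragment with its type, flank-aware coordinates, genomic
instance counts and per-sample RPM; fragments recurring in ≥ 6 of the 8
samples:

```r
subset(pipe$records, n_samples >= 6,
       c(license_plate, parent, rrf_type, start, end, inside, outside, n_samples))
#>        license_plate parent rrf_type start end inside outside n_samples
#> 17   rRF-18-RK5oK70J   5.8S        x    -5  12      1       0         8
#> 18   rRF-19-RK5oK71Z   5.8S        x    -5  13      1       0         8
#> 22   rRF-19-e1M5CS68   5.8S        i    64  82      1       0         8
#> 23 rRF-21-e1M5CSW201   5.8S        i    64  84      1       0         8
#> 39   rRF-19-eVZZo80K    18S        i   357 375      1       0         8
#> 40   rRF-20-eVZZo823    18S        i   357 376      1       0         8
#> 41   rRF-18-Y3NNa00K    18S        i   358 375      1       0         8
#> 42   rRF-19-Y3NNa023    18S        i   358 376      1       0         7
```

The two 5.8S x-rRFs start at position −5, i.e. they borrow six
nucleotides upstream of the annotated 5′ terminus — the planted
architecture, recovered. License plates decode back to the sequence:

```r
decode_plate("rRF-18-RK5oK70J")
#> [1] "GTCAAAGTTTGAACTATT"

evaluate_recovery(pipe$records, cohort, cutoffs = pipe$sn_table)$endpoint_exactness
#> [1] 1
```

Differential abundance at realistic group sizes (40 vs 40 samples, 5% of
200 fragments carrying a 4-fold planted shift):

```r
s     <- simulate_expression_matrix(n_fragments = 200, n_per_group = 40,
                                    effect_frac = 0.05, log2fc = 2, seed = 42)
sam   <- sam_two_class(s$rpm, s$labels, n_perm = 500, seed = 42)
pls   <- plsda_vip(s$rpm, s$labels)
idars <- intersect_idars(sam, pls)
nrow(idars)
#> [1] 10
jaccard_index(sam$feature[sam$significant], pls$feature[pls$significant])
#> [1] 1
head(idars[order(idars$q_value), ], 3)
#>   feature        d q_value  log2_fc      vip idar
#> 1 frag014 4.912824       0 1.821941 3.340036 TRUE
#> 2 frag025 6.770721       0 2.246990 3.869883 TRUE
#> 3 frag061 6.324286       0 2.138114 3.787276 TRUE
```

All ten planted fragments are recovered as iDARs (significant under both
SAM and PLS-DA) with no false calls, and the estimated log₂ fold changes
sit near the planted value of 2.

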