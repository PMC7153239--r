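---
title: "Methods: discovering and comparing rRNA-derived fragments"
author: "rrftools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discovering and comparing rRNA-derived fragments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Mature ribosomal RNAs are processed into large numbers of short (16–33 nt)
fragments, rRFs, that appear reproducibly in short RNA-seq libraries.
Quantifying them is harder than it looks for two reasons. First, rRNA
sequence is not confined to the annotated rRNA loci: the nuclear genome
carries tandem repeat cassettes of the 45S and 5S units and is riddled
with partial rRNA copies, so a short sequence that matches an rRNA may
have many genomic origins. Second, fragment boundaries matter: fragments
can straddle an rRNA terminus into its genomic flank, and pipelines that
map reads only against the mature rRNA body silently lose them.

`rrftools` addresses both with an explicit *rRNA space* — the interval set
against which fragment exclusivity is judged — and by mapping against
flank-padded references.

# The rRNA space

The space is the merged union of three interval sets on the genome:

* the genomic placements of the full-length reference rRNAs (located by
  exact search on both strands);
* user-supplied rRNA repeat annotations (BED, converted from 0-based
  half-open to the package's 1-based inclusive convention on read);
* partial rRNA copies found by `find_partial_copies()`.

The partial-copy search is a deterministic seed-and-extend local
aligner: exact 12-nt seeds of the query rRNA are located on both strands,
clustered by implied diagonal, and extended with a local
Smith–Waterman alignment (match +1, mismatch −2, affine gap open −4 /
extend −1). Hit significance uses Karlin–Altschul extreme-value
statistics: λ is the root of the moment condition
Σᵢⱼ pᵢpⱼ e^{λ sᵢⱼ} = 1 and K is computed from the classical series
representation with Spitzer-type terms of the n-step score-sum
distribution; for +1/−2 at uniform composition this yields λ = 1.333,
K = 0.621, matching the published ungapped BLASTN constants. Hits are
kept at E ≤ 1e−8 with an aligned genomic span of at least 16 nt. Using
ungapped (K, λ) for lightly gapped alignments slightly overstates E for
gapped hits; the copies of interest are near-exact, where the
approximation is conservative and immaterial at the 1e−8 cutoff. A
precomputed interval BED can be supplied instead of running the search.

Membership is strand-agnostic whole-interval containment: an exact
genomic occurrence of a fragment counts as *inside* only if its interval
lies entirely within one merged space interval. Occurrences that overlap
the boundary count as outside — the conservative convention, mirroring
the "exclusive" notion used for tRNA-derived fragments. For this reason
repeat annotations should cover whole repeat units (as RepeatMasker rDNA
annotations do), not just the mature rRNA bodies; otherwise
terminus-straddling fragments are scored as outside and unfairly
penalized by the S/N filter. The synthetic truth space follows the same
rule (cassette = rRNA plus its 50-nt flanks).

# Coordinates

All user-facing coordinates are 1-based inclusive on the parental rRNA,
with position 1 the annotated 5′ terminus. Flank positions continue the
axis without a gap on the downstream side (L+1 is the first downstream
base) and run …, −1, 0 upstream, with position 0 the base immediately
before position 1. A fragment reported at start −5 therefore carries six
upstream nucleotides (−5..0). Fragment types follow from coordinates:
`5p` starts at 1 (full-span fragments included, by the documented
5p > 3p precedence), `3p` ends at L, `i` is interior, `x` straddles a
terminus (start < 1 or end > L); x-rRFs additionally record whether they
extend upstream, downstream, or both.

# Read processing

Trimming removes 3′ bases below Phred 20 (a cutadapt-like default; the
upstream data source does not pin this) and then clips the 3′ adapter at
its leftmost occurrence with at least 3 nt overlap and at most 10%
mismatches of the overlap. Inserts shorter than 16 nt are discarded —
shorter sequences are too promiscuous on the genome to be attributed —
and the surviving read count is the sample's *read depth*, the RPM
denominator. A consequence of 33-cycle libraries worth knowing: a 31- or
32-nt insert leaves a 1–2 nt adapter remnant below the minimum overlap,
so those lengths are unobservable as exact matches; 33-nt inserts fill
the read exactly and are observable.

Mapping is exhaustive and exact: every distinct read sequence is looked
up against every substring of the padded references (an index of all
16–33-mers of flank5 + rRNA + flank3), reporting all occurrences,
including overlapping ones; alignments entirely within a flank are
rejected. Reads matching several rRNAs (possible between 45S sub-units
and partial copies) are reported once per parent and flagged
`multi_parent`; abundance is not split, which preserves per-rRNA hotspot
profiles and lets users exclude them explicitly.

# The three filter tiers

**Adaptive raw-count threshold.** Per sample, the species-survival curve
S(c) (distinct fragments with count ≥ c) is evaluated at the distinct
observed counts. The default "cliff" strategy places the threshold just
above the single inter-candidate step that eliminates the most species,
provided that step removes ≥ 50% of all species; otherwise the counts
are deemed inseparable and the threshold is 1. Scanning observed values
rather than a fixed grid makes the chosen fragment *set* invariant under
rescaling of the counts. A windowed plateau criterion and a fixed cutoff
are available as alternative strategies; the chosen threshold is always
returned and logged by the pipeline. The knee heuristic is a stand-in
with the same contract as published per-sample adaptive thresholding
tools: an integer cutoff, different for each sample.

**RPM floor.** RPM = raw count / read depth × 10⁶, with the *total*
trimmed read count as denominator (not mapped reads). A fragment is kept
for a sample iff RPM ≥ 10, and kept at cohort level iff it passes in at
least one sample.

**S/N length cutoffs.** For each parental rRNA r and length ℓ ∈ 16..33,
S/N(r, ℓ) = Σ inside / Σ outside over all retained fragments of that
parent and length, from brute-force both-strand genome counts. A cell
with no outside instances is +∞ and passes; a cell with no fragments is
empty. The minimum length of r is the smallest ℓ with S/N ≥ 50
(equivalently, at most ~2% = 1/51 of instances outside), and shorter
fragments of r are discarded. S/N ≥ 50 is implemented as the primary
rule; the "< 2% outside" phrasing is its approximation, and an optional
per-fragment exclusivity filter (outside fraction ≤ 0.02, default off)
is provided for stricter analyses. The per-length sums are computed over
fragments that passed the RPM filter — an assumption, flagged here,
since the alternative (all observed 16–33-mers) is not pinned upstream.

# License plates

A fragment's label is `rRF-<length>-<code>`. The T-normalized sequence
is split into blocks of up to 5 nt; each block is read as a base-4
integer (A=0, C=1, G=2, T=3) and written as two symbols of a fixed
32-character alphabet. The length in the label fixes the block
structure, so decoding is exact and the map between sequences and labels
is a bijection (property-tested exhaustively over all 4⁸ sequences of
length 8). The alphabet ships as a constant and can be swapped to match
other labeling registries byte for byte; the contract is uniqueness and
reversibility, not a particular alphabet.

# Differential abundance

Both methods operate on log2(RPM + 0.5) by default — the transform is a
package choice (not pinned upstream) that stabilizes the variance of
overdispersed abundances; raw-scale analysis is available via
`log_transform = FALSE`.

**SAM-style permutation test.** dᵢ = (x̄A − x̄B)/(sᵢ + s₀) with the pooled
standard error sᵢ and the exchangeability constant s₀ chosen among the
percentiles of the sᵢ distribution to minimize the coefficient of
variation of the d-spread (median absolute deviation) across s-bins.
The null is built from label permutations — enumerated exactly whenever
the number of distinct arrangements is at most `n_perm` (default 1000),
otherwise sampled with the recorded seed. At each observed |d| cutoff
the expected number of false calls (mean over permutations) is divided
by the observed calls and the ratios are monotonized into q-values
(non-increasing in |d|, capped at 1); significance is q ≤ 0.01. No
across-grid correction is applied on top — each comparison carries its
own FDR, matching per-comparison reporting.

**PLS-DA / VIP.** Two-component PLS-DA on autoscaled features (fit and
VIP delegated to mixOmics), with VIPⱼ = √(p · Σₐ w²ⱼₐ SSₐ / Σₐ SSₐ). The
mean of squared VIPs is identically 1, which the tests assert to 1e−9;
an independent hand-rolled NIPALS implementation in the test suite
cross-checks the scores. Significance is VIP ≥ 1.5. Constant features
are dropped with a warning before autoscaling.

**iDARs and the grid.** An iDAR is a fragment significant under both
methods in the same comparison. `pairwise_comparison_grid()` runs both
methods for all population pairs within each sex (10 × 2 comparisons for
a five-population, two-sex design) or male-vs-female within each
population (5 comparisons), skipping groups below 2 samples with a
warning, and reports per-comparison and unique counts plus Jaccard
agreement between the two methods' call sets.

# The synthetic cohort generator

The generator defines the package's reference study conditions; it is
how every stage is validated in the absence of controlled real data.

*Genome.* One background contig (default 30 kb, GC 0.41 — the genomic
average) carrying: one cassette per rRNA (two for 5S, which is tandemly
repeated in the real genome), each cassette being the rRNA flanked by
50 nt of unique context; partial copies (default: a 60-nt copy of 18S
at 90% identity and an 80-nt copy of 28S at 92%); and decoy plantings —
exact copies of every 16/17-nt fragment of the short 28S hotspot,
three copies each, guarded by mismatching bases so they break the S/N of
exactly the targeted lengths. Placement is random and non-overlapping
with bounded retries. The six reference rRNAs are random sequences at
scaled lengths (5S 121, 5.8S 157, 18S 400, 28S 500, 12S 250, 16S 300 nt):
the two short rRNAs at their real lengths, the long ones shortened so
exhaustive oracles stay cheap.

*Expression.* Ten hotspots emulate the fragment architecture reported in
lymphoblastoid data: a bimodal 5S (18/19-mers from position 103 with
ends 120/121 at 2:1, versus 32/33-mers, one mode active per sample), a
5.8S x-family starting six nucleotides upstream of the annotated 5′ end,
a central 5.8S family (19/21-mers sharing a 5′ end), an interior 18S
hotspot whose rightmost endpoint stays 24 positions short of the 3′ end,
abundant 28S 5′-fragments (20/27-mers from position 1), a short 28S
family (16/17/18-mers) paired with the decoys, 12S fragments that skip
position 1, and two 16S hotspots. Biological variability acts on
whole-hotspot activity — total counts are negative binomial with
dispersion 0.3 (the standard overdispersed choice; the upstream data
show wide within-group ranges but no explicit model) — while each
molecule's endpoints are multinomial over the hotspot's stated endpoint
probabilities. Planted effects multiply a hotspot's mean for a matching
group: by default one 16S hotspot at log2FC −2 in YRI (a
continental-contrast effect) and the central 5.8S family at +1 in
females.

*Library.* 33 cycles (matching the sequencing of the emulated cohort),
TruSeq 3′ adapter, constant Q30 qualities with a Q2 3-nt tail on 1% of
reads, and substitution errors at 1e−4 per base (post-filter
Illumina-grade; chosen, together with the tail fraction, so that ≥ 99%
of inserts are recovered exactly after trimming). Depth is normal
(mean 20 000, sd 2 000) and the remaining depth after hotspot reads is
filled with uniform random genomic substrings of 16–33 nt on either
strand. Manifest truth (per-fragment counts, hotspot definitions,
planted effects, per-sample modes, region map) accompanies every cohort,
and RPM truth uses the realized library size.

*What it does not emulate:* nucleoside-modification-induced RT stops,
ligation bias for 5′-P/3′-OH ends, facility or kit batch effects, rDNA
copy-number variation between individuals, and real rRNA sequence
composition (references are random, so sequence-composition-specific
results — e.g. which rRNA tolerates 16-mers — are configured, not
emergent). Passing tests therefore demonstrate the pipeline's
correctness and calibration, not properties of any real cohort.

# Numerical and design choices

* Padding is 50 nt per side; flanks come from the canonical placement
  (first in genome order) with a warning if other placements disagree —
  which genomic copy donates the flanks is genuinely open, and
  first-in-genome-order makes it deterministic.
* Ties and degeneracies: full-span fragments type as 5p (configurable);
  palindromic sequences count once per genomic site; both-empty sets
  have Jaccard 0 (logged); zero-variance Welch comparisons with equal
  means return p = 1.
* Genome instance counting is strand-aware in search (both strands) but
  strand-agnostic in membership; whether the original analysis counted
  strands separately is not documented, and both-strand counting is the
  symmetric choice.
* Per-sample simulation streams are seeded from a master stream rather
  than with consecutive integers — consecutive Mersenne-Twister seeds
  produce correlated early draws, which showed up as systematic
  endpoint-split biases across samples.
* Problem sizes in the shipped tests and acceptance script: 30-kb
  genomes, cohorts of 8 samples at depth ~20 000 (noiseless cohorts emit
  only hotspot reads), expression matrices of 150–200 fragments at 40
  samples per group, 200–500 permutations, and 25–50 null repeats.
  These sizes keep exhaustive oracle comparisons (naive substring scans
  of every probe against the whole genome) affordable while leaving all
  statistical conclusions stable across seeds.

# Known limitations

* Exact matching only: no mismatch tolerance, no splicing, no UMIs, no
  paired-end support. Fragments carrying sequencing errors are lost, not
  rescued.
* The E-value model for the partial-copy search is ungapped theory
  applied to lightly gapped alignments (see above).
* The adaptive threshold is a knee heuristic with the right contract,
  not a reimplementation of any published tool's internals.
* Multi-parent fragments are duplicated, not fractionally assigned;
  cohort-level uniqueness is by sequence, so summaries that sum across
  parents should exclude `multi_parent` records or deduplicate first.
* At 33 cycles, 31/32-nt fragments are invisible and can alias into
  33-mers when the first downstream base matches the adapter's first
  base; real libraries have the same blind spot.
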