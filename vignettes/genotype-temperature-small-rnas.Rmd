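---
title: "Methods: small RNA expression across genotypes and temperatures"
author: "srnaflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small RNA expression across genotypes and temperatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`srnaflow` analyses small RNA sequencing data from a two-genotype,
three-temperature design: a tropical-latitude and a temperate-latitude
nematode strain reared at 14 °C, 20 °C and 30 °C with three biological
replicates per combination. This vignette documents the models, the
parameter choices, the synthetic-data generator that stands in for
sequencing data in the test suite, and the numerical decisions made where
the design was genuinely open.

## The quantification model

### Read taxonomy

Perfectly aligned reads are classified by length, 5′ nucleotide and
annotation context:

| class | rule |
|---|---|
| 22G endo-siRNA | 21–23 nt, 5′ G |
| 26G endo-siRNA | 25–27 nt, 5′ G |
| 21U-piRNA | exactly 21 nt, 5′ U (T in DNA), aligned *sense* to an annotated piRNA locus |
| microRNA | aligned sense to an annotated microRNA locus |
| other | anything else |

The 22G/26G rules are annotation-free; the 21U and microRNA rules consult
the overlapped features at every placement of the read. The classes are not
mutually exclusive by construction (a 21 nt G-read inside a microRNA locus
is both), so the per-read `class` label resolves in the order microRNA →
21U → 22G → 26G → other, while the logical columns retain all memberships.

### Fractional counting

A placement contributes to a feature only if the read interval is *fully
contained* in the feature interval, separately for sense and antisense
orientations. A read with several placements contributes 1/N to each
contained feature, where N is the number of that read's placements
contained in at least one feature of the *same class* — so a read hitting
three genes and one repeat adds 1/3 to each gene and 1/1 to the repeat.
When two same-class features overlap and both contain a placement, each
receives 1/N (N counts placements, not features; the counting contract
states this explicitly because either convention is defensible). Placements
contained in no annotated feature are pooled into a single `unannotated`
pseudo-feature. Consequently, per feature class the fractional counts of
one read sum to at most one, and class totals never exceed the number of
aligned reads; totals across *different* classes may, because features of
different classes can overlap.

Positional summaries (per-chromosome totals, 100 kb / 150 kb window
profiles) use each read's *primary* placement. The native aligner only
produces perfect full-length placements, and the primary is chosen
deterministically: first chromosome in genome order, then leftmost
position, then + before −. Window log₂-RPM values use a 0.5-read
pseudocount before scaling; the RPM denominator is the per-sample total of
perfectly aligned reads (configurable — the choice of denominator is not
dictated by the method).

## The differential-expression model

Per-feature counts are transformed to log₂ RPM with the voom recipe,
`log2((count + 0.5)/(libsize + 1) * 1e6)`, and per-observation precision
weights come from the fitted mean–variance trend (local regression span
0.5, the published default). No between-sample scale factors are applied
beyond library size: trimmed-mean-of-M-values (TMM) normalisation assumes
most features are not differentially expressed, which a genome-wide 22G
reduction violates; TMM remains available as an option for sensitivity
checks. Each feature is then fit with

```
expression = genotype + temperature + genotype:temperature
```

where temperature is an unordered factor with 20 °C as the reference level,
so "interaction at 30 °C versus 20 °C" is a single coefficient. Residual
variances are shrunk toward a common prior (empirical-Bayes moderated t
with augmented degrees of freedom, prior df estimated from the data);
p-values are BH-adjusted across features per coefficient, with significance
at adjusted p < 0.05.

Features are classified into five non-overlapping groups from the
per-family significance calls — genotype family (one coefficient),
temperature family (both temperature contrasts), interaction family (both
interaction contrasts), a family being significant when *any* member
coefficient is:

1. `genotype_only` — significant genotype, nothing else;
2. `temperature_only` — significant temperature, nothing else;
3. `additive` — genotype and temperature, no interaction;
4. `interaction` — any significant interaction coefficient;
5. `no_effect` — nothing significant.

Whether the false-discovery control should be applied per coefficient or
jointly across all coefficients is not determined by the method; the
per-coefficient family structure above is this package's documented choice
and is what the classification tests pin down.

Features enter the fit only if they reach ≥ 1 RPM in ≥ 3 samples (across
all conditions). Sample similarity is summarised by classical
multidimensional scaling of pairwise leading-log-fold-change distances
(root-mean-square of the top 500 per-pair log-fold-changes), with each
axis's sign fixed by making its largest-magnitude loading positive.

### Aggregate models

Class-level and chromosome-level totals are fit by ordinary least squares
on log₂ RPM (0.5 pseudocount), with a chromosome main effect in the
chromosome model. Reported contrasts are the within-genotype 30 °C vs
20 °C effects, the interaction at 30 °C, and X-versus-autosome contrasts.
Fold-changes are `2^estimate`. Because totals are normalised by the whole
library, a genuine fold-f reduction of a class that makes up a fraction s
of the library appears as approximately f·(1 − s·(1 − 1/f)) on the RPM
scale; with the study-like composition used in the tests (gene-antisense
22Gs ≈ 13 % of the library) a true 2.3-fold reduction measures ≈ 2.1.

### Bin summaries and domain tests

A 100 kb bin counts as "decreased at 30 °C" when its replicate-mean log₂
RPM at 30 °C is *strictly* below the 20 °C mean; ties are not decreases.
The decrease magnitude is the mean (20 °C − 30 °C) difference over the
decreased bins only. Bins are assigned to chromosome arm or centre domains
by their midpoint; genes by their annotated start. Domain enrichment uses
the two-sided Fisher exact test.

### Target sets and correlations

Argonaute/RdRP target sets (CSR-1, CSR-1a/b, WAGO-1, RRF-1, EGO-1, HRDE-1,
non-dynamic controls) are either native gene-id lists or the image of
source-species lists under an ortholog table (many-to-many rows allowed,
duplicates collapse, unmapped ids logged). Overlaps report
`100·|A∩B|/|A|` to one decimal and an upper-tail hypergeometric p.
Expression comparisons between temperatures within a genotype use the
two-sided Wilcoxon rank-sum test on per-gene replicate means — exact for
group sizes ≤ 25 without ties, normal approximation with continuity
correction otherwise. Small RNA–mRNA correlations use Spearman's rank
correlation (average ranks for ties; exact p up to n = 1290, asymptotic
beyond), repeated on the top decile of small RNA expression, with the two
coefficients compared by a z-test after Fisher's z-transformation, and a
descriptive second-order polynomial least-squares fit.

## Pseudo-reference construction and liftover

`apply_variants` rejects multi-allelic and overlapping records and requires
REF alleles to match the reference (the consensus-substitution model is
haploid). Substitution produces a liftover map of monotone blocks: SNPs are
length-preserving and never break blocks; an indel ends the current block
at its anchor base, leaves deleted source positions unmapped, and shifts
downstream coordinates by the cumulative length difference. Insertions map
the anchor base to the first target base of the expanded span (standard
chain semantics). Lifting a mapped position forward and back is the
identity.

Annotation transfer: a feature lifts when both endpoints map. Features
with exon parts (protein-coding genes) additionally require every part to
convert *completely* — both endpoints map and the lifted part keeps its
source length, so an indel inside an exon drops the whole gene. Part-less
features tolerate internal indels, which is what makes the piRNA filters
meaningful: a lifted piRNA locus is kept only if it is still 21 bp long and
starts with T on its annotated strand in the pseudo-reference. The
transfer report records per-class input/transferred counts and a reason
(`part_failed`, `piRNA_length`, `piRNA_first_base`) per dropped feature.

Cross-strain analyses use only features present in both annotations:
id-level features (genes, pseudogenes) must transfer completely; repeat and
transposon features collapse to family level and are kept when at least one
family copy exists in both annotations.

## Read preparation

The cascade order is fixed: 3′ adapter trimming → 5′ adapter screen →
barcode demultiplexing → final length filter; every input read ends in
exactly one terminal state, so state counts conserve the input. The
original tooling leaves the relative order of the two adapter steps
ambiguous; this order is the package's stated choice.

Trimming parameters (defaults): 3′ adapter `CTGTAGGCACCATCAAT`, error rate
≤ 0.1 of the matched adapter length, post-trim length bounds 21–34 nt
(barcode still attached), 5′ adapter discard at ≥ 14 nt overlap, 4 nt
barcodes, final insert bounds 17–30 nt. Errors are counted as edit
distance (indels allowed) with N bases as mismatches. The best 3′ adapter
occurrence is the longest matched adapter stretch, then fewest errors, then
the longest retained insert; partial (read-end) occurrences shorter than
3 nt are ignored so that adapter-free reads pass through unchanged.
Barcode matching is exact — determinism is preferred over mismatch
tolerance because the original demultiplexer's behaviour is unspecified.

## The synthetic-data generator

The generator emulates the study conditions: two strains differing by SNPs
and short indels (defaults 1 SNP/kb, 0.2 indels/kb), a 2 genotype ×
3 temperature × 3 replicate design, clustered 21 bp piRNA loci starting
with T, class-specific read length and 5′ nucleotide signatures, and a
multiplicative effect table whose default entry is a 2.3-fold reduction of
protein-coding-gene antisense reads in the temperate genotype at 30 °C —
the effect structure the pipeline is meant to detect.

Counts are negative binomial per feature and sample,
`mean = baseline × folds × library scale`, `size = 1/dispersion`
(default dispersion 0.05, a typical small RNA replicate-level value);
dispersion 0 gives deterministically rounded means, the zero-noise regime
used for exact truth-recovery tests. The NB choice is this package's: the
count noise family is not dictated by the analysis, and NB is the standard
model for sequencing counts and gives the voom weights something real to
fit.

Reads from RdRP-templated classes (genes, pseudogenes, repeats,
transposons) are placed antisense to the feature, uniformly along it; 21U,
microRNA and structural RNA reads are sense reads anchored at the locus 5′
end. The class 5′ signature (G for 22G/26G, T for 21U) is realised by
*anchor-site selection*: reads start at genomic positions whose
strand-aware base already carries the signature. Overwriting the first
base of the read instead would make every signature-bearing read mismatch
the genome and fail the perfect-alignment rule, severing the generator's
truth tables from the pipeline. In the rare case a feature offers no
suitable anchor for a drawn length, the read is placed unconstrained and
its truth label downgraded accordingly. Multi-mapping is created by
copying donor feature sequence over same-length acceptor loci of the same
class (sharing a family id), so reads from either locus place at both.

What the generator does **not** emulate: sequencing errors and quality
variation (qualities are constant), PCR duplicates, ligation bias,
positional bias along transcripts, spliced alignment across introns (toy
genes have contiguous exon parts), and expression correlation between
features. Passing tests therefore demonstrate correctness of the
*computational* pipeline under a faithful count model — not robustness to
artefacts absent from the simulation.

## Numerical choices and degenerate inputs

- **Variance floor.** Zero-noise data yield residual variances of exactly
  zero, making the moderated t 0/0. Residual sds below 1e-4 (log₂ scale)
  are floored there: differences below that level are smaller than the
  quantisation introduced by count rounding and the 0.5 pseudocount, so
  they are treated as numerically zero. Precision weights are normalised
  to mean one before fitting (weighted least-squares inference is invariant
  to a global weight scale), which keeps the floor on the data scale.
- **Degenerate aggregate fits.** If a contrast has standard error < 1e-12
  (an exactly perfect fit), a zero estimate is reported as t = 0, p = 1
  rather than NaN.
- **Pseudocounts.** 0.5 reads everywhere a log is taken (voom's published
  formula for the feature model; the same constant for window and
  aggregate log₂ RPM).
- **Tie-breaks.** Primary placements and 3′ adapter occurrences are chosen
  by the deterministic rules above; equal bin means are "not decreased".
- **Coordinates.** 1-based inclusive everywhere in files and interfaces
  (GFF3/VCF convention); BED's 0-based encoding is handled by the I/O
  layer and never leaks.
- **Seeds.** Every simulation function derives its RNG stream from
  `config$seed` plus a small fixed offset per stage, so stages are
  individually reproducible and byte-identical under a repeated seed.

## Problem sizes used in the tests

The suite runs genomes of 20–100 kb with tens of features, read sets of a
few hundred to a few thousand, a 2,000-feature count-level simulation for
fold-change recovery (with 200 null replicates for the false-positive
rate), and 200-feature zero-noise classification — sizes chosen so the
whole suite completes in a few minutes on one CPU while leaving every
statistical check well-powered. Enumeration oracles (hypergeometric,
Wilcoxon, Fisher) run on instances of at most 20 elements, where exhaustive
enumeration is exact and fast.

## Known limitations

- Intron-gapped ("N" CIGAR) alignments are excluded from counting and only
  logged; the native aligner is ungapped by design.
- The per-coefficient BH family structure, the RPM denominator, the
  unannotated-region orientation convention and the N-per-placement rule
  for overlapping same-class features are documented choices, each
  configurable or isolated behind one function, rather than properties
  forced by the method.
- Orthology-mapped target sets inherit the incompleteness of their source
  experiments; the compiler reports unmapped ids but cannot correct for
  missing targets.
- With library-size normalisation, genuinely global expression shifts are
  partially absorbed into the denominator (quantified above); aggregate
  fold-changes should be read with that in mind.
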