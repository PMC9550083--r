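---
title: "Designing subspecies-discriminating InDel markers: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing subspecies-discriminating InDel markers: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(indelmarker)
library(dplyr)
```

# The problem

Two subspecies groups of an inbred crop — the motivating case is *indica*
versus tropical *japonica* (*javanica*) rice — differ at many insertion/
deletion polymorphisms. An InDel whose allele is fixed within one group and
absent from the other is a perfect diagnostic locus: a PCR primer pair
spanning it produces bands whose sizes differ by the InDel length, visible on
polyacrylamide or agarose gels without any sequencing. This package turns a
reference genome plus per-accession InDel VCFs into such a marker panel, and
then supports using the panel (band scoring, discrimination statistics,
genetic distances, clustering).

This vignette records the models, parameters, and design decisions, in the
spirit of a methods section: what each stage computes, which knobs matter,
and what the synthetic validation does and does not demonstrate.

# Variant model and normalization

An InDel is held as `(chrom, pos, ref, alt)` in VCF convention: 1-based
anchor position, both alleles sharing a leading anchor base, signed length
`nchar(alt) - nchar(ref)` (insertions positive). All internal sequence
arithmetic is 0-based half-open; every user-facing table is 1-based.

Callers may represent the same physical event at different anchors,
especially inside repeat tracts. Before any cross-sample comparison the
calls are **normalized**: shared trailing bases are trimmed, the variant is
shifted left while its last bases match (extending with the preceding
reference base), and shared leading bases beyond the anchor are removed.
The result is the leftmost parsimonious representation; normalization is
idempotent, and the identity key `(chrom, pos, ref, alt)` then makes
allele-exact matching across samples well-defined. Allele-exact matching is
deliberate: two different-length insertions at the same locus produce
different band sizes, so they must be distinct marker alleles. Multi-allelic
records are split into one candidate per called ALT allele for the same
reason.

A site absent from a sample's single-sample VCF is interpreted as reference
genotype for that sample. This matches the semantics of per-sample
short-variant calling without gVCF reference blocks, and is a documented
limitation: missing data are indistinguishable from reference calls at the
catalog stage.

# Group catalogs and specific InDels

The **group-common** set of a group contains the normalized alleles called
in *every* member. Presence means the genotype carries at least one copy of
the allele; a `require_homozygous` strict mode exists because the default is
permissive by choice — inbred rice lines are nearly homozygous, so
heterozygous calls are rare and usually artefactual, and demanding
homozygosity would mostly discard signal.

A variant is **specific** to the target group when it is (i) group-common
there, (ii) strictly longer than `min_len = 10` bp in absolute value, and
(iii) its identical allele is carried by *no* sample of the other group.
Condition (iii) is interpreted irrespective of the reference genotype: the
other group may be reference at the locus, or may carry a *different* ALT
allele — either way the two groups are uniformly distinguishable, and a
different-length ALT simply predicts a third band size on the gel. The
per-variant `rule_trace` records which situation admitted each variant.
The length threshold is strict (`> 10`, so a 10-bp event is excluded)
because band pairs differing by ≤ 10 bp are unreliable to score on routine
gels; it is exposed as a parameter.

Genome-wide distribution statistics use fixed 100-kb windows, half-open on
0-based coordinates with the last window truncated at the chromosome end,
and per-chromosome densities in counts/Mb. Exact bookkeeping (window sums
equal chromosome totals; density equals count over Mb length) is asserted by
tests on every run; reports round densities to 2 decimals.

# Primer design

Templates are the reference sequence 200 nt on each side of the InDel plus
the REF allele between them. Templates truncated below 150 nt on either
side by a chromosome end are excluded as undesignable.

Candidate primers are all substrings of the left flank (forward) and reverse
complements of right-flank substrings (reverse) with:

| parameter | range | optimum | unit |
|---|---|---|---|
| primer length | 18–25 | 21 | nt |
| melting temperature | 55–63 | 58 | °C |
| GC content | 40–60 | — | % |
| reference-allele product | 150–300 | 225 | bp |
| pair Tm difference | ≤ 3 | — | °C |
| genome occurrences | exactly 1 | — | — |

The wet-lab protocol these values come from specifies the ranges but not a
Tm formula; we use the nearest-neighbor model with the SantaLucia (1998)
unified parameter set, entropy salt correction `0.368·(N−1)·ln[Na+]`, 50 mM
monovalent cations, and 50 nM primer strand concentration — the de-facto
standard of the Primer3 family. A Wallace-rule mode
(`2(A+T) + 4(G+C)`) is provided as a closed-form oracle for short oligos and
for tests. The stated "optimum annealing temperature 48 %" in the source
protocol is treated as a typographical slip; annealing is taken at 58 °C,
consistent with its PCR program. The product-size range follows the Methods
value (150–300 bp) where the surrounding text also mentions 150–350 and
100–300; the reference-allele amplicon must lie in range, while the
alternate allele may exceed it by up to the InDel length.

Specificity is **exact full-length occurrence counting on both strands** of
the whole reference: a usable primer occurs exactly once. Exact matching
(rather than alignment with mismatches) is the conservative reading of
"uniquely aligned"; a stricter 3′-seed variant was considered and left out
of the default path. Cross- and self-dimerization are screened only by a
minimal 3′-terminal 4-mer complementarity filter; full hybridization
thermodynamics of hairpins and dimers are out of scope.

The returned pair minimizes
`1.0·(|Tm_f−58| + |Tm_r−58|) + 0.5·(|len_f−21| + |len_r−21|) +
0.02·|product−225|` (weights configurable; units 1/°C, 1/nt, 1/bp), with
deterministic tie-breaking by leftmost forward start then shortest product.
Implementation note: per-flank candidate Tm/GC values are computed from
cumulative dinucleotide sums (O(1) per candidate), and genome-uniqueness is
verified lazily in penalty order with per-primer caching — the result is
provably the same global optimum the exhaustive enumeration finds, which the
test suite asserts against an independent brute-force enumerator on random
templates. Design failure (no surviving pair) is a counted outcome, not an
error, mirroring the attrition accounting of a real validation campaign.

# In-silico PCR, virtual gel, classification

e-PCR matches both primers exactly (0 mismatches, consistent with the
specificity model; `N` never matches) and reports every forward site paired
with every downstream reverse site within a 2-kb cap. A marker **fails**
when either allele yields zero or multiple products. Band resolvability on
the virtual gel defaults to 10 bp minimum separation for 6 %
polyacrylamide and 20 bp for 4 % agarose with a 1-kb size ceiling; these
thresholds are operational inventions — electrophoretic mobility is not
modelled — and are configurable. Under the default design filters
(|length| > 10 bp, PAGE model) every designed marker's allele pair is
resolvable by construction.

Classification of a marker against a cohort partitions varieties by their
band-size sets: `failed` (any variety without a product), `monomorphic`
(identical everywhere), `discriminating_biallelic` (two distinct band sets
that separate the groups perfectly), `discriminating_multiallelic` (more
than two sets, still perfectly separating — e.g. a third allele inside one
group), and `polymorphic_nondiscriminating` otherwise. Discriminating
markers are renamed `IJ` + zero-padded ordinal in (chromosome, position)
order, chromosomes taken in reference-FASTA order, and exported as a
physical map.

# Marker application

Band matrices are binary (0/1, `.` for missing) variety × marker tables
with a group column. The discrimination report calls a marker
discriminating when its non-missing scores are constant within each group
and differ between groups, and lists varieties carrying the out-of-group
allele. Genetic distance defaults to **simple matching** — the fraction of
markers, among those scored in both varieties, at which two varieties
differ — because the band data are symmetric binary codes where shared
absence is as informative as shared presence; Jaccard is available for
workflows that treat absence as non-informative. Missing data are handled
by pairwise-complete comparison; a consequence, asserted in tests, is that
the triangle inequality is only guaranteed for complete matrices.
Clustering uses UPGMA (average linkage), whose ultrametric output matches
the interpretation of a diagnostic panel and has a closed form for two
taxa (`(A:d/2,B:d/2);`); determinism under ties comes from lexicographic
pre-sorting of varieties. Linkage-map construction from segregating
populations is explicitly out of scope.

# The synthetic cohort

The generator emulates the design of a two-subspecies resequencing panel:
10 + 10 samples, and four planted InDel classes — 200 `group_specific`
(length 11–60 bp, homozygous in every target-group sample, absent
elsewhere), 100 `shared` (in all 20 samples), 50 `private` (one sample
each), and 30 `sub_threshold` (target-group pattern but ≤ 10 bp, so the
size filter must remove them). Defaults that the protocol does not fix were
chosen once on domain grounds and not revisited: GC content 0.44 (rice-like),
three chromosomes of 200 kb (large enough for 380 sites at ≥ 500 bp
spacing — the spacing guarantees 200-nt flanking templates never overlap a
neighbouring variant — while keeping a full run around a minute), insertion/
deletion alleles drawn 50:50 with planted representations constructed to be
already left-aligned. All randomness flows from a single integer seed;
generation is deterministic and the emitted files are plain FASTA, VCF 4.2
and TSV.

What passing on synthetic cohorts shows: the set logic of catalog/specific
selection is exact (precision = recall = 1 against planted truth), the
optimizer is the true argmin of its penalty, bookkeeping identities hold,
and the pipeline is byte-deterministic. What it does not show: behaviour
under real-data pathologies — repeat-rich flanks, caller-specific
representation quirks beyond left-alignment, depth-dependent genotyping
error, segmental duplications that defeat exact-match specificity — and no
claim is made that desk-scale counts reproduce any particular resequencing
study's genome-wide totals.

# Degenerate inputs and numerical notes

Non-ACGTN genome characters, duplicated chromosome names, REF alleles that
contradict the reference, equal-length allele records, and band-matrix
entries outside {0, 1, .} are hard errors that name the offending record.
SNP records in input VCFs are silently dropped but counted. Empty variant
sets yield all-zero density tables rather than errors. Tm computation
rejects ambiguity codes; candidates containing `N` are excluded before
scoring. An optional QUAL threshold on VCF records exists but defaults to
off, since the upstream caller's filtering policy is unknown. All
floating-point comparisons in acceptance-style checks are exact-integer
wherever the quantity is a count or size difference.

# Known limitations

* Reference-genotype imputation for absent sites conflates missingness with
  reference calls (no gVCF support).
* Exact-match specificity can overstate uniqueness in diverged duplications
  and understate primability under mismatch-tolerant annealing.
* The gel model is a threshold, not a mobility curve.
* Heterozygous planting exists for testing the presence policy, but the
  pipeline's classification logic assumes largely inbred material.
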