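---
title: "Methods: cross-species sharing, ancient-DNA calling and selection classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species sharing, ancient-DNA calling and selection classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleopv)
```

This vignette is the package's own account of its methods: the models and
rules each module implements, the parameters that matter, the design
choices made where the design was genuinely open, and what the synthetic
tests do and do not establish about real data.

## The question and the two analyses

Pathogenic variants (PVs) in DNA damage repair (DDR) genes could in
principle be inherited from the common ancestors of humans and other
vertebrates, or they could have arisen within human history. The package
operationalises both tests. The phylogenetic analysis asks, for each
human single-nucleotide PV, which species in a multiple alignment carry
the human *alternate* allele at the orthologous column. The
archaeological analysis asks which catalog PVs are detectable in ancient
human (and archaic hominin) sequencing data, and when their carriers
lived.

## Catalog model

A variant is `(chrom, pos, ref, alt)` in 1-based, fully closed VCF-style
coordinates, with gene symbol, clinical class from the closed vocabulary
{pathogenic, likely_pathogenic, uncertain, likely_benign, benign,
conflicting}, and a 0–4 review-star grade. Conversion to the 0-based MAF
reckoning happens in exactly one place (the alignment boundary), which is
the simplest way to keep off-by-one errors out of the sharing calls.

Filtering parameters:

* `keep_classes` — default `{pathogenic, likely_pathogenic}`; the two
  classes are treated as one PV category, which is how clinical practice
  groups them.
* `min_stars` — default 3. A published phrase of the form "review status
  of over three stars" is ambiguous against a 0–4 scale whose maximum is
  4; we read it as "three or more" (a strict reading of "over three"
  would leave only 4-star variants). The reading is stamped into the
  provenance trail of every filtered catalog so downstream numbers are
  auditable.
* `exclude_conflicting` — default TRUE.

Every filter appends to a provenance trail and satisfies
`|input| = |kept| + |removed|`; filters are idempotent and commute with
SNV selection, and both properties are tested.

## Sharing calls against MAF alignments

The MAF dialect implemented is the UCSC one: `a`-line blocks scored,
`s`-line rows with 0-based starts on the +-strand reckoning of each
source (minus-strand starts relative to the reverse complement), row
texts gap-padded to a common length. `i`/`e`/`q` lines are ignored. The
reader and writer are part of this package because the alignment-query
step *is* part of the contribution; blocks are validated (equal text
lengths, ungapped length equal to the size field) at parse time.

`column_at()` locates the block covering a human position — the
highest-scoring block when several overlap, ties broken by file order —
and walks the reference row text counting non-gap characters. A species'
entry is its (uppercased) base, `gap`, or `absent` when the species has
no row in the block. Soft-masked lowercase bases are uppercased before
comparison: masking is an annotation, not evidence about the allele.

The sharing rule: a species **shares** a human SNV iff its aligned base
equals the human alternate allele. A non-gap, non-alternate base is
`not_shared`; gaps and absent species are `unaligned`. If the aligned
human base disagrees with the catalog reference allele the variant is
excluded as `ref_mismatch` — a coordinate or assembly inconsistency, not
biology. Unaligned species count against sharing in the percentage
denominator, so "percent shared" is over the full catalog; that is the
only convention under which the published 1497/7432 = 20.14% arithmetic
is reproducible.

The engine is verified against a brute-force per-character walk of every
reference row (oracle equivalence on 50-block simulated alignments) and
against planted convergent alleles recovered with zero errors.

## Ancient-DNA presence calls

Post-mortem cytosine deamination is the dominant aDNA artifact: C→U
lesions read as C→T near the 5′ end of reads, and as G→A near the 3′
end on the complementary strand in double-stranded libraries. Its rate
decays roughly exponentially with distance `i` from the read end:
`rate(i) = d0 · exp(−λ·i)`.

The published pipeline removed deamination artifacts with an external
recalibration script whose exact rule is not stated. We therefore adopt
an explicit, testable **read-end window rule**: an observation is
damage-suspect iff it is a C→T variant observed as T within `k` bases of
the 5′ end, or a G→A variant observed as A within `k` bases of the 3′
end. All other substitution classes are never suspect, and toggling `k`
provably never changes their calls (a metamorphic test). Defaults:

* `k = 3` bases — covers the steep part of typical double-stranded
  library damage curves; `k = 0` disables the filter (UDG-treated
  libraries).
* `min_baseq = 1` — maximally permissive, matching the published
  minimum-base-quality-one setting.
* `min_clean_alt = 1` — presence is a detection call (≥ 1 damage-clean
  alternate read), not a diploid genotype; the data are far too sparse
  for genotype likelihoods, and the published analysis reports carrier
  presence only. Depth < 2 sets a `low_depth` flag rather than a hard
  filter.

A site whose alternate support is entirely damage-suspect is called
absent with a `damage_only` flag, preserving the evidence for review.
"Recurrent" means present in ≥ 2 distinct samples; the threshold is
explicit because the source phrase ("recurrent in ancient carriers")
never states one.

`estimate_damage_profile()` is the internal stand-in for an external
damage-pattern checker: it profiles the per-position C→T mismatch
frequency over reference-C observations and fits `(d0, λ)` by least
squares on log frequencies. The fit is **weighted by the per-position
mismatch count**: the variance of a log frequency is approximately the
reciprocal of the count behind it, and an unweighted fit lets
near-zero distal positions drag the terminal estimate down
substantially. With weighting, `d0` is recovered within ±0.05 (and λ
within ±0.15) at the ~50,000-observation scale the tests use.

## Comparison statistics

* Per-gene abundance is `n_g / N`, the gene's PV count over the cohort
  total; cohorts are compared by Pearson correlation of the ratio
  vectors after aligning genes by symbol (absent genes enter as 0), with
  a two-tailed t test on `n − 2` degrees of freedom. Ratios, not raw
  counts, because the cohorts differ in size by an order of magnitude.
* Clade and group comparisons use the tie-corrected Kruskal–Wallis H via
  `stats::kruskal.test`; its type-I error is calibrated at 2000 null
  replicates in the acceptance suite.
* Carrier timing bins are `(0, 5000]`, `(5000, 10000]`, `(10000, ∞)`
  years BP — right-closed so that "within 5000", "between 5000 and
  10,000" and "before 10,000" partition the dated carriers the way the
  published 717 + 214 + 28 = 959 decomposition requires. Bin edges are a
  parameter, and the bins are asserted to partition the dated carriers.
* All printed percentages use half-away-from-zero rounding at the quoted
  precision (two decimals for the sharing percentage, one elsewhere);
  `base::round()`'s banker's rounding would disagree with printed values
  at exact halves. Summaries canonically sort their outputs so permuted
  inputs give byte-identical tables.
* Founder-variant ages may be points or ranges; a record's contribution
  to the overall age span uses its older bound, under which the packaged
  founder table spans 8675–180 years BP exactly.

## Pairwise dN/dS and selection classes

The selection analysis replaces maximum-likelihood pairwise CODEML runs
with the Nei–Gojobori (1986) counting scheme plus Jukes–Cantor
correction — transparent, dependency-free, and sufficient for the
qualitative classification (ω above/below 1) the analysis needs. Per
codon, each position's three possible single-base changes are classified
synonymous or nonsynonymous (changes to stop codons count as
nonsynonymous, so every resolved codon contributes exactly 3 sites and
`N + S = 3 × codons` holds as an invariant); observed differences are
averaged with equal weight over all minimal mutational orderings,
excluding orderings through stop codons (falling back to all orderings
in the rare case every ordering hits a stop). Proportions are corrected
with `d = −(3/4)·ln(1 − 4p/3)`; saturation (`p ≥ 3/4`) flags the result
rather than raising. Gapped or ambiguous codon columns are dropped
pairwise-complete; an internal stop is a validation error naming the
codon.

ω = 1 is measure-zero, so "neutral" is operationalised as: the
percentile interval of a codon-column bootstrap (default 1000
replicates, 95%) covers 1. Otherwise the sign of ω − 1 gives
positive/negative. Bootstrap replicates with resampled `dS = 0` are
dropped from the interval.

**Known limitation — transition bias.** NG86 assumes no
transition/transversion rate bias. Under κ > 1, transitions (more often
synonymous) are undercounted as mutational opportunity, so ω is biased
downward; at κ = 2 a truly neutral pair estimates ω ≈ 0.9, and a tight
bootstrap interval will often exclude 1. The calibration tests therefore
run the neutrality check at κ = 1 — the regime whose assumptions the
counting scheme itself makes — while ω-recovery monotonicity and the
purifying-selection calibration run at the realistic κ = 2, where the
bias does not change the ordering or the sign of ω − 1. Users comparing
distant species with strong transition bias should read near-1 ω values
conservatively; this is precisely the regime where ML codon models
improve on counting methods.

## The simulators: what they emulate, and what they do not

Generators are pure functions of (parameters, seed).

* `simulate_species_alignment()` evolves sequences down a phylogeny
  under an HKY process (via `phangorn::simSeq`) and emits reference-led
  MAF blocks; an optional multi-block mode exercises the interval index.
  No indels, no rearrangements, no alignment error — so passing tests
  show the *query and calling logic* is correct, not that real Multiz
  alignments are.
* `plant_variants()` places SNVs with a chosen substitution-class
  spectrum and writes chosen alternate alleles into chosen species —
  convergent recurrence by construction.
* `simulate_ancient_reads()` places fixed-length reads uniformly,
  emits alternate alleles on half the overlapping reads for heterozygous
  carriers (all, in homozygous mode), then applies exponential-decay
  terminal deamination and uniform sequencing error. Reads carry true
  end distances; there is no mapping error, no contamination, no
  reference bias. Carrier-recovery results on these data are therefore
  upper bounds on real-data sensitivity.
* `simulate_codon_pair()` evolves two lineages from a uniform ancestor
  for `t/2` each under a GY94-style 61-state matrix with parameters
  (ω, κ), uniform codon frequencies, rates normalised to one expected
  substitution per codon per unit `t`. Uniform frequencies make the
  rate matrix symmetric, so the transition matrix comes from a symmetric
  eigendecomposition — numerically stable with no extra dependency.

Problem sizes in the test and acceptance runs (chosen as the package's
own working scale): alignments of 1.5–4 kb over 4–10 species and up to
50 blocks; cohorts of 10–100 samples at coverage 4–30 over 40–60 catalog
sites; damage estimation on ~50k reference-C observations; codon pairs
of 1000–2000 codons with 100-replicate calibrations and 1000-replicate
bootstraps; 2000-replicate Kruskal–Wallis null calibration.

## Fixtures

The published summary tables (primate sharing entries; per-gene ancient
PV counts; the CHEK2 carrier table; founder PVs with arisen ages; the
pathway decomposition; headline counts) are transcribed as printed into
plain-text TSVs with pinned checksums. Known internal inconsistencies of
the source tables are carried as-is and documented in `notes` columns —
e.g. a species row count that disagrees with the accompanying text by
one, and a printed "84.0%" whose exact quotient (73/87) is 83.9% at one
decimal; the package always reports the exact arithmetic. The
gene→pathway panel packaged here covers the genes appearing in the
summary tables with standard KEGG-style pathway assignments and is
user-replaceable; the full original gene panel is not printed in the
source, so per-pathway splits are reproducible only for the packaged
panel's definition.

## Pipeline and export

`run_pipeline()` chains the stages that its configuration enables and
writes a bundle of canonically sorted TSVs plus a JSON summary; rerunning
with the same configuration and seed is byte-identical. The export is a
self-contained TSV/JSON bundle (one table per analysis product, carrier
annotations with dates, locations and HGVS strings) rather than a server
database — single files, diffable, and testable.
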