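# paleopv

Where did the pathogenic variants (PVs) in human DNA damage repair (DDR)
genes come from — deep vertebrate ancestry, or recent human history?
`paleopv` implements the two complementary analyses that answer this for a
ClinVar-style PV catalog:

1. **Phylogenetic**: each human single-nucleotide PV is looked up in a
   UCSC-style multiple alignment (MAF) and a species is called *sharing*
   the variant when its orthologous base equals the human **alternate**
   allele. Per-species counts roll up into the eight vertebrate clades
   (Primate, Euarchontoglires, Laurasiatheria, Afrotheria, Mammalia,
   Aves, Sarcopterygii, Fish) and are compared with a Kruskal–Wallis
   test. If PVs were inherited from common ancestors, sharing should
   track phylogenetic distance; convergent recurrence of the same coding
   change produces the opposite pattern.
2. **Archaeological**: the same catalog is searched in ancient-genome
   pileups. Post-mortem deamination reads out as C→T near 5′ read ends
   (and G→A near 3′ ends for double-stranded libraries) with a rate that
   decays exponentially into the read, `rate(i) = d0·exp(−λi)`. A
   deamination-consistent alternate read within `k` bases of the relevant
   read end is discounted; a variant is *present* in a sample when at
   least one damage-clean alternate read of sufficient base quality
   remains. Carrier dates (years BP) are binned at 5,000 and 10,000 BP,
   recurrence is ≥ 2 distinct carriers, and per-gene PV abundance
   (`n_gene / N_total`) is compared between cohorts by Pearson
   correlation.

Selection on the affected genes is classified by pairwise dN/dS:
Nei–Gojobori (1986) site/difference counting with Jukes–Cantor
correction, `ω = dN/dS`, and a codon-column bootstrap; `ω > 1` positive,
`ω < 1` negative, and *neutral* when the bootstrap interval covers 1.

A synthetic-data module generates every input format with planted ground
truth (species alignments with convergent alleles, damaged ancient reads,
codon pairs evolved at chosen ω under a GY94-style model), and the
published summary tables ship as plain-text fixtures for exact worked
examples.

## Worked example

```r
library(paleopv)

## cross-species sharing on a simulated alignment with planted truth
tree <- "(hg19:0,(chimp:0,chicken:0,zebrafish:0):0);"
sim  <- simulate_species_alignment(tree, 2000, seed = 4)
plan <- data.frame(variant = c(2, 2, 9),
                   species = c("chicken", "zebrafish", "chicken"))
pl   <- plant_variants(sim, 25, convergent_plan = plan, seed = 5)
m    <- build_sharing_matrix(pl$catalog, index_maf(pl$blocks),
                             c("chimp", "chicken", "zebrafish"),
                             c(chimp = "Primate", chicken = "Aves",
                               zebrafish = "Fish"))
sharing_summary(m)
#> shared variants: 2 of 25 -> 8 %
#>     species n_shared   clade
#> 1     chimp        0 Primate
#> 2   chicken        2    Aves
#> 3 zebrafish        1    Fish
```

Two of the 25 planted PVs are shared — exactly the two the convergent
plan placed — and both sit in distal clades while the chimpanzee shares
none: the signature of convergent recurrence, not conservation.

```r
## headline arithmetic recomputed from the packaged summary tables
hs <- headline_summary()
#> catalog share found in any vertebrate: 20.14%
#> ancient PVs: 1266 in 73 genes; recurrent: 5.3%
#> dated carriers within 5000 BP: 74.8%

## selection classification at a planted omega of 0.2
p   <- simulate_codon_pair(omega = 0.2, kappa = 2, t = 0.3,
                           n_codons = 2000, seed = 11)
res <- dnds(p)
classify_selection(res, n_boot = 1000, seed = 1)
#> omega = 0.171 [0.140, 0.206] -> negative
```

The 20.14% is 1497 of 7432 catalog SNVs found in at least one of 100
vertebrate species; 1266 PVs in 73 genes were detectable in ancient
genomes, three quarters of their dated carriers within the last 5,000
years — the quantitative core of the "recent origin" conclusion. The
simulated gene pair planted at ω = 0.2 is recovered as ω ≈ 0.17 and
classified under negative (purifying) selection.

A thin command-line wrapper over the same functions is at
`inst/cli/paleopv.R` (subcommands `share`, `call-ancient`, `dnds`,
`fixtures`, `report`).

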