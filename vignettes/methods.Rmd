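---
title: "Methods: ploidy estimation and intraspecific gene divergence in straindiverge"
author: "straindiverge authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ploidy estimation and intraspecific gene divergence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

straindiverge compares conspecific strains of small polyploid eukaryotes —
the motivating system is free-living heterotrophic protist strains with
~50 Mb haploid genomes, 16,000–19,000 genes and ploidy differences between
strains — using three kinds of evidence: allele-balance spectra from variant
calls, heterozygous k-mer pairs from raw read counts, and cross-strain gene
complements. This vignette records the models, their assumptions, the
numerical choices, and what the synthetic data generator does and does not
emulate.

## Ploidy from allele balance

At a biallelic heterozygous site in a ploidy-$m$ nucleus whose alternate
allele lies on $j$ of the $m$ haplotypes, the alternate read fraction
$y = AD_\mathrm{alt}/(AD_\mathrm{ref}+AD_\mathrm{alt})$ concentrates around
$j/m$. Each ploidy hypothesis $m \in \{2,3,4\}$ is a Gaussian mixture with
component means fixed at $j/m$, $j = 1..m-1$. Hypotheses stop at 4 because
the variant caller is run with a ploidy bound of 4.

Two constraints make the hypotheses identifiable:

* **Component proportions are fixed and equal** ($w_j = 1/(m-1)$), and only
  the per-component standard deviations are estimated by EM (floored at
  $10^{-3}$; convergence at $\Delta\log L < 10^{-6}$ or 500 iterations).
  With free proportions the diploid model is nested inside the tetraploid
  one (weights $(0,1,0)$), so a tetraploid model can imitate — and, by
  absorbing stray tail sites, strictly beat — the diploid model on diploid
  data; fixing the proportions is what makes "diploid vs tetraploid" a real
  contest. It also matches how the heterozygous carrier counts arise in the
  generator (uniform over $1..m-1$).
* **Supports are bounded and $\sqrt{n}$-scaled.** We report
  $s_m \propto \exp\{(\log L_m - \log L_{best})/\sqrt{n}\}$, normalized to
  sum to 1, and call the top hypothesis only when its support exceeds the
  runner-up by at least 0.10 (the margin rule; otherwise "ambiguous").
  Raw-likelihood softmax saturates at 0/1 for thousands of sites, making
  the margin vacuous; per-site scaling ($/n$) collapses all supports toward
  equality, leaving true triploids and tetraploids permanently below a 10%
  margin. Likelihood-ratio fluctuations grow like $\sqrt{n}$, so the
  $\sqrt{n}$ scale behaves like a z-score: decisive on genome-scale data,
  conservative on sparse contigs.

A free three-component mixture (means, weights and spreads all free; three
EM starts, best likelihood kept) serves as the likelihood ceiling; the
nesting $\log L_{free} \ge \log L_m$ is asserted in the tests.

**Denoising.** Before model comparison we fit the free mixture augmented
with a Uniform(0,1) error component and remove sites that the uniform
component claims. Three numerical choices matter. Component spreads are
capped at 0.12 — an allele-balance mode is read-sampling noise around
$j/m$ (binomial width $\le \sqrt{0.25/8} \approx 0.18$ at the depth floor,
$\approx 0.07$ at typical depth), and without the cap a free Gaussian
widens until it impersonates the uniform. Gaussian components whose fitted
weight falls below 0.05 are treated as noise shelters — any genuine mode at
ploidy $\le 4$ carries at least about a fifth of the sites, while a tiny
component camped on a patch of error sites is exactly how uniform noise
locally mimics a mode. Finally, a site is removed when the uniform
posterior exceeds 0.25 rather than 0.5: error sites kept in bias every
downstream likelihood, whereas dropping ~1% of genuine sites among
thousands is harmless, so the loss is asymmetric.

**Per-contig calls.** Contigs of at least 10 kb with at least 50 usable
sites are called separately, and the summary reports, per ploidy level,
the fraction of called-contig length assigned to it (contig-length
normalization), plus the fraction of contigs passing the margin rule.
Contigs below 50 sites are "no call" and excluded from the normalization.

## Ploidy from k-mer pairs

A heterozygous SNP produces pairs of 21-mers differing at one position.
Pair discovery buckets every k-mer by its sequence with one position
wildcarded — at every position, in both orientations, canonicalized — and
emits a pair only from buckets holding exactly two k-mers; three or more
members indicate a repeat-ambiguous locus. Pairing at any position (not
only the middle base) maximizes pairs on small genomes. The bucketing is
exactly equivalent to an all-vs-all strand-aware Hamming-distance-1 scan
with the same exclusion rule, which the tests verify by brute force.

With per-copy coverage $n$, the genotype grid is AB $(2n, 1/2)$,
AAB $(3n, 1/3)$, AAAB $(4n, 1/4)$, AABB $(4n, 1/2)$ in (total coverage,
minor fraction) space. Distances to grid centers are standardized per axis
by the sampling width the genotype itself predicts — Poisson for
$\log(\mathrm{total})$, binomial for the minor fraction — inflated by 1.25
for overdispersion.

**Haploid coverage.** Candidates come from coverage peaks: the dominant
total peak of near-balanced pairs (minor fraction $\ge 0.4$) divided by 2,
and the global dominant peak divided by 2, 3 and 4. Anchoring on the
balanced window alone mis-handles tetraploids, whose AABB smudge dominates
that window at $4n$ and would yield $\hat n = 2n$, collapsing AABB onto AB;
we therefore score every candidate by the classified-pair likelihood (each
pair under its nearest center) and keep the best. Candidates within 0.3
(in squared-z/2 units) of the best are ties resolved toward the larger
$\hat n$ — the fewest-copies explanation. That window is deliberate: a grid
that merely reinterprets the same smudges (AB read as AABB at half the
coverage) scores within ~0.2 of the truth because its surplus centers soak
up tail pairs, while the nearest genuinely wrong grid is at least ~0.4
away.

Pairs whose two best genotype distances differ by less than 5% (this is
the AB-vs-AABB ambiguity at fraction 1/2) are "unresolved" and excluded
from the modal vote; the ploidy call is the copy number of the genotype
with the most pairs.

## Variant filters and gene divergence

Sites are kept when read depth is at least 8 and at least one alternate
allele is supported by at least 10% of the reads (the boundary is
inclusive: exactly 10% survives, "below 10%" is excluded). The 10% rule is
applied per alternate allele against DP, and failing alternates are pruned
from the record; records originally multiallelic stay excluded from
allele-balance extraction even after pruning, because the mixture model is
defined on biallelic fractions. MNPs (equal multi-base alleles) decompose
into one SNP per differing base.

Pairwise gene divergence is allele-aware: for a gene family shared by two
strains, their reference sequences are aligned globally (match +1,
mismatch −1, gap opening 2, extension 0.5) and, at every column, each
strain offers its reference symbol plus any alternative alleles called at
that position (deletion alleles contribute a gap symbol; insertion alleles
fill gap columns). A mutation is counted only where the two symbol sets
are disjoint — no allelic variation could induce a match. Columns are
treated independently (the caller's genotypes are unphased, so
haplotype-consistent matching is not supportable); the brute-force oracle
in the tests enumerates full allele assignments under the same assumption
and agrees exactly. The mutation rate divides the count by the alignment
length, and a pair is "identical" at zero mutations. Per-gene variant
profiles count SNPs, insertions and deletions whose anchor position falls
in the gene's half-open interval, normalized by gene length.

## Gene complement across strains

Predicted genes from all strains are pooled and clustered greedily in
length-descending order: a gene joins the first cluster whose
representative it matches at local-alignment identity $\ge 0.8$ with
$\ge 80\%$ coverage of both sequences and length ratio $\ge 0.8$ (both
strands tried; an 8-mer shared-word screen prunes candidates before
alignment). Cluster consensus is the column-wise majority over
representative-anchored alignments, ties to the representative.
Representatives are placed back on every genome by seeded local alignment
(exact 24-mer seeds every 80 bp, diagonal-banded candidate windows, best
placement with identity $\ge 0.9$ and $\ge 80\%$ gene coverage).
Same-strand placements overlapping by at least 10% of the shorter
placement's length merge transitively into one locus (the shorter length
is the conservative reading of "10% of the gene length"; the threshold is
boundary-inclusive). Families present in all genomes are core, in several
shared, in exactly one exclusive, and gene density is the number of merged
loci per megabase of contigs longer than 500 bp (strictly), truncated to
an integer — truncation, not half-up rounding, is what reproduces all
three published densities from rounded assembly sizes.

## Category statistics

Per-gene rates are stratified by functional category (KEGG-style top
groups plus "unannotated" and organelle-targeted). Within a category,
one-way ANOVA compares per-gene rates across strains for each variant
type; pairwise divergence rates are compared across strain pairs by
Kruskal–Wallis (these rates are far from normal); both at $P < 0.01$ with
no multiple-testing correction by default. Zero-variance inputs report
$p = 1$ with a degeneracy flag rather than NaN. Post-hoc contrasts between
strain pairs use the Wilcoxon signed-rank test paired by gene family
(families missing from either group are dropped). Contrasts **between
categories** have no pairing unit — each gene belongs to exactly one
category — so they use the unpaired Wilcoxon rank-sum test; the output
labels say which test was used. Module completeness follows the
miss-at-most-one rule: a two-gene module must be complete, larger modules
may miss one gene.

## The synthetic data generator

The generator emulates the three-strain study design at desk scale: an
ancestral genome with non-overlapping genes on both strands; three derived
strains at ploidy 2, 3 and 4 sharing ~68.5% of gene families, ~80.8%
shared by at least two, with the tetraploid carrying the largest exclusive
complement; category-specific heterozygosity and divergence rates (energy
metabolism most conserved, unannotated genes most variable); heterozygous
SNPs and short indels ($\le 10$ bp) carried by $j \sim$ Uniform$(1..m-1)$
haplotypes; fixed inter-strain substitutions; fragmented contigs including
deliberate sub-500 bp pieces; negative-binomial site depths with binomial
allele depths plus a 5% uniform-error site fraction; and Poisson k-mer
counts at per-copy coverage `mean_coverage / ploidy`. A `conserved`
fraction of genes (8%) accrues no fixed substitutions in any strain, so
strain pairs share identical genes, as real conspecific strains do.
Haplotype 1 doubles as the collapsed reference assembly: heterozygous
variants are carried only by haplotypes $2..m$, so VCF records are
expressed against the written contigs exactly as a collapsed-assembly
caller would produce them, while allele fractions and k-mer coverages are
unchanged.

Default rates were chosen once to land in the study's regime — ~97–98%
inter-strain nucleotide identity (per-category divergence 0.4–1.8
substitutions per 100 bp), heterozygosity 0.2–1.2%, coverage 50× — and are
not tuned afterwards. What the generator does **not** emulate: read-level
errors and FASTQ simulation, repeats and transposons, structural variants,
spliced genes, paralog expansions, and assembly collapse artifacts.
Passing tests therefore demonstrate correctness of the algorithms under
clean polyploid genetics, not robustness to repeat-rich real assemblies.

## Problem sizes and runtime choices

The packaged checks run at sizes chosen to keep the full suite in the
minutes range on one core: ploidy-recovery calibration uses 100 replicates
per ploidy level of 5,000 sites at depth 50 with 5% noise; the two-method
concordance check uses 20 replicates per ploidy level of 1 Mb haploid
genomes at coverage 50; oracle equivalence uses 200 random small genes and
a few thousand k-mers; statistical calibration uses 1,000 null replicates.
The `paper-like` generator preset (3 strains, 1 Mb haploid, 600 genes)
generates in seconds; `mini` and `micro` presets scale the same design
down for integration tests.

## Known limitations

* Ploidy hypotheses stop at 4; aneuploidy and per-chromosome copy number
  are out of scope, and a tetraploid that recently doubled from a diploid
  shows diploid-like balance at many loci — the supports expose, rather
  than resolve, that ambiguity.
* The observation model for allele balance is Gaussian on $y$; depth
  enters only through the site filter. A beta-binomial model would weight
  deep sites more faithfully and could be swapped in behind the same
  interface.
* The built-in placement aligner is for intron-free (synthetic or compact)
  genes; spliced placements from an external aligner can be supplied in
  its place.
* Identical-gene counts depend on placement boundaries being identical
  across strains; heavily fragmented real assemblies will depress them.
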