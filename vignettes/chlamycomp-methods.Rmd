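---
title: "Methods: coding-potential audits, conservation landscapes and genome screens"
author: "chlamycomp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coding-potential audits, conservation landscapes and genome screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

chlamycomp reimplements, as a tested pipeline, the bespoke analysis layer
of reference-anchored comparative genomics in *Chlamydomonas* and its
relatives: auditing annotated gene models for coding potential, measuring
the landscape of sequence conservation over a multi-species whole-genome
alignment (WGA), and running sequence- and annotation-level genome
screens. This vignette explains the models and procedures, the defaults
and why they were chosen, what the synthetic-data generator does and does
not emulate, and the numerical decisions a maintainer should know about.

## Coordinate and sequence conventions

All internal coordinates are 0-based half-open; conversion to and from
1-based formats (GFF3, VCF) happens only in the readers and writers, so a
round trip through `read_gff3_models()`/`write_gff3_models()` preserves
coordinates bit-exactly. Soft-masked (lower-case) bases are preserved and
treated as sequence; ambiguity codes are legal everywhere and all
site-level computations treat non-ACGT bases as uncallable. Codons
containing an N are wholly uncallable rather than per-offset callable, to
avoid asymmetric classification within one codon.

## Codon degeneracy and site classes

`classify_codon_degeneracy()` labels a codon position 0D/2D/3D/4D by
counting which of the three possible substitutions are synonymous under
the standard code. Stop codons are classified by stop preservation: a
substitution is "synonymous" only if it yields another stop. This is the
convention required for high-impact diversity, where 0D positions of stop
codons are positions at which any change destroys the stop.

`call_site_classes()` partitions every base uniquely with the fixed
precedence CDS > 5'UTR > 3'UTR > intron > intergenic. Overlapping genes
are resolved purely by this class hierarchy -- there is no precedence
between genes, because only class precedence is well defined. Genes with
internal stop codons are flagged but still mapped and scored: the audit
exists to interrogate dubious models, not to discard them first.

Intergenic runs are tiled into tracts and split at 250 bp into short and
long, the boundary at which short tracts (mostly promoter-scale spacers
in a genome whose median intergenic distance is ~134 bp) behave
differently from long tracts. Contig-terminal tracts bound only one gene;
they are included and flagged, since excluding them would bias tract
length distributions on fragmented assemblies.

## Nucleotide diversity

Per-site diversity for n haploid isolates is the unbiased estimator
$\pi = \frac{n}{n-1}\left(1 - \sum_i p_i^2\right)$, with the full
multiallelic form rather than 2pq. Region-level $\pi$ divides the summed
per-site values by a denominator L that includes callable monomorphic
sites. When the variant table carries no callable mask, every non-N
reference position in the region is assumed callable; this is a
documented, overridable default, since upstream variant filtering is out
of scope here. Sites with fewer than two called alleles leave both the
numerator and the denominator (a pairwise difference is undefined there).

The per-gene statistic $\pi_{0D}/\pi_{4D}$ contrasts diversity at
zero-fold sites (all substitutions amino-acid-changing) with four-fold
sites (none are). Under purifying selection the ratio sits well below 1;
a gene model whose "CDS" is not actually coding has no reason to show the
contrast and drifts toward 1. The ratio is undefined when $\pi_{4D} = 0$
or a site set is empty; the undefined marker is propagated and the
classifier treats it as threshold-exceeding, because a gene for which the
ratio cannot be computed provides no evidence of coding constraint.

## Codon adaptation (I_TE-like) and the reference set

Codon usage is counted over the spliced CDS per gene (start codon
included -- it only feeds Met, which is never scored -- stop codon
excluded). Six-fold families are split into sub-families sharing their
first two codon positions (Leu TTR+CTN, Ser TCN+AGY, Arg CGN+AGR), the
behaviour of the "break 6-fold families into two" option of standard
codon-adaptation tools; the standard code has no eight-codon family, so
only six-fold families can split.

The highly-expressed reference set is chosen by correspondence analysis
of the usage matrix: standardized residuals under independence,
decomposed by SVD; genes' principal coordinates on axis 1 capture the
dominant usage trend. The default 5% of genes from one extreme are taken,
with the pole chosen by hypergeometric enrichment of marker genes
expected to be highly expressed (ribosomal-protein-like genes in the
synthetic data); without markers the caller must name the pole. Axis
orientation is arbitrary in CA, so formalising the pole choice this way
removes an otherwise silent sign convention.

The codon weight is a mutation-bias-adjusted ratio of ratios: for codon c
in sub-family F, $w_c = r_c / \max_{c' \in F} r_{c'}$ with
$r_c = F_{hi}(c)/F_{bg}(c)$, the codon's within-family frequency in the
reference set over the same frequency in the background (all annotated
genes minus the reference set). A pseudocount of 1/2 on every count keeps
small sub-families defined. The per-gene score is the geometric mean of
$w_c$ over the gene's codons, excluding Met, Trp, stops and sub-families
unused in the reference set. We describe the score as "I_TE-like": it is
not a line-for-line reproduction of any particular tool's internals, but
it preserves the defining property -- codon preference measured against
the mutational background, scaled so the family optimum is 1 -- and the
audit only ever consumes it through within-dataset percentiles, which
makes the classification insensitive to the exact weight normalisation.

## Kozak model and scoring

The start-codon context is ten genomic sites, -5..-1 and +4..+8 relative
to the A of ATG (+1); the ATG itself carries no information about context
strength and is excluded. The genomic (pre-mRNA) window is used rather
than spliced mRNA; genes whose window crosses the first splice donor are
flagged so either convention can be audited. Per site, base frequencies
give an information content $R_s = 2 - H_s$ bits. A query scores the sum
of $f_{consensus,s} \cdot R_s$ over sites where it matches the consensus;
the alternative reading (credit the query base's own height regardless of
match) is available behind `match_only = FALSE`. No small-sample entropy
correction is applied: training sets here are thousands of contexts, and
the correction would only perturb the ranking the audit relies on.

## The coding-potential classifier

Genes with an ortholog in a related species and/or an annotated
functional domain form the control set; genes with neither are the test
set. Per-gene coding-potential scores are aggregated from externally
computed per-exon scores (the scorer itself is an upstream tool whose
output is consumed as input): the best exon of >= 45 bp wins, because a
single misaligned exon can sink a whole-CDS score for a genuine gene;
with no qualifying exon the whole-CDS score is used; with no alignment at
all the score is 0. Thresholds are always derived from the control
distribution of the same run -- the 95th percentile of control
$\pi_{0D}/\pi_{4D}$ and the 5th percentile of control I_TE, by linear
interpolation -- never hard-coded. A test gene failing all three tests is
`lcp1` (low coding potential, strict); failing the score test plus
exactly one other is `lcp2`; control genes are never labelled lcp, since
their independent evidence outweighs the statistical tests. A score of
exactly 1 passes the score test (the cutoff is "< 1" taken literally).
An undefined I_TE (no scorable codons) fails the adaptation test,
symmetric with the undefined-ratio rule, and is flagged separately.

## WGA analyses

The alignment is consumed reference-anchored. Duplicate (paralogous) rows
are reduced to one per species by keeping the row closest to the
column-wise majority-base consensus of the block; consensus ties go to
the lexicographically first base and row-score ties keep the first row in
file order, flagged -- determinism matters more than the (rare,
arbitrary) choice itself. Reference positions covered by more than one
block take the first block, jointly for all species, and re-coverage is
counted: single-copy filtering makes multiple coverage rare, and a
deterministic rule keeps every downstream result reproducible.

Alignability counts a reference base as aligned to a species when some
retained block column pairs it with a non-gap base. 4D columns are
extracted per gene over the spliced CDS: a reference third-position 4D
site is kept only when every species has a gap-free, unambiguous triplet
at those three reference columns that is itself 4D at the third position
on the gene's coding strand; codons straddling a block boundary are
dropped and counted. UCEs are maximal runs (>= 50 bp) of reference
positions at which every species of the designated trio is aligned,
gap-free and identical to the reference; identity is measured against the
reference base, matching the reference-coordinate reporting of the
elements, and soft-masked columns participate (conservation is
conservation; repeat overlap can be flagged downstream). Because
conformance is evaluated per reference position on a pileup, runs split
across block boundaries merge automatically whenever the intervening
columns conform. The broad-conservation subset keeps UCEs whose fraction
of all-species-identical columns is >= 0.95 (the column-wise reading of
">= 95% conservation"; mean pairwise identity is the noted alternative).

CE overlap tables report, per site class (intergenic split at 250 bp),
the bases covered by externally supplied conserved elements, the share of
all CE bases, the share of the class, and diversity over CE / non-CE /
all sites. CE calling itself (a phylo-HMM over the WGA) is out of scope;
its parameters travel as provenance only. The intron analysis orders
introns by length, splits them into 50 equal-count bins (sizes differing
by at most one) and correlates per-bin mean length with the fraction of
intronic bases in CEs; the contrast of <100 bp versus longer introns and
a t-test on relative transcript position accompany it.

## Genome screens

Telomere detection scans both contig termini for tandem repeats of the
motif in any rotation (arrays rarely begin at motif phase 0), with the
reverse complement at the contig start; at least 2 copies within the
terminal 1 kb, reaching within 100 bp of the end. The copy and window
parameters are explicit knobs, since "terminating in" is not a precise
rule. Terminal annotated features (Zepp-like LINE clusters at
centromere-adjacent contig ends) use a 20 kb terminal window; windowed
density tracks report the merged coverage percentage in 50 kb windows.
Gene models are flagged when TEs/satellites cover >= 30% or
low-complexity/simple repeats cover >= 70% of the spliced CDS, or on
internal stops or proteins shorter than 30 aa. Orthogroup domain
assignment keeps a domain ID when it reaches >= 20% of the orthogroup's
genes and >= 50% of its species. Gene-family calls use
$\log_2(\text{focal count} / \text{mean count in other species})$, with
expansions > 1 and contractions < -1; zero denominators or numerators
give signed-infinity markers rather than pseudocounted ratios, keeping
calls well defined without inventing a smoothing constant.

## The synthetic-data generator

Every input the pipeline consumes is generated from a seed with a
ground-truth manifest, so each analysis can be tested against a known
answer. The default conditions are the study conditions: two 1 Mb
chromosomes at GC 0.64; 300 genes with a mean of ~8 CDS exons, an intron
length mixture with a 5% short (<100 bp) component and a lognormal body
with median ~230 bp, short introns preferentially assigned to the first
ordinal; intergenic tracts mixing short (<250 bp, weight 0.6) and longer
lognormal gaps; Chlamydomonas-type telomere arrays (TTTTAGGG, 25 copies)
at contig termini; a clustered Zepp-like TE family at a centromere-like
midpoint. A quarter of genes are planted as spurious models: GC-matched
random ORFs with random start-codon contexts, zero-or-negative external
scores and no ortholog/domain rows; genuine genes draw codons from a
biased regime (sub-family-optimal codon probability 0.8), contexts from a
planted Kozak position model (consensus probability 0.7) and positive
per-exon scores.

The alignment evolves the reference down a fixed eight-species tree
(focal-to-nearest 0.34, next 0.45, remaining species ~0.8-1.0
substitutions/site) under site-independent HKY (kappa 2.5, stationary GC
0.64), re-rooted at the reference tip so the root sequence *is* the
reference genome and patristic distances are preserved. Planted CEs
evolve at rate multiplier 0.4 -- low enough to look constrained, high
enough that a spurious 50 bp identical run inside a CE is vanishingly
unlikely, which is what lets planted UCEs be recovered exactly. UCE sites
accept no substitutions on the branches spanning the trio (none anywhere
for a deep subset), and a forced mismatch is written in the nearest
species immediately flanking each UCE so that the maximal recovered run
equals the planted interval exactly. Deletions are confined to
unconstrained non-CDS regions and grow with divergence, producing the
expected alignability contrast while keeping reading frames trivially
intact. Variants are planted site-independently: each site segregates
with probability target-pi / E[pi | segregating] under the neutral
frequency spectrum (derived-allele count with probability proportional to
1/i), so the expected per-site diversity equals its target; per-class
targets follow the published per-class magnitudes (CDS 0.0144, 5'UTR
0.0189, 3'UTR 0.0205, intron 0.0248, short/long intergenic
0.0229/0.0137), with within-CDS structure by degeneracy (genuine genes:
0D at 0.2 x 4D; spurious genes: 0D and high-impact sites at the 4D
level) and CE sites damped below their class level.

What the generator does **not** emulate -- and hence what passing tests
do and do not show about real data: linkage and demography (sites are
independent; there is no coalescent correlation, no recombination
landscape), indel evolution inside coding sequence, TE sequence
homology (repeats are annotation-level), alignment error (the MAF is
correct by construction; real aligners misalign), expression-informed
reference sets, and the upstream tools themselves (variant calling,
CE calling, coding-potential scoring are consumed as inputs). Tests
therefore validate the analysis layer's correctness and calibration, not
the robustness of upstream inference.

## Numerical choices and problem sizes

Percentiles use type-7 linear interpolation. The CA drops zero-margin
rows/columns with a warning and needs at least 2 x 2 structure. The
duplicate filter, UCE scanner and 4D extractor are all checked against
brute-force oracles in the test suite; diversity calibration is checked
over 20 seeds at L = 1e5 sites. The test suite and the acceptance script
run the full default conditions (2 x 1 Mb, 300 genes, 8 species, 17
haploids, ~110k variant sites) once and reuse the result across checks;
the end-to-end determinism check runs a 0.4 Mb single-chromosome version
of the same conditions twice and compares bytes, a size chosen so the
whole suite stays desk-scale. Sub-family weights warn rather than fail on
reference sets that never use a family, and every undefined quantity
(ratios, I_TE, correlations over zero-variance bins) is carried as an
explicit marker with a reason, never silently dropped.

## Known limitations

The I_TE-like weight is not guaranteed to match any specific published
implementation's internals (percentile use limits the impact, but
absolute score values should not be compared across tools). The Kozak
window uses genomic context for intron-interrupted starts; flagged genes
let either convention be audited but only one is computed by default.
UCE identity is reference-anchored, not mean-pairwise. The generator's
deletion model is block-wise and species-independent, which understates
correlated alignment gaps; and because CDS columns are never deleted,
coding alignability is exactly 1 by construction rather than merely
high.
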