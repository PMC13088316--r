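---
title: "Typing polymorphic immune loci from long reads: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Typing polymorphic immune loci from long reads: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polytypeR)
```

## The problem

HLA, KIR, IG/TCR and CYP genes are among the most polymorphic loci in the
human genome: thousands of named alleles per locus, high inter-locus sequence
homology, and clinically meaningful resolution down to single-field
differences. Long reads span whole alleles but carry 5--15% base error, so a
read can align convincingly to many alleles of many loci. polytypeR types a
diploid sample in four stages: bin each read to its source locus, select the
best-matched diploid allele pair per locus, reconstruct personalized
haplotype sequences, and assign database nomenclature. A companion module
computes population-level statistics on typing output.

## Read binning

For each read-allele alignment the identity is
$1 - \text{mismatch bases} / \text{alignment length}$ where the alignment
length is the block length including gap columns (the gap-inclusive dialect;
long-read aligners report residue matches and block length, so mismatch
bases fall out as their difference). Per locus the identity is the maximum
over its alleles; the read goes to the argmax locus. Reads under the
identity threshold (default 0.85) are discarded as likely off-target. A read
genuinely spanning two neighboring loci is kept for both when the gap
between its two mapped intervals, $D_{reads}$, is positive and within
$\vartheta = 2000$ bases of the reference gap between the loci. Identity
ties between loci break lexicographically so reruns are reproducible; for
reads touching three or more loci only the top two by identity enter the
two-locus rule.

## Best-matched allele pair

Per locus, alignments against the condensed candidate set (the 200 deepest
alleles by total aligned bases per database base; length-normalizing keeps
long alleles from dominating) fill three read-by-allele matrices: matched
bases $M$, mismatched bases $S$, identity $D$, with absent alignments
excluded (not zero). For a candidate pair $(a_i, a_j)$ each read is assigned
to the member it matches with higher identity, a seeded fair coin breaking
exact ties; the pair score aggregates matched bases $\alpha$, mismatched
bases $\beta$, and identity $\gamma = \alpha / (\alpha + \beta)$. Pairs
within a tolerance $\tau$ of the maximal $\alpha$ form a candidate set, and
the retained pair with maximal $\gamma$ wins. $\tau$ is interpreted as a
*relative* tolerance (default 0.02, i.e. pairs above $0.98\,\alpha_{max}$)
so the rule does not depend on sequencing depth; homozygous pairs $(a_i,
a_i)$ compete on equal footing. When every read prefers one allele, all
pairs containing it tie exactly; the zygosity call below collapses such
calls onto the major allele, so the arbitrary tie-break never leaks into the
genotype.

Zygosity uses beta-posterior allele frequencies: with per-allele depths
$d_i, d_j$ (assigned aligned bases over allele length) and a Beta(1, 1)
prior, $\kappa_i = (1 + d_i) / (2 + d_i + d_j)$, and the locus is homozygous
when $\min(\kappa_i, \kappa_j) < \chi = 0.3$.

## Haplotype reconstruction

Reads assigned to each selected allele are realigned to it; a pileup caller
(substitutions only: alternate fraction at least 0.2 at depth at least 4,
within-haplotype consensus at majority fraction 0.5) proposes variants,
phased by greedy two-coloring of read co-occurrence when a single reference
is used. Consensus, segmentation at supplied SV breakpoints, copy-number
estimation, and a spanning-read graph walk produce linear haplotypes; the
loop repeats until no variant is called or `max_iter` is reached, and the
termination reason is recorded. The cycle is the identity map when reads
match the reference and no breakpoints exist, which the tests assert.

Copy numbers divide each segment's depth by the mean over segments and
floor the ratio. Floor is the paper-exact default, but it zeroes any
ordinary segment under uneven coverage, so a documented `"round"` mode
(clamped at zero) is available. The walk orders segment copies to maximize
total spanning-read edge weight: exhaustive multiset enumeration up to 8
total copies (exact, and testable by brute force), a greedy walk with
one-step look-ahead beyond that, reference order breaking ties in both.
Spanning reads must anchor 50 bases on each side of a junction (the
anchor is configurable; no stated value exists). Finally a 20-base window
slides at stride 1 and any window with mean depth below 5 is masked to N;
masked regions are unions of failing windows, so masking never touches a
base outside them.

## Nomenclature

Reconstructed haplotypes are compared against the locus's alleles with the
local aligner; each hit reports mismatches $m$, total gap length $g$, and
mapped length $L$, giving the penalty $\iota = (m + 0.4\,g)/L$. Despite
being named an identity in the field, $\iota$ is a penalty and the minimum
wins; the gap weight 0.4 softens indel-dominated long-read error. Hits
within 2% of the maximal mapped length form the candidate set and all
alleles within $4\times10^{-4}$ of the best penalty are returned as the
ambiguity set. Mapped length is measured on the haplotype (query) side:
block length would count gap columns, letting a gappy alignment to a
divergent allele exceed the exact match's length and evict it from the
candidate set. Truth annotation from phased assemblies mirrors the same
gates with an alignment-ratio filter $\eta \ge 0.95$.

Benchmarking uses the compatible indicator: a haplotype call is correct
when its ambiguity set intersects the truth set, maximized over the two
haplotype pairings, after truncating names to the evaluated field depth.
CYP activity scores map onto poor (0), intermediate (0.5), normal (1--2)
and ultrarapid (>2) metabolizer classes; scores in the gaps between named
classes snap to the nearest class, ties to the lower, and carry an
out-of-table flag because the class table is not exhaustive.

## Population statistics

Allelic diversity uses the plug-in Shannon index plus two bias-aware
estimators: the first-order jackknife over observations, and a
coverage-adjusted (Chao--Shen style) Horvitz--Thompson estimator; the log
base is configurable because conventions differ (natural log default).
Population allele-frequency differences use the Jensen--Shannon distance --
the square root of the divergence, matching the convention of the standard
library routine, natural log by default, hence bounded by $\sqrt{\log 2}$.

The cross-family co-evolution screen filters alleles by mean binary entropy
(0.15 bits), computes Pearson correlations across populations raw and after
regressing out the top five principal components of the frequency matrix
(each allele's cross-population vector against population-level PC scores),
and then stacks robustness filters: a shared permutation null per family
pair (10,000 scrambled pairings), an empirical background null (a simulated
independent-frequency background ships with the package; an external
background distribution can be supplied), population bootstrap support
(1000 resamples; support is the fraction of resamples with a same-sign
nominally significant correlation, threshold 0.8 by the package's choice),
split-sample replication (counts split binomially per population across 100
valid splits -- a split is valid when both halves have nonzero variance for
the pair -- scored by an upper-tail binomial test with chance replication
probability $0.5 \times 0.1$), and Benjamini--Hochberg correction at 0.05.
Bootstrap and replication run only for pairs already past the raw and
PC-adjusted p-value gates, since failing pairs are rejected regardless.
The intra- versus inter-superpopulation distance comparison uses a
Mann--Whitney test (the natural nonparametric choice for unpaired distance
groups). Differential heterozygosity uses per-locus t-tests with Bonferroni
correction at 0.01 and a covariate regression (ordinary least squares on
log depth, read length, mapping quality, basecaller mode) followed by a
t-test on residuals.

The precision network regresses out the top five PCs, standardizes columns,
inverts a Ledoit--Wolf shrinkage covariance (implemented from the
squared-Frobenius oracle formulas; an external scientific-computing
implementation reproduces it to eight decimals in the tests), and prunes
edges by stability selection: 100 resamples of 80% of populations with
replacement, an edge counting when its absolute precision entry exceeds
0.02, retained at stability at least 0.75.

**A calibration caveat worth stating plainly.** The absolute 0.02 precision
cutoff is only selective when the sampling noise of precision entries is
well below it. At 10 alleles and a few hundred populations that noise is
roughly $\sqrt{1/n} \approx 0.07$, so stability selection passes noise
edges almost as often as true ones, and no chain strength avoids it: strong
chains drag spurious edges along, weak chains lose true ones. The tests
therefore demonstrate exact chain recovery at 8000 synthetic populations,
where the noise falls safely under the cutoff, and treat the
small-population regime as what it is: a regime where this cutoff does not
separate signal from noise.

## The synthetic-data generator

The generator emulates the inputs the pipeline consumes. A root sequence is
mutated into per-locus ancestors (at half the inter-locus divergence each,
so locus pairs differ at about the configured 10%) and each ancestor into
alleles (half of 2% by default; a tenth of edits are 1--10 base indels).
Loci sit on a synthetic chromosome 5 kb apart, giving the two-locus binning
rule real geometry. Reads alternate haplotypes to the target per-haplotype
depth (30x default), log-normal lengths capped at the allele, uniform
starts, errors at $1 - 0.90$ with a balanced substitution:insertion:deletion
profile (the study regime states only overall accuracy; a balanced profile
is the neutral choice), and half the reads reverse-complemented. Population
frequency tables are Dirichlet(1) per gene and population. Planted
correlated pairs are driven by a shared latent variable whose weight,
relative to private noise, sets the correlation; the logit amplitude is
kept modest so a planted pair never becomes a principal component of the
matrix, and the latent ratio is rejection-tuned until the correlation
measured on the final renormalized frequencies lands within 0.1 of the
target. Population structure, when enabled, enters as five latent gradients
loaded on every allele -- matching the number of components the screen
removes, since real structure spans several axes -- and multinomial counts
are drawn at 1000 gene copies per population.

What the generator does *not* emulate: platform error HMMs (homopolymer
bias), CDS-only database alleles, structural variation beyond supplied
breakpoints, gene fusions and CNVs, real linkage disequilibrium and
admixture. Passing tests therefore certify the algorithms against their
stated models, not performance on any particular sequencing platform or
cohort.

## Problem sizes and numerical choices

The test and acceptance workloads use 10-locus, 20-allele, 1-kb databases
with 25--50 seeded replicates for genotype recovery, 200-pair nulls for the
correlation screen, and 1000 replicates for entropy bias -- sizes chosen so
the whole suite runs on a laptop-class single core in minutes while keeping
Monte-Carlo error a few percent. Alignment uses an affine-gap local
dynamic program (match +2, mismatch -4, gap open 4, gap extend 2, N never
matches) with a k-mer seeded banded mode (half-width 150) that is
bit-identical to the full program on seeded pairs and falls back to the
full program below 5 seed k-mers. Identity ties anywhere resolve
deterministically (lexicographic order) or by a recorded seed. All
stochastic operations take explicit seeds and restore the caller's RNG
state.

## Known limitations

- Splice-aware alignment of CDS-only database alleles is not implemented;
  such databases should be typed against matching read material.
- The built-in variant caller handles substitutions only; indel variants
  enter haplotypes via external phased VCFs and the consensus machinery.
- One diploid pair per locus: CNV-bearing loci (e.g. hybrid or duplicated
  star alleles) need dedicated upstream tooling.
- The two-locus read rule considers the top two loci only.
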