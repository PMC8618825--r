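---
title: "Methods: synteny-based dating, origin mechanisms and selection tests for new genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synteny-based dating, origin mechanisms and selection tests for new genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

New genes — genes restricted to a particular species or lineage — arise by
DNA-mediated duplication, by retroposition (an mRNA reverse-transcribed and
reinserted, producing an intronless copy of a multi-exon parent), or de
novo from previously non-coding sequence.  Given a focal genome, a set of
progressively more distant relatives on a dated ladder phylogeny, and
whole-genome alignments between them, each focal gene can be dated onto
the branch of the focal lineage on which it originated, and each young
gene can be classified by its origin mechanism and tested for selective
constraint.  `genorig` implements this pipeline end to end and pairs it
with a forward genome-evolution simulator that plants dated birth events,
so that every stage can be verified against known ground truth.

# The ladder and branch ages

A `species_ladder` walks the rooted, dated phylogeny from the root to the
focal tip.  Each of the $B$ splits sheds one clade (single species or
cherry); the $B+1$ age classes are indexed $0..B$, where branch $0$ means
"present in all sampled species" (older than the sampled root) and branch
$B$ is the terminal, focal-specific branch.  The default ladder has eight
taxa and five focal-path splits: the focal species and its sister separate
41.8 Myr ago and the focal lineage's stem (split to the nearest outgroup
cherry) is 73.7 Myr old.  These two ages anchor the emergence-rate
denominators; the remaining node ages (52, 65 and 95 Myr, and cherry ages
30 and 35 Myr) are round values chosen between the anchors, as only the
anchored ages enter any reported rate.  Genes on branches $2..B$
(postdating the stem) are called lineage-specific.

Dating is Dollo parsimony: a gene present in the focal species and a set
of other taxa is assigned to the branch leading to the most recent common
ancestor of its carriers; absence is treated as never-present (no loss
model).  Presence in either member of an off-path cherry counts as
presence in that clade.  Genes with multiple exons or transcripts take the
age of the oldest exon (the minimum branch index over exons), because
partial duplications and exon shuffling can make parts of a gene younger
than the locus.

# Whole-genome alignment and the reciprocal-best net

Homology is detected with a seed-and-extend aligner: exact $k$-mers
($k=12$ by default) are matched between focal and query chromosomes on
both strands, merged along diagonals, extended without gaps under an
x-drop rule (match $+1$, mismatch $-1$, x-drop 20), and chained
colinearly with affine gap costs (open 4, extend 1); chains below score
100 are dropped.  A second chaining pass merges colinear chains on the
same chromosome pair, so that both alignment directions produce
comparable long-range chains regardless of how the first pass fragments.
Presets `near`, `mid` and `far` (shorter seeds, wider x-drop) loosen the
search for more distant query species; the preset boundaries are split
ages of 55 and 75 Myr.  Repeats are soft-masked: excluded from seeding,
available to extension.  `N` bases never count as matches.  Two
robustness choices matter in practice and were set once: a seed
occurrence ceiling of 10 (k-mers more frequent than this, typically
repeat-derived, are not used for seeding) and a minimum extended-segment
score of $2k$ before chaining; both prevent repeat-induced seed bursts
from fragmenting the chromosome-scale chains.

A chain is *reciprocal-best* when it is the best-scoring chain over its
focal interval and the best reverse-direction chain over its query
interval maps back onto the same focal interval with at least 50% mutual
overlap; ties break lexicographically by (score, focal coordinate, query
coordinate), and overlapping flagged chains are pruned greedily so each
focal base is covered at most once.  This netting is what makes dating
synteny-aware: a young duplicate copy aligns perfectly to its parent's
locus in a pre-duplication genome, but that locus's best reverse chain is
the parent's own flanking-context chain, so the copy correctly shows no
reciprocal-best coverage there.

# Presence, filters and rates

An exon is present in a species when at least 50% of its bases are
covered by reciprocal-best chain blocks.  The threshold is a package
choice (configurable, logged in every run); the source analyses of this
kind do not publish their cutoff.  A gene is excluded from dating when
more than 70% (strictly) of its exonic bases overlap annotated repeats —
computed over exons because ages derive from exons — or when it lies on
an unplaced scaffold.  The emergence rate of a branch is its gene count
divided by its duration in Myr, reported to one decimal; proportions are
percentages of stated denominators, also to one decimal.

# Origin mechanisms

Lineage-specific genes are classified with deterministic rules:

* the closest paralog is the best local protein alignment (BLOSUM62,
  affine gaps 11/1) covering at least 30% of the shorter protein with
  score at least 50, ties broken by (score, gene id);
* with a paralog: *retroposition* if the parent has $\ge 2$ CDS exons and
  the child exactly 1, otherwise *DNA-mediated duplication* (partial
  intron loss therefore scores as DNA duplication — the strict rule is
  deterministic and testable);
* without a paralog: *de novo* if at least one pre-origination species
  carries reciprocal-best homologous sequence over the gene's exons
  (coverage above 0.05 but below the presence threshold) with no
  annotated gene at the mapped location; otherwise the gene is reported
  unclassified rather than forced into a class.

# Selection tests

Ka/Ks is estimated under a GY94-style codon model over the 61 sense
codons with uniform codon frequencies, transition/transversion ratio
$\kappa$ and selection parameter $\omega$; with uniform frequencies the
rate matrix is symmetric, so transition probabilities come from a
symmetric eigendecomposition.  The likelihood of a pair of sequences is
maximised over divergence $t \in (10^{-6}, 50]$, $\kappa \in (0.01, 20]$
and (unless fixed) $\omega \in (10^{-4}, 10]$ by a fixed coarse grid
followed by bounded quasi-Newton refinement of $(\kappa, \omega)$ with
$t$ profiled out by golden-section search — fully deterministic.  Ka and
Ks derive from the fitted substitution flux with sites normalised at
$\omega = 1$, so Ka/Ks equals $\hat\omega$ exactly.  Codon alignments are
protein-guided (global BLOSUM62 alignment expanded to codon triplets,
back-translation verified); gap- or stop-containing columns are dropped
(complete deletion), and pairs with fewer than 30 usable codons are
flagged `too_short` instead of tested.

Two fixed-$\omega$ likelihood-ratio tests are used, each with
$2\Delta\ell \sim \chi^2_1$: paralog pairs against $\omega_0 = 0.5$
(constraint on duplicate copies) and de novo genes against
$\omega_0 = 1$ (departure from neutrality), with a verdict of negative
selection requiring both $p < 0.05$ and $\hat\omega < \omega_0$ — the
one-sided reading of the test.  Before testing, paralog pairs with
$K_a > 0.5$ or $K_s > 5$ are excluded, then Ks values outside
$[Q_1 - 1.5\,\mathrm{IQR},\ Q_3 + 1.5\,\mathrm{IQR}]$ of the surviving
Ks distribution (quartiles by linear interpolation, type-7) are excluded
as implausible paralog assignments.  The order — hard thresholds first,
IQR second — is a package decision; the IQR filter is skipped with a
warning below 4 values.  A Nei–Gojobori (1986) pathway-counting
estimator with Jukes–Cantor correction is implemented alongside as an
independent check; the test suite requires rank agreement between the
two estimators.

For a de novo gene, the orthologous ORF in the sister genome is
reconstructed by extending the reciprocal-best homologous interval by
10 kb on each side (truncated at chromosome ends), translating all six
frames, and keeping the longest stop-free stretch of at least 30 codons
whose local alignment to the de novo protein scores at least 50.

# The asymmetric-expression test

Expression evidence is FPKM strictly above 0.5 in at least one tissue,
with replicates averaged per tissue before thresholding; breadth is the
number of tissues above threshold.  Old (branches 0–1) and young
(branches 2–$B$) genes are contrasted on log2 median FPKM (pseudocount
1) with a two-sided Wilcoxon rank-sum test.

Left/right differential expression uses raw counts and a fully specified
negative-binomial Wald test: size factors by median-of-ratios, per-gene
dispersion by method-of-moments on normalized counts pooled within sides
(floored at $10^{-8}$), Wald statistic on the log2 fold change with the
NB variance $\mu + \alpha\mu^2$ propagated by the delta method, referred
to a $t$ distribution with $n_L + n_R - 2$ degrees of freedom.  The
small-sample $t$ reference (rather than the normal) is what brings the
test close to nominal at the triplicate design this assay uses; the
package's calibration tests verify a 5% type-I error within binomial
error on 1000 null genes and $\ge 80\%$ power for 4-fold changes at
$n = 3$ per side.  Because per-gene moment dispersion estimates from six
counts are noisy, a mild residual anticonservatism (a few tenths of a
percent above 5%) can remain on some datasets; the Benjamini–Hochberg
column is reported for stricter control when that matters.
Significance uses the raw $p < 0.05$; a Benjamini–Hochberg column is
reported for transparency but does not drive the flag.

# The simulator: what it emulates and what it does not

`simulate_genomes()` evolves an ancestral genome along the focal path of
the ladder, snapshotting at each split and evolving side lineages
independently to their tips.  Substitutions arrive as a Poisson process
(default $5 \times 10^{-4}$ /site/Myr, chosen so the deepest pairwise
divergence stays near 10% and chromosome-scale alignability is retained);
proposals follow an HKY-like kernel ($\kappa = 2$).  In coding sequence a
proposal is accepted with probability 1 if synonymous and with the gene's
$\omega$ if nonsynonymous; nonsense changes, stop loss and start-codon
loss are rejected, so true ORFs stay intact by construction.  Indels
(geometric lengths, mean 3, capped at 50) are restricted to intergenic
and intronic sequence, and all annotations are remapped after each
branch.  Repeats are interspersed copies of three 400-bp monomers at 5%
density.  All simulated genes lie on the + strand; minus-strand handling
in the I/O and CDS machinery is exercised by hand-built fixtures instead.

Planted events define the ground truth.  DNA duplications copy a parent's
genomic span (introns included) to a new intergenic locus; retropositions
insert the parent's spliced CDS as a new single-exon gene (parents are
restricted to multi-exon ancestral genes so each child has a unique,
unambiguous parent).  De novo births reuse an existing intergenic segment
in place as roughly 40% of the new exon — with in-frame stops edited out —
and add novel sequence (start, tail and stop) around it.  This composite
model reflects how de novo genes typically combine pre-existing and
lineage-specific sequence, and it is also what makes the planted truth
internally consistent: pre-origination species retain detectable
homologous non-coding DNA at the locus (sub-threshold coverage, no
annotated gene, no ORF), while a fully "minimal-edit" de novo gene would
be indistinguishable, under coverage-based presence, from an old gene.
Duplicates receive $\omega = 0.2$ (constrained) or $\omega = 0.8$
(relaxed) with equal probability; de novo genes evolve at $\omega = 1$.

Expression matrices are synthetic: log-normal FPKM baselines
(median ~5 FPKM), a configurable fraction (default 0.3) of planted genes
silent, and negative-binomial counts (dispersion 0.05, log-normal means
around 100) over a 3-tissue x 4-stage x 2-side x 3-replicate design, with
a 4-fold right/left change planted for 10 young genes at one stage/tissue
(pro-metamorphic muscle by default).  No empirical FPKM distribution is
imitated; the generator's role is to give the expression stages a known
signal and a known null, not to mimic any particular RNA-seq study.

The simulator does not model chromosomal rearrangement, gene loss,
recombination, or coding indels (an optional flag allows the latter), so
passing recovery tests demonstrates correctness of the pipeline's logic
under clean colinear evolution — not robustness to assembly error,
annotation error or deep rearrangement, which real genomes add on top.

# Problem sizes and determinism

The reference study conditions are two 1-Mb focal chromosomes, 150
ancestral genes, 37 planted events across branches 2–5, and seven query
genomes; a full pipeline run takes a few minutes on one core.
Calibration studies use 500 null likelihood-ratio replicates of
500-codon pairs and 1200-gene count matrices.  Every stochastic
component draws from the single config seed; alignment, netting, dating,
classification and both test families are deterministic given their
inputs, and rerunning a config reproduces the report byte for byte.

# Known limitations

* Presence is existence-based (reciprocal-best coverage); a positional
  synteny test beyond the netting itself is not applied.
* No gene-loss correction: a gene genuinely lost in an outgroup dates
  too young (inherent to Dollo dating without loss models).
* Codon frequencies are uniform rather than F3x4; a hook exists to
  supply other frequency models, but the likelihood-ratio calibration is
  verified only for the uniform model.
* Old-gene selection summaries are limited to genes that have paralogs;
  the package does not build cross-species ortholog alignments for old
  genes.
* The horizontal-transfer screen and external protein-database rechecks
  of de novo candidates are out of scope; an external homology table can
  veto de novo calls where available.
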