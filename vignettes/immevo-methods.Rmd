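---
title: "Methods: immune-cell transcriptomics and evolutionary divergence"
author: "immevo maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: immune-cell transcriptomics and evolutionary divergence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immevo)
```

# Overview

`immevo` implements, as a reusable and fully tested pipeline, the complete
computational analysis of a fluorescence-sorted immune-cell single-cell
RNA-seq experiment in a teleost fish, together with the cross-vertebrate
evolutionary analysis of the immune-cell-type-specific genes such an
experiment discovers.  The pipeline has six analytical stages — cell quality
control, dissimilarity/embedding/batch-adjustment/clustering, marker-based
cell typing with signature construction, per-cell detection of TCR-beta
V(D)J recombination from short reads, ortholog-conservation statistics, and
paralog neofunctionalization classification — plus a synthetic-data module
that generates every input the pipeline consumes, with planted ground
truth.  Because all inputs can be generated, every stage is exercised
end-to-end by the test suite with no downloads.

# Expression units and quality control

Expression is carried in TPM (transcripts per million; each cell's expressed
genes sum to $10^6$) and analyzed in E units, $E_{ij} = \log_2(\mathrm{TPM}_{ij} + 1)$.
The `ExpressionMatrix` class tags each matrix with its unit, so an
already-transformed matrix cannot be transformed twice.

Cell QC removes cells with fewer than 500 detected genes or fewer than
10,000 reads mapped to transcripts.  Both boundaries are strict
("fewer than"): a cell at exactly 500 genes and 10,000 reads is retained.
A gene counts as detected when its TPM is strictly greater than zero, the
same convention the detection-fraction filters downstream use.

# Embedding and clustering

Cell-to-cell similarity is the Pearson correlation of full E-unit profiles;
$1 - \mathrm{PCC}$ is the dissimilarity.  `classicalMDS()` implements
Torgerson's principal-coordinates analysis directly (double-center the
squared dissimilarities, eigendecompose, scale eigenvectors by the square
roots of nonnegative eigenvalues).  We implement it rather than call
`stats::cmdscale` because the pipeline's contract returns axes with negative
eigenvalues as zero columns, keeping the embedding dimension fixed;
`cmdscale` is used as a cross-check oracle in the tests.  Four leading
coordinates are retained by default: on correlation dissimilarities of this
kind the eigenvalue spectrum decays smoothly beyond the fourth coordinate,
and the count is exposed as a parameter.

Batch (plate/fish) effects are removed by `ebBatchAdjust()`, a parametric
empirical-Bayes location-scale model: per gene, data are standardized by the
grand mean and pooled residual variance; per-batch location and scale
estimates are shrunk toward common priors (normal for locations,
inverse-gamma for scales, hyperparameters by method of moments) and
removed.  Two degenerate regimes are handled explicitly: genes with zero
total variance pass through unchanged, and genes whose within-batch
residual variance is zero (the batch effect is exactly identified) receive
an exact location-only adjustment.  Negative adjusted values can optionally
be clamped to zero for downstream methods that require nonnegative input.
The test suite cross-checks the adjustment against `sva::ComBat` on a noisy
instance.

Clustering is agglomerative with Ward's criterion in its squared-distance
form (`hclust` method `ward.D2`) on the leading coordinates.  The number of
clusters is chosen by maximizing the mean silhouette coefficient over
candidate $k = 2..8$; the silhouette is computed in the same coordinate
space that was clustered, for consistency with the clustering input, and
ties in the argmax go to the smallest $k$.

# Cell typing and differential expression

Cell identities are first assigned from minimal literature marker sets
(T: cd4, cd8a, cd8b, cd28, ctla4; NK-like: the nitr, dicp and nk-lysin
families; myeloid: spi1b).  A set's score in a cell is the mean E over its
genes, and a cell is assigned the identity of the unique set scoring
strictly above 1 — cells where zero or several sets exceed the threshold
stay unassigned.

Differential expression between cell groups uses a two-part dropout-aware
statistic rather than a full Bayesian single-cell error model: per gene, a
detection-rate component (Fisher's exact test on detected/undetected
counts) and an expression component (Wilcoxon rank-sum on E among detecting
cells) are combined as signed z-scores by weighted Stouffer's method,
Holm-adjusted across genes, and mapped back to an adjusted z.  The design
choice here is deliberate: the downstream logic consumes only a log2
fold-change (group means of TPM with pseudocount 1) and an adjusted
z-score, which this statistic supplies with calibrated null behavior (the
suite verifies that no gene clears the thresholds under permuted labels).
Extended signatures are the genes with log2 fold-change strictly above 2
and adjusted z strictly above 3, ordered by fold-change, with genes
qualifying for several types dropped from all.  Signature scores per cell
are set means of E, min-max standardized to $[0,1]$ per signature; when all
raw scores are equal the standardized scores are defined as 0.

Enrichment of a cluster's genes in a mammalian signature is a two-sided
Fisher exact test on orthologs-in-signature counts, DE genes versus
non-DE background.  Side-scatter comparisons report the percent difference
of group medians and a Wilcoxon rank-sum p (exact up to group size 20
without ties, else normal approximation with tie correction).

# TCR-beta V(D)J detection

The detector follows a recruit-assemble-annotate-filter design.  A
synthetic recombinant reference enumerates all V$\times$J combinations,
padded with 20 N (unknown leader), 7 N (possible D segment plus
non-templated junction) and 50 N (constant region); with the full 52 V and
33 J segment sets this yields 1716 entries.  Because the N pads carry no
sequence information, read recruitment reduces to sharing an exact k-mer
(default $k = 25$, either strand, either mate) with a germline V or J
sequence; the suite verifies the recruited set equals a permissive local
alignment screen on clean reads.

Recruited reads are assembled by a deterministic greedy
overlap-layout-consensus: repeatedly merge the pair with the longest exact
suffix-prefix overlap of at least 31 bases over three orientation
combinations (flipping both sequences is the swapped pair's forward case),
absorbing contained sequences, breaking ties lexicographically, and
discarding contigs supported by fewer than 2 reads.  Exact-overlap assembly
is brittle to substitution errors, so detection wraps it in two consensus
steps: reads carrying k-mers seen fewer than 3 times in the recruited pool
are dropped before assembly (at the ~50 read-pair depth used here true
15-mers are seen tens of times, error 15-mers near-once; the filter
disables itself below 5 reads), and assembled contigs are polished by
anchoring the pool back onto them by modal k-mer offset and taking a
per-position majority vote, with one re-merge pass for polished fragments.

Contigs are annotated by Smith-Waterman local alignment (match $+1$,
mismatch $-2$; affine gaps costing $4 + L$ for a gap of length $L$) against
every germline segment on both strands; the best V and best J hits carry
percent identity over aligned columns, the fraction of the germline segment
recovered, and contig-side coverage.  Coverage is per hit over the hit's
eligible span: from the contig start to the V hit's end for V, and from the
J hit's start to the contig end for J — unexplained sequence on the side a
segment should occupy lowers its coverage, while the junction between the
hits penalizes neither.  A call passes when both hits are present and
unambiguous (no rival segment within 5% of the top score) on one strand,
identity $\ge 90\%$, recovery $\ge 90\%$, coverage $\ge 90\%$, and the
contig has no stop codon in the reading frame defined by the V segment's
frame offset from the V hit through the J hit.  Junction frameshifts that
push downstream J codons out of frame therefore fail the stop-codon rule,
which is the intended conservative behavior.

# Conservation statistics

Mammalian cell-type signatures are derived from bulk/microarray expression:
genes are prefiltered by maximal group-mean expression (5 for mouse-style
data, 8 for human-style), each merged group (CD4 + CD8 $\to$ T,
monocyte + granulocyte $\to$ myeloid) is tested against the rest with an
empirical-Bayes moderated t-statistic — per-gene pooled variances shrunk
toward a prior whose scale and degrees of freedom come from method of
moments on the log variances (trigamma inversion) — and the top 100 genes
at BH-adjusted $p < 0.01$, ordered by fold-change, form each signature,
with genes in several top lists removed from all.  The moderated t is
implemented in the package (the limit of zero prior degrees of freedom
reproduces the ordinary pooled t-test exactly, and the suite checks
agreement of the selected gene sets with an independent reference fit).

Ortholog-conservation differences between gene sets are tested per species
by permutation: the statistic is the difference in ortholog proportions,
the null permutes set-membership labels over the pooled genes 10,000 times,
and the two-sided p uses the add-one estimator
$(1 + \#\{|\mathrm{null}| \ge |\mathrm{obs}|\})/(1 + n_\mathrm{perm})$,
which can never be zero (a saturated result reports $1/10001$).  Cross-set
consistency across species uses the paired Wilcoxon signed-rank test (exact
up to 15 informative species).  Sequence-identity and dN/dS comparisons use
two-sided Wilcoxon rank-sum tests on conserved genes, with genes lacking a
value excluded and counted.  Genes with multiple orthologs carry their
average identity.  A receptor-family exclusion list is exposed for
sensitivity analyses.

For the fish-side analysis, each cluster's gene set is the top 100 DE genes
after filtering at z strictly above 1 and sorting by fold-change (ties by
gene id); the expression-matched background is the non-DE genes whose mean
E is at least the global mean of per-gene mean expression, recomputed on
the input (the corresponding value on the original study's data was 0.46) —
this removes the conservation bias of lowly expressed genes.

# Paralog neofunctionalization

Paralog pairs are stamped recent (duplication node at Actinopterygii or a
child: Neopterygii, Otophysa, Clupeocephala, Danio rerio) or early
(Euteleostomi or a parent: Vertebrata, Chordata, Bilateria); genes
appearing in both classes are excluded from both before class comparisons.
Genes are labelled by a strict precedence — cluster-specific (top-100 DE),
cluster-depleted (top-100 of the reversed two-versus-one contrast),
ubiquitous (detected in at least 10% of each cluster's cells), none.  Pairs
with an uninformative gene are excluded from the rate and counted; pairs of
two ubiquitous genes are excluded; a ubiquitous gene paired with an
informative one is kept (as diverged) only when the informative gene is
specific to or depleted from one of the two major clusters.  The
neofunctionalization rate is diverged/(diverged + conserved), overall and
per age class.  Within the depleted precedence level, a gene in several
depleted lists takes the first cluster in order; the suite checks the
labelling is order-independent.

# The synthetic-data module

The generator emulates the statistical structure the analysis assumes, not
any particular dataset.  Counts are negative-binomial (size 2) around
population-specific mean profiles; 30 marker genes per population are
boosted 32-fold in their own population and scaled to 0.1% of baseline
elsewhere, reflecting lineage-restricted expression; TPM derives from
counts and fixed per-gene effective lengths, so RSEM-style quantification
is emulated rather than reproduced.  Default conditions: 300 cells in
proportions 0.65/0.31/0.04 (apportioned by largest remainder, ties to the
earlier population), 2,000 genes, two balanced batches with a per-gene
log2-normal batch factor (SD 0.4), per-cell mapped reads log-normal with
mean 800,000 and SD 300,000 (matching a median near 0.65 million), and
logistic dropout in mean log2 expression (midpoint 6, slope 1), which
leaves roughly 1,400 of 2,000 genes detected per cell.  SSC values are
normal around per-type locations 100/125/180 so the NK-like population
runs about 25% above the T population.  Side conditions the generator
guarantees: TPM columns re-normalize to $10^6$ after dropout; every T cell
carries exactly one recombined TCR-beta transcript.

Synthetic germline segments are random sequences free of stop codons in
every reading frame, mutually below 90% global identity so annotation is
unambiguous; every J begins with "CC" so codons spanning a segment boundary
can never form a stop.  Junction lengths are uniform on 0-10; junction
bases are uniform conditional on the recombinant being stop-free in the V
frame (resampled, with an all-C fallback), so planted recombinants can pass
the no-stop filter while the length law stays exactly uniform.  Annotation
tables plant per-species ortholog presence as Bernoulli draws and
identity/dN-dS as truncated normals; paralog tables plant divergence with a
configurable probability per age class.

What passing on these data does and does not show: the generator produces
well-separated populations, homogeneous within-type profiles, and
substitution-only read errors.  Real data add contamination, doublets,
continuous cell states, indels, and alignment artifacts the pipeline does
not model; results on synthetic data certify the implementation, not
biological robustness.

# Numerical choices and problem sizes

All tolerances used in the tests derive from the quantity checked: exact
enumeration oracles at $10^{-10}$, linear-algebra round trips at $10^{-8}$,
binomial recovery bands at three standard deviations of the planted rate.
Randomness always flows through explicit seeds; generators restore the
caller's RNG state.  The test suite and the acceptance script run the full
clustering condition at its defaults (300 cells, 2,000 genes) and scale the
V(D)J condition to 30 positive plus 30 negative cells with 50 recombinant
read pairs each at 1% error, the permutation-calibration condition to 500
replicates of 200 permutations, and the paralog condition to the 37-recent
/ 129-early pair sizes — sizes chosen so each statistical check retains its
planned power while the whole suite stays interactive.

# Known limitations

The DE statistic is a calibrated replacement, not a reimplementation, of a
Bayesian single-cell error model; randomization-count parameters of such
models have no analogue here.  The assembler is a desk-scale greedy OLC
with consensus, adequate for single-transcript-scale assembly only.  D
segments are not modelled separately (the junction pad absorbs them), and
alpha/gamma/delta loci are out of scope.  The batch adjuster implements
the parametric variant only.  The pipeline consumes gene-by-cell matrices;
read trimming and transcript quantification live upstream of its scope.
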