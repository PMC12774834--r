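---
title: "Methods: relatedness on ancestral recombination graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: relatedness on ancestral recombination graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's account of the models it implements, the
choices that were genuinely open, and what its simulation-based tests do
and do not establish.

## Data model

A tree sequence is three tables. Nodes carry a time in generations before
present; edges record that a child node inherited `[left, right)` from a
parent node; sites place derived mutations on nodes at positions.
Coordinates are 0-based, half-open and real-valued; breakpoints are the
distinct edge endpoints. Two sorted edge indexes — insertion order
`(left, parent time ascending, parent id, child id)` and removal order
`(right, parent time descending, parent id, child id)` — make
left-to-right tree building deterministic: ties are broken by ids, so a
shuffled edge table on disk yields an identical tree stream. Multiple
roots per local tree are permitted (a gene-dropped ARG before
recapitation has one root lineage per founder genome), and an isolated
node is its own root with zero branch length above.

MRCA queries use an Euler tour with a sparse-table range-minimum
structure, built once per local tree (`O(N log N)`) and cached, giving
constant-time queries; any backend at or below `O(log N)` per query would
serve. The dense divergence matrix deliberately uses the plain
tree-by-tree, all-pairs algorithm — its MRCA-query count, exposed as a
diagnostic, is the package's measurable surrogate for the
`O(n_trees n²)` complexity of dense construction.

## Relatedness definitions and identities

All relatedness modes are trait covariances under an additive model with
zero-mean effects: per-locus effects of variance σ² for genotype
relatedness, per-branch effects of variance σ² × area for branch
relatedness. Only the first two moments matter, which the test suite
demonstrates by re-running the recoveries with a two-point ±σ law.
Branch effects are drawn per branch *per local tree* (variance
`length × span × σ²`), not per edge: a sample's descent from an edge may
change along the edge's interval, and the per-tree granularity is what
makes the empirical covariance equal the shared-area matrix exactly.

The identities asserted in tests, each by at least two independent code
paths, are: uncentered branch GRM = shared-area matrix; centered branch
GRM = `−PDP/2` = `PAP`; per-tree root-path relation
`d(i,r) + d(j,r) = 2b(i,j) + d(i,j)`; `E[C] = μB` under infinite-sites
mutation; and the allele-match form of the genotype GRM. The eGRM
standardizes each branch by `S̄(1−S̄)` where `S̄` counts descendant
*sample nodes* (the node-versus-individual choice is not forced by
anything upstream; node counting is used, and the diploid question is
deferred to the ploidy collapse below). Branches with `S̄` of 0 or 1 are
skipped: they carry no variance in any realized genotype, and their
standardization is undefined. The total-area normalizer still includes
them, since it measures mutational opportunity, not realized variance.

Diploid (individual-level) matrices average each pair's 2×2 block of
genome copies, the dosage-*proportion* convention; relative to allele
counts this introduces the familiar factor of four. Centering and the
block average commute when every individual has exactly two genomes, so
the individual-level matrix-free product can center at node level.

`mean_tmrca()` requires contemporaneous nodes and weights each pair by
the genomic span on which both nodes carry recorded lineages. For
samples of a fully coalesced ARG that is the whole genome and the value
equals half the mean pairwise divergence; for pedigree founders it
restricts to the intervals where their material is ancestral to the
probands, which is the natural estimator given that an ARG does not
record non-ancestral genealogy.

## The matrix-free product

The sweep maintains, per node, the subtree weight `w(n)`, an accumulated
value `v(n)`, and the last-update position `x(n)`; the pending
contribution of the branch above `n` over `(x(n), pos]` is
`z(n) = l(n)(pos − x(n)) w(n)`. Each edge removal flushes the removed
edge's own branch into its child, then walks from the edge's parent to
the current root flushing `z`, decrementing weights and accumulating the
path's values into the child; insertion mirrors this with opposite
signs, pre-subtracting the path's accumulated values so the child never
double-counts history from before it attached. Within a breakpoint the
index orders matter: insertions proceed parent-time-ascending, so during
the initial tree build every upward walk has length one, and the final
breakpoint's removals proceed parent-time-descending, so tearing the
last tree down flushes every pending value to the samples in linear
time. That final teardown *is* the algorithm's termination step: the end
of the genome is treated as an ordinary breakpoint that removes all
remaining edges.

Centering wraps the uncentered core as `P∘B∘P`; nothing in the sweep
changes. Samples must be leaves in every tree — the bookkeeping for
ancestral samples is not defined here and such inputs are rejected.
Accumulation is naive floating point; the advertised agreement with the
dense route is 1e−8 relative, though in practice it sits near machine
precision. A debug mode asserts after every transition that root weights
sum to the input total.

The per-node update count is the complexity surrogate: the suite fits
the constant in `updates ≤ c (n + n_trees log₂ n)` at n of 64 and 128
and asserts the bound with slack factor 2 at n of 1024 and 4096.

## Randomized PCA

Range estimation uses `k + oversample` Gaussian probes with QR
re-orthonormalization after each of `q` power iterations, then an exact
SVD of the projected operator; symmetry of the GRM means the small
matrix is just the transpose of the probed product, so no transpose
machinery exists. Defaults are oversample 10 and q 3: oversampling
strictly improves the range estimate at the cost of a few extra operator
applications, and q 3 is ample for the sharply decaying spectra of
relatedness matrices; oversample 0 reproduces the bare algorithm. Each
component's largest-magnitude entry is made positive so results are
seed-stable. Components of a centered operator have zero loading on the
constant vector automatically. Multi-chromosome analyses sum
per-chromosome operators (`sum_operator()`), which requires consistent
sample indexing across chromosomes; indexing is by sample id.

Coordinate remapping (`remap_coordinates()`) applies a strictly
increasing piecewise-linear position map to every edge endpoint and
site, shifting the origin to zero; topologies are untouched, so
area-based relatedness afterwards weighs regions by genetic rather than
physical distance.

## Simulators: what they emulate, and what they do not

The coalescent simulator is a Hudson-style single-population,
constant-size model: pairwise coalescence at `1/(2Ne)` per generation
(so E[pairwise TMRCA] = 2Ne), recombination proportional to tracked
ancestral material, fully coalesced segments dropped. It produces valid,
single-rooted tree sequences with realistic tree-sharing structure, but
no demography, selection, gene conversion or migration — so passing
tests show the algorithms are correct on ARGs of this character, not
that any biological conclusion transfers to structured populations.

Pedigrees are monogamous within regions with Poisson offspring counts
and optional migration; gene dropping transmits two genomes per
individual with crossovers at 0.01 per cM (genome coordinates are cM so
the crossover process is homogeneous; conversion to physical distance is
the remap in reverse) and a fair-coin starting haplotype. Per-meiosis
RNG streams are derived from the call seed, so a transmission is
reproducible regardless of evaluation order; the coalescent and
mutation simulators instead use one stream per call — still
deterministic given the seed, but not invariant under internal
reordering. Gene-dropped ARGs are simplified to proband ancestry:
non-ancestral material is removed, interior unary nodes are erased, and
founder genomes are kept as roots so recapitation can continue from
them. Recapitation is a recombination-free coalescent continuation by
default (an optional rate lets ancestral lineages recombine, as standard
recapitation tools do, but the experiments below keep the default — see
limitations). Mutations are infinite-sites: Poisson in edge area,
uniform positions, no back mutation, biallelic only.

## Study conditions and problem sizes

Monte Carlo recoveries use batched replicates (100 batches) for
standard errors and ±4 SE acceptance windows, wide enough that false
failures are negligible for single comparisons; where a whole matrix of
estimates is checked at once the 4 SE band is the simultaneous check and
named canonical quantities are held to 3 SE individually. Trait
recoveries use 50,000 effect draws; the mutation-duality check uses
1,000 mutation realizations at a rate sized for ~500 segregating sites.
Product-versus-dense validation runs 200 random ARGs up to 32 samples;
PCA accuracy is checked at 200 samples against a dense
eigendecomposition and full-rank reconstruction at 40.

The pedigree-to-branch prediction experiment uses a 6-generation
pedigree from 32 founders with Poisson(2.2) offspring, 20 gene-dropped
50 cM chromosomes recapitated at Ne = 1000. The founder count was chosen
so background kinship among probands is small: the prediction
`B ≈ θT` ignores the background terms, and in small founder pools they
visibly depress the fitted slope — a property of the condition, not an
implementation artifact. The slope of summed per-cM branch relatedness
on kinship (pairs with θ ≥ 1/16, where the approximation is meant to
hold) is compared with the founder mean TMRCA at 15%; the dispersion of
K-chromosome averages around the 20-chromosome mean is compared across
K = 1 and K = 5 with the √K-shrinkage prediction corrected for the
shared overall mean, i.e. an expected ratio of
√((1 − 1/20)/(1/5 − 1/20)) ≈ 2.52.

## Numerical choices and degenerate inputs

Symmetry is maintained by construction; PSD checks allow eigenvalues
down to −1e−9 of the trace. The `−PDP/2` versus `PAP` cross-check runs
inside `branch_grm_dense()` at 1e−9 relative and refuses to return on
disagreement. Validation reports every violation (`"time order"`,
`"edge overlap"`, `"bad interval"`, site ordering) rather than the
first. Zero-span trees cannot arise (breakpoints are distinct);
zero-length branches are rejected by the parent-older-than-child
invariant. Monomorphic genotype columns contribute exactly zero after
centering; an empty locus set is an error, not a zero matrix. In the
kinship recursion a missing parent is a unique anonymous founder,
founders are non-inbred and mutually unrelated, and selfing
(father = mother) is allowed.

## Limitations

Everything here is exact-arithmetic-validated on simulated ARGs of
moderate size; no ARG inference, no real data, and no claims about
structured or selected populations. Recapitation without recombination
makes all local trees of one chromosome share a single upper genealogy,
which inflates between-chromosome variance of deep statistics (founder
TMRCA especially) relative to a recombining continuation; the
prediction experiment absorbs this by averaging 20 chromosomes and by
measuring T from the same simulated ARGs. The eGRM's node-level `S̄`
convention, the dosage-proportion diploid convention, and the α = 0
weighting are fixed choices; alternatives would need new code paths.
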