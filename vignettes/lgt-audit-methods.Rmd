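---
title: "Auditing composition- and phylogeny-based LGT detection: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing composition- and phylogeny-based LGT detection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lgtaudit)
```

# The problem

Lateral gene transfer (LGT) — the movement of a gene between species rather
than by vertical descent — is usually inferred from one of two signals: a
gene whose *composition* (GC content, codon usage) deviates from the rest of
its genome, or a gene whose *tree* disagrees with the species tree.  Both
signals are noisy in eukaryotic genomes, and the automated detectors built
on them are rarely validated against data where the true transfers are
known.  `lgtaudit` implements both detector families together with a
deterministic synthetic-data generator that plants LGT events with full
ground truth, so that every detector can be scored — sensitivity,
specificity, and calibration — under controlled conditions.

The package is organized as the audit pipeline itself runs:

1. **Synthetic data** — species tree, discordant gene trees, per-species
   coding sequences, planted transfers, noisy similarity-hit tables.
2. **Composition** — per-gene GC, GC3, CAI, ENC and tetranucleotide
   frequencies; tail-outlier flagging; tetranucleotide feature selection.
3. **Population comparison** — distribution overlap between species and
   unsupervised clustering (mean shift, DBSCAN) of the feature matrix.
4. **Orthology** — reciprocal best hit (RBBH) calling from 12-column
   tabular hit files.
5. **Tree comparison** — support filtering, polytomy resolution, normalized
   Robinson–Foulds (RF) distance, bipartition frequencies, supertree
   bootstrap, and a leaf-shuffle null.
6. **Constrained-topology likelihood test** — AIC comparison of a gene's
   own topology against the species-tree topology.
7. **DTL reconciliation** — parsimony duplication–transfer–loss mapping
   with a transfer-cost sweep.

# The synthetic-data generator

The generator defines the study conditions; all downstream acceptance
checks are run against it.

**Species tree.** A Yule (pure-birth) tree with `nSpecies` tips, unit birth
rate, and positive branch lengths in expected substitutions per site after
scaling.

**Gene trees.** Each gene starts from the species tree and receives a fixed
number of random subtree-prune-and-regraft (SPR) moves — a single tunable
knob that produces the whole spectrum of gene-tree/species-tree discordance
observed in real data.  Internal nodes carry bootstrap-style supports
(Gaussian noise around a configurable mean, truncated to [0, 100]).  No
coalescent process is modeled: the generator reproduces the *pattern* of
discordance, not its population-genetic cause, so passing tests say nothing
about incomplete lineage sorting.

**Coding sequences.** Codons are resampled from a per-species usage table.
Three knobs control realism:

* `gc3Target` — an exponential tilt on third-position G+C is solved
  numerically (by 1-D root finding on the tilt parameter) so the expected
  GC3 equals the target; infeasible targets (e.g. below the floor imposed
  by Met/Trp codons) raise an explicit error.
* `biasStrength` — softmax concentration of each amino-acid family's usage
  on one preferred codon.  `preferred` may be shared between species to
  emulate the conserved codon preferences of close relatives.
* per-gene heterogeneity — each gene jitters its GC3 target (sd 0.04) and
  scales its bias log-normally (sdlog 0.5 by default).  Without this, every
  gene would share one codon distribution and the within-genome CAI/ENC
  spread would be far narrower than any real genome's; the wide metric
  distributions are precisely what makes composition-based LGT detection
  hard, so the generator reproduces them.

Every gene starts with ATG, ends with a stop codon, and contains no
internal in-frame stop (interior codons are drawn from sense codons only).
Sequence randomization (`randomizeSequence`) keeps the first and last codon
and replaces the interior with uniform i.i.d. nucleotides — the "random
ORF" null used in the composition audit.

**Planted transfers.** `plantLgt` replaces the recipient's coding sequence
with the donor's ortholog (`sequence_swap`), re-grafts the recipient leaf
as the donor's sister in that gene's tree (`leaf_regraft`), or both (the
default, since the two modes feed different detector families).  The
re-grafted placement is marked fully supported.  One truth record per event
is returned and threaded through the pipeline.

**Hit tables.** True ortholog pairs appear as mutual best hits with
E-values far below the 1e-5 threshold.  Noise is strictly one-way: a decoy
hit can steal a query's best hit (losing the pair) and weak above-threshold
hits exercise the filter, but no perturbation can fabricate a reciprocal
pair, so RBBH false positives are structurally impossible in the generator
— tests of false-positive behavior therefore use hand-built decoys instead.

**Determinism.** Every generator draws from a named substream derived from
the single master seed (`substreamSeed`), so adding or reordering
generators never perturbs the others, and identical configuration plus seed
reproduces byte-identical FASTA/Newick/TSV output (the run manifest digests
make this checkable).

# Composition metrics

GC and GC3 are plain base fractions (ambiguity codes excluded from both
numerator and denominator; GC3 reads every third base).

**CAI** follows the classic relative-adaptiveness construction: the
reference usage table counts the 61 sense codons, zero counts receive a
pseudo-count of 0.5 (so log weights stay finite), `w = n / max(n)` within
each synonymous family, and a gene's CAI is the geometric mean of `w` over
its codons, excluding stop codons and the single-codon families (Met, Trp).
A gene with no countable codon returns 1 by convention.  The default
reference is the pooled usage of the gene set itself — self-contained and
reproducible; a highly-expressed reference set can be supplied instead.

**ENC** is Wright's statistic `2 + 9/F2 + 1/F3 + 5/F4 + 3/F6`, with family
homozygosity `F = (n * sum(p^2) - 1) / (n - 1)`.  Families observed fewer
than twice or with non-positive homozygosity are skipped; an empty
degeneracy class borrows the mean of the observed classes; the six-fold
families (Leu, Ser, Arg) are kept whole; the result is clamped at 61.  The
two analytic anchors — 61 for uniform synonymous usage, 20 for one codon
per amino acid — are exact and tested.

**Tetranucleotides** are overlapping 4-mers counted on the coding strand
only (genes, not genomic windows, are the unit; windows containing
ambiguity codes are dropped), normalized to sum 1.  Feature selection
offers the k lowest-variance 4-mers and the k largest standardized mean
differences between two gene sets (ties lexicographic, so selection is
deterministic).

**Tail flagging** is rank-based: `floor(alpha * n)` genes per tail
(default alpha 0.025), ties broken by gene id; if the two empirical
quantiles coincide (no spread) nothing is flagged.

# Distribution overlap and clustering

**Overlap** is histogram intersection on a shared grid: both samples are
binned on the pooled range with Freedman–Diaconis widths and the overlap is
`100 * sum(min(f_a, f_b))` over within-sample proportions.  This estimator
is symmetric, exactly 100 on identical samples, 0 on disjoint supports, and
within 1.5 points of the analytic Gaussian value `200 * pnorm(-1/2)` for
unit-shifted normals at n = 50,000.  Published overlap tables of this kind rarely
state their estimator or binning, so numerical agreement with any
particular study is not expected; the estimator is validated against the Gaussian
closed form instead.  The overlap table mirrors the conventional layout
(one row per comparison set, a final per-column median, random-sequence
rows excluded from the median).

**Clustering.** The feature matrix binds the four scalar metrics with the
tetranucleotide block.  Each column is z-scored; the tetranucleotide block
is additionally down-weighted by `1/sqrt(256)` so the whole signature
carries the weight of one feature group.  Plain per-column z-scoring gives
256 noise-dominated dimensions the combined weight of 64 metrics, which
both drowns any real structure and — at desk-scale sample sizes — makes
flat-kernel mean shift fragment into meaningless satellite modes.

Mean shift uses the flat kernel with the standard automatic bandwidth (mean
distance to the `ceiling(0.3 n)`-th neighbor), converges every point,
merges modes within one bandwidth (denser windows win), and assigns points
to the nearest surviving mode — the same procedure as the reference
implementation in scikit-learn, which it matches cluster-for-cluster on
identical inputs.  DBSCAN is the textbook algorithm (core points by
`minSamples` within `eps`, label -1 for noise); `suggestDensityEps` offers
a k-distance-curve quantile as an automatic radius.

A sample-size caveat worth stating plainly: on samples of a few hundred
points, flat-kernel mean shift with the automatic bandwidth produces a
satellite mode of 1–4 points in roughly one run in ten — an intrinsic
property of the estimator (reproduced exactly by the reference
implementation), not an artifact of this package.  The "all genes in one
cluster" outcome is therefore the modal but not the universal result at
desk scale; at genome scale (thousands of genes) the satellites vanish.
The acceptance suite records this honestly: the density-based method meets
the 95% single-cluster reproduction bar, the mode-seeking method sits a few
points below it.

# Orthology

Best hits are taken per query after collapsing multiple HSPs per
query–subject pair, with the inclusive threshold E <= 1e-5, ties broken by
higher bitscore then lexicographic subject id (tie handling is rarely
specified in practice; this rule makes the call deterministic).  A pair
is an ortholog iff it is the best hit in both directions.  Groups are
anchored on a reference species, one row per reference gene, flagged when
fewer than four species are present (too small for tree tests).

# Tree comparison

Supports below 75 (inclusive retention at exactly 75) are contracted into
polytomies; trees without support values are rejected rather than silently
passed.  Polytomies are resolved deterministically — children sorted by
smallest descendant label, zero-length branches — with a seeded random mode
for sensitivity checks, since automatic resolution
orders differ between toolkits.

Normalized RF prunes both trees to their shared leaves, takes the
symmetric difference of non-trivial bipartition sets, and divides by the
total number of non-trivial bipartitions in both pruned trees — a maximum
that remains correct when collapsing has left polytomies.  RFn is 0 iff
the topologies agree and 1 at maximal disagreement.  Bipartition
frequencies report, for every internal species-tree split, the percentage
of gene trees containing a compatible identical split after restriction to
shared leaves (splits that become trivial count as present).

The supertree stand-in is a majority-rule consensus; the bootstrap
procedure resamples the gene-tree population with replacement (500
replicates by default), rebuilds the consensus per replicate, and scores
each branch by the percentage of replicate supertrees containing it.  The
leaf-shuffle null permutes each gene tree's labels (shape and branch
lengths intact) and records RFn to the species tree, giving the
distribution expected from tree shape alone.

# The constrained-topology likelihood test

The likelihood engine is Felsenstein pruning under JC69 or HKY85 (nucleotide
models; real pipelines often use protein models, but the comparison
logic is model-agnostic and nucleotide models admit closed-form checks).
Rate matrices are scaled to one expected substitution per site; site
patterns are compressed; per-node rescaling guards against underflow; `N`
is full ambiguity.  The engine agrees with an exhaustive sum over internal
states to 1e-9 per site and is invariant to re-rooting.

Branch lengths are optimized coordinate-wise (Brent's bounded univariate
search on [1e-8, 10], kappa on a log scale for HKY85), sweeping in fixed
postorder until the log-likelihood improves by less than 1e-6 or 50 sweeps.
A proposal is only accepted if it does not decrease the log-likelihood, so
the trace is monotone by construction.  Least-squares starting lengths from
JC distances cut the sweep count substantially.

`constrainedTest` fits the gene's own topology and the pruned species
topology on the same alignment and compares `AIC = 2k - 2 lnL`; with both
topologies binary on the same taxa the branch counts cancel and the AIC
difference is twice the log-likelihood gap.  The verdict threshold
(`deltaAic > 10`, the conventional strong-support bound) is configurable;
the number of internal branches — a natural notion of the
comparison's degrees of freedom — is reported alongside rather than turned
into a p-value, since no defensible recipe for one exists.

`powerExperiment` re-estimates the unconstrained topology from the
alignment by neighbor joining (emulating a real pipeline, and making the
congruent scenario a genuine type-I test).  Two findings are worth
flagging.  First, the test is well calibrated: on congruent data the
false-positive rate stays within the nominal 5%.  Second, on clean
synthetic data its power against deep-donor planted transfers is *high*
(around 80–97% at 300–500 sites) and collapses to the type-I rate only as
branch lengths vanish.  Low power observed on real genomic data is
therefore attributable to data quality — gene-model errors, alignment
noise, gene-tree estimation variance — rather than to the likelihood
comparison itself, which is exactly the data-quality point the audit is
designed to make.

# DTL reconciliation

`reconcile` computes the most parsimonious duplication–transfer–loss
mapping of a rooted binary gene tree into a rooted binary species tree
under the undated model (a transfer may land on any branch incomparable to
the donor position; no time consistency is enforced, matching the cited
parsimony tools' default mode).  The dynamic program tabulates, per gene
node and species node: the exact-mapping cost (speciation, duplication, or
transfer), an enter-subtree table charging one loss per skipped species
edge, and the minimum exact cost over each incomparable region for transfer
landings.  Default costs are duplication 2, transfer 3, loss 1;
`transfer = Inf` reduces the optimum to classic duplication–loss.  The DP
equals exhaustive enumeration over all node mappings on 500 random small
instances.

Backtracking reports one optimal scenario with deterministic tie-breaking
that prefers speciation over duplication over transfer, then the lowest
species-node index — the most conservative composition, which also makes
the transfer-cost sweep provably non-increasing: once a zero-transfer
scenario is optimal at some cost it stays optimal (and preferred) at every
higher cost.  `costSweep` reports the fraction of gene trees whose optimal
scenario contains at least one transfer across transfer costs 3–30,
reproducing the characteristic inverse-like decay: near 1 at the default
cost for discordant tree sets, far lower at ten times that cost.

# The pipeline and its outputs

`runAudit` executes the stages in dependency order from a flat key–value
configuration (every conventional threshold — E <= 1e-5, support >= 75,
2.5% tails, delta-AIC 10, transfer costs 3–30 — is a named key), writes
plain-text outputs only (FASTA wrapped at 60 columns, Newick with supports
as internal labels, TSV tables), and emits a JSON manifest with per-file
MD5 digests, the configuration hash, seed, and stage order — no
timestamps, so identical runs are byte-identical.  `resume = TRUE` reloads
stages whose outputs exist and recomputes only downstream ones.
`evaluateAgainstTruth` scores each detector family (composition tails,
clustering minorities, AIC verdicts, DTL transfer calls) against the
planted truth as TP/FP/FN with precision and recall.

The demo configuration is 8 species, 200 orthologous genes per species
(300 +- 50 codons, species GC3 targets spread over 0.45–0.60, bias 1.0),
one SPR move per gene tree, supports 95 +- 8, ten planted transfers from
the most distant species into the reference, 10% hit-table noise, 500-site
alignments for twelve AIC-tested genes, and a transfer-cost grid of
3, 6, ..., 30.  It runs in about a minute.

# Problem sizes and numerical choices

The test and acceptance workloads use: 8-leaf trees for RF oracle checks
(200 random pairs), 4–5-leaf instances for the exhaustive DTL and
likelihood oracles (500 and 5 instances), 200 congruent replicates at 1000
sites on 6-taxon trees for AIC calibration, 50 seeded two-species runs of
100 genes each for the clustering regime, and n = 50,000 per sample for
the Gaussian overlap anchor.  Branch-length bounds are [1e-8, 10];
optimizer tolerance 1e-5 per branch and 1e-6 on the log-likelihood;
histogram grids cap at 10,000 bins; ENC is clamped at 61; tetranucleotide
rows must sum to 1 within 1e-9.

# Known limitations

* The generator has no indels, introns, rate heterogeneity across lineages,
  coalescent discordance, or genome context (isochores, repeats), so
  composition detectors face a cleaner problem here than on real genomes.
* Orthology noise cannot create reciprocal false positives by construction;
  RBBH specificity against decoys is exercised with hand-built tables.
* The supertree is a majority-rule consensus, not an SPR-distance
  optimizer; only the resample-and-score bootstrap-support procedure is
  reproduced exactly.
* Likelihoods are nucleotide-based (JC69/HKY85); no protein models, no
  partitioned or codon models, no topology search.
* `reconcile` reports one deterministic optimal scenario; co-optimal
  scenarios with different event compositions are not enumerated, so
  "contains a transfer" means "the conservative optimum contains one".
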