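---
title: "Methods: gene-family dynamics at the origin of hyphal multicellularity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-family dynamics at the origin of hyphal multicellularity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hyphaevol)
```

# The scientific problem

Fungal hyphae — tubular, apically extending cells — are the structural basis
of fungal multicellularity. Comparative genomics can ask two questions about
their origin: *when* on the species phylogeny the hyphal growth form arose,
and *which gene families* changed in ways that track that origin. `hyphaevol`
implements both halves as a reusable, fully tested pipeline that operates on
a rooted species tree, a gene-family membership table, per-family gene trees
with branch supports, a binary trait coding of extant species, and (for
gene-architecture contrasts) GFF3 annotations and protein domain tables.

The organizing concept is a set of user-designated **origin nodes** on the
species tree (in fungi, the three successive splits of Blastocladiomycota,
Chytridiomycota and Zoopagomycota, often called the BCZ nodes). Every branch
of the species tree is classified relative to those nodes — `PRE_ORIGIN`
(rootward of the origin region), `ORIGIN`, `POST_ORIGIN`, `TERMINAL` (leaf
branches), or `EXCLUDED` (an outgroup clade and its stem) — and every
downstream analysis conditions on that classification. The branch subtending
each designated node carries the `ORIGIN` class; because the root has no
subtending branch, a family whose origin maps to the root is bookkept on a
root pseudo-branch that is treated as `PRE_ORIGIN` and that never enters
rate computations (it has no length).

# Dating the trait origin: the threshold model

The binary trait (hyphal / non-hyphal, with an `uncertain` category for
species that cannot be coded cleanly) is modeled with the threshold model: a
continuous latent *liability* evolves along the tree by Brownian motion and
the observed state is its sign. `ancthresh_mcmc()` samples liabilities at
all nodes by Metropolis-within-Gibbs: the full conditional of each node's
liability given its neighbors is normal with precision equal to the sum of
inverse incident branch lengths, tips are truncated to the half-line that
matches their observed state, and `uncertain` tips are unconstrained. The
posterior probability of the hyphal state at an internal node ("PP") is the
post-burn-in frequency of positive liability samples.

Identifiability and priors deserve explicit choices:

* The diffusion rate is fixed at 1 and the threshold at 0. For a binary
  trait both only set the liability scale, which is unidentifiable; fixing
  them is the standard resolution.
* The root receives an improper flat prior, realized implicitly by its Gibbs
  conditional on its children. A consequence worth knowing: if *every* tip
  is coded with the same state, the posterior is improper — all liabilities
  can drift jointly away from the threshold and PP tends to 1 for that
  state. That limit is scientifically sensible (unanimous tips say nothing
  against an arbitrarily deep shared origin), but it means posterior
  summaries are only meaningful when both states are represented.
* Burn-in defaults to 20% of generations; the default chain length of
  100,000 generations is a desk-scale choice (production analyses on
  ~70-species trees warrant an order of magnitude more; both run).

Correctness is checked three ways: a two-tip symmetric configuration must
give PP = 0.5; on 4-tip trees the sampler is compared with direct numerical
integration of the marginal posterior over internal liabilities (agreement
within Monte-Carlo error, typically < 0.01); and swapping all tip labels
must map PP to its complement. A reliability-diagram check simulates traits
forward with a diffuse root liability (the flat inference prior cannot be
sampled from, so a point-mass root would mismatch it by construction) and
verifies that nodes binned by PP are state-correct at the binned frequency.

# Gene-family events: reconciliation and Dollo mapping

Duplications and losses are inferred per family by LCA reconciliation of the
rooted gene tree with the species tree: each gene-tree node maps to the MRCA
of its leaves' species, and a node is a duplication exactly when it maps to
the same species node as one of its children. Losses follow from the mapping
gaps: a gene-tree edge whose endpoints map `d` species-branches apart skips
`d - 1` species nodes (one more when the parent is a duplication that maps
above the child), and each skipped node charges one loss to the branch of
the sibling lineage it silences. This placement makes the event map
branch-resolved, which the copy-number bookkeeping requires.

Gene-tree uncertainty is handled as in the common reconciliation practice:
internal edges with support below a threshold (default 0.9, appropriate for
SH-like supports) are collapsed, and the resulting polytomies are re-resolved
to minimize duplications by a deterministic greedy rule — repeatedly join the
pair of children whose combined species set has the deepest MRCA, breaking
ties lexicographically by smallest leaf label. This is a transparent,
testable stand-in for a full duplication–loss rearrangement search; it is
not claimed to reproduce any particular rearrangement tool's output.
Unannotated edges are never collapsed (collapsing silently on missing
support would destroy resolved topology).

Family origins use Dollo parsimony: a family is gained once, at the MRCA of
its carriers, and thereafter only lost; the minimal loss set places one loss
on the stem of each maximal carrier-free clade below the origin. Tests
verify minimality against an exhaustive search over all loss-branch subsets
on 8-leaf trees. Families without a usable gene tree are handled in
presence-only mode: `k > 1` copies in a species contribute `k - 1`
duplications on that terminal branch, which preserves copy conservation
without inventing internal events (terminal branches are excluded from the
rate screen anyway).

`ancestral_copy_numbers()` turns the event map into a nodes-by-families
copy matrix: the count at a node is the root-to-node path sum of
`gain + duplications - losses`. Leaves must recover the observed copy
vectors exactly — this conservation identity is asserted for every simulated
family and is the main end-to-end oracle of the event machinery. Any
negative intermediate count is an error naming the family.

# Enrichment, depletion, and the genome-wide screen

**Origin-branch duplication enrichment.** For a family (or functional
category), duplications on `ORIGIN` branches are compared against the
genome-wide background with the tested unit subtracted (testing a unit
against a background that contains it biases toward the null), in the 2x2
table `[[unit in-origin, unit elsewhere], [background in-origin, background
elsewhere]]`, with a two-sided Fisher exact p-value and Benjamini–Hochberg
correction within each test battery. Terminal-branch duplications count
toward the "elsewhere" reference (the reference is the whole tree); branches
of an excluded outgroup clade never count. Units with no duplications are
reported as `NA` with a reason rather than p = 1, since no association is
testable.

**Loss depletion in secondarily simplified clades.** For each yeast-like
clade and gene category, losses inside the clade (stem branch included) are
compared with the genome-wide loss rate relative to ancestral copy numbers
at the node *preceding* the clade's stem. "Retention" is intrinsically
ambiguous — ancestral-minus-losses and the extant mean differ whenever
duplications occur inside the clade — so both summaries are reported;
the Fisher test uses ancestral-minus-losses.

**The rate screen.** Per-family duplication rates (duplications divided by
branch length) on included branches are compared across the three node
classes with a one-way permutation ANOVA (three classes give treatment
df 2): the F statistic is classical, the p-value is
`(1 + #{F* >= F}) / (1 + n_perm)` under uniform label permutation, so p is
never zero. A family is a screen candidate when it is conserved (at least
one copy in at least 70% of the designated filamentous taxa, boundary
inclusive) and either its Dollo origin maps to an origin node or its rate
test rejects at `alpha = 0.05` *and* the origin-class mean rate is strictly
the greatest. The directionality requirement is deliberate: the screen
targets elevated duplication at the origin, and an undirected rejection
(e.g., depressed origin rates) would be a false positive by intent. Raw
p drives the candidate flag — mirroring the headline decision rule — with
BH q-values reported alongside.

Two design points are worth flagging. First, the screen is a per-family
one-way test across node classes; a two-factor pooled design is sometimes
described for analyses of this shape, but the per-family reading is the one
that matches per-family candidate calls and treatment df 2, and it is what
is implemented. Second, with a small number of included branches the
permutation distribution is coarse; on realistic trees (tens of internal
branches) the attainable p-values are fine-grained, and the calibration
checks below use a 24-taxon tree for exactly that reason.

# The synthetic-data generator

Every stage is tested against data with known ground truth.

* **Species trees**: pure-birth topologies; either ultrametric or with
  i.i.d. exponential branch lengths (default mean 0.2 expected
  substitutions/site, a typical inter-ordinal phylogram scale).
* **Family histories**: each family is gained once at a sampled origin node
  and evolves by a per-copy linear birth–death process along every branch
  below it (default duplication rate 0.5 and loss rate 0.3 events per copy
  per unit branch length — moderate genome turnover; an optional multiplier
  elevates the duplication rate on `ORIGIN` branches). The surviving copy
  genealogy is recorded as the true gene tree; every raw event is recorded
  on the branch where it occurred. Families that go extinct are redrawn and
  counted, which is an explicit acquisition-bias statement. Loss is
  per-copy so simulated losses carry the same semantics as reconciliation
  losses.
* **Traits**: forward Brownian liabilities with tip states given by the
  sign.
* **Features**: per-group gene models written as valid GFF3 (CDS segment
  counts and lengths, intron lengths) and per-protein domain tables, with
  the exact sampled lengths kept for round-trip checks. Multicellular
  defaults carry more and slightly longer exons, longer introns, and one
  more domain per protein than unicellular defaults.

One identifiability caveat is intrinsic and worth stating precisely: LCA
reconciliation infers *minimal* event histories. A true duplication whose
two daughter lineages survive only in disjoint sub-subclades is
indistinguishable from a speciation followed by complementary losses, so
exact event-by-event recovery from true gene trees is provable only in the
loss-free regime. The test suite therefore asserts exact per-branch
duplication recovery at loss rate 0, and at general rates asserts the
conservation identity (replaying events reproduces every extant copy
vector) — which is the property the downstream copy-number analyses actually
rely on.

Similarly, the screen's permutation test assumes exchangeable per-branch
rates under the null. The full birth–death generator violates this mildly
(expected copy number, and hence expected rate, grows with distance from
the origin conditional on survival), so the null-calibration condition is
the dedicated `simulate_poisson_dup_families()` generator: presence
everywhere, i.i.d. Poisson(rate x length) duplications per included branch.
Calibration is measured as the fraction of null families with permutation
p < 0.05, with the duplication rate set high enough (expected ~5 events per
branch) that rates are effectively continuous — with sparse counts the
permutation distribution is atom-heavy and the test is conservative, which
is a property of permutation tests on discrete data, not a defect. The
calibration tree additionally uses equal included-branch lengths: a rate is
a count divided by its branch length, so Poisson counts over heterogeneous
lengths give *heteroscedastic* rates (variance proportional to 1/length),
and when one node class happens to hold systematically shorter branches the
permutation test can be anticonservative (empirically up to ~0.14 at
nominal 0.05 on unfavourable trees). This heteroscedasticity is intrinsic
to per-branch rate screens of this design and applies to real data too —
a caveat for interpretation, not something the package can remove.

# Gene structures and domain architectures

`extract_gene_structures()` reads GFF3 (1-based, inclusive) via standard
Bioconductor import, selects the longest mRNA per gene (a deterministic rule
for multi-isoform annotations; ties break lexicographically), and derives
intron coordinates strictly between consecutive CDS segments — UTRs are
ignored throughout, so "gene length" is the annotated gene span while CDS
and intron lengths are exon-anchored. Group contrasts (plesiomorphically
unicellular vs multicellular species) use Welch's unequal-variance t-test;
the unpooled form is the deliberate reading of the underlying protocol,
since `var.equal = FALSE` *defines* the Welch test.

Domain architectures are ordered tuples of domain accessions — `A>B` and
`B>A` are distinct — and an architecture counts as conserved in a group when
at least 70% of that group's species carrying the family have it (the
denominator is family carriers within the group, since absence of the whole
family is a copy-number signal, not an architecture signal). Per-family
domain-count contrasts use a Poisson log-link GLM with a likelihood-ratio
test against the intercept-only model, with a Pearson dispersion diagnostic
reported; constant-count families are flagged degenerate with p = 1 rather
than erroring. Note that a deterministic one-domain difference at 10
proteins per group is *not* significant under a Poisson likelihood
(LRT p ≈ 0.16) — the distributional assumption matters, and the test suite
pins this value against a closed-form likelihood oracle.

# Problem sizes and reproducibility

The bundled checks run at desk scale by design: 24-taxon trees for the
screen (500 null families at 399 permutations; 150 elevated families at a
10x origin elevation with at least 20 expected origin events), 220 simulated
families for event recovery, 100,000-generation chains on small trees for
the ASR oracles, and 250 forward simulations for the reliability diagram.
All generators and samplers are bit-reproducible given their seed, and the
pipeline writes its configuration, seed and package versions into the run
log. `scripts/acceptance.R` recomputes the headline quantities from scratch
with a single `--seed`.

# Known limitations

* Polytomy re-resolution is greedy, not an exhaustive duplication-loss
  search; on adversarial polytomies it can exceed the true minimum.
* Dollo mapping treats families whole; decomposition into orthogroups
  before mapping (as some pipelines do) is out of scope, so deep paralogy
  inside a family inflates apparent age.
* The threshold-model sampler fixes the liability process to Brownian
  motion; rate heterogeneity or stabilizing processes are not modeled.
* The screen's per-branch rates ignore phylogenetic autocorrelation across
  branches; the permutation null treats branches as exchangeable units, and
  heterogeneous branch lengths make count-per-length rates heteroscedastic
  (see above), which can inflate the nominal type-I error on real trees.
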