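---
title: "Methods: ancestral C1A gene content, classification and transfer detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ancestral C1A gene content, classification and transfer detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(c1aprofiler)
```

# The problem

The papain family (C1A cysteine peptidases: papain, the lysosomal
cathepsins and their relatives) is present across Bacteria, Archaea and
Eukaryota. Eukaryotes carry a conserved repertoire of eight ancestral
paralogous lineages — cathepsins B, C, X, L, F and H, the 26/29 kDa
peptidase, and the type 1 long C1 peptidase — whose joint distribution
across eukaryote supergroups implies they were already present in the last
eukaryotic common ancestor (LECA), whereas the first eukaryotic common
ancestor (FECA) and the last universal common ancestor (LUCA) carried a
single unresolved C1A progenitor. This package makes that inference chain
explicit and testable: sequence → family assignment → phyletic profile →
ancestral content → branch-mapped losses, with a parallel detector for
sequences that crossed lineages horizontally.

# Reference data

Three kinds of reference data ship with the package (generated by
`make_fixture()`, golden-tested against the shipped files):

* **Distribution tables.** Transcriptions of the published
  presence/absence tables: eukaryote supergroups × 8 families, the Obazoa
  detail (10 families, including cathepsin O and vWFA-C1), the prokaryote
  phyla × short/multidomain C1A, plus the ancestral-state tables used as
  expected outputs. Cells are `1`/`0`/`?`; the one blank printed cell
  (Tunicaraptor × cathepsin C) is encoded unknown rather than absent.
* **Backbone taxonomies.** Rooted Newick trees whose leaves are exactly
  the table rows and whose internal labels (LECA, FECA, LUCA,
  Diaphoretickes, Amorphea, "Excavata", Obazoa, …) are query handles.
  Where the tables list lineages flatly the trees carry polytomies — the
  branching order is deliberately not asserted. "Excavata" is kept as a
  named (possibly non-monophyletic) polytomy of Discoba + Metamonada
  because the reference tables report states for it. FECA is a singleton
  stem node between the archaeal sister clade and LECA; the in-package
  tree structure supports singleton nodes precisely for this reason (an
  `ape::phylo` cannot represent them cleanly, which is why the container
  is bespoke). Branch lengths are absent and default to 1.0 wherever a
  method needs them.
* **Synthetic sequence fixtures.** Seed alignments for the family
  profiles and the five-transfer-case dataset, both generated by the
  simulator under fixed internal seeds. They are labelled synthetic
  throughout: no database sequences are redistributed.

The third matrix state `?` (unknown) is an addition relative to the
binary published tables: public sequence databases differ enormously in
coverage, and "no hit in a thin transcriptome" must not count as absence.
Reconstruction treats unknown as missing data in both engines.

# Dollo parsimony (primary reconstruction)

Each family is assumed to originate exactly once — appropriate for
paralogous lineages born by duplication, where independent re-invention is
not credible — and to be subsequently only lost. The gain is placed at the
MRCA of the taxa carrying the family; a node is present iff it lies on the
minimal subtree connecting those taxa; one loss is charged per maximal
branch into a subtree containing no present leaf (and at least one
known-absent one). Subtrees consisting purely of unknown leaves inherit
their parent's state and generate no events, so unknowns never manufacture
losses. A property test checks the loss count against exhaustive
enumeration over all single-origin labelings on random trees up to 12
leaves.

Families suspected to be horizontally acquired pseudoparalogs can be
excluded from the matrix before reconstruction by feeding the HGT module's
calls to `matrix_from_assignments()`/`merge_matrices()` upstream; the
reconstruction itself stays agnostic.

# The gain/loss Markov model (cross-check)

The two-state chain with gain rate λ01 and loss rate λ10 per unit branch
has the closed-form transition matrix implemented in
`transition_matrix()`; likelihoods come from Felsenstein pruning with
per-node rescaling, marginal posteriors from the standard up–down
recursion, and unknown leaves enter with partial likelihood (1,1).
Likelihood correctness is tested against exhaustive enumeration to 1e-10
relative tolerance.

Numerical choices:

* **Rate fitting** is bounded golden-section search on log10 rates in
  [1e-4, 100], coordinate-wise, deterministic start (0.1, 0.1), tolerance
  1e-6. A two-parameter, derivative-free problem does not warrant more
  machinery; a grid scan in the tests confirms the optimum found is
  global on the reference data.
* **Root prior** is the stationary frequency of the fitted rates — the
  standard default when nothing else is known.
* **Posterior ties** at exactly 0.5 render as unknown, never silently as
  present.
* **Simulating under the model** (for the rate-recovery property) draws
  the root from the stationary distribution; content generators used as
  classification oracles instead start present at the root, because there
  the question is recovery of a known repertoire, not of rates.

## Where ML dissents from Dollo — and why it is reported, not hidden

On the merged eukaryote tables, per-family fitted ML agrees with Dollo on
LECA presence for seven of the eight ancestral families. The exception is
the type 1 long C1 peptidase: its scattered 11-of-32 leaf pattern, on a
taxonomy whose branch lengths are an arbitrary 1.0, is better explained by
a reversible model as repeated gains (LECA posterior ≈ 0.36 per-family,
≈ 0.15 under shared rates, where cathepsin H also becomes borderline at
0.491). This is not a numerical artifact — the likelihood surface was
grid-scanned and the pruning is enumeration-checked — but a real statement
about model assumptions: the single-origin conclusion for exactly this
family rests on the Dollo premise that a paralogous lineage cannot be
re-invented. The tests assert this divergence explicitly rather than
papering over it, and `ml_reconstruct(model = "fit_per_family")` exists so
the cross-check is run under family-specific turnover (families as
different as cathepsin B and type 1 long should not share rates).

## The FECA/LUCA table and the generic character

Prokaryotes are scored for a single character `C1A_generic` (any C1A
peptidase); eukaryote leaves derive it as "any family present". Dollo then
places the generic character's origin at LUCA, and
`render_ancestral_table()` applies one documented supersession rule: the
generic character is reported absent wherever a named family is present at
the node. That is how a LUCA/FECA/LECA content table is read — "C1A"
means *a C1A peptidase not yet resolved into the named families* — and it
reproduces the published table exactly: one generic lineage in LUCA, FECA
and the prokaryote groups; eight named families (and no generic row) in
LECA. The published table prints finer prokaryote ranks than the
distribution table provides, so the backbone expands Pseudomonadota into
α-, γ- and δ-proteobacterial leaves, all scored present for short C1As.

# Classification

Iterative homology searching against live databases is out of scope, so
each family is a position-specific score matrix built from a packaged seed
alignment: log2((count + 0.5)/(n + 10)/0.05) per column and residue,
columns over 50% gaps dropped, catalytic triad columns auto-detected as
the first fully conserved C, then H, then N. Scoring is profile-global /
sequence-local affine-gap dynamic programming (gap open 11, extend 1) in
compiled code. Significance keeps only the functional form of
Karlin–Altschul statistics, E = K·m·n·2^(−S) with K fixed at 0.1: the
published acceptance threshold E ≤ 1e-5 is the load-bearing quantity, not
absolute E-values. Acceptance additionally requires a 5-bit margin over
the runner-up family; ties below the margin return `"unclassified"` rather
than a coin flip — the original survey never states how hits were placed
into named families, so the margin rule is this package's explicit
decision. The catalytic check accepts Asn or Asp at the third triad
position (family variation); the I29 propeptide is called when the
propeptide profile scores significantly within the N-terminal 40% of the
sequence; the length classes are `long_type1` (single C1 hit, 450–700 aa),
`multidomain` (second disjoint significant hit, or hit covering under 40%
of the sequence) and `short`.

# Gene trees

Neighbor joining on Poisson-corrected distances (d = −ln(1 − p), p capped
at 0.95 to keep saturated pairs finite; capped pairs and clamped negative
NJ branches are counted and reported) is a deliberate desk-scale stand-in
for full ML inference under WAG+I+G4 with model selection — the uses here
(family monophyly, transfer placement) need correct splits, which NJ
recovers exactly on additive matrices (tested on 50 random trees), not
optimal branch support. Bootstrap resamples alignment columns with
replacement; support is the fraction of replicate NJ trees containing each
split of the point tree; the test default is 100 replicates (scaled down
for runtime; the CLI default is 1000). Both outgroup rooting and midpoint
rooting are provided, since published figures use each in different
places, and neither is asserted as canonical.

# HGT detection

The operating criterion — unusually high conservation between distantly
related organisms — is made numeric as an alien-index-style differential:
`score = max identity to out-group − max identity to in-group`, identities
from banded global affine alignments in compiled code, own-species
sequences excluded from the in-group maximum. The flagging threshold
(default 0.10 identity units) is this package's explicit, configurable
choice; the source analysis prints no cut-off. Flagged calls are clustered
into independent events by single linkage: two calls join iff they share
the donor clade (majority label of the first gene-tree sister set
containing out-group taxa; ties give `"ambiguous"`, still one event) and
the recipient label, and are monophyletic together on the gene tree
(donor-side tips are expected context and do not break monophyly). The
recipient rank used in the linkage key is an argument: at domain rank a
transfer radiating into green algae *and* chytrid fungi counts — as the
source analysis counts it — as one bacteria→eukaryote event; at clade rank
it splits. A test pins the coarser-rank count at or below the finer-rank
count. Whether the published 44%/56% archaeal split counts sequences or
species is not stated; `origin_fractions()` counts sequences.

# What the simulator emulates — and what it does not

`simulate_content()` evolves binary family content down a species tree
under the gain/loss chain (default regime loss-dominated: gain 0.05, loss
0.3 per unit branch on a unit-depth 20-leaf Yule tree — losses common,
re-gain rare, matching the loss-dominated reading of the reference
tables). `simulate_sequences()` evolves one archetype per family by an
equal-exchangeability 20-state substitution process (residue retained with
probability 1/20 + (19/20)e^{−(20/19)d}), catalytic triad positions held
fixed, I29 propeptides prepended for the cathepsin-L-like zymogens, the
type 1 long archetype drawn in the 500–650 aa window. Archetypes avoid
C/H/N outside the triad so triad auto-detection is identifiable by
construction. Transfer regimes encode each transfer as an *independent*
donor lineage whose database reference stays close to the transferred copy
(post-transfer divergence 0.05 subs/site) while recipient copies diverge
fast (0.35): without that asymmetry an identity-differential score
mathematically cannot separate co-recipients of one transfer from vertical
genes, because their best out-group and in-group identities coincide.
Donor–recipient clade divergence is kept at or above 0.5
substitutions/site, comfortably detectable by design.

Not emulated: insertions/deletions (alignments are implicit; the NJ tests
pad unequal families with terminal gaps), rate heterogeneity across sites,
amino-acid exchangeability structure (WAG), within-genome duplication
dynamics beyond content presence, composition/codon signals of transfer,
and any form of database search noise. A green test therefore establishes
that the *algorithms* recover a stated truth under their own model
assumptions — not that the biological conclusions are robust to alignment
error or model misspecification.

The `archaea_default` configuration encodes the archaeal origin mixture as
configuration data (56% transferred of n = 200, as an exact count): the
generator reads it, the detector never does. The acceptance target is that
the detector *measures* the configured mixture within ±5 percentage
points.

# Known limitations

* Taxonomy branch lengths are a convention (1.0), so ML rate estimates on
  reference data are in arbitrary units and the ML cross-check inherits
  that arbitrariness (see the type 1 long discussion above).
* The NJ stand-in cannot reproduce published tree topologies or bootstrap
  values; it is not meant to.
* E-values are shaped, not calibrated; only the 1e-5 threshold behaviour
  is meaningful.
* Clustering transfers by donor/recipient/monophyly undercounts events
  when two genuinely independent transfers from the same donor clade land
  in the same recipient clade and happen to be adjacent on the gene tree.
* The gene-tree-based donor assignment assumes the query and its donor
  references are on one connected gene tree; sequences absent from the
  tree are a placement error, reported as such.
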