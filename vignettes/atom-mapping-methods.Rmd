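---
title: "Symmetry-aware atom mapping by deep graph matching: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Symmetry-aware atom mapping by deep graph matching: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atommatch)
```

## The problem

A chemical reaction rearranges bonds while conserving atoms, so a
one-to-one correspondence — the *atom mapping* — exists between the heavy
atoms of the reactant side and those of the product side.  Knowing it
identifies the reaction center, the bond edits, and reaction templates.
`atommatch` learns this correspondence end-to-end: both sides become
featurized graphs, a shared-weight graph neural encoder embeds every
atom, and the inner products of reactant and product embeddings, after a
softmax, give each reactant atom a probability distribution over product
candidates.

Molecular symmetry makes the target ambiguous: in a molecule with two
indistinguishable methyl groups, either assignment of the pair is equally
valid, and a model should not be penalized for picking the "other" one.
The package therefore detects *topologically equivalent atoms* — atoms of
the same element whose three-hop neighborhoods are indistinguishable —
with an adapted Weisfeiler-Lehman (WL) refinement, and pools probability
mass over these equivalence classes both in the training loss and in
evaluation.

## The model

Each molecule is a graph $G(V, A, X, E)$: heavy atoms $V$, symmetric
adjacency $A$, a 106-column atom feature matrix $X$ (one-hot blocks for
atom type over a fixed 64-element vocabulary, heavy-neighbor count,
formal charge, hybridization, explicit valence, chirality type and
hydrogen count, plus ring/aromaticity bits and min–max–scaled atomic
mass and van der Waals/covalent radii) and a 6-column bond feature
matrix $E$ (bond-type one-hot, conjugation, ring membership).
Hydrogens are implicit: they appear as per-atom counts, never as nodes,
and the mapping covers heavy atoms only.

The encoder is a graph isomorphism network (GIN).  With $h^{(0)} = X
W_{in} + b_{in}$ and per-layer edge transforms, layer $t$ computes for
every atom $i$

$$z_i^{(t)} = h_i^{(t-1)} + \sum_{j \in N(i)} h_j^{(t-1)}
  + \Big(\sum_{j \in N(i)} e_{ij}\Big) W_e^{(t)}, \qquad
  h_i^{(t)} = \mathrm{MLP}^{(t)}(z_i^{(t)}),$$

where each $\mathrm{MLP}$ is a two-layer perceptron with ReLU and the GIN
$\epsilon$ is fixed at 0 (the common minimal variant).  Mean and
component-wise max aggregation are available alternatives to the sum;
sum is the default because it is the discrimination-preserving GIN
choice and performed best in our synthetic benchmark.  The final
embedding concatenates all layers (*jumping knowledge*), including the
layer-0 projection: dropping layer 0 cost several accuracy points in the
benchmark, so it stays in.

For a reactant graph with embeddings $H_R$ and a product graph with
$H_P$ (same weights on both sides), the raw affinity is $\hat M = H_R
H_P^\top$, and matching probabilities are a softmax over each reactant
atom's row:

$$\tilde M_{ii'} = \frac{\exp \hat M_{ii'}}{\sum_{k \in V_P} \exp \hat M_{ik}}.$$

The literal column-wise variant (normalizing each product atom over
reactant candidates) is available via `normalization_axis =
"per_product_atom"`; the row-wise default is used because the loss and
the top-$k$ evaluation both read row $i$ as a distribution over product
candidates for reactant atom $i$.

Probability mass is then pooled over product-side equivalence classes,
$M_{ij} = \sum_{j' \sim j} \tilde M_{ij'}$, and training minimizes the
negative log-likelihood of the ground-truth cells, $\mathcal{L} =
-\sum_{i} \log M_{i, \pi(i)}$.  Pooling means two equivalent product
atoms that split the mass $0.5/0.5$ contribute a full $1.0$ at the true
class — the model is never punished for an ambiguity it cannot resolve.
Reactant-side classes are used only in evaluation (and only behind a
flag), since the loss already reads one row per reactant atom.

## Weisfeiler-Lehman equivalence

`wl_refine()` starts from element symbols and iteratively relabels each
atom with the canonical combination of its label and the sorted multiset
of neighbor labels.  Three iterations implement the three-hop
equivalence radius; the count is overridable.  Canonical strings are
used instead of integer hashes so label equality can never collide.
Bond orders are excluded from the neighbor tokens by default —
equivalence is about connectivity and element — but
`use_bond_order = TRUE` gives the stricter variant.  WL refinement can
merge atoms that no graph automorphism exchanges, but never the
converse; the test suite checks on hundreds of random graphs that every
automorphism orbit (computed independently via BLISS) lies inside one WL
class.  This one-sided guarantee is exactly what the loss needs: pooling
over a too-coarse class can only under-penalize, never mis-penalize.

`enumerate_symmetric_mappings()` composes adjacency-preserving
within-class permutations of both sides with the known mapping.  A
reactant with two independently swappable methyl pairs yields four
mappings (identity, each swap, both); a benzene identity reaction yields
the twelve automorphisms of the 6-cycle.  A configurable cap (default
$10^4$ candidate permutations) guards against combinatorial blow-up on
highly symmetric inputs.

## Reaction records and the edit engine

A dataset line is `SMILES \t lost_h \t gained_h \t deleted_bonds \t
added_bonds`, with atoms addressed by atom-map numbers, bond lists
semicolon-separated (`i-j` or `i-j-order`, order defaulting to single).
`apply_edits()` rebuilds the product from the reactant: hydrogen gains
are applied before losses (the net count is order-independent, and an
atom may pass along a hydrogen it just received), bond deletions and
additions adjust the adjacency, and the result is validated against
per-element maximum valences.  Reactions are balanced in the heavy-atom
sense — element multisets of both sides agree — while implicit hydrogen
totals may differ under hydrogen-transfer edits, which is deliberate:
the mapping covers non-hydrogen atoms.

Because a dataset whose product atom order mirrors the reactant order
would let a model cheat on positions, `remap_reaction()` permutes both
sides independently with seeded uniform permutations and rewrites the
ground-truth matrix accordingly.  The SMILES writer emits atoms in a
deterministic depth-first order, so a generated record reparses and
reformats byte-identically.

## The synthetic generator

Because the package must be testable without downloads, a seeded
generator emulates the record format with known ground truth.  Molecules
grow as random trees over a palette of C, N, O, S, F, Cl with
conservative valences (C 4, N 3, O 2, S 2, F 1, Cl 1), up to two
probabilistic ring closures, and an unsaturation pass that upgrades
bonds to double (probability 0.3) or triple (0.05) where both endpoints
have spare valence, so bond-type, hybridization and conjugation features
vary across the dataset.  With probability `symmetry_fraction` a
molecule is instead built by attaching two copies of a random fragment
to one anchor atom, guaranteeing a nontrivial equivalence class.  Edits
are rejection-sampled among hydrogen-balanced changes (a deleted single
bond credits one hydrogen to each endpoint; an added bond debits one),
so every generated product is valence-legal by construction.  Defaults
follow the benchmark conditions used throughout: 1,000 reactions, 6–16
heavy atoms, 1–3 bond edits, 40% symmetric molecules, 70/10/20
train/validation/test split.

What the generator does *not* emulate: aromatic ring systems (aromaticity
only enters via parsed SMILES), charged species, stereochemistry, and
the long-tailed molecule sizes and multi-component reactant sets of
patent data.  Passing tests on this data show the machinery is correct
and that symmetry handling behaves as designed; they do not certify
accuracy on real reaction corpora.

## Training, defaults, and numerical choices

Training uses Adam at a fixed learning rate ($10^{-4}$ by default, the
published setting), per-minibatch updates, and early stopping on
validation loss (patience 10 epochs, minimum improvement $10^{-4}$);
the returned parameters are those of the best validation epoch.
Softmaxes are stabilized by max-subtraction; log arguments are clamped
at $10^{-12}$ (a clamped ground-truth cell logs a warning).  Weights are
Glorot-uniform initialized from the run seed, and batch order is drawn
from per-epoch sub-seeds, so a seed fixes the entire training history
bitwise.  Divergence (non-finite loss) aborts with diagnostics rather
than continuing.  The desk-scale default width is 64 per layer with 3
message-passing layers; 512 reproduces the published full-scale setting
at a proportionally higher cost.  Reverse-mode gradients are
implemented in-package and verified against central finite differences
to $10^{-9}$ relative error in the tests.

Prediction ranks each reactant atom's product candidates by probability
(ties broken by ascending atom index) and emits a one-to-one mapping by
greedy assignment without column reuse; an optimal linear-assignment
mode (shortest-augmenting-path Hungarian) is available and is checked
against brute-force enumeration in the tests.  Predicted mappings are
written as atom-map numbers on the *unchanged* input atom order, so
downstream comparison never fights an atom permutation.

## Evaluation

`evaluate_matcher()` reports, for depths $k \in \{1, 3, 5, 10\}$, the
percentage of reactions whose every reactant atom has a correct
candidate among its top $k$; a candidate is correct when it lies in the
ground-truth atom's equivalence class (strict exact-index scoring is the
`symmetry_aware = FALSE` variant).  The headline *average accuracy* is
the mean over reactions of each reaction's top-1 atom hit rate — a
reaction mean, not a pooled atom mean; both are reported because the two
conventions differ on uneven reaction sizes.  Reaction-level correctness
requires all atoms by default and can be relaxed to a fraction
threshold.

On the default synthetic benchmark (seeded dataset above, reduced model,
single CPU, a few minutes of training) the held-out symmetry-aware
average accuracy reaches the mid-80s percent, several points above
strict scoring — the same direction the symmetry machinery is designed
to produce — with reaction-level top@5 and top@10 in the high 90s.  The
residual top-1 errors concentrate on edit-touched atoms, whose local
neighborhoods differ between the two sides; on 6–16-atom molecules a
bond edit perturbs the three-hop environment of a third of the atoms,
which makes the synthetic task proportionally harder than mapping large
molecules with localized reaction centers.  `scripts/acceptance.R`
recomputes these numbers from scratch.

## Known limitations

- SMILES support covers the daylight organic subset plus bracket atoms,
  ring closures and multi-component strings; isotopes and directional
  bond stereo are out of scope, and chirality enters only as the
  chirality-type feature.
- WL equivalence is a (sound) over-approximation of graph automorphism
  orbits, not a canonical-labeling algorithm.
- The matcher scores atoms independently; the emitted one-to-one
  assignment enforces mutual exclusivity only at decode time.
- Unbalanced reactions (differing heavy-atom multisets) are rejected
  rather than partially mapped.
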