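---
title: "Substructure-attention DDI prediction: model, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Substructure-attention DDI prediction: model, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(molddi)
```

This vignette is the package's own account of the science it implements:
the model and its assumptions, the tunable parameters and their defaults,
the numerical choices made where the design was genuinely open, what the
synthetic-data generator does and does not emulate, and the limitations a
user should keep in mind. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## The prediction problem

A drug–drug interaction (DDI) dataset is a set of tuples
$(d_x, d_y, r, y)$: two drugs given as SMILES strings, an interaction type
$r$ from a fixed vocabulary, and a binary label. The model learns a
function $D \times D \times R \to [0,1]$ estimating the probability that
the pair interacts through relation $r$. The working hypothesis of this
model family is that interactions are caused by specific chemical
substructures, and — the distinctive element here — that the structure of
*one* drug can be used to locate the responsible substructure of the
*other*.

## Input representation

SMILES are parsed into hydrogen-suppressed attributed graphs. Seven atom
properties are encoded as concatenated one-hot blocks: element
$\{C,N,O,S,F,Cl,Br,I,P,\text{other}\}$, heavy-atom degree $0\ldots5$,
formal charge $-2\ldots+2$, hybridization, aromaticity, total hydrogen
count $0\ldots4$, and chirality tag ($d = 37$). Three bond properties give
$d' = 6$: bond type (single/double/triple/aromatic), conjugation, ring
membership. The two directed edges derived from one bond carry identical
features.

Because no cheminformatics toolkit exists in the target R environment,
the parser is hand-written for the OpenSMILES subset the package needs
(organic-subset and bracket atoms, branches, ring closures, aromatic
lowercase notation, charges, multi-fragment dots). Its output is pinned
against RDKit (via Python) in the unit tests for atom/bond counts,
aromaticity, degrees, hydrogen counts, charges and ring membership. Three
perception rules are deliberately simple and documented here because they
differ from a full toolkit:

* **Implicit hydrogens** use smallest-fitting default valences with
  aromatic bonds counted as 1.5 (so pyrrole-type NH must be written
  `[nH]`).
* **Hybridization** is a heuristic from explicit bond orders (aromatic →
  sp2, triple or two doubles → sp, one double → sp2, else sp3).
* **Conjugation** marks aromatic bonds and bonds whose both endpoints
  touch some *other* multiple/aromatic bond; lone-pair conjugation (e.g.
  the amide C–N) is not perceived.

These affect only feature channels, not graph topology, and are held
fixed across all experiments.

## The encoder

Message passing operates on directed bond-level states, excluding the
immediate back-edge — the directed-MPNN update — so a radius-$t$ state
summarizes non-backtracking walks of length $t$ into the edge. The
directed-MPNN literature this model builds on often leaves the per-step
update rule implicit; we use the canonical shared-weight form
$$h^{(t)}_{pq} = \mathrm{ReLU}\Big(h^{(0)}_{pq} + W_m \sum_{k \in N(p)\setminus\{q\}} h^{(t-1)}_{kp}\Big),$$
which the test suite verifies against a brute-force enumeration of
non-backtracking walks on all small molecules (linear activation).

**GSAPooling.** At each radius the importance of every directed edge is
$\beta = \mathrm{softmax}(\alpha \cdot \mathrm{GCN}(A, H) + (1-\alpha)\cdot \mathrm{FC}(H))$
over the molecule's line graph (two bonds adjacent iff they share an
atom; the two directions of one bond are also adjacent). Choices made
here, where the formula leaves room:

* the GCN score is one symmetric-normalized propagation
  $\hat{A}(Hw_g + b_g)$ with self-loops, mapping states to one scalar per
  edge;
* softmax scopes are always per-graph, never per-batch;
* $\beta$ is recomputed at every radius from $h^{(t)}$ (the readout
  indexes states by $t$, so a single static $\beta$ would be
  inconsistent);
* the mixing weight defaults to $\alpha = 0.6$.

**Radius attention.** Each radius readout $g_b^{(t)} = \sum \beta h^{(t)}$
is scored by $e^{(t)} = c^{(t)} \cdot \tanh(W_b g_b^{(t)} + b_e)$ with a
*per-step* vector $c^{(t)}$ but shared $W_b, b_e$ (only $c$ carries a step
superscript in the defining equations), and normalized by a softmax over
$t = 1..T$ — the only reading of the normalizer that actually normalizes.
The final edge state is the $\lambda$-convex blend across radii, so each
atom's substructure feature
$s_p = f_s(W_{proj}\,x_p + \sum_{q} h_{qp})$ mixes neighborhood sizes
with graph-specific weights. $f_s$ is a two-layer perceptron of width $f$
(depth/width are unspecified in the source formulation; two layers is the
minimal "MLP"), and $x_p$ is projected $d \to f$ before the addition for
dimensional consistency.

**Degenerate molecules.** Bare ions and salt fragments give graphs with
zero bonds. By convention their bond-level readouts are zero vectors,
$\lambda$ is exactly uniform, and $s_p$ reduces to a function of the
atom's own features — so calcium-carbonate-like inputs flow through
training, evaluation and attribution unchanged (this is asserted by an
acceptance test).

## Relation-aware interaction

The initial drug representation is an atom-level GSAPooling readout of
the substructure features (separate parameters from the bond-level
pooling, since it weights atoms, not bonds). The DRIP stage builds one
shared context $o = \mathrm{Concat}(W_h g_{x}, W_t g_{y}, r_z)$ and
applies three residual perceptrons to co-update both drugs and the
relation embedding. The updated $r_{z,new}$ is transient — it exists per
forward pass; the stored embedding table changes only by gradient
descent, keeping training order-independent.

SDUP scores every substructure of drug $y$ against drug $x$'s mid-stage
representation (and vice versa). The two directions share $W_u$, $W_v$
and $f_\mu$, because the defining equations introduce only one set of
those parameters; $f_\mu$ is a two-layer perceptron $2f' \to f' \to 1$.
The final representation is the $\mu$-weighted aggregation, hence always
inside the elementwise envelope of the substructure vectors.

The head is $P = \sigma(r_{z,new} \cdot f_w(\mathrm{Concat}(g_{x,fin},
g_{y,fin})))$ — order-sensitive by design, since many DDI relation types
are directional ("drug 1 increases the metabolism of drug 2").

## Training

Binary cross-entropy with probabilities clipped to $(10^{-7},
1-10^{-7})$; Adam; mini-batches; learning rate $lr \cdot 0.96^{\eta}$ at
0-based epoch $\eta$ (asserted to be exact in the tests). Default
configuration follows the published full-scale settings ($T = 8$, $f =
128$, $lr = 10^{-3}$, batch 256, 100 epochs); all desk-scale tests and the
acceptance script use $T = 3$, $f = 32$, $lr = 5\cdot10^{-3}$ and
40–80 epochs, which reach convergence on the synthetic world in seconds
to minutes on one CPU. Dropout (rate 0.3, applied after $f_s$ and inside
$f_w$) is available for inductive runs and off by default. Gradients for
every parameter group come from the package's reverse-mode tape and are
validated against central finite differences at relative error
$<10^{-4}$.

Two exact ablation switches reproduce the reduced variants used for
component analysis: `mean_pool` replaces every pooling weight by the
uniform distribution (bond- and atom-level), and `no_drip` short-circuits
the relation co-update (mid = init, relation embedding untouched). Both
are implemented as forward-path branches, so the equivalence is exact
tensor equality, not approximate.

## Evaluation protocols

*Transductive:* tuples are split 60/20/20 into train/validation/test,
stratified by relation type so every split keeps the same relation mix;
relation types with fewer than 5 tuples cannot be stratified and are
pooled into one rare-type stratum. One negative is sampled per positive
by corrupting one drug (coin flip which side) uniformly from the drug
pool, rejecting known positives, self-pairs and no-op corruptions.

*Inductive (cold start):* one-fifth of the drugs become novel ($D_{new}$);
tuples with both drugs novel form $M_{s1}$, exactly one novel $M_{s2}$,
none $M_{train}$. Negative sampling is range-constrained: $M_{train}$
negatives never contain a novel drug; $M_{s1}$ replacements come only
from drugs in both $D_{new}$ and $M_{s1}$. The stated rule for $M_{s2}$
("the same as $M_{s1}$") is ambiguous because $M_{s1}$'s literal rule
refers to its own drug set; we read it as: replacements from $D_{new}$
intersected with the drugs of $M_{s2}$ itself. Whether $M_{s2}$ serves as
validation or test is likewise unspecified; the package returns all three
subsets and leaves that choice to the caller.

Metrics are ACC/F1/precision/recall at threshold 0.5 (the natural choice
for 1:1 sampling; the source leaves the threshold unstated), plus AUROC
(Mann–Whitney, ties half-counted) and average precision over score
thresholds; both are pinned to scikit-learn values in the tests and are
reported `NA` on single-class inputs rather than inventing a number.

## The synthetic world

The generator emulates the premise that substructure pairs cause
interactions. A library of `n_drugs` small molecules (≤ ~25 heavy atoms)
is built from seven scaffold classes — sulfonamides, carboxylic acids,
amides, dialkyl ethers, alkylpyridines, alkylbenzenes, alkanes — with
randomized chain lengths, branching and halogen decorations, and a quota
of at least 5 molecules per planted motif. Three default rules plant
interactions (sulfonamide × carboxylic acid; amide × pyridine N; ether ×
sulfonamide), echoing the carbonyl/sulfonamide chemistry that DDI
attribution studies typically highlight. Positives are rule-satisfying
pairs, negatives rule-violating pairs (one per positive), and labels are
flipped with probability `noise` (default 0.05 — a realistic level of
annotation error that also caps attainable accuracy near 95 %). The
causal motif atoms are recorded per genuine positive, which defines the
motif-recovery score: the fraction of held-out positive directions whose
top-μ atom lies inside the planted motif.

What a green test does establish: the architecture can learn planted
substructure-pair rules from ~400 tuples and place its importance mass on
the causal atoms substantially more often than chance. What it does not
establish: performance on real pharmacology. The synthetic molecules are
far simpler than drug-like chemistry (no polycycles, no stereocenters in
practice, few heteroatom patterns), relations are perfectly rule-defined
rather than mechanistic, and drug frequency follows the uniform sampler
rather than the long-tailed distributions of curated databases. Headline
benchmark numbers from full-scale curated datasets are therefore out of
scope here; reproducing them needs those datasets and GPU-scale training.

## Numerical and engineering choices

* Parameters are Glorot-uniform, biases zero, all seeded; every source of
  randomness (init, shuffling, dropout, sampling, splitting) derives from
  explicit integer seeds, and byte-identical reruns are tested.
* Softmaxes subtract the per-scope maximum before exponentiation.
* The batched training path and the readable per-molecule functions
  (`encode_molecule()`, `rsam_forward()`, `predict_interaction()`) are
  two implementations of the same mathematics; a unit test pins them to
  each other at $10^{-12}$, and the hand-computed oracles pin the
  per-molecule path to closed-form values.
* The whole drug library is encoded once per optimization step and
  tuple-level computations gather from it; at desk scale (hundreds of
  drugs) this is faster and much simpler than per-batch subgraph
  assembly. For libraries of thousands of drugs a per-batch encoder would
  be the first optimization to make.
* Training aborts with a diagnostic on non-finite loss rather than
  continuing silently.

## Known limitations

* The SMILES subset excludes isotopic/stereo bond notation beyond @/@@
  tags, wildcard atoms and reaction syntax; unsupported strings fail
  loudly with the offending input named.
* Aromaticity is trusted from the input notation (lowercase), not
  perceived from Kekulé structures.
* `mu` attribution is a model property, not a causal guarantee; the
  motif-recovery test quantifies it only on the synthetic world.
* The relation vocabulary is closed at fit time; unseen relations at
  prediction time are an error by design (cold-start over *relations* is
  a different problem from cold-start over drugs).
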