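---
title: "Models and methods behind ddipath"
author: "ddipath authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ddipath}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddipath)
```

# Overview

`ddipath` classifies drug pairs into typed drug–drug interactions (DDIs)
by fusing three per-drug views — SMILES sequence semantics, molecular
topology, and pathway-anchored knowledge-graph (KG) context — and then
explains predicted interactions post hoc by ranking the shared pathways
that topologically bridge the two drugs' KG neighborhoods. This vignette
documents the model, the numerical and design choices that were genuinely
open, and what the synthetic study conditions do and do not establish.

# SMILES tokenization and the sequence branch

A single compiled regular expression splits a SMILES string with
longest-match-first alternation: bracket atom groups `\[[^]]*\]`,
two-letter halogens `Cl|Br` (optionally case-insensitive), two-digit
`%nn` ring closures, then any single character. This realizes the usual
token classes — multicharacter atoms, bracket groups, ring-closure
digits, bond markers (`- = # :`), branches, stereo marks — while
guaranteeing the *cover property*: concatenating the tokens reproduces
the input exactly. An unterminated `[` is a tokenization error. The
vocabulary reserves `<PAD>`, `<UNK>`, `<CLS>`, `<SEP>` at the four lowest
IDs; `<SEP>` is reserved for compatibility but never placed, and unseen
tokens map to `<UNK>`. Sequences are `<CLS>`-prefixed and padded or
prefix-truncated to a fixed length L (default 128).

The sequence branch embeds tokens (width `dEmb`), projects to `dModel`,
and applies N post-norm Transformer encoder layers with a padding mask,
reading the `<CLS>` row as the drug's sequence vector. **No positional
encoding is added in this branch.** A consequence worth stating plainly:
the `<CLS>` representation is then exactly invariant under reordering of
the real tokens (self-attention sees a multiset), and the test suite
asserts this. Order-aware information enters the model only through the
graph branch below, which is where positional signals are attached by
design.

# Molecular graphs and the GAT branch

The token stream is re-walked with standard SMILES semantics to build an
L×L weighted adjacency aligned to token positions (position 1 is `<CLS>`
and never an atom): consecutive atoms bond with the pending bond weight,
`(`/`)` push and pop the attachment atom, matching ring labels bond their
opening atoms, `.` separates components. Bond weights follow
multiplicities — single 1, aromatic 1.5 (implicit between two aromatic
atoms, explicit via `:`), double 2, triple 3 — and a ring closure takes
an explicit marker before the closing digit, else the marker recorded at
opening, else the aromatic/single default. Self-loops (weight 1, on by
default) stabilize attention on low-degree atoms. Stereo tokens are
parsed but create no geometry; valence is not validated. A ring label
left open — including one cut by truncation at L — is a construction
error rather than a silent partial molecule. On a 20-molecule panel of
real drug SMILES the builder's atom counts and undirected bond sets are
asserted equal to an independent OpenBabel parse (bond orders compared
where no aromatic system forces kekulization).

Node features are H̃ = E + P on atom rows and zero elsewhere, where E is
the shared token-embedding matrix and P a damped sinusoid:
P[pos, 2k] = sin(pos/10000^(2k/d))·g(pos),
P[pos, 2k+1] = cos(pos/10000^(2k/d))·g(pos), with logistic envelope
g(pos) = 1/(1+e^(−pos/100)). The published rendering of this formula is
typographically ambiguous about whether the logistic term multiplies or
divides; we adopt the multiplicative (bounded, |P| ≤ 1) form and expose
the division reading behind `posDamping = "divide"` so the alternative is
one configuration change. `usePositional = FALSE` is the positional
ablation mode and runs the full pipeline unchanged.

The K-head GAT computes attention logits
LeakyReLU(a<sup>T</sup>[W h<sub>i</sub> ‖ W h<sub>j</sub>]) (slope 0.2),
softmax-normalized over each node's neighborhood as defined by the
nonzeros of A (self-loops included). Bond weights define the edge set
*and* scale messages (A<sub>ij</sub>·α<sub>ij</sub>·W h<sub>j</sub>);
`useEdgeWeights = FALSE` keeps only the edge-set role. Per-head
aggregation uses an ELU; heads are concatenated (width K·d′), pooled over
atom positions only (mean by default, max available), and passed through
a one-hidden-layer MLP with a skip connection from the pooled vector.

# Knowledge-graph branch

The KG pipeline filters a typed triple file to the retained entity
families (CGPDS keeps Compound/Gene/Pathway/Disease/Side-effect; CGPD
drops side effects), attaches self-loops to edge-less drugs, samples a
per-drug neighborhood by random walk with restart, and keeps the nodes
within 4 undirected hops of a pathway encountered by the walks. The walk
parameters named in the source material (step count, restart probability
0.3, iteration count, spread) are exposed in `runConfig`; the walk
algorithm itself is not published, so we implement the plainest reading —
independent walks with uniform transitions over incident edges,
restarting to the seed with the given probability, accumulating distinct
nodes up to the `spread` budget. Each walk draws from a seed derived from
the master seed and the walk index, which makes halving either budget
explore a deterministic *subset* of the full-budget neighborhood; the
qualitative budget-sensitivity property (smaller budgets can only
increase the number of pathway-unreachable drugs) therefore holds
exactly rather than only in expectation. Desk-scale defaults
(steps 200, iterations 100, spread 10⁴) keep synthetic runs fast; the
published-scale values remain one config change away. Drugs with no
usable edges or no pathway within 4 hops are removed together with their
DDI rows, with a per-drug reason in the removal report.

Each retained subgraph is embedded by stacking the TransE vectors of its
entities (lexicographic order) and distinct relation types
(lexicographic order) into M_d with S = |E_d| + |R_d| rows — the order is
deterministic but carries no biological meaning, and no pre-aggregation
is applied. A Conv2D (kernel 5×5, stride 3×3, zero padding 1, C output
channels) over the 1-channel S×dim grid, a LeakyReLU, global average
pooling and a linear layer produce z_kg ∈ ℝ^20 for any S ≥ 1. One
boundary case needed a decision: with padding 1 and kernel 5, an S ≤ 2
matrix would yield a zero-height output grid under the floor formula, so
the patch extraction pads with additional zero rows up to one output
cell; size invariance then holds for every S ≥ 1, which the tests assert
over S ∈ {1, 5, 11, 50, 500}. The convolution is a learnable
set-to-vector aggregator, not a spatial model; the embedding store itself
is frozen, computed once, and byte-compared across folds (the
frozen-feature contract). A toy margin-based TransE trainer exists so the
tests can create realistic stores from scratch; it is not a
knowledge-base-scale trainer.

# Fusion, training, evaluation

Pair features concatenate the six blocks in fixed order (a before b), so
D = 2(dModel + K·d′ + dKg); ablation variants keep only their blocks.
Pairs are used as given — (a, b) is not symmetrized by default, with
`symmetrizePairs` available as an augmentation switch. The head is
[D → 256 → 128 → C] with batch normalization, LeakyReLU and dropout 0.3
(config-exposed); binary mode uses a 2-logit softmax for uniformity.
Training minimizes cross-entropy with Adam (defaults lr 10⁻³,
β = 0.9/0.999) in full batch: each epoch encodes every drug once and
takes one step, which keeps the per-epoch cost linear in the number of
drugs rather than pairs. Gradients are clipped to a global norm of 5 —
full-batch Adam on a small model can otherwise destabilize late in
training. Early stopping halts after `patience` (default 10)
non-improving validation epochs; the checkpoint restored at the end is
the best-validation epoch and includes the batch-normalization running
statistics, not just the weights. All neural components run on a small
reverse-mode autodiff core written for this package; its gradients are
finite-difference-checked in the test suite.

Cross-validation is pair-stratified by default: per class, shuffled
round-robin assignment keeps per-fold class counts within one of the
ideal; classes with fewer than k members are pooled into a reported
remainder stratum for splitting only. With k ≥ 3 the validation set is
the next test fold; with k = 2 a seeded 25% of the training fold is held
out instead, since no spare fold exists. The drug-disjoint mode
partitions drugs, trains on pairs of non-holdout drugs and tests on
holdout–holdout pairs, and logs the (empty) train/test drug
intersection as a certificate. Metrics are accuracy, per-class
precision/recall/F1 with support, macro and support-weighted averages
(zero-denominator classes reported as 0 and flagged), plus ROC-AUC (via
the rank identity, cross-checked against pROC) and step-wise PR-AUC in
binary mode.

# Pathway-level interpretability

The screen is strictly post hoc: it consumes labels/predictions and
subgraphs, and feeds nothing back into training. For an anchor drug and
interaction label, partners split into interacting (that label) and
noninteracting (no recorded interaction with the anchor) groups; each
partner's subgraph is merged with the anchor's, and each candidate shared
pathway's four centralities are recorded within that pair-specific
merged subgraph — never on the global KG, so globally popular hubs do not
dominate. Partners whose merge lacks the pathway count against coverage
only.

Two centrality conventions required care because merged subgraphs are
often *disconnected* (the two neighborhoods only connect when a pathway
is shared):

* **Closeness** uses the harmonic form (mean reciprocal distance,
  1/∞ = 0). Reciprocal-mean closeness normalized within components is
  *anti*-monotone when a bridging pathway connects a new cluster — the
  component grows faster than distances shrink — which would invert the
  direction-consistency check for exactly the pathways the screen is
  meant to find.
* **Eigenvector** centrality is computed per component and scaled to
  maximum 1 per component. Unit-norm scaling shrinks a hub's score as
  its component grows, coupling the score to merge size with the wrong
  sign; max-1 scaling keeps hub scores comparable across merges.

Degree is normalized by n−1 and betweenness by the unordered
non-incident pair count. All four are asserted equal to brute-force
oracles (Floyd–Warshall distances, explicit shortest-path counting,
dense eigendecomposition) on every non-isomorphic connected graph with
at most 6 nodes.

Screening then (1) drops pathways below minimum interacting-partner
coverage (default 0.3); (2) runs two-sided Mann–Whitney U tests per
centrality (two-sided rather than one-sided, with the direction handled
as an explicit post-hoc check, since the original sidedness is
unstated); (3) applies Benjamini–Hochberg correction across the full
pathway × centrality family of the anchor's screen; (4) keeps pathways
with at least one significant centrality where every significant
centrality shifts positive with Cliff's delta ≥ 0.147 (the conventional
small-effect bound); and (5) ranks survivors by
Σ REP_W[c] · SMD_c with REP_W = {betweenness 0.40, eigenvector 0.30,
degree 0.20, closeness 0.10}, ties broken lexicographically. The
standardized mean difference is our combining statistic: the source
material names centrality-wise mean/median differences and the fixed
weights but not the combination, and optional coverage and
eigenvector-prominence multipliers are exposed off by default. Groups
with fewer than two covered partners per side are skipped with a note.
Kernel-density summaries with the pooled 95th percentile marker
(quantile type 7) are descriptive only — overlapping merged subgraphs
make the samples dependent — and a constant sample falls back to a
histogram with a warning.

# Synthetic study conditions

The generators define the study conditions and are not tuned per test:
50 drugs, mediator density 0.3 (fraction of drug pairs given a planted
Drug–Gene–Pathway–Gene–Drug bridge, each leg 2 hops so a 4-hop
extraction retains it), 5 interaction classes with class = 1 +
(pathway index mod 4) for planted pairs and 0 otherwise, label noise 0
by default (configurable below 0.5), embedding dimension 32 (400
available for shape-fidelity checks), and per-drug private gene→pathway
attachments so reachability never depends on sharing. Unreachable test
drugs are wired through a 5-hop gene chain, one hop past the limit.
SMILES come from a 20-molecule real-drug panel plus a small random
grammar over C/c/N/O/S/Cl/Br with rings, branches and bracket atoms;
every emitted string satisfies the tokenizer's cover property.
Translational embedding stores pin each entity to head + relation +
noise on first use, so true triples score near zero under the TransE
objective while corrupted triples score like random pairs.

Problem sizes in the tests are chosen for a single CPU: the overfit
sanity check trains the full model (d_emb = d_model = 16, one encoder
layer, 2 GAT heads × 8, d_kg = 16, head 128/64, dropout 0.1, lr 5·10⁻³,
gradient clip 5) on 500 pairs over 50 drugs for up to 200 epochs; the
screening properties use 20 planted replicates and 200 shuffled-label
anchors over ~40-node graphs. For the screening scenarios the per-drug
neighborhoods are deterministic hop-limited ego graphs rather than
random walks: on a desk-scale KG a budget-limited walk covers the whole
component, and the ego construction reproduces the locality that the
walk produces on a realistically large graph.

What passing these tests shows: the architecture can represent and learn
planted pair structure (training accuracy on the 500-pair condition
reaches 1.0 within 200 epochs); the screen recovers a pathway that truly
bridges interacting pairs and controls its false-positive rate under
label shuffling; the pipeline is deterministic given a seed. What it
does not show: real-data predictive accuracy (no DrugBank-scale
benchmark is attempted here), chemistry beyond SMILES syntax (no valence
or stereochemistry), or causal pathway mediation — the screen is
hypothesis-generating by construction.

One desk-scale result deserves an honest caveat. On held-out folds of
the planted-label task the cross-validated accuracy sits at the majority
baseline rather than above it, across full-model and KG-only runs, walk
budgets and training lengths. The pair label is the *identity of the
shared planted pathway*; after global average pooling, a drug's
pathway-membership information survives in z_kg only as an
O(1/S)-amplitude signature, and learning to intersect two such
signatures from a few hundred training pairs does not materialize at
these dimensions. The training-side capacity checks pass; held-out
generalization on this synthetic task is reported by
`scripts/acceptance.R` next to its majority baseline rather than
asserted. At realistic scale — hundreds of embedding dimensions and
hundreds of thousands of labeled pairs — the corresponding signal is far
better resolved; the desk-scale shortfall bounds what the synthetic
benchmark can certify, not the pipeline's mechanics.

# Known limitations

* The Transformer branch sees token multisets only (by design); drugs
  whose SMILES are permutations of the same tokens are distinguished
  solely by the graph branch.
* Aromatic bond weight 1.5 is a convention; the original weighting is
  unstated.
* Truncation at L that cuts a ring open is an error rather than a
  recovery; very long SMILES need a larger configured L.
* The toy TransE trainer is for test-scale stores only.
* Full-batch training is the only implemented regime; it is the right
  trade-off at desk scale but not for hundreds of thousands of pairs.
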