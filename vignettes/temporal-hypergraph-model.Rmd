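---
title: "Predicting future concept hyperedges with temporal hypergraph contrastive learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting future concept hyperedges with temporal hypergraph contrastive learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Every biomedical article can be reduced to the set of concepts (genes,
diseases, chemicals, species, ...) it mentions. Treating each such set as a
*hyperedge* over a shared concept vocabulary, and grouping hyperedges by
publication year, yields a temporal hypergraph that records how groups of
concepts have co-occurred over time. Hypothesis generation then becomes a
future hyperedge prediction problem: which concept sets are likely to appear
together in next year's literature?

The hard part is not rejecting arbitrary concept sets — those differ from
real ones in many obvious ways — but rejecting *deceptive* candidates that
overlap heavily with real science yet are not grounded in how a line of
research actually evolves. `hypertrail` implements a model built around that
difficulty: hard negatives made by partially corrupting real hyperedges, a
historical context ("trail of ideas") for every candidate, and a
time-anchored contrastive objective that forces real continuations to stay
close, in embedding space, to their own history.

## The model

**Trails of ideas.** For a target hyperedge at time $t$, a temporally
constrained random walk moves backward one time step at a time, choosing at
each step a predecessor that shares at least one concept with the current
hyperedge. The sequence, oldest first, plus the target itself forms the
model input. Predecessor choice is weighted by concept overlap raised to a
power $\gamma$ (default $\gamma = 8$, configurable; raw proportional and
uniform policies are available). We use a large $\gamma$ because chance
overlaps of one or two concepts are numerous: at realistic density their
summed proportional weight exceeds that of the single high-overlap true
continuation, and on synthetic data with known lineages the proportional
walk follows the planted parent in under a quarter of its steps, destroying
the historical context the model depends on. A high power makes the walk
near-greedy for the strongest continuation — restoring parent recovery to
its attainable level — while remaining stochastic for tie-breaking and
exploration.

**Tokenization.** Each hyperedge in the sequence becomes one token with
three ingredients:

* *Local structure*: a hypergraph convolution restricted to the sequence's
  own hyperedges. With member features $x_j$, one layer computes
  $h_i = \phi_1(\{x_j\}_{j \in e_i})$ (mean by default, sum optional),
  updates $\tilde x_j = \sigma(x_j A_1 + \bar h_j A_2)$ where $\bar h_j$
  aggregates $h_i$ over the local hyperedges containing $j$, and reads out
  $z_i$ as the mean of $\tilde x_j$ over members. The aggregation in the
  node update is summation by default (mean optional): summing preserves
  each concept's local degree — how many sequence hyperedges contain it —
  which is precisely the signal separating a concept kept from the
  candidate's lineage (it also appears in trail hyperedges) from a freshly
  substituted one. Mean aggregation nearly cancels that signal, because the
  candidate's own message and its parent's are almost identical and the
  normalization erases the count. Through this coupling, $z$ carries the
  candidate-trail overlap information that separates a true continuation
  from a corrupted one.
* *Global structure*: concept features are learnable and initialized from
  random-walk positional encodings on the hypergraph's bipartite expansion —
  entry $(j, l)$ is the probability that an $l$-step walk returns to concept
  $j$ ($l \le L = 5$; odd entries are exactly zero by bipartite parity).
  Encodings are computed on the training period only, so no structural
  information from evaluation years leaks into the features. Concepts first
  appearing after the training period get zero encodings.
* *Time*: a learnable cosine encoding $\psi(t) = \cos(W t + b)$ of the
  0-based time index, concatenated to $z$ (token dimension
  $d_\text{token} = d + d_\text{time}$). $W$ initializes to geometric
  frequencies no faster than about one cycle per six steps. Faster
  components act as parity features of the year index: they fit the training
  years perfectly and alias at unseen ones, which in early experiments
  inverted the ranking of test-year positives against global negatives.
  Slowly varying components extrapolate; $W$ and $b$ remain free to sharpen
  during training.

**Causally masked attention.** The token sequence passes through a
post-norm transformer encoder block (multi-head attention, residual, layer
norm, position-wise feed-forward, residual, layer norm). An additive mask
(zero at or below the diagonal, a large negative sentinel above) restricts
each position to itself and earlier positions, so the contextualized
embedding $h^{(k)}$ is a function of tokens $0..k$ only. Attention logits
are scaled by $\sqrt{d_\text{token}}$ — the full token dimension, as the
model's defining equations print it, rather than the per-head width that is
the more common convention. A position-wise two-layer MLP with a final
sigmoid turns each $h^{(k)}$ into a prediction score $s^{(k)} \in (0, 1)$.

**Objective.** For each scored position, three scores enter a binary
cross-entropy term
$-\log s_\text{pos} - \log(1 - s_\text{hard}) - \log(1 - s_\text{gns})$:
the real hyperedge, a hard negative made by replacing a fraction $r$
(default $0.2$, i.e. $\lceil r\,|e|\rceil$ concepts) of its members, and a
global negative drawn uniformly from the training hypergraph. The
time-anchored contrastive term uses the previous position's embedding $a$
as anchor:
$2\alpha\|a - h_\text{pos}\|^2 + (1-\alpha)\big[\max(0, m - \|a - h_\text{hard}\|)^2 + \max(0, m - \|a - h_\text{gns}\|)^2\big]$,
with $\alpha = 0.5$, margin $m = 1$, weight $\beta = 0.5$ by default. The
first sequence position has no anchor and contributes only its BCE term.
Negative scores come from rerunning the forward pass with the negative
substituted at the scored position (the sequence truncated there) and
reading only that position; the local convolution is rerun too, because its
coupling through shared concepts means earlier tokens are not independent
of the candidate.

## Training

All gradients are derived in closed form and implemented as matrix-level
reverse-mode passes in base R; a finite-difference test validates every
parameter group to $10^{-4}$. The optimizer is Adam (learning rate
$10^{-2}$, 40 epochs, batch 32) with global gradient-norm clipping at 5 and
optional decoupled weight decay (default off — it did not improve held-out
discrimination at this scale).
Negatives are redrawn every epoch from seeds derived deterministically from
the master seed: with negatives fixed once, the model memorizes the
particular corrupted sets (near-perfect discrimination of the stored
negatives, chance on fresh ones) instead of learning the rule.

Two further protocol points matter. Training global negatives come from the
training split only — sampling them from the full temporal hypergraph would
expose evaluation-period hyperedges during training and teaches the model
that late timestamps mean "negative". And positional encodings, trails and
negative pools for training never touch hyperedges outside the training
period.

## Evaluation protocol

Hyperedges are filtered to sizes 5–30, split by calendar year into
training, validation and test periods, and any validation or test hyperedge
whose member set equals (as a set) some training hyperedge's is removed.
The validation period is halved at random: one half (`val_opt`) is reserved
for model optimization, the other (`val_trail`) stays available as
historical context at test time. For each test target, a trail is built
from training plus `val_trail` hyperedges strictly earlier than the target;
the target and one freshly sampled negative (hard by default, global
optionally) are scored at the final position, and AUC, accuracy, precision,
F1 and average precision are computed over the pooled balanced set
(threshold 0.5, ties predicted positive; AUC counts ties one half).

## The synthetic generator

`simulate_hypergraph()` plants explicit evolutionary structure so the whole
pipeline — and the two empirical claims below — can be exercised without
external data. Lineages seed at time 0 with sizes drawn from a normal with
target mean 11 and sd 6, truncated to $[5, 30]$ by resampling (the raw
location is re-centred so the *truncated* mean hits 11). At each step every
lineage's hyperedge spawns a child with $\lceil p\,\text{size}\rceil$
concepts replaced ($p = 0.2$), and fresh lineages are born at rate 0.05 per
lineage per step. Defaults (300 concepts, 40 lineages, 8 steps) give a few
hundred hyperedges — large enough for stable ranking metrics, small enough
that a full training run takes about a minute on one CPU; the methods and
acceptance checks below use these sizes.

What the generator emulates: heavy-tailed-ish hyperedge sizes in the
filtered range, gradual concept turnover along lineages, cross-lineage
chance overlap, lineage births. What it does not: Zipfian concept
frequencies, semantic clustering of concepts, citation structure, and any
notion of concept types. Passing tests on this data therefore demonstrate
that the machinery learns planted evolutionary structure under realistic
shape parameters — not that it reproduces results on real literature.

One property of the protocol shows up clearly at this scale: a test
target's immediate parent lies in the validation year, and half of those
parents sit in `val_opt`, which test trails may not use when the validation
set serves model optimization. Because the synthetic check optimizes
nothing on the validation set, its learnability evaluation passes the full
pre-test history (train plus both validation halves) to `evaluate_model()`;
with half the parents removed instead, the attainable hard-negative AUC
collapses toward chance for the affected targets (an oracle overlap feature
measures about 0.60), which would test the protocol artifact rather than
the model. The default history of `evaluate_model()` remains the
paper-faithful train-plus-`val_trail` pool. The replacement-rate difficulty
check runs on a reduced corpus (200 concepts, 20 lineages, 6 steps, about
100 hyperedges, 15 epochs per fit) since it needs six trainings.

## Numerical choices and degenerate inputs

* Log arguments are clamped to $[\varepsilon, 1-\varepsilon]$,
  $\varepsilon = 10^{-7}$; score gradients are taken through the logits.
* The attention mask uses $-10^9$ rather than $-\infty$; layer norm adds
  $10^{-5}$ inside the square root.
* Contrastive hinge gradients at exactly zero distance use the zero
  subgradient.
* Targets at the earliest time have empty trails and are scored from their
  own token alone; hyperedges whose replacement pool within their own year
  is too small fall back to the global vocabulary.
* Odd validation counts give the extra element to the optimization half.
* Ties in evaluation scores are ranked with midranks (AUC) and predicted
  positive at the threshold.

## Limitations

* The transformer sees at most one trail per target; averaging several
  sampled trails would reduce variance at extra cost.
* Training cost is quadratic in trail length through the negative reruns
  per scored position; at literature scale the R implementation would need
  the compiled-code treatment its reference packages use.
* The anchor-separation property (claim 2 below) is measured against the
  stored instances of the fitted object; it requires nonempty trails.
```
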