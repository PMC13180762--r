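# hypertrail

Temporal hypergraph contrastive learning for predicting future concept
co-occurrences in the biomedical literature.

## What problem this solves

Each article in a literature corpus can be reduced to the set of biomedical
concepts it mentions — genes, diseases, chemicals, species. Treating each
such set as a **hyperedge** over a shared concept vocabulary, stamped with
its publication year, turns a corpus into a **temporal hypergraph**
$\mathcal{H} = \{\mathcal{H}^{(0)}, \ldots, \mathcal{H}^{(T)}\}$.
Hypothesis generation then becomes *future hyperedge prediction*: given the
literature up to year $t-1$, which concept sets are likely to co-occur in
year $t$?

The package is aimed at computational biologists and literature-mining
researchers who want a self-contained, inspectable implementation of this
formulation: data model and file I/O, the full predictive model, a
planted-lineage synthetic generator for controlled experiments, and the
trail-aware evaluation protocol.

## The model

For a candidate hyperedge $e^{(t)}$, a temporally constrained random walk
collects a **trail of ideas** — a chain of concept-overlapping predecessor
hyperedges $(e^{(t_0)}, \ldots, e^{(t_k)})$, each sharing at least one
concept with its successor. Trail plus candidate are tokenized (local
hypergraph convolution + random-walk positional encodings on the bipartite
expansion + learnable cosine time encoding $\psi(t) = \cos(Wt + b)$) and
passed through a causally masked transformer,

$$\mathrm{MaskedAttention}(Q, K, V) = \mathrm{softmax}\!\left(\frac{QK^\top + M}{\sqrt{d_\mathrm{token}}}\right) V,$$

whose per-position embeddings $h^{(k)}$ feed a sigmoid MLP producing scores
$s^{(k)} \in (0,1)$. Training combines, per position, a binary cross-entropy
over the positive, a **hard negative** (a copy with a fraction $r = 0.2$ of
its concepts replaced) and a **global negative** (a uniform draw from the
training hypergraph),

$$\mathcal{L}_\mathrm{BCE} = -\log s_\mathrm{pos} - \log(1-s_\mathrm{hard}) - \log(1-s_\mathrm{gns}),$$

with a time-anchored contrastive term that pulls the positive's embedding
toward the previous position's embedding $a$ and pushes negatives beyond a
margin $m$:

$$\mathcal{L}_\mathrm{CL} = 2\alpha\,\lVert a - h_\mathrm{pos}\rVert^2 + (1-\alpha)\left[\max(0, m - \lVert a - h_\mathrm{hard}\rVert)^2 + \max(0, m - \lVert a - h_\mathrm{gns}\rVert)^2\right].$$

The total objective averages $\sum_k (\mathcal{L}_\mathrm{BCE}^{(k)} +
\beta\,\mathcal{L}_\mathrm{CL}^{(k)})$ over training hyperedges. Everything
— forward passes, reverse-mode gradients, Adam — is implemented in base R
matrix code and validated against finite differences. See the methods
vignette (`vignettes/temporal-hypergraph-model.Rmd`) for assumptions,
parameter meanings and design rationale.

## Worked example

```r
library(hypertrail)

# a synthetic temporal hypergraph with planted lineage evolution
sim <- simulate_hypergraph(synthetic_config(seed = 1))
sim$th
#> Temporal hypergraph: 300 concepts, 395 hyperedges, 8 time steps (years 2000-2007)

# fit: filter sizes 5-30, split by year, de-leak, build trails + negatives, train
fit <- hypertrail(sim$th, hypertrail_config(seed = 1))
fit
#> Temporal hypergraph contrastive model
#>   hypergraph: 299 concepts, 395 hyperedges, 8 time steps
#>   instances: 274 (train), r = 0.20, beta = 0.50
#>   dims: d = 32, d_time = 8, heads = 2, blocks = 1
#>   training loss: 8.0370 (epoch 1) -> 1.3879 (epoch 40)

# held-out final year, one fresh hard negative per target
history <- c(fit$splits$train, fit$splits$val_opt, fit$splits$val_trail)
evaluate_model(fit, history = history, negatives = "hard")
#> AUC 0.769 | Acc 0.703 | Prec 0.750 | F1 0.672 | AvgPrec 0.803  (64 pos / 64 neg)
evaluate_model(fit, history = history, negatives = "global")
#> AUC 0.915 | Acc 0.789 | Prec 0.951 | F1 0.743 | AvgPrec 0.912  (64 pos / 64 neg)
```

The first report says the trained model ranks a real future hyperedge above
a deceptively similar corruption (80% of its concepts intact) about 77% of
the time; against unrelated hyperedges drawn from history the separation is
much stronger. Both numbers are computed on the final, held-out year, with
trails built only from earlier hyperedges.

Real data enters through `read_hyperedges()` (JSONL or TSV: one record per
article with an id, a year, and its concept labels), and a thin command-line
wrapper is installed as `exec/hypertrail` with `simulate`, `prepare`,
`train`, `evaluate`, `claims` and `report` subcommands.

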