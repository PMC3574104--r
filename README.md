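# consensusbn

Discrete Bayesian networks are a standard model for gene regulatory
pathways (for example, the reactive oxygen species detoxification pathway
of *E. coli*), but a few hundred microarray profiles are rarely enough to
learn an accurate network from one database. `consensusbn` implements the
*consensus Bayesian network* approach: learn a network from each available
source — literature-derived structures, public expression compendia, local
experiments — and **combine** them into a single network that is
approximately the network one would have learned from the merged database.

The package is aimed at computational biologists and anyone combining
categorical-data Bayesian networks from heterogeneous sources.

## What is inside

* **Structure learning** — the three-phase information-theoretic learner
  (draft via a maximum-weight spanning tree on mutual information, thicken
  and thin via conditional-independence tests with threshold δ), collider
  detection plus local MDL edge orientation, and maximum-likelihood CPT
  estimation.
* **CPT algebra** — the heart of the method. Two conditional probability
  tables of the same node with different parent sets are *extended* into a
  common form over the union parent set (independence lets rows be
  replicated unchanged), *aggregated* position-wise by the weighted linear
  opinion pool

  P\*(x | pa) = (w₁ P₁(x | pa) + w₂ P₂(x | pa)) / (w₁ + w₂),

  with the weight wᵢ a positive-integer belief in network i, and then
  *simplified*: a parent whose conditional distributions have average
  variance σ̄² ≤ ε is independent of the child (the variance test), so the
  bogus edge is deleted and the table marginalised. With sample-count
  weights and per-configuration counts the aggregate equals the
  maximum-likelihood estimate on the concatenated databases **exactly** —
  the identity the whole construction rests on.
* **Whole-network combination** — prior-order alignment by
  joint-preserving covered-edge reversal, same-variable-set combination,
  and extension of a network to a larger variable set (new nodes and
  "extended" edges copied from a reference network, affected conditionals
  rebuilt by exact Bayes composition with variable-elimination inference).
* **Study tools** — the MI-based associated-gene prediction program,
  directed-edge similarity (Dice or Jaccard), edge diffs against a known
  truth, the split/merge validation harness, and an MI-connectivity
  analysis.
* **Preprocessing and I/O** — tertile (q3) discretization of expression
  matrices into underexpressed / normal / overexpressed, a plain-text
  network interchange format, a BIF reader, and benchmark fixtures
  (canonical 8-node Chest-clinic network; the 37-node / 46-edge ALARM
  structure with synthetic parameters; seeded random networks).

## Worked example: split, learn, combine, compare

```r
library(consensusbn)

bn_true <- fixture_chest_clinic()               # 8 nodes, 8 edges
data    <- forward_sample(bn_true, n = 1000, seed = 8)

idx <- seq_len(250)
b1  <- learn_bn(data[idx, ])                    # from 250 samples
b2  <- learn_bn(data[-idx, ])                   # from 750 samples
b3  <- combine(b1, b2, aggregation_spec(weights = c(250, 750)))
b4  <- learn_bn(data)                           # reference: all 1000

b3
#> <bayesian_net> 8 nodes, 6 edges, weight 1000
b3$dag
#> <dag> 8 nodes, 6 edges
#>   bronc -> smoke; smoke -> lung; lung -> either; tub -> either;
#>   bronc -> dysp; either -> xray
edge_similarity(b3$dag, b4$dag)
#> [1] 1
edge_diff(bn_true$dag, b3$dag)
#>   n_edges n_missing   n_extra
#>         6         3         1
infer_distribution(b3, "dysp", c(smoke = "yes"))
#>       yes        no
#> 0.5061109 0.4938891
```

The consensus network `b3` here matches the full-data reference `b4`
exactly (similarity 1). Against the *generating* network it has 6 of 8
edges: the asia→tub edge carries ≈ 4×10⁻⁴ nats of mutual information and
is undetectable at n = 1000, and two edge directions differ within the
Markov equivalence class — see the vignette for why that is expected.

A command-line surface with the same operations (`discretize`, `learn`,
`combine`, `extend`, `predict`, `simulate`, `evaluate`) is in
`inst/cli/cbn.R`:

```sh
Rscript inst/cli/cbn.R learn --data expr_discrete.tsv --out net.txt
```

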