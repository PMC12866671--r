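# ncdlink

Heterogeneous graph learning for ncRNA–drug resistance association
prediction in R.

Non-coding RNAs — lncRNAs and miRNAs — modulate tumour response to
chemotherapy, and curated databases record thousands of experimentally
supported ncRNA–drug *resistance associations*.  Those records are sparse:
most ncRNA–drug pairs are simply unobserved.  `ncdlink` is for
computational biologists who want to prioritize candidate associations (and
explain the predictions) by completing this bipartite structure on a
heterogeneous molecular network, entirely in R with no deep-learning
framework dependency.

## The model

The package builds a network with three node types and six undirected
relations `R = {ll, mm, dd, lm, ld, md}`: ncRNA co-expression similarity by
Kendall tau-b over cell-line expression profiles, drug similarity by the
Tanimoto coefficient over circular (ECFP4-style) fingerprints — both keeping
only edges with similarity > 0.5 — plus lncRNA–miRNA interactions and the
two association relations.  Node embeddings come from relation-type-aware
message passing: per directed relation *r*,

    f_r(v) = W_r^self h_v + Σ_{u ∈ N_r(v)} W_r^neigh h_u

and per node type the relation messages are pooled elementwise
(`min`/`mean`/`sum`/`max`) and passed through a LeakyReLU, e.g.

    h_lncRNA = σ( ⊕( f_ll, f_lm, f_ld ) ).

A pair (ncRNA, drug) is scored by concatenating the two embeddings and
applying a three-layer MLP; training is full-batch Adam under mean binary
cross-entropy with 2:1 fixed negative sampling and a stratified
0.6/0.2/0.2 split.  Validation/test association edges are removed from the
message-passing graph (asserted on every fit), so evaluation is
leakage-safe.  Evaluation covers AUC, AUPR and Precision/Recall/NDCG@k plus
leave-one-ncRNA-out and leave-one-drug-out cold starts.  Predictions are
explained by integrated gradients over node features *and* network edges
(via a continuous edge-mask relaxation), with top-k edge subnetworks and
ranked meta-paths.  Gradients are derived by hand and verified against
finite differences in the test suite.

## Worked example

Every component runs offline against the package's synthetic benchmark: a
latent community model with planted associations (200 lncRNAs, 100 miRNAs,
30 drugs by default).

```r
library(ncdlink)
sim <- synth_generate(synth_config(seed = 42))
dataset <- build_dataset(sim$truth$LD,
                         ncrna_universe = sim$network$nodes$lncRNA,
                         drug_universe  = sim$network$nodes$drug,
                         seed = 42, task = "LD")
model <- train_model(sim$network, dataset, train_config(epochs = 50, seed = 42))
model
#> ncRNA-drug heterogeneous graph link-prediction model
#>   task LD | hidden 64 | layers 2 | aggregation min
#>   trained 50 epochs (lr 0.0005), best validation AUC 0.9546 at epoch 17

evaluate_split(model, split = "test", k_list = c(10, 30))
#> AUC 0.9204 | AUPR 0.8516  (60 pos, 120 neg)
#>   @10: precision 1.0000  recall 0.1667  ndcg 1.0000
#>   @30: precision 0.9000  recall 0.4500  ndcg 0.9204
```

The held-out AUC of 0.92 means the model recovers the planted association
signal well above the 0.5 of an uninformative ranker (a label-shuffled
control trains to ≈ 0.5); precision 0.9 in the top 30 says 27 of the 30
highest-scored test pairs are true planted associations.  Explaining one
test positive:

```r
pair <- unlist(dataset[dataset$split == "test" & dataset$label == 1, ][1, 1:2])
expl <- attribute_prediction(model, pair, steps = 50)
expl
#> Attribution for <L009, D030>
#>   logit 10.1109 (baseline -0.0146), completeness gap 3.47e-02 at 50 steps

round(type_contribution_shares(expl)$edge_types, 1)
#>   ll   mm   dd   lm   ld   md
#> 29.4  6.3  1.3 20.4 26.0 16.6

sub <- top_k_edge_subnetwork(expl, k = 300)
head(enumerate_meta_paths(sub, pair[1], pair[2], max_len = 3), 3)
#>                       path relations     score
#>  L009 | D012 | L172 | D030  ld|ld|ld 0.5117606
#>  L009 | D012 | M054 | D030  ld|md|md 0.4304749
#>  L009 | D013 | L172 | D030  ld|ld|ld 0.4295909
```

The attribution sums reproduce the logit difference (completeness), the
share table says which relation types carried the prediction, and the
meta-paths are ranked mechanistic hypotheses connecting the pair inside the
top-300-edge subnetwork.

Real data enter through `load_expression_matrix()`, `load_smiles_table()`
and `load_pair_list()`, then `assemble_network()`; a command-line interface
(`inst/cli/ncdlink.R`) exposes `simulate`, `build-network`, `train`,
`evaluate`, `explain` and `loo` subcommands over run directories.

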