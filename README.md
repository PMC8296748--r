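# gatnet

Graph attention networks with learnable attention pooling for
classifying weighted functional brain networks, plus a model
interpretation stage that ranks node-feature importance and measures
explanation fidelity by feature perturbation.

## Who this is for

Neuroimaging and network-biology researchers who represent each subject
as a weighted graph — nodes are brain regions (ROIs), edge weights are
absolute Pearson correlations |ρᵢⱼ| between regional time series, and
each node carries its signed connectivity profile (the matrix row) as a
feature vector — and want to (a) classify such graphs (e.g. patients vs.
controls), and (b) understand *which connections* the classifier relies
on.

## The model

Node representations are learned by masked multi-head graph attention.
For one head with weights `W` and attention vector `a`,

    a_ij = softmax_{j in N_i}( LeakyReLU( aᵀ [W h_i ‖ W h_j] ) )

with the softmax restricted to node i's structural neighborhood N_i
(self-loops included). Hidden layers concatenate the heads, the last
layer averages them; the layer activation σ is the logistic function.
The novel readout replaces fixed pooling rules: every node
representation is mapped to a score

    P_i = σ(Wᵖ h′_i),

the graph representation `P` (one entry per node) receives learned
contribution weights `A = softmax(W^A P)`, and the prediction is the
convex combination

    prob = Σ_i A_i P_i,

trained with cross-entropy. Setting `W^A = 0` recovers average pooling
exactly. Comparison models ship alongside: average pooling (`gat_average`),
a dense softmax head on spliced node vectors (`gat_fc`), GCN node
learners (first-order and Chebyshev filters) feeding the same
pooling head, and conventional baselines (linear SVM, PCA+SVM, random
forest, MLP, CNN) on the flattened upper-triangle features.

The interpretation stage learns a global N×F feature mask (entries in
[0, 1]; near-zero means unimportant) by penalized gradient descent
through the trained network, computes gradient saliency
(|mean sample gradient| per feature), and evaluates any ranking by
*feature hacking*: zero the top-k entries and record the change of
prediction probability (CPP), the number of label flips (NLCI), and the
metric suite (accuracy, sensitivity, specificity, F1, AUC, MCC).

## Worked example

```r
library(gatnet)

# labelled benchmark: 500 complete 30-node graphs, uniform(0,1) weights;
# one fixed subset of 15 nodes defines the label through the statistic
# W0 = 2*(within-subset weight sum) + (cross weight sum) vs. its mean
d <- synthetic_graphs(n_graphs = 500, n_nodes = 30, n_selected = 15, seed = 1)
d
#> graph_dataset: 500 graphs, 30 nodes, 250 positive / 250 negative
#> synthetic ground truth: selected nodes 1 2 4 7 10 11 14 18 19 21 23 25 27 28 30

# small datasets spend many epochs in their initial transient, so give
# the round-over-round early-stopping rule more patience than its
# benchmark default of 15
fit <- gat_fit(d[1:400], model = "gat2", heads = c(4, 4), units = c(16, 16),
               validation = d[401:500],
               control = gat_control(learning_rate = 1e-3, max_epochs = 300,
                                     patience = 50))
fit
#> gatnet model 'gat2': GAT layers [heads 4,4; units 16,16; concat,average]
#>   -> attention head; 30 nodes, 7188 parameters; trained 300 epochs (best 38)

classification_metrics(dataset_labels(d[401:500]), predict(fit, d[401:500]))
#>    accuracy sensitivity specificity          f1         auc         mcc
#>   0.7600000   0.8965517   0.5714286   0.8125000   0.7807882   0.5040302

# which connections does the model use? learn a feature mask and rank
mask <- learn_feature_mask(fit, d[401:500], steps = 200)
head(rank_features(mask), 3)
#>   node feature     score
#> 1   27      21 0.9725905
#> 2   11      15 0.9697023
#> 3    1      15 0.9677134

# explanation fidelity: zero the top-k features, watch the model degrade
perturb_evaluate(fit, d[401:500], rank_features(mask), ks = c(0, 50, 200))
#>     k        cpp nlci accuracy sensitivity specificity        f1       auc        mcc
#> 1   0 0.00000000    0     0.76   0.8965517   0.5714286 0.8125000 0.7807882 0.50403020
#> 2  50 0.01094347   52     0.48   0.2068966   0.8571429 0.3157895 0.7155172 0.08227024
#> 3 200 0.04544916   70     0.42   0.0000000   1.0000000 0.0000000 0.4601806 0.00000000
```

Even at this deliberately small scale, 19 of the mask's top 20 entries
touch the generator's selected nodes (the top connection, 27-21, lies
entirely within the ground-truth subset), and zeroing the top-ranked
features flips half the test set's labels. At the published scale (4000
graphs, fivefold cross-validation) the attention-pooling classifier
reaches ~95% mean test accuracy against ~93% for the linear SVM and ~64%
for the random forest, reproducing the reported ordering GAT2 > SVM ≫ RF.

Real data enter through `pearson_connectivity()` (ROI time series →
connectivity matrix), `build_graph()` (absolute-value edge weights,
optional `threshold` sparsification), and `load_dataset()` (manifest of
per-subject CSV matrices or time series). A thin command-line wrapper
(`inst/cli/gatnet.R`; subcommands `simulate`, `construct`, `train`,
`baseline`, `explain`, `perturb`) drives the same functions from a
shell.

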