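# htinet

Herb–target interaction prediction from a heterogeneous biological
network.

Medicinal herbs are mixtures of many compounds, so predicting which
proteins an herb acts on via the usual herb → ingredient → target route
requires compound data that mostly does not exist. `htinet` takes the
network route instead: herbs, symptoms, diseases, drugs and proteins
form a five-node-type, eleven-layer association network (herb–herb
efficacy similarity, drug–drug ATC similarity, protein–protein
interactions, herb–symptom, herb–disease, disease–symptom, drug–symptom,
drug–disease, drug–protein, disease–disease, symptom–symptom), and
herb–protein relationships are read out of that network's topology.

The model, in the field's standard notation:

1. **node2vec embeddings.** Second-order biased random walks sample node
   neighborhoods: from node *v*, having arrived from *t*, the walk steps
   to neighbor *x* with probability ∝ α(t, x) · w(v, x), where
   α = 1/p if d(t, x) = 0, α = 1 if d(t, x) = 1, and α = 1/q if
   d(t, x) = 2. Skip-gram with negative sampling over the walk corpus
   fits a map f : V → R^d maximizing neighborhood co-occurrence
   likelihood.
2. **Hadamard pair features.** A candidate pair (herb u, protein v) is
   featurized as f(u) ⊙ f(v), the elementwise product.
3. **Supervised scoring.** A classifier (KNN by default; SVM, logistic
   regression, decision tree, random forest, GBDT also wrapped) is
   trained on known interactions plus an equal number of sampled
   non-interacting pairs. The KNN score of a pair is the fraction of
   positives among its k = 5 nearest training features, so predictions
   are quantized to {0, 0.2, 0.4, 0.6, 0.8, 1}.
4. **Evaluation.** 10-fold cross-validation with matched, disjoint
   negative samples per fold; AUROC (Mann–Whitney) and AUPR (step-wise);
   paired Wilcoxon signed-rank comparison between pipelines; and a
   PRINCE network-propagation baseline
   (F ← αW′F + (1 − α)Y on the symmetrically normalized adjacency).

A planted-signal synthetic generator ships with the package, so the
entire pipeline is testable and benchmarkable without any external
database: nodes get latent clusters, every layer links within clusters
densely and across clusters sparsely, and true herb–target pairs are
planted within clusters, making network proximity informative of
interaction by construction.

## Worked example

```r
library(htinet)

cfg <- synth_config(herbs = 40, symptoms = 20, diseases = 20,
                    drugs = 15, proteins = 60, n_clusters = 3,
                    n_positives = 90, seed = 7)
gen <- generate_network(cfg)
summary(gen$network)
#> Heterogeneous network: 155 nodes, 433 edges
#> Nodes per type:
#>    herb symptom disease    drug protein
#>      40      20      20      15      60

fit <- htinet(gen$network, gen$positives, model = "knn",
              d = 16, num_walks = 5, walk_length = 20, seed = 7)
fit
#> HTINet model (knn)
#>   embedding: 155 nodes x 16 dims
#>   training: 90 positives + 90 sampled negatives

predict(fit, gen$positives[1:5, ])
#> [1] 0.8 0.8 0.8 1.0 0.8
```

Known interactions score high (0.8–1.0): at k = 5 each value is the
fraction of interacting pairs among the five nearest training pairs in
Hadamard-feature space.

Cross-validated performance on the default planted benchmark
(200 herbs, 300 proteins, 500 planted interactions; d = 64, 10 walks of
length 40, k = 5), against the propagation baseline on identical folds:

```r
cfg <- synth_config(seed = 1)
gen <- generate_network(cfg)
uni <- list(herbs = nodes_of_type(gen$network, "herb"),
            proteins = nodes_of_type(gen$network, "protein"))
emb <- node2vec(gen$network, d = 64,
                config = walk_config(num_walks = 10, walk_length = 40,
                                     seed = derive_seed(1, "walks")),
                seed = 1)
cross_validate(htinet_pipeline(emb, model_spec("knn", k = 5)),
               gen$positives, uni, n_folds = 10, seed = 1)
#> KNN-HTINet: 10-fold cross-validation
#>   mean AUROC = 0.8969, mean AUPR = 0.8395
cross_validate(prince_pipeline(gen$network), gen$positives, uni,
               n_folds = 10, seed = 1)
#> PRINCE: 10-fold cross-validation
#>   mean AUROC = 0.8975, mean AUPR = 0.8378
```

(The PRINCE line shows the seed-1 run; on this cluster-planted
benchmark both methods approach the same structural ceiling — see the
methods vignette's limitations section.)

An end-to-end, config-driven run with reproducible outputs:

```r
htinet_run(list(synth = list(), seed = 1), "runs/demo")
```

writes `embeddings.txt`, `report.json`, `manifest.json` (and optionally
a candidate ranking) to the run directory; reruns with the same config
are byte-identical. A thin command-line wrapper lives at
`inst/cli/htinet.R` (`run`, `sweep`, `summarize` subcommands).

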