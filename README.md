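# bmaclust

Bayesian model averaging of cluster ensembles, with probabilistic
allocations and per-observation uncertainty.

## The problem

Different unsupervised clustering algorithms routinely give plausible but
different partitions of the same data, and reporting one "best" model
discards the uncertainty that comes from choosing it. `bmaclust` combines
the solutions of several clustering algorithms — hard (k-means,
hierarchical, PAM, spectral, ...) or soft (Gaussian mixtures, fuzzy
c-means) — into a single probabilistic clustering in which every
observation receives a probability of belonging to each averaged cluster,
together with a model-based uncertainty
*u*<sub>*i*</sub> = 1 − max<sub>*k*</sub> *A*<sub>*ik*</sub>. It is aimed
at applied analysts (e.g. in health and biomedical research) who want
cluster-based inferences that acknowledge disagreement between candidate
models.

## The method

Each input solution *m* is an *N* × *K*<sub>*m*</sub> allocation matrix
*A*<sup>*m*</sup> whose rows lie on the probability simplex. The pipeline:

1. **Similarity representation.** Each solution becomes an *N* × *N*
   similarity matrix of pairwise co-assignment probabilities,
   *S*<sup>*m*</sup> = *A*<sup>*m*</sup>(*A*<sup>*m*</sup>)<sup>⊤</sup>
   with unit diagonal — comparable across models regardless of cluster
   count or labelling.
2. **Model weights.** Each model is scored with a clustering internal
   validation index (default: Calinski–Harabasz; S_Dbw and a pluggable
   registry are provided). Scores are normalised —
   *Ŵ*<sub>*m*</sub> = *W*<sub>*m*</sub>/∑*W*<sub>*m*′</sub> for a
   maximised index, reciprocals for a minimised one — and, under equal
   model priors 1/*M*, *Ŵ*<sub>*m*</sub> approximates the posterior model
   probability p(M<sub>*m*</sub>|*Y*).
3. **Consensus.** The weighted element-wise average
   *C* = ∑<sub>*m*</sub> *Ŵ*<sub>*m*</sub>*S*<sup>*m*</sup> is a posterior
   similarity matrix over the ensemble.
4. **Factorisation.** Symmetric simplex matrix factorisation (SSMF)
   decomposes *C* ≈ *AA*<sup>⊤</sup> with rows of *A* on the simplex,
   by projected gradient descent on the off-diagonal residual with an L2
   penalty that can empty redundant columns; empty clusters are pruned.
5. **Uncertainty.** Per-observation uncertainty is one minus the maximum
   allocation probability, capturing both within-model softness and
   across-model disagreement.

## Worked example

```r
library(bmaclust)

d <- simulate_clusters(n_clusters = 3, points_per_cluster = 500,
                       n_dims = 2, sep_val = 0.1, seed = 1)
fit <- cluster_bma(features = d$features, algorithms = bma_algorithms(),
                   control = ssmf_control(seed = 1))
fit
#> Model-averaged clustering of 1500 observations
#>   input models: hc_average (k=3), diana (k=3), kmeans (k=3), pam (k=3),
#>     affinity_propagation (k=3), spectral (k=3), gmm (k=3), som (k=3),
#>     fuzzy_cmeans (k=3)
#>   averaged clusters: 3
#>   mean allocation uncertainty: 0.0395

adjusted_rand_index(fit$labels, d$labels)
#> [1] 0.9311831

hc <- high_certainty_subset(fit, 0.8)
hc$proportion
#> [1] 0.9626667
adjusted_rand_index(fit$labels[hc$indices], d$labels[hc$indices])
#> [1] 0.9710898
```

The fit combines nine base algorithms on three simulated spherical Gaussian
clusters at separation index 0.1. The averaged labels agree with the truth
at ARI 0.93; 96% of points have an allocation probability above 0.8, and
restricted to those the agreement rises to ARI 0.97 — uncertainty
concentrates at cluster boundaries, where the base algorithms disagree.
`plot(fit)` draws the clusters with point size proportional to
uncertainty; `summary(fit)` reports weights, cluster sizes and the
uncertainty distribution.

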