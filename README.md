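# stgcl

Spatial domain identification for spatial transcriptomics by
**subspace-enhanced graph contrastive learning**, in R.

Spatial transcriptomics assays record a gene expression profile at every
capture spot along with its tissue coordinates and, often, a histology
image. The analysis step everything else depends on is partitioning spots
into *spatial domains* — regions coherent in expression, location and
morphology (cortical layers, tumour compartments, laminae). `stgcl`
learns a spot embedding tailored to that task and clusters it.

## The model in brief

Spots form a graph: a blend of spatial and expression k-nearest-neighbour
adjacencies, $A = (1-\alpha)A_S + \alpha A_E$. A GCN encoder
$H = \sigma(W_e X \hat S)$ (with $\hat S$ the self-loop-normalized
adjacency, PReLU activation, $d' = 64$) is trained contrastively on four
views — the original graph, a gene-masked positive, an edge-perturbed
positive guided by a histology-derived morphology graph through
$\tau_A(A) = A\odot(1 - L\odot(A - A\odot A_I)) + (1-A)\odot(L\odot(A_I - A\odot A_I))$,
and a feature-shuffled negative — under three losses weighted 1:1:1:

* a **local–global contrastive loss**: a bilinear discriminator scores
  spots against the sigmoid-mean summaries of the positive views;
* a **local–subspace contrastive loss**: each spot is scored against its
  own context $z_{1i}, z_{2i}$, columns of $Z_v = \hat H_v C$, where the
  self-expression matrix
  $C = (\hat S^\top K \hat S + \beta I)^{-1}\hat S^\top K$ is the exact
  closed-form minimizer of the kernel self-expression problem
  $\min_C \frac12\lVert\Phi(H)\hat S C - \Phi(H)\rVert_F^2 + \frac\beta2\lVert C\rVert_F^2$,
  re-solved every 100 iterations in alternation with Adam training;
* a **reconstruction loss** $\frac1n\lVert X - X'\rVert_F^2$ through a
  mirrored GCN decoder.

Top-$k$ filtering of $C$ per column yields the co-domain neighbour matrix
$C^*$, an interpretable map of which spots explain which. Embeddings are
clustered with model-based Gaussian mixtures (mclust) or Louvain.
Everything — GCN, analytic gradients, Adam, the closed-form solve — is
implemented in base R matrix algebra; gradients are verified against
finite differences in the test suite.

## Worked example

Synthetic gridded tissue, fully offline: 20×30 spots in 3 banded domains,
50 genes with 5 markers per domain shifted by 3 noise SDs, plus
domain-correlated morphology features.

```r
library(stgcl)

sim <- simulate_spatial_grid(seed = 1)   # dataset + labels + morphology
ds  <- preprocess_st(sim$dataset)        # HVG selection, normalize, log1p
ds
#> st_dataset: 50 genes x 600 spots
#>   coords range: x [1.0, 30.0], y [1.0, 20.0]
#>   reference labels: 3 classes

fit <- stgcl(ds, morphology = sim$morphology,
             control = stgcl_control(seed = 1))
fit
#> Graph-contrastive spatial domain model
#>   50 genes x 600 spots, embedding dim 64, 1 layer(s)
#>   500 iterations; total loss 1093.2171 -> 34.8420

predict(fit, type = "clusters", method = "gmm", k = 3)
#> st_clustering (gmm): 600 spots in 3 clusters
#>   ARI = 1.0000, NMI = 1.0000

# do the co-domain neighbours in C* respect the planted domains?
mean(neighbor_majority_label(fit$C_star, sim$labels) == sim$labels)
#> [1] 0.9883333
```

The total loss falls from 1093.2 to 34.8 over the 500 iterations
(`plot(fit)` shows the three components), and Gaussian-mixture clustering
of the learned embedding recovers the three planted bands exactly
(ARI = NMI = 1). Majority-voting each spot's retained self-expression
neighbours agrees with the planted domains for 98.8% of spots.
`ablate_control()` switches off the subspace module or the
morphology-guided augmentation for comparison runs.

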