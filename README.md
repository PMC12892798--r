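# nnmf — neighborhood nonnegative matrix factorization

`nnmf` factorizes spatial transcriptomics count matrices into gene
signatures and per-cell signature activities while making the activities
vary smoothly across the tissue. It is aimed at analysts of imaging-based
(MERFISH-style) or spot-based (Visium-style) data who want soft spatial
clusters, their defining genes, and hard domain labels, at scales from a
few hundred spots to millions of cells across multiple slices.

## The method

Counts $V$ ($N$ cells × $M$ genes) are modeled as Poisson with rate
$WH$, where $W$ ($N \times K$) holds nonnegative signature weights per
cell and $H$ ($K \times M$) holds gene signatures whose rows sum to one.
Maximum likelihood is equivalent to minimizing the generalized
Kullback–Leibler divergence $D(V\,\|\,WH)$. Spatial structure enters
through a Gaussian kernel over cell locations,
$S_{ij} = \exp(-\|x_i - x_j\|^2/\phi^2)$, and the fit iterates

1. $H \leftarrow \mathrm{rnorm}\big(H \otimes (W^\top \frac{V}{WH})\big)$
2. $W \leftarrow W \otimes \big(\frac{V}{WH} H^\top\big)$
3. $W \leftarrow \mathrm{rnorm}(S_\phi)\,W$

— the Poisson-NMF multiplicative updates plus a neighborhood-averaging
step that correlates the weights of nearby cells. The length scale
$\phi$ is estimated by a leave-self-out prediction grid search, the
number of signatures $K$ by AIC ($2D + 2(NK + KM)$), and large or
multi-slice data are handled with per-batch kernels (`groupondist()` /
`slice_batches()`). Signatures are interpreted through a TF-IDF-style
uniqueness reweighting of genes, and cells are hard-labeled either by
their top signature or by K-means on the weight vectors.

## Worked example

```r
library(nnmf)

# synthetic tissue with 4 planted smooth signatures and known truth
sim <- simulate_spatial_counts(N = 1500, M = 120, K = 4,
                               phi_true = 0.08, mean_depth = 200, seed = 11)

# estimate the smoothing scale, pick K by AIC, fit
sel <- select_length_scale(sim$V, sim$X, phi_grid = 0.08 * 2^seq(-2, 2, 0.5))
scan <- select_k(sim$V, sim$X, k_grid = 2:7, phi = sel$phi, seed = 11,
                 max_iter = 150, tol = 1e-5)
fit  <- fit_nnmf(sim$V, sim$X, K = scan$best_k, phi = sel$phi, seed = 11)
fit

match_signatures(fit$H, sim$H_true)$mean_similarity
head(top_genes(fit, n = 3))
```

Output from this exact script:

```
#> Neighborhood NMF fit: 1500 cells x 120 genes, K = 4, phi = 0.0565685
#>   227 iteration(s), converged (tol 1e-06); final GKL 75771.9
#> [1] 0.9963704
#>   signature rank    gene original_weight rescaled_weight
#> 1         1    1 gene_52      0.10942905       0.4622467
#> 2         1    2 gene_70      0.04106352       0.4517119
#> 3         1    3 gene_41      0.06302623       0.3693027
#> 4         2    1 gene_91      0.09039801       0.7180639
#> 5         2    2  gene_8      0.07974367       0.5268571
#> 6         2    3 gene_94      0.08792363       0.5197640
```

The fit converges in 227 iterations; the estimated signatures match the
planted ones with mean cosine similarity 0.996; the top-gene table ranks
genes by how *unique* they are to each signature (`rescaled_weight`),
carrying the raw signature weight alongside. Hard domain labels come from
`hard_clusters(fit, scan$best_k)`, soft memberships are the columns of
`fit$W`, and `write_fit(fit, "out/")` serializes everything as TSV + JSON.

A command-line wrapper with `fit`, `select-k`, `select-phi`, `simulate`
and `report` subcommands is installed at
`system.file("cli", "nnmf.R", package = "nnmf")`.

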