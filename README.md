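# spectralsvg

Graph Fourier analysis of spatial omics data: spatially variable gene
detection, low-pass signal enhancement, functional tissue unit discovery,
and frequency-domain features for downstream machine learning.

## The problem and the model

Spot-based spatial transcriptomics (Visium and similar platforms) measures
a gene-by-spot count matrix together with the 2-D position of every spot.
A central question is which genes are **spatially variable genes (SVGs)** —
genes whose expression forms an organised tissue pattern (a hotspot, a
band, a gradient) rather than varying randomly from spot to spot.

`spectralsvg` treats each gene's expression profile as a **signal on a
graph**. Spots become vertices of a symmetric K-nearest-neighbour graph
(`K = round(ratio_neighbors * sqrt(n))`, edges by union of directed KNN
relations), with adjacency `A`, degree matrix `D`, and combinatorial
Laplacian `L = D - A`. The eigendecomposition `L = U Λ Uᵗ` supplies a
Fourier basis for the tissue: eigenvectors `μ_k` (Fourier modes) oscillate
more rapidly as their eigenvalues `λ_k` (frequencies) grow, and the
**graph Fourier transform (GFT)** of a gene `f_g` is `f̂_g = Uᵗ f_g`.
Everything else follows from this representation:

* **SVG detection.** A spatially organised gene is approximately
  *k-bandlimited*: its energy concentrates in the low-frequency modes. Each
  gene gets a score
  `GFTscore(f_g) = Σ_k exp(-λ_k) · |f̂_gk| / Σ_i |f̂_gi|`
  (zero-frequency modes excluded), a knee-point (Kneedle) cutoff on the
  ranked score curve separates candidates from the bulk, and a one-sided
  Wilcoxon rank-sum test compares low-band against high-band coefficient
  magnitudes per gene, with Benjamini–Hochberg FDR control. A gene is an
  SVG when its score exceeds the cutoff *and* its q-value is below 0.05.
* **Signal enhancement.** The minimiser of
  `‖f − f_g‖² + c · fᵗ L f` is the closed-form low-pass filter
  `f* = U (I + cΛ)⁻¹ Uᵗ f_g`: each coefficient is shrunk by
  `1/(1 + c λ_k)`, optionally truncated to the first
  `round(ratio_fms · sqrt(n))` modes, and transformed back (inverse GFT).
  This imputes dropout-ridden genes and denoises noisy protein channels.
* **Functional tissue units (FTUs).** SVGs are clustered on their
  low-frequency coefficients (cosine-similarity gene KNN graph + Louvain);
  each cluster's pseudo-expression surface is split by 1-D 2-means into a
  high-expression spot set; the Louvain resolution is chosen to minimise
  the mean pairwise overlap of those spot sets.
* **Frequency features.** Stand-alone building blocks used to inject
  spatial structure into external methods: spot-level Fourier features of
  the spot-similarity matrix (`Uᵗ X Xᵗ`), cosine-distance cost matrices
  between annotation and spot coefficients with `β`-fused cost updates,
  frequency-domain gene/spot cosine similarity terms for reconstruction
  objectives, and a spreading-entropy regulariser
  `−Σ p_k log p_k`, `p_k = f̂_k²/‖f̂‖²`.

A seeded synthetic-data module (`make_benchmark()`, `make_ftu_benchmark()`)
emulates Visium-like lattices with planted hotspot/stripe/gradient genes
under Poisson or negative-binomial noise, so the whole pipeline is testable
with known ground truth; `set_metrics()`, `ari()` and `ssim()` provide the
matching benchmark metrics.

## Worked example

```r
library(spectralsvg)

ds    <- make_benchmark(n_svg = 20, n_null = 180,
                        coords = make_grid(15, 15), seed = 42)
expr  <- normalize_counts(filter_genes(ds$raw))   # CPM + log1p
graph <- build_knn_graph(expr$coords)
graph
#> <spot_graph> 225 spots, K = 15, 2037 edges, degree range [15, 25]
basis <- eigendecompose(laplacian(graph))
basis
#> <spectral_basis> n = 225 modes, lambda in [0, 26.5], n_low = 15, n_high = 15

res <- identify_svgs(expr, basis)
glance(res)
#> # A tibble: 1 × 7
#>   n_genes n_svg cutoff_score n_low n_high sensitivity alpha
#> 1     200     4      0.00746    15     15           6  0.05
tbl <- tidy(res)
head(tbl[order(tbl$rank), ], 5)
#>   gene  gftscore  rank    pvalue qvalue is_svg cutoff_score
#> 1 svg1    0.0267     1 0.000842  0.0337 TRUE        0.00746
#> 2 svg7    0.0263     2 0.00752   0.132  FALSE       0.00746
#> 3 svg3    0.0213     3 0.0000607 0.0121 TRUE        0.00746
#> 4 svg13   0.0200     4 0.000387  0.0194 TRUE        0.00746
#> 5 svg16   0.0197     5 0.000318  0.0194 TRUE        0.00746

set_metrics(svg_genes(res), ds$truth$gene[ds$truth$is_svg])
#>   jaccard precision recall    f1 tversky    tp    fp    fn
#> 1     0.2         1    0.2 0.333   0.333     4     0    16
```

The score column ranks planted pattern genes first (`svg*` names); the
conjunction of score cutoff and FDR-controlled band test then calls a
conservative subset — precision 1 here, with recall limited by the modest
size of this 225-spot example (see the methods vignette for how power
scales with spot count). `autoplot(res)` draws the ranked score curve with
the knee cutoff; `plot_spots(expr$coords, expr$values["svg1", ])` maps any
gene on the tissue.

A thin command-line wrapper is installed with the package
(`system.file("scripts", "spectralsvg", package = "spectralsvg")`) with
subcommands `simulate`, `svg`, `enhance`, `ftu`, `features`, `evaluate`
over TSV/Matrix Market files; every run writes a manifest with all
parameters, the seed, and a basis hash.

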