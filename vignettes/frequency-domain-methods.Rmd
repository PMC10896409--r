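---
title: "Frequency-domain analysis of spatial omics: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frequency-domain analysis of spatial omics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spectralsvg)
```

This vignette is the package's own account of the model it implements, the
parameters that matter, the numerical choices made where the design was
genuinely open, and what the synthetic benchmarks do and do not show.

## The graph signal model

A spot-based spatial omics experiment yields a gene-by-spot matrix `X` and
a 2-D coordinate per spot. We build an undirected graph over spots: each
spot points at its `K` Euclidean nearest neighbours and an edge exists
when either endpoint points at the other (union symmetrisation). `K`
scales as `round(ratio_neighbors * sqrt(n))` so the neighbourhood covers a
comparable tissue fraction across platform resolutions;
`ratio_neighbors = 1` is the default and `0.5–2` is the sensible range.
No expression information enters the graph — coordinates only — so the
basis is a property of the tissue geometry alone and is shared by all
genes, which is what makes the per-gene transform cheap.

The combinatorial Laplacian `L = D − A` is symmetric positive
semi-definite; its eigenvectors are the tissue's Fourier modes and its
eigenvalues their frequencies: a mode's quadratic form
`μᵗLμ = ½ Σ a_ij (μ_i − μ_j)²` equals its eigenvalue, so small eigenvalues
mean slow variation across neighbouring spots. The first eigenvalue is
always 0 with a constant eigenvector (one zero eigenvalue per connected
component); these carry no spatial information and are excluded from
scoring. The graph Fourier transform of a gene is `f̂ = Uᵗ f`, with exact
inverse `U f̂` and Parseval norm preservation, both of which the test
suite asserts to 1e-8.

Numerical choices: the decomposition uses LAPACK's dense symmetric solver
(`eigen(symmetric = TRUE)`), adequate up to a few thousand spots — the
scale this package targets; eigenvalues below 1e-12 are snapped to zero;
each eigenvector's sign is fixed so its largest-magnitude entry is
positive (ties to the lowest index), making the basis reproducible;
KNN distance ties resolve to the lower spot index.

## Scoring spatial organisation

A spatially organised gene is approximately *k-bandlimited*: its spectral
energy sits in the low-frequency modes. The score

`GFTscore(f) = Σ_{λ_k > 0} exp(−λ_k) · f̃_k`, with
`f̃_k = |f̂_k| / Σ_i |f̂_i|`,

is a frequency-weighted sum of normalised coefficient magnitudes.
Magnitudes (rather than signed coefficients) are used in both numerator
and denominator because signed sums could cancel; the normalisation makes
the score invariant to positive rescaling of the gene, so library-size
and unit choices do not move ranks. The `exp(−λ)` weight decays quickly:
in practice only modes with `λ ≲ 5` contribute, which is exactly the
"smooth pattern" regime.

The cutoff on the ranked score curve is placed by the Kneedle knee
detector (curve rescaled to the unit square, rotated to concave
increasing, knee = first local maximum of the difference curve whose lead
exceeds `S · mean(Δx)`). The sensitivity default is `S = 6`; smaller `S`
declares knees earlier on short curves. When no knee exists (flat or
linear score curves) the cutoff falls back to the 90th percentile with a
warning.

## The band test and its calibration

Scores rank genes but give no error control. The statistical test
compares, per gene, the magnitudes of the low-band coefficients (modes
`2..1+n_low`) against the high-band ones (last `n_high`) with a one-sided
Wilcoxon rank-sum test (alternative: low > high), followed by
Benjamini–Hochberg adjustment; a gene is called an SVG when its score
exceeds the knee cutoff *and* its q-value is below `alpha = 0.05`.

**Band placement.** The package's default places `n_low = n_high =
round(sqrt(n))` modes in each band. We also provide knee-based band
detection on the eigenvalue curve (increasing scan for the low edge,
decreasing scan on the reversed curve for the high edge, fallback
`⌈n/10⌉`), but it is not the default for a structural reason: the
ascending eigenvalue curve of a dense KNN graph is essentially linear
and then plateaus, so no convex-increasing knee exists, and a fallback
band of `n/10` modes is wide enough that the rank-sum statistic
*saturates* — a gene whose pattern occupies ~10 modes diluted into a
40-mode band cannot exceed z ≈ 2.5 even with zero noise, so the FDR step
can never fire. A square-root band keeps the signal-bearing modes a
substantial fraction of the band, and matches the square-root scaling
used everywhere else in this method family (neighbourhood size,
enhancement truncation).

**Discreteness.** At band sizes around `sqrt(n)` the rank-sum null is
discrete with p-value atoms of order 1e-2, which visibly distorts the
null p-value distribution and biases BH. Small bands
(`n_low + n_high ≤ 25`) therefore use the classical exact p-value
(valid, conservative — and exactly reproducing textbook enumeration);
larger bands use an exact *smoothed* p-value
`P(U > u) + c·P(U = u)` in which the smoothing variate `c` is computed
from the coefficient magnitudes themselves. For continuous i.i.d. data
the ranks are independent of the order statistics, so `c` is uniform and
independent of `U` under the null; the resulting p-values are uniform
(the package's calibration check holds Kolmogorov–Smirnov uniformity over
10,000 null genes) while remaining a deterministic function of the input.
Bands above 200 total modes, or tied magnitudes, fall back to the
tie-corrected normal approximation without continuity correction.

## Signal enhancement

The denoising problem `min_f ‖f − f_g‖² + c fᵗLf` balances fidelity to
the measurement against graph smoothness; its unique minimiser is the
spectral shrinkage `f̂_k → f̂_k / (1 + c λ_k)`. The package implements
exactly this (`keep_all = TRUE`, verified against a direct linear solve
of `(I + cL)f* = f` to 1e-8), plus the practical variant that also
truncates to the first `round(ratio_fms·sqrt(n))` modes before the
inverse transform. Defaults `c = 0.005`, `ratio_fms = 15` are the values
that perform well on Visium-scale data; `ratio_fms` must satisfy
`ratio_fms ≤ sqrt(n)` or the truncation is meaningless and an error is
raised. The zero mode is weighted 1, so the signal mean is preserved when
the graph is connected; the filter is linear and may produce small
negative values, which are clipped only on request (`clip_negative`) and
never silently.

## Functional tissue units

Groups of SVGs sharing one spatial pattern delineate recurrent tissue
structures. The pipeline: (i) represent each SVG by its low-band
coefficient vector; (ii) build a gene KNN graph
(`k = min(15, n_svg − 1)`) weighted by cosine similarity — non-positive
similarities are dropped because Louvain requires non-negative weights —
and cluster with Louvain at a given resolution; (iii) per cluster, sum
the log-scale expression of its genes into a pseudo-expression surface
and split spots with 1-D 2-means (Lloyd iterations from the deterministic
min/max initialisation; the high-mean cluster is the unit); (iv) choose
the resolution in `seq(0.2, 3, 0.2)` minimising the mean pairwise
intersection `2 Σ_{k<l}|S_k ∩ S_l| / (n(n−1))`, ties to the smaller
resolution. Clustering on low-frequency coefficients (not the full
spectrum) is deliberate: the low band carries the pattern, the rest mostly
noise; a full-spectrum mode is available by passing wider coefficient
matrices.

The pseudo-expression sum operates on log-scale values; an
`expression_matrix` records whether its values are already
log-transformed so the log is applied exactly once — summing raw CPM and
double-logging both distort the surface.

## Synthetic data: what it emulates, and what it does not

`make_benchmark()` plants hotspot (Gaussian bump), stripe (band with
graded edges), and gradient genes on a rectangular lattice among
spatially flat null genes, then draws Poisson (or negative binomial)
counts with log-normal library-size factors (`sdlog = 0.3`). Defaults —
50 pattern genes among 450 nulls on a 20×20 grid, per-gene baselines
log-uniform on 1–10 expected counts, peak fold change 5 — were chosen to
mirror the regime of moderately expressed marker genes on a Visium-like
capture. `make_ftu_benchmark()` plants two gene families on sharp-edged,
disjoint discs (so the truth spot sets are unambiguous) over a 450-gene
flat background; the background size matters, because with only a few
dozen simulated genes the planted modules dominate per-spot totals and
CPM normalisation halves their own contrast (a compositional artefact
that a transcriptome-scale denominator suppresses).

What passing these benchmarks shows: the transform, score, test,
filter, and FTU machinery behave as derived, with calibrated error
control and exact recovery of cleanly separated planted structure. What
they do not show: performance on real tissue, where patterns are not
drawn from three archetypes, noise is overdispersed and spatially
correlated, segmentation and capture artefacts exist, and the "truth" is
curated rather than planted.

Two scale effects in these small simulations are worth knowing. First,
power: at 400 spots the band test detects roughly a third of planted
genes at FDR 0.05 under the default conditions, because a simple pattern
occupies only ~10 modes and the rank statistic's resolution grows with
band size; the same generator at 30×30 already recovers ~45%, and the
method's intended operating range is thousands of spots. Reported
recall on the 20×20 benchmark should be read with that in mind. Second,
composition: with 500 simulated genes, strong planted patterns leave a
visible imprint on per-spot totals, so CPM induces weak *genuine* inverse
patterns in null genes; the score cutoff filters most of these, and the
false-discovery proportion stays below ~0.1.

## Problem sizes used by the test suite

Unit tests run on lattices between 3 and 400 spots with analytic or
brute-force oracles (closed-form path-graph spectra, exact rank-sum
enumeration up to 6+6, pairwise ARI counting, direct linear solves); the
calibration check uses 10,000 null genes on a 225-spot basis; the
recovery benchmarks use the generator defaults above. These sizes were
chosen so every expected value is independently computable while the
graphs remain representative of the method's small-sample regime.

## Known limitations

* Dense eigendecomposition limits the basis to a few thousand spots; an
  iterative partial-spectrum backend would be needed for slide-scale data.
* The band test is a per-gene two-sample test on ~`2 sqrt(n)` values: at
  a few hundred spots it is conservative (see above), and it tests
  low-versus-high frequency dominance, not any specific pattern shape.
* The FTU step inherits Louvain's resolution dependence; the overlap
  objective selects among candidates but cannot create separations the
  coefficient space does not contain.
* CPM+log normalisation is the convention of this method family; counts
  with strong compositional structure may warrant alternatives upstream.
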