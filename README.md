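# pavecell

Quantitative analysis of leaf epidermal **pavement-cell shape** across
species, in an explicitly phylogenetic setting.

Pavement cells — the tabular, non-stomatal cells tiling a leaf surface —
range from simple bricks to extreme "jigsaw-puzzle" shapes with deeply
undulating anticlinal walls. `pavecell` turns traced cell outlines (or
binary segmentation masks) into a comparative dataset and asks the two
questions such surveys turn on: *which clades are characterized by
particular base shapes or undulation patterns*, and *do related species
resemble each other more than chance* (phylogenetic signal)?

## What it computes

For each closed outline, the four traditional shape descriptors:

- **area** *A* (µm² for cells, mm² for leaves);
- **aspect ratio** *AR = width / length* after alignment to the principal
  axis of the vertex covariance — 1 for isotropic shapes, → 0 for elongate
  cells;
- **circularity** *C = P² / (4πA)* — 1 only for a circle; grows with both
  elongation and margin undulation;
- **solidity** *S = A / A(convex hull)* — 1 for convex outlines; low
  values mean undulate (or strongly curved) margins.

On top of these: elliptic Fourier analysis (Kuhl–Giardina coefficients
*(aₙ, bₙ, cₙ, dₙ)*, first-harmonic normalization, harmonic-power
selection, inverse synthesis), PCA of the descriptor table, quartile
classification, per-species/per-leaf-side aggregation, the
adaxial–abaxial solidity difference, Spearman correlations between leaf
and cell aspect ratio (p from *t = ρ√((n−2)/(1−ρ²))* on *n − 2* df), and
phylogenetic signal via **global and local Moran's I** on inverse
patristic-distance weights with conditional-permutation p-values:

  *Iᵢ = (zᵢ / m₂) Σⱼ wᵢⱼ zⱼ*,  with *zᵢ = xᵢ − x̄*, *m₂ = Σz²/n*.

A synthetic-data module generates lobed cell outlines with controlled
solidity and aspect ratio, superellipse leaves, rasterized masks,
clade-structured species datasets and matching ultrametric phylogenies,
so every stage is testable without microscopy data.

## Worked example

Measure one synthetic lobed cell (semi-axes 40 × 25 µm, 8 lobes of
relative amplitude 0.25):

```r
cell <- make_lobed_cell(a = 40, b = 25, k = 8, amp = 0.25, n_points = 300)
measure(cell)
#> # A tibble: 1 × 6
#>    area perimeter solidity aspect_ratio circularity border
#>   <dbl>     <dbl>    <dbl>        <dbl>       <dbl> <lgl>
#> 1 3237.      347.    0.725        0.626        2.96 FALSE
```

Solidity 0.73 says the margin undulates moderately (the outline fills 73%
of its convex hull); aspect ratio 0.63 a mildly elongate base shape; and
circularity 2.96 reflects both at once.

Test for phylogenetic signal in species-mean solidity on a small
two-clade tree (one clade undulate, one nearly convex):

```r
tree <- read_phylogeny("(((A:1,B:1):1,(C:1,D:1):1):2,((E:1,F:1):1,(G:1,H:1):1):2);")
W <- proximity_matrix(tree)                        # w_ij = 1/d_ij, row-normalized
x <- c(A=0.62, B=0.60, C=0.64, D=0.63, E=0.88, F=0.90, G=0.86, H=0.91)
res <- local_moran(x, W, n_perm = 999, seed = 1)
glance(res)
#> # A tibble: 1 × 7
#>       n global_i expectation p_value n_hotspot frac_hotspot n_perm
#>   <int>    <dbl>       <dbl>   <dbl>     <int>        <dbl>  <dbl>
#> 1     8    0.324      -0.143   0.017         8            1    999
```

Global *I* = 0.32 far above its null expectation −1/(n−1) = −0.14, with
all 8 tips flagged as hotspots: both clades are pockets of similar trait
values, i.e. strong phylogenetic signal.

The full pipeline — simulate (or extract from masks), measure, EFA,
summarize, PCA, correlate, test signal — runs from one seeded
configuration:

```r
cfg <- pipeline_config("out", seed = 1)
run_pipeline(cfg)          # writes tidy CSVs + manifest.yaml under out/
```

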