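# ggoseg

Automatic random-walker segmentation of ground-glass-opacity (GGO)
pulmonary nodules in 2D CT slices.

GGO nodules are hazy, low-contrast lesions with inhomogeneous interiors,
irregular outlines and blurred boundaries — and a higher malignancy rate
than solid nodules. Classical seeded (random-walker) segmentation handles
such lesions well but needs a human to click reliable seeds, which does
not scale to screening workloads. `ggoseg` removes the human: it is aimed
at medical-image-analysis researchers and pipeline builders who need a
deterministic, fully automated 2D nodule segmenter with quantified seed
confidence and standard evaluation metrics.

## Method

The slice is a graph: one node per pixel, 8-neighbour edges, affinity

```
w_ij = exp(-||z_i - z_j||^2) * exp(-beta_I (I_i - I_j)^2) * exp(-||T_i - T_j||^2)
```

with pixel coordinates `z`, unit-scaled intensity `I` and texture
`T = (LBP, Gabor)`. Seeds are acquired automatically: Otsu threshold →
morphological cleanup → geodesic-distance core `O_0` (the band within `T`
of the maximum inward distance) → local similarity search with
`S(i,j) = ||T_i - T_j||^2 * exp(||I_i - I_j||^2)` growing the nodule set
(`S < kappa`) and the background ring (`S > eta`). Two Gaussian mixture
models fitted on the seed features turn posteriors into per-seed
confidence weights `u_i`, and the segmentation minimises the
label-constrained energy

```
E(F) = 1/2 F' L F + alpha/2 (F - b)' U (F - b),   L = D - W,
```

by solving the single sparse SPD system `(D - W + alpha U) F = alpha U b`;
pixels with `F >= 0` are nodule. Defaults follow the published operating
point: `T = 2`, `T1 = 100`, `kappa = 10`, `eta = 5`, `alpha = 100`,
F-measure weight `beta = 0.3`. Evaluation implements the overlap (Jaccard)
score, pixel-count precision/recall, the beta-weighted F-measure and
50%-consensus multi-rater ground truth. A synthetic GGO phantom generator
with exact ground truth makes every stage testable without any dataset.

## Worked example

```r
library(ggoseg)

ph  <- make_phantom(phantom_spec(noise = 8, seed = 1))  # image + exact truth
seg <- segment(ph$image)                                # full pipeline
seg
#> <rw_segmentation> 128 x 128, 955 foreground pixels, 620+3413 seeds (1.78s)

glance(seg)
#> # A tibble: 1 × 7
#>   n_pixels n_seeds_nodule n_seeds_background mask_area alpha residual elapsed
#>      <int>          <int>              <int>     <int> <dbl>    <dbl>   <dbl>
#> 1    16384            620               3413       955   100 1.94e-12    1.78

evaluate_masks(seg$mask, ph$truth, case_id = "phantom_01")
#> # A tibble: 1 × 5
#>   case_id    overlap precision recall f_measure
#>   <chr>        <dbl>     <dbl>  <dbl>     <dbl>
#> 1 phantom_01   0.934         1  0.934     0.984
```

620 nodule seeds (all inside the true nodule) and 3413 background seeds
anchor the solve; the residual shows the linear system solved to machine
precision; overlap 0.934 means the recovered mask shares 93.4% of its
union with the exact phantom truth, with no false-positive pixels
(precision 1). `autoplot(seg)` overlays the mask contour and both seed
sets on the slice.

A command-line front end wraps the same functions:

```sh
inst/cli/ggorw phantom  --size 128 --radius 18 --noise 8 --seed 1 --out img.png --truth gt.png
inst/cli/ggorw segment  --input img.png --alpha 100 --T 2 --T1 100 --kappa 10 --eta 5 --out mask.png
inst/cli/ggorw evaluate --pred mask.png --truth gt.png --out metrics.csv
```

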