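# mserg — multi-scale spectral embedding registration

`mserg` co-registers pairs of 2-D images whose appearances differ so much
that plain mutual-information (MI) registration breaks down — the archetype
being an ex vivo histology section against its in vivo T2-weighted MRI
slice. Instead of registering intensities, the package builds
*spectral-embedding (SE) representations* of both images and registers
those.

For a length scale $\kappa$ (the texture window side in pixels), the pair is
spatially concatenated and, on the joint image:

1. Haralick co-occurrence features (contrast, correlation, energy, entropy,
   homogeneity) and a 4-orientation Gabor bank are extracted in
   $\kappa\times\kappa$ windows (9 maps);
2. ICA reduces the 9 maps to 6 independent components;
3. a graph-Laplacian spectral embedding of the components yields 3 ordered
   coordinate images, shared by both halves because the eigenbasis is
   computed once on the concatenated image.

Because anatomy drives texture in both modalities, the two halves' SE
vectors look far more alike than the raw intensities. Registration then
maximizes a k-nearest-neighbour entropic-graph $\alpha$-mutual-information
($\alpha = 0.99$, $k = 20$) over the stacked channels of one scale (SSERg)
or several scales (MSERg, default $\kappa \in \{5,7,17\}$) with a cubic
B-spline free-form deformation on a 3-level pyramid ($\eta = 4,2,1$). An
intensity histogram-MI baseline, learning-set scale selection, Dice / RMSD /
mean-deformation-difference (MDD) evaluation metrics, thin-plate-spline
landmark warping and a seeded synthetic multimodal phantom generator are
included, so the whole method is exercisable without clinical data.

## Worked example

```r
library(mserg)

## a synthetic multimodal phantom: one anatomy, two very different renderings
ph    <- make_multimodal_phantom(phantom_spec(seed = 1))
pair0 <- preprocess_pair(ph$pair$fixed, ph$pair$moving)

## how alike are the modalities — raw intensity vs SE representation?
histogram_nmi(pair0$fixed$pixels, pair0$moving$pixels)$nmi
#> [1] 1.100339
reps <- build_scale_representation(pair0, kappa = 9,
                                   reg_config(n_anchors = 500, seed = 101))
mean_pairwise_nmi(reps$fixed, reps$moving)
#> [1] 1.185957

## deform modality B with a known warp, then try to recover it
case <- make_deformed_case(ph, grid_spacing = 32, max_disp = 8, seed = 301)
pair <- preprocess_pair(case$fixed, case$moving)
cfg  <- reg_config(iterations_per_level = 30, sites_per_iter = 250,
                   cp_per_iter = 6, n_anchors = 600, seed = 41)
fit  <- register_serg(pair, scales = c(5, 7, 17), cfg)
base <- register_intensity(pair, cfg)
print(fit)
#> <mserg_registration> method 'mserg' (kappa = 5,7,17), similarity 'alpha_mi'
#>   field: mean |u| 2.190 px, max 6.580 px
#>   iterations run per level: 30, 30, 30
zero <- deformation_field(array(0, dim = dim(case$truth$displacements)))
c(induced   = mdd(case$truth, zero),
  intensity = mdd(case$truth, base$field),
  mserg     = mdd(case$truth, fit$field))
#>   induced intensity     mserg
#>  2.108894  9.430064  2.371783
```

The raw-intensity NMI (1.10) barely exceeds the independence value of 1 on
this `bands`-remapped phantom, while the SE representation at $\kappa = 9$
lifts the cross-modal similarity to 1.19. On the deformed case the
intensity-MI baseline is actively misled — it *quadruples* the mean
deformation error (9.43 px against a 2.11 px induced field) — whereas the
multi-scale SE registration stays at the induced magnitude (2.37 px) at
this reduced 30-iteration budget. The registration object is a fitted
model: `coef()` returns the B-spline control displacements, `predict()`
warps a new image, `plot()` shows the similarity trace and the
displacement-magnitude map, and `summary()` the per-level optimization.

A command-line front end mirroring the R API lives in `inst/cli/mserg.R`
(`register`, `synth`, `evaluate`, `select-scales` subcommands).

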