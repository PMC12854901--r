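# condensr

Quantitative confocal analysis of biomolecular condensates in R.

Synthetic biomolecular condensates — micron-scale liquid-like droplets formed
by phase-separating scaffold proteins — are an emerging compartmentation tool
in plant metabolic engineering. Assessing whether such structures behave like
a liquid–liquid phase-separating (LLPS) system requires quantifying, from 3D
fluorescence z-stacks, the scaffold concentration in the dilute phase
(nucleoplasm, C_dil), in the dense phase (condensates, C_den), the condensate
volume fraction φ, and how each scales with the total expression level C_tot
across many cells. `condensr` implements that pipeline for researchers
working with confocal stacks of condensate-forming cells, together with a
fully controllable synthetic-scene generator so every stage can be validated
against known ground truth.

## The method

Per image (TIFF z-stack or in-memory array):

1. **3D median filter**, 5 × 5 × 3 voxels (y, x, z).
2. **Mode background subtraction**: the modal intensity of the full 3D stack
   (the detector floor) is subtracted, negatives clamped to zero.
3. **Intensity-weighted histogram**: each voxel contributes weight
   proportional to its own intensity, which keeps rare bright condensate
   voxels visible next to the bulk populations.
4. **Gaussian-sum fits**: the histogram is fitted with k = 2, 3 and 4
   component sums

   f(x) = Σᵢ Aᵢ exp(−(x − μᵢ)² / 2σᵢ²)

   by bounded Levenberg–Marquardt with multi-start and forward
   initialisation; the model with the highest **adjusted R²**
   (with a parsimony tie margin) is selected.
5. **mean + 3·SD thresholds**: the nucleus is segmented at μ₁ + 3σ₁ of the
   first (background) component, the dense phase at μ₂ + 3σ₂ of the second
   (nucleoplasm) component; the nucleus mask is reduced to its largest
   26-connected component with interior holes filled.
6. **Phase metrics**: C_tot, C_dil, C_den as mean voxel intensities over the
   corresponding masks, φ as the condensate voxel share, condensate counts
   and per-object volumes from 26-connected labelling.

Across a series of images spanning a range of C_tot, Pearson correlations of
φ, mean condensate volume, C_den and C_dil against C_tot discriminate simple
**binary** phase separation (C_dil and C_den pinned at saturation while φ
grows) from **multicomponent** behaviour (both phase concentrations keep
rising with C_tot).

Auxiliary quantifications: FRAP curve normalisation (max → 1, min → 0, with
the ≥ 50 % bleach inclusion rule), voxelwise Pearson co-localisation, line
transects, sum-projection integrated intensities (semi-quantitative protein
levels), and Mann–Whitney U group comparisons with the usual star codes.

## Worked example

```r
library(condensr)

# a synthetic nucleus with known ground truth
sc  <- generate_scene(scene_params(rng_seed = 51))
rep <- run_image(sc$image)
rep$metrics[, c("c_tot", "c_dil", "c_den", "volume_fraction",
                "n_condensates", "k_selected")]
#> # A tibble: 1 × 6
#>   c_tot c_dil c_den volume_fraction n_condensates k_selected
#>   <dbl> <dbl> <dbl>           <dbl>         <int>      <int>
#> 1  95.5  73.8  371.          0.0731             3          3
sc$truth
#> <scene_truth> C_dil=75.79 C_den=379 C_tot=100 phi=0.07984, 4 condensates
```

The per-image report recovers the generating concentrations (C_dil 73.8 vs
75.8 true, C_den 371 vs 379, φ 0.073 vs 0.080) and selects a three-component
model: background, nucleoplasm, dense phase. `autoplot(rep$fit)` draws the
fitted histogram with the two segmentation thresholds.

A concentration-dependence series and its verdict:

```r
ser <- generate_series(thermo_series_spec(n_images = 40, rng_seed = 11))
out <- run_series(ser)
out$verdict
#> <behaviour_verdict> multicomponent-like
#> # A tibble: 4 × 4
#>   metric                     n     r        p
#>   <chr>                  <int> <dbl>    <dbl>
#> 1 volume_fraction           40 0.994 2.75e-38
#> 2 mean_condensate_volume    40 0.197 2.24e- 1
#> 3 c_den                     40 0.998 7.45e-48
#> 4 c_dil                     40 0.999 2.76e-58
```

Volume fraction and both phase concentrations rise significantly with C_tot —
the generator was run in its multicomponent regime and the pipeline
classifies it accordingly (the mean condensate volume stays flat because the
generator grows the condensate *number*, not the droplet size, across a
series).
`autoplot(out)` reproduces the four concentration-dependence panels with
binned mean ± SEM ribbons; `write_series_report(out, "out/")` writes
`metrics.csv`, `objects.csv`, `verdict.json` and per-metric profile CSVs.

A thin command-line front end ships in `inst/scripts/condensate-quant`
(subcommands `image`, `series`, `sim-scene`, `sim-series`, `sim-frap`).

## Limitations

The synthetic scenes render idealised nuclei (uniform phases with weak
smooth texture, spherical condensates, sharp optics); passing recovery tests
on them validates the pipeline's internal consistency, not its robustness to
every property of real tissue (see the methods vignette for the full
discussion, including why the binary-regime verdict is conservative at
n = 40 images).
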