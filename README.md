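# fibertrace

Automated extraction and quantification of **actin stress fibers** from
single-channel fluorescence micrographs (e.g. TIRF images of
phalloidin-stained cells).

Stress fibers are contractile F-actin bundles that appear as bright
curvilinear ridges in micrographs, interrupted by crossings, branch points,
puncta and diffuse background. `fibertrace` recovers their centerlines in
four stages:

1. **Anisotropic enhancement.** The *line filter transform* (LFT) scores
   each pixel with the maximum directional mean over a rotating line probe
   of half-length *r*,
   `L(x,y) = max_θ (2r+1)^{-1} Σ_{t=-r..r} I(x + t cosθ, y + t sinθ)`,
   and records the preferred orientation. The *orientation filter
   transform* (OFT) then sums orientation-doubled agreement
   `ρ cos(2(θ − α))` along the best probe direction, scoring membership in
   a coherent filamentous structure while suppressing isotropic blobs.
2. **Segmentation.** Otsu thresholding of the OFT map, thinning to an
   8-connected skeleton, and junction removal, yielding unbranched
   *filament fragments*.
3. **Reconstruction.** Fragment termini are re-paired under four geometric
   criteria — similarity, proximity (gap ≤ d_max), continuity, and an
   inner-fragment (bridge) rule — with candidates ranked by a normalized
   two-term angular cost; chains of accepted pairings become whole fiber
   traces.
4. **Quantification.** Fiber width from the distance level with maximal
   image gradient (width = 2 × that level), per-pixel orientation fields,
   actin density versus distance from the cell edge, and false-positive /
   false-negative scoring (`1 − M/D`, `1 − M/G`) against ground truth.

A synthetic-phantom module renders ground-truth filament scenes (Gaussian
PSF σ = 72 nm at 108 nm/px, additive Gaussian noise at controlled PSNR), so
the entire pipeline is testable without external data.

## Worked example

Render the shipped nine-filament benchmark scene (four concentric arcs
crossed by five straight chords, 512 × 512 px at 108 nm/px) at 25 dB PSNR,
run the pipeline, and score the result:

```r
library(fibertrace)

scene <- make_phantom(benchmark_scene_spec(psnr = 25, seed = 1))
scene
#> <phantom_scene> 512x512 px, 9 filaments, PSNR 24.99 dB

res <- extract_fibers(scene$noisy_image)
glance(res$fragments)
#>   n_fragments total_px skeleton_px median_length_px
#> 1          49     2846        2846               65

glance(res$traces, pixel_size = 108)
#>   n_fibers n_fragments total_length_px total_length_um mean_length_px
#> 1        9          49            3590           387.7          398.9

match_and_score(res$traces, scene$truth_paths, shape = dim(scene$noisy_image))
#>   D G M false_positive_ratio false_negative_ratio
#> 1 9 9 9                    0                    0
```

The 49 junction-separated fragments reassemble into exactly the 9
ground-truth filaments (D detected, G true, M matched; both error ratios
0). Each trace is an ordered pixel chain — `tidy(res$traces)` gives the long
`fiber_id / point_index / row / col` table, `autoplot(res$traces)` draws
them, and per-fiber widths in px and µm come from `estimate_width()`.

`run_pipeline(pipeline_config(...))` wraps the same stages with TIFF/CSV/
JSON exports and a parameter manifest; `inst/cli/fibertrace` is a thin
command-line front end (`fibertrace run -i image.tif -c config.yaml -o out`).

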