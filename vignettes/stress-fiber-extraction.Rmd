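---
title: "Extracting actin stress fibers from fluorescence micrographs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting actin stress fibers from fluorescence micrographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibertrace)
```

Actin stress fibers are contractile bundles of F-actin prominent in adherent
cells. In TIRF micrographs of phalloidin-stained cells they appear as bright
curvilinear ridges against a clutter of puncta, diffuse background, and
densely interwoven secondary networks. `fibertrace` extracts their
centerlines automatically in four stages — anisotropic enhancement,
segmentation, fragment reconstruction, quantification — and ships a
synthetic-phantom benchmark so every stage can be validated without any
external data.

## The enhancement model

The **line filter transform** (LFT) scores each pixel by the best directional
mean in its neighborhood. A line probe of half-length $r$ is swept through
orientations $\theta \in (-90°, 90°]$; at each angle the image is sampled at
unit steps along the probe (bilinear interpolation). The intensity map is

$$L_{int}(x, y) = \max_\theta \frac{1}{2r+1} \sum_{t=-r}^{r}
I(x + t\cos\theta,\; y + t\sin\theta),$$

and the orientation map $L_{ori}$ records the maximizing $\theta$. A pixel on
a fiber scores its full ridge intensity at the aligned angle; an isotropic
blob of comparable peak dilutes across every angle.

The **orientation filter transform** (OFT) then asks whether the neighbors
along the best direction *agree in orientation*. Each neighbor contributes
its LFT pair $(\rho, \theta)$ as an orientation-doubled vector,
$\rho\cos(2(\theta - \alpha))$, summed along a probe at angle $\alpha$; the
probe angle $\alpha_{max}$ maximizes the absolute sum, and the signed sum at
$\alpha_{max}$ is the OFT score. Doubling the angle makes the agreement
measure 180°-periodic, as orientations are. The score of a pixel inside a
coherent fiber is close to $(2r+1)\,\rho$; pixels whose neighborhood
orientations are incoherent (noise) or anti-aligned (perpendicular clutter)
score near zero or negative. It is the OFT map that is thresholded for
segmentation.

Two readings of the transform were genuinely open and are resolved as
follows:

* the probe maximizes $|\Sigma|$ but the stored value is the *signed* sum at
  the maximizing angle, so anti-aligned neighborhoods are reported negative
  and handled by thresholding rather than folded away;
* the weight $\rho$ and orientation $\theta$ of a term are those of the
  *neighbor* sample (intensity bilinear, orientation at the nearest pixel),
  not of the base pixel.

## Segmentation into fragments

The OFT map is thresholded at the Otsu level of its 256-bin histogram
(user-scalable via a multiplier), binarized, and thinned to an 8-connected
one-pixel skeleton (Zhang–Suen, followed by a staircase-pruning pass that
removes pixels whose neighbors form a single connected component — raw
Zhang–Suen output on diagonal structures retains thick staircases that would
otherwise be misread as junctions). Junction pixels — skeleton pixels with
three or more skeleton neighbors — are deleted together with their skeleton
neighbors within one pixel, cleanly separating branch arms. What remains is
a pool of unbranched *filament fragments*, each an ordered pixel chain with
a center of mass and two termini; the propagation direction of a terminus
points from the center of mass to that tip.

## Reconstruction by terminus pairing

Whole fibers are reassembled by pairing fragment termini under four
geometric criteria. For a base terminus with propagation direction
$\phi_i$ and a candidate terminus $j$ at gap vector $d_{i,j}$:

1. **similarity** — the angle between $\phi_i$ and the *reverse* of
   $\phi_j$ is at most $\phi_{max}$;
2. **proximity** — $\lVert d_{i,j}\rVert \le d_{max}$;
3. **continuity** — the angle between $\phi_i$ and the gap vector is at
   most $\psi_{max}$;
4. **inner fragment** — if a third fragment inside the search fan could
   itself bridge the two (its near tip satisfying similarity and continuity
   against the base, its far tip against the candidate), the direct pairing
   is rejected in favor of pairing through the bridge.

Candidates are gathered inside a fan (radius `search_radius`, half-sweep
`search_angle`) anchored on the propagation direction. Survivors are ranked
by the cost

$$C_i = c_{angle}\,\frac{\Delta\theta_i}{\max_k \Delta\theta_k}
      + c_{gap}\,\frac{\Delta\theta_{gap,i}}{\max_k \Delta\theta_{gap,k}},$$

the two terms being the similarity and continuity mismatches normalized by
the worst candidate (a zero maximum makes that term zero for all candidates,
so a single perfect candidate costs 0). The lowest cost wins; ties break by
smaller gap, then smaller fragment id.

Bases are visited in descending order of fragment length, so prominent
fibers anchor the assembly; passes repeat to a fixed point and a pairing,
once accepted, is never revisited. Accepted pairings chain fragments into
simple open curves; the rare cyclic chain is broken at its highest-cost
link. Directions live on the full 360° circle and orientations on the 180°
circle; the two spaces are never mixed, and every angular difference is
folded into [0°, 180°].

## Quantification

* **Width** — the Euclidean distance map around a trace is binned into
  integer levels (nearest-integer binning: level $\ell$ holds distances in
  $[\ell-\tfrac12, \ell+\tfrac12)$); the level with the highest mean image
  gradient (central differences on the raw image) marks the fiber edge and
  the width is twice that level. For a Gaussian cross-section of standard
  deviation $\sigma$ the gradient $\propto d\,e^{-d^2/2\sigma^2}$ peaks at
  $d = \sigma$, so the estimator reads $2\sigma$. Floor-binning was
  considered and rejected: it offsets each band by half a pixel, which at
  $\sigma \approx 3$ px makes adjacent level means nearly degenerate and
  noise-fragile, whereas centered bins recover the peak robustly.
* **Orientation field** — per skeleton pixel, the principal axis of the
  skeleton coordinates inside an odd window (default 15 px), reported in
  (−90°, 90°].
* **Density profile** — coverage ratio of actin pixels per distance-from-
  cell-edge bin, the bins partitioning the cell mask.
* **Accuracy** — a detected trace matches a ground-truth path when ≥ 75% of
  its pixels lie within 3 px of the path *and* ≥ 50% of the path lies
  within 3 px of the trace; matching is one-to-one by greedy best overlap.
  False-positive and false-negative ratios are $1 - M/D$ and $1 - M/G$.
  The two-sided rule penalizes both hallucinated and fragmented traces; the
  coverage fractions and tolerance are exposed as arguments since the
  matching criterion admits several reasonable operationalizations.

## The synthetic phantom

`make_phantom()` rasterizes parametric centerlines (0.25-px arc-length
sampling, nearest-pixel marking), convolves them with a Gaussian PSF
(σ = 72 nm at 108 nm/px, matching a TIRF microscope's resolving power),
scales to a peak intensity, and adds Gaussian noise at a requested peak
signal-to-noise ratio, defined here as
$PSNR = 20\log_{10}(\text{peak}/\sigma_{noise})$ dB (the natural reading
for additive Gaussian noise). Noise is not clipped, so intensities may go
negative; all downstream stages tolerate that. The noise realization is a
pure function of the seed.

The shipped benchmark scene (`benchmark_scene_spec()`) is nine filaments —
four concentric arcs crossed by five straight radial chords — in a
512 × 512 px (55 × 55 µm) frame. Crossings are the essential feature:
junction removal at each crossing fragments both fibers, and the
reconstruction stage must undo exactly that. Arcs are spaced 80 px apart and
chords 15° apart so that distinct fibers never come within the default
pairing gap of one another. The width benchmark
(`width_benchmark_spec()`) is a single ~490 px gently curved fiber whose
cross-section σ is the parameter under test; its length matters because
each distance level then averages the gradient over several hundred pixels,
which is what makes the estimator noise-resistant.

What the phantoms deliberately do **not** emulate: photon-counting (Poisson)
noise, camera gain and offset, diffuse cytoplasmic background, puncta and
other non-linear clutter, intensity variation along and between fibers, and
branching fibers. Passing the benchmark therefore demonstrates geometric
correctness of the pipeline — enhancement, fragmentation, regrouping,
scoring — under controlled degradation; it does not certify performance on
real micrographs, where threshold multipliers and the pairing bounds
typically need per-dataset adjustment.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `radius_r` | 11 | px | probe half-length; ~1.2 µm at 108 nm/px. Too small: insufficient averaging against noise. Too large: smears curvature and merges near-parallel structures. |
| `angle_step` | 5 | deg | sweep resolution; 36 angles, comfortably finer than the ~20° fan tolerance downstream. |
| `multiplier` | 1.0 | — | scale on the Otsu level; raise to segment conservatively. |
| `min_fragment_length` | 5 | px | fragments shorter than this are skeletonization noise. |
| `phi_max`, `psi_max` | 30 | deg | similarity / continuity bounds; set above the ~20° fan-angle resilience floor. |
| `d_max` | 16 | px | maximum allowable gap (~1.7 µm). |
| `search_radius`, `search_angle` | 16 px, 30° | | candidate fan; radius defaults to `d_max` but both are independently configurable. |
| `c_angle_weight`, `c_gap_weight` | 0.5, 0.5 | — | cost weights; equal by default. |
| `window` | 15 | px | orientation-field window. |
| `tol` | 3 | px | trace/path matching tolerance. |

## Numerical choices

* Angle grids cover (−90°, 90°] without duplicates; argmax ties (flat
  fields, symmetric corners) resolve to the smallest absolute angle, with a
  relative tolerance of 1e−9 so that floating-point jitter cannot flip a
  tie.
* Probe offsets are snapped to exact half-integers when within 1e−9 of one,
  and half-offsets round away from zero: sin 30° and cos 60° differ by one
  ulp around 0.5 in floating point, and without snapping, rotation-partner
  angles would sample different neighbors, breaking the 90°-rotation
  equivariance of the transforms.
* Out-of-bounds probe samples are dropped and the LFT mean renormalized by
  the in-bounds count, avoiding dark rims that would distort the Otsu
  threshold.
* Otsu class statistics are computed exactly per histogram bin (no bin-mid
  approximation); tied maximizing edges — which arise whenever an empty gap
  separates two modes — are averaged, centering the threshold in the gap.
* A constant map binarizes to an empty mask with a warning; an empty mask
  yields zero fragments and zero traces; a constant image yields the
  degenerate "no edge" width (level 1, flagged).
* Exports are deterministic: the same configuration and seed reproduce
  byte-identical CSVs.

## Benchmark scales

The test suite and the acceptance script run the full pipeline on the
512 × 512 scene with three noise seeds per scanned value, the scan grids
being roughly 6–12 values per parameter and 2 dB steps in PSNR. These sizes
were chosen so the entire benchmark reruns in minutes on one CPU while
keeping every scan's threshold estimate stable to one grid step.

## Known limitations

* Traces are simple open curves: branching fibers are split at junctions
  and reconstructed as separate fibers.
* The greedy pairing with fixed iteration order is faithful to the
  method's description but is not a globally optimal assignment.
* Fragmentation in this implementation is cleaner than in the original
  MATLAB-era realization of the method (minimal pruned skeletons, 1-px
  junction dilation), so the tip-to-tip gaps it must bridge are small
  (typically 4–8 px at PSNR 25) and the measured search-radius floor sits
  below the ~16 px the method's authors reported; the qualitative plateau
  structure is unchanged.
* No multiscale radius pyramid, no temporal linking across movie frames,
  no Poisson noise model.
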