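---
title: "Methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records how each statistic in cotranscoloc is defined, what
the synthetic generator does and does not emulate, and why the open design
choices were made the way they were. It states no empirical results beyond
what the test suite and `scripts/acceptance.R` themselves compute.

## The per-cell enrichment ratio

The headline image statistic asks: is a protein's immunofluorescence (IF)
signal elevated at the positions of a given mRNA? Per cell:

1. mRNA spots are restricted to the cytoplasm (2D mask containment on the
   spot's (y, x); z unrestricted). Cell and nucleus outlines are 2D while
   spots are 3D — the common design for thin adherent cells.
2. The IF stack is sampled at each spot's *nearest voxel* (no
   interpolation: the statistic is defined on pixel reads) and the median
   taken.
3. A normalization factor is the median IF intensity over the cytoplasm
   pixels across the inclusive z-slice range spanned by the spots.
4. The ratio of (2) to (3) is the cell's enrichment ratio.

Using medians on both sides makes the ratio robust to bright IF aggregates
and exactly invariant to any positive rescaling of the IF channel. A
`norm = "mean"` switch replaces the denominator with the cytoplasmic mean:
descriptions of this statistic alternate between the two and neither is
canonical, so both are implemented and the choice is recorded in the
output. The default is the median, consistent with the numerator.

Cells with fewer than `min_spots = 5` cytoplasmic spots are excluded (a
median over fewer reads is unstable); the threshold is configurable and
excluded cells are reported with their reason rather than dropped
silently.

Condition summaries are mean ± SD (n − 1) with a t-based 95% CI over cells
— each cell is one observation. Conditions are compared with the
two-sample Kolmogorov–Smirnov test: D is the sup-difference of the two
ECDFs at the pooled sample points, and the p value uses the asymptotic
Kolmogorov distribution at effective size `n_a n_b / (n_a + n_b)` with the
Stephens correction `λ = (√n + 0.12 + 0.11/√n) D`, matching the behaviour
of the widely used two-sample implementations. Exact small-sample p values
are deliberately not computed; per-cell ratios are continuous and the
per-condition n in this design (tens of cells) is where the corrected
asymptotic form is accurate. Calibration is verified by simulation in the
acceptance suite (null rejection rate at α = 0.05 inside the binomial 99%
band over 200 replicates).

## Dual-colour co-localization by gated assignment

Two detected point clouds (one per FISH colour) are matched one-to-one by
minimising the total Euclidean distance in physical nm, with pairs beyond
a gating radius `d_max` forbidden. The gate is built into the assignment
by augmenting the rectangular cost matrix with per-point dummy partners of
cost `d_max` (and forbidden entries set far above any feasible total), so
"unmatched" is a first-class outcome with a well-defined price: a pair is
formed exactly when it lowers the global objective
`Σ matched distances + d_max · #unmatched`. Because matching any gated
pair saves at least `d_max` over leaving both points unmatched, every
optimum matches as many pairs as the gate allows. The augmented square
problem is solved with the Hungarian algorithm (`clue::solve_LSAP`); tests
verify exact agreement of the objective with exhaustive enumeration over
all gated partial assignments on small clouds.

Defaults: `d_max = 300` nm — one z-step, the natural axial resolution
bound; the fraction's denominator is the first-listed (reference) channel.
Both are parameters and both are always reported in the output, since
neither has a single field-wide convention. Distances are computed in nm
so xy/z anisotropy enters through the coordinates (70 nm pixels, 300 nm
z-steps), not through weights. Among exactly tied optimal pairings the
solver's deterministic choice is returned; total cost and pair count are
identical across ties.

The randomization null redraws the second cloud uniformly in the cell's
cytoplasm (same count, z uniform over the observed extent) and recomputes
the fraction `n_perm` times; `p = (1 + #{null ≥ observed}) / (n_perm + 1)`.
This is an in-silico negative control for designs without a control mRNA
channel; it tests spatial association beyond density, not biological
specificity.

Chance co-localization is a density effect: with spot density λ (spots
per µm³) the expected fraction of reference spots with a random partner
inside the gate is ≈ `1 − exp(−λ · 4πd³/3)`. At the synthetic default
densities and `d_max = 150` nm this is ≲ 0.04; analyses at higher density
or wider gates should interpret fractions against the randomization null
rather than as absolute values.

## Spot detection

The detector is a standard single-molecule pipeline: difference-of-
Gaussians band-pass at the expected spot scale (σ_xy in pixels, σ_z in
slices — anisotropy is handled by separate sigmas, never by resampling
the data), 3D 26-neighbour local maxima with a positive band-pass
response and raw intensity ≥ threshold, duplicate maxima within 1 σ
merged keeping the brighter, and sub-voxel refinement. Two refiners are
available:

* `"gauss"` (default): a three-point parabola fitted to the log of the
  baseline-subtracted σ-smoothed intensity along each axis. For an
  isolated Gaussian peak this is the exact maximum-likelihood centre; the
  smoothed image is used so the fit is noise-damped.
* `"centroid"`: intensity-weighted centroid in a ±2 σ window after
  subtracting the window minimum. This is the simpler estimator but its
  window-truncation bias grows with the peak's sub-voxel offset; it is
  retained as an option and as the fallback where the parabola fit is
  ill-posed (borders, flat or non-concave log-profiles).

Spots whose refinement window is clipped by the stack border are flagged
`"border"`, not dropped — downstream analyses decide. Detection settings
are recorded verbatim in every `spot_set`, so analyses comparing
conditions can assert that identical settings were used. All-zero images
yield an empty spot set (not an error); implausibly dense detections
(> 2000 per megavoxel by default) raise a threshold-below-noise warning.

## Projection and segmentation

`focus_projection()` picks, per pixel, the z-plane maximising the local
intensity variance (window 15 px), restricted to ±1 plane around the
globally best-focused plane, ties to the lowest z. Local variance is the
simplest metric implementing a local + global focus criterion; the
projection preserves in-focus spot detail.

Mask estimation deliberately does **not** use the focus projection: a
max-like selector keeps single noisy samples in flat regions, which is
exactly wrong for thresholding. `mean_projection()` (noise reduced by
√nz) feeds the segmentation stages instead.

Nuclei: Otsu threshold on the (normalised) DAPI projection, hole filling,
distance-transform watershed to split touching nuclei, objects under
`min_area` removed, labels renumbered in scan order. Cells: the
CellProfiler-style secondary-object workflow — Gaussian smoothing (σ = 2
px), Otsu on the log-transformed image (the FISH channel is effectively
trimodal: extracellular background, diffuse cell body, bright spots; log
compression keeps the sparse bright tail from dominating the Otsu
criterion), then seeded region growing (`EBImage::propagate`) of the
nucleus labels across the foreground. Each cell inherits its seed label,
seeds are never merged, and a nucleus outside the foreground becomes its
own (degenerate) cell with a warning. Watershed/propagation tie-breaking
is the library's deterministic scan-order flooding.

Manually drawn outlines enter through `load_geometry()`: nuclei are
matched to cells by maximal overlap, pairs relabelled 1..K, orphan nuclei
rejected with reasons, nucleus pixels outside the matched cell clipped
(counted in the report), and cells without nuclei dropped. The function is
idempotent on its own output. Cells with empty cytoplasm are kept in the
masks but flagged non-analysable.

## RIP-qPCR calculus

Cp (crossing point) is the qPCR cycle at which fluorescence crosses
threshold; one cycle is a factor of 2 in template. The statistics:

* `percent_input = 100 · 2^[(Cp(input) − c) − Cp(IP)]` with `c = 6.644`
  by default. The constant encodes the input fraction and dilution
  (saving 10% of extract and diluting it 1:10 gives 1/100 of the IP's
  template, and `log2 100 = 6.6439 ≈ 6.644`); labs with other input
  fractions set `input_correction = log2(1/input_fraction)`.
* `fold_enrichment` (ΔΔCp[IP/mock]): with input Cp values available the
  input-normalised double delta; otherwise a single-delta fallback,
  flagged in the output. The notation does not fix which is meant, both
  are standard, and the output always records which was used.
* `relative_fold_enrichment`: ratio of two fold enrichments (target vs
  reference gene).
* `relative_expression`: reference-gene-normalised ΔΔCp between two
  conditions.

−RT controls (no reverse transcriptase) must sit at least 10 Cp above the
matched +RT reaction; a −RT reaction that never crossed threshold in the
run passes. Failing (gene, role) combinations are excluded from
aggregation by default. Technical replicates are averaged on the Cp (log)
scale — Cp is the measured quantity and ΔΔCp arithmetic lives on that
scale — then the statistic is computed per biological replicate, then
summarised as mean ± SD with per-replicate values retained. The order
(tech, then statistic, then bio) is declared, not inferred; it is
row-order invariant. Not-detected Cp values are `NA` throughout — a
distinct state, never a sentinel number.

## The synthetic generator

The generator exists to give every stage a known truth. Cells are
non-overlapping 2D ellipses (radii jittered 0.85–1× the nominal radius)
extruded over z, with concentric elliptical nuclei — matching the 2D-mask
/ 3D-spot analysis design. Spots are uniform in the cytoplasm, z uniform
inside an axial margin (2 slices). For two-colour scenes, exactly
`round(rho · n)` channel-b spots per cell sit at a channel-a partner
position plus per-axis Gaussian jitter truncated at 3 SD (so the stated
jitter genuinely bounds every partner distance), redrawn to stay inside
the cytoplasm. FISH channels render each spot as an anisotropic 3D
Gaussian (amplitude = peak value) over a low uniform in-cell background
(8/255 by default — real images have diffuse cellular background, and the
cell body must be visible for FISH-channel segmentation), plus Gaussian
camera noise, clipped to the bit depth with clipped-voxel counts reported.
The IF channel is flat background over the cell raised to `background · r`
within σ_xy (and σ_z axially) of each channel-a spot, so the true
enrichment ratio equals `r` by construction — enrichment is a factor, not
an additive bump, precisely so that the estimand is exact. DAPI is the
nucleus mask at a constant level. Optics defaults are 70 nm xy, 300 nm z,
8-bit.

Each operation draws from a single RNG stream seeded from its parameters
(`seed` for scene synthesis, `seed + 1` for rendering), and the caller's
RNG state is restored afterwards; identical parameters give bit-identical
scenes, stacks and tables.

The Cp simulator inverts the percent-input formula:
`Cp = base_cp − log2(template) + N(0, σ)`, with input template
`abundance · input_dilution` and IP/mock template
`abundance · efficiency`. The default `input_dilution = 2^−6.644` is the
formula's own constant, making the noise-free round trip through
`percent_input` algebraically exact. Default IP efficiencies (~15%) sit in
the range typical of efficient RIP experiments (roughly 7–25% of input);
mock efficiency is ~0.2%. −RT rows are placed 12+ cycles above the clean
+RT value, past the 10-cycle QC gap, and censored at 45 cycles.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: realistic PSFs (no Gibson–Lanni model; spots are
ideal Gaussians), autofluorescence and photobleaching, 3D nuclear texture,
cell-shape irregularity beyond ellipses, chromatic aberration between
colour channels, optical sectioning blur of the masks, and qPCR
amplification-efficiency differences between primer pairs. Recovery
results on this simulator validate the estimators' correctness, not their
robustness to those real-world effects.

## Problem sizes and scale

Synthetic scenes are desk-scale: cells of radius ~14–40 px (1–3 µm) in
stacks of ~50–220 px per side and 6–12 planes, tens of spots per cell,
scene counts of 20–30 cells per condition and 200 replicates for
calibration checks. Real adherent cells are orders of magnitude larger in
area (~2500 µm²) at much lower spot density (~0.01–0.1 spots/µm²); scene
defaults therefore compress geometry while keeping the statistics'
regimes honest. One consequence is documented in the ledgered tests:
segmentation accuracy is evaluated at a moderate density (25 spots per
radius-30 cell) because at the most compressed densities spot halos cover
most of the cell body, a regime denser than any real data. Likewise the
enrichment ratio at 50 spots per small cell carries a small (< 7%)
compression of the recovered `r`, because elevated spot neighbourhoods
occupy a non-negligible fraction of the tiny cytoplasm and lift the
normalization median — at real densities this fraction is vanishing.

## Numerical and degenerate-input conventions

Voxel `i` (0-based) covers `[i, i+1)` in pixel units with its centre at
`i + 0.5`; physical nm = pixel units × voxel size; nearest-voxel lookup is
`floor(nm / size)`. Masks are half-open pixel areas under the same
convention. Separable convolutions use zero padding (translation
equivariance away from borders); local variance windows are
edge-count-corrected. Single-plane stacks project to themselves with a
warning; constant images are a "no foreground" error for nuclei and a
ratio of exactly 1 for enrichment (any constant cancels); empty spot
clouds yield empty matchings, not errors; an empty reference cloud or a
zero normalization factor is an error naming the cell. Watershed,
propagation, LAP and all filters are deterministic; the only randomness
anywhere is explicitly seeded.
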