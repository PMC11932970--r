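---
title: "Quantifying microglial engulfment in 3D: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying microglial engulfment in 3D: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagoquant)
```

## The assay

Microglia remodel neural circuits by engulfing synaptic terminals, axon
segments and dying cells. The standard volumetric assay images tissue
sections as multi-channel confocal z-stacks — a pan-microglial marker
(Iba1), a lysosomal marker (CD68), and one neurite or synapse marker (VGAT,
VGLUT2, a tdTomato-labelled afferent, or cleaved caspase-3) — binarises each
channel, and measures volumes of overlap. The core readout is the nested
triple overlap

$$
\%\,\text{engulfed} \;=\; 100 \times
\frac{V(\text{marker} \wedge \text{CD68} \wedge \text{Iba1})}{V(\text{marker})},
$$

the fraction of total marker volume that sits inside lysosomes that are
themselves inside microglia. `phagoquant` implements this pipeline — I/O
with voxel metadata, geometric pre-processing, global thresholding, 3D
connected components, overlap volumes, per-animal aggregation — together
with an apoptotic-cell counting/mapping module and the statistical layer
used with this experimental design (two-way ANOVA with Sidak post-hoc
comparisons, Welch's *t*, and BCa bootstrap estimation of mean differences).
Because real imaging data are large and external, the package ships a
synthetic-volume generator with exact ground truth, so every stage is
testable end to end.

## Image model and conventions

A `channel_stack` is an intensity array indexed `(channel, z, y, x)` with a
physical `voxel_size` in micrometres. Conventions chosen where the assay
itself is silent:

* **Axis order** is `(channel, z, y, x)`; indices are R's native 1-based.
  Slice 1 in z is the imaging surface (`flip_z()` handles stacks acquired
  the other way up), which makes the adult depth rule a leading-axis slice.
* **Field-of-view crop** (`crop_xy`): a physical target (typically
  192 µm) converts to `floor(target/dx)` pixels and the window is centred;
  an explicit offset reproduces specific placements. Flooring standardises
  the pixel-grid rounding that arises when the target is not an integer
  multiple of the pixel size.
* **Depth rule** (`crop_top_z`): adult sections keep the first
  `ceil(depth/dz)` slices (inclusive of a partial slice) from the imaging
  surface, reflecting limited antibody penetration; neonatal sections are
  analysed at full thickness. At the 63x preset (dz = 0.23 µm) a 5 µm rule
  keeps 22 slices.
* Volumes are always voxel counts times `dx·dy·dz`; masks are hard sets
  with no partial-voxel weighting.

TIFF I/O uses a JSON sidecar for voxel size, channel names and the
intensity scale (baseline TIFF in R stores 32-bit fixed point on [0, 1];
integer data round-trip bit-exactly). OME-XML `PhysicalSize` metadata is
parsed when present, and an explicit override always wins; a stack with no
voxel-size source is an error, never a silent default.

## Segmentation

Thresholding is **global per channel per 3D stack** (no per-slice
thresholds): the default is Otsu's criterion over 256 levels spanning the
data range, with `fixed` and `quantile` alternatives for sensitivity
analyses; the applied threshold is recorded in the mask and in the run
report. A constant image is a hard error under Otsu — an all-true or
all-false mask would silently corrupt downstream volumes.

Connected components (`label_components`) use 26-connectivity by default
(the common 3D-ROI convention; 6-connectivity available) on the voxel
adjacency graph. Components under `min_voxels = 10` are discarded to
suppress shot-noise specks; the filter is configurable and logged. Note the
overlap volumes themselves are computed from the full masks — the component
stage serves ROI tables and blob counting.

Two overlap metrics are emitted per section: the primary triple overlap
(marker ∧ CD68 ∧ Iba1) and a secondary contact volume (marker ∧ Iba1,
irrespective of lysosomal localisation), since "overlap with microglia" is
ambiguous between the two readings and the difference is biologically
meaningful (contact without engulfment).

**Aggregation.** Animals, not sections, are the experimental unit: each
animal's sections (at least 6 by default) are averaged before any
statistics, and animals under the section minimum are excluded with a
warning.

## The synthetic generator

`make_section()` draws true binary structures and renders them through a
standard fluorescence forward model:

* **Cells** (Iba1): spheres (soma radius 2.5–3.5 µm) with 3–5 branches,
  each a jittered random-walk skeleton dilated to a 0.6–1.0 µm radius.
  This is a morphological cartoon — containment guarantees and plausible
  volume fractions are the design goals, not microglial realism.
* **Lysosomes** (CD68): 4–7 spheres of 0.8–1.2 µm radius per cell, placed
  so the whole sphere fits inside the cell (erosion-based sampling; one
  radius drawn per cell so a single erosion suffices).
* **Puncta** (marker): spheres of 0.35 µm radius at 40 per 1000 µm³. A
  controlled fraction (default 0.04) is *engulfed* — placed so the whole
  punctum fits inside the lysosome-in-cell mask — and the rest placed
  entirely outside the cell mask. The realized voxel-overlap fraction then
  equals the requested count fraction up to punctum–punctum overlap, and
  the generator records it as ground truth. Defaults put percent engulfed
  in the low single digits, the regime this assay typically reports.
* **Optics**: anisotropic Gaussian PSF blur, constant background (0.02),
  Poisson shot noise (150 photons at unit intensity) and Gaussian read
  noise (sd 2 photons). The default PSF sd, (z, y, x) = (0.45, 0.12, 0.12)
  µm, follows diffraction theory for a 1.0-NA confocal at ~520 nm emission
  (lateral FWHM ≈ 0.28 µm, axial ≈ 1.1 µm); real synapse stacks in this
  assay are usually deconvolved before analysis, so the sharp end of the
  realistic range is the right default. An over-blurred sensitivity
  setting, e.g. `optics_params(psf_sigma_um = c(0.7, 0.25, 0.25))`,
  degrades small-punctum segmentation markedly (mask inflation ≈ 4.5×) and
  is useful for stress-testing.

`make_cohort()` builds full factorial cohorts over sex × neonatal incision
× adult incision with additive group shifts on the engulfed fraction,
puncta density and cell scale, between-animal and within-animal
variability (CVs, defaults 0.2 and 0.1), and latent fractions clipped to
[0, 1] with a flag. All randomness descends from one master seed through a
documented splitting scheme (`split_seed`), so per-animal and per-section
draws are independent streams and cohorts extend without disturbing
earlier draws.

**Two truth pathways.** With `render = "full"` every section is rendered
and the ground-truth masks travel alongside the stack (the analysis can be
run with segmentation bypassed — the oracle path — or with real
segmentation). With `render = "none"` no voxels are built, but each
section still realizes its Poisson puncta count and binomial engulfed
count, so per-section fractions carry realistic counting noise; this is
the fast ground-truth pathway used for power simulations at hundreds of
replicates.

`make_apoptosis_sections()` emulates the apoptosis arm: per-section counts
are Poisson (defaults 0.30 and 0.53 cells/section for control and
incision, putting the group difference at the scale such cohorts report),
and locations are drawn from a three-component Gaussian hotspot mixture on
a unit half-ellipse hemisection template (superficial lateral dorsal horn,
central canal, ventral horn). The anatomical outline is not digitised;
normalized (u, v) coordinates come from the template directly, and mapping
real sections would require user-supplied landmarks (out of scope).

## What passing synthetic tests do and do not show

The generator reproduces the *geometry* of the assay — nested compartments,
sparse sub-resolution puncta, anisotropic sampling, shot/read noise — so
recovery tests validate the measurement chain: exact overlap arithmetic,
threshold behaviour, volume bookkeeping, aggregation and statistics. It
does not emulate tissue autofluorescence, uneven staining, vasculature,
section damage, registration error, or real microglial morphology; passing
tests therefore say nothing about segmentation quality on such artefacts,
and the section-quality screening the real assay does by eye has no
synthetic counterpart.

With the default optics, full segmentation recovers per-animal percent
engulfed within a few percent relative (slight overestimate from blur
halos at lysosome borders) and preserves group rank order; under the
over-blurred sensitivity setting recovery degrades to roughly −25%
relative bias, which is worth keeping in mind when comparing absolute
percentages across acquisition settings. Group *differences* are far more
robust than absolute values, which is one reason the statistical layer
works on within-cohort contrasts.

## Statistical layer

* **Two-way ANOVA** (`two_way_anova`): full factorial linear model; Type
  III sums of squares with sum-to-zero contrasts for unbalanced data
  (matching the conventions of the graphing packages this assay is usually
  analysed with; on balanced data all types coincide, which is how the
  implementation is validated against textbook cell-means formulas). A
  constant response returns F = 0 everywhere rather than 0/0.
* **Sidak post-hoc** (`sidak_adjust`): \(p_{\mathrm{adj}} = 1-(1-p)^m\).
  The comparison family is explicit configuration, never inferred; the
  default set for the 2×2 incision design is the four within-row/column
  pairs (e.g. IN(−,−) vs IN(+,−), IN(−,+) vs IN(+,+)).
* **Welch's t** (`welch_t`): unequal-variance statistic with
  Welch–Satterthwaite df.
* **BCa bootstrap** (`bca_ci`): estimation-statistics companion for the
  mean difference, default 5000 resamples at the 95% level. Groups are
  resampled independently; bias correction \(z_0\) from the proportion of
  bootstrap statistics below the point estimate; acceleration \(a\) from
  the pooled leave-one-out jackknife skewness; endpoints by
  normal-quantile interpolation of the order statistics. The seed is a
  mandatory argument — no hidden global RNG state. Degenerate inputs give
  a zero-width flagged interval; zero-variance jackknife falls back to
  \(a = 0\).

Sexes are pooled for estimation plots while remaining a factor in the
ANOVA; both pathways are provided and the run report records which was
used, along with alpha, the bootstrap size and the seed.

**Known limitation.** BCa intervals have \(O(1/n)\) coverage error: at
n = 10 per group with normal data the 95% interval covers at ≈ 92% (the
package's Monte-Carlo estimate, consistent with the reference
implementation in `boot`). At the animal numbers typical for this design
(n ≈ 5–10 per group), BCa intervals should be read as slightly
anti-conservative.

## Numerical choices

* Pixel conversions guard against binary representation error
  (`192/0.3` must be exactly 640): a 10⁻⁹ epsilon inside `floor`/`ceil`.
* Component ties (equal voxel counts) are ordered by centroid
  lexicographic order so ROI tables are deterministic.
* The separable Gaussian blur renormalises truncated kernels at the
  volume boundary rather than padding, so rendered intensity is conserved
  near edges.
* Integer sub-seeds stay below 2³¹ (a multiplicative-congruential hash).
* Lysosome placement retries with a shrinking radius (5 attempts) before
  raising an error; puncta that cannot be placed are a hard error, never
  silently dropped.

## Problem sizes used by the test-suite simulations

Chosen to exercise each property at meaningful precision: overlap oracle
checks on ~100 random volumes up to 32³; a rendered 2×2 factorial recovery
cohort of 4 animals × 6 sections per group at 128 × 128 × 24 voxels; power
simulation with 200 ground-truth replicates (16 animals each); ANOVA
type-I error over 2000 null replicates; BCa coverage over 1000 replicates
at 5000 resamples; apoptosis mapping over 50 seeds. The same quantities
are recomputed from scratch by `scripts/acceptance.R`.
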