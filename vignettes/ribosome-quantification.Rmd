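---
title: "Quantifying ribosomes in resin-section electron tomograms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying ribosomes in resin-section electron tomograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribotomo)
```

## The measurement problem

Ribosomes are dark, roughly spherical, 20–30 nm particles in stained,
resin-embedded electron tomograms. Counting them per unit cytoplasmic
volume, and scaling that density up to a whole cell, requires a chain of
corrections that this package implements end to end:

1. **Segmentation** of ribosome-sized globular particles in a 3D volume,
   with size, edge-contact and flatness gates.
2. **Beam-collapse correction.** Plastic sections collapse along Z in the
   electron beam, so the reconstructed stack is thinner than the section
   that was cut. A *shrinkage factor* — the ratio of initial (cut) to
   calculated (reconstructed) thickness — repairs the resulting density
   overestimate. The shipped default, `EPON_ARALDITE_SHRINKAGE = 1.575`,
   is the mean over 77 stitched Epon/Araldite serial-section datasets and
   is resin-specific; override it via `shrinkage_factor()` with your own
   thickness records when using another embedding medium.
3. **Cell-volume measurement** from confocal membrane/nucleus stacks, with
   a 10% organelle correction:
   $V_\mathrm{cyto} = (V_\mathrm{cell} - V_\mathrm{nuc})(1 - f_\mathrm{org})$.
4. **A biochemical cross-check**: 18S/28S rRNA peak areas from capillary
   electrophoresis, ladder-calibrated to concentrations and converted to
   molecules per cell by
   $N = c \cdot V_\mathrm{elu} \cdot N_A / (M \cdot n_\mathrm{cells})$.

Every stage is testable offline because the package ships a
synthetic-tomogram generator with exact ground truth.

## The size gates and where 25–830 voxels come from

A 30 nm sphere has volume $\tfrac{4}{3}\pi 15^3 \approx 14{,}137$ nm³. At a
2.572 nm pixel a voxel holds $2.572^3 \approx 17$ nm³, so a ribosome can
occupy at most about 830 voxels — the upper gate. For the lower gate, a
20 nm sphere squashed by the Z collapse occupies about
$\tfrac{4}{3}\pi 10^3/1.575 \approx 2{,}660$ nm³, i.e. 156 voxels:

```{r bounds}
voxel_count_bounds(ribosome_geometry(20, 30, 2.572), shrink = 1.575)
```

In practice stained ribosomes measure smaller than their nominal size, so
the working lower thresholds are the empirical 25/50/100 carried by
`segmentation_params()`; `run_pipeline()` always reports counts at all
three so the threshold dependence stays visible, exactly as the density
results should be read.

## Segmentation chain

`run_pipeline()` executes, in fixed order: intensity inversion (stained
particles become bright maxima), a true-median denoise over a cubic kernel
whose 7.72 nm diameter equals 3 voxels at the default pixel size, blob
detection, a touching-edge filter on the two Z faces only (an object cut
by the section surface has a truncated volume; XY-edge objects are kept),
a plane-count filter (`> 1` removes flat artefacts), and voxel-count
gating. Each filter returns a subset of its input objects; the final label
volume is gated at the smallest lower threshold so exported object tables
can be re-gated without re-segmentation.

### The blob detector

The reference workflow used a closed-source "blob finder" parameterised by
diameter, probability threshold and split sensitivity. This package
implements those semantics with a fully specified open equivalent:

* **Response.** A multiscale difference-of-Gaussians filter, scales
  geometric (ratio 1.6) from 1 voxel up to the blob radius over
  $\sqrt{3}$, maximum-projected over scales. Bright globular objects up to
  the configured diameter score highly.
* **Normalisation.** The response is converted to z-scores against a
  background-noise scale estimated from its 10th–30th percentile spread.
  Lower quantiles are used deliberately: at the upper end of biological
  densities (~25,000 particles/µm³) particles occupy tens of percent of
  the volume and would contaminate a median/MAD estimate, whereas the
  lower tail remains background-dominated up to very high volume
  fractions.
* **No-signal gate.** If the maximum z-score stays below 12 the volume is
  declared empty. On pure-noise volumes of desk-scale size the maximum
  smoothed-noise z-score stays near 8, while particles at signal-to-noise
  ≥ 5 score above 20, so the gate separates the two regimes with margin on
  both sides without any per-volume tuning.
* **Threshold.** Voxels with $z \ge p \cdot z_\max$ are kept, where $p$ is
  `probability_threshold` (default 0.30). Higher thresholds give fewer,
  tighter detections.
* **Splitting.** Connected regions are flooded in order of decreasing
  response. A fresh regional maximum opens a candidate particle; where two
  candidates meet, they are merged if the saddle lies less than
  $(1 - s)$ of the shallower peak's height (measured above the region's
  response floor) below that peak, with $s$ = `split_sensitivity`. At
  $s = 0$ touching particles are never split; at the default $s = 0.7$ a
  dumbbell of two just-touching 25 nm spheres is split into two. Anchoring
  the cutoff to each peak rather than to the whole connected region keeps
  splitting effective in dense fields, where a multi-particle cluster's
  total response range would otherwise swamp every individual saddle.

All image kernels (median, separable Gaussian, 26-connected labelling,
watershed flooding) are compiled code, so a ~1-million-voxel subvolume
segments in about two seconds.

## Applying the collapse correction exactly once

The shrinkage correction has two algebraically equivalent formulations:
divide the measured density by the factor, or multiply the Z voxel size by
it. Applying both silently compounds a ×1.575² ≈ ×2.5 error. The package
therefore treats the division form (`density_per_um3()`) as canonical,
offers the metadata form as `correct_z_voxel_size()` which stamps the
volume, and refuses to divide a stamped volume a second time.

```{r collapse-guard, error = TRUE}
vol <- volume_image(array(0, c(4, 4, 4)), 2.572)
vol <- correct_z_voxel_size(vol, 1.575)
density_per_um3(100, vol, shrink = 1.575)
```

## What the synthetic generator emulates — and what it does not

`generate_tomogram()` renders solid dark spheres (diameters uniform in
20–30 nm) at rejection-sampled non-overlapping positions on a light
background, smoothed by a ~1-voxel Gaussian to mimic the soft edge of
stained particles, optionally squashed along Z by a known collapse factor
(linear interpolation; collapse is treated as a thickness-only effect),
plus additive Gaussian noise. Defaults follow the imaging regime the
pipeline targets: 2.572 nm pixels, nominal SNR 5 (contrast 60 over noise
SD 12), and densities in the 5,000–25,000/µm³ range observed across cell
types. The requested density times the physical volume, rounded, *is* the
ground-truth count, so recovery is measured against construction rather
than against another detector.

The generator deliberately omits: tilt-series acquisition, the missing
wedge and reconstruction artefacts; background texture from ribosome-free
cytoplasm (the noise model is an uncorrelated stand-in, since the
granularity of real cytoplasm is not characterised in the protocol this
package follows); membranes and organelles beyond simple dark ellipsoid
distractors; and any ribosome sub-structure. Passing recovery tests on
these volumes therefore demonstrates that the *quantification chain* is
correct and unbiased under its stated assumptions — not that the detector
would reach the same absolute accuracy on real tomograms, where the
closed-source reference detector also cannot be matched bit for bit.

A known, deliberate bias: the touching-edge filter removes genuinely
present particles whose masks touch the top/bottom section face, biasing
densities slightly low. The effect scales inversely with section
thickness (~11% of objects in a 52-plane stack, ~4% at 160 planes); the
reference protocol carries the same uncorrected bias. Validation of the
collapse round-trip therefore uses a thick stack (252 pre-collapse
planes) so this surface effect does not mask the correction being tested.

## Numerical choices and degenerate inputs

* Bounds 830/156 are floors of the real-valued quotients; the printed
  "about 830"/"156" match floor at printed precision.
* The shrinkage factor is oriented so that collapsed extent × factor =
  initial thickness (i.e. initial/calculated); a factor < 1 warns but does
  not fail.
* `apply_collapse()` resamples voxel centres (`(j+0.5)·nz/nz' − 0.5`) and
  leaves the voxel-size metadata stale on purpose — that *is* the defect
  the correction repairs.
* Median kernels snap to the nearest odd voxel diameter (minimum 1);
  rank 50% is an exact median, with the even-count midpoint averaged.
* Peak integration uses a trapezoid rule with a straight-line baseline
  between the user's bounds (mirroring manual baseline adjustment) and
  clips negative excursions at zero; tie-breaks and grids are inherited
  from the strictly increasing position vector enforced by
  `electropherogram()`.
* Degenerate inputs fail loudly: impossible particle packings, blob
  diameters under one voxel, blank confocal stacks, inverted integration
  bounds, nuclear volume exceeding cell volume, RIN exactly at the gate
  (excluded — the gate is strict).
* `segment_stack()` thresholds with 2-means seeded at the 5th/95th
  intensity percentiles (deterministic), fills holes in 3D, keeps the
  largest component, and in membrane ("cell") mode erodes one voxel to
  remove the stain halo that a half-intensity contour adds outside the
  true surface.

## Molar masses for the rRNA cross-check

The subunits-per-cell equation needs 18S and 28S molar masses, which the
quantification protocol does not print. The shipped defaults derive from
human rRNA lengths (1,869 and 5,070 nt) at a mean nucleotide mass of
320.5 g/mol and are explicit, overridable constants (`RRNA_MOLAR_MASS`).
Measured concentrations are stored as-read from the instrument; the 1:50
dilution is reversed through explicit metadata
(`rna_sample(dilution_factor = )`), never inferred from magnitudes.

## Problem sizes used in the shipped validation

The test-suite volumes range from 30×80×80 to 252×150×150 voxels
(~0.005–0.1 µm³, 45–500 particles), chosen so that each property is
exercised at the density regime it concerns while a full run of the suite
stays in the low minutes on a single CPU. The Monte-Carlo power check for
the Welch comparison draws 1,000 replicate pairs of n = 20 groups from the
published distal-gonad means and standard deviations (20,618 ± 3,566
versus 12,817 ± 4,956 per µm³).

## Known limitations

* The detector is behaviourally, not bit-for-bit, equivalent to the
  commercial blob finder; absolute densities on real tomograms will
  differ at the percent level even with identical gates.
* Collapse is modelled as pure Z-resampling; lateral beam effects are not
  simulated.
* The organelle fraction is a single scalar (default 0.10); if real
  non-ribosomal compartments occupy more, whole-cell totals are
  overestimated proportionally.
* The edge-filter surface bias is reported, not corrected; thin sections
  should be interpreted with that in mind (or measured with a guard-zone
  estimator, which this package does not implement).
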