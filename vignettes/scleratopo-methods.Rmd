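---
title: "Artefact-free corneoscleral topography: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Artefact-free corneoscleral topography: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scleratopo)
```

## The measurement model

A corneoscleral profilometer returns a scattered elevation cloud
$(x_i, y_i, z_i)$ in mm over a disc of up to 20 mm diameter, with the
optical axis roughly along $z$. Three facts shape the pipeline:

* the eye fixates a near target during the scan, so the measured surface is
  tilted by a few degrees in an eye-specific way;
* the anterior surface of a healthy eye is convex everywhere, cornea and
  sclera having distinctly different curvatures that meet at the limbus
  (horizontal visible iris diameter about 12 mm);
* the scan periphery is contaminated by lid, lash and tear-film artefacts
  that are not anatomy and must be removed before any statistic is taken.

All analysis happens per meridian: the cloud is resampled onto 1° angular
sectors and a 0.05 mm radial grid (`resample_polar()`), with the nasal
meridian at 0° for both eyes after the anatomical-frame conversion
(`to_anatomical_frame()` re-signs $x$ for left eyes; right and left eyes
are never pooled and no mirror symmetry is assumed).

## Levelling about the limbus

Along a meridian the slope $z'(r)$ grows from zero at the apex, peaks just
before the limbus, dips across it and grows again on the sclera; the limbus
is therefore the turning point of $z''(r)$. `detect_limbus_meridian()`
smooths $z(r)$ with a Gaussian kernel ($\sigma = 0.15$ mm), forms $z''$ by
central differences, and takes the *innermost* interior extremum of
$z''$ deviating from the window's median by at least six median absolute
deviations, refined to sub-grid precision with a parabola. Design notes:

* the transition is always a *positive* excursion of $z''$ (slope steps
  from the steeper cornea to the flatter sclera), which rejects
  noise-driven negative dips;
* *innermost* matters: peripheral artefacts create their own curvature
  excursions further out, and the first transition beyond the cornea is the
  limbus;
* a single sphere has no interior extremum and correctly yields
  "limbus not found"; detections outside a 3–9 mm plausibility band are
  flagged and excluded from the plane fit.

Detected radii are smoothed circumferentially with an 11-meridian circular
moving median (the limbus is a smooth anatomical curve; isolated detection
outliers should not bend the plane). The limbus points are fitted with a
total-least-squares plane (SVD), and the tilt angles follow from the
inverse cosine of the dot products of the unit normal with the $y$ and $x$
unit vectors, $\alpha_x = -\pi/2 + \arccos(N_y)$ and
$\alpha_y = -\pi/2 + \arccos(N_x)$, with $\alpha_z = 0$: a level plane
gives $(0, 0)$, and $N = (0, \sin t, \cos t)$ gives $\alpha_x = -t$.
(Dotting the normal with $(0,0,1)$ instead, a formulation sometimes seen
for the second angle, returns $-\pi/2$ for a perfectly level eye and
cannot drive a levelling loop; the second angle must mirror the first.)

`level_eye()` applies $R_y(\alpha_y) R_x(-\alpha_x)$ and iterates a purely
geometric inner loop — rotating the *same* limbus points and refitting
their plane — until the refitted normal is vertical to $10^{-6}$ rad,
then re-detects once on the levelled surface. The split matters: the
geometric loop converges quadratically, whereas re-detection has a noise
floor around $10^{-3}$ rad that would make a 1e-6 tolerance unreachable.
Finally the origin moves to the apex, located as the maximum of a local
quadratic fit over a 0.5 mm neighbourhood of the highest sample (grid-free
and robust to micrometre noise); an apex on the boundary of the lateral
support aborts processing, because the measurement was decentred.

## Edge-effect elimination

Two strategies run per meridian, both restricted to radii beyond the
detected limbus plus a 0.25 mm guard band (the limbal transition itself
must never be classified as an artefact):

1. **Moving-median slope screen.** The absolute first derivative
   $|dz/dr|$ is screened by a sliding-window statistic whose window is
   capped both at $\pm 0.1$ mm in radius and at 11 elements, shrinking at
   the meridian ends. The robust default statistic is the median; the
   windowed *mean* (the literal averaging formula) is available as an
   option and both are tested against a brute-force oracle. Where the
   screen exceeds three times its own mean, a first cutting edge fires.
   The threshold baseline is computed over the post-limbus portion only —
   a full-meridian baseline (also available) would be inflated by the
   steep limbal slope and mask artefacts.
2. **Pre-edge elevation minimum.** Artefacts that blend in smoothly can
   defeat the slope screen, but they still turn the convex profile upward
   and leave a local elevation minimum. The innermost strict local minimum
   before the first edge (or anywhere beyond the limbus when no first edge
   exists) with prominence of at least 20 µm becomes the second cutting
   edge. "Innermost" resolves the ambiguity between radius- and
   value-ordering in favour of the most conservative cut, and the 20 µm
   prominence floor ignores noise wiggles.

The *ultimate* cutting edge is the defined candidate closest to the apex;
all nodes at or beyond it are invalidated, never interpolated over. A
surface with more than half of its meridians fully cut is rejected as
unusable. In practice the two strategies are complementary: plateauing
lift-offs and tear pools are caught by the elevation minimum at their
onset, while sustained ramps and lash spikes trip the slope screen.

## Reference sphere and relative elevation

The scleral annulus (limbus + 0.25 mm out to each meridian's cut — by
construction artefact-free) is fitted with a sphere minimising the squared
algebraic residual $\sum_i ((X_i-X_c)^2 + (Y_i-Y_c)^2 + (Z_i-Z_c)^2 -
R_s^2)^2$. The linear (Kåsa) solution is in fact the exact global minimiser
of this objective; a Levenberg-style refinement is still run (step
tolerance $10^{-10}$ mm) so that the geometric-distance objective — fitted
orthogonal distances, available via `objective = "geometric"` — shares the
same code path. Relative elevation is $Z_i - Z_{si}$ with the upper-sheet
sphere height; the quadrants used for correlating a sclera against the
11.5 mm anatomical reference are 90° sectors centred on the nasal,
superior, temporal and inferior meridians (sector width is a package
choice; no standard exists).

## Asymmetry statistics

Elevation (raw or relative) is sampled at radius 8 mm by linear
interpolation between bracketing valid nodes — never across a cut — and
differenced as $v(\theta) - v(\theta - 180°)$ for $\theta \in [0°, 179°]$.
Group aggregation is missing-aware (each angle reports its contributing
eye count). Per meridian, the two samples $\{v_e(\theta)\}$ and
$\{v_e(\theta-180°)\}$ are compared with Welch's two-sample t-test
(pooled-variance optional), two-sided, decision $= 1$ iff $p < 0.05$
strictly; per-angle p-values are reported raw, mirroring ophthalmic
practice, with a Benjamini–Hochberg column provided for reference but never
driving the decision.

**Locating the maximum-asymmetry meridian.** The mean-difference profile is
a smooth function of angle estimated at 180 points with nearly independent
micrometre-scale errors. Near its (flat) maximum, the signal deficit two
or three degrees away is smaller than the estimation noise, so the raw
argmax jitters by several degrees no matter how many eyes contribute. The
package therefore locates the maximum on an antiperiodically extended
9° circular moving average of the mean profile — unbiased in position for
a symmetric peak, amplitude bias under 0.5% — and also reports the raw
argmax (`argmax_raw_axis_deg`). The reported label follows the signed,
nasal-referenced convention: the angle is given on the side of the axis
where the mean difference is positive.

## The synthetic eye: what it emulates, what it does not

`generate_eye()` builds a conicoid cornea (apical radius 7.8 mm,
asphericity $Q = -0.25$, the standard prolate physiological value) joined
C0 at limbus radius 5.95 mm (HVID ≈ 11.9 mm) to an 11.5 mm scleral
sphere; the curvature discontinuity at the junction is exactly the signal
the limbus detector exploits, and a configurable C1 blend zone exists to
test detector robustness. Defaults: 120 000 surface points (the instrument
class delivers > 250 000; 120 000 keeps every 1° × 0.05 mm cell
supported), 5 µm Gaussian height noise applied along $z$ after tilting
(a profilometer measures height), tilt 0 unless planted.

Asymmetry harmonics modulate scleral height as
$a\cos(k(\theta - \phi))$, faded in with a smoothstep between 0.75 and
1.75 mm beyond the limbus. The fade placement is deliberate: a fade
starting at the limbus perturbs the detected limbal radii, tilts the
fitted plane, and the levelling then silently absorbs up to a third of the
planted asymmetry — the planted signal must be orthogonal to the
levelling degrees of freedom for ground-truth comparisons to be meaningful.

Artefacts: `liftoff` ramps up over `ramp_width` and plateaus at its
amplitude (a lifted tear/lid surface); `tearpool` drops sharply within a
few hundredths of a millimetre of its onset and recovers slowly, so the
elevation minimum sits at the onset; `lash_spike` is a narrow
high-amplitude bump. Amplitudes of 0.3–0.6 mm with onsets at 6.8–8 mm
reproduce the qualitative morphology seen in clinical scans.

What the generator does *not* emulate: tear-film optics and fluorescein
physics, blink-to-blink variability, fixation drift within a scan,
non-spherical (e.g. toric) scleral shape beyond the planted harmonics, and
the vendor's proprietary preprocessing. A green test establishes that the
pipeline recovers planted geometry under realistic sampling and noise — not
that clinical scans satisfy the generator's assumptions.

## Numerical choices and degenerate inputs

* Resampling interpolates each angular sector with monotone
  piecewise-cubic interpolation (Fritsch–Carlson), falling back to linear
  below 4 points; points closer than a fifth of the radial step are
  averaged first, because near-coincident noisy knots give the Hermite
  scheme enormous tangents and oscillations of ~100 µm. Nodes without a
  data point within one radial step, or outside the sector's radial span,
  are invalid — never extrapolated. Interior sampling voids are bridged
  linearly for differentiation only; meridians more than 25% void are
  skipped.
* The radial step (0.05 mm) guarantees the 0.1 mm moving-window half-width
  spans at least two nodes; sectors do not overlap, keeping meridians
  statistically independent for the t-tests.
* Sphere fits reject coplanar point sets (smallest singular value below
  1 µm-scale) and fewer than 10 points; `sphere_height` errors outside the
  lateral footprint unless asked to return `NA`.
* Zero-variance t-test inputs: equal means give $p = 1$, unequal means
  $p = 0$; groups below $n = 2$ skip the test. The decision at exactly
  $p = 0.05$ is 0.
* All angles are stored in degrees in $[-180°, 180°)$; meridian labels
  follow the signed nasal-referenced printing convention.

## Known limitations

* The limbus detector assumes the scleral curvature is flatter than the
  corneal one at the junction (true of healthy eyes; post-surgical
  geometry may violate it).
* Strategy 1's threshold baseline includes the artefact zone itself; very
  extended artefacts raise their own threshold. Strategy 2 and the
  ultimate-edge minimum limit the damage, but a meridian that is mostly
  artefact can keep spurious data.
* Sampling at a fixed 8 mm radius requires the cut to reach past 8 mm;
  heavily trimmed meridians go missing from the asymmetry profile, and the
  annulus-mean sampling mode is the fallback for such data.
* The per-eye pipeline costs a few seconds per 10^5-point cloud in pure R;
  cohort-scale batching is linear and embarrassingly parallel, but no
  parallel backend is built in.
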