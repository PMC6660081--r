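# scleratopo

Artefact-free processing of corneoscleral topography and quantification of
scleral asymmetry.

## The problem

Modern anterior-eye profilometers measure elevation over a disc of up to
20 mm diameter — cornea, limbus and a ring of exposed sclera. The scleral
periphery of such scans is routinely contaminated by *edge effects*: tear
pooling at the lid margins, lid and lash interference, and instrument
limits produce surface regions that are not ocular anatomy. Any statistic
computed from the raw periphery (for example scleral asymmetry, the key
quantity in scleral contact-lens fitting) inherits those artefacts.
`scleratopo` implements a fitted-parameter-free pipeline that

1. **levels** each eye about its own limbus: the limbus is detected per
   1° meridian as the turning point of the elevation's second derivative
   `z''(r)` (the cornea and sclera have different curvatures), the detected
   points are fitted with a total-least-squares plane with unit normal
   `N = (Nx, Ny, Nz)`, and the surface is rotated by the tilt angles

   ```
   alpha_x = -pi/2 + acos(N . (0, 1, 0))
   alpha_y = -pi/2 + acos(N . (1, 0, 0)),   alpha_z = 0
   ```

   then re-origined at the apex;
2. **removes edge effects** per meridian with two complementary
   strategies: a moving median (0.1 mm half-window, at most 11 elements,
   shrinking at the ends) of the absolute slope `|dz/dr|` screened against
   three times its mean (strategy 1), and the innermost pre-edge elevation
   minimum (strategy 2); the *ultimate cutting edge* is whichever detected
   edge lies closest to the apex, and everything beyond it is discarded;
3. **fits the best-fit scleral sphere** by least squares on the trimmed
   scleral annulus, minimising
   `sum_i ((Xi-Xc)^2 + (Yi-Yc)^2 + (Zi-Zc)^2 - Rs^2)^2`, and maps the
   relative elevation `Zi - Zsi` with
   `Zs = Zc + sqrt(Rs^2 - (x-Xc)^2 - (y-Yc)^2)`;
4. **quantifies scleral asymmetry**: elevation sampled at radius 8 mm per
   meridian, differenced against the opposite meridian
   (`diff(theta) = v(theta) - v(theta - 180)`, nasal meridian at 0°),
   averaged over eyes, with per-meridian Welch two-sample t-tests and a
   binary decision at the 95% level.

Because clinical scans are rarely shareable, the package also ships a
synthetic-eye generator (aspheric cornea, C0 limbal junction at radius
5.95 mm, 11.5 mm scleral sphere, planted tilt, harmonic asymmetry, noise
and edge artefacts) whose ground truth makes every stage testable.

## Worked example

```r
library(scleratopo)

# a synthetic right eye: 3.0 / -2.0 degrees of tilt, lid lift-off beyond
# 7.5 mm on the superior side, 5 um measurement noise
rec <- eye_recipe(tilt = c(3, -2),
                  artefacts = list(artefact_spec("liftoff", 7.5, c(40, 140))),
                  seed = 7)
eye <- generate_eye(rec)

pe <- process_eye(eye$cloud)
pe$limbus
#> <limbus_fit> mean radius 5.965 mm, tilt (3.010, -2.007) deg, 360/360 meridians accepted
pe$sphere
#> <sphere_fit> centre (0.0099, -0.0033, -12.4326) mm, Rs = 11.5000 mm, rms 2.94e-03 mm, n = 21116
table(pe$edges$strategy_fired)
#>    2 none
#>  101  259
```

The levelling stage recovered the planted (3, −2)° tilt to within 0.01°,
99% of the 360 limbal detections sit within ±0.1 mm of the planted 5.95 mm
junction, the best-fit scleral sphere radius matches the planted 11.5 mm to
four decimals (its centre depth −12.43 mm is the C0-continuity position),
and the 101 meridians inside the lift-off sector were cut by the pre-edge
minimum strategy at the planted onset.

Group analysis over a cohort:

```r
co <- generate_cohort(50, list(asymmetry_harmonics = list(c(1, 0.1, -38))),
                      seed = 601)
profs <- lapply(co, function(e)
  asymmetry_profile(process_eye(e$cloud)$raw_at_r, "raw"))
g <- aggregate_group(profs)
g
#> <group_asym> basis raw (r=8mm): max |asymmetry| 0.2045 +/- 0.0288 mm at -38 deg; 177/180 meridians significant
```

The planted order-1 asymmetry (0.2 mm opposite-meridian difference,
maximal at −38° on the nasal side) is recovered at exactly −38° with a
2% amplitude error.

A command-line front end is installed at `inst/cli/scleratopo`:

```sh
Rscript inst/cli/scleratopo simulate --n-eyes 2 --seed 5 --out-dir sim/
Rscript inst/cli/scleratopo process sim/eye_001.csv sim/eye_002.csv --laterality OD --out-dir proc/
Rscript inst/cli/scleratopo group proc/eye_001 proc/eye_002 --laterality OD --out-dir group/
```

Every output file carries the MD5 hash of the configuration that produced
it; identical seeds give bitwise-identical outputs.

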