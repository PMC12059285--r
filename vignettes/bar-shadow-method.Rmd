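---
title: "Measuring the focal-spot position of a bore-type linac from bar-shadow profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the focal-spot position of a bore-type linac from bar-shadow profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(focalspot)
```

## The measurement problem

On a conventional linac the x-ray focal-spot position can be checked with
collimator-mounted apertures or the portal imager. Ring-gantry ("bore-type")
machines such as helical tomotherapy units have neither the mounting space
nor an EPID, and their collimator cannot rotate, so none of those techniques
apply. The bar-shadow method replaces them with a minimal apparatus: a thin
metal bar suspended in the beam on a thread, and an ionization chamber
stepped laterally across the field below it. The bar shadows the beam and
produces a local dip in the recorded current; the lateral position of that
dip is the projection of the bar as seen from the focal spot.

The key idea is to acquire the profile twice, with the bar at an *upstream*
and a *downstream* height separated by a known travel, while the bar's
lateral position stays fixed at the reference center (the MV-CT image center
stands in for the gantry rotation axis). A laterally displaced focal spot
projects the two shadows by different magnifications, so the *difference*
between the two dip-center deviations isolates the focal-spot offset and
cancels any common lateral misalignment of the bar or the stage origin.

## Projection model

Let `A` be the distance from the focal spot to the upstream bar position,
`B` the distance between the two bar positions, and `C` the distance from
the downstream bar position to the acquisition plane (all in cm). A focal
spot displaced laterally by `a` (mm) casts the bar's shadow at

* upstream:   `d1 = -a (B + C) / A`
* downstream: `d2 = -a C / (A + B)`

so that

```
a = (d2 - d1) / k,    k = (B + C)/A - C/(A + B).
```

For the reference machine (source-axis distance 85 cm, so `A = 85 - B` with
the downstream bar at isocenter, `B = 20.473` cm of bar travel, `C = 3.65`
cm) the divisor is `k = 0.33090...`, conveniently rounded to 0.33. The
package defaults to the full-precision `k`; `divisor = "paper_rounded"`
uses 0.33 so that results computed with the rounded form are reproduced
digit-for-digit.

```{r}
geom <- measurement_geometry()      # SAD 85, B 20.473, C 3.65
magnification_factor(geom)
estimate_focal_offset(-0.14, 0.00, geom, scan_axis("IEC_X"),
                      divisor = "paper_rounded")
```

Two properties of this estimator are worth stating because the tests rely on
them: it is exactly linear in `a` (forward/inverse round-trips are exact to
machine precision), and adding a common shift to both `d1` and `d2` leaves
`a` unchanged — a uniform stage-origin error cannot masquerade as a focal
offset. A *per-level* bar misalignment does not cancel, however, which is
exactly why session-to-session bar set-up enters the uncertainty budget.

### Axis orientation signs

The chamber stage defines the raw coordinate; mapping it onto the IEC 61217
patient axes requires a per-axis orientation sign. The sign is configurable
(`axis_sign_x`, `axis_sign_y`); the defaults (+1 for IEC-X, -1 for IEC-Y)
are the convention under which the reference results (+0.42 mm along IEC-X,
-0.36 mm along IEC-Y from `d1 = -0.14, d2 = -0.02`) come out with their
published signs. We deliberately expose the sign rather than hard-coding it,
because it is a property of how the stage is mounted, not of the method.

## Locating the dip center

The dip center is *defined* as the position where the derivative of current
with respect to position crosses zero. The derivative is computed by central
three-point differences, `(c[i+1] - c[i-1]) / (x[i+1] - x[i-1])`, which are
valid on the nonuniform acquisition grid and exact for locally linear data;
the two endpoints are dropped.

Two details matter numerically:

* On a nonuniform grid the three-point secant estimates the derivative at
  the **midpoint of the two neighbours**, not at the central sample (the two
  coincide on a uniform grid). Ignoring this biases any fit that straddles a
  step-size change, so both dip locators place each derivative sample at its
  midpoint abscissa.
* The sampled derivative must be turned into a zero-crossing position. The
  protocol's repeatability (±0.01–0.02 mm) requires sub-interval
  interpolation, so two explicit schemes are provided:
  `bracket_interp` linearly interpolates the sign change nearest the
  minimum-current sample — the literal reading of the definition — and
  `local_linear_fit` (the default) fits a least-squares line to all
  derivative samples within ±1 mm of the minimum-current sample and returns
  its root. The fit window is then re-centered on the root and the fit
  repeated (three passes in total, with a divergence guard): a window
  asymmetric about the true center otherwise leaves a small bias through
  the odd curvature of the derivative. On noiseless simulated profiles the
  two methods agree within 0.05 mm and recover injected offsets to better
  than 0.01 mm; the linear fit is the default because it averages
  single-sample noise over the whole fine-sampled region.

No smoothing is applied by default and none is needed on the default
sampling schedule; the estimators are scale-invariant (current units cancel)
and shift-equivariant.

The default sampling schedule mirrors the protocol: 1 mm steps from ±10 to
±5 mm, 0.2 mm from ±5 to ±1 mm, and 0.1 mm within ±1 mm, with 5 electrometer
samples averaged per point.

## The forward simulator

Hardware-free testing needs a forward model of the whole measurement, so the
simulator is first-class, tested code. It emulates:

* **Geometry** — rays from the source through the bar to the acquisition
  plane, with the bar at either height. The chamber scans across the bar's
  short axis, so an in-plane ray sees the bar's circular cross-section; the
  path length is the exact line–circle chord (verified in the tests against
  brute-force quadrature of the inside-bar indicator at 1 µm steps).
  Attenuation is `exp(-mu * path)` with a generic effective `mu = 0.4/cm`
  for a metal bar at 6 MV. The dip *depth* depends on `mu`; the dip
  *center* provably does not (an invariance the tests check over
  `mu` in 0.1–5 /cm).
* **Source size** — the focal spot is given a Gaussian lateral intensity
  profile (FWHM 1 mm by default, 21-node quadrature). The true focal-spot
  size of the reference machine is not public; the default is a plausible
  placeholder, and the dip center is first-order insensitive to it.
* **Chamber aperture** — uniform lateral averaging over a 2 mm window
  (11 nodes), again a generic stand-in for the real chamber response.
* **Reading noise** — each of the 5 per-point samples gets multiplicative
  Gaussian noise with coefficient of variation 0.002; the per-point mean is
  recorded. Noise is seeded per profile, so every simulated file is exactly
  reproducible from the manifest.
* **Open field** — flat across the scanned ±10 mm (the central region of a
  5 × 10 cm field); no penumbra model, since only the central dip is
  analyzed.
* **Session structure** — `generate_session()` emits 2 axes × 2 bar levels
  × repeats × sessions. Repeats within a session share the bar alignment and
  differ only by reading noise (repeatability). Each session redraws the bar
  lateral alignment from `Normal(0, 0.08 mm)` (reproducibility of the weekly
  set-up); 0.08 mm is a modeling choice that echoes the magnitude of
  published reproducibility figures, not a measured value.

What the simulator does **not** emulate: scatter, spectral effects, the
thread and PMMA build-up cap (no lateral structure), gantry-angle-dependent
sag (the method is defined at gantry 0°), and any MV-CT imaging. Passing
tests on simulated data therefore validate the *analysis chain and its
geometry*, not the dosimetric realism of a particular machine.

```{r}
det0 <- detector_spec(noise_cv = 0)       # noiseless variant for illustration
up <- simulate_profile(source_spec(offset_mm = 0.42), "upstream", detector = det0)
dn <- simulate_profile(source_spec(offset_mm = 0.42), "downstream", detector = det0)
c(find_dip_center(up)$center, find_dip_center(dn)$center)
estimate_focal_offset(find_dip_center(up)$center, find_dip_center(dn)$center,
                      geom)$offset_a
```

## Uncertainty budget

Repeatability (consecutive repeats) and reproducibility (between sessions)
of `d1` and `d2` are Type A components, taken as their standard deviations
(`sd` mode by default — the literal published treatment; `sd_of_mean` is
available because published budgets are ambiguous on this point). The finest
sampling interval (0.1 mm) enters as a Type B component; the standard GUM
rectangular model gives `(0.1/2)/sqrt(3) = 0.029 mm`, and since published
budgets sometimes assign a different value whose derivation is not stated
(e.g. 0.087 mm for the same interval), an `as_given` mode accepts such a
value verbatim. Components combine by root-sum-square with unit sensitivity,
expressed at the acquisition plane — the literal published combination:

```{r}
comps <- mapply(uncertainty_component,
                name = c("d1 (repeatability)", "d2 (repeatability)",
                         "d1 (reproducibility)", "d2 (reproducibility)",
                         "d1 (interval: 0.1 mm)", "d2 (interval: 0.1 mm)"),
                utype = c("A", "A", "A", "A", "B", "B"),
                value_mm = c(0.048, 0.048, 0.087, 0.087, 0.087, 0.087),
                SIMPLIFY = FALSE)
combine_uncertainty(comps)
```

`propagate_to_focus = TRUE` divides the combined value by `k`, translating
the plane-level uncertainty to target height through the estimator; it is
offered as a clearly labeled extension, not the default. Geometry-distance
uncertainties (A, B, C) are an order of magnitude smaller than those of the
dip centers and are excluded by default. Expanded uncertainty (k = 2) and
effective degrees of freedom are out of scope.

## End-to-end pipeline and reproducibility

`analyze_session()` reads a directory of profile CSVs, locates every dip,
pools repeats within sessions (pooled within-session SD → repeatability) and
across sessions (SD of session means → reproducibility), inverts the
geometry per axis, and attaches the budget. Reported positions are
chamber-stage coordinates at the acquisition plane; the magnification
between that plane and the isocenter plane is absorbed in the estimator and
must not be re-applied.

Problem sizes used throughout the test suite were chosen to exercise the
statistics at the protocol's scale: the standard 71-point schedule, 10
repeats × 3 sessions for the synthetic study, 50 seeded repeats for the
noise-scaling property, and dense 1 µm or 1 mm grids where an oracle needs
them. A full 120-profile synthetic study simulates and analyzes in about a
second.

Known limitations: the method measures only the *lateral* focal-spot
position at gantry 0°, one axis at a time; with a single bar level it cannot
distinguish a focal offset from a bar misalignment (hence two levels); the
simulator's source size, chamber aperture and attenuation coefficient are
generic placeholders; and the reproducibility model reduces weekly set-up
variation to a single lateral bar shift.
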