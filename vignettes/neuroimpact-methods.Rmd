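---
title: "Methods: concussive impact mechanics and the worm cytometry index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: concussive impact mechanics and the worm cytometry index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`neuroimpact` bundles two computational readouts of concussive closed-head
injury: a plane-strain explicit-dynamics finite-element model of a
region-partitioned viscoelastic mouse-brain section struck by a weight-drop
impactor, and a large-particle flow-cytometry index quantifying
trauma-induced GFP loss in sorted *C. elegans* neuron populations.  This
vignette is the package's account of the underlying models, the numerical
choices, and the limits of what the synthetic test problems can show.

## Constitutive model

Brain tissue is modeled as a linear viscoelastic solid.  The deviatoric
stress follows the hereditary integral

$$\tau(t) = \int_0^t G(t-s)\,\dot\gamma(s)\,ds,$$

with the shear relaxation modulus represented by a two-term Prony series

$$G(t) = G_0\left(g_L + g_1 e^{-t/\tau_1} + g_2 e^{-t/\tau_2}\right).$$

The built-in table (`builtin_material_table()`) carries published fits for
six P56 mouse-brain regions (pons, cortex, cerebellum, thalamus, medulla;
the hippocampus row is an adult-rat fit, the only characterization
available).  Instantaneous shear moduli range from 2674 Pa (thalamus) to
7643 Pa (pons); relaxation times from 12 to 265 ms.  The ratio columns of
most regions sum to 1.000, which fixes the interpretation of $G_0$ as the
instantaneous modulus scale; the hippocampus row sums to 0.862 and is kept
exactly as published rather than renormalized.  Brain density is
1040 kg/m³.  The skull is isotropic elastic (E = 1 GPa, ν = 0.33,
ρ = 1710 kg/m³), as are the impactor metals (brass 100 GPa/8480 kg/m³,
nylon 2.3 GPa/1120 kg/m³).

The published material model specifies no bulk behavior, so the volumetric
response is elastic, $p = -K\,\varepsilon_v$ with
$K = 2G_{\mathrm{inst}}(1+\nu)/(3(1-2\nu))$ and an *effective Poisson
ratio* $\nu$ governing how nearly incompressible the tissue is.

**Why the default is $\nu = 0.4995$.**  Soft-tissue FE models conventionally
use $\nu$ between 0.49 and 0.4999.  The choice matters much more here than
in quasi-statics: the shear wave speed of these materials is only
$c_s=\sqrt{G/\rho}\approx 1.6\!-\!2.7$ m/s while the impact imposes
velocities of 4.5 m/s, so any mechanism that converts skull motion into
brain shear produces order-one strains.  At $\nu = 0.49$
($K/G \approx 50$) the brain is volumetrically compliant enough that the
accelerating skull quasi-statically crushes it — simulated strains exceed
60% and elements invert.  At $\nu = 0.4995$ ($K/G \approx 1000$) the brain
co-translates with the cranial cavity (the interior solution for a rigidly
translating cavity filled with an incompressible medium is uniform
translation), strains at all five monitors fall inside the experimentally
reported 5–45% band, and the runs complete.  The time step is controlled by
the stiff skull either way, so the stricter incompressibility is free.

## Time integration and the stress-update kernel

The solver (`run_explicit()`, compiled C++) uses 4-node fully integrated
plane-strain quadrilaterals (2×2 Gauss), row-sum lumped masses, and
central-difference (leapfrog) integration at
$\Delta t = 0.8\,\min_e(\ell_e/c_e)$ with
$c = \sqrt{(K + 4G_{\mathrm{inst}}/3)/\rho}$ the dilatational wave speed
and $\ell_e$ the element area over its longest diagonal.  Kinematics are
small-strain: strains come from the displacement gradient on the reference
configuration.  Full integration needs no hourglass control, at the price
of mild volumetric locking that the near-incompressible setting tolerates
at the mesh densities used here.

The viscoelastic kernel advances one internal deviatoric stress tensor per
Prony branch with the exact exponential recurrence
$s_i \leftarrow e^{-\Delta t/\tau_i}(s_i + 2 G_0 g_i\,\Delta e)$, treating
each strain increment as a jump at the start of the step.  Two properties
follow: a step-strain relaxation test is reproduced *exactly* at the grid
times (the verification suite measures ~1e-15 relative error against the
closed form for all six materials), and smooth histories are integrated
first-order accurately (the error halves when the step halves), which is
immaterial inside explicit dynamics where $\Delta t/\tau \sim 10^{-5}$.
Dissipation is tracked as internal work (midpoint rule) minus recoverable
energy (volumetric plus per-branch deviatoric), so the energy ledger
splits cleanly into kinetic, stored, viscous-dissipated and
contact-penalty storage; the audit residual of an elastic penalty bounce
is below 2% and a free impact conserves momentum to round-off.

Linear bulk viscosity (coefficient 0.06 of $\rho c \ell\,\dot\varepsilon_v$)
damps dilatational ringing inside the dynamic solver — the standard
explicit-dynamics regularization, enabled by default in the major
commercial codes.  The closed-form verification problems (wave bar,
oscillator, bounce) run with it off.

Contact between the impactor tip and the skull is frictionless
node-to-segment penalty contact: a skull node penetrating the (rigid,
vertically translating) tip face by $\delta$ receives a purely normal force
$k_n\delta$, with $k_n$ set to 10× the stiffest adjacent element's
stiffness estimate times the node's tributary length.  The time step is
additionally capped at half the contact-oscillator stability limit.

## Synthetic geometry

The atlas-derived section of the original experiment is not printable, so
`build_sagittal_domain()` generates an idealized stand-in: a dome-capped
brain outline whose depth tapers to 55% of the central 9.5 mm at the
anterior/posterior poles of the 15 mm section, partitioned by a fractional
tile layout into cortex (dorsal band), hippocampus/thalamus/cerebellum
(middle band), medulla/midbrain/pons (deep band) and a ventral medulla
floor.  The distinct `midbrain` tile hosts the substantia-nigra monitor and
uses thalamus material parameters, the closest characterized region.  Tile
boundaries snap to mesh lines (and the default grids are multiples of 20
columns/rows), so labeled region areas are refinement-invariant to <1%.

A 1.5-mm skull shell is extruded outward around the *entire* brain
boundary loop.  An early dorsal-cap-only variant failed a load-path
analysis: with a free ventral boundary every bit of impactor momentum must
transit the soft brain column, which predicts centimetre-scale crush.  The
closed cranial ring — anatomically the faithful configuration — lets the
impact momentum accelerate the head through the stiff skull while the brain
sees transient waves.  Because the ring is extruded from the brain
boundary, skull and brain share interface nodes: the exact conforming
equivalent of a tie constraint.

Monitor points sit at the published offsets from the impact point: cortex,
thalamus and substantia nigra at 2.4, 4.1 and 8.2 mm vertical depth;
cerebellum and brainstem 4.7 mm posterior at 4.1 and 8.2 mm.  Each is
snapped to its host element with isoparametric coordinates, and field
values are bilinearly extrapolated from the Gauss points — monitors are
geometric points, not nodes.

The impactor is a brass body with a slightly concave nylon tip (tip radius
2 mm, concavity 0.2 mm); its printed dimensions are not recoverable, so the
mesh is a configurable surrogate.  In the supported rigid mode it moves as
one vertical degree of freedom with a mass per unit thickness of
13.75 kg/m — the 220 g drop weight divided by the 16 mm extrusion depth of
the original 3D model.  Results are insensitive to this value above
~2 kg/m (the head is accelerated to near the impactor speed regardless),
which is why it is exposed as a calibration parameter rather than tuned.

## The impact experiment

`run_impact()` drops the impactor from its 0.9 mm standoff at 4.54 m/s,
integrates 4 ms of response (covering the sub-2-ms events reported
experimentally with margin), and reports monitor traces sampled every
0.01 ms, a peak table, the energy ledger, and optional VTK field
snapshots.  "Effective stress" is reported as von Mises stress; because von
Mises excludes the hydrostatic part, and these tissues carry most of their
load as pressure, the peak table also reports the maximum principal stress,
which is pressure-inclusive.  This distinction matters when comparing with
published full-model numbers: stress–strain peak pairs of tens of kPa at
tens of percent strain are mutually consistent only for a
pressure-inclusive stress measure, since the Prony shear moduli cap the von
Mises stress at roughly $2\!-\!3.5\,G_{\mathrm{inst}}\times$ strain, i.e. a
few kPa below 45% strain.  The package reports both and leaves the
interpretation explicit.

At the default desk scale (about 1280 elements; the refinement check uses
about 5120) the simulation shows: wave arrival ordered cortex → thalamus →
substantia nigra by depth; peak principal strains of roughly 10–40% at all
five monitors with the deep substantia-nigra strain comparable to (here
larger than) the cortex strain — the distal-strain transfer that motivates
the biology; and von Mises peaks of 1–6 kPa.  Two caveats are part of the
honest picture.  First, the brainstem monitor registers a small *early*
precursor peak conducted around the fast skull ring before the slow
tissue wave arrives, so the four-monitor first-peak ordering ends with the
substantia nigra after the brainstem.  Second, the late-time (>2 ms)
response is a shear slosh of the nearly incompressible brain inside the
ringing elastic ring; its maxima are not mesh-converged at these
resolutions (changes well above 10% under one refinement level), a known
consequence of resolving an interface shear layer whose physical thickness
($c_s t \lesssim 1$ mm) is comparable to the element size.  The early wave
phase is the converged, physically meaningful part of the signal.

## The cytometry index

`simulate_sort()` emulates a sorted worm experiment: per-worm uninjured
fluorescence is lognormal (median 200 a.u., coefficient of variation 0.3 —
typical inter-animal variability for neuronal GFP reporters), injured
worms draw independently from the same law scaled by the injury
attenuation, and worms split evenly over biological repeats and condition
arms.  The defaults are the dopaminergic 24-h study conditions: 1181 worms
over two sorts at attenuation 0.579 (a 42.1% loss).

`gfp_index()` computes, per repeat, retention = mean injured / mean
uninjured fluorescence; averages retentions across repeats; normalizes by
the empty-vector (EV) retention of the same batch; and propagates errors in
quadrature: each repeat's error $\delta X$ (quotient rule from the two
arms' standard errors) is scaled by $1/(1-EV)$, where $EV$ is the
empty-vector loss constant of that experiment, summed in quadrature, and
combined with the between-repeat standard error.  Two conventions the
source formulas leave open are implemented as: EV normalization *divides*
retentions (rather than subtracting losses), and worms are aggregated per
sort before ratioing.  Both are flagged here because alternative readings
exist; the division convention makes the index scale-invariant, which the
test suite asserts.

What the generator does *not* emulate: gating artifacts, size-dependent
fluorescence, sort carry-over, or non-lognormal outliers from dead worms —
so passing tests certify the estimator and its error propagation, not
robustness to instrument pathology.

## Numerical choices and degenerate inputs

* Degenerate geometry (zero skull thickness, empty or overlapping layout
  tiles) is rejected at specification time with the offending field named.
* Monitors outside the tissue (e.g. a brain shallower than 8.2 mm) raise a
  placement error naming the monitor.
* An element whose current-configuration corner Jacobian turns non-positive
  aborts the run with the element id and time; the last recorded state is
  returned.  NaNs are screened on the same cadence.
* Peak extraction takes the earliest local maximum reaching 5% of the
  trace's global maximum (configurable); a still-rising trace returns its
  endpoint flagged `boundary_peak`, a flat trace returns (0, 0) flagged.
* All tables are stored in their published units (Pa, ms) and converted to
  SI in a single audited function at assembly time.

## Problem sizes

The test suite and the acceptance script use: single elements for
constitutive checks; a 200-element confined bar for the wave-speed check
(front-arrival error 1.3%, dominated by grid dispersion); ~560-element
domains for pipeline behavior tests; and 1280/5120-element domains for the
default and refined impact scenarios, 4 ms each.  These sizes were chosen
so the full suite characterizes the method in minutes on one core while
keeping the skull shell at least two elements thick.

## Known limitations

2D plane strain (the limit of the original extruded model, not full 3D);
small-strain kinematics read at face value although simulated strains reach
tens of percent, so reported principal strains are infinitesimal-measure
approximations; no CSF layer, so skull-brain tangential coupling is
over-stiff; no foam support under the head (free boundary); the skull ring
rings undamped, which drives the unconverged late slosh; and the published
full-model peak values (tens of kPa at specific sub-2-ms times) are not
reproducible without the unpublished atlas geometry and the
2.5-million-element 3D mesh — the package targets the *phenomenology*
(ordering, strain band, distal transfer) at desk scale instead.
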