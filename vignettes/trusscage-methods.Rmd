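---
title: "Methods: a lumped-spine / beam-lattice model of strain on trussed interbody cages"
author: "trusscage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a lumped-spine / beam-lattice model of strain on trussed interbody cages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trusscage)
```

## Problem and scope

Trussed titanium interbody cages are strut lattices whose surfaces may
deliver bone-stimulating strains to attached cells. The quantity of interest
is the distribution of absolute maximum principal strain over the strut
surface under physiological lumbar loading — in particular the fraction of
surface exceeding the 200 µε bone-maintenance/formation stimulus level —
together with the contact pressures the cage applies to the caudal
vertebral endplate, and how both vary across patients versus across loading
conditions (neutral, extension, flexion).

`trusscage` answers this at desk scale. It deliberately replaces two
expensive components of a full patient-specific continuum model with
physically-motivated surrogates:

* the continuum lumbar spine (vertebrae, poro-hyperelastic discs, ligaments,
  facets) becomes a **serial chain of functional spinal units (FSUs)** with
  calibrated nonlinear moment–rotation maps, and
* the microCT-derived tetrahedral cage mesh becomes a **parametric Timoshenko
  beam lattice**, which captures strut-level membrane, bending and torsional
  surface strains (the strain carriers that matter at the 200 µε scale)
  while omitting sub-strut surface microfeatures, which a continuum mesh of
  printable resolution also cannot resolve.

No imaging, segmentation, mesh morphing, fluid-flow time integration or
geometric nonlinearity is in scope.

## The virtual cohort

`sample_cohort()` draws patients uniformly and independently within a narrow
fusion-candidate envelope: weight 60–74 kg, height 164–172 cm, lumbar
lordosis 29–40°, Pfirrmann degeneration grade II–IV per disc, bone quality
0.7–1.0. The envelope is deliberately narrow — it represents a subgroup
selected to share one cage size — so passing cohort-level checks says
nothing about, e.g., osteoporotic or obese patients. Grades, lordosis and
bone quality are sampled independently because no joint distribution is
available; the independence assumption inflates cohort variance slightly, if
anything. Sampling is bit-reproducible for a fixed seed and leaves the
caller's RNG state untouched.

Bone quality enters the mechanics as a multiplier on the contact-layer
modulus (an endplate-preparation/quality effect); weight and height drive
the follower load; grades drive FSU stiffness and disc swelling; lordosis is
carried for completeness but does not enter the lumped chain, whose
moment–rotation maps are calibrated at the FSU level.

## The parametric cage

`generate_cage()` builds a PLIF-class box lattice: two rectangular node
grids (the caudal and cranial contact surfaces) joined by verticals,
X-braced diagonals in both vertical plane families, and in-plane chords.
Defaults: footprint 25 × 10 mm (length anterior–posterior), height 11 mm,
pitch 3 mm, strut diameter 0.5 mm. The exact commercial geometry is
proprietary; the claims this package supports are statistical properties of
a strut network, not of one topology, and every dimension is a config
parameter.

The posterior screw-insertion block — which in the real cage is a nearly
solid region that attracts a large share of the load and thereby shields
the free struts — is represented by the posterior 20% of the lattice with
struts of 3× effective diameter (≈ 9× axial, ≈ 81× bending stiffness),
keeping the whole model inside the beam formulation.

With jitter disabled (default) node coordinates are mirror-symmetric about
the cage midsagittal plane by construction; `jitter_mm > 0` adds a seeded
uniform perturbation for symmetry-breaking robustness studies.

**Calibration of the defaults.** Strut diameter (0.5 mm) and block fraction
(0.20) were fixed once by calibrating the default configuration against the
headline target of the reference protocol — roughly 30% of cage surface
above 200 µε in flexion, with peak von Mises stresses in the 250–300 MPa
class and mean caudal pressures below 10 MPa — and then frozen. They are
design defaults of this package, not measurements of any specific implant.

## The lumped spine surrogate

Each FSU carries the strictly monotonic map

$$M(\theta) = k_0 \, a(\theta)\, b \sinh(\theta / b),$$

with $k_0$ the stiffness at neutral (N·m/°), $b = 5°$ the softening scale
(stiffening becomes pronounced beyond ±5°), and $a = 0.38$ for $\theta < 0$:
extension is substantially more compliant than flexion, reproducing the
asymmetric lumbar load–deflection profile (reaction moments near −9 N·m at
20° extension versus +22 to +24 N·m at 20° flexion for the default cohort).
Per-level baselines $k_0$ = 3.8/3.5/3.3/3.2/3.0 N·m/° (L1-2 … L5-S1) are
multiplied by a per-grade factor (0.85/1.0/1.2/1.45/1.7 for grades I–V):
degenerated discs lose height and stiffen.

The compressive **follower load** is interpolated bilinearly from built-in
per-condition tables over (weight, height). The tables are linear in both
variables and were calibrated so that every patient inside the default
envelope lands within the physiological per-condition ranges 368–454 N
(neutral), 748–888 N (extension), 976–1148 N (flexion), increasing with
both weight and height. Outside the table hull the inputs are clamped with
a warning.

**Rotation distribution** (`distribute_rotation()`) solves series
equilibrium: a single chain moment $M$ is transmitted through all FSUs and
is found by bisection so that the per-level rotations $\theta_i(M)$ (each an
analytic or, at the instrumented level, numeric inverse) sum to the imposed
total of ±20°, to an absolute tolerance of $10^{-8}$ degrees (at most 200
bisection steps — the residual is monotone in $M$, so bisection cannot
fail on a valid bracket). The instrumented L4-5 level adds the
pedicle-screw/rod construct in parallel: two Ti rods bending as fixed-guided
beams ($k_t = 2 \times 12EI/L^3$ with $L$ = 35 mm posterior segment height)
acting at a 40 mm posterior lever arm, i.e. a rotational stiffness
$k_t \cdot \text{offset}^2 \approx 56$ N·m/°. The operated level therefore
attracts only ~0.2–0.4° of the 20°, consistent with an instrumented fusion
segment.

**Intradiscal pressure** uses an undrained short-time superposition (the
loading steps last seconds; the multi-hour swelling transient is collapsed
into a constant baseline):

$$\mathrm{IDP} = \pi_\text{swell} f_\text{grade} + c_u \frac{F}{A} +
c_m |M| \, g(\text{condition}),$$

with $\pi_\text{swell} = 0.15$ MPa, per-grade swelling factors
1.1/1.0/0.6/0.35/0.2 (degenerated discs hold less water), undrained gain
$c_u = 1.5$ (nucleus pressure exceeds the mean applied stress), moment gain
$c_m = 0.025$ MPa/N·m and condition weights $g$ = 0/0.35/1.0 for
neutral/extension/flexion (flexion pressurizes the nucleus most). These
constants were calibrated once so the default cohort lands in physiological
bands — neutral 0.5–0.6 MPa, flexion 1.5–1.9 MPa, extension 0.8–1.1 MPa —
and produce the expected orderings (flexion > extension everywhere;
degenerated discs lower). One published band is exceeded marginally: our
most-loaded extension discs reach ≈ 1.13 MPa versus a literature ceiling
of ≈ 1.1 MPa; we accepted this rather than re-tuning against multiple bands
simultaneously. Note the grade factor multiplies only the swelling term, so
grade differences fade as mechanical load dominates.

## The cage finite-element model

`assemble()` turns every strut into a two-node 3D Timoshenko beam with
circular-section properties $A = \pi d^2/4$, $I = \pi d^4/64$,
$J = \pi d^4/32$ and shear correction $\kappa_s = 0.9$. The element
stiffness is the standard shear-deformable form (parameter
$\Phi = 12EI/(\kappa_s G A L^2)$), exact for nodal loading, so a single
element reproduces the Timoshenko cantilever closed form to round-off.
Titanium: $E = 116$ GPa, $\nu = 0.32$.

`solve_load_case()` places the lattice between:

* a **fixed caudal plate**: each caudal surface node rests on foundation
  springs $k_n = E_\text{layer} A_\text{trib}/t$ (normal) and
  $k_t = k_n/(2(1+\nu_\text{layer}))$ (tangential), with layer defaults
  $E = 1000$ MPa, $\nu = 0.3$, $t = 2$ mm, and the tributary area
  $A_\text{trib}$ = footprint / number of surface nodes (exact force
  conservation, uniform-by-construction);
* a **rigid cranial plate**: sagittal rotation prescribed (the segment
  share from the surrogate, with flexion tilting the anterior edge
  caudally), off-axis rotations and in-plane translations fixed, vertical
  translation free and loaded by the axial follower-load share. Cranial
  surface nodes couple to the plate through the same foundation springs;
* the **instrumentation**: a bonded vertical spring of stiffness
  $2 \times 12EI/L^3$ between plate and ground at the posterior lever arm,
  the same construct the surrogate uses, closing the parallel load path
  (posterior stress shielding and the flexion-tension tie-back).

Left and right cages are solved as two independent models, each carrying
half the segment axial force and the full rotation; under the sagittally
symmetric default protocol the two are identical to solver precision, which
the tests assert.

### Contact algorithm and numerical choices

Unilateral mode runs two nested iterations:

* **Active set (inner):** springs found in tension are released, released
  springs found penetrating are re-activated, until the set is fixed
  (≤ 100 passes). Hysteresis thresholds (release beyond $10^{-10}$ N
  tension, re-activate beyond $10^{-8}$ mm penetration) suppress chattering
  of nodes numerically on the boundary. A genuine degeneracy remains
  possible: a node pair exactly grazing the contact boundary can cycle
  between "released but penetrating ~$10^{-5}$ mm" and "active but tensile
  ~0.1 N". The cycle is detected by a repeating set signature and resolved
  by freezing such nodes released: equilibrium of the remaining forces stays
  exact and no tensile pressure is ever transmitted; the cost is a
  sub-micrometre unpenalized penetration, i.e. a ~0.1% local force error.
* **Coulomb friction (outer):** tangential springs stay assembled and an
  under-relaxed correction force (start $\omega = 0.5$, accelerated to 0.95
  while contracting) drives the net tangential force of sliding nodes onto
  the friction cone $|f_t| \le \mu f_n$ ($\mu = 0.2$), to a force tolerance
  of $10^{-8}$ N. Keeping the springs assembled (rather than deleting them
  on slip) preserves conditioning and is what makes the fixed point
  converge. Monotonic single-ramp loading is assumed, so no stick–slip
  history is tracked.

`bonded` mode ties all springs bilaterally and is intended for
interface-stiffness side studies.

Every solution records the global force balance
$|\sum \text{reactions} + \text{applied}|/|\text{applied}|$, which the
tests require below $10^{-8}$, along with iteration counts; one log line
per solve reports both.

### Strain recovery

With loads only at nodes, each element's internal resultants are exact from
its end forces: constant axial force and torque, linear bending moments.
Strut surfaces are sampled at `n_axial = 3` stations × `n_circ = 8` angles
(deliberately modest: internal fields are linear along the element, so
denser axial sampling only refines the area weighting, not the field
itself). Per sample:

$$\varepsilon(s,\theta) = \varepsilon_m(s) + \tfrac{d}{2}\left[\kappa_y(s)
\sin\theta + \kappa_z(s)\cos\theta\right], \qquad
\gamma(s) = \tfrac{d}{2}\,\varphi'(s),$$

and the reported absolute maximum principal strain is
$|\varepsilon|/2 + \sqrt{(\varepsilon/2)^2 + (\gamma/2)^2}$, in µε, signed
by the fiber strain for tensile/compressive labelling. Samples carry their
share of lateral strut surface area as weight, so the threshold fraction and
histograms are area-weighted; with uniform sampling density this coincides
with node counting on a uniform surface mesh. Von Mises stress per sample is
$\sqrt{(E\varepsilon)^2 + 3(G\gamma)^2}$. Screw-block strut surface is
included by default (`include_block = FALSE` excludes it — the stimulation
argument concerns free struts, and the choice moves the flexion threshold
fraction by a few points).

## Metrics

* `threshold_fraction()`: area-weighted percent of samples with
  $|\varepsilon_p|$ **strictly** above the threshold (default 200 µε);
  boundary samples do not count.
* `strain_histogram()`: half-open bins $[e_i, e_{i+1})$ on $|\varepsilon_p|$,
  last bin open-ended, summing to 100 exactly (bin edges default
  0/100/200/500 µε and are configurable).
* `mean_contact_pressure()`: total caudal normal force over the **active**
  contact area (the mean over the loaded patch, matching contact-pressure
  semantics of a two-body formulation); normalization by nominal footprint
  is available via `normalize = "nominal"`.
* `cohort_summary()`: coefficients of variation (unbiased SD/mean, %)
  across patients within condition and across conditions within patient,
  with left/right cage values averaged within patient first, plus the flag
  `condition_variation_dominates`.

## What the synthetic data does and does not show

The generator reproduces the statistical envelope of a small, homogeneous
fusion cohort and a generic strut-lattice cage under an idealized symmetric
protocol. Passing tests therefore demonstrates internal consistency of the
mechanics (equilibrium, analytic limits, orderings, variance structure) and
plausibility of the calibrated magnitudes — not patient-level predictive
accuracy. Real cages have asymmetric placement, curved endplates, irregular
strut topology and surface microstructure; real spines couple levels through
ligaments and facets that are collapsed here into one map per FSU; cell-scale
stimuli (fluid flow, attachment geometry) are outside the model class.

## Known limitations

* Linear kinematics: no geometric stiffening, no subsidence or endplate
  plasticity; peak contact pressures should be read as interface demand, not
  as a subsidence prediction.
* The extension response is strongly shielded by the posterior block and
  instrumentation; the extension threshold fraction (~1–2%) is therefore
  lower than the flexion one by design of the load path, and small changes
  in block geometry move it noticeably.
* The follower-load tables and IDP gains are calibration constants chosen to
  land in physiological bands, not fits to any individual dataset; all are
  overridable through `run_config()` / the `spine:` YAML section.
* One cage topology family (box lattice with X-bracing) is implemented;
  `read_lattice_txt()` accepts arbitrary node/strut graphs for other
  designs.

## Problem sizes

The default lattice has 72 nodes, 272 struts and 438 beam DOFs plus 6 plate
DOFs; a full default cohort (4 patients × 3 conditions × 2 cages = 24
solves, each with nested contact iterations) runs in well under a minute on
one core, and the analytic validation suite in about a second. These sizes
were chosen so the full pipeline, tests and reproduction script are
comfortable on a laptop while keeping enough struts for stable area-weighted
statistics (≈ 6500 surface samples per case).
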