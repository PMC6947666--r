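---
title: "Helical airway stent mechanics and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Helical airway stent mechanics and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helistent)
```

## The problem

Tracheobronchomalacia — intrinsic weakness of the tracheal wall — lets the
pediatric airway collapse during expiration. The clinical fallback,
positive pressure ventilation at 5–10 cmH₂O, keeps the airway open but
ties the child to a ventilator. A helical wire stent can supply the same
support mechanically while covering only a narrow helical strip of
epithelium, preserving mucus transport and allowing screw-like,
atraumatic removal. Designing such a stent means choosing a wire
diameter and helix pitch that hold the airway open under a
ventilation-equivalent external pressure while placing as little foreign
material in the airway as possible. `helistent` implements the stent
deformation model and the design-space search that support this choice.

## The model

The stent is a NiTi wire shape-set into a helix of centerline diameter
$d_0$, pitch $p_0$ and wire diameter $d_w$, with $n$ complete coils. The
wire is modelled as an inextensible, unshearable, linearly elastic rod;
only its central helical region is considered, since deployed stents
extend past the supported segment at both ends and end effects decay away
from the ends. In the body frame (z tangent to the wire, x toward the
helix axis) the undeformed curvature vector is

$$\hat u = \left(0,\; \frac{2\pi^2 d_0}{c_0^2},\; \frac{2\pi p_0}{c_0^2}\right),
\qquad c_0 = \sqrt{\pi^2 d_0^2 + p_0^2},$$

where $c_0$ is the arc length of one coil and $\ell = n\,c_0$ the total
wire length (constant under deformation, by inextensibility).

**Pitch at a prescribed diameter.** A radially compressed helix of
linearly elastic wire stays helical away from its ends, with a new
diameter $d < d_0$ and pitch $p$. At fixed $d$ the pitch is the minimizer
of the stored elastic energy

$$E = \frac{\ell}{2}\,(u - \hat u)^\top K\,(u - \hat u),
\qquad K = \mathrm{diag}(k_b, k_b, k_t),$$

with $u = u(d, p)$ the deformed curvature, $k_b = E_Y \pi r^4/4$ and
$k_t = G \pi r^4/2$ the bending and torsional rigidities of the round
wire ($r = d_w/2$, $G = E_Y / (2(1+\nu))$). Setting $dE/dp = 0$ and
clearing the positive prefactor leaves a quartic in $p$ whose $p^2$
coefficient vanishes identically; the equilibrium pitch is the positive
real root with least energy. Compression lengthens the stent: $p$
increases monotonically as $d$ shrinks.

**Pressure at a prescribed diameter.** A uniform external pressure
$\rho$ acting on the stented cylinder is statically equivalent to a
radial force per unit wire length
$f = \rho\,\pi d p / \sqrt{p^2 + \pi^2 d^2}$ (the pressure on the band
of tracheal wall carried by one coil, divided by the coil's arc length).
The Cosserat rod equilibrium of a helix under a purely radial,
frictionless distributed load collapses to a closed form,

$$f_x = \frac{u_y^2 + u_z^2}{u_z}
  \Big((k_t - k_b)\,u_y u_z - k_t \hat u_z u_y + k_b \hat u_y u_z\Big),$$

evaluated at the deformed curvature. In this frame the x-axis points at
the helix center and $f_x$ is positive under compression, i.e. the load
is radially inward; the package reports the magnitude. Combining the two
force expressions gives the supported pressure $\rho(d)$, which is zero
at $d = d_0$ and increases monotonically as the stent is compressed.
Because $f_x$ is linear in $(k_b, k_t)$, $\rho$ scales exactly linearly
with the elastic modulus.

**Diameter at a prescribed pressure.** $\rho(d)$ has no closed-form
inverse (the equilibrium pitch is embedded in it), so
`diameter_under_pressure()` inverts it numerically (below).

## Parameters and defaults

| parameter | meaning | default | why |
|---|---|---|---|
| $E_Y$ | wire Young's modulus | 75 GPa | typical austenitic NiTi; the model is linearly elastic, so a single effective modulus stands in for the superelastic response |
| $\nu$ | Poisson ratio | 0.3 | standard metallic value; only enters through $k_t/k_b = 1/(1+\nu)$ |
| template | shape-setting mandrel diameter | 12.7 mm | the bench template; the reference for angle↔pitch conversion |
| $d_0$ | helix centerline diameter | template + $d_w$ | the wire centerline sits half a wire off the template on each side |
| $n$ | coil count | 3 | the deployed in vivo length; per-unit-length results are independent of it |
| $\rho_{\text{ref}}$ | design evaluation pressure | 10 cmH₂O | the upper end of clinical positive-pressure ventilation |

All functions are unit-agnostic given a consistent system (SI
recommended); the CSV/JSON writers and the CLI convert to and from mm
and cmH₂O (1 cmH₂O = 98.0665 Pa, exact). "Diameter" is always the wire
centerline diameter; the outer diameter ($d_0 + d_w$) is reported
alongside. Cross-sectional area ratio is $(d/d_0)^2$ on the centerline
diameter; lumen-based definitions differ only at order $d_w/d_0$.

## Numerical choices

* **Quartic roots** come from the eigenvalues of the 4×4 companion
  matrix; eigenvalues with relative imaginary part below $10^{-9}$ are
  accepted as real and polished with two Newton steps on the polynomial.
  Energy ties below $10^{-12}$ relative resolve to the root nearest
  $p_0$, preserving continuity of the deformation path. No positive real
  root raises an error carrying all four roots.
* **Pressure inversion** runs Newton from $d = d_0$ with a
  central-difference derivative (step $10^{-8} d_0$) on a signed variant
  of $\rho(d)$ that stays smooth through $d_0$, stopping at
  $|\Delta d| < 10^{-10}$ (length units; 0.1 nm in SI) or 100
  iterations. If an iterate leaves $(0.05\,d_0, d_0]$ or the derivative
  degenerates, the solver falls back to bisection on $[d_{lo}, d_0]$,
  with $d_{lo}$ starting at $0.5\,d_0$ and halving until the bracket
  straddles. Only compression is modelled: negative transmural pressure
  is rejected rather than extrapolated.
* **Pressure sweeps** warm-start each solve from the previous diameter
  and assert along the way that the area ratio never increases; a
  violation aborts rather than silently returning a multivalued inverse.
* **Criterion solvers** use bisection on pitch at 0.01 mm tolerance, and
  first verify on a coarse scan that the objective is monotone over the
  bracket. The default brackets are helix angles 5–60° on the template
  for the target-reduction criterion and 5–45° for the
  wire-insensitivity criterion: the area-ratio difference between two
  wire diameters grows with pitch only while both stents still carry
  most of the load, and turns over beyond roughly 50° at 10 cmH₂O where
  both collapse nearly completely, so the insensitivity bracket stays
  below that regime.

## The design procedure

`build_design_table()` enumerates wire diameter × helix angle designs
(defaults: {0.38, 0.51} mm × {15, 20, 25, 30, 35}°, the ten bench
stents), converting angles to pitches on the template diameter — with
the 12.7 mm template this reproduces the published pitch set
{10.7, 14.5, 18.6, 23.0, 27.9} mm — and evaluating each design's area
ratio at the reference pressure.

The pitch window itself comes from two criteria at 10 cmH₂O:

* `max_pitch_for_target_reduction()` — the pitch at which the (thinner)
  wire's stent-only area reduction reaches 30%; larger pitches
  under-support the airway.
* `wire_insensitive_pitch()` — the largest pitch at which the two wire
  diameters predict area ratios within 0.05 of each other; below it the
  thin wire performs like the thick one, so shorter pitches buy nothing
  for the extra foreign material.

Both criteria are evaluated on the stent-only area predicted by the
model; the additional reduction from tracheal tissue stretching between
coils is an experimental quantity outside this package's scope. With the
default 75 GPa modulus the two criterion pitches land within a degree of
the nominal 15°/35° design-band edges (the acceptance script computes
them at ≈14.2° and ≈35.3°); the exact angles scale with the assumed
modulus, which shifts both in the same direction.

`select_stent()` implements the deployment rule: the smallest prepared
stent diameter at least as large as the measured tracheal diameter, so
the stent is preloaded against the wall (resisting migration), with a
warning when the preload margin exceeds a configurable cap (default
2 mm).

## What the fixture generator emulates — and what it does not

`fixture_generator()` draws admissible design points spanning the
clinically plausible envelope: templates 8–20 mm (pediatric tracheal
range), wires 0.2–1.0 mm, helix angles 10–40°, moduli 40–83 GPa
(martensitic-to-austenitic NiTi), loads up to 20 cmH₂O. The oracle
suites check, over these cases, that the closed-form equilibrium pitch
matches dense-grid energy minimization (≤1 µm grid plus local
refinement) and that the closed-form line force matches a virtual-work
finite difference of the minimized energy.

Passing these tests shows the closed forms solve the stated variational
problem — not that the model predicts real airways. Real tracheas have
cartilage rings, nonuniform stiffness, tissue that stretches between
coils (the dominant area-loss mechanism at large pitch in bench
phantoms), friction, and superelastic wire behavior; none of these are
modelled. Model predictions here are a worst-case *stent-only* bound on
area preservation.

## Problem sizes in the shipped tests

The test suite runs the oracle comparison on 100 seeded random cases
plus the ten bench geometries at compressions $d/d_0 \in \{0.99, 0.95,
0.9, 0.8\}$, monotonicity and inverse-roundtrip checks on 21-point
sweeps to 20 cmH₂O per bench geometry, and 100-point forward scans of
$\rho(d)$ on $[0.7\,d_0, d_0]$ — sizes at which every check is
discriminating yet the whole suite completes in well under a minute.

## Known limitations

* Linear elasticity: superelastic plateau, hysteresis and temperature
  dependence of NiTi are not represented; the effective modulus is the
  user's choice.
* Central-helix idealization: end coils, which deviate from a helix, are
  not modelled.
* Frictionless contact: the axial force component is exactly zero; no
  friction option exists.
* Compression only; adjacent-coil contact and buckling are outside the
  model's validity and are not detected.
* Tissue mechanics are out of scope entirely: predicted area ratios are
  stent-only.
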