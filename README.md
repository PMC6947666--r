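# helistent

Mechanics-based design of helical airway stents.

Children with tracheobronchomalacia have airways that collapse during
expiration; the standard treatment, positive pressure ventilation at
5–10 cmH₂O, keeps them ventilator-bound for months. A helical NiTi wire
stent can supply equivalent radial support while covering only a thin
helical strip of epithelium — preserving mucus transport and allowing
removal by unscrewing. Sizing such a stent requires predicting how much
a given helix (diameter, pitch, wire gauge) is compressed by a uniform
external pressure, and then searching the pitch × wire-diameter design
space for the least invasive design that still holds the airway open.
`helistent` is that model and that search, for engineers and
device-design researchers working on compliant-airway stenting.

## The model

The stent wire is an inextensible, unshearable, linearly elastic rod
whose centerline remains a helix away from the ends. A helix of
diameter *d* and pitch *p* has body-frame curvature
u = (0, 2π²d/c², 2πp/c²), c = √(π²d² + p²). Holding the stent at a
reduced diameter d < d₀ stores elastic energy

    E = (ℓ/2) (u − û)ᵀ K (u − û),   K = diag(k_b, k_b, k_t)

with k_b = E_Y π r⁴/4 and k_t = G π r⁴/2 the section rigidities of the
round wire. The equilibrium pitch at fixed d minimizes E — a quartic
stationarity condition solved in closed form via its companion matrix.
The Cosserat rod balance under a frictionless, purely radial distributed
load then gives the contact line force in closed form,

    f_x = ((u_y² + u_z²)/u_z) ((k_t − k_b) u_y u_z − k_t û_z u_y + k_b û_y u_z),

and projecting pressure onto one coil (f = ρ π d p / c) converts it to
the supported external pressure ρ(d). The map ρ(d) is inverted by
safeguarded Newton iteration to get the deformed diameter, pitch and
normalized cross-sectional area (d/d₀)² at any load.

## Worked example

The deployed in vivo design — 13.21 mm helix diameter, 18.6 mm pitch
(a 25° helix angle on the 12.7 mm template), 0.51 mm wire — under
10 cmH₂O:

```r
library(helistent)

geom <- helix_geometry(d0 = 13.21e-3, p0 = 18.6e-3, d_wire = 0.51e-3, n_coils = 3)
mat  <- wire_material()          # E = 75 GPa, nu = 0.3 (austenitic NiTi)
diameter_under_pressure(geom, mat, pressure_convert(10, "cmH2O", "Pa"))
#> Deformed stent state
#>   pressure    : 980.665  (10 cmH2O if SI)
#>   diameter    : 0.0128082  (d0 = 0.01321)
#>   pitch       : 0.0187782  (p0 = 0.0186)
#>   area ratio  : 0.94009  (5.99% reduction)
#>   line force  : 16.6874   energy: 0.000223778
```

Under a full positive-pressure-ventilation load the stent itself gives
up only 6% of its cross-sectional area (diameter 13.21 → 12.81 mm) while
its pitch grows from 18.6 to 18.78 mm — the stent lengthens as it
narrows. (Real airways lose additional area to tissue stretching between
coils, which this stent-only model deliberately excludes.)

The design-space sweep over the two candidate wires and the five
design helix angles, evaluated at the same reference pressure:

```r
tbl <- build_design_table(mat = mat)
round(data.frame(wire_mm = tbl$d_wire*1e3, angle_deg = tbl$theta_deg,
                 pitch_mm = tbl$p0*1e3, area_ratio = tbl$area_ratio_at_ref), 3)
#>    wire_mm angle_deg pitch_mm area_ratio
#> 1     0.38        15   10.691      0.919
#> 2     0.38        20   14.522      0.882
#> 3     0.38        25   18.605      0.835
#> 4     0.38        30   23.035      0.777
#> 5     0.38        35   27.937      0.705
#> 6     0.51        15   10.691      0.972
#> 7     0.51        20   14.522      0.959
#> 8     0.51        25   18.605      0.940
#> 9     0.51        30   23.035      0.915
#> 10    0.51        35   27.937      0.881
```

Larger pitch and thinner wire mean a softer stent (smaller area ratio);
the design goal is the softest stent that still meets the support
criteria, solved by `max_pitch_for_target_reduction()` and
`wire_insensitive_pitch()`. `select_stent()` then picks the deployment
diameter that preloads against a measured trachea.

The same operations are available from a shell:

```sh
scripts/helistent deform --wire-mm 0.51 --angle-deg 25 --template-mm 12.7 \
    --coils 3 --pressure 10cmH2O
scripts/helistent design-table --out designs.csv
scripts/helistent select --candidates-mm 10.03,11.62,13.21,14.80,16.38 --trachea-mm 13.2
```

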