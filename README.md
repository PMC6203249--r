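# smolrate

Steady-state Smoluchowski reaction rates and the effect of off-center
binding sites in enzyme models.

## The problem

Promiscuous enzymes often bind non-native substrates at sites well away from
the catalytic center — in hydroxycinnamoyltransferases, for example, a
neutral non-native acyl acceptor binds in a pocket more than 8 Å from the
catalytic histidine and has to diffuse through the lumen to react. Does such
an *off-center* binding site speed the reaction up (by concentrating
substrate inside the lumen) or slow it down (by trapping it far from the
chemistry)? `smolrate` answers this quantitatively for anyone modelling
diffusion-influenced enzyme kinetics: computational structural biologists,
enzyme engineers, and students of diffusion-reaction theory.

## The model

The substrate density ρ(**x**) satisfies the steady-state Smoluchowski
equation in a potential U,

∇ · D e^(−U/k_BT) ∇( e^(U/k_BT) ρ ) = 0,

with ρ = c_bulk on a far-field boundary, zero normal flux on reflecting
walls, and the radiation (Collins–Kimball) condition **J**·**n** = α ρ on the
catalytic surface (α = ∞ ⇒ perfect absorber, ρ = 0). The rate constant is
the flux integrated over the catalytic surface, k = (1/c_bulk) ∮ **J**·**n** dS,
reported in Å³/ns and M⁻¹s⁻¹. A binding site is a spherical square well
(U = ΔG_b ≤ 0 inside a sphere of radius r_b), and the quantity of interest is

Δk = 100 · (k − k₀) / k₀ (%),

from paired solves with and without the site on one shared finite-volume
grid. Geometries: a parameterized cylindrical enzyme model (lumen H_in × r_in
carved into a reflecting body, catalytic disk in the base) and imported
surface meshes (OFF/PLY/STL) with tagged catalytic patches. On top of the
solver sit affinity/volume/reactivity/elongation scans, a site-splitting
experiment with matched distance distributions, MD-trajectory metrics (swing
angle, two-state transition rates, occupancy maps, visited volume, contact
lifetimes), and seeded synthetic-trajectory generators that validate them.

## Worked example

```r
library(smolrate)

geom <- build_cylinder_model()                    # H_in = 9 A, r_in = 6 A
site <- place_site(geom, d = 3, r_b = 1.8, dG_b = -2)
compute_delta_k(geom, site, transport_params())
```

```
k = 501.951 A^3/ns = 3.023e+08 M^-1 s^-1
k0 = 460.855 A^3/ns = 2.775e+08 M^-1 s^-1 (no binding site)
delta_k = +8.917 %
```

Read: without any binding site, substrate diffusing at D = 78 Å²/ns reaches
the perfectly absorbing 2.5-Å catalytic disk at k₀ = 2.8×10⁸ M⁻¹s⁻¹ — the
diffusion-limited scale. Adding a weak (−2 kcal/mol) 1.8-Å-radius site 3 Å
above the catalytic center raises the rate by ~9%. Deepening the well to
−4 kcal/mol only nudges Δk to ~10% (the well's Boltzmann factor already
saturates its effect), while doubling the site's *volume* at −2 kcal/mol
takes Δk to ~19% — size beats strength. The same call with
`scan_reactivity` shows the whole effect evaporating once the reaction is no
longer diffusion-influenced (k₀ ≲ 10⁷ M⁻¹s⁻¹).

Trajectory side, in one breath:

```r
gen <- generate_telegraph_trajectory(rate = 1.7, duration = 10000, seed = 1)
ser <- detect_transitions(swing_angle(gen$trajectory, gen$reference, resno = 372))
ser$rate      # ~1.8 /us on this seed; mean over 20 seeds = 1.72
```

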