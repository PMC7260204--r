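# beadscape

Three-dimensional simulation of superparamagnetic microbead transport over
patterned soft-magnetic thin films — the steering mechanism behind many
magnetophoretic lab-on-a-chip devices, where beads carrying biomolecular
cargo are trapped by the stray field of micron-scale magnetic elements and
walked across the chip by rotating or switching an external field.

## Who this is for

Designers of magnetic bead-transport chips (discs, element lattices,
exchange-biased stripe ratchets, asymmetric track elements) who want to
forecast bead trajectories — including out-of-plane looping and lifting that
optical microscopy cannot measure — before fabricating a structure.

## The model

Given a discretized magnetization state **M**ₚ of the parent structure (from
a micromagnetic solver via OVF files, or the built-in saturated-mask
generator), the bead is a field-aligned point dipole
**m** = χ **H**ₑₓₜ (4π/3) r³ and its potential energy at position **s** comes
from the magnetostatic reciprocity theorem:

    U(s) = -μ₀ ∫ Mₚ · [2 H_mb(r - s)] dV

so the parent's stray field is never computed.  The map sampled on
(field state × z × y × x) is compressed into a continuously evaluable form

    U(t, s) = F₁ᵀ(t) 𝒜 p(s) + F₂ᵀ(t) 𝔅 p(s)

with Fourier rows F₁, F₂ up to order N in time and the 11-term polynomial
basis p(s) = (1, x, y, z, xy, xz, yz, xyz, x², y², z²) fitted per 3×3×3
submatrix in space.  Forces are the analytic negative gradient, and the
equation of motion

    m_eff s̈ = -Γ_hd ṡ ∘ (1 + 9r/16(r+z), 1 + 9r/16(r+z), 1 + 9r/8(r+z))
              + F_m + F_f (+ F_G)

is integrated with a stiff solver under a 0.7 ms step cap, with
wall-corrected Stokes drag (Γ_hd = 6πηr), dry friction proportional to the
downward magnetic force at ground contact, buoyancy-corrected gravity,
automatic 2D/3D regime switching, a floor clamp at the surface, and periodic
boundary handling with unwrapped coordinates.  See the methods vignette
(`vignettes/bead-transport-model.Rmd`) for assumptions and numerical
choices.

## A worked example

An 8 µm bead circling a 15 µm permalloy disc under a 20 mT field rotating at
0.9 Hz — the overcritical regime where the bead periodically detaches,
loops outward and upward, and is recaptured:

```r
library(beadscape)
res <- run_scenario(build_scenario("disc", coarse = TRUE))
res$metrics$looping[, c("t_start", "max_edge_distance", "max_z")]
```

```
    t_start max_edge_distance        max_z
1 0.4381912      1.116353e-05 6.891583e-07
2 1.2249755      1.115584e-05 6.820185e-07
3 2.0061599      1.116782e-05 6.749225e-07
...
```

Eight looping events in six field periods: the bead swings out to ~11 µm
beyond the disc edge at each loop apex (the published experiments report
~10 µm) and lifts ~0.7 µm off the surface.  The lift is the one quantity
that depends strongly on the internal flux-closure structure of the disc's
onion state, which the built-in uniform saturated mask deliberately omits —
see the vignette for what the synthetic states do and do not emulate.

The four scenario presets (`"disc"`, `"triangles"`, `"stripes"`, `"ovals"`)
carry the published geometry, field sequences, susceptibility χ = 0.0256,
friction coefficient 0.03 and fit orders; `coarse = TRUE` scales grid
resolutions (never physics) for desk-scale runs.

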