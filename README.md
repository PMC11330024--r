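# harlequin

Simulation and analysis of spotted and harlequin pigmentation patterning on
*Phalaenopsis* (moth orchid) flowers, modelled as a two-species
activator–inhibitor reaction–diffusion system.

## The model

Anthocyanin spots on *Phalaenopsis* sepals/petals are patterned by the MYB
activator **PeMYB11** (concentration `A`, μM) and the diffusible repressor
**PeMYBx** (`H`, μM), interacting as a Gierer–Meinhardt system on a periodic
square domain:

```
∂A/∂t = G_A·A²/(H + k) + ρ_A + D_A·ΔA − μ_A·A
∂H/∂t = G_H·A²              + D_H·ΔH − μ_H·H
```

`G_A` is the self-activation potency of PeMYB11, `G_H` the potency with
which `A²` drives PeMYBx production, `D_A ≪ D_H` the diffusion rates
(local self-activation, lateral inhibition), `μ_A`, `μ_H` degradation
rates, `ρ_A` a basal activator source, and `k` a saturation constant.
The standard parameter set is `D_A = 0.01`, `D_H = 0.5`,
`μ_A = μ_H = 0.03`, `G_A = 0.08`, `G_H = 0.12`, `ρ_A = 0.01`,
`k = 0.001`. The activator starts uniform-random on [0, 1] per cell, the
inhibitor at zero; time and space are dimensionless.

Two documented genetic perturbations are encoded as named scenarios:

* **solo-LTR *HORT1* insertion** in the *PeMYB11* promoter enhances
  transcription → increased `G_A` (0.1632, 0.66, 2.712 = 33.9 × 0.08, and
  the high-end probes 7 and 70);
* **reduced miR858** (which targets *PeMYB11* mRNA) in purple tissue →
  reduced `μ_A` (0.01);
* their **combination**, and a **heterogeneous** tissue where piece-wise
  `G_A` values (`G_A_pur = 7` where the enhancing solo-LTR sits,
  `G_A_whi = 0.0296 = 0.37 × 0.08` where full-length *HORT1* represses)
  are assigned via a binary mask.

The package provides: a spectral semi-implicit (IMEX) solver with an
explicit-Euler reference scheme, linear (Turing) stability analysis,
seeded synthetic initial fields and masks, and quantitative pattern
metrics (spot labelling on the periodic domain, area fraction, fusion
index, activator–inhibitor correlation, radial spot decay).

## Worked example

```r
library(harlequin)

## Is the standard set Turing unstable, and at what spacing?
dispersion_relation(kinetic_params())
#> Dispersion relation:
#>   lambda_max = 0.000814862 at q = 0.6473 (wavelength 9.71 grid units)
#>   q = 0 growth rate: -0.0100017
#>   Turing unstable: TRUE

## Simulate the standard spotted pattern on the 100 x 100 periodic grid
sim <- simulate_pattern("standard", seed = 1)
sim
#> Reaction-diffusion pattern: scenario 'standard', 100 x 100 grid, seed 1
#>   t = 9818.39 after 5663 steps (steady state reached)
#>   A in [0.47, 6.33], H in [3.37, 10.5] uM

summary(sim)
#> Scenario 'standard' (t = 9818.39, converged)
#> Pattern summary (threshold 2 uM):
#>   spots: 96, area fraction: 0.0488
#>   spot area: mean 5.1, max 7 cells; fusion index 0.014
#>   activator-inhibitor correlation: 0.893

plot(sim)                   # heatmap of A
plot(sim, type = "contour") # spot outlines at the 2 uM threshold
```

The dispersion relation predicts a fastest-growing wavelength of ~9.7 grid
units, i.e. on the order of a hundred spots on the 100 × 100 grid — and the
simulation delivers 96 disjoint spots covering ~4.9 % of the tissue. The
positive activator–inhibitor correlation (0.893) shows the two expression
patterns are in phase, and each spot's concentration decays monotonically
from its centre (median radial-decay fraction 1.0 for this run):

```r
rd <- radial_decay_check(sim$A, summary(sim)$spots)
rd$median
#> [1] 1
```

Scenario presets are listed by `preset_scenarios()`; e.g.
`simulate_pattern("combined_2712", seed = 1)` reproduces the fused
harlequin-like patches (fusion index 1.0 versus 0.04 for the enhanced-`G_A`
scenario alone). A thin command-line wrapper with `simulate`, `sweep`,
`analyze`, `stability` and `presets` subcommands is installed at
`inst/cli/harlequin`.

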