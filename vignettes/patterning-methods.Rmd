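---
title: "Modelling harlequin Phalaenopsis pigmentation patterning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling harlequin Phalaenopsis pigmentation patterning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 5,
                      fig.height = 5)
library(harlequin)
```

## The model and its assumptions

Spotted anthocyanin patterning on *Phalaenopsis* flowers is modelled as a
two-species Gierer–Meinhardt system: the MYB activator PeMYB11 (`A`, μM)
self-activates saturably and drives production of the diffusible repressor
PeMYBx (`H`, μM), which in turn suppresses the activator:

$$\frac{\partial A}{\partial t} = \frac{G_A A^2}{H + k} + \rho_A
  + D_A \Delta A - \mu_A A, \qquad
\frac{\partial H}{\partial t} = G_H A^2 + D_H \Delta H - \mu_H H.$$

The assumptions built into this formulation:

* **Two species suffice.** The many other MYB repressors known in the
  system are collapsed into the single diffusible inhibitor; this keeps
  the model identifiable from pattern-level observations.
* **Local activation, lateral inhibition.** `D_H` must exceed `D_A` for a
  Turing instability; the constructor enforces `D_H > D_A` (an escape
  hatch, `check_diffusion = FALSE`, exists solely for stability negative
  controls such as equal diffusion).
* **Dimensionless time and space.** No time unit or physical grid spacing
  is asserted for this system; the package treats both as dimensionless
  and labels concentrations in μM. The domain is the periodic square
  `[0, L]²` with `L = 100` and unit grid spacing by default
  (`sim_grid(n)` uses `L = n` so spacing stays 1 at any resolution).
* **Initial conditions.** `A(0, r)` is i.i.d. uniform on [0, 1] per grid
  cell (seeded, Mersenne-Twister); `H(0, r) = 0`, since the inhibitor is
  produced only downstream of the activator. These are the study
  conditions, not tunables.

The standard coefficients are `D_A = 0.01`, `D_H = 0.5`,
`μ_A = μ_H = 0.03`, `G_A = 0.08`, `G_H = 0.12`, `ρ_A = 0.01`,
`k = 0.001`.

## Linear stability as the analytic backbone

`homogeneous_steady_state()` solves the scalar balance on the nullcline
`H = (G_H/\mu_H) A^2` by a bracketed root search on
`[10^{-8}, A_{hi}]`, `A_{hi} = 10\,(G_A/(\mu_A G_H/\mu_H) + \rho_A/\mu_A)`,
taking the *largest* sign change (the stable outer branch) and polishing
with Newton steps until both reaction residuals are below `1e-12`. The
bracket covers every scenario in the preset registry; the residual check
turns any regression into a hard error rather than a silently wrong fixed
point.

`dispersion_relation()` evaluates the largest real eigenvalue of the
linearization at each wavenumber on `[0, π]` (200 points by default; π is
the Nyquist limit at unit spacing, and 200 points resolve the unstable
band for all presets):

```{r dispersion}
dr <- dispersion_relation(kinetic_params())
dr
plot(dr)
```

The fastest-growing mode (`q ≈ 0.65`, wavelength ≈ 9.7 grid units) is the
package's analytic oracle: it predicts on the order of `(100/9.7)² ≈ 106`
spots on the default grid, which the nonlinear simulation corroborates
(~90–100). Its growth rate `λ_max ≈ 8×10⁻⁴` also sets the patterning
timescale: the pattern needs tens of e-folding times
(`1/λ_max ≈ 1200` time units) to emerge and saturate, which motivates the
default stopping cap below.

## Time integration

The production scheme (`solver_control(scheme = "imex")`) is first-order
semi-implicit: diffusion *and* linear decay are solved implicitly through
the exact spectral diagonalization of the periodic 5-point Laplacian (2-D
FFT; eigenvalues `-4\sin^2(\pi m/n)/h^2` summed over the two axes), while
the nonlinear reaction terms stay explicit. Folding the decay terms into
the implicit operator keeps the step stable even when the explicit part is
large (the `G_A = 70` scenario reaches activator levels of ~8000 μM).
An explicit-Euler scheme over the same stencil serves as the independent
reference.

Numerical choices that matter:

* **Step policy.** The adaptive default starts at `dt = 0.1` and grows
  the step geometrically (×1.05 per step) to `dt_max = 5`. Because the
  inhibitor starts at zero and `k` is small, the first instants are
  violent — `A²/k` is of order 10³–10⁴ — so every step is additionally
  limited so the explicit increment cannot exceed half the current field
  scale (`limiter = 0.5`). Without this limiter the strongly enhanced
  scenarios (`G_A ≥ 2.712`) are thrown onto an unphysical trajectory and
  never pattern; with it, every preset converges. The limiter replaces
  step-doubling error control at a third of the cost.
* **Stopping rule.** No stopping time is asserted for the system, so the
  solver stops on a convergence criterion:
  `max|ΔA, ΔH| / (dt (1 + max A)) < 10⁻⁶`, with a hard cap
  `t_end = 20000`. The cap is sized from the dispersion analysis above —
  standard-scenario runs typically converge near `t ≈ 10⁴`. The slowest
  presets (combined enhancement + low degradation) keep coarsening past
  the cap; their metrics are insensitive to this (the pattern is already
  fully fused), and the `converged` flag reports the distinction honestly.
* **Positivity.** Concentrations are clamped at zero after every step
  (`positivity = TRUE`); the clamp is part of the scheme, not a fix-up —
  the uniform-[0,1] initial activator with zero inhibitor otherwise
  produces transient negative undershoots in the implicit solve.
* **Determinism.** Identical seed and configuration give bit-identical
  fields within a scheme; all randomness flows through the seed.

### Scheme agreement

IMEX and Euler share the steady equation (the dt-dependence cancels at a
fixed point), so their converged patterns differ only through transient
trajectory divergence, which is concentrated in the violent initial
instants. Integrating both schemes with fine fixed steps (`dt = 0.0125`)
until `t = 100` and `dt = 0.2` thereafter yields thresholded masks that
disagree on ~1.2 % of cells on the 100 × 100 grid; with coarse early
steps the spot positions shift by a cell or two (~5 % of cells) while all
summary metrics remain equal to within a few percent.

## Scenarios

`preset_scenarios()` encodes each documented perturbation with printed
parameter values: enhanced self-activation (`G_A` of 0.1632, 0.66, 2.712,
7, 70), reduced degradation (`μ_A = 0.01`), both combined, and the
piece-wise tissue (`G_A_pur = 7`, `G_A_whi = 0.0296`, `μ_A = 0.01`).
Two registry values deserve a note: the tetraploid preset stores the
conventional rounded 0.66 rather than the exact `0.1632 × 4 = 0.6528`
(the scaling helpers `fold_scaled_GA()` / `ploidy_scaled_GA()` stay
exact), and `solo_ltr_2x` stores 0.1632 verbatim rather than recomputing
an implied fold change.

For the heterogeneous tissue the assignment rule for which cells carry the
enhancing versus repressing insertion is only known pictorially, so the
mask is a user input. `make_mask()` offers Bernoulli, block, and blob
generators plus CSV file input; the default used by
`simulate_pattern("heterogeneous")` is a seeded blob mask (white noise
smoothed with a periodic Gaussian of 5 grid units, thresholded at its
empirical quantile for a 0.5 covered fraction). Blob masks guarantee the
covered fraction by construction and give contiguous patches several
cells across — plausible for a clonal insertion pattern, but *not* a
reconstruction of any real flower; conclusions for that scenario are
therefore property-based (coverage, fusion, layering), never
pixel-matching.

## Pattern metrics

All metrics operate on the final activator field:

* `threshold_mask()` uses a strict `>` at the 2 μM visualization
  threshold (a cell exactly at threshold is background).
* `label_spots()` labels connected components with 4-connectivity by
  default and merges across the periodic boundary, matching the solver's
  topology; both choices are flags. An independent min-label-propagation
  oracle backs it in the tests.
* `pattern_summary()` reports spot count, area fraction, mean/max spot
  area, the **fusion index** (largest spot area / total above-threshold
  area — dimensionless, monotone under merging, 1.0 when fully fused),
  and the Pearson correlation of `A` and `H` as the operational meaning
  of "in-phase" (the fields' maxima coincide spatially; a linear
  association captures this without phase machinery).
* `radial_decay_check()` bins each spot's cells by rounded toroidal
  distance from its peak and scores the fraction of consecutive ring
  pairs with non-increasing mean (ties count as non-increasing;
  single-ring spots score 1).
* `relative_threshold()` implements the deep-colour layer for piece-wise
  runs: the `G_A_whi/G_A_pur` proportion of the maximum activator level,
  clamped from below by the basic 2 μM threshold. The clamp matters: for
  the documented pair (0.0296, 7) the raw proportion times any plausible
  maximum sits *below* 2 μM, so without the clamp the "deep" layer would
  invert. With ratio 0.4 and a 10 μM maximum the rule gives the 4 μM
  deep-layer threshold used for two-tone renderings.

## What the simulations show

Run at the study conditions (100 × 100 grid, five seeds), the scenarios
reproduce the documented qualitative transitions, quantified:

* **Standard:** ~96 disjoint spots, area fraction ~0.05, `A`–`H`
  correlation ~0.89, median radial-decay fraction 1.0.
* **Rising `G_A`** (0.08 → 0.1632 → 0.66 → 2.712): median area fraction
  climbs ~0.05 → 0.09 → 0.22 → 0.39, monotonically, while the fusion
  index stays below 0.05 — enhanced transcription alone enlarges spots
  but does not fuse them. Beyond 2.712 the *coverage* saturates and then
  dips slightly at `G_A = 7` (the amplitude grows tenfold against a fixed
  2 μM threshold, so spots become fewer, taller and individually larger:
  mean spot area keeps rising), which is why the package asserts
  coverage monotonicity on {0.08, …, 2.712} and mean-level/spot-size
  monotonicity on the full range.
* **`μ_A = 0.01`:** the pattern floods — area fraction ~1.0 ("full red").
* **Combined (2.712, 0.01):** a single system-spanning patch — fusion
  index 1.0 and a largest spot of ~10⁴ cells versus ~150 at standard
  degradation; the harlequin morphology.
* **Heterogeneous:** coverage ~0.77 with both tones present; cells under
  the *repressed* potency still colour (lateral activation across the
  mask boundary), consistent with finding the repressing insertion inside
  purple tissue.

## What the synthetic inputs do and do not emulate

The uniform-random activator field emulates unbiased developmental noise
at patterning onset; the blob masks emulate contiguous clonal sectors.
Real petals add everything the model idealizes away: curved growing
domains, anisotropic growth, boundary effects at petal edges (the torus
has none), parameter gradients, and the full multi-repressor MYB network.
Passing tests therefore demonstrate internal consistency of the mechanism
— differential-diffusion instability plus the documented parameter shifts
produce the documented pattern transitions — not a calibrated model of
any particular flower.

## Problem sizes and limitations

The test-suite and acceptance runs use the full 100 × 100 grid with five
seeded replicates per scenario; smaller grids (16–32) appear only in unit
tests of solver mechanics where the physics is not at issue. Known
limitations: first-order time accuracy (adequate because only the steady
attractor is of interest); the spectral implicit solve requires uniform
`D` and `μ` (only `G_A` may vary spatially — exactly the heterogeneity
the scenarios need); metrics assume the periodic topology; and scenario
conclusions for the heterogeneous tissue depend on the mask family chosen,
as discussed above.
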