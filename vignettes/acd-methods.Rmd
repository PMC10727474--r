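---
title: "Modelling autologous cell defection: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling autologous cell defection: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acdsim)
```

## The problem

Cancer cells cooperate: they secrete diffusible cancer growth factors
(CGFs) that raise the fitness of neighbouring cells carrying the matching
receptors, at a metabolic cost to the producer. Autologous cell defection
(ACD) is a proposed therapy that weaponises this cooperation: tumour cells
are extracted, engineered so that they no longer produce CGFs (while still
responding to them and resisting lactate acidification), and re-implanted.
These "hypertumour" defectors parasitise the cancer cluster — they enjoy
the public goods without paying for them — and, once the producers are
gone, should collapse by themselves because their mutation burden makes
them inferior to normal tissue.

`acdsim` implements two complementary models of this process:

1. a **stochastic spatial simulator**: a 2D lattice of cells with nine
   boolean oncogene loci, diffusible CGFs and lactate, one-way mutation,
   immune surveillance, a death–birth update rule, and CGF-reducing drugs;
2. a **deterministic interface model**: four cells straddling the
   hypertumour–cancer boundary, used to ask when a CGF-reducing drug
   promotes or impedes hypertumour progression under different
   CGF-to-fitness transformations.

## The genotype and cell classes

A genotype is nine one-way boolean loci: production of GF1–GF3 and of
lactate (the Warburg effect), reception of GF1–GF3, lactate resistance, and
immune evasion. Mutation turns a locus on, never off; at the population
level normal cells can therefore only arise by replication of normal cells.

Classes follow CGF emission and reception only (Warburg status and immune
evasion are deliberately orthogonal, so class counts reflect the
public-goods roles):

* **NORMAL** — all loci wild-type;
* **CANCER** — produces and receives all three CGFs (full hallmarks);
* **HYPERTUMOUR** — produces no CGF, receives all three, lactate-resistant;
* **PARTIAL_HYPERTUMOUR** — produces no CGF, receives one or two;
* **OTHER_MUTANT** — everything else.

The engineered implants keep every hallmark except CGF production
(`make_archetype("HT_WARBURG")`), optionally also dropping lactate
production (`"HT_NO_WARBURG"`). The design choice here is that extraction
and modification remove *only* CGF production: the implants retain immune
evasion and lactate resistance.

Immune elimination is linear in the mutated-allele fraction,
`p = alpha * m/9`, and evasion is absolute. Linearity is the simplest
monotone choice consistent with "more mutated, more visible"; `alpha` is
configurable.

## Diffusion

Each factor has a square kernel stencil of radius
`max(1, round(base_radius * scale(model)))` whose weights decay as
`exp(-d/lambda)` in the Euclidean offset `d`, with `lambda = radius/2`,
rescaled so the weights sum to the factor's *mass*. Mass is conserved
exactly across the permeability models A/B/C (scales 1, 0.5, 2): a more
permeable tissue spreads the same total amount over a wider range at lower
average concentration. Default base radii are GF1 = 2, lactate = 3,
GF2 = 4, GF3 = 6 (GF1 shortest, GF3 longest, lactate in between); masses
default to 1. The exact profile and radii are not constrained beyond the
orderings and the conservation law, so both are configuration.

Fields are recomputed from the current occupancy each step (no temporal
accumulation or decay) by clipped-edge convolution; contributions falling
off the grid are lost. With all activity central in the standard geometry,
edge effects are negligible. The compiled core updates fields
incrementally — only sites whose production bits changed since the last
step restamp their kernels — which is algebraically identical to the full
recomputation up to floating-point associativity.

## Fitness

For a cell with genotype `g` and local concentrations `g_k`:

```
w = max(eps, w_base + sum_k rec_k A_k r_k g_k
                    - sum_k prod_k c_k - prod_L c_L
                    - (1 - resist) d g_L - mu * n_mutated)
```

CGF benefits are linear (the simulator's stated assumption); a drug
multiplies received concentrations by `r_k` in (0, 1], the standard
treatment being `(0.5, 0.5, 1)` — halve GF1 and GF2. Lactate harms
non-resistant cells through a fitness penalty rather than an extra death
probability (it "damages" rather than kills). Every mutated locus costs
`mu`, which is what makes hypertumours collapse once their cancer hosts are
gone.

The magnitudes are not published, so the defaults (`A_k = 1`,
`c_k = 0.3`, `c_L = 0.05`, `d = 0.5`, `mu = 0.05`, `w_base = 1`) were
calibrated once against four qualitative constraints and then frozen:

1. a full cancer cell beats normal tissue inside its own CGF cloud;
2. a hypertumour beats a cancer cell at an equal field;
3. normal tissue beats an isolated hypertumour (mutation burden);
4. on the initial fitness map of the standard implant geometry, the
   hypertumour cells at the implant boundary beat the adjacent cancer
   cells — the condition for encroachment to start.

The first three are asserted at load by `check_fitness_regime()`.
Constraint 4 is the sharp one: it ties the production-cost saving
(`3 c_k + c_L`) to the CGF gradient across one lattice spacing, which the
short-ranged GF1 kernel makes steep. Costs of 0.1 per factor fail it (the
implant is eaten by the cancer ring); 0.3 satisfies it with a clear margin.

## Dynamics

One step runs: fields → fitness map → death → birth → mutation → metrics.
The order is a design choice — fitness reflects the configuration at the
start of the step, and newborns can mutate immediately. Death is uniform
(`p_death`, default 0.05) compounded independently with immune detection;
fitness affects replication, not survival. Every vacancy with a live von
Neumann neighbour is refilled synchronously by a fitness-proportional copy
of a neighbour (pre-fill occupancy: offspring cannot parent in the same
step); if all candidates sit at the floor `eps` the parent is uniform.

Randomness is a single seeded stream consumed in a fixed documented order
(death draws, birth draws, mutation draws, each column-major), so a run is
bit-reproducible from `(initial, config, n_steps, seed)`. The R phase
functions and the compiled core follow the same draw order and agree
bit-for-bit; the test suite asserts this.

Metrics are computed over live cells only, which makes fixation of the
(partial) hypertumour proportion at exactly 1 representable.

## Experiments

The standard geometry is a 100×100 normal field, a centred 22×22 block of
full-hallmark cancer, and a 12×7 implant hole at its centre (0-based rows
46–52, columns 44–55; since 22 − 7 is odd the extra row goes below
centre). The hole holds normal cells (control) or one of the two
hypertumour archetypes. The full design crosses three centre fills with
drug on/off for each diffusion model — six ensembles of 500 replicates ×
10 000 steps each (30 000 for Model B without drug). Replicate `i` runs
with seed `base_seed + i`, making ensembles order-independent.

Because the final composition can diverge between replicates,
`split_by_final_proportion()` partitions an ensemble at a threshold
(default 0.5) on the final hypertumour + partial-hypertumour proportion
and re-aggregates each group.

The package's own acceptance checks run a scaled-down version of this
design — 20 replicates × 3000 steps, Model A — which is where the
qualitative treatment effects are already stable under the default
parameters: implants lower the final cancer proportion versus control;
non-Warburg implants end with fewer hypertumours than Warburg ones (the
lactate field lets Warburg defectors linger in normal tissue); and the
GF1/GF2-halving drug lowers the cancer proportion under linear benefits.
The full 500 × 10 000 design remains reachable through configuration.

What the generator does *not* emulate: cell migration, vasculature,
continuous time, factor decay kinetics, or anisotropic tissue. Passing the
scaled ensembles shows that the model's comparative statics are robust in
this regime, not that the parameter magnitudes are biologically calibrated.

## The interface model

Four cells at a flat hypertumour–cancer interface carry concentrations
`g1 > g2 > g3 > g4 >= 0` (cells 1–2 cancer, 3–4 hypertumour). With a
monotone transformation `F`:

```
omega1 = F(g1) - c    omega2 = F(g2) - c
omega3 = F(g3)        omega4 = F(g4)
```

Hypertumours progress stably iff `omega1 < omega3` and `omega2 < omega4`.
A drug rescales concentrations to `r g_i` (0 < r < 1); the induced fitness
changes `d_omega_i = F(r g_i) - F(g_i)` are cost-free, and

```
phi = d_omega1 - d_omega3   (or d_omega2 - d_omega4)
```

is the relative drug effect: `phi < 0` means the drug promotes hypertumour
progression. For linear `F` this is a theorem — `(r-1) A g1 < (r-1) A g3`
iff `g1 > g3` — verified both on randomized scenarios and on a
deterministic parameter lattice.

The logistic transformation is

```
F(t) = k0 / (1 + exp(-k1 (t - 1))) + k2
```

with inflection at `t = 1`. Its displayed algebraic body is corrupted in
the available source text, so the package encodes the form as the unique
three-constant logistic that satisfies the two printed boundary conditions
`F(0) = 0` and `lim F = 1`, which give `k0 = 1 + exp(-k1)`,
`k2 = -exp(-k1)`; at steepness `k1 = 5` these round to the printed 1.0067
and −0.0067, and the form reproduces every published spot value we can
check. `solve_logistic_constants()` performs the solve; the constants are
never hard-coded.

`phi_grid()` sweeps `phi` over cancer-side concentrations (default 101
points in [0.05, 5]) and hypertumour/cancer ratios (99 points in
(0.01, 0.99)) at drug factors 0.8/0.5/0.2 (20%/50%/80% reduction). With
the logistic both signs occur: a cancer cluster on the plateau with
hypertumours near the inflection yields `phi > 0` (the drug impedes ACD).
The convex/concave supplementary families are normalised powers
`min(1, (t/scale)^p)` — only their qualitative shape is specified, so the
family is configuration with documented defaults (`p = 2` / `p = 0.5`,
`scale = 5`).

```{r phi, fig.width = 6, fig.height = 4, eval = FALSE}
f <- fitness_function("LOGISTIC", k1 = 5)
autoplot(phi_grid(f, r = 0.5))
```

## Numerical choices and degenerate inputs

* Kernel weights are exact up to one final rescale; masses agree across
  models to well below 1e−9.
* The fitness floor `eps = 1e-6` keeps birth weights positive; an
  all-floor neighbourhood falls back to a uniform parent.
* An empty lattice yields `NA` proportions (live-cell denominators); a
  vacancy with no live neighbour stays vacant.
* Incremental field updates introduce only last-ulp floating-point drift
  relative to from-scratch convolution; all field tests compare against a
  brute-force oracle at 1e−10.
* Problem sizes in the test-suite reproduction (20 replicates × 3000
  steps) were chosen as the scale at which the three comparative effects
  are already unambiguous under the default parameters.

## Known limitations

* The paper's exact oncogene table and parameter magnitudes (its
  supplementary material) are not reproduced; the defaults here are this
  package's own calibrated choices, exposed as configuration.
* No coupling between the stochastic simulator and the deterministic
  interface model; they answer different questions.
* No animation export; snapshots are plain CSV grids for external
  rendering.
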