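# acdsim

Spatial simulation of **autologous cell defection (ACD)** — a proposed
cancer therapy in which a patient's own tumour cells are engineered into
non-producing "hypertumour" defectors and re-implanted to parasitise the
cancer cluster — together with the deterministic fitness model of the
hypertumour–cancer interface.

The package is for researchers in cancer evolutionary dynamics and
evolutionary medicine who want a reproducible, configurable testbed for
public-goods dynamics in tumours: diffusible cancer growth factors
(CGFs), Warburg-effect lactate acidification, one-way oncogene mutation,
immune surveillance, and CGF-reducing drugs.

## The models

**Stochastic lattice simulator.** Cells on a 2D grid carry nine boolean
oncogene loci (production of CGF1–3 and lactate, reception of CGF1–3,
lactate resistance, immune evasion). Each step: per-factor concentration
fields are the convolution of producer occupancy with mass-conserving
diffusion kernels (models A/B/C vary the range at fixed total mass);
fitness is linear in received CGF minus production costs, lactate damage
and a per-locus mutation burden,

```
w = max(eps, w_base + Σ_k rec_k A_k r_k g_k − Σ_k prod_k c_k
             − prod_L c_L − (1 − resist) d g_L − μ n_mut)
```

cells die at a baseline rate compounded with immune detection
(`α · m/9`, voided by evasion), and each vacancy is refilled by a von
Neumann neighbour chosen proportionally to fitness (death–birth process).
The standard experiment implants a 12×7 block of engineered hypertumours
inside a 22×22 cancer cluster on a 100×100 field.

**Deterministic interface model.** Four cells at the hypertumour–cancer
boundary with CGF concentrations `g1 > g2 > g3 > g4 ≥ 0`; cancer cells pay
the production cost `c`: `ω1 = F(g1) − c`, `ω2 = F(g2) − c`,
`ω3 = F(g3)`, `ω4 = F(g4)`. Hypertumours progress iff `ω1 < ω3` and
`ω2 < ω4`. A drug rescales concentrations by `r ∈ (0,1)`; the relative
drug effect `φ = Δω1 − Δω3` (with `Δω_i = F(r g_i) − F(g_i)`) is negative
when the drug *promotes* hypertumour progression. For linear `F` that is
always the case; for the logistic
`F(t) = k0/(1 + e^{−k1(t−1)}) + k2` (constants solved from `F(0)=0`,
`lim F = 1`) both signs occur.

## Worked example

```r
library(acdsim)

# implant non-Warburg hypertumours in the standard geometry and run
sim <- run_simulation(make_initial(scenario("HT_NO_WARBURG")),
                      step_config(), n_steps = 3000, seed = 7)
glance(sim)
#>    step live_count prop_normal prop_cancer prop_hypertumour prop_partial_ht
#> 1  3000      10000       0.785           0           0.0003          0.0787
```

By step 3000 the cancer cluster is extinct (`prop_cancer = 0`): the
implant encroached on it, and the defectors then collapsed themselves
(`prop_hypertumour = 0.0003`) because without CGF they lose to normal
tissue — the ideal ACD outcome. Spontaneously arising partial hypertumours
(receptive to one or two CGFs) linger at ~8%.

```r
# interface model: the printed logistic constants …
solve_logistic_constants(5)
#>      k0      k2
#>  1.0067 -0.0067

# … and the two signs of the drug effect
f <- fitness_function("LOGISTIC", k1 = 5)
phi(interface_scenario(c(3, 2.9, 1.2, 1.1), r = 0.8), f)  #  0.2819  drug impedes ACD
phi(interface_scenario(c(2, 1.9, 1.0, 0.9), r = 0.5), f)  # -0.0696  drug promotes it
autoplot(phi_grid(f, r = 0.5))   # full heatmap
```

A positive `φ` arises when the cancer cells sit on the plateau of the
logistic while the hypertumours sit near its inflection: the drug then
barely touches the cancer but sharply cuts the defectors' fitness.

Ensembles and the command line:

```r
ens <- run_ensemble(scenario("HT_WARBURG", n_steps = 3000, n_replicates = 20))
autoplot(ens)
split_by_final_proportion(ens, 0.5)
```

```sh
exec/acd-sim simulate --scenario ht-no-warburg --model A --drug off \
    --steps 3000 --seed 7 --out out/
exec/acd-sim interface-grid --f logistic --k1 5 --r 0.5 --out phi.csv
```

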