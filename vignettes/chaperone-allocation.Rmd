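---
title: "Cost-efficient allocation of holdases and foldases: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cost-efficient allocation of holdases and foldases: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proteocost)
```

# The model

`proteocost` treats proteostasis as two coupled circuits acting on the
pool of unfolded client protein `U`. The first circuit is an
ATP-consuming **foldase** (HSP60/70/90-class) that converts unfolded
protein to the native state. Foldases are saturable, so their flux is
Michaelis–Menten in the free unfolded concentration:

$$v_{foldase} = \frac{k_{foldase}\,[F]}{1 + K_m/[U]}$$

The pool is fed by new synthesis ($v_{syn} = k_{syn}[clients]$) and by
spontaneous unfolding of native protein ($v_{N\to U} = k_{N\to U}[clients]$).
Setting inflow equal to outflow gives the steady state implemented by
`steady_state_u()`:

$$[U] = \frac{K_m}{k_{foldase}[F]/v - 1}, \qquad v = v_{syn} + v_{N\to U}$$

This diverges as the load approaches the foldase capacity — the overflow
regime in which unprocessed protein accumulates and the model refuses to
return a steady state (it reports the capacity deficit instead). Far from
saturation the linear approximation
$[U] \approx K_m v / (k_{foldase} [F])$ (`linear_u()`) is accurate, but at
capacity = 10× load its relative error is already 11%, which is why the
allocator's exact mode exists.

The second circuit is an ATP-independent **holdase** (small-HSP class)
that binds unfolded protein reversibly with dissociation constant $K_d$,
holding clients in a refolding-competent state until a foldase takes them.
Because the foldase circuit equilibrates on catalytic timescales (seconds)
while holdase buffering matters over protein lifetimes (hours to days),
the two are solved sequentially — foldase steady state first, then the
binding equilibrium — rather than as a coupled dynamical system.
`holdase_partition()` solves the conservation-constrained equilibrium
exactly, and `limiting_case_u()` provides the closed-form limits (scarce
holdases; tight binding; low unfoldedness). In the physiologically typical
low-unfoldedness regime ($[U_{tot}], K_d \ll [H]$) holdases are mostly
client-free and the free unfolded level factorizes
(`combined_u_free(mode = "multiplicative")`):

$$[U_{free}] \approx \frac{K_m v}{k_{foldase}[F]} \cdot \frac{K_d}{[H]}$$

# Costs and the optimality condition

Each chaperone molecule has a one-time synthesis cost — 5 ATP per residue
polymerized and proofread, so 3,500 ATP for a 70 kDa foldase — and, for
foldases only, a running cost of `atp_per_cycle × cycle_rate` while
engaged, times an `idle_activity_fraction` when not. The default treats
the running cost as constant and load-independent (idle fraction 1,
"always on"); the variants below relax this. A chaperone runs for its
effective half-life, taken equal to the client turnover time $1/k_{syn}$.
For an HSP70-class foldase the cumulative running cost equals the
synthesis cost after `breakeven_time()` ≈ 9.7 h; HSP60-class cycles an
order of magnitude slower at comparable ATP per kDa per cycle, stretching
this to ~97 h. Beyond the breakeven, running — not making — dominates the
budget, which is the engine of every slow-growth result below.

The cell's constraint is a fixed *unfolded dwell-time budget*: a client
molecule's total expected time spent free and unfolded over its lifetime
is held constant, so the tolerated level is proportional to turnover,
$[U_{free}] \le u_o k_{syn}$ (`requirement("proportional")`; a fixed
100 nM target is available as a variant). Minimizing total ATP cost
density $c_F(k_{syn})[F] + c_H [H]$ subject to this constraint makes the
marginal decrease in $[U_{free}]$ per marginal ATP equal across the two
classes at an interior optimum; with the multiplicative equilibrium this
reduces to the unit-cost ratio

$$\frac{[H]}{[F]} = \frac{c_{foldase}}{c_{holdase}} = a + \frac{b}{k_{syn}}$$

implemented analytically in `optimal_ratio_analytic()` and verified
numerically (`marginal_residual` column) at every interior optimum.

# Default parameters

| Parameter | Default | Units | Meaning / rationale |
|---|---|---|---|
| `k_foldase` | 0.1 | 1/s | one folding attempt per ~10 s ATPase cycle (HSP70-class) |
| `Km` | 1 | µM | foldase Michaelis constant for unfolded client |
| `Kd` | 2 | µM | small-HSP functional-unit affinity for unfolded client |
| `k_NU` | 1 | 1/day | native proteins unfold over hours–days |
| `client_conc` | 100 | µM | foldase-dependent client pool |
| `u_o` | 0.1 | µM·day | dwell-time budget (100 nM·day) |
| foldase size | 70 | kDa | ⇒ 3,500 ATP synthesis cost at 5 ATP / 100 Da residue |
| holdase size | 40 | kDa | functional-unit placeholder, ⇒ 2,000 ATP |
| `atp_per_cycle`, `cycle_rate` | 1, 0.1/s | | 1 ATP per ~10 s cycle ⇒ 360 ATP/h always-on |

These are the package's defaults, chosen to be physiologically
representative of the HSP70/small-HSP system; every one is overridable
through the constructors or the flat YAML config (`read_config()`). The
holdase functional-unit size is a placeholder — small HSPs oligomerize and
no consensus per-unit mass exists. Internally concentrations are µM and
time is days; per-second catalytic rates are converted once at the
constructor boundary.

# The optimizer

`optimize_allocation()` eliminates the holdase level through
`required_holdase()` — the binding equilibrium inverts in closed form, so
the smallest holdase level meeting the target is exact, not searched — and
minimizes the resulting one-dimensional cost over $\log [F]$ between the
saturation boundary and the foldase-only solution with Brent's method
(`stats::optimize`, tolerance 1e-10 in log space). The foldase-only corner
([H] = 0) is evaluated explicitly and kept when cheaper; the structure is
near-convex in the regimes of interest, so no multistart is used. The
marginal condition is then checked by central finite differences (relative
step 1e-6) using *marginal* per-unit costs, so it remains exact for the
load-dependent-engagement variants where the average and marginal foldase
cost differ. Engagement, where it matters, is defined as load over
capacity, $v/(k_{foldase}[F])$.

Two equilibrium modes are provided because it is genuinely open which one
the model's published optimization used. The `"exact"` mode (foldase
steady state + full binding quadratic) is the default for full sweeps,
since the linear approximation fails near saturation at fast synthesis.
The `"multiplicative"` mode is the regime in which the asymptotic scaling
laws are *derived*, and it is what the slope experiments use: at the
default absolute concentrations the exact binding inversion carries a
$-K_d$ offset (holdase levels are only ~3–10× $K_d$ in the slow-growth
decade), which biases the perfect-foldase slope from −0.50 to −0.61
without changing the underlying law. The two modes agree within 15%
whenever holdases exceed 10× max($U_{tot}$, $K_d$) and capacity exceeds
10× load, which the tests verify on a random grid.

The numerical quadratic for the binding equilibrium is evaluated in one of
two algebraically equivalent forms depending on the sign of
$b = K_d + [H] - U_{tot}$, avoiding subtractive cancellation in both the
tight-binding and holdase-deficit regimes (relative accuracy ~1e-12
against an independent bisection oracle). Degenerate zeros (no holdase, no
unfolded protein) return trivially.

# Variants

`apply_variant()` reproduces the model's sensitivity analyses:
`size_x10` (700 kDa / 35,000 ATP foldase), `idle_10pct` (idle ATPase at
10% of the engaged rate), `perfect_foldase` (zero idle ATPase — the
efficient chaperone buffer), `fixed_requirement` (100 nM target at all
$k_{syn}$), and `Kd_tight` / `Kd_loose` (10 nM / 1 µM). Under the
constant-run-cost baseline the slow-growth slopes of optimal levels versus
$k_{syn}$ are −1 (holdase) and 0 (foldase); under `perfect_foldase` the
foldase's $[F]$-dependent cost collapses to its synthesis cost and both
classes share the −1/2 slope, splitting the slow-growth burden equally.

One empirical note: under the default parameter set the fast-synthesis
optimum is foldase-only — the proportional requirement loosens with
$k_{syn}$ faster than the load grows, so holdases price themselves out
above ~0.8/day. The U-shaped *total* chaperone curve and the slow-growth
holdase rise are robust; the fast-growth holdase level is known to be
assumption-dependent and is not asserted by the tests.

# Synthetic data

The package ships no empirical tables; the generators produce data with
the statistical structure the analysis assumes, so the whole chain is
testable offline.

`gen_abundance_table()` emulates cross-species chaperone levels: rates
log-uniform over 3 decades (a mouse-to-large-mammal span of basal
metabolic rates), abundances following a power law with lognormal scatter
(normal in log10 — proteomic abundances are ratio-scale), optionally one
planted, flagged outlier. With the default calibration (slope −1,
σ = 0.3 log10 units, n = 6) the OLS fitter recovers the generating slope
within ±0.35 in ≈96% of seeds. `gen_aging_trajectory()` emulates aging
proteomics: $k_{syn}$ falls geometrically by a configurable 15–30-fold
across adulthood (default 20-fold from 0.25/day, i.e. young-adult protein
half-lives of a few days), and each chaperone class tracks the model
sweep's optimal level at that $k_{syn}$ with multiplicative noise — so on
the cost-efficient path holdases rise roughly in proportion to the
synthesis decline while foldases stay within two-fold of flat.

What the generators deliberately do *not* emulate: real cross-species data
have phylogenetic correlation, tissue composition effects and measurement
error in the rate variable (none of which OLS on log-log axes corrects;
an RMA option is provided for the error-in-x concern); real aging
proteomics mix compartments and include holdases that deviate from the
average path. Passing the round-trip tests therefore shows the estimators
are consistent under the model's own assumptions, not that those
assumptions hold in any particular dataset.

All randomness flows from a single integer seed through named
sub-streams, and generation is byte-reproducible; the caller's RNG state
is left untouched.

# Problem sizes and reproducibility

Default sweeps use 61 log-spaced points over $k_{syn} \in
[10^{-3}, 10^3]$/day (fully deterministic); slope experiments use 13
points per decade; property tests use 1000 random equilibrium draws, a
200×200 brute-force grid on 10 random parameter sets against the 1-D
optimizer, and 500 Monte-Carlo seeds for the slope-recovery calibration.
These sizes make the full suite run in about a minute on one core while
leaving Monte-Carlo error well below the tolerances being asserted.
`run_pipeline()` writes every stage as tidy CSV plus a JSON manifest
(config hash, seed, package version) so any run can be reproduced exactly.

# Known limitations

The model is deliberately a toy: one average client class, no aggregation
flux (overflow is a boundary, not a species), no co-chaperone cycle
(HSP40/NEF), no heat-shock-response regulation, and chaperone turnover
tied to client turnover. Costs exclude degradation machinery and, by
default, amino-acid material costs (a per-residue surcharge flag exists).
The empirical scaling fits are estimation machinery only — reproducing
published cross-species slopes requires the external datasets themselves.
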