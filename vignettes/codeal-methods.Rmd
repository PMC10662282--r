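---
title: "Competitive dynamic enzyme allocation in the soil nitrogen cycle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Competitive dynamic enzyme allocation in the soil nitrogen cycle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Soil inorganic nitrogen cycles through six substrates — ammonium (NH4),
nitrate (NO3), nitrite (NO2), nitric oxide (NO), nitrous oxide (N2O) and
dinitrogen (N2) — transformed by six microbial enzyme functional groups:
ammonia oxidases (nitrification), the four denitrification reductases
(nitrate, nitrite, nitric-oxide and nitrous-oxide reductases), and
nitrogenases (biological N fixation, BNF). `codeal` reduces this system to
a single question: **how should a microbial community split a fixed enzyme
synthesis budget among competing enzyme groups?**

Each transformation follows Michaelis–Menten kinetics,

$$F_i = V_{max,i}\, E_i\, \frac{N_i}{K_{s,i} + N_i},$$

with $E_i$ the enzyme pool (mg enzyme-C kg$^{-1}$), $V_{max,i}$ the maximal
specific rate (mg N (mg enzyme-C)$^{-1}$ d$^{-1}$) and $K_{s,i}$ the
half-saturation constant (mg N kg$^{-1}$). BNF is additionally inhibited by
ammonium availability through the factor $1 - \mathrm{NH4}/(\mathrm{NH4} +
K_{s,\mathrm{NH4}})$: fixing N2 is pointless when mineral ammonium is
already abundant.

Enzyme synthesis is biomass-proportional, $p_{EP} B(t)$, and divided by
time-variant *allocation coefficients* $f_i(t)$ recomputed at every
instant from the current substrate vector (no smoothing or lag — that is
what "dynamic" means here):

| scheme | weight $w_i$ | reading |
|--------|--------------|---------|
| A0 | $N_i$ | proportional to concentration |
| A1 | $N_i / K_{s,i}$ | proportional to the saturation level |
| A2 | $K_{s,i} / N_i$ | inverse saturation (stable-flux strategy) |

with $f_i = w_i / \sum_j w_j$, so the coefficients always sum to one and
the total synthesis cost $\int p_{EP} B \, dt$ is identical under every
scheme: allocation moves enzyme carbon between groups, it never changes
the bill. Each coefficient belongs to the enzyme group that consumes the
corresponding substrate (nitrogenase ↔ N2, ammonia oxidase ↔ NH4, and so
on down the denitrification chain).

The static heart of the scheme comparison is a rearrangement inequality:
for any substrate state, allocating in proportion to the saturation level
(A1) yields at least as much instantaneous flux per unit of enzyme as the
inverse weighting (A2),

$$\sum_i f_i^{A1} \, s_i \;\ge\; \sum_i f_i^{A2} \, s_i,
\qquad s_i = \frac{N_i}{N_i + K_{s,i}},$$

with equality exactly when all $N_i/K_{s,i}$ coincide. This is the kernel
of *enzyme cost minimization*: A1 is the enzyme-efficient pathway.
`test-allocation.R` and the acceptance suite check this property over
thousands of randomized states.

### Pool balances

The ODE tracks the six inorganic pools, six enzyme pools, an organic N
pool (mineralized at a first-order rate $k_{min}$), and two cumulative
boundary-exchange accumulators:

```
dNH4 = F_min + F_fix - F_nit - U_NH4 + I_NH4
dNO3 = F_nit - F_nar - U_NO3 + I_NO3
dNO2 = F_nar - F_nir
dNO  = F_nir - F_nor - gNO * NO
dN2O = F_nor - F_nos - gN2O * N2O
dN2  = 0 (boundary mode)  or  F_nos - F_fix (dynamic mode)
dON  = L - F_min
dE_i = f_i * pEP * B - rE * E_i
```

Nitrification is lumped as a single NH4 → NO3 step catalyzed by ammonia
oxidases; NO2 appears only as a denitrification intermediate. This reduced
topology matches how the observed pool is defined (NO3 and NO2 are
measured together) but is a simplification of the full host model, whose
exact intermediate structure is not reproduced here. The
ammonium-inhibition factor of BNF is likewise a reduced form: the
mechanism (inhibition by NH4 saturation) is established, the specific
expression $(1 - s_{\mathrm{NH4}})$ is this package's choice.

Plant N uptake is Michaelis–Menten in NH4 and NO3, scaled by a prescribed
plant-activity factor; microbial biomass $B(t)$ is forcing, not a state —
carbon dynamics are out of scope. Enzyme pools are carbon and deliberately
excluded from the N balance (their N content is ignored); the conservation
tests therefore audit the six inorganic pools plus organic N only.

### Dinitrogen boundary

N2 is by far the largest freely available N reservoir, so by default the
N2 pool is held at a fixed boundary concentration and fixation/terminal
reduction cross the system boundary (they are booked in the `cumIn` /
`cumOut` accumulators). Setting `N2_boundary = "dynamic"` closes the cycle;
in that mode total tracked N is a first integral of the exact dynamics,
which the tests verify to relative drift below $10^{-6}$ over 1000 d
(observed: $\sim 10^{-15}$).

## Numerical choices

* **Solver.** Default: `lsoda` with `rtol = 1e-8`, `atol = 1e-10`; a
  fixed-step RK4 is available and is used for the order-of-convergence
  check. The right-hand side is compiled (C, via deSolve's compiled-model
  interface) for the three built-in schemes; user-registered schemes fall
  back to an interpreted closure. A reference R implementation
  (`codeal_rhs()`) exists purely as documentation-grade ground truth and
  the test suite pins all three paths together. The compiled path matters:
  A2 drives trace-gas pools toward zero where its $K_s/N$ weights make the
  system very stiff.
* **Nonnegativity.** Every consuming flux is Michaelis–Menten or
  first-order in its own pool, so consumption vanishes with the pool and
  the exact dynamics cannot cross zero; inside the right-hand side pools
  are additionally clamped at zero before flux evaluation so integrator
  undershoot never produces negative fluxes. Output states more negative
  than `neg_tol` (default $10^{-6}$) abort the run as a solver failure;
  smaller undershoot is reported as zero. Derivatives are never clipped —
  that would silently break the mass-balance audit.
* **A2 at zero concentration.** The weight $K_s/N$ diverges as
  $N \to 0$; concentrations are floored at `alloc_floor` ($10^{-10}$
  mg N kg$^{-1}$, configurable) before weighting so all three schemes are
  total and continuous.
* **Output grid.** Decoupled from solver steps; allocation coefficients
  and instantaneous fluxes are re-evaluated exactly at the output times.
  Aggregations (Flux-Ninorg, Enz-Ninorg) are trapezoidal integrals on that
  grid.

## Evaluation statistics

* **Flux-Ninorg**: time-integral of the sum of the six enzymatic
  transformation fluxes (BNF + nitrification + denitrification).
* **Enz-Ninorg**: enzyme investment, in two readings. *Production*
  (default): cumulative gross synthesis $\int f_i\, p_{EP} B\, dt$ —
  matching "total production"; its grand total is scheme-invariant by
  construction. *Standing pool*: time-mean enzyme stock. Note that with a
  shared synthesis budget and a common turnover rate the total standing
  pool is also scheme-invariant ($d \sum E / dt = p_{EP}B - r_E \sum E$);
  under this reduced model, scheme contrasts in enzyme *totals* are
  therefore ties, and the informative contrast is the per-group breakdown
  and the efficiency ratio Flux-Ninorg / Enz-Ninorg. A model in which the
  totals genuinely differ would need feedback from allocation to biomass
  growth, which is out of scope here.
* **Percent bias**: $100(\bar{y}_{sim} - \bar{y}_{obs})/\bar{y}_{obs}$.
* **NSE**: Nash–Sutcliffe efficiency, the standard goodness-of-fit
  companion.
* **Wilcoxon signed-rank** for paired scheme comparisons: zero differences
  dropped (classical convention; a Pratt variant is available), average
  ranks for ties, $W = \min(W^+, W^-)$; exact p-values from the full
  sign-assignment distribution for $m \le 25$ tie-free pairs, otherwise a
  normal approximation with tie and continuity corrections. Pairing across
  schemes is by shared replicate parameter draws (n = 24 by default); what
  the paired units represent in the field data this design emulates is not
  stated there, so the synthetic pairing is an explicit stand-in.
* **Compact letter display**: insert-and-absorb; two schemes share a
  letter exactly when their pairwise p ≥ α (α = 0.001 by default).
* **ReUn**: relative uncertainty of an ensemble output, the width of its
  90% inter-percentile interval (type-7 interpolated percentiles, p5–p95)
  divided by its mean. Parameter ensembles are Latin hypercube samples
  (one draw per stratum, independently permuted per parameter), by default
  ±25% multiplicative around the base values of all $V_{max}$, all $K_s$,
  $p_{EP}$ and $r_E$. Both the 90%-width construction and the ±25% default
  are package choices; the source analysis names the statistic without
  printing its construction or ranges.

## Calibration

The objective interpolates each simulated observable to the observation
times (replicates averaged; NO3 and NO2 summed before comparison to the
combined observed pool) and scores

$$J = \sum_k w_k \left[ \tfrac12 \min(|\mathrm{PBIAS}_k|/100, 1)
 + \tfrac12 \frac{1 - \max(\mathrm{NSE}_k, -1)}{2} \right],$$

zero only for a perfect fit, at most 1 per unit-weight observable.
Weights default to equal — the relative weighting of pools versus fluxes
in the original analysis is unknown. The optimizer is a seeded, bounded
differential evolution (rand/1/bin, F = 0.8, CR = 0.9, LHS
initialization, reflection at the bounds, fixed evaluation budget,
deterministic given the seed). Any bounded seeded population search
satisfies the same contract. On the reference testbed with 5% observation
noise and 24 replicates, two free maximal rates are recovered to well
under 1% with a 500-evaluation budget; the narrow objective basin on
long horizons makes generous budgets worthwhile.

## The synthetic testbed

`default_scenario()` freezes the package's canonical experiment, emulating
a multi-year grassland monitoring design: 12 years of daily forcing with
sinusoidal plant activity (mean 0.5, amplitude 0.45, summer peak), litter
input proportional to plant activity (peak 0.4 mg N kg$^{-1}$ d$^{-1}$),
constant mineral N deposition (0.05 + 0.05 mg N kg$^{-1}$ d$^{-1}$),
constant biomass (200 mg C kg$^{-1}$), monthly observations with mean-one
lognormal noise (CV 0.2 by default) in 24 replicates. The default kinetic
parameters are **not** a fitted set (the original calibrated values are
not published in the main text); they were chosen once for realistic
magnitudes and so that the six saturation levels stay heterogeneous
(CV ≈ 0.5 at mid-horizon) — heterogeneity is what separates the three
schemes — and are frozen here. The faster maximal rates of the trace-gas
reductases reflect the short lifetimes of NO and N2O in soil.

On this testbed (12 y, daily output):

* A1 produces the largest total inorganic N flux (≈ 24% above A0; A2
  collapses to ~0.05% of A1) at the same total enzyme cost, hence the
  best efficiency ratio;
* A2 starves nitrogenase (its N2 weight $K_s/N_2$ is minute), BNF falls
  to ~0.02% of A1's, ammonium accumulates and further inhibits fixation —
  the qualitative failure mode expected of the inverse strategy;
* all pairwise scheme contrasts of Flux-Ninorg over 24 paired replicate
  runs are significant at p < 0.001, giving three distinct letters.

What passing these tests does **not** show: behavior under real forcing
(weather, freeze–thaw, fertilization events), treatment effects,
scheme-specific recalibration, or carbon–nitrogen feedbacks. In
particular, the published robustness ordering — smallest ensemble ReUn
under A1, largest under A2 — does *not* reproduce on this testbed: here
A2's flux is collapsed near zero (as the scheme comparison itself
requires), and a collapsed flux has a compressed relative spread, while
all schemes share the dominant $p_{EP}/r_E$ budget uncertainty. That
ordering evidently needs each scheme held near observation-constrained
behavior by its own calibration, which requires the external forcing and
fitted parameter tables this package deliberately does not depend on. The
corresponding acceptance check is kept as specified and fails honestly.

## Problem sizes used in the shipped tests

Unit tests run on 1–2-year scenarios; the scenario-level checks use the
frozen 12-year testbed (single runs), 100-member ensembles for ReUn, 24
paired replicate runs for the Wilcoxon letters, and a 500-evaluation
calibration. The complete suite plus the acceptance script runs in a few
minutes on one CPU.

## Known limitations

* No soil temperature or moisture response functions, no carbon cycle, no
  microbial dormancy, no isotopes, no spatial structure.
* Enzyme pools are carbon-only; their nitrogen content is ignored.
* The nitrification pathway is lumped (no oxidative NO2 intermediate).
* Scheme contrasts in total enzyme investment are structurally ties (see
  above); per-group breakdowns carry the signal.
* The default parameter set is a synthetic reference point, not an
  estimate of any real soil.
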