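# codeal

Competitive dynamic enzyme allocation (CODEAL) in the soil inorganic
nitrogen cycle: an R package for simulating six microbial enzyme
functional groups — nitrogenases, ammonia oxidases, and the nitrate,
nitrite, nitric-oxide and nitrous-oxide reductases — that compete for a
shared synthesis budget while driving Michaelis–Menten transformations of
the six inorganic N substrates (NH4, NO3, NO2, NO, N2O, N2).

The question the package operationalizes: *how should a microbial
community allocate enzyme production among competing pathways?* Each
group's time-variant allocation coefficient is a normalized weight linked
to its substrate:

| scheme | weight | interpretation |
|--------|--------|----------------|
| A0 | N_i | concentration-proportional |
| A1 | N_i / Ks_i | saturation-level-proportional |
| A2 | Ks_i / N_i | inverse saturation (stable-flux strategy) |

with f_i = w_i / Σ w_j, so enzyme synthesis `pEP · B(t)` is conserved
across schemes. Transformation fluxes are
`Vmax_i · E_i · N_i / (Ks_i + N_i)`; biological N fixation is additionally
inhibited by the ammonium saturation level. A1 is the enzyme-efficient
strategy: for any substrate state it yields at least as much flux per unit
enzyme as A2 (rearrangement inequality), the static kernel of enzyme cost
minimization.

Around the ODE core the package provides the full evaluation toolkit:
Flux-Ninorg and Enz-Ninorg aggregation, percent bias, Nash–Sutcliffe
efficiency, exact Wilcoxon signed-rank comparisons with compact-letter
display, Latin-hypercube parameter ensembles with the relative-uncertainty
statistic ReUn = (p95 − p5)/mean, a seeded differential-evolution
calibrator, and a synthetic multi-year grassland scenario generator so
that everything runs self-contained.

## Worked example

```r
library(codeal)

sc  <- default_scenario()          # frozen 12-year synthetic testbed
frc <- make_forcing(sc$spec)

out <- sapply(c("A0", "A1", "A2"), function(s) {
  cfg <- sc$config; cfg$scheme <- s
  tr <- run_simulation(cfg, sc$params, frc)
  c(flux = flux_ninorg(tr),
    enz  = enz_ninorg(tr, frc, "production")$total,
    bnf  = pracma::trapz(tr$times, tr$flux[, "F_fix"]))
})
round(out, 1)
#>          A0      A1      A2
#> flux 41363.2 51376.3    24.8
#> enz   4380.0  4380.0  4380.0
#> bnf   6743.5  8449.5     1.4
```

Over 12 years, saturation-weighted allocation (A1) converts the same
4380 mg kg⁻¹ of enzyme carbon into 51 376 mg N kg⁻¹ of total inorganic N
transformation flux — 24% more than concentration weighting (A0) — while
the inverse strategy (A2) starves nitrogenase of enzyme and collapses
both N fixation (1.4 vs 8449 mg N kg⁻¹) and the whole downstream cycle.

Scheme comparison with paired replicates, Wilcoxon tests and letters:

```r
cmp <- compare_schemes(sc$config, sc$params, frc, n_rep = 24, seed = 1)
print(cmp)
#> <codeal_report> allocation-scheme comparison
#>  scheme flux_ninorg enz_production enz_standing efficiency letters
#>      A0   41363.241           4380       19.922  9.4436622       a
#>      A1   51376.305           4380       19.922 11.7297500       b
#>      A2      24.846           4380       19.922  0.0056725       c
```

All three pairwise contrasts are significant (p < 0.001), so each scheme
gets its own letter.

Ensemble robustness of the total flux under ±25% parameter perturbation:

```r
ensemble_reun("A1", sc$params, sc$config, frc, n = 100, seed = 42)$reun_flux
```

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/codeal.R synth --years 12 --out-dir fixtures
Rscript inst/cli/codeal.R simulate --config fixtures/config.json \
        --forcing fixtures/forcing.csv --scheme A1 --out traj.csv
```

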