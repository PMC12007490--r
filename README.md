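# crisprisim

Kinetic simulation of CRISPRi transcriptional repression for plant promoters
with multiple guide RNA target sites.

## The problem

CRISPR interference (CRISPRi) represses a promoter by steering
catalytically dead Cas9 (dCas9) to target sites with a guide RNA (gRNA).
Strong repression usually needs several target sites, which poses a design
choice for promoter engineers:

* **heterogeneous sites** — each site has its own gRNA sequence, so existing
  promoter sequence can be targeted, but every site needs an independent
  dCas9–gRNA binding event, and the gRNA species compete for dCas9;
* **identical sites** — one gRNA serves every site, which requires promoter
  modification but removes the competition and lets a bound dCas9–gRNA
  complex *scan* laterally along the DNA to occupy a neighbouring identical
  site after a single solution-phase binding event.

`crisprisim` builds and integrates ODE models of both strategies in a
two-vector transient-expression setting (an agroinfiltration-style delivery:
vector V1 carries the gRNA cassette(s) at initial dosage D1, vector V2
carries dCas9 and the GFP reporter at dosage D2, and all stable species
dilute as cells divide), quantifies fold repression of the reporter, and runs
the robustness analyses that probe whether the identical-site advantage
depends on the particular parameter values.

## The model

For every architecture the vectors dilute, `dV/dt = -λV`. Free gRNA `g`,
free dCas9 `C` and the complex `Cg` follow

```
dg/dt  = α_r·V1 − δ_g·g − k_Cg·C·g
dC/dt  = α_C·V2 − λ·C − k_Cg·C·g        (summed over gRNA species)
dCg/dt = k_Cg·C·g − λ·Cg
```

Promoter occupancy does not consume complex (promoter copies are few against
complex molecules). For *n* heterogeneous sites each per-site occupancy
fraction obeys `dθ_i/dt = k_on·Cg_i·(1−θ_i) − k_off·θ_i`; for *n* identical
sites a chain over the number `k` of occupied sites, `P_0 … P_n`, moves up at
rate `k_on·Cg·(n−k) + [k≥1]·k_scan·(n−k)` (solution binding plus lateral
scanning) and down at `k_off·k`. Each occupied site attenuates reporter
production by a factor ρ, so the reporter integrates

```
dG/dt = α_G·V2·R(t) − λ·G,   R = Π_i (1 − (1−ρ)θ_i)  or  Σ_k P_k·ρ^k
```

Fold repression is the pointwise ratio `G_base(t)/G_repressed(t)` against the
unregulated system, averaged over the 72–96 h window (hourly grid, endpoints
inclusive) — late enough that base expression has peaked, early enough that
vector dilution has not eroded repression.

## Worked example

```r
library(crisprisim)
params <- crispri_params()          # shipped defaults, D1 = 10, D2 = 3
tab <- repression_table(params)     # simulates all 11 regulated architectures
print(tab)
#> Mean fold repression over 72-96 h (vs Base Expression):
#>                         label fold_repression
#>                   Single gRNA           6.957
#>  2 Heterogeneous Target Sites          20.550
#>  3 Heterogeneous Target Sites          28.500
#>  4 Heterogeneous Target Sites          31.300
#>  5 Heterogeneous Target Sites          32.670
#>  6 Heterogeneous Target Sites          33.580
#>      2 Identical Target Sites          24.140
#>      3 Identical Target Sites          35.340
#>      4 Identical Target Sites          40.070
#>      5 Identical Target Sites          43.130
#>      6 Identical Target Sites          45.630
```

At every matched site count the identical-site promoter represses more
strongly than the heterogeneous one, both beat the single-gRNA circuit, and
the largest per-site gain comes from adding the second site. Fitting the
base-expression model to a synthetic calibrated-fluorescence (MEFL) time
course — 18 time points, 27 readings each (3 plants × 3 leaves × 3 reads) —
recovers the generating rates through hierarchical replicate noise:

```r
fit <- fit_base_expression(
  generate_timecourse(params, background = 0, seed = 1),
  init = crispri_params(alpha_G = 5000, lambda_dilution = 0.005))
print(fit)
#> Base-expression fit (log-space least squares):
#>   alpha_G          1239.32
#>   lambda_dilution  0.0216147
#>   RSS 9.69701e+10 (initial 3.26097e+14), 12 iterations, converged: TRUE
```

(The generating values were `alpha_G = 1000`, `lambda_dilution = 0.02`; the
residual offsets reflect the lognormal replicate noise.) Robustness analyses:
`scan_parameter()`, `scan_dosage()`, `cell_variation()`; whole-pipeline runs
with CSV/JSON outputs: `run_pipeline()` or the thin CLI wrapper in
`inst/cli/crispri-sim.R`.

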