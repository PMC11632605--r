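# etkin

A mechanistic model of endothelin-1 (ET-1) kinetics and competitive
receptor antagonism, for pharmacologists and modellers studying the
endothelin system — in particular the question of how an ETA-selective
antagonist's concentration and selectivity change activation of the
*unantagonized* ETB receptor, the pathway implicated in the fluid
retention that has limited this drug class.

ET-1 is produced by ECE-mediated conversion of Big ET-1, distributes
between a plasma and a tissue compartment, and is cleared by binding to
its own receptors (mostly ETB) followed by internalization of the
complex. The package implements this as a two-compartment ODE system
with quasi-equilibrium receptor binding: free ET-1 $u$ satisfies the
mass balance

$$ET1_{tot} = u + \frac{R_{A,tot}\,u}{K_d(1 + I/K_{ia}) + u}
            + \frac{R_{B,tot}\,u}{K_d(1 + I/K_{ib}) + u},$$

a cubic in $u$ under a competitive antagonist at concentration $I$,
solved by safeguarded bracketed root-finding. Receptor-mediated
clearance is $K_{int}$ times the bound complex, so blocking either
receptor raises ET-1 itself. On top of the core dynamics the package
provides:

* the published calibration and validation infusion protocols, with
  dose-unit conversion (`builtin_protocol()`, `convert_dose_rate()`);
* steady-state initialization from physiological constraints
  (`steady_state_init()`, `tissue_free_steady()`);
* ODE simulation with a compiled right-hand side, antagonist exposure
  models and an optional pharmacodynamic delay (`et_simulate()`);
* steady-state and finite-horizon antagonist concentration-selectivity
  sweeps (`sweep_perfect()`, `run_sweep()`, `fb_scenario()`);
* simultaneous multi-study least-squares estimation with study-specific
  ECE and Gauss-Newton standard errors (`et_fit()`);
* Sobol global sensitivity analysis on a scrambled Sobol' sequence
  (`sobol_design()`, `sobol_indices()`, `et_sobol()`);
* a synthetic plasma ET-1 generator for end-to-end estimator validation
  (`generate_tristudy()`, `generate_suite()`).

See the vignette (`vignettes/et1-kinetics.Rmd`) for the model, its
assumptions, and the package's design decisions.

## Worked example

```r
library(etkin)
p <- et_params()                 # the calibrated parameter set

steady_state_init(p)$free
#> ET1_t0 ET1_p0
#>   88.9    3.2
```

The baseline puts free plasma ET-1 at 3.2 pmol/L and free tissue ET-1 at
88.9 pmol/L — the tissue value follows from the plasma steady-state
constraint and matches the published derived value (88.3) to within the
rounding of the printed parameters.

```r
sw <- sweep_perfect(p, "ETA")    # perfectly selective ETA antagonist,
                                 # 0.001-1000 x K_ia, steady state
round(max(sw$pct_ET1_RB_p), 1)   # 43.5  (% rise, plasma ET1-ETB complex)
round(max(sw$pct_ET1_RB_t), 1)   # 33.0  (% rise, tissue)
summarize_sweep(sw)
#>   compartment selectivity max_rise_pct mult_at_max supp50_mult zero_cross_mult zero_cross_reached
#> 1      plasma         Inf         43.5        1000        1.40              NA              FALSE
#> 2      tissue         Inf         33.0        1000        1.69              NA              FALSE
```

As the drug suppresses the ETA complex toward 100%, reduced clearance
raises ET-1 and the ETB complex climbs by ~44% in plasma and ~33% in
tissue. The concentration giving 50% ETA-complex suppression is shifted
right of $K_{ia}$ (1.40x / 1.69x) by the same ET-1 rise, and the ETB
complex never falls below baseline on this grid (`zero_cross_reached =
FALSE`) — at steady state the internalization flux must carry the fixed
production flux. The mirror sweep, `sweep_perfect(p, "ETB")`, shows the
much larger consequence of blocking the dominant clearance receptor: the
ETA complex rises by >700% (plasma) and >260% (tissue).

Parameter recovery on noise-free synthetic data from the three
calibration designs, started at twice the true values:

```r
ds  <- generate_tristudy(p, cv = 0)
truth <- c(Vp = 81.6, Vt = 2.64, Kpt = 0.87, Ktp = 0.98, Kint = 0.0095,
           Rtot_p = 460, ECE.bolus_tracer = 162.6, ECE.stepped_et1 = 98,
           ECE.stepped_biget = 27)
et_fit(ds, init = truth * 2, multistart = 5, seed = 7)
#> <et_fit> SSE = 3.09502e-10  convergence = 0
#>                     estimate rse_pct
#> Vp                8.1600e+01 0.01230
#> Vt                2.6404e+00 0.00344
#> Kpt               8.7004e-01 0.01110
#> Ktp               9.7972e-01 0.00522
#> Kint              9.5009e-03 0.00321
#> Rtot_p            4.6003e+02 0.02130
#> ECE.bolus_tracer  1.6260e+02 0.00632
#> ECE.stepped_et1   9.7992e+01 0.00402
#> ECE.stepped_biget 2.6998e+01 0.00461
```

All nine parameters return to truth to better than 0.1%.

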