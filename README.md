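# tightbind

Tight-binding enzyme inhibition kinetics in R: global Morrison-equation
fitting over a substrate × inhibitor rate grid, inhibition-mode
discrimination by AIC, and depletion-corrected IC50 estimation.

## The problem

When an inhibitor is potent enough that binding the enzyme visibly
depletes the free inhibitor pool — the *tight-binding* regime, reached
whenever K_i is comparable to the enzyme concentration — the classical
assumption [I]_free ≈ [I]_total fails. Lineweaver–Burk patterns then no
longer separate competitive from noncompetitive inhibition, and naive
IC50s inflate with [E]. The motivating case is GC7
(N1-guanyl-1,7-diaminoheptane), which inhibits bovine serum amine oxidase
(BSAO) at concentrations comparable to the enzyme itself while spermidine
is in vast excess.

The correct treatment fits Morrison's closed-form solution of the
enzyme–inhibitor binding quadratic,

    vi/v0 = 1 − [([E]+[I]+Ki_app) − sqrt(([E]+[I]+Ki_app)² − 4[E][I])] / (2[E])

globally across the (S, I) grid, with v0(S) = Vmax·S/(Km+S) and the
substrate dependence of the apparent inhibition constant encoding the
mode:

* competitive: Ki_app = Ki(1 + S/Km)
* noncompetitive (mixed, with factor α): Ki_app = (S+Km)/(Km/Ki + S/(αKi))
* uncompetitive: Ki_app = Ki(1 + Km/S)

The three fits are compared with the least-squares AIC,
n·ln(RSS/n) + 2(k+1), and the tight-binding IC50 at each substrate level
is Ki_app(S) + [E]/2, cross-checked against a three-parameter
log-logistic fit of the dose–response.

The package also covers the assay plumbing: Beer–Lambert conversion of
absorbance slopes to rates (ε = 12,500 M⁻¹cm⁻¹ for benzaldehyde at
250 nm; ε = 26,000 M⁻¹cm⁻¹ for the DCHBS/AAP quinonimine adduct at
515 nm), initial-rate slope estimation, CSV/JSON/YAML I/O, and a seeded
synthetic-data generator for rate grids and absorbance traces.

## Worked example

Simulate a realistic assay (6 substrate levels 20–1000 µM × 6 inhibitor
levels 0–2 µM, 3 replicates, 2% proportional noise) from a mixed-type
tight-binding truth, then ask the package which inhibition mode the data
support:

```r
library(tightbind)
truth <- gc7_reference_params()   # Km 173.8, Vmax 12.98, Ki 0.30775, alpha 2.28419, [E] 0.218
grid  <- simulate_rate_grid(truth, "noncompetitive", simulation_design(seed = 1))
cmp   <- compare_inhibition_modes(grid, strategy = "joint")
cmp
#> Inhibition-mode comparison (AIC)
#>
#>            mode        rss   n k       aic delta_aic converged
#>     competitive 10.3252245 108 4 -243.5345  276.5716      TRUE
#>  noncompetitive  0.7828794 108 5 -520.1061    0.0000      TRUE
#>   uncompetitive 19.7896924 108 4 -173.2728  346.8333      TRUE
#>
#> best mode: noncompetitive
cmp$fits$noncompetitive
#> Morrison tight-binding fit: noncompetitive mode (joint strategy)
#>   Km    = 173.457 (+/- 2.31)
#>   Vmax  = 13.0686 (+/- 0.0597)
#>   Ki    = 0.326799 (+/- 0.0129)
#>   alpha = 2.13282 (+/- 0.111)
#>   E     = 0.169974 (+/- 0.0229)
#>   RSS = 0.782879 on 108 points, k = 5 free, AIC = -520.1061
```

The mixed model wins by ΔAIC > 275 and the five parameters land within
noise of the generating truth. Depletion-corrected IC50s rise with
substrate, as they must for a mixed inhibitor with α > 1:

```r
ic50_tight_binding(cmp$fits$noncompetitive$params, "noncompetitive",
                   S = c(20, 100, 1000))
#> [1] 0.4307736 0.4905614 0.6820182   # µM
```

`run_analysis()` chains the whole pipeline (read/simulate → MM fit →
three-mode comparison → per-substrate IC50 table → JSON + CSV report)
from an R list or YAML config.

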