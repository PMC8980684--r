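# ctffr

Reduced-order coronary hemodynamics, CT-FFR boundary-condition calibration,
and virtual diagnostic-accuracy trials.

## The problem

Fractional flow reserve (FFR) — distal coronary pressure divided by aortic
pressure under maximal hyperemia — is the reference standard for deciding
whether a stenosis causes ischemia (FFR < 0.80 is ischemic; values in the
0.76–0.80 *gray zone* are the hard cases).  CT-FFR estimates FFR
non-invasively by simulating flow on CT-derived vessel geometry.  Its
accuracy hinges on boundary-condition parameters that cannot be measured
from CT and must be calibrated against invasive measurements, then frozen
for prospective use.

`ctffr` is for people who study that workflow rather than run it clinically:
it provides the reduced-order (1-D network) hemodynamic engine on which
such calibrations operate, the calibration itself, a seeded generator of
synthetic trial cohorts, and the complete per-vessel diagnostic-performance
analysis a validation trial reports.

## The model

Each vessel-tree segment obeys the standard stenosis loss law

    ΔP = a·Q + b·Q·|Q|

with `a = ∫ 8μ/(π r(s)⁴) ds` the integrated Poiseuille coefficient of the
lumen profile and `b = K_t·(ρ/2)·(1/A_throat − 1/A_ref)²` the post-stenotic
expansion loss at the lesion throat.  Outlets drain through hyperemic
microvascular resistances allocated by a diameter power law,
`R_i = (R_ref/h)·(d_i/d_ref)^(−k)`, to zero venous pressure; the ostium is
held at aortic pressure `P_a`.  The solver is damped fixed-point iteration
with an exact resistor-tree solve per pass; CT-FFR is the pressure ratio
`P/P_a`, read 25 mm distal to the lesion as the invasive protocol
prescribes.  `calibrate_ffr()` fits `{R_ref, k, K_t}` by bounded
multi-start Nelder–Mead on the mean squared error against measured FFR.
See `vignettes/ctffr-methods.Rmd` for the full model account.

## A worked example

Solve a left anterior descending (LAD) tree with a 72% proximal stenosis
and read the CT-FFR distal to it:

```r
library(ctffr)
tree <- build_tree(data.frame(
  id = c("prox", "main", "side"), parent = c(NA, "prox", "prox"),
  length = c(35, 50, 25),
  prox_diameter = c(3.4, 3.1, 2.1), dist_diameter = c(3.2, 2.2, 1.8)))
tree$lesions <- list(lesion("prox", 6, 14, 72))

sol <- solve_steady_flow(tree, boundary_params())
print(sol)
#> <flow_solution> 3 segments, 22 iteration(s), residual 8.66e-09
#>   ostium 93.0 mmHg; min FFR 0.8802

measure_ffr(sol, tree$lesions[[1]])
#> CT-FFR 0.8877 at 10.0 mm on segment 'main'

round(ffr_field(sol), 4)
#> ostium   prox   main   side
#> 1.0000 0.8886 0.8802 0.8809

solution_tables(sol)$flows
#>   segment_id flow_mL_s
#> 1       prox 0.9041323
#> 2       main 0.5714598
#> 3       side 0.3326725
```

The 72% stenosis drops the pressure ratio to 0.89 just past the lesion —
above the 0.80 ischemia threshold, so this vessel would be called negative.
The tree carries 0.90 mL/s of hyperemic flow, split between the main
continuation and the side branch.

An end-to-end virtual trial — generate a retrospective cohort, calibrate,
freeze the parameters, score a prospective cohort, and run the full
diagnostic analysis — is one call:

```r
res <- run_virtual_trial(trial_config(seed = 1, n_vessels = 400))
print(res$evaluation)   # metric tables, AUC, bin accuracies, strata, ORs
```

The evaluation layer also works directly on count data.  Reconstructing a
published per-vessel confusion matrix (152 true positives, 17 false
negatives, 173 true negatives, 24 false positives):

```r
diagnostic_metrics(confusion_counts(tp = 152, fn = 17, tn = 173, fp = 24))
#>        metric value_pct ...
#> 1 sensitivity      89.9
#> 2 specificity      87.8
#> 3    accuracy      88.8
#> 4         ppv      86.4
#> 5         npv      91.1
```

## Command line

A thin CLI over the same functions ships in `inst/cli/ctffr.R` with verbs
`simulate`, `calibrate`, `apply`, `evaluate`, and `trial`:

```sh
Rscript inst/cli/ctffr.R trial --seed 1 --out trial_report
```
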