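# ivtpk

Ocular pharmacokinetics of intravitreally injected antibodies from
longitudinal PET imaging.

After an intravitreal injection of a radiolabelled antibody (e.g. a
zirconium-89 immuno-PET conjugate), the decay-corrected activity in the eye
declines biphasically. `ivtpk` implements the full desk-side analysis of
such studies for pharmacometricians and preclinical imaging groups:

* the **open two-compartment model** of intravitreal clearance — eye
  (observed, compartment 1) exchanging with blood and well-perfused organs
  (compartment 2):

  $$X_1(t) = A e^{-\alpha t} + B e^{-\beta t}, \qquad A + B = D = 100\%,$$

  with hybrid constants $\alpha > \beta$ (1/h) linked to the micro
  rate constants by $k_{12}+k_{21}+k_{20}=\alpha+\beta$ and
  $k_{12}k_{20}=\alpha\beta$;
* **weighted nonlinear least-squares fitting** of per-eye time-activity
  curves (weights $1$, $1/\hat y$ or $1/\hat y^2$, iteratively reweighted),
  with curve-stripping initial estimates, a goodness-of-fit battery
  ($R^2$, $S_{y \cdot x}$, RMSE, AICc) and asymptotic parameter CV%;
* **derived quantities**: phase half-lives, $AUC_{0-\infty}$, AUMC, MRT;
* **PET-side quantification**: radioactive decay correction, first-frame
  normalisation, ellipsoidal ROI extraction from voxel volumes, percent
  injected dose per organ, total blood activity from theoretical blood
  volume, and semiquantitative anterior/posterior autoradiograph splits;
* a **synthetic-data module** that simulates whole cohorts (per-eye
  parameter heterogeneity, multiplicative measurement noise, the 16-point
  imaging schedule: 0-36 h then daily to day 10) plus voxel phantoms and
  autoradiographs with known ground truth;
* **group-level reporting**: per-eye fits aggregated into mean ± SD
  summary tables, Welch and permutation group comparisons.

Everything is tidyverse-native: functions take data frames and return
tibbles, fitted objects support `tidy()`, `glance()` and `autoplot()`.

## Worked example

```r
library(ivtpk)

# an eye with the healthy-group mean kinetics (k12 = 0.05/h)
hp <- hybrid_params(A = 13.7515, alpha = 0.2714, beta = 0.0147)
derived_parameters(hp)
#> # A tibble: 1 × 5
#>   t_half_alpha t_half_beta auc_inf aumc_inf   mrt
#>          <dbl>       <dbl>   <dbl>    <dbl> <dbl>
#> 1         2.55        47.2   5918.  399319.  67.5

# simulate one measured curve on the imaging schedule and refit it
curve <- generate_curve(hp, noise_cv = 0.02, seed = 7)
fit <- fit_two_compartment(curve)
fit
#> <ivt_fit>  two-compartment intravitreal model, weighting = 1/yhat2
#>   A = 13.8668  alpha = 0.3862 /h  beta = 0.0145 /h  (D = 100)
#>   R2 = 0.9997  Sy.x = 0.586  RMSE = 0.529  AICc = -8.767  converged: TRUE
```

The terminal elimination rate $\beta$ (and with it the half-life, AUC and
MRT) is recovered tightly; the fast distribution rate $\alpha$ carries much
less information because only the 2-12 h samples see it (the t = 0 frame is
the normalisation reference). At higher noise some eyes lose the fast phase
entirely; such fits are flagged `converged = FALSE` and excluded from group
summaries with a reported count.

A whole two-group study — simulate, fit every eye, summarise, compare —
is one call:

```r
demo <- run_demo(seed = 1, out_dir = "demo_out")
demo$report   # mean ± SD per parameter and group + Welch/permutation p-values
```

which also writes `cohort.csv`, `truth.csv`, `per_eye_fits.csv`,
`report.csv`, `comparisons.csv` and `run_config.csv` — byte-identical for
identical seeds.

## Package layout

| file | contents |
| --- | --- |
| `R/pk_model.R` | closed-form model, parameter conversions, derived PK, ODE cross-check |
| `R/fit_engine.R` | curve stripping, weighted NLS, GOF battery, CV%, tidy/glance/autoplot |
| `R/quantify.R` | decay correction, normalisation, ROI extraction, %ID, blood, autoradiographs |
| `R/synthetic_data.R` | cohort/phantom/autoradiograph generators with ground truth |
| `R/cohort_report.R` | per-eye fitting over cohorts, group summaries, comparisons, report tables |
| `R/io.R` | CSV readers/writers, the end-to-end demo pipeline |

The methods vignette
(`vignettes/two-compartment-intravitreal-pk.Rmd`) documents the model,
the estimator, the simulator's assumptions and the package's design
decisions in detail.
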