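# indibird

Spatio-temporal Gompertz abundance models for point-count breeding-bird
surveys, and a randomized benchmark for judging indicator species — do
titmice (Paridae) actually index total forest-bird density better than a
random handful of species would?

The package is for quantitative ecologists working with repeated
point-count data who want to (1) fit a dynamic species-distribution model
of biomass density with spatially and spatio-temporally correlated random
fields, and (2) stress-test a candidate indicator group against random
control groups drawn from the same community.

## The model

Observed forest-bird biomass `b_i` (g) at location `s_i`, year `t_i`:

    b_i ~ gamma( a * d(s_i, t_i), sigma_m^2 )          (mean a*d; CV or
                                                        absolute dispersion)
    log d(s,t) = beta(t) + omega(s) + eps(s,t)
                 + gamma1 * tit + gamma2 * tit^2 + gamma3 * PC

    omega      ~ MVN(0, sigma_omega^2 * R)              static spatial field
    eps(.,t)   ~ MVN(rho_eps * eps(.,t-1), sigma_eps^2 * R)   AR(1) dynamics
    R_jk       = (kappa d_jk) K1(kappa d_jk)            Matern, nu = 1

Fields live on a knot mesh (one knot per survey point, or seeded k-means
centers); each sample uses its nearest knot. The AR(1) log-density
dynamics are the Gompertz (density-dependent) part. Fixed effects are
estimated by maximizing the Laplace-approximated marginal likelihood with
fully analytic gradients; random fields come from empirical Bayes,
standard errors from the delta method, and the linear-vs-quadratic
titmouse model is chosen by AIC plus significance of `gamma2`.

The control-group benchmark refits the linear model 300 times with random
six-species sets replacing the titmouse covariate (`gamma4`) and
classifies each converged refit against the titmouse estimate
(`not_significant` / `weaker` / `not_different` / `stronger`).

## Worked example

Simulate a survey with known parameters, fit both candidate models, let
AIC + significance choose, and trace the predicted response curve:

```r
library(indibird)
cfg <- simConfig(n_sites = 60, n_years = 8, seed = 7)   # truth: gamma1 = 0.198
sim <- simulateObservations(cfg)
fit_q <- fitSGM(sim$samples, spec = sgmSpec(), seed = 7)
fit_l <- fitSGM(sim$samples, spec = sgmSpec(include_quadratic = FALSE), seed = 7)
chosen <- selectQuadratic(fit_l, fit_q)
print(chosen)
```

    Spatial Gompertz model fit (gamma family)
      samples: 480  knots: 60  years: 8
      marginal NLL: 3689.2722  AIC: 7408.5444
      converged: TRUE (rel. gradient 1.75e-06, 0 restart(s))
            term estimate      se       lo       hi significant
       gamma_tit  0.18437 0.03716  0.11153  0.25722        TRUE
        gamma_pc -0.08667 0.03791 -0.16097 -0.01236        TRUE
     sigma_omega  0.77154 0.13145  0.51390  1.02917        TRUE
       sigma_eps  0.30039 0.06160  0.17966  0.42112        TRUE
         rho_eps  0.57917 0.24071  0.10739  1.05096        TRUE
         sigma_m  0.70754 0.02640  0.65579  0.75928        TRUE
           kappa  0.07772 0.01753  0.04335  0.11208        TRUE

The titmouse effect (truth 0.198) is recovered at 0.184 ± 0.037 and
declared significant; the quadratic model lost the AIC comparison
(ΔAIC = −0.67) with a non-significant `gamma2`, so inference falls back to
the linear fit — exactly the selection rule the package encodes. A
response curve with a 95% band propagated from the joint covariance of
`(beta, gamma1)`:

```r
responseCurve(chosen, tit_grid = c(-1, 0, 1), seed = 7)
#   tit    lo median     hi    fit
#    -1 9.155  9.763 10.313  9.752
#     0 9.345  9.944 10.502  9.937
#     1 9.522 10.120 10.683 10.121
```

`log d` rises by about 0.18 per SD of titmouse biomass, as fitted.

Survey ingestion (`readPointCounts`, `pairsToIndividuals`,
`mergeBreedingPeriods`, `applyGuildFilters`, `buildSamples`), climate
covariates (`screenClimateCells`, `productivityIndex`,
`assignHabitatClasses`), the control benchmark (`drawControlGroups`,
`controlBenchmark`) and the stage runner (`runPipeline`, with a thin CLI
at `inst/cli/indibird.R`) are documented on their help pages; the methods
vignette (`vignettes/spatial-gompertz-methods.Rmd`) explains the model,
its assumptions and the numerical choices.

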