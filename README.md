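# trailuse

Hierarchical Bayesian analysis of mammal site use and diel activity overlap
from multi-array camera-trap surveys along recreation and land-use
gradients.

Camera-trap networks increasingly pool many independent survey arrays to ask
whether wildlife responses to outdoor recreation generalize across
landscapes — for example, whether prey aggregate near humans to shield
themselves from predators (the human shield hypothesis) and whether
carnivores avoid recreated areas. trailuse provides the full analysis chain
for that question, for ecologists working with station-level detection
data: event processing, a two-level Bayesian count model separating local
from landscape-scale recreation effects, and a circular-statistics analysis
of diel activity overlap between species pairs.

## The models

**Site use.** Counts of independent detections at station *i* in array *j*
follow an overdispersed negative binomial (NB2):

    y_i  ~ NB2(exp(eta_i), r)
    eta_i = b1*rec_i + b2*logging_i + b3*road_i + b4*days_i + b5*NDVI_i
            + b6*rec x logging_i + b7*rec x road_i + eps_j(i)
    eps_j ~ Normal(b8 * rec_land_j, sigma_array^2)

The camera-array random intercept is itself regressed on landscape-scale
recreation (the standardized array mean of local rates), so b1 and b8
separate station-level from landscape-level responses. Priors are flat
(beta ~ U(-10,10), sigma_array ~ U(0,10), r ~ U(0.01,50)); sampling is by
an adaptive Metropolis-within-Gibbs sampler in compiled code, with
split-chain Gelman-Rubin convergence checks (R-hat <= 1.1) and evidence
classified by 95% (strong) / 80% (weak) credible intervals.

**Diel overlap.** Detection times are mapped to sun-anchored radians
(sunrise = pi/2, sunset = 3*pi/2, via the NOAA solar equations), activity
densities are estimated with von Mises kernels, and pairwise overlap per
station is the Dhat4 coefficient (the estimator of `int min(f,g)`
recommended for large samples). Station-level overlap coefficients are then
modelled with a Bayesian Gaussian mixed model with an array random
intercept.

A seeded synthetic-data generator (`simulation_truth()`,
`simulate_dataset()`) emulates 10-array surveys with known ground truth, so
every stage is validated by parameter recovery without any field download.

## Worked example

```r
library(trailuse)

# a survey with a moose-like local recreation effect planted as truth
truth <- simulation_truth(beta = c(-0.49, 0, 0, 0, 0, 0, 0, 0), seed = 5)
stations <- generate_stations(truth)           # 400 stations, 10 arrays
y <- generate_counts(stations, truth)
d <- trailuse:::sim_design(stations)

fit <- fit_spatial(list(y = y, X = d$X, array_index = d$array_index,
                        landscape_recreation = d$landscape_recreation),
                   mcmc_profile("test", seed = 1))
summarize_posterior(fit, c("beta_recreation", "sigma_array", "r"))
```

```
beta_recreation              =  -0.32, 95% CI: -0.65 to 0.00 [weak, -]
sigma_array                  =   0.38, 95% CI: 0.13 to 0.77 [strong, +]
r                            =   1.08, 95% CI: 0.76 to 1.52 [strong, +]
```

The 95% interval for the recreation effect covers the planted truth
(-0.49) with the right sign — on this particular simulated survey the 95%
interval grazes zero, so the evidence classification is "weak" (the 80%
interval excludes zero); across replicate surveys the effect is classified
strong with the correct sign in the large majority of fits (see the
acceptance tests). The generator's array SD (0.5) and dispersion (r = 1)
sit inside their intervals. (`sigma_array` and `r` are positive by
construction; their "strong" labels are incidental.)

The numbered scripts under `analysis/` run the same machinery as a
narrative workflow — simulate, preprocess, fit the site-use model, compute
station overlaps, fit the overlap models — writing tables under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_preprocess.R
Rscript analysis/03_fit_spatial.R
Rscript analysis/04_overlap.R
Rscript analysis/05_overlap_lmm.R
```

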