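# camtrapDens

Estimating how landscape accessibility to hunters shapes a prey community and
its top predator, from multi-site camera-trap surveys. The package implements
the full analysis chain used in accessibility-gradient studies of large
Neotropical forest mammals:

* **Prey occupancy** — single-season site-occupancy models
  (ψ = probability of site use, p = per-occasion detection) with logit-linear
  accessibility covariates: distance to the nearest road or river (*RR*, km),
  distance to the nearest settlement (*ST*, km), habitat class (*H*,
  ridge/valley) on ψ, and paired-camera spacing (*DC*, m) on p. The 16-model
  candidate set is ranked by AICc, and station-level ψ̂ are averaged into
  site-level summaries with delta-method SEs.
* **Prey biomass index** — per station, BI = Σᵢ nᵢwᵢ/t (kg/day): independent
  photo events (1-hour window) times species mean mass per active trap-day,
  split into all-prey / ungulate / non-ungulate classes; Kruskal–Wallis tests
  across sites and Pearson correlations with accessibility, with Bayesian
  bootstrap (Dirichlet-weighted) 95% highest-density intervals.
* **Bayesian SECR density** — data-augmented spatially explicit
  capture–recapture for the individually identified predator: activity
  centers on a 1/km² grid over the trap envelope buffered by 15 km,
  half-normal detection with Bernoulli encounters
  p(d) = 1 − exp(−λ₀e^(−d²/2σ²)), M = 30× augmentation, a C++
  Metropolis-within-Gibbs sampler (50% burn-in, thinning 10), and Geweke
  convergence checks (|z| < 1.6) with automatic iteration escalation.
* **Classical density** — D = N̂/ETA per 100 km²: Burnham–Overton (Mh)
  jackknife abundance with CAPTURE-style order selection, a span-based
  closure diagnostic, pooled full MMDM as the buffer, union-of-disks
  effective trapping area, and the delta-method SE.

A synthetic-survey generator (`sim_scenario()`, `simulate_survey()`)
reproduces the study design — four sites from remote to roadside, 25 stations
per site in ~107 km² polygons at 2–3 km spacing, 90 days — with known
parameters, so every estimator is verified by oracle checks and parameter
recovery without any field data.

## Worked example

```r
library(camtrapDens)

scen <- sim_scenario(config = ct_config(seed = 7))   # study-design defaults
sim  <- simulate_survey(scen)
sv   <- sim$survey                                   # validated ct_survey

## occupancy for the most hunting-sensitive species
rep <- occupancy_report(sv, "white-lipped peccary")
head(rep$ranking, 3)
#>               model K    logLik     AICc    dAICc    weight
#> 1   psi(RR+ST)p(DC) 5 -350.5970 711.8324 0.000000 0.4446526
#> 2      psi(ST)p(DC) 4 -352.2600 712.9410 1.108618 0.2554392
#> 3 psi(RR+ST+H)p(DC) 6 -350.3322 713.5677 1.735282 0.1867279
rep$best
#> Occupancy fit psi(RR+ST)p(DC) [white-lipped peccary]: logLik -350.597, K = 5
#>                 estimate     se
#> psi_(Intercept)  -6.6728 1.6948
#> psi_RR            0.2745 0.1646
#> psi_ST            0.7681 0.1932
#> p_(Intercept)    -2.6458 0.4927
#> p_DC              0.1670 0.0465
```

The settlement-distance effect is recovered near its simulated value
(β_ST = 0.77 logits per km), and site-averaged ψ̂ reproduces the remote-high /
roadside-low gradient (`rep$site_psi`: 0.89 and 0.99 at the two remote sites
vs 0.32 and 0.35 at the accessible ones).

```r
## predator density, both estimators
res <- secr_site(sv, "Lorocachi", n_iter = 10000, escalate = FALSE, seed = 2)
res$density
#> $mean 5.14   $sd 1.29   $ci95 3.06 7.83   (true simulated density: 4.97)

nonspatial_density_report(sv)[2, c("site", "Nhat", "mmdm_km", "eta_km2", "D", "D_se")]
#>        site Nhat mmdm_km eta_km2    D  D_se
#> 2 Lorocachi 22.9    6.14     390 5.87 0.791
```

Each `secr_fit` carries per-parameter Geweke z values; with escalation
enabled (the default) runs double their iterations until the abundance and
inclusion chains pass, and report honestly when σ/λ₀ remain poorly mixed.

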