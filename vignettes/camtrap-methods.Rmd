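---
title: "Methods: occupancy, prey biomass and predator density from camera-trap surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: occupancy, prey biomass and predator density from camera-trap surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(camtrapDens)
```

camtrapDens implements the analysis chain of a multi-site camera-trap study
of a large Neotropical predator and its prey along a gradient of landscape
accessibility to hunters: prey occupancy with accessibility covariates, a
per-station prey biomass index, and two density estimators for the
individually identifiable predator. This vignette explains each model, its
assumptions, the tunable constants and their defaults, and the design choices
made where the methodology left them open.

## Survey data model

A survey is four tables: stations (projected km coordinates, distances to the
nearest road, river and settlement, a ridge/valley habitat class, the spacing
in metres between the two paired cameras, and an activity window in 1-based
survey days), time-stamped photo events with group counts, individually
identified predator capture records, and mean adult body masses. The default
window is 90 days; occupancy uses 9 occasions of 10 days and
capture-recapture 30 occasions of 3 days. All distances are planar Euclidean.
When a user-supplied window does not divide evenly, the final short occasion
is kept and its reduced effort recorded (the default design divides evenly,
so this only affects external data). Camera-failure days enter as shortened
activity windows: station-occasions with zero active days become missing
cells, the standard missing-at-random treatment.

All randomness flows from one master seed in `ct_config()`; each stage
derives an independent substream with `derive_seed()`, so re-running one
stage never perturbs another.

## Single-season occupancy

For station $s$, presence $z_s \sim \mathrm{Bernoulli}(\psi_s)$ with
$\mathrm{logit}(\psi_s) = \beta_0 + \beta_{RR} RR_s + \beta_{ST} ST_s +
\beta_H H_s$, and detection per occasion
$\mathrm{logit}(p_s) = \alpha_0 + \beta_{DC} DC_s$. The likelihood is the
usual zero-inflated product over occasions; missing occasions drop out of the
product. Because the species are wide-ranging, $\psi$ is interpreted as
probability of site use rather than closure-strict occupancy.

Covariates enter untransformed (km, m, 0/1) so coefficients are directly
comparable across species; internally the optimiser works on standardized
covariates and maps the solution and its covariance back exactly, which keeps
the quasi-Newton search well-conditioned without changing the reported scale.
Fitting uses multi-start BFGS with the analytic score (a zero start, a
naive-occupancy start, and three random starts); standard errors come from
the inverse observed information. A fit is flagged non-converged, and
excluded from ranking, if the optimiser fails, the score norm at the optimum
exceeds 1e-4, or the information matrix is not positive definite.

The candidate set crosses all eight subsets of $\{RR, ST, H\}$ on occupancy
with constant-or-$DC$ detection: 16 models. The emulated study counted 15
without stating the omitted combination; `strict_15 = TRUE` drops the
doubly-null model $\psi(.)p(.)$ as one plausible reading, and the default
reports all 16. Ranking uses
$\mathrm{AICc} = -2\ell + 2K + 2K(K+1)/(n-K-1)$ with $n$ = number of stations
(the conventional effective sample size; a config knob). Site-level occupancy
is the arithmetic mean of station-level unconditional predictions
$\hat\psi_s$ within each site, with a delta-method SE; conditional
(history-informed) predictions are the other defensible choice, but
unconditional predictions are comparable across stations with different
detection histories.

## Prey biomass index

Photo events of a species at a station are reduced to independent events with
a fixed 1-hour window anchored at the opening event: photos within the window
merge into one event carrying the maximum group count; the first photo at or
past the window boundary opens the next. This reading reconciles "a minimum
of 1 hour between detections" with "choose the picture with the largest
number of individuals"; a rolling-gap variant is available behind
`rule = "gap"` for sensitivity analysis.

The station index is $BI = \sum_i n_i w_i / t$ (kg/day), with $n_i$ the
summed independent-event counts of species $i$, $w_i$ its mean adult mass and
$t$ the station's active days. Three class filters are computed: all
terrestrial species of at least 1 kg, ungulates only, and non-ungulates; the
sympatric puma is excluded as non-prey. The species roster and the mass table
are editable data, not constants, because the masses used in the original
analysis are not printed and any replication depends on them. Site
differences are tested with the Kruskal-Wallis rank test (tie-corrected,
chi-square p), and the association of ungulate biomass with each
accessibility distance is a Pearson correlation whose uncertainty comes from
the Bayesian bootstrap: flat-Dirichlet observation weights, 1000 posterior
draws of the weighted correlation, and the narrowest 95% highest-density
interval.

## Bayesian SECR

The predator model is the standard data-augmented spatial capture-recapture
null model. Activity centers live on a discrete state space: a regular grid
at one center per km2 over the trap envelope buffered by 15 km (convex hull
by default; a rectangle mode gives deterministic geometry in tests), each
center carrying a binary habitat-suitability flag (all suitable by default).
Detection is half-normal with Bernoulli encounters,
$p(d) = 1 - \exp(-\lambda_0 e^{-d^2/2\sigma^2})$, so $\log(1-p)$ equals the
negative hazard exactly, which the sampler exploits. Augmentation adds
all-zero histories up to $M = 30\times$ the observed count (20-40x is
conventional); $N_{super}$ is the number of included centers and
$D = 100\,N_{super}/A$ per draw, with $A$ the suitable area.

The sampler is Metropolis-within-Gibbs, written in C++: log-scale random
walks for $\sigma$ and $\lambda_0$ with uniform priors on wide positive
ranges (0.1-20 km and 1e-4-5 by default; both are logged config knobs since
the original tool's prior ranges are unstated), step sizes adapted toward
20-40% acceptance during burn-in only; a Beta draw for the inclusion
probability $\psi$; Gibbs indicators for the augmented individuals; and exact
categorical Gibbs draws of every activity center over the grid. Direct
center Gibbs is a deliberate design choice over random-walk center proposals:
on a discretized state space the full conditional is available in closed
form, mixes far better at camera-trap sparsity, and removes a tuning
parameter. Burn-in is 50% and thinning 10. Convergence is judged by the
Geweke z (first 10% vs last 50%, spectral-density SEs; |z| < 1.6 passes);
if $N_{super}$ or $\psi$ fail, the run escalates by doubling iterations up to
600,000 and otherwise reports the failure honestly — with sparse data
$\sigma$ and $\lambda_0$ often remain poorly mixed even when the abundance
chain is stable, and the fit reports that per-parameter rather than hiding
it.

## Classical density

The non-spatial estimate is $D = \hat N / ETA$. Abundance uses the
Burnham-Overton jackknife under individual heterogeneity (model Mh), orders
1-5 from the capture-frequency counts, with the closed-form variance and the
sequential between-order test at level 0.05 choosing the reported order; a
linear interpolation between the adjacent orders in the attained p-value of
the last significant test is also reported (the classical program
interpolates near the selection boundary; the exact rule is not published, so
both the integer-order and interpolated values are exposed, plus a
fixed-order override for exact reproducibility). A span-based closure
diagnostic aggregates, over individuals captured at least twice, the exact
null moments of the capture-span under occasion-exchangeability.

The buffer is the full MMDM — the mean over individuals captured at two or
more distinct stations of their maximum inter-station distance, pooled across
sites (full rather than half MMDM is the more conservative published choice
for this predator). ETA is the area of the union of buffer disks around the
stations, computed by exact interval union in y integrated over a fine x grid
(4096 strips; relative error well under 0.5%, cross-validated against
Monte-Carlo quadrature in the tests). Because the classical SE formula needs
a variance for ETA that the source chain does not define, the package uses a
symmetric buffer perturbation: half the range of ETA recomputed at
buffer ± SE(MMDM). The density SE is the delta method,
$SE(D) = D\sqrt{Var(\hat N)/\hat N^2 + Var(ETA)/ETA^2}$. These estimates are
known to depend on trap spacing and recapture counts; the package reports
them alongside SECR rather than preferring them.

## The synthetic survey generator

`sim_scenario()` / `simulate_survey()` generate the full survey with known
truth. Defaults emulate the study design: four sites ordered from remote to
roadside, 25 stations per site on a jittered grid (rows play the role of cut
transects) inside a 10.2 x 10.5 km polygon (~107 km2, within the 104-110 km2
field range), 2 km minimum spacing, 90 days. Covariates are true distances
to simulated features (a road line, a river line, a settlement point per
site), spanning roughly 1-75 km to roads and 3-16 km to settlements across
the gradient, like the field arrays; a direct-draw mode is not needed because
the features are explicit. Prey occupancy and detection coefficients default
to the published best-fit values for the eight prey species, so the strongest
effect (settlement distance on white-lipped peccary, 0.77 logit/km) is the
recovery benchmark. Quantities the field data do not pin down are free
choices, stated here once: photo events per detected occasion (zero-truncated
around 1.5), zero-truncated-Poisson group sizes (mean 5 for the herding
peccary, 2 for its congener, 1 otherwise), uniform event times within
occasions, and camera spacing uniform on 6-14 m.

The predator truth defaults to density 5 per 100 km2, sigma 2.5 km and
lambda0 = 0.2 per occasion — the recovery conditions used throughout the
tests; the observed study animals are sparser, and any jaguar-like scenario
is one `sim_scenario(D =, sigma =, lambda0 =)` call away. Centers are a
binomial point process (fixed $N$ = round of $D \cdot A/100$; a Poisson
variant is switchable) over the buffered rectangle, and captures are exact
draws from the half-normal/Bernoulli observation model, so the generator's
expected observed count has a closed form that the tests check by quadrature.

What passing recovery tests do and do not show: the generator draws from the
same model families the estimators fit, so recovery demonstrates correctness
of the likelihoods, samplers and plumbing — not robustness to the
misspecifications real surveys carry (temporal heterogeneity, behavioral
responses to bait, non-uniform space use, mis-identification). The biomass
stage's event stream places a random number of photo events inside each
detected occasion, which exercises the independence filter, but it does not
emulate animal-specific movement autocorrelation.

## Problem sizes used in the checks

The bundled checks run at sizes chosen to give tight Monte-Carlo error at
desk scale: 1000 random small instances for the likelihood-enumeration
oracle; 200 simulated surveys (100 stations x 9 occasions) for Wald coverage
of the settlement effect; 20 simulated sites at 10,000 MCMC iterations for
SECR density recovery (mean posterior-mean error and 95%-interval coverage);
1000 random capture matrices for the jackknife oracle; 50 random layouts
against 1e6-point Monte-Carlo quadrature for the disk-union area. The
replication entry point (`replicate_study()`) additionally reproduces the
published tables when pointed at local copies of the study's deposited
workbooks, which are not redistributed here.

## Known limitations

Single-season models only (no dynamics, no density covariates, no behavioral
response); detection covariates are station-level; the SECR model is the
null model with homogeneous density; sites are treated as independent
populations; the XLSX readers tolerate modest layout variants of the
deposited workbooks but cannot be validated against files that are absent
from this environment.
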