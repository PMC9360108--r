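---
title: "Methods: population PK with transit-compartment absorption"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population PK with transit-compartment absorption}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(transitpk)
```

This vignette is the package's own account of its models, estimation
methods, numerical choices and limitations. It states no empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

## The structural model

Oral imatinib absorption is delayed and highly variable. The package's
final structural model sends the dose through a chain of $N$ transit
compartments with mean transit time $MTT$ (transit rate
$k_{tr} = (N+1)/MTT$), producing the depot input rate

$$r(t) = D\,k_{tr}\frac{(k_{tr}t)^N e^{-k_{tr}t}}{\Gamma(N+1)},$$

a gamma$(N+1, k_{tr})$ density scaled by the dose. $\Gamma(N+1)$ is
evaluated through the log-gamma function, so $N$ is a continuous,
estimable parameter. The depot empties at the first-order rate $K_a$ into
a two-compartment disposition system (apparent parameters $CL/F$, $V_1/F$,
$Q/F$, $V_2/F$) with first-order elimination from the central compartment.
Bioavailability $F$ is not identifiable with oral-only data and never
appears as a separate symbol: all volumes and clearances are apparent.

The candidate ladder around this model — one- to three-compartment
disposition; first-order absorption with and without a lag; zero-order
(constant-rate) input with a lag; a double-peak model splitting the dose
over two parallel first-order paths (optionally sharing one rate constant);
the transit model — is available through `pk_structure()` so the model
development sequence can be replayed on simulated data. The reported
OFV/AIC values of that development sequence ship as `model_ladder()`; two
rows whose printed AIC is not internally consistent with $OFV + 2p$ (A2,
and B3, which also reported unrealistic estimates) are flagged
`aic_consistent = FALSE` and excluded from exact-arithmetic checks.

**Solution method.** All disposition systems are linear, so the unit
impulse response of the depot–central system is a sum of exponential modes
(Bateman-type coefficients; eigendecomposition for three compartments).
First-order, lagged, zero-order and double-peak models are solved in
closed form. The transit model convolves $r(t)$ with the impulse response,
per mode $\lambda$:

$$I(t) = e^{-\lambda t}\left(\frac{k_{tr}}{k_{tr}-\lambda}\right)^{N+1}
P(N+1, (k_{tr}-\lambda)t), \qquad k_{tr} > \lambda,$$

with $P$ the regularised lower incomplete gamma function, evaluated in log
space (a compiled kernel; this is the hot path of the conditional
estimation loop). Modes with $\lambda$ near or above $k_{tr}$ — reachable
during optimizer excursions — fall back to two-panel Gauss–Legendre
quadrature (40 nodes over the gamma mass up to its upper $10^{-9}$
quantile, 40 over the remainder). The tests verify the kernel against an
independent `deSolve` integration of the ODE system to about $10^{-7}$
relative error, and mass balance (compartment contents plus cumulative
elimination equal cumulative input) to $10^{-6}$.

**Steady state** is realised by explicit superposition of doses every
$\tau$ hours, with the number of doses chosen from the smallest
disposition eigenvalue so the trough is converged to 0.1% (verified
against a 30-dose brute-force superposition). Dose linearity and
superposition are property-tested. Times after the last dose may exceed
$\tau$, which is how samples after a skipped or delayed dose are
represented.

**Degenerate inputs.** A transit model with $N = 0$ and $MTT \to 0$
collapses to plain first-order absorption (tested at tolerance $10^{-3}$);
repeated disposition roots and $K_a$ colliding with a disposition
eigenvalue are handled by relative nudges of $10^{-7}$–$10^{-8}$;
non-finite or non-positive parameter trials return `NaN` predictions,
which the estimation layer converts to a large penalty.

## Estimation: FOCE with interaction

For subject $i$ with observations $y_i$, lognormal random effects
($P_i = TV\,e^{\eta_i}$, $\eta \sim N(0,\Omega)$) and residual variance
$v_{ij}$ (additive, proportional or combined), the conditional mode
$\hat\eta_i$ minimises the joint objective

$$\sum_j\left[\log v_{ij}(\eta) + \frac{(y_{ij}-f_{ij}(\eta))^2}{v_{ij}(\eta)}\right]
+ \eta'\Omega^{-1}\eta,$$

with the variance evaluated at the conditional prediction ("interaction").
The population objective linearises $f$ around $\hat\eta_i$:

$$OFV_i = \log|C_i| + r_i'C_i^{-1}r_i,\qquad
C_i = J_i\Omega J_i' + \mathrm{diag}(v_i),\quad
r_i = y_i - f_i(\hat\eta_i) + J_i\hat\eta_i,$$

summed over subjects and excluding the $n\log 2\pi$ constant, so that
$AIC = OFV + 2p$ and likelihood-ratio differences follow $\chi^2$. On
linear-Gaussian submodels this reproduces the exact marginal
$-2\log L$ to $10^{-6}$ (tested), and conditional weighted residuals are
the standardised $C_i^{-1/2}r_i$.

Numerical choices, all chosen before any benchmark against reported
values and kept fixed:

* inner $\eta$ search: BFGS to relative tolerance $10^{-12}$. The
  conditional objective can be multimodal (most visibly through exchange
  between the absorption rate $K_a$ and the transit rate $k_{tr}$), so the
  mode is searched from both $\eta = 0$ and the previous outer iteration's
  warm start, keeping the deeper mode; between periodic resynchronisations
  the warm chain alone is followed, which is cheap and smooth;
* Jacobians $\partial f/\partial\eta$: central differences, relative step
  $10^{-4}$;
* outer search: BFGS on transformed parameters — $\log\theta$,
  log-Cholesky $\Omega$ blocks, $\log\sigma$, `log1p` for proportional
  covariate shifts — with a forward-difference gradient (relative step
  $10^{-4}$, reusing the objective at the expansion point); positivity is
  therefore structural, and a non-positive-definite $\Omega$ or failed
  Cholesky yields a $10^{10}$ penalty. Because the warm chains make the
  objective mildly history-dependent, the best visited point is tracked
  explicitly and BFGS is restarted from it until a round improves the OFV
  by less than `restart_tol` (default 0.5);
* the covariance step takes twice the inverse Hessian of the OFV (central
  differences on the transformed scale, relative step $10^{-3}$) and
  delta-methods it to the natural scale; a non-positive-definite Hessian
  sets `covariance_ok = FALSE`, and model candidates failing this step are
  skipped during covariate scanning;
* IIV is reported as $CV\% = 100\sqrt{e^{\omega^2}-1}$ (the lognormal
  convention; the alternative $100\,\omega$ differs by under 3% at
  $\omega \approx 0.25$);
* `poppk_control()` exposes a jittered multi-start
  (`n_starts`, `jitter_sd = 0.2` on the transformed scale, sub-seeds
  derived from `seed`); the default is a single start from the supplied
  initial values, which on the rich 17-sample design converges to the
  same optimum as jittered restarts (property-tested at reduced size) —
  multi-start is recommended for sparse or irregular designs.

The omega block: the reference analysis reports a strong correlation
between the CL and V1 empirical Bayes estimates ($r > 0.9$) and a block
between those two random effects, although one table caption instead says
CL–Ka; the package follows the text (CL–V1), makes block membership
configurable in `iiv_spec()`, and uses $r = 0.9$ as the simulation truth —
a documented choice, since only the inequality is reported.

## Covariate machinery

Continuous covariates enter multiplicatively through linear, power,
exponential or hockey-stick forms referenced at the cohort median (the
hockey-stick break point is the median, and the form is continuous there
by construction); body weight can additionally use fixed-exponent
allometry (0.75 on clearances, 1 on volumes, estimable on request).
Categorical covariates use a proportional shift $TV(1+\theta)$ per
non-reference level with $\theta > -1$ enforced; a level set with $k$
categories consumes $k-1$ parameters and the LRT degrees of freedom follow.
Pharmacogene diplotypes are pooled to CPIC-style phenotype groups by
`pool_phenotypes()`; unmapped diplotypes become an explicit
`"unclassified"` category, never a silent drop. The stepwise scan adds the
candidate with the smallest forward p-value below 0.05 and then removes any
covariate whose backward elimination p-value is at or above 0.01, so a
chance forward inclusion (expected for roughly one candidate in twenty
under the null) is pruned unless it survives the stricter backward test —
the behaviour the null-control test exercises. Age is excluded from the
default candidate set because the emulated cohort spans only 19.7–31 years.

## Non-compartmental analysis

AUC uses the linear-up/log-down trapezoid by default (plain linear
optional); for single oral doses a zero concentration is anchored at the
dose time. The terminal slope is the best adjusted-$R^2$ log-linear
regression over the last 3–6 quantifiable points strictly after tmax
(minimum 3; slopes below $10^{-8}$ h$^{-1}$ are not accepted, so flat
profiles report no extrapolation-dependent quantities); the exact
point-selection rule of the original NCA report is not restated there, so
the adjusted-$R^2$ rule is this package's documented choice. tmax ties
break to the earliest time. The model-based comparator reports CL and
$V_1+V_2$ from the individual parameters and Cmax/tmax/AUC from the
individual predicted curve on a 0.01 h grid; comparisons use paired
t-tests on logs for lognormal metrics and a paired sign-rank test (or
paired t) for tmax.

## Evaluation tools

The VPC simulates `n_sim` replicates at the observed design and overlays
observed 5th/50th/95th percentiles on the 95% simulation envelopes,
binning by exact scheduled time for protocolised designs (the synthetic
schedule) and by supplied edges, with empty bins merged leftwards, for
irregular data; the original analysis does not state its binning, so
exact-time binning is a documented choice. The bootstrap resamples
subjects with replacement to the original cohort size, refits from the
base estimates, counts failed replicates in the success rate and excludes
them from the median/CI summaries, and is stratification-free. Both take
explicit seeds and are bit-reproducible.

## Synthetic cohorts: what they emulate, and what they do not

The healthy design: 26 subjects, one 400 mg dose, 17 samples at 0.5, 1,
1.5, 2, 2.5, 3, 3.5, 4, 4.5, 5, 6, 8, 10, 12, 24, 48, 72 h — dense through
the absorption peak, inside the 16–19-sample range of the emulated study,
whose exact per-subject times are reported only as ranges. Demographics
are drawn from truncated lognormals matching the reported medians and
ranges (age 23.0 y, weight 69.5 kg, BMI 22.5 kg/m², BSA 1.86 m² via
Mosteller, 18 M : 8 F); genotypes follow Hardy–Weinberg proportions with
plausible European allele frequencies that are deliberate placeholders,
not estimates from the emulated cohort. The patient design: 40 patients on
200/300/400/600 mg q.d. or 400 mg b.i.d. (400 q.d. dominant), 3–6
observations each, recorded times-after-dose lognormal around the dosing
interval ($\sigma_{\log} = 0.5$, so about half the samples fall inside the
prescribed interval, exercising the interval filter), clearance scaled by
0.75 ($13.2 \times 0.75 = 9.9$ L/h), and a 5% rate of observations after
an unrecorded skipped dose. Observations below the 0.01 mg/L limit of
quantification are excluded, not modelled (the exclusion approach of the
emulated analysis; an M3-style censored likelihood is out of scope).

What passing tests on these cohorts do **not** show: the generators share
the structural model with the estimator, so parameter-recovery results
demonstrate estimator correctness, not model adequacy for real imatinib
data; assay error is ideal proportional noise; dosing histories are exact
apart from the modelled non-compliance; and covariate effects exist only
when injected.

## MAP Bayesian monitoring, and a geometry worth knowing

`map_apply()` holds the population parameters fixed and estimates each
patient's $\eta$ by MAP, with
$CL_{bayes} = CL_{pop}e^{\hat\eta_{CL}}$, prediction errors
$PE_{DV} = (IPRED-DV)/DV \times 100$ and
$PE_{CL} = (CL_{pop}-CL_{bayes})/CL_{bayes} \times 100$, and bias/precision
as median and median-absolute PE. Trough-only data chiefly informs
$\eta_{CL}$; the absorption and distribution effects move little (tested).

One consequence of the correlated CL–V1 prior deserves emphasis. At a
24 h trough, *lowering* $V_1$ lowers the predicted trough (faster
terminal elimination outweighs the higher peak). When a patient
population's clearance is scaled down without a matching volume shift, the
MAP solution drags $\hat\eta_{V1}$ negative along the prior ridge, which
lowers the predicted trough and forces $\hat\eta_{CL}$ further down than
the true deviation: at the package's patient conditions the median
$PE_{CL}$ comes out around 10 points above the algebraic
$1/0.75 - 1 = 33.3\%$. With sampling spread across the dosing interval
(e.g. 2/6/12/24 h), clearance and volume separate and the algebraic value
re-emerges (tested); with an uncorrelated prior the usual shrinkage toward
the population mean dominates instead. Trough-based $PE_{CL}$ from a
correlated-prior model should therefore be read as a detector of
clearance deviation, not an unbiased estimate of its size.

Patients recorded "at steady state" are taken at face value; abnormally
low observations are kept (non-compliance is only simulated, never
auto-excluded); the dosing-interval filter (24 h q.d., 12 h b.i.d.)
provides the within-interval sensitivity analysis.

## Problem sizes in the test suite

The suite exercises the full 26 × 17 FOCE-I recovery at three seeds, the
population simulation at $10^4$ subjects, the bootstrap property at 100
replicates of a reduced one-compartment cohort, VPC calibration at 150–200
simulations, and the covariate scan on a 26-subject one-compartment
cohort — sizes chosen so each property is tested at meaningful power while
the whole suite stays convenient to run routinely.

## Known limitations

No inter-occasion variability, no SAEM or full Bayesian posterior, no
saturable elimination or enterohepatic recirculation, no metabolite
kinetics, no below-LOQ likelihood, no prediction-corrected VPC (a single
dose level in the rich cohort makes plain VPC appropriate), and no
dose-adjustment logic — the package estimates and evaluates; dosing
decisions remain with the analyst.
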