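---
title: "Analytic GEE power for complete and incomplete stepped wedge trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analytic GEE power for complete and incomplete stepped wedge trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swgeepower)
library(dplyr)
```

## The problem

Stepped wedge cluster randomized trials (SW-CRTs) roll an intervention out
across clusters at staggered, randomized times, so every cluster eventually
crosses from control to intervention. Real stepped wedge studies are often
*incomplete*: some cluster-periods collect no data because of implementation
periods (a block of time needed to activate the intervention), staggered
study entry, or early termination. Power methods for SW-CRTs have mostly
targeted complete layouts and continuous outcomes; `swgeepower` implements
an analytic ("fast", non-simulation) power procedure for marginal models
fitted by generalized estimating equations (GEE) that handles complete and
incomplete layouts, binary and continuous outcomes, and five intracluster
correlation structures — together with the GEE/MAEE estimation machinery and
simulators needed to check the analytic predictions against empirical size
and power.

## Marginal model

For individual $k$ in cluster $i$ at calendar period $t_{ij}$, the marginal
mean $\mu_{ijk}$ follows

$$g(\mu_{ijk}) = \beta_0 + \beta_1 (t_{ij} - 1) + u_{ij}\,\delta,$$

with a linear period effect and a treatment term $u_{ij}$. Linear (rather
than categorical) period effects matter for designs with many more periods
than clusters: the t-test uses $I - 3$ cluster degrees of freedom, which
stays positive when $I > 3$ regardless of the period count. Two treatment
parameterizations are supported:

* **average effects**: $u_{ij} \in \{0, 1\}$ and $\delta$ is the
  intervention effect on the link scale, irrespective of time on treatment;
* **incremental effects**: the $m$-th period on treatment carries
  $u_{ij} = m / q$, modelling gradual uptake; $\delta$ is the effect after
  $q$ periods on treatment ($q = 10$ by default, so a 10-period effect).

Binary outcomes use the logit link with variance $\mu(1 - \mu)$ and
dispersion $\phi = 1$; continuous outcomes use the identity link, variance
function 1 and free dispersion $\phi$; count outcomes (log link, variance
$\mu$) are supported as plumbing.

## Design representation

A design is specified per sequence by the calendar periods of data
collection under control ($b_{s0} .. b_{s1}$) and intervention
($q_{s0} .. q_{s1}$); the gap $c_s = q_{s0} - b_{s1} - 1$ is the number of
implementation periods. Equivalently, a **design pattern matrix** (entries
0 / 1 / missing) and the derived 0/1 **completeness matrix** encode the same
layout as a sequences-by-periods grid, and each completeness row defines an
**incidence matrix** $K_s$ that deletes unobserved periods from any
complete-design object: design matrices, correlation, variance and
derivative matrices all restrict by $K_s (\cdot) K_s'$ or $K_s (\cdot)$.
The individual-level design matrix is the Kronecker expansion
$X_s^{(inc)} \otimes 1_N$ for cluster-period size $N$.

The built-in `connect_home_design()` reconstructs the motivating trial: six
skilled nursing facilities, 22 monthly periods, two implementation periods
per sequence, staggered entry and termination, 15 observed periods per
sequence and 360 patients in total. The published description pins this
layout through four anchors (the sequence-2 taxonomy $b = (2,7)$,
$q = (10,18)$; $c = 2$ everywhere; ten intervention periods for sequence 1;
and the 360-patient total at four per cluster-period), which jointly force
the closed form used here: sequence $s$ has control periods $s..2s+3$,
implementation $2s+4..2s+5$ and intervention $2s+6..s+16$. The original
figure is not machine-readable from text, so the reconstruction is
validated by this internal consistency — and, empirically, by exact
reproduction of all published predicted-power values computed from it.

## Correlation structures

Five working structures cover cross-sectional designs (new individuals each
period) and closed cohorts (individuals followed across periods):

| Structure | Within-period | Between-period, different individual | Same individual |
|---|---|---|---|
| EX (exchangeable) | $\alpha_0$ | $\alpha_0$ | — |
| NE (nested exchangeable) | $\alpha_0$ | $\alpha_1$ | — |
| ED (exponential decay) | $\alpha_0$ | $\alpha_0\rho^{|t - t'|}$ | — |
| BE (block exchangeable) | $\alpha_0$ | $\alpha_1$ | $\alpha_2$ |
| PD (proportional decay) | $\alpha_0$ | $\alpha_0\rho^{|t - t'|}$ | $\rho^{|t - t'|}$ |

Decay exponents use **calendar-period distance**, not observed-period index
distance. This is the consequential choice for incomplete designs: an
implementation gap of two periods contributes to the decay even though no
data are collected in it (`incomplete_correlation()` tests pin this down).
BE reduces to NE when $\alpha_1 = \alpha_2$, and ED with $\rho = 1$ is EX;
these nesting identities are enforced entrywise and carry over to power.

Each structure corresponds to a generalized linear model for the pairwise
correlations: identity link with indicator covariates for EX/NE/BE
($\rho_{pair} = z_0\alpha_0 + z_1\alpha_1 + z_2\alpha_2$), log link for the
decay structures ($\log \rho_{pair} = z_0\gamma_0 + z_1\gamma_1$ with
$z_1 = |t - t'|$, $\alpha_0 = e^{\gamma_0}$, $\rho = e^{\gamma_1}$), which
is also how the fitting algorithm estimates them.

## Fast power

With $D_i = \partial\mu_i/\partial\theta'$ and working covariance
$V_i = A_i^{1/2} R_i A_i^{1/2}$, the model-based covariance of the GEE
estimator is $\Sigma_1^{-1} = \left[\sum_i D_i' V_i^{-1} D_i\right]^{-1}$,
and $\mathrm{var}(\hat\delta)$ is its (3,3) element. Predicted power for the
two-sided Wald test of $H_0{:}\ \delta = 0$ at level $\alpha$ is

$$\Phi\!\left(z_{\alpha/2} + |\delta| / \sqrt{\mathrm{var}(\hat\delta)}\right)
\quad\text{(z-test)}, \qquad
\Phi_{t, I-3}\!\left(t_{\alpha/2, I-3} + |\delta| /
\sqrt{\mathrm{var}(\hat\delta)}\right) \quad\text{(t-test)},$$

where $z_{\alpha/2}$ and $t_{\alpha/2, I-3}$ are *lower-tail* quantiles
(negative), making the formulas literal, and the t version uses the central
t distribution shifted by the standardized effect. All clusters in a
sequence share $X$ and $R$, so one representative cluster per sequence is
computed and weighted by $m_s$; solves use the symmetric factorizations and
no correlation matrix is explicitly inverted.

```{r power}
design <- connect_home_design(6)
model <- mean_model("binomial", beta0 = 0.85, beta1 = -0.01, delta = -1.2)
sw_power(design, model, corr_structure("EX", alpha0 = 0.03))
```

For sample-size determination, `sw_power_curve()` sweeps the cluster-period
size or the cluster count:

```{r curve}
sw_power_curve(design,
               mean_model("binomial", beta0 = 0.85, beta1 = -0.01,
                          delta = -1.4),
               corr_structure("NE", alpha0 = 0.03, alpha1 = 0.015),
               cluster_period_size = 4:9, target_power = 0.8)
```

## Estimation: GEE with MAEE and bias-corrected variances

`sw_gee()` fits the marginal model by alternating Fisher scoring for
$\theta$ (solving $\sum_i D_i' V_i^{-1} (y_i - \mu_i) = 0$), estimating
equations for the correlation parameters, and a method-of-moments update of
$\phi$ for continuous outcomes. The correlation equations use
matrix-adjusted estimating equations (MAEE): cross-products of Pearson
residuals are adjusted by the cluster leverage
$H_i = D_i \Sigma_1^{-1} D_i' V_i^{-1}$ to reduce finite-sample bias. The
adjusted products used here are the symmetrized one-sided form
$s_{ab} = ([(I - H_i)^{-1}\hat e_i]_a \hat e_{ib} +
[(I - H_i)^{-1}\hat e_i]_b \hat e_{ia})/2$ with identity working weights;
setting the adjustment off (`control = list(maee = FALSE)`) recovers plain
moment estimation, and the estimate is consistent as the number of clusters
grows — these two contracts are what the test suite enforces, since
published accounts of the adjustment differ in detail. Decay structures are
updated on the $\gamma = (\log\alpha_0, \log\rho)$ scale by Gauss–Newton;
iterates stepping outside $(0, 1)$ on the natural scale are step-halved up
to 10 times and then declared a (boundary) convergence failure, mirroring
the failure mode reported for decay structures in small samples.

Numerical defaults: at most 100 iterations; convergence when the largest
absolute parameter change falls below $10^{-6}$; $\theta$ initialized at the
working-independence GEE solution and correlations at 0.01 (or
$\gamma = \log 0.01$).

Five variance estimators accompany every converged fit, assembled as
$\Sigma_1^{-1}\hat\Sigma_0\Sigma_1^{-1}$ with
$\hat\Sigma_0 = \sum_i F_i D_i'V_i^{-1}B_i \hat e_i \hat e_i' B_i' V_i^{-1}D_iF_i$
(residuals on the response scale):

* **MB** — model-based $\Sigma_1^{-1}$, valid under a correctly specified
  working correlation; the quantity the power method predicts.
* **BC0** — uncorrected sandwich ($F_i = B_i = I$); biased downward with
  few clusters.
* **BC1** — Kauermann–Carroll, $B_i = (I - H_i)^{-1/2}$ (computed by
  eigendecomposition of the non-symmetric $I - H_i$).
* **BC2** — Mancl–DeRouen, $B_i = (I - H_i)^{-1}$.
* **BC3** — Fay–Graubard, diagonal inflation
  $F_i = \mathrm{diag}\{(1 - \min(\zeta, [D_i'V_i^{-1}D_i\Sigma_1^{-1}]_{jj}))^{-1/2}\}$
  with bound $\zeta = 0.75$.

Because leverage elements lie in $(0, 1)$, the intervention-effect variances
are ordered $BC0 \le BC1 \le BC2$, which the tests assert on every simulated
fit.

## Simulators

`simulate_sw_trial()` draws outcomes with *exactly* the means and
correlations the power engine assumes. Binary vectors use the conditional
linear family (CLF) method: records are generated sequentially with
conditional success probability
$\lambda_m = \mu_m + c_m' \mathrm{Var}(Y_{<m})^{-1}(y_{<m} - \mu_{<m})$,
where the covariances are implied by the margins and target correlations
($\mathrm{cov}(Y_a, Y_b) = r_{ab}\sqrt{v_a v_b}$). Generation follows the
fixed period-major record ordering; the realized moments do not depend on
the ordering, only feasibility can. A conditional probability outside
$[0, 1]$ aborts with the offending record rather than clipping, because
clipping would silently bias the correlations. Continuous vectors are
multivariate normal with covariance $\phi R$ via Cholesky. Positive
definiteness is checked up front (`feasibility_check()`, minimum eigenvalue
$> 10^{-10}$); infeasible structures are rejected for generation but only
flagged for power, where invertibility suffices.

The generator's defaults are the study conditions of the motivating trial:
6 or 12 clusters with 4 or 2 patients per cluster-period (360 patients
total), baseline prevalence 0.7 declining gently to 0.65 over 22 months
($\beta_0 = 0.85$, $\beta_1 = -0.01$ on the logit scale), effect sizes
$\delta \in \{-1.2, -1.4\}$ (average model) and $\{-1.8, -2.4\}$
(incremental, $q = 10$), correlations $\alpha_0 = 0.03$,
$\alpha_1 = 0.015$, $\alpha_2 = 0.2$, $\rho = 0.8$ (ED) or $0.7$ (PD);
continuous analogues use $\beta_0 = 2$, $\beta_1 = -0.05$, $\phi = 1$. What
the simulator emulates is the *marginal* structure only: it does not model
covariate-driven heterogeneity, missingness beyond the planned design,
varying cluster-period sizes, or open-cohort churn, so passing simulation
checks demonstrate the internal consistency of the method under its own
assumptions, not robustness to real-data violations of them.

## Simulation harness

`run_scenario()` ties the pieces together: generate, fit, test, aggregate.
Rejection rates are computed over converged replicates only, with the
convergence rate always reported alongside (the exclusion rule is explicit
because published practice is not). Acceptance bands are recomputed from
the binomial model rather than hard-coded: the size band is the 95% normal
interval around the nominal level (at 2000 replicates,
`size_band(0.05, 2000)` rounds to [4.0%, 6.0%]) and the power margin is the
largest deviation of the exact binomial 95% CI (at 1000 replicates,
`power_margin(0.8, 1000)` rounds to 2.6%). Replicates draw from
per-replicate seed substreams, so results are reproducible and independent
of scheduling.

```{r scenario, eval = FALSE}
run_scenario(connect_home_design(12),
             mean_model("binomial", beta0 = 0.85, beta1 = -0.01,
                        delta = -1.4),
             corr_structure("EX", alpha0 = 0.03),
             reps = 1000, seed = 1)
```

Default replicate counts follow the study conditions (1000 for power, 2000
for size); the examples here and several tests use reduced counts purely to
keep the documentation fast, and the acceptance checks run the full counts.

## Design choices in open territory

* **Effect sizes as printed.** The binary effect sizes are the rounded
  values $-1.2 = \log 0.3$ and $-1.4 = \log 0.25$ (to one decimal) used in
  the published tables, not the exact logs; the reproduction tolerance
  absorbs the difference.
* **Implementation cells in the reference design.** The complete-design
  reference matrix assigns control status ($u = 0$) to implementation-period
  rows before deletion; this is what reproduces the published worked
  matrices, and those rows are deleted by $K_s$ anyway.
* **Incremental time-on-treatment counts observed intervention periods**
  (1, 2, ..., $q_s$), not calendar gaps — again pinned by the worked
  matrices.
* **Central t.** The t-test power uses the central t distribution shifted
  by the standardized effect, reading the formula literally; a noncentral-t
  variant would differ slightly but is not what the formula states.
* **Grid file dialect.** Design grids are text rows over {0, 1, .} with
  `.` for cells without data collection, plus a small YAML sidecar for
  cluster counts and sizes.

## Known limitations

Cluster-period sizes are constant within a design; open-cohort designs with
individual-specific time sets are out of scope; correlation structures are
homogeneous across clusters; and the MAEE adjustment follows the contract
described above rather than any single published variant. For six clusters
the t-test with $I - 3$ degrees of freedom is conservative, and analytic
power is closer to the empirical power of the model-based variance than of
BC1 — with twelve clusters the analytic prediction tracks the BC1 t-test
well, which is the method's central validation claim and is re-checked by
this package's acceptance tests.
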