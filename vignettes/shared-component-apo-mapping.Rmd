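---
title: "Joint spatio-temporal mapping of adverse pregnancy outcomes: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint spatio-temporal mapping of adverse pregnancy outcomes: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apomap)
```

## The problem

Low birth weight, pre-term birth, stillbirth and neonatal death are rare
relative to live births, share major risk factors (malaria exposure, anaemia,
antenatal-care access, micronutrient supplementation), and are reported
through routine facility systems at a spatial resolution — here sub-counties
— where single-outcome, single-area estimates are unstable. A joint
(shared-component) disease-mapping model borrows strength in three
directions at once: across neighbouring areas, across consecutive years, and
across the outcomes themselves.

## The model

For area $i = 1,\dots,N$, period $j = 1,\dots,J$ and outcome
$k = 1,\dots,K$, with $Y_{ijk}$ events out of $n_{ij}$ live births (one
denominator per area-period, shared across outcomes):

$$Y_{ijk} \sim \mathrm{Binomial}(n_{ij},\ \pi_{ijk}),$$
$$\mathrm{logit}(\pi_{ijk}) = \alpha_k + X_i\beta^{(s)} + X_{ij}\beta^{(st)}
  + \mu_{ijk},$$
$$\mu_{ijk} = \gamma^s_k u^s_i + u^s_{ik} + \gamma^t_k u^t_j + u^t_{jk}
  + \nu_{ij}.$$

* $u^s$ is a spatial field **common to all outcomes**, with an intrinsic CAR
  (ICAR) prior on the areal adjacency graph: the log-density is
  $-\tfrac{\tau}{2}\sum_{a\sim b}(u_a - u_b)^2$ up to the rank-deficient
  normalising convention below. Each outcome scales it by a positive weight
  $\gamma^s_k$; a large weight means that outcome's geography is dominated
  by the shared surface.
* $u^s_{ik}$ are outcome-specific ICAR fields capturing geography *not*
  shared with the other outcomes.
* $u^t$ and $u^t_{jk}$ are the temporal analogues with first-order
  random-walk (RW1) priors penalising $\sum_j (u_{j+1}-u_j)^2$, and
  $\gamma^t_k$ the temporal scaling weights.
* $\nu_{ij}$ is the space-time interaction: exchangeable normal by default
  (Knorr-Held Type I), optionally an independent RW1 per area (Type II).
* Covariate effects $\beta$ are pooled across outcomes by default (one
  coefficient per covariate, the shape in which such estimates are usually
  reported), with the outcome-specific alternative available through the
  parameterisation.

### Identifiability constraints

The ICAR and RW1 priors are improper: they do not fix the level of a field,
and multiplying the shared field while dividing its weights leaves the
likelihood unchanged. The package therefore works in a constrained
parameterisation: every field sums to zero (per graph component for spatial
fields), the interaction surface sums to zero overall, and the scaling
weights satisfy the product-one constraint
$\sum_k \log\gamma^s_k = \sum_k \log\gamma^t_k = 0$.

A note on the spatial-weight constraint: the additive form
$\sum_k \gamma^s_k = 0$ sometimes appears in print, but additive sum-to-zero
on multiplicative weights forces negative weights and conflicts with the
shared-component literature's positivity requirement. The package defaults
to product-one for both weight vectors and provides
`constraint = "literal"` to reproduce the additive spatial version for
comparison.

`apply_constraints()` projects any state onto this parameterisation,
compensating through the intercepts (and, for the literal spatial shift,
through the outcome-specific fields) so the likelihood is unchanged — it is
a reparameterisation, not a model change, and it is idempotent. The
compensation is exact on a connected graph; on a disconnected graph the
per-component offsets cannot all be absorbed into a single intercept, a
known limitation noted below.

### Priors and hyperpriors

None of the hyperpriors are dictated by the data sources this model is
typically fit to, so they are explicit and configurable
(`hyperpriors()`):

| block | prior | default |
|---|---|---|
| $\alpha_k$, $\beta$ | Normal$(0, \sigma^2)$ | $\sigma = 10$ |
| $\log\gamma_k$ | Normal$(0, \sigma_\gamma^2)$ | $\sigma_\gamma = 0.68$ (weights mostly in 0.2–5) |
| each precision $\tau$ | Gamma(shape, rate) | $(0.5,\ 0.0005)$ |

Rank-deficient blocks use the $(\mathrm{rank}/2)\log\tau$ convention with
rank $=$ areas $-$ components for ICAR blocks, $J-1$ for RW1 blocks and
$NJ-1$ (Type I) or $N(J-1)$ (Type II) for the interaction, so the conjugate
precision updates are proper. Isolated areas (singleton components) receive
a proper exchangeable normal term $-\tfrac{\tau}{2}u_i^2$ with the same
precision and contribute one to the rank.

## Computation

`run_chains()` runs an adaptive Metropolis-within-Gibbs sampler written in
C++ (the approach areal-model packages standardly take for this inner
loop):

* single-site Gaussian random-walk Metropolis for intercepts, covariate
  effects and every random-effect site;
* weight updates proposed *inside* the sum-to-zero log subspace (a move of
  $d(\mathbb{1}[l=k] - 1/K)$ on the log weights), so every state satisfies
  the constraint by construction;
* conjugate Gamma draws for each block precision given its quadratic form;
* the constraint projection re-applied after every sweep with intercept
  compensation;
* proposal scales adapted toward a 0.44 acceptance rate during burn-in
  only, in windows of 100 sweeps, so the post-burn-in chain is a valid
  Markov chain.

Initial values are the empirical pooled logit for each intercept, zeros for
fields and effects, ones for weights and precisions. The reference chain
protocol is two chains of 80,000 iterations with 4,000 burn-in
(`chain_config()` defaults); thinning (default 10) bounds memory. All
randomness flows through R's RNG, so a seed reproduces a run bit-for-bit.

Diagnostics follow the usual practice: the Gelman–Rubin potential scale
reduction factor (flagged converged below 1.1 — a conventional cut-off, not
one the underlying analysis protocol specifies), trace exports for every
retained scalar parameter, and a batch-means Monte-Carlo error check with
$\lfloor\sqrt{n}\rfloor$ batches applying the "MC error/SD below 5%"
stability rule.

## Covariate screening

`screen_covariates()` implements the two-step selection used in mapping
exercises: for each (covariate, outcome) pair a non-spatial Poisson
regression of the counts on the single covariate with a log live-birth
offset, fit by IRLS (`stats::glm`); covariates significant at Wald
$p < 0.05$ for any outcome are carried forward (the joint model pools the
covariate block); among selected pairs correlated beyond $|r| > 0.7$ the
larger-p member is dropped, with deterministic tie-breaks (deviance, then
name). The 0.7 threshold is a common epidemiological convention — the
procedure's description does not fix one — and is a flag. Intervals
reported at this stage are frequentist Wald intervals; the screening stage
is maximum-likelihood, not Bayesian.

## The synthetic-data generator

`generate_dataset()` simulates exactly the generative structure the model
assumes, so every downstream stage can be tested with known truth and no
data download. Defaults emulate the study conditions:

* a 29 × 10 rook lattice (290 areas, matching the sub-county count), 4
  annual periods, 4 outcomes;
* one live-birth denominator per area-period, uniform on 500–5,000;
* baseline logits $(-3.00, -3.75, -3.96, -4.97)$, the logits of
  national-scale rates of roughly 4.7 and 2.3 per 100 and 19 and 7 per
  1,000 live births for the four outcomes;
* covariates: one spatially smooth (standardised ICAR draw) and one white
  noise variable per block, so screening tests can distinguish signal from
  noise; effects $\pm 0.04$–$0.08$, the magnitude typical of the pooled
  covariate estimates such analyses report;
* shared spatial precision 4 and specific 16 (geography dominated by the
  shared surface), shared temporal precision 100 and specific 400 (yearly
  movements of a few percent on the logit scale), interaction precision
  400; weights $\gamma^s = (1.4, 1.1, 0.9, 0.8)$ and
  $\gamma^t = (1.3, 0.8, 1.2, 0.9)$, normalised to product one;
* an optional uniform missingness fraction (default 0).

What it deliberately does **not** emulate: reporting-completeness artefacts
(e.g. strike-year dips), outcome misclassification, facility-vs-community
denominator undercount, or spatially structured missingness. Tests passing
on this generator demonstrate that the machinery recovers the truth *when
the model is correctly specified*; they do not validate the model against
real reporting pathologies.

Tests and the workflow run on 3×3 to 8×8 lattices with denominators around
2,000; parameter-recovery checks use ten replicates of a 6×6 cube with two
chains of 20,000 iterations, and the holdout calibration an 8×8 cube so at
least 200 cells are held out. These sizes are chosen to make the full suite
replay on a desk machine in minutes while keeping every statistical check
at meaningful power.

## Holdout validation

`holdout_split()` removes a uniform 20% of observed (area, period, outcome)
cells — the cell, not the area, is the sampling unit, with an optional
per-outcome stratification — and the model is refit on the remainder
(refit-and-predict, matching the removed-points re-input described for the
original analysis). `posterior_predictive_compare()` then draws
$Y^* \sim \mathrm{Binomial}(n, \pi^{(\mathrm{draw})})$ per retained draw
and reports per-cell predictive medians, 95% intervals, interval coverage
and the mean absolute error on the rate scale. Coverage and rate-MAE are
this package's instrumentation; the original procedure states only that
posterior estimates were compared with observed values.

## Numerical choices and edge cases

* Binomial log-likelihoods use a softplus formulation,
  $y\eta - n\log(1+e^{\eta})$, stable for $|\eta|$ large; the generator
  warns and clamps if a configuration implies $|\mathrm{logit}\,\pi| > 30$.
* Cells that are masked or have $n = 0$ contribute exactly zero to the
  likelihood; a held-out cell with $n = 0$ is excluded from the predictive
  comparison with a warning.
* `gelman_rubin()` returns $\sqrt{(n-1)/n}$ for byte-identical chains
  (between-chain variance zero) and requires only two draws, so the
  textbook toy-array oracle can be checked directly.
* A constant chain makes the MC-error ratio undefined; it is flagged
  degenerate and fails the stability rule explicitly.
* Percent change is undefined from a zero baseline and errors rather than
  returning infinity. Presentation rounding is one decimal (R's
  round-half-even).
* Collinearity and significance filtering is fully deterministic, with
  documented tie-breaks.

## Identifiability of the scaling weights

With four annual periods the shared temporal trend has three free values of
magnitude ~0.1 on the logit scale, so the temporal weights $\gamma^t_k$ are
weakly identified: their posteriors are wide (hence well-calibrated — in the
recovery tests their 95% intervals cover the truth essentially always) but
their point estimates cannot reliably separate weights that differ by
10–20%. The spatial weights are much better identified because the shared
spatial field is large; their medians track the truth closely, and the
extreme weights order correctly essentially always, but adjacent weights
0.1–0.2 apart still swap in a minority of replicates at desk-scale data
quantities. Rank statements about the full weight vector should therefore
be read with the interval widths in view.

## Limitations

* National-scale *model-based* rates and covariate coefficients from the
  original application require the full sub-county extract, which this
  package does not ship; the bundled reference table supports the exact
  arithmetic identities (totals, percent changes, crude rates) only.
* On disconnected adjacency graphs the constraint compensation is exact
  only per component; with several components the shared intercept absorbs
  the average level and per-component levels remain in the fields. Supplying
  a connected graph (or bridging islands in the edge list) is recommended.
* The sampler is single-threaded; the reference 80,000-iteration protocol
  on a 290-area cube takes on the order of an hour. The shortened protocols
  used in the workflow scripts reproduce the structure in minutes.
* No Hamiltonian/NUTS or INLA backends; no non-binomial likelihoods; no
  spatially varying coefficients.
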