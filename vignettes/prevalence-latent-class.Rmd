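---
title: "Estimating prevalence from imperfect diagnostic ascertainment"
author: "prevalca"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating prevalence from imperfect diagnostic ascertainment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prevalca)
```

## Motivation

Disease prevalence estimated by counting coded diagnoses in an
administrative database implicitly assumes the code is a perfect test.
It is not: a diagnostic code detects a true case with sensitivity $S$ and
clears a true non-case with specificity $C$, both below 1. The observed
positivity proportion is then

$$P = \pi S + (1 - \pi)(1 - C),$$

a mixture of detected true cases and false positives, where $\pi$ is the
true prevalence. For rare diseases even small specificity losses dominate:
with $P = 1\%$ and $S = C = 99.5\%$ the inversion

$$\pi = \frac{P + C - 1}{S + C - 1}$$

yields $\pi = 0.5\%$, half the naive estimate. `prevalca` implements this
closed-form correction and the Bayesian latent class machinery needed when
$S$ and $C$ are themselves uncertain or unknown.

## Models

### Closed form (`apparent_prevalence`, `correct_prevalence`)

The inversion above is exact when $S$ and $C$ are known and
$S + C > 1$ (an *informative* test). Two boundary situations need a
policy, which the closed form resolves as follows and which we regard as
numerical choices, not statistics:

* **$S + C = 1$** — the test carries no information about status and the
  estimand is undefined; this is an error, never a clamp.
* **Observed $P$ outside $[1 - C,\, S]$** — possible by sampling noise
  alone. The raw inversion then leaves $[0, 1]$; we clamp to the nearest
  boundary and warn. The Bayesian samplers handle the same situation
  coherently (the posterior simply concentrates near the boundary), and
  they are the recommended route whenever $P$ is near the feasible edge.

No interval accompanies the closed form: uncertainty quantification is
delegated to the Bayesian models.

### Identifiability accounting (`identifiability`)

A two-class latent class model for $k$ conditionally independent binary
tests has $2k + 1$ parameters; the multinomial over $2^k$ response
patterns supplies $2^k - 1$ degrees of freedom. Hence $k = 1$ gives 3
parameters on 1 df (not identifiable), $k = 2$ gives 5 on 3 (still not),
and $k = 3$ gives 7 on 7 — the smallest identifiable design, and the
reason "three independent clues" (a diagnostic code, a
disease-specific medication, a procedure code) is the canonical setup.

### Single-test Bayesian model (`single_test_gibbs`)

With one test the data are a binomial count and the likelihood constrains
only $P = \pi S + (1-\pi)(1-C)$: an entire ridge of $(\pi, S, C)$ values
is observationally equivalent. Prior information on $S$ and $C$ — ideally
beta densities elicited from a validation sub-study comparing the code
against chart review — selects the relevant part of the ridge. The
sampler augments the data with the latent numbers of true cases among
test-positives and among test-negatives; given those counts all three
parameters have conjugate beta full conditionals.

Two behaviors deserve emphasis:

* With flat priors the $\pi$ posterior **remains wide at any sample
  size** (the tests in this package assert width $> 0.5$ at $n = 10^3$
  and $10^5$). More data sharpen $P$, not $\pi$.
* At large $n$ the augmented sampler moves slowly *along* the ridge, so
  independent chains started from dispersed (prior-drawn) points may
  disagree for many iterations. This is reported honestly: R-hat stays
  far above 1 until the chains have traversed the ridge. Summaries from
  several dispersed chains remain a fair picture of the wide posterior;
  a large R-hat here signals the model's non-identifiability rather than
  a bug, and informative priors restore fast mixing.

### k-test latent class model (`lca_gibbs`, `lca_em`, `lca_loglik`)

Given true status, test results are assumed independent (the standard
latent class assumption), so pattern $r$ has probability
$\pi \prod_j p_j(r) + (1-\pi) \prod_j q_j(r)$ with $p_j = S_j$ or
$1 - S_j$ and $q_j = 1 - C_j$ or $C_j$ by the $j$-th bit of $r$. The
Gibbs sampler augments each pattern's count with its latent true-case
count (a binomial draw), after which $\pi$, each $S_j$ and each $C_j$
have conjugate beta updates pooled over patterns.

The likelihood is invariant under the mirror relabeling
$S \to 1 - C$, $C \to 1 - S$, $\pi \to 1 - \pi$. We resolve this label
switching by the epidemiological convention that tests are informative:
every retained draw satisfies $S_j + C_j > 1$, enforced by rejection at
each $(S_j, C_j)$ update. If 1000 consecutive proposals violate the
constraint (essentially impossible away from pathological priors) the
mirrored pair $(1 - C_j, 1 - S_j)$ is substituted; these fallbacks are
counted in `$details$relabel_fallbacks` rather than hidden.

`lca_em` maximizes the same likelihood by EM and serves as the
frequentist cross-check: with flat (`Beta(1,1)`, "minimum information")
priors and identifiable data, posterior means and the MLE agree
numerically — one of the package's acceptance checks at $n = 10^5$
(agreement within $\pm 0.01$ for all seven parameters). Because the
likelihood can be multimodal, EM uses a moment-based start plus five
jittered restarts, keeping the best log-likelihood; the trace is exposed
and is non-decreasing by construction. The EM solution is mapped to the
informative-test labeling by the global mirror transform when the
majority of tests violate the constraint (the global transform is the
only likelihood-invariant relabeling, so on structureless data a
per-test guarantee is not attainable).

### Hierarchical multi-region model (`fit_hierarchical`)

For region-level prevalence mapping, separate fits per region are
unbiased but noisy for small regions; the hierarchical model places

$$\mathrm{logit}(\pi_i) \sim N(\mu, \tau^2)$$

across regions $i$, with $S$ and $C$ shared (the clues are the same
database fields everywhere; `share_sc = FALSE` relaxes this). The
logit-normal population form was chosen because it is the standard
unbounded-scale choice for hierarchical prevalence modeling and suits a
random-walk Metropolis step. Hyperpriors are a diffuse normal
$N(0, 5^2)$ for $\mu$ (effectively flat across plausible prevalences)
and a half-normal with scale 1 for $\tau$ (generous for between-region
spread on the logit scale); both are overridable in `hier_priors`.

The sampler alternates:

1. latent true-case counts per region and pattern (conditional
   binomials);
2. conjugate constrained beta updates for the shared $S_j, C_j$, pooling
   the latent counts across regions;
3. a random-walk Metropolis update of each $\mathrm{logit}(\pi_i)$, step
   sizes auto-tuned during burn-in to an acceptance rate in 0.2–0.5 and
   frozen afterwards (acceptance rates are reported in `$details`);
4. a conjugate normal update for $\mu$ and a random-walk update on
   $\log \tau$ (with Jacobian) under the half-normal prior;
5. a **joint location-shift update** proposing a common increment to all
   $\mathrm{logit}(\pi_i)$ and $\mu$ simultaneously. This step is our
   design addition: without it, per-region moves are confined to a
   $\tau$-neighborhood of $\mu$, and in the complete-pooling limit
   $\tau \to 0$ the sampler freezes wherever it was initialized. With
   it, the $\tau \to 0$ limit demonstrably reproduces the pooled
   single-panel fit, and the well-identified case is unaffected.

`compare_fits` tabulates per-region means, equal-tailed intervals,
interval widths and the shrinkage displacement between the separate and
hierarchical fits — the robustness comparison the two-strategy design
calls for. Expected behavior, asserted in the tests: the hierarchical
interval for the smallest region is no wider than its separate-fit
interval, and its estimate moves toward the population mean.

## Synthetic data (`simulate_panel`, `simulate_regions`)

The generator draws each subject's true status
$\mathrm{Bernoulli}(\pi)$, then each test independently given status —
exactly the conditional-independence structure the estimators assume.
A multinomial shortcut samples the pattern table directly from the cell
probabilities; the two methods are distributionally identical (tested by
a two-sample chi-square) and the individual-level path is the default
only to keep per-subject extensions possible. Multi-region collections
draw region prevalences logit-normally and derive per-region seeds
deterministically (`derive_seed`, an affine map of the master seed and
stream index computed exactly in doubles), so everything is reproducible
from one integer.

What the generator does **not** emulate: claims-stream artifacts
(billing dates, repeated visits, coder behavior), conditional
*dependence* between clues, and covariate structure. A green test
therefore establishes correctness of the estimators *under the model's
own assumptions* — it says nothing about robustness to correlated tests,
which the conditional-independence latent class model is known to be
sensitive to. That caveat applies equally to real analyses with this
model family.

Default simulation operating points in the test suite mirror the
scenarios the models are meant for: a rare condition
($\pi \approx 0.5\%$–10%) screened by an excellent code
($S, C \approx 99.5\%$) for the single-test examples, and a three-clue
panel with $S = (0.9, 0.85, 0.8)$, $C = (0.95, 0.9, 0.97)$, $\pi = 0.1$
for the identifiable designs.

## Numerical and interface choices

* **Pattern order** is fixed package-wide: test 1 is the most
  significant bit, 1 = positive; file formats and `pattern_matrix`
  enforce it.
* **MCMC defaults**: 20000 iterations, 5000 burn-in, 4 chains, no
  thinning; the seed has no default — reproducibility is opt-out-proof.
  Chains initialize from prior draws (dispersed starts).
* **R-hat** is the classic Gelman–Rubin
  $\sqrt{((n-1)/n\,W + B/n)/W}$; for identical chains this equals
  $\sqrt{(n-1)/n}$, i.e. 1 to order $1/n$. One chain reports `NA`
  rather than a fabricated value.
* **Effective sample size** truncates the autocorrelation sum at the
  first negative lag pair (initial positive sequence), per chain, summed
  over chains and capped at the retained draw count.
* **Zero cells** need no continuity correction anywhere: conjugate beta
  updates and the EM weighted proportions handle them natively.
* **Counts files**: CSV (`test_1..test_k`, `count`, optional leading
  `region`) or JSON (pattern-string keys); missing patterns read as
  zeros with a warning since sparse tables are expected at small $n$.
  The CLI config is JSON (no YAML parser is assumed). Machine output is
  proportions to 6 significant digits; percentages appear only in
  human-readable text.

## Limitations

* Conditional dependence between tests (pairwise covariance terms) is
  out of scope; with correlated clues the model underestimates
  uncertainty and can bias $\pi$.
* Two latent classes only; no ordinal or continuous tests.
* No spatial correlation between regions (no CAR/ICAR structure) and no
  covariate regression on prevalence.
* The non-identifiable single-test posterior is exact but its sampler
  mixes slowly along the likelihood ridge at large $n$ under flat
  priors; use informative priors (the realistic use case) or long,
  dispersed multi-chain runs, and read R-hat.
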