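---
title: "Modelling social influence on attractiveness ratings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling social influence on attractiveness ratings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(socinf)
```

## The experiment and the estimand

In a group rating experiment, participants rate stimuli (male faces, male
hands, abstract artwork) on a hidden 0–100 attractiveness slider, are then
shown genuine peer information — the mean rating of all other group
members, of the two highest raters, or of the two lowest — and finally
rate every stimulus again. The question is how far the final rating moves
from the initial rating toward the displayed social rating, and whether
that movement differs between mate-relevant stimuli (faces), other
person-related stimuli (hands) and stimuli unrelated to mate choice
(artwork). Differential movement would be evidence for a domain-specific
mate-choice-copying mechanism; uniform movement points to domain-general
conformity.

The estimand is the *social influence parameter* $s$: a mixing
coefficient between the rater's own initial rating ($s = 0$, no change)
and the peer rating ($s = 1$, full adoption). Values above 1
(over-adjustment) and below 0 (contrariness) are meaningful and are not
excluded by the model.

## The model

Raw ratings $X \in [0, 100]$ are mapped to the open unit interval by

$$Y = (X / 100) \times 0.999 + 0.0005,$$

so every observation lies in $[0.0005, 0.9995]$ and a beta likelihood is
well defined. Writing $I_{ij}$ and $S_{ij}$ for participant $i$'s
transformed initial rating and displayed social rating on trial $j$, with
stimulus condition $c(j)$, the final rating is modelled as

$$Y_{ij} \sim \mathrm{Beta}\big(\mu_{ij}\,\phi,\ (1 - \mu_{ij})\,\phi\big),
\qquad
\mathrm{logit}(\mu_{ij}) = \mathrm{logit}(I_{ij}) +
  s_{ij}\,\big(\mathrm{logit}(S_{ij}) - \mathrm{logit}(I_{ij})\big),$$

$$s_{ij} = \beta_{c(j)} + u_i, \qquad u_i \sim \mathcal{N}(0, \sigma^2_u).$$

The beta distribution is parameterised by its mean $\mu$ and a precision
$\phi$ shared across trials, so the two shape parameters are
$\mu\phi$ and $(1-\mu)\phi$. Priors are $\beta_c \sim \mathcal{N}(0, 1)$,
$\sigma^2_u \sim \mathrm{Exp}(1)$ and $\phi \sim \mathrm{Exp}(1)$.

Two points in this construction were genuinely open and are package
design decisions:

* **Where the interpolation happens.** A beta GLMM with a logit link
  admits two readings of "final ratings as a function of initial ratings,
  social ratings and an influence parameter": interpolation on the
  logit scale (the default, `influence_spec(link = "logit")`) or on the
  raw unit scale (`link = "raw"`, clamped to $[10^{-6}, 1 - 10^{-6}]$).
  The logit placement is the default because it preserves the exact
  endpoint semantics ($s = 0 \Rightarrow \mu = I$,
  $s = 1 \Rightarrow \mu = S$) while keeping $\mu$ strictly inside
  $(0,1)$ for *any* real $s$, so over-adjustment and contrariness need no
  clamping. Both variants are first-class and can be compared as a
  sensitivity analysis.
* **The random-effect prior.** The participant effect is hierarchical:
  $u_i \sim \mathcal{N}(0, \sigma^2_u)$ with an $\mathrm{Exp}(1)$
  hyperprior on the variance. A description that mentions both a normal
  prior for the participant effect and an exponential hyperprior for its
  variance is read here as this conditional-normal law, not as an
  independent fixed-variance prior on each $u_i$.

Two documented variants: `random_effects = "per_condition"` gives each
participant one deviation per condition, $u_{i,c} \sim \mathcal{N}(0,
\sigma^2_c)$, with one $\mathrm{Exp}(1)$-priored variance per condition;
`flat_priors = TRUE` widens the condition-effect priors to variance 100
(the hierarchical variances keep their $\mathrm{Exp}(1)$ priors) for
prior-robustness checks. `random_effects = "none"` drops the hierarchy
entirely; it exists for degenerate designs — for a single participant,
$\beta$ and $u$ are confounded and the reduced model is the one a
brute-force quadrature oracle can integrate exactly.

Trials on which the displayed rating happens to equal the initial rating
carry no information about $s$ (the interpolation path is a point), but
they still inform $\phi$; they are retained.

## Sampling and diagnostics

The posterior is explored with adaptive random-walk
Metropolis-within-Gibbs: one block per condition effect, per participant
deviation, per variance (log scale) and for the precision (log scale).
Proposal step sizes adapt every 50 iterations toward roughly 44%
acceptance *during burn-in only*, so the retained chain is a fixed-kernel
Markov chain satisfying detailed balance. Chains start overdispersed
(condition effects drawn from their prior, perturbed variance and
precision) from independent seed substreams of one master seed; the same
call is bit-reproducible. Defaults mirror the study's budget — 3 chains
of 50,000 iterations, 5,000 burn-in, thinning by 10, i.e. 4,500 kept
draws per chain — and the contract is the posterior, not the algorithm:
any sampler that passes the quadrature oracle and convergence checks
would be conformant.

Convergence is assessed with the original (non-split) Gelman–Rubin
statistic $\hat R = \sqrt{\hat V / W}$ with
$\hat V = \frac{n-1}{n} W + B/n$, plus an F-based upper confidence
limit; a split-half variant was deliberately not substituted, matching
how the statistic is conventionally reported for this design. Information
content is measured by an autocorrelation ESS with initial-positive-
sequence truncation (the autocorrelation sum stops at the first negative
sample autocorrelation), summed across chains; ESS definitions differ
between tools, so the rule is stated here. Posterior summaries are
medians and equal-tailed credible intervals of the draws pooled across
chains, using type-7 quantile interpolation (interval endpoints at two
decimals can shift under other quantile types). Contrasts such as
$\beta_{\text{face}} - \beta_{\text{hand}}$ are computed draw-wise (same
chain, same kept iteration) and summarised identically.

Model fit is checked in-sample: the per-trial posterior mean of
$\mu_{ij}$ — averaging over each participant's *own* $u_i$ draws, i.e.
conditional predictions — is correlated with the observed final rating;
the correlation and its square (pseudo-$R^2$) are both reported because
both conventions circulate.

## What the simulator emulates

`simulate_experiment()` generates the full experiment: groups of 5–10
participants (six groups by default), 30 trials each balanced 10/10/10
across conditions, blocks of 10 or 5 stimuli (two thirds of groups get
the three-blocks-of-10 scheme), every group member rating every
within-group stimulus, and the peer-rating rule drawn i.i.d. per trial
with probabilities 1/3 each — the original procedure says only that the
rule was provided randomly. Final ratings are drawn from the model's own
observation law with known parameters, so recovery can be checked
exactly.

Initial ratings are *not* described by the study; the simulator's law is
a modelling choice. On the logit scale, an image-quality effect
$q_{\mathrm{img}} \sim \mathcal{N}(0, 0.7^2)$ shared by all raters of an
image is added to rater noise $\mathcal{N}(0, 1)$; the shared component
induces realistic between-rater agreement, which is what makes the
top-two/bottom-two rules produce genuinely different social information
(their purpose in the design). Real-valued ratings are kept (a mean of
two sliders is generally fractional); simulated values are mapped back
through the inverse transform and clamped to $[0, 100]$, which only
affects values beyond the slider's range.

Default generative parameters are the study's operating point:
$\beta = (0.13, 0.13, 0.14)$ for face/hand/art, $\sigma^2_u = 0.06$. The
precision is not a reported quantity; $\phi = 30$ was fixed once because
it yields mid-scale rating noise of roughly 4–5 slider points and an
in-sample predicted–observed correlation near 0.9, the regime the study
reports. Orientation scores are drawn with ~86% of mass on 0–1 so that
the default inclusion filter (score ≤ 1, "exclusively or
near-exclusively heterosexual"; the all-participants variant is one
argument away) retains about the observed 42-of-49 fraction.

What passing recovery tests on these data do **not** show: robustness to
misspecified initial-rating laws, to raters who round to multiples of 5
or 10, to memory decay between blocks, or to non-beta outcome noise. The
simulator reproduces the design, not human behaviour.

## Numerical choices

* Transformation constants (0.999, 0.0005) are named constants; the
  transform rejects out-of-range input naming the offending value, and
  the inverse composes with it to identity within $10^{-9}$.
* Under the raw-scale link, $\mu$ is clamped to
  $[10^{-6}, 1 - 10^{-6}]$; under the logit link no clamping is needed.
  Inside the compiled likelihood $\mu$ is guarded at $10^{-12}$ so
  extreme proposals return $-\infty$ and are rejected rather than
  producing NaN.
* Proposals that would make $\phi \le 0$ or $\sigma^2_u \le 0$ cannot
  occur (both are updated on the log scale); the reference
  `influence_logprior()` returns $-\infty$ for such states instead of
  erroring.
* Constant chains make the autocorrelation undefined; ESS is then
  reported as the total draw count with a warning. Identical non-constant
  chains give the degenerate $\hat R = \sqrt{(n-1)/n} < 1$.
* A recovery replicate whose core parameters show $\hat R \ge 1.1$ is
  excluded from the recovery report with a message, so bias and coverage
  summarise converged fits only.

## Problem sizes used by the tests

The test suite validates the sampler against a 400×400 grid quadrature on
a three-trial toy (posterior means agree within 0.02), and runs a
20-replicate recovery study at the study's scale (42 participants × 30
trials) with a reduced desk-scale budget of 3 chains × 5,000 iterations,
1,000 burn-in, thinning by 5 — chosen as the package's standard quick
budget; the study-scale budget (3 × 50,000 / 5,000 / 10) remains the
documented replication preset in `replicate_study()`. At the reduced
budget, condition-effect bias stays below 0.03 and 95%-interval coverage
at or above 90%.

## Limitations

* The common level of the condition effects trades off against the mean
  of the 42 participant deviations (identified only through the
  $\mathcal{N}(0, \sigma^2_u)$ shrinkage), so single-dataset estimates of
  all three $\beta_c$ share a small correlated offset of order
  $\sigma_u / \sqrt{n_{\text{participants}}}$; contrasts between
  conditions are free of it.
* Random-walk sampling mixes slowly in that same direction; effective
  sample sizes for $\beta_c$ are accordingly the smallest of all
  parameters and should be checked before trusting interval endpoints.
* The model conditions on initial and social ratings; it does not model
  response times, block-order memory effects, or dropout, and no model
  comparison (WAIC/LOO) is provided.
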