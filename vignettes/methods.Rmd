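---
title: "Methods: policy interrupted time series and the reproducibility audit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: policy interrupted time series and the reproducibility audit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(odpeval)
```

`odpeval` packages the statistical machinery of a two-part meta-research
evaluation: the effect of a mandatory journal open-data policy on
article-level outcomes, and an audit of whether published statistics can be
recomputed from the shared data. This vignette is the package's own account
of the models, the choices that were genuinely open, and what the synthetic
validation does and does not establish.

## The segmented logistic interrupted time series

The unit of analysis is the article. For a binary outcome $Y$ (presence of
a data-available statement, or in-principle reusability of the shared
data) the model is

$$\operatorname{logit} P(Y=1) = \beta_0 + \beta_1\,\mathrm{time} +
\beta_2\,\mathrm{post} + \beta_3\,\mathrm{time}\times\mathrm{post},$$

with `time` the submission date in units of 50 days relative to the policy
date (negative before it) and `post` the indicator of submission on or
after the policy date. An article submitted exactly on the policy date is
post-policy with `time = 0`: the policy applies from that day. The model
is equivalent to separate linear-on-logit trajectories in the two periods,
meeting the interrupted-time-series logic: $\exp(\beta_2)$ is the odds
ratio of the discontinuity ("level change") at implementation,
$\exp(\beta_1)$ the pre-policy secular trend per 50 days, and
$\exp(\beta_1+\beta_3)$ the post-policy trend. The causal reading assumes
articles submitted just before and just after the boundary are comparable
and that no co-intervention coincides with the policy; the model itself is
an ordinary logistic GLM and is estimated by iteratively reweighted least
squares (deviance tolerance $10^{-10}$, at most 100 iterations), with the
coefficient covariance from the inverse observed information. Designs in
which either period lacks one of the two outcome classes, and fits whose
probabilities collapse numerically to 0 or 1, are rejected with an
explicit separation error rather than returned.

## Risk ratios, anchors, and the trend decomposition

Since the outcomes are common, odds ratios overstate probability ratios.
Effects are therefore reported on the risk-ratio scale via the Zhang–Yu
conversion $RR = OR / ((1-P_0) + P_0\,OR)$, which is exact for a logistic
model in the sense that it reproduces the ratio of model probabilities at
the anchor probability $P_0$. The anchors are a modelling choice the data
cannot fix, and we use the most local reading of each contrast:

* **level change** — anchored at $\operatorname{expit}(\beta_0)$, the model
  probability immediately before implementation;
* **pre-policy trend** — the same anchor;
* **post-policy trend** — anchored at
  $\operatorname{expit}(\beta_0+\beta_2)$, the probability immediately
  after implementation;
* **slope ratio** — the ratio of the converted post- and pre-trend risk
  ratios (its Wald p-value is the test of $\beta_3$).

`estimate_effects()` exposes the anchors as an argument so other
conventions can be swapped in. Confidence intervals are delta-method
intervals on the log-RR scale, using analytic gradients of
$\log RR(\beta)$, then exponentiated.

The *decomposition* answers "of the combined 50-day improvement after the
policy, how much is baseline trend, how much policy, how much their
interaction?". We treat one post-policy time unit as joint exposure to one
50-day interval and to the policy, map the three odds ratios
$e^{\beta_1}, e^{\beta_2}, e^{\beta_1+\beta_2+\beta_3}$ to risk ratios by
the square-root approximation $RR \approx \sqrt{OR}$ (appropriate at these
outcome prevalences, and self-consistent across the three terms), and
attribute the excess relative risk additively:

$$\mathrm{share}_{time} = \frac{RR_{10}-1}{RR_{11}-1},\quad
\mathrm{share}_{policy} = \frac{RR_{01}-1}{RR_{11}-1},\quad
\mathrm{share}_{int} = \frac{RR_{11}-RR_{10}-RR_{01}+1}{RR_{11}-1},$$

the last being the relative excess risk due to interaction (RERI) scaled
by the joint excess. The three shares sum to one by construction; the
decomposition is declined (an error, never a silent `NA`) when the joint
risk ratio does not exceed 1, since "shares of an improvement" is then
meaningless. Standard errors flow through the full chain
$\beta \mapsto$ shares with an analytic Jacobian; the unit tests verify
the Jacobian against central differences at $10^{-6}$. Following the
evaluation design, the decomposition's p-values are one-sided tests of
each share being zero, while all other inference is two-sided Wald.
Share confidence intervals are formed on the natural scale; the two
structurally non-negative shares are truncated to $[0,1]$ only in printed
output, never in the stored object.

## Proportion machinery

Binomial proportions get Wilson score intervals *with* continuity
correction in Newcombe's closed form; the bound hitting $x=0$ or $x=n$ is
pinned to the boundary. The 2×2 test is the plain Pearson χ² without the
Yates correction — the corrected statistic would not reproduce the
published values of the statistics this package is designed to recompute,
and the uncorrected statistic equals the squared pooled two-proportion
z-statistic, which the tests exploit as an algebraic oracle.

The three-category article outcomes need *simultaneous* multinomial
intervals, for which we implement the Sison–Glaz construction: all cells
share the half-widths $c/n$ (below) and $c/n + 2\gamma/n$ (above), where
$c$ is the smallest integer whose approximate simultaneous coverage
$\nu(c)$ satisfies $\nu(c) < 1-\alpha \le \nu(c+1)$ and
$\gamma \in [0,1)$ interpolates linearly between $\nu(c)$ and $\nu(c+1)$.
$\nu(c)$ is the conditional probability that independent truncated
Poisson($x_i$) counts all stay within $\pm c$ of $x_i$ given their sum,
evaluated with a second-order Edgeworth expansion of the conditioning
density from the truncated factorial moments. Two numerical details are
worth recording: $\nu(0)$ is computed exactly (the truncated variables are
degenerate, so no expansion is needed), and a tie $\nu(c) = 1-\alpha$
resolves to that $c$ with $\gamma = 0$. Because the upper widths carry the
fractional adjustment $2\gamma/n$, the intervals of equal counts are
identical but *not* mirror images about their midpoint — an asymmetry
inherent to the construction. The test suite checks the calibration two
independent ways: against published interval bounds, and by exhaustive
enumeration of all multinomial outcomes at $k=3, n=35$ and $k=4, n=20$,
where the exact simultaneous coverage of the nominal 95% procedure must
fall in $[0.90, 0.99]$.

## The audit engine

The reproducibility audit compares each re-obtained value with the value
*as printed*. The percentage error is
$PE = |obtained - reported| / |reported| \times 100$, with two deliberate
conventions. First, the obtained value is rounded to the reported value's
printed precision before the comparison, so agreement at printed precision
is exactly $PE = 0$; this prevents floating-point tails from manufacturing
spurious minor errors, and it is why the audit table stores the reported
value as a string (`parse_reported()` recovers value, decimals and any
inequality prefix). Second, the denominator is $|reported|$ so that
negative effect sizes produce positive PE. A reported value of exactly
zero cannot support a relative error: if the obtained value also rounds to
zero the pair is a match, otherwise the case is flagged (PE of `Inf`) and
classified as a major error.

Classification: insufficient-information flags dominate; otherwise
$PE = 0$ is a match, $0 < PE < 10$ minor, $PE \ge 10$ major — the
boundary itself is major. For p-values a *decision error* (reported and
obtained on opposite sides of 0.05, with sides defined as $p \le 0.05$
versus $p > 0.05$, so equality at the boundary on both sides is no
decision error) takes precedence over the numerical classes, but the
PE-based class is retained in a separate column so value-type tallies can
still count p-value numerical errors. A value that matches at printed
precision is never a decision error. Inequality-form reported values such
as `<0.001` contribute no numeric PE: they match when the obtained value
satisfies the bound; a failed bound is judged by the decision rule when
the sides of 0.05 differ, and is otherwise a major numerical error (the
reanalysis contradicts the printed bound) — the underlying convention is
not recoverable from the audit design itself, so we fixed this reading
once and document it here.

Article outcomes evaluate the final stage (after author assistance when it
was requested, else before): any remaining blocking error (major, decision
or insufficient) makes the article not fully reproducible; only
minors/matches make it reproducible, qualified by whether assistance was
needed to reach that state. The classification is monotone: adding a
blocking value can never improve an article's outcome, which the suite
tests directly.

## The synthetic generators

The corpus generator emulates the study conditions the pipeline was built
for: 591 articles, submission days uniform over $[-1915, 523]$ around the
policy date, outcome drawn from the segmented logistic model, and a
conditional cascade accessibility → completeness → understandability for
statement-bearing articles. Its default coefficients are obtained by
inverting the effect transformations (`beta_for_rr_targets()`) so that the
implied pre-trend, level-change and slope-ratio risk ratios are 1.04, 1.53
and 1.14 — the effect scale the pipeline is meant to detect — from a
baseline probability of 0.35 at the policy date, a value consistent with a
pre-policy statement rate near 25% that is already rising towards the
boundary. The cascade defaults (0.97, 0.70, 0.66) put in-principle
reusability near 45% of statement-bearing articles overall, between the
pre- and post-period rates observed in practice. These defaults are the
study conditions, fixed once; they are not tuning knobs. A single root
seed feeds named sub-streams (dates, outcomes, cascade, extras) through
`sub_seed()`, so adding a stream never perturbs the others and a fixed
seed yields a byte-identical CSV.

Uniform dates are a simplification: a real corpus's submission intensity
drifts, and the pre/post article split here follows the date-range ratio
rather than being fixed at 417/174. The generator also draws one global
cascade-probability set, while real pre/post periods differ; the
deterministic `corpus_from_margins()` covers that case by constructing a
table whose per-period margins (417/104/23 and 174/136/85, two
inaccessible datasets per period) are exact, which is what the count-based
statistics need. Consequently, passing tests demonstrate correct
*machinery* — estimation, conversion, classification, tallying — not that
any particular real corpus follows this generating process.

The audit generator injects labelled errors at configured rates, realising
each label with fixed multipliers chosen to land unambiguously inside the
intended PE band after printed-precision rounding (minor ×1.03, major
×1.25, decision 0.04 → 0.06; p-value minors draw reported values of at
least 0.20 so the perturbation survives two-decimal rounding). Author
assistance resolves each blocking error independently with the configured
probability. `audit_fixture_paper_margins()` instead constructs the
margins deterministically — 1324 values over 35 articles; final errors 64
major (with the 17/17/10/8/4/4/1/1/2 value-type breakdown), 146 minor, 2
insufficient, 0 decision; outcomes 11/11/13; 57 issues with 33 resolved —
so pipeline tests can demand exact recovery rather than distributional
agreement.

## Validation problem sizes

The test suite fixes its simulation sizes as part of the package's design:
parameter recovery runs 500 corpora of 591 articles at the default
coefficients (median recovered risk ratios within 10% of truth; 95% CI
coverage within $[0.90, 0.98]$), a tighter 3%-band check uses 120 corpora
of 5000 articles, the fit itself is verified against an independent
BFGS maximum-likelihood oracle to $10^{-6}$ on fixed small designs, the
Zhang–Yu conversion is checked as an exact algebraic identity on $10^4$
random draws at $10^{-12}$, and the Sison–Glaz coverage enumerations use
$k=3, n=35$ and $k=4, n=20$.

## Known limitations

* The anchor probabilities and the slope-ratio construction are
  conventions; other defensible choices shift the converted risk ratios
  slightly (the odds-ratio scale is unaffected). They are exposed as
  arguments rather than hidden.
* The decomposition inherits the $\sqrt{OR}$ approximation; at outcome
  probabilities far from the common-outcome regime its shares drift from
  the Zhang–Yu-converted effects.
* Wald inference throughout: no profile likelihood, no autocorrelation
  adjustment (articles are treated as independent given submission date),
  and no Poisson/robust ITS variants.
* The audit engine classifies; it does not re-run any original analysis,
  parse statistics out of documents, or judge whether non-reproducibility
  affects substantive conclusions.
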