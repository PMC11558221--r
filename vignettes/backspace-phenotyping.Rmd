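---
title: "Backspace-rate digital phenotyping: models and methods"
author: "keymix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Backspace-rate digital phenotyping: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(keymix)
```

`keymix` turns raw smartphone keystroke metadata into discrete digital
phenotypes of mood and relates them to clinical symptom measures. This
vignette is the package's own account of the science: the models, their
assumptions, the tunable parameters, the synthetic data generator, and the
numerical choices that required a decision.

## 1. From keypresses to daily backspace rates

The keyboard logger records, for every keypress, a UTC timestamp, the IANA
timezone the user was in, and a category (alphanumeric, backspace,
autocorrection, punctuation, autosuggestion, special) — never content. Two
processing rules matter:

* **Sessions** end after 6 seconds of keyboard inactivity. A gap of exactly
  6 s stays within a session (`segment_sessions(gap_seconds = 6)`); the rule
  is "after 6 seconds", so the boundary is inclusive.
* **Days** are bounded at local midnight in the *recorded timezone*, not
  UTC. Typing is diurnal; bucketing by the calendar day the user actually
  experienced prevents an evening of typing in Chicago from being split
  across two UTC days.

The daily backspace rate is backspaces divided by *all* keypresses that day,
backspaces included in the denominator. All six categories count toward the
denominator by default; `aggregate_daily(denominator = ...)` makes this
configurable because one could argue autocorrection events are not
finger-presses. Days below `min_keypresses` (default 1) are dropped rather
than emitted as 0/0.

## 2. The bounded Gaussian mixture

Rates live in (0, 1) and cluster into bands. The model is a K-component,
equal-variance normal mixture truncated to the unit interval, with the
latent class at the **subject** level:

$$y_{ij} \mid z_i = k \sim \mathrm{TN}(\mu_k, \sigma^2;\, 0, 1), \qquad
  z_i \sim \mathrm{Cat}(\pi), \qquad i = 1..n,\; j = 1..n_i.$$

All days of a subject share one class; days are conditionally iid given it.
This matches the scientific object of interest — a *person-level* phenotype
— and respects the nesting of ~2900 daily observations in ~128 subjects.
`bgmm(mixing = "observation")` switches to day-level mixing for sensitivity
analysis; it treats each day as its own unit and is not the default because
it would let one subject occupy several phenotypes simultaneously.

A single shared $\sigma$ is deliberate: the phenotype bands are close
together on the rate scale, and unequal variances in 1-D mixtures invite
degenerate spikes on single subjects.

### Priors

Conjugate and effectively noninformative: $\mu_k \sim N(0.5, 10)$ restricted
jointly to the ordered region $0 < \mu_1 < \dots < \mu_K < 1$ (over the unit
interval this is essentially a flat ordered prior), $\sigma^2 \sim
\mathrm{InvGamma}(0.001, 0.001)$, $\pi \sim \mathrm{Dirichlet}(1)$. The
ordering constraint does two jobs: it resolves the label-switching symmetry
inside the sampler, and — more importantly for model comparison — it pins a
component that currently holds no subjects between its neighbours. Without
it, an empty component performs a random walk over the diffuse prior, and
sorting the draws afterwards scrambles posterior means, modal class counts
and the plug-in deviance for every component. `relabel_draws()` (ascending
means, weights and class indicators permuted consistently) is still applied
defensively before all summaries, and is the correct tool for draws produced
outside the constrained sampler.

### Sampling

`bgmm()` runs, per chain, a Gibbs sweep: classes $z_i$ from their exact
discrete conditional (computed from per-subject sufficient statistics with a
log-sum-exp shift), weights from the conjugate Dirichlet, and $\mu_k$ and
$\log\sigma^2$ by **slice sampling their exact full conditionals**. With the
(0, 1) truncation the conjugate kernels acquire a normalizer correction
$C(\mu_k,\sigma)^{-n_k}$, $C = \Phi((1-\mu)/\sigma) - \Phi(-\mu/\sigma)$;
at ~3000 observations this factor is far from negligible, and a Metropolis
step that proposes from the *uncorrected* conjugate conditional can freeze
for astronomically many iterations once the chain sits outside the
proposal's effective support. Slice sampling (stepping-out with shrinkage)
targets the corrected conditional exactly and needs no tuning. With
`truncation = FALSE` the updates reduce to pure conjugate Gibbs.

Defaults follow the study protocol: 5000 burn-in iterations, then 2 chains
of 10,000 retained iterations. Chains start from jittered data quantiles
(means) and the pooled within-subject SD (sigma). Convergence is monitored
with split-$\widehat R$ on all parameters; anything above 1.05 triggers a
warning and marks the fit non-converged. Identical seed and configuration
reproduce draws bit for bit. Rates lying exactly on 0 or 1 are clamped to
$(\varepsilon, 1-\varepsilon)$, $\varepsilon = 10^{-6}$, with a warning.

### DIC

`dic()` reports $\mathrm{DIC} = \bar D + p_D$ with $\bar D$ the posterior
mean deviance of the subject-level marginal likelihood and $p_D = \bar D -
D(\hat\theta)$, $\hat\theta$ the posterior mean of the relabeled parameters.
For continuous densities the deviance, and hence the DIC, is negative; lower
is better. One numerical safeguard is essential in mixtures: when K exceeds
the number of clusters the data support, the posterior alternates between
different ways of splitting a cluster, the averaged parameters fit nothing,
and the posterior-mean plug-in produces $p_D < 0$ — an impossible effective
parameter count. In that event `dic()` switches the plug-in to the posterior
mode (the highest-likelihood draw), which lower-bounds the deviance and
guarantees $p_D \ge 0$; the `plug_in` field records the switch and `pD_mean`
always carries the raw value. Without this safeguard an overfitted K "wins"
the DIC comparison by arbitrary margins purely through the artifact.

## 3. Choosing the number of phenotypes

`select_model()` encodes the study's dual criterion over K = 2..4:

1. **Class size.** Any model whose smallest modal class holds fewer than 5
   subjects is excluded — too small to be clinically interpretable.
2. **External validity.** Among the survivors, models whose modal classes
   associate with the clinical diagnoses (Pearson chi-square on the
   class-by-diagnosis table, no continuity correction, $p < .05$) are
   preferred: if any candidate is externally valid, the choice is restricted
   to those.
3. **Internal fit.** The lowest DIC wins, except that candidates within 2
   DIC units are treated as tied and resolved toward the smaller K
   (parsimony).

One design decision was genuinely open: what to do when *no* size-passing
candidate reaches external significance. At n = 128 the chi-square test has
limited power (about 0.76 at the effect size the default generator encodes),
so this situation is a routine sampling outcome, not a pathology. We fall
back to internal fit alone and record an audit note — external validity
adjudicates between otherwise acceptable models rather than vetoing all of
them. Every rejected K carries its explicit reason in the report.

## 4. Phenotype scoring

Two rules, for two uses:

* **Cohort assignment** (`assign_subjects()`): each fitted subject takes the
  class with the highest MCMC posterior probability; ties go to the lower
  class. Labels are Low / Medium / High for K = 3.
* **Single-rate scoring** (`class_density_scores()`): a practitioner holding
  only the published parameters scores a new rate $r$ by the plain normal
  densities $f(r \mid \mu_k, \sigma)$ — *unweighted* and *untruncated* by
  default. With means (0.112, 0.180, 0.268) and SD 0.048, $r = 0.14$ scores
  (7.01, 5.87, 0.24), normalized (0.53, 0.45, 0.02): label Low, with Medium
  nearly as compatible. Flags `use_weights` and `use_truncation` switch on
  the statistically conventional alternatives; with weights, the normalized
  scores are exactly the single-observation posterior class probabilities.

The unweighted default is the practitioner-facing convention this package
reproduces; the weighted variant answers a different question ("what class
is this person from, given the population mix") and down-weights rare
classes like High.

## 5. Association models

* `lmm_group_test()`: rate ~ group with a random intercept per subject,
  maximum likelihood, Wald test. A singular random-intercept fit falls back
  to OLS with subject-clustered robust standard errors, flagged.
* `severity_regression()`: OLS of HAM-D totals on phenotype (Low reference),
  optionally adjusting for medication and diagnosis.
* `hurdle_gamma()`: YMRS totals are mostly zero and right-skewed when
  positive. A "zero-inflated gamma" with a latent always-zero class is not
  identifiable because a gamma density has no atom at zero, so the
  likelihood factorizes exactly into a logistic model for $P(Y > 0)$ and a
  gamma GLM (log link) on the positives — implemented as such, with the
  decomposition asserted in the tests. Totals are treated as continuous in
  the gamma part despite being integer-scored.
* `ordinal_item_model()`: proportional-odds (cumulative logit) regression of
  one symptom item on phenotype, odds ratios with Wald 95% CIs. Binary items
  are fitted by logistic regression, which is the one-threshold special
  case. **Structural zeros** — a phenotype group showing a single observed
  category — make the group's effect inestimable; the model is marked
  non-convergent, the group is dropped, the model refit on the remainder,
  and the note recorded. This mirrors how the degenerate item models were
  handled in the source analyses. `symptom_item_scan()` runs all items of a
  scale; no multiple-testing correction is applied by default (none was in
  the source), with a Benjamini–Hochberg option.

Wald inference (z statistics, $\exp(b \pm 1.96\,\mathrm{SE})$ intervals) is
used throughout, matching the reporting style of the tables this pipeline
emulates.

## 6. The synthetic cohort generator

`generate_cohort(cohort_config())` draws cohorts with the study's structure;
its defaults *are* the study conditions and are not tuned per analysis:

| quantity | default | source of the value |
|---|---|---|
| subjects | 27 HC + 87 unipolar + 14 bipolar = 128 | participant counts |
| class given diagnosis | HC (13,14,0)/27; unipolar (27,54,6)/87; bipolar (7,4,3)/14 | published class-by-diagnosis counts |
| mixture truth | means 0.112/0.180/0.268, shared SD 0.048 | fitted mixture |
| days per subject | Poisson(23), min 1 | ~2948 subject-days / 128 |
| keypresses per day | Poisson(500), min 20 | a realistic daily typing volume (only the rate's granularity depends on it) |
| medication | P(yes) = .222 (HC) / .594 (MD) | sample characteristics |
| depression truth | intercept 4.5, b(Medium) = 2.32, b(High) = 0.5, SD 4.5 | reported Medium effect; intercept/SD set so MD totals average ≈ 7, near the reported sample mean |
| mania hurdle truth | logit: intercept logit(0.25), b(Medium) 0.5, b(High) 1.91; log: intercept log(1.5), b(Medium) 0.79, b(High) 1.46, shape 1.5 | reported hurdle effects; intercepts set for a mostly-zero outcome with plausible positive means |
| item truths | per-item ORs incl. middle insomnia OR(High) 6.82; structural-zero patterns for guilt, suicide, weight loss, hypochondriasis, insight, and the degenerate YMRS items | published item tables and their non-convergence notes |

Daily rates are drawn from the truncated normal via the inverse CDF (checked
against a rejection sampler by a Kolmogorov–Smirnov test), then converted to
counts: $n_b = \mathrm{round}(r \cdot n_{\text{key}})$, rate $= n_b /
n_{\text{key}}$, so every emitted record satisfies the count invariants
exactly at the cost of a rounding granularity of ~0.002.

Totals and items are generated from *separate* truths: HAM-D/YMRS totals
come from the severity and hurdle models directly (so regression recovery is
exactly calibrated), while item scores come from their own proportional-odds
truths. Synthetic totals therefore do not equal the item sums — a deliberate
trade of internal consistency for calibration transparency; for real data,
`read_clinical()` computes totals as item sums.

`generate_keystroke_events()` inverts `aggregate_daily()`: integer-second
gaps of 0–2 s within sessions and 8–30 s between sessions, all events inside
one local day starting at 09:00, exactly the recorded number of backspaces.
The round trip reproduces the daily table exactly and the generator's own
session bookkeeping is recovered by `segment_sessions()`.

**What the generator does not emulate** — and hence what passing tests do
not certify about real data: circadian and weekday usage patterns,
within-subject drift of the backspace rate over the study month,
missing-not-at-random adherence, between-subject variance within a phenotype
class (all subjects of a class share one mean), correlation between symptom
items beyond their common phenotype, and any dependence of typing volume on
mood. Two printed summaries are knowingly in tension in the source and in
the generator: the class percentages (37.5/54.4/8.1) versus the integer
counts (47/72/9 of 128), and the within-class SD (0.048) versus the overall
daily SD (0.062), which the class spread implies should be ≈ 0.066. The
generator follows the counts and the class means/SD; the implied overall SD
lands near 0.066.

## 7. Problem sizes used by the tests

The test-suite fits are sized to verify properties, not to squeeze MCMC
precision: mixture unit tests use a few hundred iterations; replicated
recovery and selection studies use cohorts at the full study size (128
subjects, ~23 days) with 300 burn-in / 600 retained draws per chain, which
this sampler mixes well within (split-$\widehat R$ ≈ 1.00); one acceptance
fit runs the full 5000/10,000 × 2 protocol. Replicated properties use 20–60
seeded replicates; 60 where a ≥90% hit-rate bound needs its binomial noise
kept small.

## 8. Known limitations

* The plug-in DIC, even with the mode fallback, remains a rough instrument
  for mixtures; the class-size rule, not the DIC, is what reliably rejects
  an overfitted K on 3-class data.
* With 9 expected High-class subjects, a sizeable minority of cohorts
  legitimately produce a High class below the 5-subject minimum, or an
  external chi-square above .05 (power ≈ 0.76); selection then falls to K=2
  or reports no externally valid model. This is a property of the design
  size, not of the estimator.
* Item-level models at n = 128 with a 9-subject group yield wide CIs and
  occasionally separate; the structural-zero protocol catches the extreme
  cases, Wald CIs remain approximate in the rest.
* The sampler is pure R; a full-budget 3-class fit on ~3000 observations
  takes on the order of a minute of CPU.
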