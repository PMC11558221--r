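# keymix

Digital phenotyping of mood disorders from smartphone backspace rates.

Passively sensed keystroke metadata — the timing and category of every
keypress, never the typed content — carry a surprisingly informative signal
about mood. One of the simplest features is the **daily backspace rate**: the
number of backspace presses divided by all keypresses on a local calendar
day, a proxy for error correction and possibly ruminative typing. `keymix`
implements a complete analysis pipeline for deriving discrete *digital
phenotypes* from this single feature and relating them to clinical symptoms
of depression (HAM-D) and mania (YMRS):

1. **Keystroke processing** — read raw keypress event tables, segment typing
   sessions at 6 seconds of inactivity, and aggregate to per-subject daily
   backspace rates (`read_keystroke_events()`, `segment_sessions()`,
   `aggregate_daily()`).
2. **Bounded Gaussian mixture** — fit a K-component, equal-variance normal
   mixture truncated to (0, 1) by Gibbs sampling with subject-level latent
   classes (`bgmm()`). For daily rates `y_ij` of subject `i`:

   ```
   y_ij | z_i = k ~ TN(mu_k, sigma^2; 0, 1),   z_i ~ Categorical(pi),
   pi ~ Dirichlet(alpha),  mu ~ ordered N(m0, s0^2) on (0,1),
   sigma^2 ~ InvGamma(a0, b0)
   ```

   with noninformative defaults, 5000 burn-in and 2 chains of 10,000
   retained iterations, split-R-hat convergence monitoring and the deviance
   information criterion (`dic()`).
3. **Model selection** — choose K by combining the DIC, a minimum class size
   of 5 subjects, and a chi-square test of external validity against the
   HC / unipolar / bipolar diagnoses (`select_model()`, `pearson_chisq()`).
4. **Phenotyping** — label subjects Low / Medium / High from posterior class
   probabilities (`assign_subjects()`), and score any single observed rate
   against the fitted components with plain normal densities
   (`class_density_scores()`), the rule a practitioner can apply with just
   the published parameter estimates.
5. **Association models** — linear mixed model for the HC-vs-MD group
   contrast on the continuous rates (`lmm_group_test()`), linear severity
   regression for depression totals (`severity_regression()`), a hurdle
   gamma model for zero-inflated mania totals (`hurdle_gamma()`), and
   proportional-odds models per symptom item with structural-zero handling
   (`ordinal_item_model()`, `symptom_item_scan()`).
6. **Synthetic cohorts** — `generate_cohort()` draws full cohorts (daily
   rates, diagnoses, medication, item-level symptom scores) under the study
   conditions so the entire pipeline is testable end to end, and
   `generate_keystroke_events()` expands daily rates back into raw keypress
   logs that aggregate to the same table exactly.

## Worked example

```r
library(keymix)

coh <- generate_cohort(cohort_config(), seed = 2)
fit <- bgmm(coh$daily, K = 3, n_burn = 1000, n_iter = 2000, seed = 3)
fit
#> Bounded Gaussian mixture (3 components, subject-level classes)
#>   2994 daily rates from 128 units; 2 chain(s) x 2000 retained draws
#>              Low Medium   High
#> mean       0.114  0.180  0.270
#> weight     0.321  0.565  0.114
#> n (modal) 41.000 73.000 14.000
#> Shared sigma: 0.0479   DIC: -9524.533
#> Max split R-hat: 1.001 (converged)
```

The three phenotypes sit at backspace rates of roughly 0.11, 0.18 and 0.27
with a shared SD near 0.048; about half the cohort types in the Medium
band. A clinician handed a new patient's rate of 0.14 can score it against
the fitted components directly:

```r
class_density_scores(0.14, means = c(0.112, 0.180, 0.268), sigma = 0.048)
#> Phenotype density scores
#>               Low Medium High
#> unnormalized 7.01   5.87 0.24
#> normalized   0.53   0.45 0.02
#> Label: Low
```

The unnormalized numbers are the normal densities of the observed rate
under each class; after dividing by their sum they read as a soft
classification — this rate is most compatible with the Low phenotype but
the Medium class remains nearly as likely, which a hard cutoff would hide.

Downstream, the phenotype labels carry clinical signal:

```r
asg <- assign_subjects(fit)
severity_regression(coh$clinical, asg)
#> severity regression: hamd_total ~ phenotype
#>         term estimate    se    z      p
#>  labelMedium     1.85 0.844 2.19 0.0284
#>    labelHigh     1.59 1.340 1.19 0.2360
```

Medium-phenotype subjects score about 1.9 HAM-D points above Low ones in
this synthetic cohort (generated with a true effect of 2.32 and residual
SD 4.5, so a single replicate lands within sampling error of the truth),
while the High phenotype is not associated with depression severity — but is with
mania (see `hurdle_gamma()` and the vignette).

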