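---
title: "Divisive normalization models of single-trial visuomotor learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Divisive normalization models of single-trial visuomotor learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divnorm)
```

## The problem

When a reaching movement is accompanied by rotated visual feedback, the next
movement shifts against the imposed error: a single-trial learning response
(aftereffect), measurable as a lateral force impulse against a force channel.
Two families of models explain how this response depends on the visual error
— and in particular how it degrades when the feedback is uncertain (several
cursors at once, or a cloud of cursors drawn from a distribution):

* a **divisive-normalization (DN) population model**, in which each cursor
  drives direction-tuned units and the pooled squared activity normalizes the
  integrated output; and
* a **maximum-likelihood (MLE) cue-combination model**, in which the observed
  error is shrunk toward the predicted (zero) error according to the relative
  reliabilities of observation and prediction.

`divnorm` implements both, fits them to condition-mean responses, and
reproduces the fit-then-predict workflow in which parameters identified on
single-cursor conditions are used, unchanged, to predict multi-cursor and
cursor-cloud conditions.

## The DN model

A bank of `M` units has preferred directions $\varphi_j$ tiling
$[-180^\circ, 180^\circ]$ with tuning width $s$ (degrees). For a set of
cursor errors $\mathbf{e} = (e_1, \dots, e_N)$ each unit responds to the
nearest cursor only (max operation):

$$f_j(\mathbf{e}) = \max_i \exp\!\left(-\frac{(e_i - \varphi_j)^2}{2s^2}\right),
\qquad x_j(\mathbf{e}) = w\,\varphi_j f_j(\mathbf{e}),$$

and the compensatory command is integrated under divisive normalization:

$$X(\mathbf{e}) = \frac{\sum_j x_j(\mathbf{e})}{kM + \sum_j x_j^2(\mathbf{e})}.$$

For a single cursor the sums have closed forms
(`analytic_single()`, `linear_response_single()`):

$$X(e) = \frac{2\sqrt{2\pi}\,w s e}{720k + \sqrt{\pi}\,w^2 s (s^2 + 2e^2)},
\qquad X_{\text{no-DN}}(e) = \frac{\sqrt{2\pi}\,w s}{360 k}\,e.$$

The quadratic error term in the denominator produces saturation with a peak
at $e^* = \sqrt{(720k + \sqrt{\pi} w^2 s^3)/(2\sqrt{\pi} w^2 s)}$
(`analytic_peak()`), and the ratio $w^2/k$ (`nonlinearity_index()`)
summarizes how strongly normalization bends the response: learning responses
show values near 0.36, within-trial feedback responses near 0.0018 — a
difference of more than two orders of magnitude for the same participants.

Two structural properties matter more than any fitted number. Because of the
max operation, duplicating a cursor changes nothing
(`dn_response(c(30, 30), p) == dn_response(30, p)`), while the MLE model
treats a duplicate as an extra observation and strictly grows. And because
the units are integrated divisively, same-direction cursor pairs are
sub-additive. These are the discriminating predictions the package's tests
pin down.

### Parameters and defaults

| parameter | meaning | default | why |
|---|---|---|---|
| `s` | tuning width (deg) | 22 | the value used throughout the modeled experiments |
| `M` | number of units | 3601 | 0.1 deg spacing; results are insensitive for large `M` |
| `w` | unit gain | fitted | response units per degree of weighted tuning output |
| `k` | normalization constant | fitted | sets the strength of the divisive term via $w^2/k$ |

## The MLE competitor

With signal-dependent observation noise
$\sigma(e) = \sigma_v + k_v |e|$, the single-cursor response is
$x(e) = c\,e / (1 + (\sigma(e)/\sigma_p)^2)$ and multiple cursors combine by
precision weighting (`mle_multi()`). Only the gain $c$ and the ratios
$\sigma_v/\sigma_p$, $k_v/\sigma_p$ enter the response, so `mle_params()`
stores exactly that identifiable triplet; `mle_params_absolute()` accepts
absolute noise magnitudes and normalizes immediately. The *ordinary* MLE
variant fixes $k_v = 0$ (`constant_sigma = TRUE`), making the single-cursor
response exactly linear.

### The ordinary-MLE declining-rate ratio

For cursor clouds $N(\mu, \sigma^2)$ the *declining rate* at dispersion
$\sigma$ is $(r(0) - r(\sigma))/r(0)$ at fixed $\mu$. Applying the
multi-cursor combination rule with constant per-cursor noise makes the
expected cloud response exactly proportional to $\mu$ and independent of
$\sigma$ — both declining rates are identically zero and their ratio is
0/0. The informative reading of the ordinary-MLE account, and the one the
cloud-of-dots literature uses, is that the cloud dispersion itself acts as
the visual-feedback uncertainty inside the shrinkage factor:
$x(\mu, \sigma) = c\,\mu / (1 + (\sigma_v/\sigma_p + u\sigma)^2)$ with a
positive per-degree scaling $u$. `ordinary_mle_decline_ratio()` implements
this: the shrinkage is independent of $\mu$, so the declining-rate curves at
any two mean errors coincide and their ratio is 1 at every $\sigma$ — for
any $c$, $\sigma_v/\sigma_p$ and $u$. The function computes the ratio by
division of model-derived rates (analytically via linearity of the
expectation, or by Monte Carlo over cloud draws), never by assertion. The DN
model, by contrast, predicts rates that are larger at small $\mu$ than at
large $\mu$, so the ratio departs from unity — the key divergence between
the accounts under feedback uncertainty.

Orientation of the ratio: both `small-mu / large-mu` and its reciprocal are
reported by `decline_ratio()`, because the conventional direction is
ambiguous when a rate is negative (empirically the large-mean rate at small
dispersion can be negative). The figure-facing orientation used in
`run_analysis()` output is the one below unity for the DN model at the
largest dispersion, i.e. `large_over_small`.

## Fitting

`fit_dn_single()` and `fit_mle_single()` minimize squared error on
condition means with bounded Levenberg–Marquardt (`minpack.lm::nls.lm`),
multi-started from log-spaced grids (DN: $w \in 10^{-5..-2} \times k \in
10^{-8..-4}$, 5×5; MLE: $c \in 10^{3..7}$, $\sigma_v/\sigma_p \in
10^{1..3}$, $k_v/\sigma_p \in 10^{-1..2}$). Internally the optimizer works
on log-parameters: the parameters span orders of magnitude, positivity is
then automatic, and the MLE model's poorly conditioned scaling ridge
($c, \sigma_v/\sigma_p, k_v/\sigma_p) \to (\gamma^2 c, \gamma
\sigma_v/\sigma_p, \gamma k_v/\sigma_p$), broken only by the constant term
in the denominator) is navigable. Function tolerance is $10^{-12}$ with at
most $10^4$ evaluations per restart; the best-of-restarts solution is
invariant to restart order. The zero-error condition is included as a fitted
point (its model value is identically zero, so it is harmless and anchors
the intercept). $R^2$ is computed about the observed mean; prediction
$R^2$ on held-out conditions is computed without refitting, which is why it
can be negative for a poor model.

### What is and is not identifiable

On noiseless data both fits recover their generating parameters essentially
exactly (the tests require < 1%). Under realistic noise the picture is
sharper than "all parameters recover": the DN gain $w$ recovers to a few
percent, but $k$ contributes only 5–8% of the single-cursor denominator at
the fitted regime, so percent-level response noise inflates to tens of
percent of $k$; and the MLE triplet is ridge-degenerate, so only its
response *curve* is identified. The test suite asserts exact noiseless
recovery, well-conditioned curve recovery, and gain recovery; treating the
weakly identified coordinates as point estimates on noisy data would be a
mistake in real analyses too.

## The synthetic-data generator

`build_exp1_schedule()` reproduces the 39-condition multi-cursor design
(9 single, 18 double with $|e_1| \ne |e_2|$, 12 triple; 9 cycles of 4-trial
sets, 1404 trials). `build_exp23_schedule()` reproduces the 15-condition
cursor-cloud design ($\mu \in \{0, \pm 14, \pm 40\} \times \sigma \in
\{0, 7, 20\}$, five cursors, 12 cycles, 720 trials), with online or
endpoint feedback mode. `simulate_responses()` evaluates a ground-truth DN
model per participant × condition × cycle — cloud conditions redraw their
five cursors every perturbation trial — adds i.i.d. Gaussian noise to the
scalar response, and averages cycles within participant before any
across-participant averaging (matching the order in which standard errors
across participants are computed). Defaults are the modeled study
conditions: 8 participants, and generating parameters equal to the
single-cursor fits for the chosen experiment and response type (e.g.
learning responses $w = 5.3271\times10^{-4}$, $k = 7.7806\times10^{-7}$;
endpoint-feedback data use the smaller $w = 4.7525\times10^{-4}$ reflecting
the generally weaker endpoint learning response). The noise SD defaults to
15% of the generating model's peak single-cursor response, chosen so that
synthetic across-participant error bars are comparable in relative size to
the published condition means; it is a config knob, not a fitted quantity.

What the generator deliberately does **not** emulate: hand kinematics and
force-channel mechanics (responses are scalar impulses), movement-onset
detection and filtering, velocity-based trial exclusion, and washout-trial
dynamics. Passing tests therefore validate the statistical pipeline and the
models' structural predictions, not the motor-control data processing that
precedes condition means in a real experiment.

`collapse_symmetric()` maps each sign-mirrored condition pair $(C, -C)$ to
$(r(C) - r(-C))/2$, assigned to the positively oriented member (positive
error sum; positive $\mu$ for clouds); self-mirrored conditions (all-zero
errors, $\mu = 0$) pass through. For the multi-cursor design this yields 20
collapsed conditions (5 single + 9 double orbits + 6 triple orbits) — the
count is derived from the pairing rules and asserted in the tests. The
antisymmetric combination also cancels any constant response offset.

## Numerical choices

* **Grid.** Preferred directions use the symmetric inclusive lattice
  $\varphi_j = -180 + (j-1)\,360/(M-1)$ with odd `M`, built as a mirrored
  half-grid so $-\varphi_j$ is bitwise a grid point; `dn_response()` sums
  mirror pairs, which makes $X(0) = 0$ and $X(-\mathbf e) = -X(\mathbf e)$
  hold exactly in floating point, not just approximately.
* **Grid residual.** Because the denominator constant is $kM$ while the
  sums effectively scale with $M - 1$, refining the grid from $M = 3601$ to
  $7201$ moves responses by ~$3\times10^{-6}$ relative (the $kM$ share of
  the denominator, a few percent, times $1.4\times10^{-4}$). The tests
  assert stability at $10^{-5}$; the discrete-vs-closed-form agreement is
  asserted at $10^{-3}$.
* **No angular wrapping.** The Gaussian tuning is a small-angle
  approximation of circular tuning; error sets with magnitudes above
  $90^\circ$ are accepted but flagged with a warning.
* **Monte Carlo.** Cloud expectations default to $10^5$ independent draws
  with a fixed seed (20231220) and per-condition seed offsets; a
  zero-dispersion cloud short-circuits to the exact single-cursor response
  with zero standard error. RNG state of the caller is always preserved.
  Plain summation is used throughout ($M \le 10^5$ needs no compensated
  sums at these tolerances). The vignette and tests run the cloud machinery
  at a few thousand draws — standard errors are far below the effect sizes
  of interest there — while `run_analysis()` defaults to $10^5$.

## A compact example

```{r example, eval = FALSE}
p <- dn_params(w = 5.3271e-4, k = 7.7806e-7)
dn_response(c(15, -30), p)          # two concurrent cursors
analytic_peak(p)                    # saturation peak, ~16.3 deg

res <- run_analysis(list(experiment = "exp1", model = "both",
                         synthetic = list(noise_sd = 0)))
res$prediction_r_squared            # DN: 1; MLE: strongly negative
```

## Known limitations

* The Gaussian (non-circular) tuning makes responses to errors beyond
  ~90° untrustworthy; they are flagged, not forbidden.
* $k$ and the MLE noise ratios are weakly identified from five condition
  means (see above); no uncertainty quantification (bootstrap, CIs) is
  provided, and model comparison is by held-out prediction $R^2$ only.
* Participant-level inferential statistics (t-tests, repeated-measures
  ANOVA) are out of scope; the pipeline reports descriptive means ± SE.
* The outlier rule excluding participants with extreme decline ratios in
  endpoint-feedback data is documented but not applied automatically.
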