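---
title: "Staging chronic disease progression with continuous-time hidden Markov models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Staging chronic disease progression with continuous-time hidden Markov models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cthmmprog)
```

## The problem

Slowly progressing chronic diseases — neurodegenerative disorders are the
archetype — are observed only through registry and study visits: discrete,
irregular snapshots of a process that evolves continuously. A single
patient's record covers a fraction of the multi-decade course, so a full
trajectory has to be stitched together statistically from many partially
overlapping records. Symptoms are multifaceted (motor, functional,
cognitive), and for rare diseases there is no accepted biomarker-based
staging to lean on.

`cthmmprog` addresses this with a continuous-time hidden Markov model
(CTHMM). The latent disease state $S(\tau) \in \{1, \dots, M\}$ evolves as
a continuous-time Markov chain with generator $Q$ ($M \times M$, rows
summing to zero; $Q_{ij}$ is the instantaneous rate of moving from state
$i$ to state $j$). Observations at visit times $\tau_1 < \dots < \tau_T$
are feature vectors $Z_{t} \in \mathbb{R}^K$ with independent Gaussian
emissions per state, $Z_{t,k} \mid S_t = m \sim \mathcal{N}(\mu_{m,k},
\sigma^2_{m,k})$. The probability of moving between states across a visit
gap $\delta$ is the matrix exponential $A(\delta) = \exp(\delta Q)$, so
irregular spacing is handled exactly rather than by discretizing time.

## Structural constraints

Clinical knowledge enters through constraints on $Q$, built with
`structure_mask()`:

* **full** — any state to any state (progression and recovery);
* **forward** — only to later states (irreversible progression);
* **forward chain of order $L$** — only to the next $L$ states.

The last state can be declared **absorbing** (zero outgoing rates), which
models a terminal stage. An irreversible neurodegenerative disease is
naturally modeled as a second-order forward chain with an absorbing final
state: at any instant a patient stays, advances one state, or skips one.

```{r mask}
mask <- structure_mask(9, "forward_chain", order = 2, absorbing_last = TRUE)
mask
```

## Estimation

Parameters $\Theta = \{Q, \pi, \mu, \sigma^2\}$ are estimated by soft
expectation-maximization.

**E-step.** For each patient, the scaled forward–backward algorithm over
the interval-specific matrices $A(\tau_t - \tau_{t-1})$ yields the exact
per-visit posteriors $\gamma_t(m)$ and per-interval pairwise posteriors
$\xi_t(i,j)$, together with the observed-data log-likelihood. Because the
chain is hidden *between* visits as well, the sufficient statistics for
$Q$ are the endpoint-conditioned expectations
$E[N_{kl}(\delta) \mid S(0)=i, S(\delta)=j]$ (number of $k \to l$ jumps)
and $E[R_k(\delta) \mid S(0)=i, S(\delta)=j]$ (time spent in $k$). These
are computed through the exponential of the auxiliary $2M \times 2M$ block
matrix $\begin{pmatrix} Q & B \\ 0 & Q \end{pmatrix}$ with a one-hot $B$:
its top-right block equals
$\int_0^{\delta} e^{sQ} B e^{(\delta-s)Q}\,\mathrm{d}s$. One exponential
per needed $(k,l)$ is required; results are cached per distinct gap
(canonicalized to $10^{-6}$ years, a no-op at data precision). The
block-matrix route was chosen over eigendecomposition because forward
chains routinely produce defective (non-diagonalizable) generators with
tied rates. Accumulating $\xi_t(i,j)$-weighted sums of these expectations
gives the cohort-level expected counts $\hat N_{kl}$ and sojourns
$\hat R_k$; the pairwise posterior weight is the computable realization of
the per-interval transition tallies, since the states themselves are never
observed.

**M-step.** Closed forms: $Q_{kl} = \hat N_{kl} / \hat R_k$ on allowed
entries (diagonal restoring zero row sums, absorbing rows untouched),
$\pi$ = mean first-visit posterior, and posterior-weighted means and
variances for the emissions. A note on $\pi$: it is the distribution of
the state at each patient's *first observed visit*, not at biological
onset — observational cohorts are left-truncated, and the model makes no
attempt to undo that.

Although decoded state sequences are available at any time via the Viterbi
algorithm, estimation is soft EM throughout: the emission updates are
defined with posterior probabilities, and soft EM carries the
monotone-likelihood guarantee that the test suite checks on every fitted
cohort. Viterbi serves decoding and reporting only, with ties broken
deterministically toward the lower state index.

**Numerical choices.** Per-visit scaling constants (log-accumulated) keep
forward–backward exact for series up to 25 visits and a dozen states.
Emission variances are floored at $10^{-6}$ to prevent collapse onto
single points. Estimated rates are clipped to $[10^{-6}, 10^3]$ per year —
disease sojourns of interest span days to decades — which also keeps the
exponentials well conditioned. Convergence is declared when the relative
log-likelihood change drops below $10^{-6}$ (the default `fit_control()`),
and the best of 3 random restarts is returned; EM is a local optimizer and
restarts are cheap insurance.

**Initialization.** K-means with $M$ clusters on the pooled visit features
gives starting means and variances; clusters are relabeled in ascending
order of a severity score (projection on the first principal axis of the
pooled features, signed so that the score increases over within-patient
time), so that state 1 is the mildest. Starting rates put 0.3/year on the
first allowed jump of each row and 0.05/year on the second. Any further
allowed entries (full masks, higher-order chains) start at 0.02/year
rather than zero: an exact zero rate is an absorbing point of EM — the
expected count $\hat N_{kl}$ is identically zero when $Q_{kl} = 0$ — so a
zero start would silently forbid the transition.

## Choosing the number of states

`select_num_states()` implements held-out selection: split the cohort *by
patient* (80/20 by default), fit one model per candidate $M$ on the
training side, evaluate each on the held-out side, and take the argmax of
the held-out log-likelihood (ties to the smaller model). A single seeded
split is the default, matching common practice for large cohorts;
per-visit normalization is available for unbalanced cohorts.

Two properties of this procedure are worth knowing. First, on real
clinical data the candidate family never contains the truth, and the
held-out curve typically shows a clear peak. Second, on data *simulated
from a model inside the candidate family*, the curve rises steeply until
the true $M$ and then plateaus: extra states act as near-duplicates whose
held-out penalty shrinks as the training set grows, so with a very large
simulated cohort the argmax among $M \geq M_{\text{true}}$ approaches a
coin flip. Selection studies on synthetic data are therefore run at
moderate cohort sizes, where the overfit penalty of redundant states is
still visible, and candidates are run to tight convergence with the
multi-restart default — a redundant state accumulates its overfit during
the slow final phase of EM, and an under-converged candidate hides it.
The penalty of a redundant state scales with its parameter count (about
$2K + 2$ held-out degrees of freedom), so feature dimensionality matters:
at the nine features of the target data shape the penalty (~5 nats at an
80/20 split) clearly exceeds the split noise (~2 nats), while a
three-feature study sits at the noise floor and the argmax becomes
unreliable. The studies here mirror the usual two-cohort design: a
smaller subset of patients with several visits each (at least 4) for
selection, the full cohort with at least 2 visits for the final fit.

## The cohort simulator

`simulate_cohort()` provides ground truth for every estimation and
selection study. Per patient it draws an entry time into the disease
course (uniform over the first 30 years by default, emulating left
truncation), simulates the hidden trajectory by Gillespie sampling, lays
down a visit schedule — visit count $1 + \text{Poisson}(\bar T - 1)$
truncated at 25, gamma gaps with mean one year — and emits Gaussian
observations. Visit times are rounded to 0.01 years, about date-level
precision for registry data. The defaults (mean 2.9 visits, 1–25 range,
roughly annual spacing) reproduce the shape of large integrated
observational cohorts.

`hd_preset()` packages a nine-state second-order forward chain with an
absorbing ninth state whose expected durations are 9.7, 9.2, 3.8, 2.9,
5.8, 3.5, 3.0 and 3.2 years, an 80/20 split between one-step and two-step
jumps except out of states 3 and 4 (45% skipping mass, reflecting
alternative pathways through the transition period), and nine features in
three domains: motor factors trending up, functional and cognitive factors
trending down, unit variances, roughly 2 SD between adjacent states. The
emission means are *illustrative*, chosen for that separation; no
published per-state factor values exist to calibrate them.

What the simulator does **not** emulate: missingness mechanisms, visit
schedules correlated with severity, measurement batch effects across
studies, covariate-dependent progression rates, or the latent-factor
extraction that produces such features from raw clinical instruments.
Passing recovery tests on this generator therefore demonstrates
correctness of the estimation machinery under the model's own assumptions,
not robustness to the ways real registry data violate them.

## A worked example

```{r example, eval = FALSE}
sim <- simulate_cohort(hd_preset(num_patients = 1000, seed = 1))
mask <- structure_mask(9, "forward_chain", order = 2, absorbing_last = TRUE)
fit <- fit_cthmm(sim$cohort, mask,
                 fit_control(num_restarts = 2, seed = 1))
expected_durations(fit$params$Q)
decode_cohort(fit$params, sim$cohort)        # patient, time, state
report_state_profiles(fit$params, sim$cohort, delta = 1)
```

The study sizes used throughout the test suite (cohorts of 150–500
patients, 3–5 visits on average) were picked so that each validation
study is informative at desk scale: parameter recovery uses 500 patients
with ~5 visits (posterior SEs small enough to resolve 25% rate errors),
selection uses a 250-patient cohort filtered to ≥4 visits for the reasons
above.

## Known limitations

* Time-homogeneous generator: no covariates on rates, no change over
  calendar time or age; semi-Markov (non-exponential sojourn) dynamics are
  out of scope.
* Independent Gaussian emissions only; other exponential-family emission
  models are a natural extension point but are not implemented.
* The forward prediction `predict_future()` — posterior at the last visit
  propagated through $A(h)$, features as the mixture of state means — is a
  standard construction; published systems may use richer
  patient-individualized schemes.
* No standard errors or intervals for $\Theta$; the validation studies
  quantify recovery error by simulation instead.
* Visits with any missing feature are dropped at load time; there is no
  imputation.
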