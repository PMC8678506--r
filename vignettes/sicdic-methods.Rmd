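---
title: "Methods: early sequential prediction of SIC and sepsis-associated DIC from irregular labs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: early sequential prediction of SIC and sepsis-associated DIC from irregular labs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The clinical problem

Coagulation dysfunction complicates half to two thirds of sepsis admissions.
Its early phase, sepsis-induced coagulopathy (SIC), is scored from platelet
count, PT-INR and the SOFA score; a subset of SIC patients progress to overt
disseminated intravascular coagulation (DIC), scored by the ISTH system from
platelets, a fibrin-related marker, PT prolongation and fibrinogen.
Sepsis-associated DIC is diagnosed *sequentially*: a patient is labeled
DIC-positive only along the SIC-then-overt-DIC path. Because DIC becomes
treatment-refractory once clinically obvious, the useful problem is
*early warning*: from the labs observed in a sliding 24 h sampling window,
estimate the risk that the patient will satisfy the SIC or DIC criteria
8·n hours later (n = 1…6).

ICU laboratory data are irregular: each variable is measured on its own
schedule, and the *pattern* of measurement is itself informative (sicker
patients are sampled more). `sicdic` therefore never imputes values. Missing
structure is made explicit and handed to the models.

# Ground-truth labeling

`sic_score()` and `isth_dic_score()` implement the published score tables.
Both are exhaustively tested against independently written nested-if oracles.
The exact cutoffs are configurable via `scoring_cutoffs()` because published
variants differ between hospitals; defaults:

* SIC (total 0–6, positive at ≥ 4): platelets < 150/< 100 ×10⁹/L → 1/2;
  INR > 1.2/> 1.4 → 1/2; SOFA ≥ 1/≥ 2 → 1/2. An optional auxiliary rule
  (platelet + INR sub-scores > 2) can be switched on.
* ISTH overt DIC (total 0–8, positive at ≥ 5): platelets < 100/< 50 → 1/2;
  D-dimer ≥ 1/≥ 5 mg/L FEU → 2/3 (FDP at 10/25 mg/L is the documented
  fallback when D-dimer was never drawn); PT prolongation ≥ 3/≥ 6 s over a
  configurable laboratory reference (default 12.0 s — references are
  lab-specific and rarely published); fibrinogen < 1 g/L → 1.

`assess_stream()` walks a patient's stream and scores at every timestamp where
a scoring variable updates. Each input uses its most recent value within a
staleness horizon (default 24 h, matching the sampling window); a stale or
absent input makes that score *not computable* — never silently imputed. The
two-step sequential rule is applied here: `dic_positive` requires the raw ISTH
rule *and* SIC positivity at or before the same assessment. A configuration
flag relaxes this, since a small fraction of real DIC cases present without a
prior SIC-positive assessment.

`build_label_timeline()` aggregates assessments into consecutive 8 h windows.
A window's observed label is that of its latest computable assessment. Windows
without one are filled by forward interpolation: agreeing flanking labels
propagate; disagreeing flanks take the *earlier* label. The forward tie-break
avoids look-ahead leakage — a future deterioration must never justify labeling
the past as diseased. Leading windows before any observation stay absent;
trailing windows are forward-filled from the last observation (same
past-to-future logic), which keeps long-horizon targets defined near the end
of stay.

# Encoding irregular streams

For a patient with observation timestamps $s_1 < s_2 < \dots < s_T$ and $D$
variables, the encoder produces per timestamp $t$ and variable $d$:

* the value $x_t^d$ (min-max normalized; see below),
* the mask $m_t^d \in \{0,1\}$, 1 exactly where $x_t^d$ was observed,
* the global step $\Delta_t = s_t - s_{t-1}$,
* the interval $\delta_t^d$: time since variable $d$ was last observed,
  accumulated through unobserved steps —
  $\delta_1^d = 0$; for $t > 1$, $\delta_t^d = s_t - s_{t-1}$ if
  $m_{t-1}^d = 1$, else $s_t - s_{t-1} + \delta_{t-1}^d$.

Whether the adjacent step is global or per-variable is genuinely ambiguous in
the field; we default to the global $\Delta_t$ and expose the per-variable
view through $\delta$, which carries the same information accumulated.

Windows: a 24 h sampling window slides in 8 h steps; membership is half-open
`[start, end)` so boundary observations are never double-counted. Targets at
horizon $h$ are the timeline labels of the window containing `window_end + h`.
$\delta$ is **not** reset at window boundaries: the recurrence is defined on
the whole series, so a window knows how stale each variable was when the
window opened. A window with zero observations is retained as a single query
row at the window end with an all-zero mask — under informative sampling,
total silence is itself a signal.

Normalization is min-max per variable, learned on training patients only
(values first clamped to broad physiologic reportable ranges, documented in
`default_ranges()` as stand-ins for hospital-specific ranges). Out-of-range
test values clamp into [0, 1]. Unobserved entries carry fill value 0 after
normalization; the mask makes the fill recoverable, which is the standard
contract for mask-aware sequence models. Constant training variables are
dropped with a warning.

`discretize_for_tabular()` gives fixed-dimension models their view: per 8 h
grid cell and variable, the last observed value and the observation count,
plus each variable's $\delta$ at the window end — `3·2·D + D` features for the
default geometry.

# The model roster

Eight models share one contract: per (window, disease, horizon), a risk in
[0, 1].

**Tabular baselines** (on discretized features, one independent fit per head):
logistic regression (`stats::glm`), an RBF support-vector machine
(`e1071::svm` with probability outputs; rows subsampled to a cap because
kernel fitting is quadratic), and two gradient-boosted tree variants —
`xgboost` with the `gbtree` and `dart` boosters — standing in for the usual
pair of boosted-tree libraries.

**Sequence models** (shared recurrent trunk, one sigmoid head per disease ×
horizon) are implemented in the package itself, including backpropagation
through time and the Adam/SGD optimizers, with gradients verified against
numerical differentiation:

* *RNN* and *LSTM* consume the temporally discretized grid view — three fixed
  8 h steps of `(x, m)`. By construction they cannot see within-cell timing;
  a test asserts exactly this.
* *decay-RNN* consumes the irregular event view `(x, m, δ/24)`. Before each
  update after a gap $\Delta_t$, the hidden state is decayed elementwise by
  $\gamma_t = \exp(-\max(0, w_\gamma \Delta_t + b_\gamma))$ with learned
  per-dimension rates: old evidence fades as gaps grow, and $\gamma = 1$ at
  zero gap recovers the plain RNN step.
* *ODE-RNN* propagates the hidden state between observations by a learned
  ordinary differential equation $dh/dt = \tanh(h W_1 + b_1) W_2$ and applies
  a recurrent jump update at each observation. The hidden state is therefore
  defined in continuous time and queryable at arbitrary within-window times
  (`ode_rnn_forward(query_t = …)`).

Numerical choices. The ODE is solved with fixed-step RK4 — reproducibility is
worth more here than adaptivity. Single-window queries use step
`min(0.1 h, gap/4)`. Batched training uses a fixed number of RK4 substeps per
inter-observation gap (default 2), so windows with different gap patterns
batch into one matrix computation; this is a discretize-then-optimize choice
(gradients flow through the unrolled solver). A flow-composition test pins the
solver's consistency to 1e-4, and a closed-form linear-decay check pins its
accuracy. Training: masked binary cross-entropy (absent targets contribute
nothing), inverse-prevalence class weights per head (on by default — onset
labels are heavily imbalanced), global gradient-norm clipping at 5, minibatch
Adam (default) or momentum SGD, and model selection by best mean validation
AUROC across heads. Everything is deterministic given the seed; a test trains
twice and requires identical weights. Hidden size defaults to 32 — at the
cohort sizes this package targets, larger trunks only slow the fit.

# Evaluation

AUROC is the Mann–Whitney statistic (ties counted half; exactly all-pairs
concordance, tested against brute force). AUPRC is step-wise average
precision. F1 is reported at a 0.5 default threshold; `alarm_metrics()` sweeps
thresholds 0.1–0.9 (including the clinically discussed 0.7) and reports
window-level sensitivity/specificity plus event-level precision and recall
(an event being a patient's first positive target window at the lead time).

Confidence intervals are percentile bootstrap over 1,000 resamples, drawn at
the **patient** level by default: windows within a patient are strongly
correlated, and window-level resampling understates variance. Window-level
resampling is available by flag. Single-class resamples are skipped and
counted; the intervals are deterministic given the seed.

`horizon_report()` assembles the model × disease × horizon table;
`report_table()` pivots it into the familiar wide layout, leaving missing
cells empty rather than zero.

# Interpretation

*Occlusion* asks what happens when a variable is never measured at all: the
evaluation set is re-encoded with the variable's events removed — mask 0
everywhere, fill values, and $\delta$ recomputed so the variable accumulates
staleness from the start of the stream, exactly what the interval recurrence
prescribes for a never-observed variable. The model is not retrained and
nothing is mutated (a test hashes model and baseline windows before and
after). Value-zeroing alone would leave a contradictory "measured but zero"
signature; global masking keeps the encoding semantics coherent.

*SHAP* for the boosted-tree models is delegated to xgboost's exact tree-path
additive attributions; the package exports global feature- and variable-level
importance, per-sample rows (whose sum plus base value reproduces the margin
output — asserted numerically), and a top-pair dependence table.

*Lite models*: `build_lite_set()` combines the SHAP and occlusion rankings by
mean rank, applies manual clinical include/exclude overrides, and returns at
most k = 10 variables for re-encoding and retraining on the reduced panel.

# The synthetic cohort generator

No public dataset carries sequential SIC→DIC annotations, so the package
ships a generator that the whole test suite runs against. Per patient it
draws a latent monotone disease path — sepsis, possibly SIC onset (uniform
after the first day), possibly DIC onset 16–72 h later; never DIC without SIC
— then emits labs from state-conditional piecewise-linear means (6 h ramps at
transitions) with multiplicative lognormal noise (default sd 0.08), at
per-variable thinned-Poisson sampling times with intensity
`rate_base × (1 + coupling × severity)` (defaults: 3 observations/variable/24 h,
coupling 0.6). SOFA is emitted directly as a daily score stream — deriving it
from organ variables is out of scope. Every patient gets a full admission
panel at t = 0. Default target prevalences are SIC 37.1% and DIC 17.8%, the
reported cohort rates this pipeline is designed around. Stays are 72–240 h
(exponential extension beyond the 3-day inclusion minimum, mean 84 h).
Per-patient random substreams derive from `(seed, patient index)`, so cohorts
are reproducible and stable under size changes.

The state-conditional mean levels were chosen once so that applying the SIC /
ISTH scoring to noisy generated labs recovers the latent state in well over
90% of assessed timestamps — the premise that makes the generator's latent
states usable as recovery ground truth; a test enforces the 90% floor.

What the generator does **not** emulate: prodromal drift before onset (labs
jump to the new state over a 6 h ramp), treatment effects and label reversals,
vital-sign streams, and inter-variable noise correlation. Two consequences to
keep in mind when reading results on synthetic data: post-onset windows are
easy (the state persists and is visible in the labs), so window-level AUROC
and alert sensitivity are optimistic relative to real data; and predicting a
patient's *first* positive window at a high threshold is nearly impossible
(there is no prodrome to see), so event-level lead-time recall on synthetic
data is pessimistic. Passing recovery tests therefore demonstrates that the
pipeline machinery is correct and leak-free — not that the trained models
would match their synthetic-data discrimination on hospital data.

# Problem sizes

The shipped tests and the acceptance script run at desk scale, chosen as the
smallest sizes at which the properties under test are stable: 700 patients
(≈ 9,500 windows) for the model-recovery checks and the acceptance script
(ODE-RNN: 8 epochs on at most 4,000 training windows per epoch), 200 patients
for the end-to-end reproducibility runs, 1,000–2,000 for generator prevalence
and informative-missingness properties, and 1,000 bootstrap resamples wherever
intervals are reported.

# Known limitations

* The generator is openly synthetic; none of its distributional parameters
  are estimates of hospital data.
* The SIC/ISTH cutoff defaults reconstruct the published tables; a site
  deploying this pipeline must configure its own laboratory PT reference and
  marker scales.
* The SVM baseline subsamples large training sets, and its probability
  calibration (Platt scaling inside libsvm) is the one non-seeded stage of
  the roster; exact byte-reproducibility is guaranteed for the other seven
  models.
* Sequence models train on CPU in minutes at the shipped sizes but are not
  engineered for cohorts orders of magnitude larger.
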