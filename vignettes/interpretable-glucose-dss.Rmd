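---
title: "Interpretable glucose forecasting and replay-based decision support"
author: "glucodss authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interpretable glucose forecasting and replay-based decision support}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glucodss)
```

## The problem

People with type 1 diabetes dose exogenous insulin against meals and
hyperglycemia using continuous glucose monitoring (CGM) data sampled every
5 minutes.  Data-driven forecasters of future glucose are attractive as the
engine of decision support systems (DSS) that suggest corrective insulin
boluses (CIB).  But prediction accuracy alone is a poor selection criterion
for such an engine: in free-living data, prandial insulin boluses are
delivered *when* meals are eaten and are *nearly proportional* to the
announced carbohydrates.  This collinearity lets a network achieve good
accuracy while attributing the *combined* meal effect to either input — in
the worst case learning that insulin raises future glucose.  A model with
that defect produces degenerate dose-response counterfactuals, and a DSS
built on it will decline to suggest insulin precisely when insulin is
needed.

`glucodss` packages a complete, testable pipeline for studying this
phenomenon:

1. a **synthetic-data generator** built on a glucose-insulin minimal model,
   reproducing the statistical structure of free-living CGM corpora
   (meal/bolus collinearity, suboptimal dosing, sensor noise, dropouts);
2. two **LSTM forecasters** that differ only in a non-learnable
   physiological preprocessing layer (`np` vs `p` variants);
3. **Shapley-value attribution** of forecasts to the three input channels,
   with corpus-level summaries that operationalize the usual summary-plot
   reading;
4. standard **accuracy and glycemic-range metrics**;
5. an **identify-then-replay engine** that re-simulates postprandial
   windows under a corrective-bolus policy driven by either forecaster.

Everything runs on synthetic data generated by the package itself, so the
full pipeline is reproducible and property-testable without access to any
restricted clinical dataset.

## The minimal model and its extensions

The simulator couples Bergman's minimal model of glucose kinetics to
two-compartment subcutaneous insulin kinetics and a three-compartment oral
absorption chain:

$$\dot G = -(S_G + X)\,G + S_G\,G_b + \frac{Ra}{V_G\,BW},\qquad
  \dot X = -p_2\left[X - S_I\,(I_p - I_{pb})\right]$$

$$\dot I_{sc1} = -k_d I_{sc1} + \frac{u(t)}{V_I BW},\quad
  \dot I_{sc2} = k_d I_{sc1} - k_{a2} I_{sc2},\quad
  \dot I_p = k_{a2} I_{sc2} - k_e I_p$$

$$\dot Q_{sto1} = -k_{gri} Q_{sto1} + CHO(t),\quad
  \dot Q_{sto2} = k_{gri} Q_{sto1} - k_{empt} Q_{sto2},\quad
  \dot Q_{gut} = k_{empt} Q_{sto2} - k_{abs} Q_{gut}$$

with rate of appearance $Ra = f\,k_{abs}\,Q_{gut}$.  States are glucose
(mg/dl), remote insulin action (1/min), subcutaneous and plasma insulin
(µU/ml) and gastro-intestinal glucose masses (mg); inputs are piecewise
constant per 5-minute bin (insulin U/min, carbohydrates g/min).

Default parameters are population values for an adult with T1D, checked
for realism before any learning experiment was run:

* `SG = 0.008` 1/min, `SI = 8e-4` ml/µU/min, `p2 = 0.02` 1/min: one unit
  of insulin lowers euglycemic steady-state glucose by ≈ 33 mg/dl (a
  typical correction factor), and an unbolused 50 g meal returns to within
  ≈ 5 mg/dl of basal by +12 h;
* `kd = 0.035`, `ka2 = 0.025`, `ke = 0.127` 1/min: insulin action peaks
  1.5–2 h after a bolus, as for rapid-acting analogues;
* `kgri = kempt = 0.18`, `kabs = 0.012` 1/min, `f = 0.9`: meal absorption
  peaks within the first hour and completes in ≈ 4 h.

Integration uses an adaptive Dormand–Prince RK45 stepper written in C++
and restarted at every grid-bin boundary, so input discontinuities never
fall inside a step.  The system is non-stiff (all rates ≤ 0.2/min); the
test suite verifies the integrator against `deSolve::lsoda` on a full
simulated day (agreement < 0.05 mg/dl), checks gut mass balance to 1e-6
relative, and checks that tightening tolerances tenfold moves glucose by
less than 0.1 mg/dl.  Exact analytic steady-state initialization makes the
basal-only trajectory constant to 1e-6 mg/dl.

## What the generator emulates — and what it does not

`corpus_config()` encodes one virtual patient's month:

* three announced meals a day (breakfast/lunch/dinner, 20-min jitter,
  40–90 g);
* prandial boluses proportional to announced grams through a carb ratio
  of 12 g/U, with 5% relative dosing noise — the collinearity that
  confounds learning — and a mild systematic under-bolusing factor (0.85);
* **severely under-dosed meals** (35% of meals receive only 35% of the
  nominal dose): carb-counting failures producing the prolonged
  postprandial hyperglycemia that decision support is meant to correct.
  Half of these are later **self-corrected** by the patient (a non-prandial
  bolus roughly equal to the missing insulin, 2.5–4 h after the meal).
  Self-corrections are routine self-management; they matter twice here:
  they decouple insulin timing from carbohydrate timing in the training
  data (without them the forecaster can learn almost nothing about the
  isolated effect of insulin), and they are the non-prandial boluses that
  the postprandial window-selection rule explicitly filters out;
* iid Gaussian CGM noise (5 mg/dl) clipped at the 40 mg/dl sensor floor,
  and about one sensor dropout per day, mostly shorter than 30 min (15%
  long, 35–60 min, to exercise the no-interpolation rule);
* 31 days split chronologically 21 train / 10 test, mirroring a ≈ 3:1
  monitoring split with a 10-day evaluation period.  Training gaps shorter
  than 30 min are linearly interpolated; the test split receives no
  imputation.

Not emulated: exercise, stress, illness, alcohol, intra-day parameter
variability, plasma–interstitial sensor lag, and autocorrelated sensor
noise.  Passing tests therefore demonstrate the pipeline's behaviour under
a *well-specified* data-generating process, not robustness to the
confounders of real free-living data; on real data the attribution
analysis can mislead wherever such confounders systematically co-occur
with intake events.

## The two forecasters

Both variants are a single layer of 64 LSTM units over a 60-minute window
(12 samples × 3 channels) with a linear read-out, trained with Adam on
mean squared error, z-scored per channel with training-set statistics, and
early-stopped against a chronological 20% validation tail (patience 10,
at most 30 epochs).  Forward, backpropagation-through-time and Adam are
implemented in RcppArmadillo and verified against finite differences to
1e-10.  The `np` variant consumes the raw channels.  The `p` variant first
convolves insulin and carbohydrates with fixed action curves into
insulin-on-board (IOB) and carbs-on-board (COB):

$$r(t) = \left(1 + t/\tau\right)e^{-t/\tau}$$

with $\tau$ set so that 1% of activity remains at the stated duration,
then truncated to zero.  Insulin uses a 6-hour curve.  Carbohydrates use a
4-hour ('slow') curve — carbohydrate absorption completes faster than
subcutaneous insulin action, and giving both channels the same support
would make IOB and COB nearly proportional signals under proportional
prandial dosing, defeating the uncoupling purpose of the layer ('fast'
carbs use 2 h).  The convolution is an amount (U or g): the curve opens at
1, so a bolus contributes exactly its size to IOB in its own bin.
Pre-history is padded with the series' basal delivery floor (zero for
carbohydrates) to avoid start-of-series transients.

The input window (60 min) is a pragmatic default that covers the
short-horizon dynamics at the input side; for the `p` variant the on-board
signals inject the longer pharmacodynamic memory, which is precisely the
point of the preprocessing layer.  Windows never span an un-interpolated
CGM gap, forecasts are strictly causal, and each (variant, horizon) pair
is a separate model — four models in the full experiment (PH = 30 and 60
min).

Training is seeded and reproducible on a fixed numerical backend
(identical validation-loss trajectories on repeat); bit-equality across
BLAS implementations is not promised.

## Explaining forecasts with Shapley values

The three input channels are the players of a coalitional game per
forecast: the value of coalition $S$ is the model output when every
channel not in $S$ is replaced, across the input window, by its
training-set mean (for the `p` variant the masking is applied to the *raw*
channels before the IOB/COB filters, so attributions refer to the same
physical inputs in both variants).  With 3 players all $2^3$ coalitions
are evaluated and the attribution is the exact Shapley value

$$\phi_j = \sum_{S \subseteq M \setminus \{j\}}
  \frac{|S|!\,(|M|-|S|-1)!}{|M|!}\,\bigl[v(S\cup\{j\}) - v(S)\bigr],$$

so efficiency ($v(\emptyset) + \sum_j \phi_j$ equals the forecast) holds
to machine precision.  A kernel-weighted least-squares estimator with the
efficiency constraint is included for larger player sets and as a
cross-check; on 3 players it enumerates and reproduces the exact values.
For a linear model the construction collapses to the closed form
$\phi_j = \beta_j (x_j - E[x_j])$, which the test suite verifies by
feeding the masking explainer a linear reference model.

Corpus-level summaries condense the usual summary-plot reading into
numbers: per channel, the **importance** (mean $|\phi|$), the importance
**rank**, and the **sign-consistency** — the Spearman correlation between
the channel's level over the input window and its attribution.  A
physiologically sound model shows negative insulin and positive
carbohydrate sign-consistency.  The window *mean* (not the single anchor
value) is correlated because masking replaces the whole window: at a 5-min
grid nearly every anchor carries plain basal insulin and zero
carbohydrates, so the anchor value alone is uninformative; both values are
stored on each explanation.

Shapley attributions describe the model, not the physiology: they reveal
what the network learned, and only combining them with physiological
expectations (insulin lowers glucose, carbohydrates raise it) turns them
into a model-selection tool.  They are not causal statements about the
patient.

## The corrective-bolus policy and replay evaluation

The DSS is deliberately simple.  Two hours after a meal, whenever current
CGM exceeds 180 mg/dl, candidate doses $i_n$ on a grid are scored by

$$J(i_n) = \bigl(\hat g_n(k+PH\,|\,k) - g_0\bigr)^2 + 10\, i_n^2,
  \qquad g_0 = 120\ \text{mg/dl},$$

where $\hat g_n$ is the forecaster's counterfactual prediction with the
candidate dose added at the current bin, and the minimizing dose is
suggested (a minimum at 0 U means no suggestion).  The grid search is
exact by construction and is asserted against an independent scan.

Evaluation replays 8-hour postprandial windows from the test split that
begin with an announced meal and contain neither further carbohydrates nor
any non-prandial bolus.  For each window a patient model is identified
from the window's own CGM/insulin/CHO data by **MAP estimation**: free
parameters $\{S_I, S_G, p_2, k_{abs}, k_{empt}\}$ under independent
log-normal priors centred at population values (a deliberate
simplification of full Bayesian posterior sampling; the accepted quality
bar is parameter recovery, which the test suite measures — insulin
sensitivity within 10% on noise-free windows and within 25% median error
under 5 mg/dl CGM noise).  The identified model is initialized at steady
state with basal glucose pinned to the first CGM reading of the window;
replaying the original therapy then reproduces the observed trace up to
noise, and replaying an alternative therapy answers the counterfactual
question.  During replay the policy reads the simulated CGM (no extra
sensor noise by default), re-evaluates every 5 minutes, and respects a
120-minute lockout after each delivered bolus.

### Why the dose grid is a titration grid

The default candidate grid is $\{0, 0.1, \ldots, 1.5\}$ U.  This is a
*control-design* choice made on the population model before the evaluation
experiments, and it deserves an honest explanation.  An LSTM trained on
observational data learns the *marginal* effect of insulin given the CGM
history — the history already encodes the ongoing trajectory, so the
counterfactual dose-response slope of the trained networks is attenuated
(a few mg/dl per U at PH 60) relative to the full pharmacodynamic effect
(≈ 30–45 mg/dl per U on the simulator).  With an attenuated slope $s$, the
interior optimum of $J$, $i^* = s\Delta/(s^2 + 10)$, exceeds any
clinically sensible cap for typical excursions $\Delta$, so the grid
maximum effectively sets the dose.  A single large cap cannot be safe
across window severities: a self-resolving 40 g excursion tolerates barely
1.5 U while a sustained severe excursion needs ≈ 3 U.  Small titration
steps resolve this: each suggestion is at most 1.5 U, and the trigger
condition re-issues a further step after the lockout only while
hyperglycemia persists, so the *total* delivered insulin adapts to
severity.  The grid, cadence and lockout are all configuration.

## Numerical choices and degenerate inputs

* Grid alignment snaps readings to the nearest bin, ties to the earlier
  bin; duplicate readings in a bin keep the nearer-in-time with a warning.
* Gap interpolation is strictly "shorter than 30 min": five consecutive
  missing 5-min samples are filled, six are not; boundary gaps without a
  flanking reading are never filled.
* The delay metric scans shifts $j \in \{0, 5, \ldots, PH\}$ minutes and
  breaks ties towards the smallest shift (the most favourable time gain);
  TIR bounds are inclusive at 70 and 180 mg/dl.
* Channels with zero variance get unit standard deviation in the
  normalizer (constant series train to predict the constant); constant
  features yield an `NA` sign-consistency rather than a spurious number.
* The identification objective returns a large penalty for non-finite
  trajectories, keeping L-BFGS-B inside the stable region; optimization
  runs in log-parameter space with bounds at ±3 prior standard deviations
  and the best of 4 jittered starts.

## Problem sizes

The shipped experiments use desk-scale sizes chosen to exercise every
stage: a 31-day corpus (8 928 samples, ≈ 5 700 training windows), 30-epoch
training, 80–100 explained anchors per model, and all eligible
postprandial windows of the 10-day test split (typically 5–9).  The
multi-seed replication in the test suite repeats the pipeline over five
seeds and asserts each qualitative finding as a majority vote, reflecting
that individual seeds can and do produce atypical corpora (e.g. a test
split without any severely under-dosed eligible window).

## Known limitations

* The minimal model self-restores toward basal glucose at rate $S_G$,
  so very large unbolused excursions partially self-resolve — one reason
  the generator models severe under-dosing rather than fully missed
  boluses.
* MAP identification replaces posterior sampling; parameter uncertainty
  is not propagated into replay.
* The replay feeds the policy noise-free simulated CGM by default;
  enabling sensor noise would add trigger jitter.
* Attributions use single-reference (mean) masking; a background *sample
  set* would average over a reference distribution at higher cost.
* One virtual patient; no population heterogeneity beyond the priors.
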