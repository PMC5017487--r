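---
title: "Methods: activity recognition, the AAEI recursion and fuzzy prompting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: activity recognition, the AAEI recursion and fuzzy prompting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aaei)
```

This vignette is the package's own account of the science it implements: how
raw arm-worn accelerometry becomes a daily MET·minute amount, how that amount
drives the Accumulated Activity Effective Index (AAEI), and how the index
drives an automated fuzzy-logic decision about whether — and how much — to
prompt a user to exercise. It also records the numerical and design choices
made where the method leaves room, and what the synthetic-data tests do and
do not demonstrate.

## 1. From acceleration to MET·minutes

A tri-axial accelerometer on the upper arm samples at 40 Hz in units of g.
The raw signal is the sum of gravity and body motion; the two are separated
with a second-order elliptic IIR low-pass at 0.5 Hz applied causally per
axis, motion being the per-sample difference raw − gravity (so the
decomposition is exact by construction). Two numerical choices matter here:

* **DC normalisation.** An even-order elliptic design sits `Rp` dB below
  unity at DC, which would leak a constant fraction of gravity into the
  motion channel of a device at rest. The coefficients are rescaled to unity
  DC gain; the passband then ripples slightly above 1 instead of around it,
  which is immaterial at a 0.5 Hz cut-off against gait at 1–3 Hz (the 20 dB
  stopband still attenuates a 2 Hz oscillation to about 1% in the gravity
  channel).
* **Warm-up.** A causal IIR filter starts from zero state. Each axis is
  primed with 10 s of its first sample — steady-state initial conditions for
  a resting device — and the pad is discarded, so a constant trace produces
  zero motion from the first sample and early windows of a real trace are
  not misread as activity.

The motion stream is cut into non-overlapping 2 s windows (80 samples; a
trailing partial window is dropped, matching a real-time 2 s buffer). Each
window yields ten features: SMV (mean per-sample Euclidean magnitude), SMA
(mean per-sample sum of absolute axis values), the y- and z-axis maxima, and
the three largest non-DC FFT magnitudes of the per-sample magnitude signal
with their frequencies (0.5 Hz bin resolution at N = 80; ties resolve to the
lower frequency; no detrending or window taper). SMV and SMA are means
rather than sums so their scale does not depend on the window length. One
consequence of taking the FFT of the *magnitude* is worth knowing: a pure
oscillation with no DC pedestal is full-wave rectified by the magnitude
operation, so its dominant bin appears at twice the oscillation frequency.
For arm-worn gait this is harmless — gravity provides the pedestal in the
raw signal, and in the motion channel the rectified spectrum is still
monotone in step frequency, which is all the classifier needs.

Windows are classified into five categories — stationary, light, moderate,
vigorous, very vigorous — by an information-gain decision tree (rpart with
the `"information"` split criterion, minimum leaf size 5, no
cost-complexity pruning), serialisable as a documented JSON structure and
predicted by an internal walker so that a freshly trained model and one
loaded from JSON behave identically. Each category carries a representative
MET value: 1, 2, 5, 7.5, 10 (band midpoints; moderate = 5 is anchored by the
calibration that 10 minutes of moderate walking equals 50 MET·minutes). The
day's amount of physical activity is

\[ MT = \sum_{\text{non-stationary windows}} \mathrm{MET} \times
\tfrac{2}{60}\ \text{min}, \]

stationary windows contributing nothing — MT models exercise, and crediting
idle wear time would inflate it.

## 2. Synthetic signals

No recorded accelerometry ships with the package; the generator makes the
pipeline trainable and testable. A trace is
`orientation · (1 + m(t)) + noise` with
`m(t) = A(sin 2πft + 0.5 sin 4πft)`: exactly 1 g of gravity along a unit
orientation, a gait fundamental with a half-weight second harmonic along the
same axis, and white Gaussian noise per axis. Placing the oscillation along
gravity (the arm hangs along it) keeps the magnitude signal ≈ `1 + m(t)`,
so the dominant non-DC frequency of a walking trace equals the step
frequency. Class defaults rise monotonically with intensity — step
frequency 0/1.5/2/2.5/3 Hz and amplitude 0/0.15/0.35/0.6/0.9 g for
stationary through very vigorous, noise 0.02 g at rest and 0.05 g in
motion — and the labeled-dataset generator jitters step frequency and
amplitude by ±10% and tilts the orientation by up to 15° per trace.

What passing tests show, and do not show: the synthetic classes are
separated by construction (amplitude and spectral peak both order them), so
the ≥ 90% ten-fold cross-validation bar demonstrates that the filter,
windowing, features, tree and evaluation plumbing are correct — not that
the classifier would reach any particular accuracy on real devices, whose
noise spectra, orientations and behaviours are far richer. Per-class
precisions on real treadmill data cannot be reproduced without that data
and are deliberately not acceptance values here.

## 3. The AAEI recursion

With daily amounts `MT(t)` the index evolves at day resolution:

\[ I(t) = \max\{0,\ I(t-1) + k\,MT(t) - E(t)\}, \qquad
E(t) = A(t-1)\,C^{-\alpha}, \qquad A = I/7, \]

\[ \alpha = \sum_{i\ge 1} \frac{MT(t-i) - A(t-i)}{A(t-i)}\,W^{i-1},
\quad \alpha \ge -2, \]

with `k = 1`, `C = 2`, `W = 0.5`. The threshold E is the decay mechanism:
when recent activity falls short of the accumulated average, α goes
negative and E grows geometrically, up to the clamp at −2 (the exact limit
of the series under indefinite rest at W = 0.5). Useful exact facts, all
test-enforced against a naive from-scratch re-derivation:

* Constant activity `MT = m` has the exact fixed point `I = 7m` (α = 0,
  E = m). A 600-point goal therefore corresponds to ~86 MET·min/day.
* From a fixed point, rest days yield E = m, then 2A, then C^{1.5}A, …;
  seven consecutive rest days from I = 700 end at I ≈ 12.6, under 2% of the
  start.
* Interleaving the same number of rest days with exercise decays the index
  less than taking them consecutively, and the first rest day is punished
  less than later ones — the structure rewards regularity.
* The approach to a fixed point from below is underdamped: from I = 0 under
  MT = 100 the index overshoots to ≈ 717 around day 11 before settling at
  700 (within 5% by day 60). The index is monotone in *today's* MT, not in
  time.

Degenerate-input rules: α terms with A = 0 contribute 0 (no accumulated
activity exerts no decay pressure, consistent with E = 0 when A = 0); the
index is clamped at 0, taking the printed invariant I ≥ 0 over the
unclamped arithmetic, which can go negative during long rest; a new user
starts at I = 0 with empty history; missing calendar days in a ledger are
filled with MT = 0; the α series runs over the full monitoring window —
`W^{i-1}` makes truncation unnecessary. Rolling 7- and 30-day averages in
series tables are trailing means over the days available (shorter at the
start); the fuzzy factors below instead pad pre-monitoring days with zeros
and always divide by 7, matching their defining sums.

## 4. The fuzzy prompting decision

Once a day (in the morning, before activity) the engine evaluates the state
through the previous evening. The zero-activity prediction is
`I_pred = max(0, I − E(t+1))`, and four factors compare index, prediction
and the goal `G` (default 600, a high standard of sufficient activity;
400 is the lower edge of the sufficiency band):

* `P1 = PAI − I_pred` with `PAI = (Σ last 6 I + I_pred)/7` — will tomorrow's
  index sit below its own predicted 7-day average? (achievement principle)
* `P2 = G − I_pred` — is the user below goal?
* `P3 = G − mean_7(I)` — is the 7-day average below goal? (maintenance
  principle)
* `P4 = G − (I(t) + I(t−1) + I_pred)/3` — the predictive 3-day view.

Eight Mamdani rules pair (P1,P2) and (P3,P4) with High/Low antecedents;
consequents are High for rules 1, 5, 6, 7 and Low for 2, 3, 4, 8. Rule
strength is the min of the antecedent degrees, consequent sets are clipped
at the strength, and the aggregate is the pointwise max, defuzzified by
centre of area into a prompting level PL on [0, 10]; a prompt is delivered
when PL strictly exceeds 5.

**Membership breakpoints.** The published shapes are trapezoids but the
breakpoints are not printed; the defaults here are the package's
calibration. High for P1–P3 rises over [0, 100] (two minimum-progress
units) and for P4 over [0, 50] (one unit); Low is the mirrored falling ramp
on the negative side ([−100, 0], [−50, 0]). The mirrored — rather than
complementary — Low is deliberate: it leaves a dead zone at 0 where neither
set is active, and it is what makes the two canonical behaviours come out
right. A user at the comfortable fixed point I = 700, m = 100 has factors
(85.7, 0, −100, −66.7); only Low-consequent rules fire and PL ≈ 2.04 — no
prompt. A fully inactive user has factors (0, 600, 600, 600); only rule 5
fires (High) and PL ≈ 7.96 — prompt. With a complementary Low, the
inactive user's P1 = 0 would fire rule 3 (Low consequent) at full strength
and the aggregate would defuzzify to exactly 5: no prompt for a user who
has done nothing, which contradicts the mechanism's purpose. All
breakpoints, the goal, the threshold and the quantisation are configurable.

**Quantisation.** The output universe is sampled at `n_grid = 1001` levels
taken as midpoints of equal cells. An endpoint-spaced grid overweights the
two universe edges by half a cell and biases the plain-sum centroid by
≈ 2.5 × 10⁻³; midpoints reduce the discretisation error below 10⁻⁶ against
a dense-grid oracle. If every membership degree is zero (the dead zone), PL
is defined as 0.

**Monotonicity is local, not global.** Because rules 2, 3 and 6 mix High
and Low antecedents across factors, PL is not monotone in every factor
separately (e.g. raising P4 with P3 high first silences rule 6 before rule
5 takes over). What holds, and is property-tested: PL is non-decreasing
along a worsening maintenance deficit, and across constant-activity fixed
points the deliver flag flips exactly once — prompts for every fixed point
up to m = 90 (I = 630) and none from m = 95 up. That a user can be prompted
with a 7-day average slightly *above* 600 is the prediction at work: their
zero-activity index for tomorrow dips below goal.

**Prompting value.** When a prompt is delivered, the suggestion is
`PV = max(progress, mean_7(I) − I + E(t) + progress)` MET·min, where
`ps = mean_7(I) · PL/100` and `progress = max(50, ps)`; 50 MET·min is 10
minutes of moderate walking, the minimum worth suggesting. The gap term
uses the current day's threshold `E(t)` exactly as the method defines it
(not the predicted `E(t+1)` used in `I_pred`; the asymmetry is preserved
as printed). The outer max keeps a delivered suggestion positive even when
the index sits above its own average. The inactive new user receives
exactly PV = 50.

## 5. The closed-loop simulator

Exercise arrives as a compound Poisson process: daily session counts are
Poisson with rate `sessions_per_week / 7`, session durations exponential
with mean `mean_duration`, intensity fixed at `mean_met`. The defaults —
5 MET, 30 min, 3 sessions/week — give a mean of 64.3 MET·min/day, an
insufficiently active user whose 30-day average settles well below the 600
goal. This parameterisation (per-day arrivals, exponential durations) is
one consistent reading of a Poisson activity model matching those three
averages; arrival structure within a day is not modelled.

With prompting on, the decision engine runs each morning on yesterday's
state; if it delivers and an independent Bernoulli compliance draw
succeeds, the prompting value *replaces* the day's generated activity
(replacement, not addition — the simulated user does what the prompt says
instead of what they would have done). At compliance 1 the 7-day average
climbs monotonically to the goal (reached around day 34 when starting from
nothing with no background activity) and holds above it; at compliance 0
the schedule passes through untouched. All draws for a run are taken up
front under one seed, so a run is fully reproducible and the generated
schedule is identical with prompting on or off.

Problem sizes used in the shipped checks — 20 seeds × 60 days per
simulation regime, a 70-day deterministic schedule at the WHO minimum
(five consecutive 150 MET·min days per week, which settles at a 7-day
average of ≈ 717, comfortably above the 400 sufficiency edge), and 200
traces per class (5000 windows) for cross-validation — were chosen as the
smallest runs at which the stochastic summaries are stable across seeds.

## 6. Known limitations

* Membership breakpoints are calibration choices, not published values;
  conclusions about borderline prompting (PL near 5) depend on them.
* The synthetic signal model has a fixed gait harmonic structure and white
  noise; it does not emulate real device noise spectra, posture changes or
  non-locomotor activities, so classifier accuracies on it do not transfer.
* The compliance model is a single Bernoulli knob; no behavioural dynamics.
* MET values are category midpoints; MT is only as good as the window
  classification feeding it.
* The tree is trained per dataset; no pruning or cross-device calibration
  is attempted beyond the minimum leaf size.
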