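---
title: "Queueing policies for a single CT scanner: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Queueing policies for a single CT scanner: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctqsim)
```

## The system

One CT machine performs ordinary scans for three patient classes over a
13-hour working day (minutes 0–780, i.e. 8:00–21:00):

* **GP** — general, appointment-based patients; waiting-time threshold
  40 min;
* **UP** — urgent patients, 70 % of the emergency stream; threshold
  20 min;
* **EP** — emergency patients, the remaining 30 %; always served at the
  highest priority.

The simulator is a terminating-replication discrete-event model: each
replicated day starts empty, arrivals stop at closing, and the scanner
works overtime until the queue drains, so the daily examination quantity
equals the daily demand.  Days are independent; indicators are averaged
across days and reported with Student-t 95 % confidence intervals
(`summarize_replications()`).

Modelling assumptions, stated once:

* **Non-preemptive service.**  An arriving EP never interrupts an exam in
  progress: exams are short (1–7 min) relative to the thresholds, so
  preemption would buy little and is clinically unrealistic mid-scan.
* **No balking or reneging** — every arrival is eventually served.
* **Continuous time, integer service minutes.**  Arrival times are real
  minutes; durations are drawn from discrete empirical tables.
* **Deterministic tie rules.**  At equal timestamps a service completion
  is processed before an arrival; simultaneous arrivals keep draw order.
* **Empty start.**  Whether the historical days carried overnight backlog
  is unknown; we assume none, consistent with treating each day as one
  terminating replication.

## Input distributions

Examination durations use built-in empirical tables
(`gp_duration_dist()`, `ep_duration_dist()`):

```{r durations}
gp_duration_dist()
ep_duration_dist()
```

GPs average 2.26 min (support 1–4), the emergency stream 3.195 min
(support 1–7); urgent patients use the emergency table because they are
drawn from the same stream.  The emergency stream arrives as a Poisson
process with mean interarrival 7 min by default, each arrival labelled
urgent with probability 0.7, independently.

GP arrivals follow a nonhomogeneous Poisson process with piecewise-
constant hourly rates, realized exactly by mapping unit-rate exponential
epochs through the inverse cumulative intensity.  This is the simplest
process that matches an empirical arrival pattern at the level of daily
counts and congestion, which is all the calibration targets constrain.

## The synthetic arrival profile and its calibration

The real historical GP arrival pattern is not available, so
`default_profile()` ships a synthetic stand-in: 13 hourly rates summing
to 162 expected GPs/day with a pronounced morning peak in which arrivals
temporarily exceed scanner capacity, a quieter afternoon and a sparse
evening.  The peak is essential: at roughly 245 patients/day total, the
scanner's utilisation is about 0.85, and a *stationary* stream at that
load produces mean GP waits of only ~15 min.  Hour-long waits at this
throughput can only come from a transient overload that builds a backlog
which drains over the rest of the day.  We verified the converse as well:
flatter profiles with a slowly draining afternoon can also reach hour-long
mean waits, but only at loads that push the daily total far above the
feasible band, so the peaked shape is essentially forced by the pair of
calibration targets.

`calibrate()` then matches a target congestion level:

1. bisect a scalar multiplier on the GP rates until pilot replications of
   the **base** discipline reproduce the target mean GP wait (default
   66.8 min) — GP wait is monotone in GP load, so bisection is safe;
2. if the expected daily total (default 245) is off, adjust the emergency
   stream's mean interarrival within [7, 9.3] min and repeat.

The admissible interarrival range reflects a genuine ambiguity in the
source statistics: the stated exponential "parameter 7" implies ~111
emergency-stream patients/day, while the reported 34.2 % emergency share
of 245 implies ~84/day (mean ≈ 9.3 min).  With the default profile the
targets are met at the 7-min end, which also reproduces the historical
~2.5-min EP wait under the base discipline.

Numerical choices: pilots use 800 replicated days per candidate (daily
mean GP wait has a standard deviation around 35 min, so smaller pilots
leave the calibrated congestion off-centre by several minutes of pure
stream noise); the bisection aims at one eighth of the ±10 % wait
tolerance; infeasible targets (e.g. zero wait at positive load) raise an
explicit calibration error after a bounded number of evaluations.
Calibration is deterministic given its seed, and recalibrating an
already-calibrated profile starts from the incumbent multiplier, so it
converges immediately (idempotence).

## The three disciplines

All disciplines share one event kernel (`simulate_day()`); they differ
only in where an arrival is inserted into the ordered waiting list and
which waiting patient is dispatched at a service completion.

**Base (severity-ordered class priority).**  An arrival joins immediately
after the last waiting patient of the same or higher severity
(EP > UP > GP): the emergency stream wedges before all GPs, FIFO within
class.  `up_as` chooses the urgent patients' rank on the three-class
stream: `"EP"` (default) merges them with EPs into one emergency class —
the historical discipline, under which UP and EP waits coincide;
`"UP"` keeps the split ranks (then an arriving EP wedges ahead of waiting
UPs, and the discipline coincides exactly with the fixed discipline at
*P* = 0); `"GP"` demotes them — useful as a worst-case comparator.

**Fixed-interval wedging.**  GPs join the tail; EPs join after the last
EP.  An arriving UP finds the last waiting UP (else the last EP, else the
queue head) and, if more than *P* GPs trail that marker, wedges exactly
*P* GPs past it; otherwise it joins the tail.  "More than *P*" is strict,
and the patient in service never counts.  *P* ranges 0–10: with mean GP
exams of ~2 min, ten wedged GPs already approach the UPs' 20-minute
tolerance.

**Dynamic (aging) priority.**  Arrivals join the tail; at each dispatch
the patient minimising `f` is served, with `f = 1` for EPs and
`f = threshold / wait` clamped below at 1 for UPs and GPs.  `f` is
evaluated lazily at dispatch instants only; because `f` is a fixed
monotone transform of the wait, the induced order is invariant to when it
was last refreshed.  A zero wait maps to `f = Inf` (the limit of
`threshold/wait`): a just-arrived non-emergency patient outranks no one.

### Tie-breaking at equal priority

Every patient at or beyond its threshold sits at `f = 1`, so the
tie-break among them is a genuine design choice the priority formula does
not determine.  Four rules are implemented (`tie_break`):

* `"class"` (default) — severer class first, then earlier arrival.  An
  urgent patient reaching 20 min jumps all over-threshold GPs; emergency
  patients effectively retain absolute precedence.  This is the only rule
  we found whose behaviour is consistent with both of the reported
  properties of the historical system's dynamic-priority experiment:
  EP waits stay at the head-of-queue minimum (~1.5 min) *and* mean UP
  waits remain inside the 20-minute threshold even under heavy
  congestion.
* `"deadline"` — EPs first; UPs and GPs at rank 1 ordered by the time
  they crossed their threshold (`arrival + threshold`).  This is what a
  rank queue produces if promotion re-inserts a patient at the tail of
  rank 1.  It delays UPs past their threshold under congestion.
* `"ep_fifo"` — EPs first, then earlier arrival regardless of class.
* `"fifo"` — earlier arrival outranks everything at equal `f`.  Under
  congestion this queues EPs behind long-waiting GPs, which no reported
  behaviour of the real system supports; it is retained because it is the
  literal reading of "over-threshold patients share the EPs' rank", and
  because with both thresholds sent to zero it degenerates to global
  FIFO — a useful structural check.

Sub-threshold comparisons are unaffected: a UP with wait `w` outranks a
GP with wait `w_g` exactly when `w_g < 2 w`, a direct consequence of the
20/40 threshold ratio.

## Output indicators

Per day: mean waits per class and overall (the overall mean is the
count-weighted mean of the class means, an exact identity), satisfaction
rates — the fraction of a class waiting within (inclusively) its
threshold, with EPs excluded (threshold effectively infinite) — the daily
examination quantity, and the fraction of UPs beyond their threshold.
Patients served after closing count toward their day.  A day with no
patients of a class yields `NA` for that class's indicators and is
excluded from that indicator's replication summary.

Policy comparisons (`compare_policies()`) run every discipline on
identical arrival and duration streams: all randomness derives from
substreams of `(master_seed, rep, stream)` fixed before the policy acts,
a classical variance-reduction device for ordinal comparisons.  The
common-random-number contract is enforced — combining runs with different
master seeds is an error.

## What the generator does and does not emulate

The synthetic profile reproduces, after calibration, the *mean* historical
congestion: GP waits near 66.8 min, ~245 examinations/day, EP waits near
2.5 min under the base discipline.  It does **not** reproduce the
historical wait-time *distribution*: a single smooth morning peak yields
more short waits (arrivals early in the ramp) and a thinner mid-range than
the historical pattern, which the feasibility analysis above shows cannot
be widened without breaking the daily-total target.  Consequences flow
downstream: policy *orderings* (which discipline helps whom, monotone
trends in *P*) are robust, but cell-level magnitudes that depend on the
shape of the wait distribution — notably the exact size of the dynamic
policy's GP-wait reduction and the dynamic UP mean wait — land at the
conservative end of their plausible ranges.  Passing tests therefore
demonstrate faithful mechanics and calibrated mean congestion, not a
distributional match to any particular historical stream.  Day-of-week
effects, seasonality and overnight backlog are out of scope.

## Problem sizes

The shipped experiments use the scale of the original study: 100
replicated days per policy, ~240–270 patients/day, with 800-day pilot
replications inside the calibration.  A full calibration plus a 13-policy
common-random-number sweep at 100 days runs in well under a minute; the
event kernel processes a day in a few milliseconds.

## Known limitations

Single scanner only (no multi-machine synergy); no preemption, balking or
reneging; priority labels beyond the ordered list are not modelled (the
wedging case analysis is unambiguous at the position level, and the
numeric labels sometimes attached to it are contradictory); and the
arrival stand-in limitation described above.
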