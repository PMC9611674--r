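---
title: "Event-driven digital twins for the banana cool chain: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Event-driven digital twins for the banana cool chain: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cooltwin)
```

## The problem

Refrigerated banana shipments are monitored by temperature sensors, but the
quantities that matter commercially cannot be read off a sensor: how
efficiently is this particular container cooling, how much heat are the
fruit producing during artificial ripening, and how many days of *green
life* — the time until spontaneous ripening makes the fruit unusable for
commercial processing — are left. These are outputs of mathematical models
that must run *live*, updating with every sensor message, switching on and
off as the shipment moves through its life cycle (packing, ocean
transport, harbor handling, ripening), and answering operator queries
about the future ("what will the temperature be on arrival?", "what do we
gain if we lower the setpoint by half a degree?").

`cooltwin` implements a desk-scale digital-twin runtime for exactly this
kind of workload: a publish/subscribe topic log, a configuration-driven
wrapper framework that connects *updateable* models to the stream, the
four banana-chain models, and a synthetic scenario generator so the whole
system can be exercised and tested without any external infrastructure or
proprietary voyage recordings.

## Architecture

### Enriched streams

Every shipment owns a linear chain of topics. Sensor readings, life-cycle
events and queries enter at `Transports_Shipment_<ID>_Sensors`. Each model
subscribes to exactly one topic, copies *everything* it receives to its
output topic, and appends its own results as namespaced fields
(`CoolIdent.k_M`, `RipeHeat.q`, ...). Downstream models therefore see the
complete history — raw sensor values plus all upstream estimates — on a
single topic, which eliminates the synchronization problems of reading
from several streams at once. The cost is data duplication along the
chain; at desk scale this is irrelevant, and at deployment scale it is a
storage rather than a latency concern.

Two structural invariants follow directly from this design and are
checked after every run by `check_run()`:

* **stream continuity** — one output message per input message, per model;
* **enrichment conservation** — the input payload is a subset of the
  output payload, values unchanged.

### Configuration and life cycle

Which models run for a cargo type, how their topics chain together, and
how transport events translate into model commands is pure configuration
(YAML, one section per cargo type). Topic patterns contain an `#ID` token
replaced by the shipment number when a plan is instantiated, so every
shipment gets an isolated topic chain. Announcing a plan publishes one
`MODEL_CONFIG` message per model to the `Model_Config` topic; model
handlers filter announcements by model name and spawn one wrapper
instance per shipment. Duplicate announcements are suppressed by the
(shipment, model) key, which makes handler processing idempotent under
at-least-once delivery.

Each wrapper instance runs a phase machine

```
WAITING -> COLLECTING -> ARMED -> ACTIVE -> STOPPED
```

with shortcuts `WAITING -> ACTIVE` (models that need no collector phase)
and `COLLECTING -> STOPPED`. The command vocabulary is closed
(`Start_Collect`, `Stop_Collect`, `Start_Model`, `Stop_Model`), so the
machine is small enough to verify exhaustively; commands that are illegal
in the current phase are logged and ignored rather than applied. The
`ARMED` phase holds a model between the end of its collector phase
(`Arrive_Transport`) and its activation (`Start_Ripening`) — the ripening
model spends the harbor gap there. A model that is not ACTIVE still
forwards every message unchanged, which keeps the chain alive for
downstream models whatever the phase pattern; the instrumented call log
proves after every run that `step()` ran only in ACTIVE and `collect()`
only in COLLECTING.

### Sampling checks and gap filling

Sensor streams are nominally periodic (default 1 h). The generic wrapper
classifies each incoming sample against the nominal interval with a ±10 %
tolerance band: inside the band it is processed normally; a longer
interval is a *gap*, filled by feeding the last known payload to the model
at each missing nominal tick (at most `max_fill = 48` ticks, beyond which
the gap is logged as a data outage and the model simply re-anchors on the
next good sample); a non-advancing timestamp *or* an interval shorter than
the lower band edge is rejected — dropped from model processing but still
forwarded, so continuity holds. Treating too-fast samples as rejects
rather than a fourth category keeps the classification total with three
outcomes; out-of-order delivery across topics is not modeled, since the
broker is a strictly ordered log.

## The four models

The package's models are deliberately the simplest forms consistent with
the behavior the chain requires; each sits behind the same three-method
wrapper contract (`sw_collect`, `sw_step`, `sw_predict`), so a richer
model can be swapped in without touching the framework.

### Cooling model and parameter identification

Box temperature is modeled first order against the supply air, stepped
explicitly at the sampling interval:

$$T_{i+1} = T_i + \Delta t\,\bigl(-k_M (T_i - T^{supply}_i) + q\bigr)$$

with cooling efficiency $k_M$ (1/h) and heat production $q$ (K/h; the
fruit's heat capacity is absorbed into $q$, avoiding an unidentifiable
extra parameter). The explicit scheme requires $\Delta t\,k_M < 1$, which
is enforced. During cooling $q \approx 0$ (ripening has not started), so

$$y_i \equiv \frac{T_i - T_{i+1}}{\Delta t} = k_M\,x_i, \qquad
  x_i \equiv T_i - T^{supply}_i$$

is a regression through the origin; the estimator keeps the running sums
$S_{xx}, S_{xy}$ and reports $\hat k_M = S_{xy}/S_{xx}$. If ripening heat
were in fact present during estimation it would bias the estimate
(positive residual); this is documented behavior, not corrected. The
estimate is flagged **stable** only after (a) at least 72 h of data —
three days of cooling — and (b) a relative spread of the estimate below
2 % over the trailing 24 h window; the spread rule is this package's
concretization of "stable", and both numbers are configuration keys. With
identical box and supply temperatures there is nothing to identify;
24 uninformative samples raise an identifiability error.

### Temperature prediction

`predict_temperature()` iterates the same recursion with $q = 0$ from the
current box temperature, holding the supply at a constant — by convention
the mean of the last 24 supply readings, i.e. the last known operating
level — and returns one value per hour until the estimated arrival. Using
one shared recursion for generation, estimation and prediction means a
noiseless simulated voyage is predicted *exactly*, which pins down every
plumbing error in the chain; real-data accuracy is of course a property
of the model, not of the plumbing, and is outside what these tests can
show.

### Ripening-heat observer

Once $k_M$ is known, the heat production is observable by algebraic
inversion of the cooling model:

$$\hat q_i = \frac{T_{i+1} - T_i}{\Delta t} + k_M\,(T_i - T^{supply}_i).$$

The raw $\hat q$ inverts the generator exactly (sample-wise, to float
precision, for arbitrary $q(t)$ sequences — a property test). The
*reported* `RipeHeat.q` is a 5-sample moving average of the raw values,
clipped at zero with a logged notice, because on real (noisy) data the
raw inversion amplifies measurement noise by $1/\Delta t$; the raw value
is also published (`RipeHeat.q_raw`). The smoothed value lags the raw
series by half a window.

### Green life

Green-life consumption follows a Q10 rate law:

$$r(T) = Q_{10}^{(T - T_{ref})/10} \quad\text{days consumed per day},
\qquad D \mathrel{+}= r(T)\,\frac{\Delta t}{24},
\qquad \mathrm{remaining} = GL_0 - D.$$

Defaults $GL_0 = 28$ d, $Q_{10} = 3$, $T_{ref} = 13\,^\circ$C are
plausible configuration values for bananas, not measured constants, and
live in the `models:` section of the configuration file. The dose $D$ is
additive by construction (one-pass integration equals any split — a
property test to $10^{-12}$). On a query, the model continues the
integral over the predicted temperature array and reports the remaining
green life at arrival; if it crosses zero inside the horizon the crossing
hour is located by linear interpolation. The hindsight reference used in
the tests feeds the *measured* series through the same integrator, so a
prediction fed the measured series must reproduce it exactly.

### What-if scenarios

A query may carry a setpoint override (absolute or delta). The predictor
then publishes two temperature arrays — baseline supply and override —
and the green-life model reports both outcomes and their difference in
days. Overrides below the chilling floor (default 12.5 °C) are computed
but flagged, since bananas suffer chilling injury at low temperatures; in
practice the operational freedom to lower the setpoint is small. On the
reference voyage, a −0.5 K override queried 1.5 days after transport
start gains about 0.65 days of green life (recomputed by
`scripts/acceptance.R`), consistent in magnitude with the roughly one day
per half degree observed in cool-chain practice for early queries.

## The scenario generator

`build_scenario()` synthesizes what the models are meant to face: warm
loading (26 °C), cooling transport toward a 13.2 °C setpoint over 14 days,
a 12 h harbor gap with cooling off (relaxation toward 18 °C ambient at
0.02/h — cooling is simply "interrupted", so this is a modeling choice),
then 4 days of ripening at $q = 0.3$ K/h, with Gaussian noise
(σ = 0.05 K default) on both published temperatures, hourly sampling, and
life-cycle events at the phase boundaries. All values are synthetic study
conditions chosen as realistic for the trade; the setpoint sits in the
customary 13.0–14.4 °C banana range.

One generator choice deserves emphasis: the *published* (noisy) sample is
the state from which the next true step proceeds, i.e. sensor noise is
treated as a small process disturbance rather than pure measurement
error. This keeps the measured series exactly consistent with the model
recursion — noiseless runs are exactly identifiable, and the
least-squares estimator faces exogenous noise only in the response, not
an errors-in-variables problem it does not model. What passing tests
therefore show is that the chain is *internally* exact; they cannot show
robustness to sensor biases, drifts, or model misspecification, which
only recorded voyages can.

Playback decouples logical time (hours, carried in every message) from
wall-clock speed: the default mode replays as fast as possible and is
fully deterministic under the scenario seed (the generator saves and
restores the caller's RNG state); wall-clock mode paces at a configurable
rate — hourly samples at 10 messages per second per shipment, the classic
accelerated-playback shape — and is used for latency reporting only.
Latency (publish-to-final-result, matched by a correlation id) is a
property of the host, not of the models, and is reported, never asserted.

## Numerical and testing choices

* Problem sizes: the test suite runs one full reference voyage
  (451 hourly samples through the four-model chain), a 10-shipment ×
  ~100-message load shape executed twice for replay determinism, a
  20-point $(k_M, \Delta t)$ recovery sweep, and a 200-replicate noise
  study — all chosen to exercise every code path in well under a minute.
* The noise study (RMSE of $\hat k_M$ versus window length 24/72/240 h,
  σ = 0.1 K) runs at slow cooling, $k_M = 0.01$/h. At the reference
  0.05/h the thermal transient is over after about three days, so the
  longer windows add essentially no information and the comparison
  degenerates to a flat line within replicate noise; at 0.01/h the
  cool-down spans the full 240 h and the expected
  monotone-improvement property is actually informative. The value lies
  inside the 0.01–0.2/h range over which exact recovery is separately
  verified.
* JSON encoding writes numbers at full precision (no rounding), so topic
  dumps replay byte-identically; this is what the determinism tests
  compare.
* Degenerate inputs: zero-length prediction horizons yield empty arrays;
  `dt = 0` green-life updates are no-ops; queries without an arrival time
  are answered with an error field rather than dropped, preserving
  continuity.

## Known limitations

* The broker is an in-memory, single-partition ordered log. Adapters to
  external brokers can implement the same publish/subscribe contract, but
  consumer groups, replication and exactly-once semantics are out of
  scope.
* Only linear model chains are supported; meshed topologies must be
  rearranged into a chain (which the enriched-stream design makes
  possible, since every model sees all upstream fields).
* The model equations are intentionally minimal concretizations: first
  order thermal dynamics, regression-through-origin estimation, algebraic
  observation, Q10 dose. Kalman-filter observers, respiration-dependent
  heat models and humidity effects are natural extensions behind the same
  wrapper contract.
* Green life before transport start is not integrated (the model arms at
  `Start_Transport`); warm pre-transport storage is invisible to it.
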