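---
title: "Simulating an immunisation-service digital twin: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating an immunisation-service digital twin: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinvax)
```

`twinvax` simulates the monitoring loop of an immunisation service — storage
temperature sensing, alerting, store-and-forward telemetry, vaccination
reminders and coverage — as a single deterministic discrete-event system.
This vignette documents the models behind each component, the parameters
that matter, and the design decisions taken where the problem was genuinely
open.

## The event engine

Everything runs on a minimal discrete-event core. Time is measured in
real-valued **minutes** since scenario start, a unit in which the sensing
cadence (hourly), window length (5 min) and reminder leads (whole days)
all convert exactly. Events are dispatched in strict `(time, priority,
insertion order)` order; the priority layering (regime switches before
buffer flushes before reminders and dose administrations before sensing
windows before transmissions) makes same-instant interactions — e.g. a
failure beginning exactly on a window boundary — well defined and
replayable.

Every stochastic component draws from its own named RNG stream
(`thermal/<unit>`, `population`, `adherence`), each derived
deterministically from the scenario seed. Streams are mutually
independent, so adding a second refrigerator never changes the first one's
temperature path, and two runs of the same configuration produce
byte-identical output bundles.

## Thermal model

No physical heat-transfer model of an ice-lined refrigerator is attempted.
Storage temperature is modelled as an Ornstein–Uhlenbeck process — the
simplest continuous-time process with a stable operating point and
Gaussian fluctuations — relaxing toward a drift target `m` at rate θ:

$$T' = m + (T - m)e^{-\theta \Delta t} + \sigma\sqrt{\tfrac{1 - e^{-2\theta \Delta t}}{2\theta}}\,\varepsilon,
\qquad \varepsilon \sim N(0,1).$$

The *exact* discretization is used rather than an Euler step, so the update
is unbiased at any step size and the stationary law is exactly
$N(m, \sigma^2/2\theta)$ regardless of how the simulation subdivides time.
An equipment malfunction is a switch of the drift target from the setpoint
μ to the ambient temperature for the failure interval; recovery switches it
back. This reproduces the qualitative failure signature that matters for
alerting — an abrupt, sustained drift out of the cold-chain band — without
claiming fidelity to any particular refrigerator.

Defaults: μ = 5 °C (mid-band), θ = 0.5 h⁻¹ (a ~2 h relaxation time,
plausible for a lined refrigerator), σ = 0.15 °C, ambient 25 °C. Under
these values the stationary SD is σ/√(2θ) = 0.15 °C, so a stable unit stays
within the 3–7 °C alert band with overwhelming probability (≈ 13 SDs of
headroom) — the "stable" preset is alert-free by construction, not by
filtering.

## Sensing, classification, episodes

Sensing follows the monitored-service cadence: once per hour, a 5-minute
window of readings every 30 s (11 readings), reported as the window
**mean**. The stored record — not the instantaneous trace — is what gets
classified, because the record is what the twin actually receives; this
resolves the open question of whether alerts compare means or instants.
Classification is strict: a low alert iff value < 3 °C, a high alert iff
value > 7 °C; exactly 3.0 and 7.0 are normal, reading "falls below" /
"exceeds" literally.

Excursion **episodes** are maximal runs of identically-classified
out-of-band records. Missing windows (telemetry gaps) should not split an
ongoing excursion into spurious fragments, so a run bridges a gap of one
missing window; two or more missing windows end the episode (the state of
the unit is genuinely unknown for over two hours). Exactly one alert is
emitted at each episode onset; the unit re-arms once a normal window is
seen. Alert messages are the direction-specific templates
(`"Alert: Temperature below 3°C. …"` / `"… above 7°C. …"`), chosen over the
composite "below 3°C or above 7°C" variant because the direction-specific
form is what both worked examples use; thresholds are interpolated from the
active configuration.

The alert **response time** is anchored at the first instant the *true*
temperature leaves the [3, 7] °C band, not at the first out-of-band record,
so sensing cadence shows up as measurable latency: with the link up the
detection component is bounded by the inter-window gap plus the window
length (65 min under defaults), and buffering delay during outages adds on
top. To localize true crossings between windows the thermal state is
advanced in 5-minute sub-steps across the inter-window gap (the exact
discretization makes this free of bias; it only refines the trace).

## Telemetry

The sensing-to-twin link has configurable outage intervals. During an
outage, records and alerts enter a bounded FIFO buffer; on reconnection the
buffer flushes in order, stamping `delivered_at` with the reconnect time and
leaving creation timestamps untouched. On overflow the **oldest** record is
dropped and counted: for a state-mirroring twin the freshest observation is
worth more than the oldest, and the drop counter preserves accounting
(`offered = delivered + buffered + dropped` holds at every instant). Alerts
created during outages are buffered like any record, so their response
times honestly include the outage. Persistence technology (SQLite etc.) is
out of scope; only the queue contract is modelled.

## Population, schedule, reminders

The synthetic population realizes a fixed seven-stratum age design — under
1 year (3), 1–6 (7), 7–9 (3), 10–19 (8), 20–39 (23), 40–59 (28), 60+ (28);
100 individuals — with birth dates uniform over each stratum's admissible
age range at the scenario start date. The design is treated as a fixture:
the per-stratum counts come from a restricted source registry and cannot be
re-derived, but their total is checkable against Cochran's
finite-population-corrected minimum sample,
$n = \lceil n_0 / (1 + (n_0-1)/N) \rceil$ with
$n_0 = z^2 p(1-p)/e^2$: at N = 3,527, 95 % confidence, 10 % margin and the
maximum-variance choice p = 0.5 (nothing is known about the estimated
proportion), n = 94 ≤ 100. Largest-remainder rounding (ties to the earlier
stratum) is used wherever a real-valued allocation must become integer
counts, because it is exact in total and order-deterministic.

The default schedule fixture is deliberately illustrative — BCG dose 1 at
30 days, Hepatitis B at birth and 60 days, an adult tetanus booster — since
the full national calendar is not enumerable here; any schedule can be
supplied as a CSV of (antigen, dose index, due age, type).

Reminder ladders: 7/15/30 days before the due date for patients under
1 year, 30/60/90 days otherwise. Three boundary decisions were open and are
resolved as follows. (1) "Over 1 year" means age ≥ 1 year *at the alert's
emission date*, evaluated per lead, so a child crossing their first
birthday mid-ladder receives each alert under the ladder appropriate to
their age on that day. (2) Leads whose emission date precedes enrollment
are skipped — a patient enrolled 60 days before a deadline gets the 60- and
30-day alerts, not a stale 90-day one. (3) An entry whose leads have all
passed (including overdue entries) gets exactly one immediate alert at
enrollment; the overdue message variant ("… is overdue for the … vaccine!")
is this package's own wording, since no canonical overdue text exists.
Reminders route to the patient — or to the legal guardian when the patient
is a minor (< 18 years) — plus the immunisation team and unit manager;
temperature alerts go to the three staff roles. Channels (SMS/WhatsApp) are
recorded as intent metadata only.

Coverage denominators include only patients already past an entry's due
age, and an empty denominator reports `null` rather than zero — a ward full
of newborns has undefined, not zero, BCG coverage. Dose administration in a
scenario is a Bernoulli adherence draw (default 0.9) on each due date
falling inside the horizon, against a finite stock ledger; out-of-order
doses and empty stock are rejection errors.

## Scenario presets and problem sizes

Three presets mirror the study conditions; each differs from `stable` only
in the keys it changes. The condition *classes* are given but their
parameters are not, so the presets fix them as package choices: the
malfunction preset fails unit `ILR-1` for 48 h starting on day 2 (long
enough for the OU drift at θ = 0.5 h⁻¹ to cross 7 °C within the first
sensing interval and to reach ambient); the outage preset cuts the link for
6 h on day 2 with the default 10,000-record buffer, which is ample (a unit
generates 6 records in 6 h), so conservation with zero drops is the
expected outcome. The default horizon is 7 days — 168 sensing windows per
unit — which exercises every reminder lead boundary while keeping a full
scenario run in the low seconds; the property suites use 1,000 randomized
status streams for the episode–alert bijection, 10⁵ OU steps for
stationary-moment recovery (within three standard errors, with
autocorrelation-adjusted standard errors), and randomized outage schedules
for telemetry conservation.

## What the generator does and does not emulate

The synthetic data reproduce the *structure* of the monitored service: the
age stratification, schedule arithmetic, sensing cadence, threshold
geometry and buffering behaviour. They do not emulate real thermal
dynamics (door openings, compressor cycles, thermal mass), real adherence
behaviour (socio-economic covariates of non-compliance), seasonal or
campaign effects, or registry data-quality problems (late or missing dose
records). Passing tests therefore demonstrate that the monitoring *logic*
— detection, deduplication, ordering, conservation, coverage accounting —
is correct under the stated models, not that any particular facility will
see these latencies or coverage figures.

## Known limitations

* The thermal model is phenomenological; excursion shapes other than
  drift-to-ambient (e.g. brief door-opening spikes) must be injected as
  explicit failure episodes.
* Catch-up scheduling beyond the single overdue alert is out of scope, as
  are EHR/HL7 ingestion, transport protocols and dashboards.
* Coverage is computed from the simulator's own dose ledger; there is no
  model of reporting delay between administration and registration.
* With very short horizons (< 1 h) no sensing window completes and the
  temperature log is empty; the indicator summary then omits stability
  statistics rather than fabricating them.
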