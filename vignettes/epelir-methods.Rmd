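---
title: "Scoring, simulating and evaluating the EPELI virtual-apartment task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring, simulating and evaluating the EPELI virtual-apartment task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The assessment and what this package computes

EPELI ("Executive Performance in Everyday LIving") assesses goal-directed
behavior in children by having them carry out everyday errands in a virtual
apartment. The assessment consists of 13 short scenarios. Before each one, a
guide character reads out the scenario's subtasks; the child then has 90
seconds to execute them, navigating by teleport waypoints and interacting
with objects using a hand controller. There are 70 subtasks in total: 52 can
be done at any time, 13 must be done at a stated clock time (time-based
prospective memory), and 5 are triggered by a sound cue (event-based
prospective memory). Scenario order is counterbalanced — every other
participant plays the scenarios in reverse — and auditory/audiovisual
distractors are embedded in seven scenarios of the forward order and six of
the reverse order, so at the group level each scenario is played with
distractors in half of all gameplays.

`epelir` is a headless re-implementation of this assessment's measurement
layer. It contains no rendering or hardware code; its inputs are a
machine-readable task specification and timestamped gameplay event logs, and
its outputs are the eight behavioral measures plus the psychometric analyses
built on them. Because the original study's raw data are not available, the
package also includes an agent-based simulator that generates full synthetic
gameplay logs from latent behavioral traits, which lets every part of the
scoring and analysis pipeline be exercised end to end and tested against
independent oracles.

## The eight measures

Replaying a scenario log against the task specification yields, per
scenario and per session:

* **Total score** — the number of correctly performed subtasks (max 70 per
  session). A subtask completes at the event finishing its required step
  sequence; steps are matched in order within a subtask, subtasks complete
  in any order, and completion is recognized regardless of timing.
* **Task efficacy** — relevant non-waypoint actions divided by all
  non-waypoint actions during execution. An action is *relevant* iff it
  advances the next step of some not-yet-completed subtask; redundant clicks
  on an already-completed target are irrelevant.
* **Navigation efficacy** — total score divided by distance covered: the
  Euclidean path over consecutive teleport destinations plus the reach from
  the current waypoint to each manipulated object.
* **Controller motion** — summed geodesic rotation angle
  `2*acos(|<q_i, q_{i+1}>|)` over consecutive execution-phase orientation
  samples, in degrees; invariant to the quaternion double-cover ambiguity.
* **Total actions** — execution-phase object clicks (including pickups and
  drops), drum hits, and instruction-phase clicks.
* **TBPM** — time-based subtasks completed within ±10 s of their target.
* **Clock checks** — execution-phase watch-viewing events.
* **EBPM** — event-based subtasks completed within 10 s after cue onset.

Three scoring conventions deserve explicit statement because the measure
definitions alone do not pin them down; each is a documented switch with the
following default:

* *Waypoint clicks are excluded from Total actions.* The efficacy measure
  excludes them explicitly, and the action measure is framed as interaction
  with objects; counting navigation clicks would conflate the two.
* *A time-based subtask completed outside its ±10 s window still counts
  toward Total score.* Scenarios end when all subtasks are performed, which
  implies completion is recognized regardless of timing; TBPM separately
  captures timing accuracy. Likewise an event-based subtask completed
  before its cue counts toward Total score but never toward EBPM.
* *Window boundaries are inclusive* (±10 s and 10 s): a tie at the boundary
  credits the participant.

Session aggregates sum the count measures; the efficacies aggregate as
ratio-of-sums (summed numerators over summed denominators), so a scenario
with an undefined per-scenario efficacy still contributes its denominator.
A mean-of-ratios alternative is available via
`aggregate_session(..., efficacy_aggregate = "mean_of_ratios")`; undefined
per-scenario cells are excluded listwise when item matrices are built, with
the number of dropped participants logged on the matrix.

## Event timestamps and phases

Events are timestamped from scenario onset. The instruction phase occupies
`[0, instruction_duration_s]` and ends at the single `instruction_end`
event; every scoring window runs on the execution clock (timestamp minus the
instruction-end time), and the 90 s limit applies to the execution phase.
Orientation is sampled nominally at 20 Hz during execution only; the rate is
a configuration key of the simulator, not of the scorer, which consumes
whatever samples the log contains.

## The bundled task specification

The printed design fixes the totals (13 scenarios; 70 subtasks split
52/13/5; 4–6 subtasks per scenario; 90 s; 10 s windows; a 7 + 6 distractor
partition) but not the per-scenario breakdown, so the bundled default uses
one admissible layout: six scenarios of six subtasks, six of five, one of
four; one time-based subtask per scenario (targets between 35 and 80 s);
five event-based subtasks spread over five scenarios (cues between 30 and
50 s). Each scenario includes one transport subtask (pick an object up,
drop it at a waypoint in another room) and the six-subtask scenarios open
with a two-step subtask, so the replay engine's in-order step matching is
exercised by the default task itself. The floor plan — six reachable rooms,
eleven waypoints, within-room complete teleport graphs joined by doorway
edges, plus an unreachable balcony — is invented scaffolding: no navigation
topology is published, only the room inventory. Distances are metres, times
seconds.

`validate_task_spec()` enforces referential integrity and the 4–6 bound
always; the printed totals are enforced in strict mode (the default), while
`strict = FALSE` admits research variants.

## The agent simulator

The simulator stands in for child participants. Each agent is a small trait
vector with direct behavioral meaning:

| trait | unit | default | drives |
|---|---|---|---|
| `encode_p` | probability | 0.7 | which subtasks are encoded at instruction time |
| `impulsivity_rate` | clicks/s | 0.08 | Poisson stream of irrelevant clicks |
| `motor_level` | deg/s | 60 | baseline controller angular speed |
| `motor_burst_deg` | deg | 25 | extra rotation around each action |
| `nav_noise_p` | probability | 0.15 | suboptimal teleport detours per hop |
| `monitor_rate` | checks/min | 2.5 | spontaneous clock checks |
| `timing_sd_s` | s | 6 | Gaussian error of time-based execution |
| `cue_response_p` | probability | 0.8 | answering a cue within its window |
| `action_latency_s` | s | 2 | time per interaction (teleports take 0.5 s) |

Encoded any-time subtasks are executed in instruction order via
shortest-path navigation; encoded time-based subtasks at target plus
Gaussian error, each preceded by a clock check (the gating glance — a hard
Poisson gate would make a zero-error agent's perfect TBPM unattainable,
which the scoring ceiling requires); encoded event-based subtasks are
answered with probability `cue_response_p` at a cue-onset latency drawn from
an exponential truncated to the 10 s window, so `cue_response_p` is exactly
the probability of an in-window response and non-responders simply never
answer. Distractor scenarios multiply the irrelevant-click rate by 1.5.
Controller orientation follows a single-axis rotation whose per-sample step
is `motor_level/rate` plus bursts at action times; the angular-displacement
measure depends only on per-step geodesic angles, which this reproduces
exactly while keeping generation vectorized.

The population model maps covariates to traits linearly with Gaussian noise
and clipping. The default effect signs are the qualitative structure
expected of this population — girls and older children encode better and
act less impulsively, timing precision improves with age, girls check the
clock less — and the magnitudes were chosen once so that a cohort of 77
yields comfortably detectable effects; none are estimates of published
coefficients. Covariate proxies follow the same logic: the instruction
recall score is `Binomial(30, encode_p)`, the behavioral-regulation rating
analog rises with impulsivity, the metacognition analog falls with encoding,
and the global composite is their sum (ranges 0–56, 0–88, 0–144; the
printed range of the metacognition scale is internally inconsistent with
its printed mean, so these ranges are configuration, not constants).
Serial-position effects on encoding are not modeled.

What the simulator does *not* emulate matters for interpreting green tests:
there is no physical body continuity (parallel activity streams may
teleport "instantly" between interrupts), no learning or fatigue across
scenarios, no strategic reordering of subtasks, and trait-covariate maps
are linear by construction. Passing the recovery suites therefore shows the
pipeline is correct and well-calibrated under its own generative
assumptions — not that real children behave this way.

## Statistical pipeline

* **Outlier screen** — univariate first: any measure beyond 3 sample SDs
  from the group mean excludes the participant; Mahalanobis screening
  against the χ²(8) upper tail at p < 0.001 is then run on the remainder.
* **Reliability** — Cronbach's alpha over the participant × scenario item
  matrix, with sample (n−1) variances throughout; a 95% percentile
  bootstrap CI over participant resamples (default 1000; degenerate
  resamples are redrawn and counted); 0.70 as the acceptability bar.
  `alpha_drop_scan()` gives alpha-if-item-dropped, and
  `alpha_reduced_sets()` the greedy backward-elimination curve used to ask
  how short the task could be made (the published supplement does not
  specify its subset rule; greedy maximization is this package's choice).
* **Background models** — OLS per measure on age, gender (girl = 1),
  gaming background, familiarity (1–7) and headset type, with stepwise AIC
  selection in three directions: forward, backward, and combination
  (forward moves plus one-out/one-in swaps). AIC is the full Gaussian
  log-likelihood version, `n·ln(2π·RSS/n) + n + 2(p+1)`; only differences
  matter for selection, and ΔAIC is reported against the full model. Ties
  break toward fewer terms, then lexicographically, making selection
  deterministic. When both age and gender are selected, an age × gender
  interaction refit is attempted and kept only if it lowers AIC.
* **Correlations** — Pearson r between the eight measures and the three
  rating scalars, with Benjamini–Hochberg adjustment over the full 24-cell
  family and stars assigned from adjusted p.

## Numerical and design choices

* Completion matching uses a per-scenario "micro-step" machine (transport =
  pickup then drop-at-destination); when several subtasks could absorb an
  event, the earliest in instruction order wins.
* Timestamp ties in generated logs are ordered by event priority
  (scenario start, instruction end, execution events, scenario end).
* Replay is bit-for-bit deterministic; all simulator randomness flows from
  one master seed through deterministic child-seed derivation
  (per participant, per scenario, per analysis stream), all below 2³¹.
* Degenerate inputs: constant score vectors flag no univariate outliers; a
  singular covariance aborts Mahalanobis screening with a typed error;
  constant covariates are dropped from stepwise candidate sets; zero
  non-waypoint actions or zero distance give undefined (NA) efficacies, a
  value state rather than an error.

## Problem sizes used in the checks

The test and acceptance suites run at the sizes the analyses are meant for:
scoring oracle equivalence on 100 simulated scenario logs; the
Spearman–Brown closed-form check at 5000 × 13 (inter-item correlation 0.3,
implying alpha 0.8478); bootstrap CI coverage over 500 replications at
n = 77; stepwise-vs-exhaustive agreement over 100 seeded 5-candidate
problems plus 1000 replications of the single-noise-candidate rate
(asymptotically P(χ²₁ > 2) ≈ 0.157); and 100 replicate cohorts of n = 77
for planted-effect sign recovery. The replication study runs in memory;
file-based stages are exercised at smaller cohort sizes.

## Limitations

Test–retest reliability, mixed-effects modeling and normative scoring are
out of scope. The simulator is a measurement-layer testbed, not a cognitive
model; its traits are operational dials, not psychological theory. Logs
from the commercial implementation use an unpublished format and cannot be
parsed directly — the JSON-Lines schema here is this package's own.
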