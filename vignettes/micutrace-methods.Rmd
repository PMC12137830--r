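---
title: "From badge records to contact histories: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From badge records to contact histories: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micutrace)
```

## The measurement problem

Healthcare-associated infections spread along contacts: between healthcare
professionals (HCPs), and between HCPs and the surfaces and spaces of
patient rooms. Ultra-wideband (UWB) proximity badges measure these contacts
directly: worn badges exchange ranging messages, and whenever two badges are
within the contact distance threshold — six feet (72 inches), with roughly
ten-centimetre ranging accuracy — a *contact* is recorded. Stationary badges
(*anchors*) placed at fixed stations turn the same mechanism into a coarse
localisation system: each patient room carries four anchors (door, sink,
computer workstation, vitals monitor), installed so that no two anchors in
the unit are within six feet of each other, which prevents anchor-to-anchor
contacts.

The badges are imperfect instruments. They sample neighbours on a low-level
signalling cycle of a few seconds, and a higher-level processing cycle —
once every 15 seconds — decides when a contact interval opens or is purged.
Consequently matched contact durations are quantised to multiples of 15 s,
contacts shorter than the processing cycle tend to leave a *start* record
with no *end* record, and per-badge clocks drift by some seconds between
synchronising scans. `micutrace` implements the full processing chain that
turns these raw observations into analysis-ready objects, together with an
agent-based simulator that emits raw data in exactly the same format plus
the ground truth behind it, so that every stage can be validated without
access to a real deployment.

## Record formats

A raw record is a 5-field JSON array,

```
["pr014", "pr037", "datetime(2023,4,25,7,39,43)", 74, 0]
```

reporting badge, detected badge, start time of contact, sensed distance in
inches, and duration (0 = start of contact; a nonzero value marks the end
record, which carries the *start* time of its interval). Badge labels encode
roles by prefix: `b` anchors, `pr` providers, `n` nurses, `ss` support
staff. Files may be xz (LZMA) compressed; `parse_raw_records()` /
`write_records()` round-trip both forms. Datetime strings are accepted
liberally (optional quotes and spaces) and always emitted in the canonical
no-space form. All pipeline times are naive local time held as `POSIXct` in
the `"UTC"` zone; the UTC-to-local conversion applied during acquisition
(subtracting five hours) is outside the pipeline's scope.

Each day splits into two 12-hour shifts (day 07:00–19:00, even indices;
night 19:00–07:00, odd indices). Badges were handed out fresh each shift,
so badge identity is only meaningful within one shift; every history and
contact graph therefore spans a single shift.

## From raw records to contact intervals

`build_intervals()` composes three stages.

1. **Distance filter.** Records sensed at less than 12 inches are skipped
   (exclusive bound: 12 in survives). Worn badges cannot be that close;
   such records arise from badges lying together in a receptacle around
   handout and turn-in.
2. **Start/end matching.** Starts and ends match on the exact key
   (reporter, detectee, start time). A matched pair yields the end record's
   duration — a multiple of 15 s. A lone start becomes a 10-second
   substitute interval. Orphan ends (starts can be filtered or lost) are
   retained at their stated duration and logged; duplicates are
   deduplicated, and among conflicting ends the largest duration wins.
3. **Bidirectional union.** The (a,b) and (b,a) views of one contact can
   disagree by some seconds of clock drift. Overlapping spans of a pair are
   rewritten to [minimum start, maximum end], repeated to a fixpoint so
   chained overlaps coalesce, and every span is mirrored so the output is
   symmetric. The merged distance is the minimum (closest approach) of the
   constituents — a deterministic, conservative choice. The overlap slack
   defaults to 0 s (strict intersection of half-open spans) and is
   configurable because the drift magnitude is not known precisely.

All interval spans are half-open `[start, start + duration)`, which makes
window additivity exact throughout the package.

## Imputed histories and in-room inference

`impute_history()` maps each second of a shift to the set of concurrent
contacts per HCP badge. Symmetry between HCP badges is forced (the pooled
(a,b)/(b,a) spans are used), anchors never appear as primary keys — but
they remain inside contact lists, so location information survives — and
anchor-to-anchor intervals (which the placement rule should prevent) are
logged and dropped. Internally the history is sparse (per-pair second
runs); the serialised JSON materialises one entry per badge-second,
including state-only seconds with an empty contacts list, and the reader
accepts both sparse and dense files.

`annotate_inroom()` adds the door-versus-in-room heuristic: contact with a
room's *interior* anchors (sink, computer, vitals) is evidence of being in
the room, while a door contact alone is not (one may linger at, or pass
through, a doorway). The state machine per badge, scanned in time order:

* contact with an interior anchor of patient room *r* sets
  `{room = r, inroom = TRUE}`;
* a later contact with any anchor **outside** room *r* clears the state.
  We read "outside" literally: another room's door anchor clears, the
  current room's own door anchor does not. A flagged alternative reading
  (own door clears too) was considered and rejected because it would end
  episodes on every doorway pass;
* with simultaneous interior contacts in two rooms (physically possible
  through a wall, since UWB ranging is not blocked by drywall), the
  contact that began most recently wins; ties go to the smaller room
  number and are logged;
* state is null at shift start and persists between anchor contacts.

From the annotated history, `room_dwell_times()` totals inroom-true seconds
per badge and room, `transit_times()` measures gaps between consecutive
inroom episodes in *different* rooms, and `contact_graph()` builds the
weighted undirected contact graph of any window (weights = contact
seconds; additive over disjoint windows).

Note the heuristic's known bias: an HCP who leaves a room without touching
any other anchor keeps the inroom state until the next anchor contact, so
dwell times are upper estimates. This mirrors the deterministic heuristic's
behaviour on real data; no probabilistic occupancy model is attempted.

## The validation statistic

`mean_badge_count_per_bin()` reproduces the deployment's high-level
validation: for each ten-minute interval of the day, the number of distinct
HCP badges with at least one contact (HCP or anchor) in that interval,
averaged separately over day-shift and night-shift histories. A day of
600-second bins yields exactly 144 bins (24 × 6; we use the 144 consistent
with 600-second bins tiling 24 hours). With the default rosters — day
12/19/12 versus night 6/15/8 (providers/nurses/support) — day-shift counts
exceed night-shift counts away from the handover peaks, which is the
qualitative signature the statistic is designed to confirm.

## The simulator

The simulator closes the loop: it generates raw records in the exact file
format, along with the ground truth, so recovery can be measured.

**Layout.** Rooms of 16 × 16 ft line both sides of a 14-ft corridor;
each holds its four stations, placed so all anchors in the unit are more
than six feet apart (checked by `validate_placement()`). The default
scenario has 26 rooms and hence 104 anchors, all in patient rooms; corridor
(common-area) anchors at the nurse-station desks are available as an option
(`common_anchors`). Coordinates are exported in layout-image pixels at a
configurable pixels-per-foot scale (default 10).

**Mobility.** No mobility law is given for the emulated unit, so the
package defines one and treats it as a modelling choice: a semi-Markov
station-to-station process. Nurses are biased to two assigned rooms (70%
room / 25% nurse station per move, mean dwell 9 min in rooms), providers
round across all rooms in a personal order (75% / 25%, mean 4 min),
support staff split between nurse stations and sporadic room visits
(50% / 50%). Dwell times are gamma-distributed (shape 2); walks go through
the room door to the corridor walk line at 4 ft/s, so door pass-bys and
corridor encounters arise naturally. All parameters live in
`sim_scenario()$mobility`.

Two realism constraints matter for the 12-inch filter: agents stand at
arm's length (1.5–3.5 ft) from the station they use, on its approach side,
and badge-to-badge distances have a 15-inch hard-core floor (badges are
worn on the chest; bodies exclude closer approach). Without them,
zero-size point agents could sit for minutes at sub-foot distance from an
anchor and the genuine contact would be eaten by the receptacle filter —
an artifact of the 2-D point abstraction, not of the sensing model.

**Sensing.** Every low cycle (default 3 s — the signalling period is known
only to be "a few seconds", so it is a configuration choice) each badge
measures the distance to its neighbours with Gaussian noise (SD 4 in ≈
10 cm, truncated at zero). An episode of under-threshold samples opens a
contact at its first sample; a full high cycle (15 s) without a sample
purges it. The emitted duration is the sample span rounded to a multiple
of the high cycle; an episode whose span rounds to zero leaves a lone
start record — reproducing both the 15-second duration quantisation and
the lone-start phenomenon for brief contacts. The record's distance field
is the episode's median sensed distance, the robust analogue of "a
distance sensed around the time of the interval". Each badge senses each
direction independently and reports times shifted by its own constant
clock offset (uniform on ±5 s by default). Optional artifacts reproduce
deployment quirks: sub-12-inch receptacle records around handout and
turn-in, and extra powered-on unworn badges that disappear within half an
hour of shift start.

**Ground truth.** A true contact is a maximal period with true distance at
or below threshold on the sampling grid. When validating recovery, truth
episodes separated by less than a full high cycle between samples are
coalesced first — the firmware cannot see such gaps by construction — and
the 10% per-pair total-seconds check is applied to pairs of purely
sustained contact (episodes ≥ 30 s) with totals of at least 105 s, because
the per-episode quantisation bound (high/2 + low = 10.5 s) makes a 10%
guarantee arithmetically impossible below that total. Boundary recovery
(≤ 15 s for every sustained episode) is asserted without any scoping.

## Problem sizes and numerical choices

The test suite validates merging and imputation against literal
brute-force oracles (pairwise rewrite to fixpoint; per-second expansion)
on 200 random instances of up to 10 badges and 50 intervals over spans up
to 2500 s, recovery on a one-hour noiseless simulation of a 6-room unit
with 8 staff, and the day/night validation statistic on two full-roster
12-hour shifts of the default 26-room unit — sizes chosen so the whole
suite runs in about a minute while every property is exercised at
realistic density. `scripts/acceptance.R` measures the duration
quantisation on one simulated 8-room shift (~11,000 matched intervals).

Degenerate inputs are defined behaviour: empty files round-trip; a
zero-duration interval is rejected at construction; unknown badge prefixes,
unparseable datetimes and wrong-arity records report their record index
(with an optional lenient skip-and-log mode); windows outside a history
span, bin widths not dividing 86400 s, unknown anchors in a history, and
anchor labels used as history keys are all errors.

## Limitations

The simulator is a 2-D point-agent model: no walls in the radio sense, no
patient agents (patients wore no badges), no radio-propagation physics —
UWB's point is precisely that RSSI-style multipath modelling is
unnecessary. Passing tests therefore demonstrate that the *processing
chain* is correct and that recovery degrades only through the documented
sensing mechanisms (cycle quantisation, brief-contact loss, clock drift),
not that the mobility model reproduces real staff behaviour. Real
deployments add effects the simulator only sketches: staff leaving the
unit mid-shift, badges removed or unworn, anchor memory saturation, and
handover crowding beyond the simple stagger modelled here.
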