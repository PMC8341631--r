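---
title: "Building and querying origin-destination-time mobility cubes"
author: "odtcube authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and querying origin-destination-time mobility cubes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(odtcube)
library(data.table)
```

## The model

Human movement records — geotagged social-media posts, device pings —
arrive as points, but most epidemiological questions are about flows
between *places*: how many people moved from county A to county B on day
t? `odtcube` organises such flows as a sparse **ODT cube**: a map from
`(origin place, destination place, day)` to a count, held at one
geographic level of a nested ladder (block group < county < state in the
synthetic worlds used here). The cube is place-based rather than
coordinate-based — each daily origin–destination matrix is independent, so
the cube stores flow volumes, not trajectories. Slicing the cube yields
the three classical matrices: OD (flows between places over a period), OT
(outflows per origin-day) and DT (inflows per destination-day). Diagonal
cells (`O = D`) hold intra-place movements: displacements with positive
distance that never cross the place boundary.

Two extraction rules turn raw point streams into entity-level flows:

* **Single-day movement**: for an entity with at least two events on one
  calendar day, the origin is the day's first event and the destination
  the event farthest (great-circle) from that initial location.
* **Cross-day movement**: for an entity with events on two consecutive
  days, the flow runs from the mean center of day-d points to the mean
  center of day-(d+1) points, dated to day d.

Both rules discard zero-distance movements. The two flow types are
combined *presence-based*: an aggregate cube cell counts distinct
entities, so a single-day and a cross-day flow of one entity with the
same `(origin, destination, day)` collapse to one contribution.

Home-based device-count records take a different path: each record names
a home census block group, a map of destination block groups to device
counts, and a date. Here the "entity" is the home block group and the
counts are devices, not distinct people — weights **sum** under
aggregation, so a device visiting several block groups of one county is
counted once per visited block group. This asymmetry between the two
sources is deliberate and preserved: event-derived flows carry weight 1
per entity-cell, record-derived flows carry device counts.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `level` | finest | geographic level of extraction/aggregation |
| `utc_offset_hours` | 0 | day-boundary convention for event timestamps |
| source `allow`/`deny` | none | bot filtering by posting-client string |
| `min_count` threshold | none | strict `cnt > threshold` display filter |
| correlation `method` | pearson | `spearman` available |

The day boundary is a convention the data do not fix; UTC dates are the
default and a fixed offset is available. Cross-day flows are dated to the
earlier day — the alternative (the later day) is a one-line change and
does not affect any algebraic property. For the single-day rule, the
farthest-event tie is broken by the earliest timestamp, and the
destination is taken to be the farthest event itself, the only reading
consistent with defining the day's movement as the maximum displacement
from the initial location.

## Cube algebra

`rollup_spatial` re-keys cells through parent links (for FIPS-style codes
this agrees with code-prefix truncation) and sums; `rollup_temporal` bins
by ISO week or calendar month; `dice` restricts by origin set,
destination set and a **closed** date interval; the three `slice_*`
operations project one axis by summation. All of these conserve total
mass, which the test-suite asserts against brute-force nested-loop
oracles on random cubes. Flow-direction series follow the portal
conventions: `inflow` and `outflow` exclude the diagonal, `intraflow` is
the diagonal, and `in_and_out = inflow + outflow` — the diagonal is *not*
part of `in_and_out`, since intraflow is its own direction. Drill-down
below a cube's stored level is not possible from the cube alone;
recomputation from finer entity flows is the supported route, making the
information loss explicit. The classical "pivot" operation is omitted: it
has no defined semantics for this data model here.

## Downstream analyses

The monthly **mobility reduction rate** against a baseline month is
$R_i = (M_i - M_{\mathrm{base}}) / M_{\mathrm{base}}$ — 0 at the
baseline, $-0.5$ at half the baseline mass, $+1$ at double, invariant to
uniform rescaling of all masses.

The **outflow–case correlation** fixes a flow vector (total outflows from
a focal place to every other place over a window, e.g. the last days
before a lockdown) and correlates it, day by day, against the cumulative
confirmed cases of the destination places. Pearson correlation is the
default, matching the linear framing of the analysis; cumulative rather
than daily-new cases are used because the design correlates a fixed
pre-lockdown flow vector against evolving totals. Destination places
absent from the sparse cube are included with zero flow — absence of a
cell means no observed movement, not missing data. Days with fewer than
three paired places, or a constant vector, report a missing value rather
than a number.

## What the synthetic generator emulates — and what it does not

The generator produces every input the pipeline consumes, under one seed:

* a 3-level nested square-grid geography with FIPS-like nested ids
  (12-digit block group, 5-digit county prefix, 2-digit state prefix), so
  prefix truncation and geometric containment agree by construction;
* random walkers emitting jittered events (Poisson event counts per day,
  a stay-probability between events, bounded steps), with a bot fraction
  posting from known automated sources;
* home-based records with sampled destination maps and positive counts;
* cumulative case counts whose daily increments are
  `intercept + a * outflow + noise`, clamped at zero and cumulated, so a
  planted linear dependence with a computable analytic correlation.

Defaults: 50 walkers, 30 days, 12×12 fine grid over 36 counties and 4
states, 2 events per walker-day, stay probability 0.6, 10% bots, 20
records per day with ~4 destinations each — small enough to run in
seconds, large enough that every rule (eligibility, ties, dedup,
self-loops) is exercised. Event jitter keeps points at least 10% of a
cell away from every cell boundary, so floating-point noise cannot flip a
containment decision.

The ground truth is computed by a **deliberately independent oracle**: it
re-applies the extraction rules to the raw itineraries in straight-line
code using arithmetic cell assignment (not ray casting), spherical
law-of-cosines distances (not haversine) and explicit-loop means. The
duplication is the point: agreement between the two paths is evidence,
shared code would be none.

A green suite on this world therefore establishes the *logic* of
extraction and cube algebra. It does not establish robustness to what
real feeds contain and the generator omits: GPS error and coordinate
truncation, daylight-saving and mixed-timezone timestamps, multi-polygon
and sliver geographies, antimeridian-straddling points (arithmetic
lon/lat mean centers are wrong there; synthetic worlds stay away from
±180°), device churn, or provider-side stop-detection artefacts.

## Numerical choices

* Great-circle distances use the haversine form on a 6371 km sphere,
  numerically stable at short range where the law of cosines loses
  precision (the two agree to < 1 m in tests).
* Point-in-polygon is even–odd ray casting with the boundary counted as
  inside; when two polygons share a claimed boundary point, the
  lexicographically smallest place id wins — reproducibility over
  geometric fastidiousness. No spatial-geometry dependency is used; at
  desk scale a bounding-box prefilter is the only index, and the contract
  is equality with an exhaustive scan, not speed.
* The export dialect prints coordinates with fixed six decimals (≈ 0.1 m)
  and LF endings, so write → read → write is byte-stable; cell counts and
  keys round-trip exactly.
* All time intervals are closed `[start, end]` calendar-date intervals.

## Known limitations

Single-threaded and in-memory by design — the contract of the billion-cell
original is kept (sparse cells, multi-scale roll-up, the four query
scenarios, the CSV dialect) but not its distributed execution. Geography
readers expect well-formed, non-overlapping polygons; no topology repair
is attempted. Mean centers are arithmetic in longitude/latitude and the
generator keeps worlds far from the poles and the antimeridian.
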