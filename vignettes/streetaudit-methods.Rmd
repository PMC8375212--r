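---
title: "Auditing the completeness and temporal validity of municipal GIS layers with historic street-level imagery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing the completeness and temporal validity of municipal GIS layers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(streetaudit)
```

## The problem

Health-geography studies of children's physical-activity and food
environments lean on administrative GIS layers: footpaths, pedestrian
crossings, bus stops, traffic calming, parks, food outlets. Two quality
defects are endemic. First, **completeness**: councils often cannot supply
some layers at all, or supply them with large gaps. Second, **temporal
validity**: layers are provided "as is", describing the world at provision
time, with no metadata saying whether a feature existed during the study
window a retrospective cohort actually experienced. A feature installed
after the window inflates exposure estimates; a missing footpath deflates
them.

Historic street-level panoramas carry capture dates, so they can arbitrate
both defects: an auditor looking at imagery captured *inside* the window
can add features the council omitted (gap-filling) and confirm which
council features demonstrably existed then (temporal validation). This
package implements that audit pipeline end to end, together with a
synthetic town that makes every stage testable against known ground truth.

## Pipeline and model

### Road network and service areas

Centerlines (GeoJSON polylines in a projected metric CRS) become an
undirected graph: nodes at polyline endpoints, merged within a 0.5 m snap
tolerance (metre-scale data; avoids false merges), polyline endpoints
moved onto node coordinates so geometry and topology agree exactly, edge
weights equal to exact polyline lengths. Inputs whose coordinates look
geographic (degree-range values over a sub-2-unit extent) are refused with
a CRS error rather than silently producing kilometre-scale nonsense.

Homes, schools and any query points are snapped to an (edge, chainage)
location by exact point-to-segment projection, ties broken by smallest
edge id then smallest chainage. Routing allows mid-edge departure and
arrival (geocoded homes rarely coincide with junctions) by temporarily
splitting the terminal edges at the query chainage; path search is
Dijkstra on edge length.

The **network buffer** (service area) of radius $d$ around an origin is
computed analytically: with $d_u, d_v$ the network distances to an edge's
endpoints, the covered chainage set on an edge of length $L$ is
$\{c : \min(d_u + c,\; d_v + (L - c)) \le d\}$, a union of at most two
intervals cut **exactly at the distance frontier**. Including partial
edges matters: a whole-edge-only service area would bias the sampled
length and hence every downstream count. Degenerate cases behave sensibly
($d = 0$ yields the origin point as a zero-width portion).

### Activity spaces

A participant's activity space is the union of three components, kept
separately for reporting: an `r_home` = 800 m network buffer around home,
an `r_school` = 800 m buffer around the nearest school, and the portions
of the network within `corridor` = 200 m Euclidean distance of the
shortest home–school route. The defaults are the construction used for
the study cohort this tool was built around; 800 m network buffers are
also the radius most consistently associated with physical activity in
the buffer-size literature. "Nearest school" uses network distance for
consistency with the rest of the construction (Euclidean available as a
switch). The corridor is a Euclidean sausage around the route polyline
mapped back onto network edges, because sampling happens on the network;
with `corridor = 0` it degenerates to exactly the route's own edge
portions. Service areas are not clipped to administrative boundaries.

### Coordinate sampling

Audit coordinates are placed along every included edge portion
$[c_0, c_1]$ at chainages $c_0, c_0 + s, c_0 + 2s, \dots \le c_1$ with
$s$ = 35 m by default. The convention (start at the lower chainage, no
forced endpoint) makes per-edge counts a closed form,
$\lfloor L/s \rfloor + 1$ on a fresh edge, so counts are auditable.
Coincident points at junctions (within 0.5 m, matching the snap
tolerance) are deduplicated keeping the smallest edge id, so no location
is photographed twice. Points shared by overlapping activity spaces are
pooled across the cohort, recording every owning space id.

The spacing sensitivity analysis reports, per candidate spacing
(10–50 m), the number of points, the **duplicate rate** (fraction of
points whose visibility disc overlaps the previous point's disc on the
same edge — near-identical imagery) and the **miss rate** (fraction of
ground-truth features beyond the visibility radius of every point). Tight
spacings duplicate imagery; wide spacings miss features; 35 m sits at the
elbow. The default visibility radius here is 20 m, the same constant the
line-feature buffer uses.

### Imagery requests and the date filter

Each coordinate generates four requests at headings 0/90/180/270° (a full
panoramic view; the heading set is configurable). The date window is
calendar-year inclusive, 2012–2016 by default; months are used only for
tie-breaking and reporting. A pluggable provider answers
`query(lon, lat)` with available panoramas and capture dates. Per
request, the newest panorama inside the window is selected (latest year,
then largest month, then first panorama id lexicographically — newest
imagery maximises feature visibility); if none falls inside the window
the outcome is `out_of_range` with the nearest-dated panorama's year
recorded; no panoramas at all is `unavailable`. Outcomes conserve
(`in_range + out_of_range + unavailable = requested`) and headings never
affect availability. The manifest CSV (image id = coordinate id +
heading suffix, coordinates, outcome, panorama id, year, month)
round-trips exactly, and a cached provider can replay a manifest offline.
An adapter for a real street-imagery HTTP API would implement the same
provider contract; none is included.

Geographic coordinates come from a `crs_transform`. The synthetic town
uses a declared pseudo-CRS (an exactly invertible local equirectangular
plane); a full NZTM2000 transverse-Mercator transform (GRS80, Krüger
series to fourth order in the third flattening) is provided for real
New Zealand layers and is tested against a numerically integrated
meridian-arc oracle and sub-0.1 mm round-trips.

### Coding, layers, merging, validation

Coder checklists (CSV batches) are validated against the feature
dictionary and the coordinate manifest; unknown codes, unknown
coordinates and exact duplicates are reported, not fatal, and ingestion
is idempotent. Speed bumps and traffic-calming signs share one
`traffic_calming` code with a free-text subtype, and food-outlet subtypes
follow the usual place-tag vocabulary. A seeded 10% QA subset (sampled
globally, half-up sizing) supports independent re-review.

Point layers take one member per distinct coordinate where a code was
recorded. Line layers clip the network to 20 m discs around observed
coordinates — solved per segment as a quadratic in the along-segment
parameter, so a single observation on a straight edge yields exactly
40 m — and merge adjacent intervals. Gap-fill merging is a plain GIS
merge: council members verbatim, imagery members appended, provenance per
member, **no cross-provenance deduplication** (mirroring how such merges
are done in desktop GIS; a separate dedup pass can be applied
afterwards if wanted). Validation matches council points to same-code
observations within a match radius and reports rates rounded half-up to
integer percent (feature summaries use one decimal); half-up rounding is
used everywhere a percentage is printed so reported rates are
reproducible across platforms.

Because observations live at *imagery coordinates*, a feature seen from a
panorama can lie up to the visibility radius away from the observing
coordinate. The match radius should therefore be at least the coder
visibility radius whenever observations come from imagery; the end-to-end
evaluator defaults to exactly that. The 20 m default on
`temporal_validate()` is the right scale when observations are already
feature-located (e.g. re-audits of point layers).

## The synthetic town

The generator emulates the study's inputs, not its imagery pixels:

* **Network**: an `nx × ny` grid of 100 m blocks (urban core) with a
  configurable fraction of bent, longer "irregular" edges and half-weight
  feature placement on the fringe, emulating a mixed urban–rural town.
* **Features**: per-code counts are Poisson(density × network km), placed
  along edges with probability proportional to (weighted) edge length;
  point features sit within 10 m laterally of the centerline (streetscape
  furniture hugs the road reserve), line features attach to whole edges.
  A fraction *f* of features are **anachronisms** — installed after the
  window ends (2017–2019) — the rest predate the window (2000–2011).
* **Council export**: within-window features are omitted independently
  with probability *q* (default 0.3, reflecting the materially incomplete
  provision such audits encounter); anachronisms are always exported
  (they exist at provision time); the export carries no dates.
* **Panoramas**: each location has a panorama in each schedule year
  (2008–2019) with probability *p*, deterministically per (seed,
  location). The default *p* = 0.30 yields an in-range probability of
  $1 - 0.7^5 \approx 0.83$ over a five-year window — the scale street
  imagery of that vintage actually achieves.
* **Coder oracle**: for every in-range coordinate, each feature present
  during the window and within the visibility radius (default 40 m) is
  recorded with probability $1 - m$ (default miss probability 0.05).

All randomness flows from the single spec seed; identical seeds give
byte-identical towns, exports, panoramas and observations.

What the generator does **not** emulate: occlusion and viewing-angle
effects (visibility is a clean disc), coder disagreement and drift,
spatially correlated imagery gaps, geocoding error, mid-window
installation/removal churn (features are present for the whole window or
not at all — the `removal_year` field exists but is not populated by
default), and the irregular street geometry of real towns beyond the
bent-edge fraction. Passing tests therefore demonstrate that the
*pipeline machinery* is correct and that the estimators behave as
designed under known conditions — not that any particular real council
layer will show a given validation rate.

## Evaluation semantics and experimental design

`end_to_end_eval()` runs the full pipeline on a town and scores it:

* **validation rate** over council points — with complete imagery
  (*p* = 1) and perfect coding (*m* = 0) this estimates $1 - f$, since
  anachronistic features cannot appear in in-window imagery;
* **gap-fill sensitivity** — the fraction of omitted within-window
  features recovered by the imagery layers (1.0 in the ideal limit, by
  the coverage argument below);
* **gap-fill precision** — the fraction of imagery-derived point members
  matching a true within-window feature.

By default the evaluator audits the whole town network (so every feature
is scorable); `audit = "cohort"` audits the union of the cohort's
activity spaces and restricts scoring to ground truth on the audited
network.

Two design points deserve explicit statement.

**Coverage.** A feature at lateral offset ≤ 10 m is guaranteed visible
from some sample point when
$\sqrt{s_{\mathrm{gap}}^2 + 10^2} \le$ visibility, where the worst
along-edge gap is at most the spacing $s$. At the default 35 m spacing
the 40 m visibility radius satisfies this; the parameter-recovery
experiments in the test suite use 15 m spacing with 20 m visibility,
which also satisfies it. This is what makes "every in-window feature
observed" a theorem rather than a tendency, and hence gap-fill
sensitivity exactly 1.0 in the ideal limit.

**Collision bias in the recovery experiment.** Because validation matches
council points to observation *coordinates*, an anachronistic council
point is falsely validated when a *different* in-window feature of the
same code lies within roughly visibility + match radius of it. The
false-validation probability is approximately
$2(\text{vis} + r_{\mathrm{match}}) \times \lambda_{\mathrm{code}}$ with
$\lambda_{\mathrm{code}}$ the same-code in-window density per network
metre. A recovery experiment that tests the estimator against a binomial
error band must therefore keep this bias an order of magnitude below the
band: the packaged experiment uses a 130 km network with ~0.77 point
features/km/code (≈ 500 council points, bias ≈ 1–2% of the anachronistic
share versus a 3-SE band of ≈ 6 percentage points). At realistic urban
densities the bias is a genuine property of the method — coordinate-based
validation is slightly anticonservative where same-code features
cluster — and users should read validation rates accordingly.

Problem sizes throughout the suite (towns of 6×6 to 26×26 blocks,
brute-force oracles on ≤ 30-edge fixtures densified at 2–5 cm) were
chosen so each property is tested at the smallest scale at which it is
meaningful.

## Numerical choices, degenerate inputs, tie-breaks

* Node snap and junction dedup tolerance: 0.5 m; zero-length features are
  dropped with a warning; features collapsed to zero length by snapping
  likewise.
* Snapping ties: smallest edge id, then smallest chainage. Panorama
  selection ties: latest year, largest month, lexicographic id. Nearest
  school ties: smallest school id. Shortest-path ties resolve
  deterministically from the fixed graph construction order.
* Interval arithmetic uses a 1e-9 m coalescing tolerance; zero-width
  portions (buffer radius 0) are legal.
* Route corridors densify the route polyline at 1 m, so the corridor
  boundary on edges is resolved to ~0.5 m; line-layer clipping is exact
  (per-segment quadratic), not densified.
* Percentages: half-up rounding, integer for validation rates, one
  decimal for feature summaries; 0 of 0 reports NA, never 0%.
* The degrees-vs-metres guard refuses inputs whose coordinates fit in
  degree ranges *and* span less than 2 units — a metric layer spanning
  under 2 m is degenerate anyway.

## Known limitations

Turn restrictions, one-way streets, travel-time weighting and elevation
are out of scope; so are GPS-derived activity spaces and kernel-density
neighbourhoods. Shapefile I/O is not provided — layers exchange as
GeoJSON and CSV. The real-imagery adapter is a contract only; nothing in
this package performs HTTP access. Validation is anticonservative under
same-code clustering (above), and a validation failure cannot distinguish
"feature absent" from "no imagery of the feature's era" — the in-range
rate should always be reported alongside validation rates, as the
reporting functions do.
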