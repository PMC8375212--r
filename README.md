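# streetaudit

Administrative GIS layers — council footpath, crossing, bus-stop or
food-outlet datasets — are routinely incomplete, and almost never say *when*
a feature existed. Both problems bite hard in retrospective studies of
children's physical-activity and food environments, where exposure must be
measured over a past study window (e.g. 2012–2016) inside child-specific
activity spaces. `streetaudit` implements a practical audit pipeline for
this situation: it uses date-filtered historic street-level imagery to
**gap-fill** missing features and to **temporally validate** the features a
council did provide, and it ships a seeded synthetic town so the entire
pipeline can be exercised and scored against known ground truth with no
external downloads.

## The method

For each study participant the pipeline builds an **activity space** on the
road network:

- an 800 m *network* buffer (service area, not a Euclidean disc) around the
  home,
- an 800 m network buffer around the nearest school (network distance),
- a 200 m corridor around the shortest home–school route,

then samples audit coordinates every 35 m along the included network
(service areas cut edges exactly at the distance frontier, so sampled
length is unbiased). Each coordinate is converted to geographic
coordinates and queried against a panorama provider with **four compass
headings** (0/90/180/270°) and an inclusive calendar-year date window;
images captured inside the window are *in range*, others are filtered out.
Coders record visible streetscape features per coordinate against a fixed
dictionary. Point features become point layers directly; line features
(footpaths, parking) are built by clipping the network to 20 m discs
around observed coordinates — at 35 m spacing neighbouring discs overlap,
so a continuously observed footpath yields a contiguous segment. Finally:

- **gap-filling**: imagery-derived layers are merged (plain GIS merge, with
  per-member provenance) into the council layers;
- **temporal validation**: a council point is *validated* if an observation
  of the same feature code lies within the match radius — i.e. the feature
  demonstrably existed during the window. Reports give per-feature
  provided/validated counts and rates.

The synthetic town generator emulates the study inputs — a grid-with-fringe
metric road network, Poisson-placed dated features, council exports with
omission rate *q* and anachronism fraction *f* (features installed after
the window), per-location panorama availability with capture years, and a
coder oracle with visibility radius and miss probability — all driven by a
single seed. Under complete imagery and perfect coding, the validation rate
estimates 1 − *f* and gap-fill recovers every omitted feature, which is
exactly what the test suite checks.

## Worked example

```r
library(streetaudit)

spec  <- town_spec(seed = 1)          # study conditions; window 2012-2016
town  <- generate_town(spec)
town
#> <synthetic_town> seed 1: 18.2 km network, 143 features (31 anachronistic), 5 participants

cohort <- build_cohort_spaces(town$network, town$participants, town$schools)
cohort$summary[1:2, ]
#>   participant_id school_id audit_length_m route_length_m status
#> 1        child01  school01       17484.87       666.2642     ok
#> 2        child02  school02       15509.50       158.1746     ok

pts  <- to_geographic(sample_cohort_points(cohort$spaces, spacing = 35), town$crs)
reqs <- plan_requests(pts, date_window = spec$window)
recs <- resolve_requests(reqs, synthetic_provider(spec$schedule_years,
                                                  spec$coverage_prob,
                                                  seed = spec$seed))
summarize_in_range(recs)
#> $n_requested [1] 1968   $n_in_range [1] 1656   $pct_in_range [1] 84

obs     <- join_observations(coder_oracle(town, recs), pts)
council <- export_council(town)
temporal_validate(council$points, obs, match_radius = spec$visibility)$report
#>                  code n_provided n_validated rate_pct
#> 1    public_transport          7           6       86
#> 2 pedestrian_crossing          9           6       67
#> 3     traffic_calming          8           7       88
#> 4     park_playground          5           4       80
#> 5         food_outlet         19          13       68
#> 6               total         48          36       75
```

Reading the output: 492 pooled audit coordinates gave 1968 four-heading
requests, 84% of which found an in-window panorama (the provider's
per-year coverage of 0.30 over 2008–2019 implies ≈ 83% in range). Of the
48 council points, 75% could be temporally validated; the shortfall against
the simulated 1 − *f* = 80% reflects imperfect imagery coverage and the 5%
coder miss rate — precisely the ambiguity the method is designed to
expose. `end_to_end_eval(spec)` runs the same pipeline and additionally
scores gap-fill sensitivity/precision against ground truth.

A thin CLI over the same functions is installed at `inst/cli/streetaudit`
(`simulate-town`, `sample`, `plan-resolve`, `evaluate`).

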