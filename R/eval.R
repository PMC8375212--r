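#' Run the full audit pipeline on a synthetic town and score it
#'
#' Generates the town, exports the (gappy, undated) council layers, samples
#' audit coordinates, plans and resolves date-filtered imagery requests
#' against the synthetic provider, codes features with the oracle, builds
#' imagery-derived layers, and scores the pipeline against the known
#' ground truth:
#'
#' * **validation rate** — fraction of council points temporally validated;
#'   with complete imagery and perfect coding this estimates `1 - f`, the
#'   within-window fraction, since anachronistic council features cannot
#'   be seen in in-window imagery;
#' * **gap-fill sensitivity** — fraction of within-window features withheld
#'   from the council export that the imagery-derived layers recover;
#' * **gap-fill precision** — fraction of imagery-derived point members that
#'   match a true within-window feature of the same code.
#'
#' A feature observed from a panorama can lie up to the visibility radius
#' from the panorama's coordinate, so the spatial matching tolerance
#' defaults to the town's visibility radius.
#'
#' @param spec a [town_spec()].
#' @param spacing sampling interval in metres (default 35 m).
#' @param match_radius matching tolerance in metres (default: the spec's
#'   visibility radius).
#' @param audit `"network"` to audit the whole town network, or
#'   `"cohort"` to audit the union of the cohort's activity spaces (then
#'   only ground truth on the audited network is scored).
#' @return list of metrics: feature and request counts, `pct_in_range`,
#'   `validation_rate_pct`, `gapfill_sensitivity`, `gapfill_precision`,
#'   plus the intermediate objects in `$detail`.
#' @export
end_to_end_eval <- function(spec, spacing = 35, match_radius = NULL,
                            audit = c("network", "cohort")) {
  audit <- match.arg(audit)
  match_radius <- match_radius %||% spec$visibility
  town <- generate_town(spec)
  net <- town$network
  council <- export_council(town)

  if (audit == "network") {
    space <- whole_network(net)
    spaces <- NULL
  } else {
    spaces <- build_cohort_spaces(net, town$participants, town$schools)
    space <- do.call(subnetwork_union,
                     lapply(spaces$spaces, function(s) s$audit))
  }

  pts <- sample_points(space, spacing = spacing, space_id = "audit")
  pts <- to_geographic(pts, town$crs)
  reqs <- plan_requests(pts, date_window = spec$window)
  prov <- synthetic_provider(spec$schedule_years, spec$coverage_prob,
                             seed = spec$seed)
  recs <- resolve_requests(reqs, prov)
  inr <- summarize_in_range(recs)
  obs <- coder_oracle(town, recs)
  obs <- join_observations(obs, pts)

  val <- temporal_validate(council$points, obs, match_radius = match_radius)
  overall <- val$report[val$report$code == "total", ]

  scored <- council$omitted
  if (audit == "cohort" && nrow(scored))
    scored <- scored[on_subnetwork(scored, space), , drop = FALSE]
  gs <- gapfill_scores(town, scored, obs, net, match_radius)

  inw <- present_in_window(town$features, spec$window)
  list(n_features = nrow(town$features),
       n_in_window = sum(inw),
       n_anachronistic = sum(town$features$anachronistic),
       n_council_points = nrow(council$points),
       n_omitted_scored = nrow(scored),
       n_points = nrow(pts),
       n_requests = nrow(reqs),
       pct_in_range = inr$pct_in_range,
       validation_rate_pct = overall$rate_pct,
       n_validated = overall$n_validated,
       gapfill_sensitivity = gs$sensitivity,
       gapfill_precision = gs$precision,
       total_network_m = network_length(net),
       detail = list(town = town, council = council, points = pts,
                     records = recs, observations = obs,
                     validation = val, spaces = spaces))
}

on_subnetwork <- function(features, space, tol = 1e-6) {
  vapply(seq_len(nrow(features)), function(i) {
    p <- space$portions[space$portions$edge_id == features$edge_id[i], ,
                        drop = FALSE]
    any(p$c0 - tol <= features$chainage[i] &
        features$chainage[i] <= p$c1 + tol)
  }, logical(1))
}

gapfill_scores <- function(town, omitted, obs, net, match_radius) {
  if (nrow(omitted) == 0L)
    return(list(sensitivity = NA_real_, precision = gap_precision(
      town, obs, match_radius)))
  rec <- logical(nrow(omitted))
  for (i in seq_len(nrow(omitted))) {
    o <- obs[obs$feature_code == omitted$code[i], , drop = FALSE]
    if (nrow(o) == 0L) next
    if (omitted$kind[i] == "point") {
      d2 <- (o$x - omitted$x[i])^2 + (o$y - omitted$y[i])^2
      rec[i] <- any(d2 <= match_radius^2)
    } else {
      # a line feature is recovered when its buffer-clipped layer covers
      # part of the feature's edge
      lay <- build_line_layer(obs, omitted$code[i], net)
      mm <- lay$members
      mm <- mm[mm$edge_id == omitted$edge_id[i], , drop = FALSE]
      rec[i] <- any(mm$c1 > omitted$c0[i] & mm$c0 < omitted$c1[i])
    }
  }
  list(sensitivity = mean(rec),
       precision = gap_precision(town, obs, match_radius))
}

# Fraction of imagery-derived point-layer members matching a true
# within-window same-code feature.
gap_precision <- function(town, obs, match_radius) {
  f <- town$features
  f <- f[present_in_window(f, town$spec$window) & f$kind == "point", ,
         drop = FALSE]
  dict <- feature_dictionary()
  pcodes <- intersect(unique(obs$feature_code),
                      dict$code[dict$kind == "point"])
  tp <- 0L
  n <- 0L
  for (cd in pcodes) {
    lay <- build_point_layer(obs, cd, dict)
    ft <- f[f$code == cd, , drop = FALSE]
    for (i in seq_len(nrow(lay$members))) {
      n <- n + 1L
      if (nrow(ft) &&
          any((ft$x - lay$members$x[i])^2 +
              (ft$y - lay$members$y[i])^2 <= match_radius^2))
        tp <- tp + 1L
    }
  }
  if (n == 0L) NA_real_ else tp / n
}
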