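#' Feature layers
#'
#' A `feature_layer` holds the GIS representation of one feature code:
#' point members (audit coordinates or council points) or line members
#' (chainage intervals on network edges), with per-member provenance
#' (`council`, `gsv` or both after a merge).
#'
#' @param code feature code (see [feature_dictionary()]).
#' @param kind `"point"` or `"line"`.
#' @param members data.frame of members; points carry `x`, `y` (and
#'   `coordinate_id` when derived from imagery), lines carry `edge_id`,
#'   `c0`, `c1`.
#' @param provenance default provenance recorded on members lacking one.
#' @return a `feature_layer`.
#' @export
feature_layer <- function(code, kind = c("point", "line"), members,
                          provenance = "council") {
  kind <- match.arg(kind)
  if (is.null(members$provenance))
    members$provenance <- rep(provenance, nrow(members))
  structure(list(code = code, kind = kind, members = members),
            class = "feature_layer")
}

#' @export
print.feature_layer <- function(x, ...) {
  cat(sprintf("<feature_layer> %s (%s): %d member(s) [%s]\n",
              x$code, x$kind, nrow(x$members),
              paste(unique(x$members$provenance), collapse = "+")))
  invisible(x)
}

#' Attach coordinates to an observation table
#'
#' @param observations data.frame from [ingest_batches()] or
#'   [coder_oracle()].
#' @param points data.frame of audit coordinates (`point_id`, `x`, `y`).
#' @return observations with `x`, `y` columns joined by coordinate id.
#' @export
join_observations <- function(observations, points) {
  m <- match(observations$coordinate_id, points$point_id)
  observations$x <- points$x[m]
  observations$y <- points$y[m]
  observations
}

#' Build a point layer from observations
#'
#' One member per distinct coordinate id at which the feature was
#' recorded (repeat sightings at a coordinate collapse to one member).
#'
#' @param observations observation table with coordinates (see
#'   [join_observations()]).
#' @param code a point-kind feature code.
#' @param dictionary feature dictionary.
#' @return a `feature_layer` with provenance `gsv`.
#' @export
build_point_layer <- function(observations, code,
                              dictionary = feature_dictionary()) {
  check_kind(code, "point", dictionary)
  obs <- observations[observations$feature_code == code, , drop = FALSE]
  obs <- obs[!duplicated(obs$coordinate_id), , drop = FALSE]
  members <- data.frame(coordinate_id = obs$coordinate_id,
                        x = obs$x, y = obs$y)
  members <- members[order(members$coordinate_id), , drop = FALSE]
  rownames(members) <- NULL
  feature_layer(code, "point", members, provenance = "gsv")
}

#' Build a line layer from observations by buffer-and-clip
#'
#' Line features (footpaths, cycleways, parking) are visible along a
#' stretch of road, not at a single point, so the layer is the set of
#' network portions within `buffer` metres (Euclidean) of any coordinate
#' where the feature was recorded. At the default 20 m buffer,
#' consecutive 35 m-spaced observed coordinates produce one contiguous
#' clipped segment. Adjacent clipped intervals on an edge are merged.
#'
#' @param observations observation table with coordinates.
#' @param code a line-kind feature code.
#' @param net a `road_network`.
#' @param buffer clip radius in metres (default 20 m).
#' @param dictionary feature dictionary.
#' @return a `feature_layer` of line members with provenance `gsv`.
#' @export
build_line_layer <- function(observations, code, net, buffer = 20,
                             dictionary = feature_dictionary()) {
  check_kind(code, "line", dictionary)
  obs <- observations[observations$feature_code == code, , drop = FALSE]
  obs <- obs[!duplicated(obs$coordinate_id), , drop = FALSE]
  iv <- edge_intervals_within(net, data.frame(x = obs$x, y = obs$y), buffer)
  feature_layer(code, "line", iv, provenance = "gsv")
}

check_kind <- function(code, kind, dictionary) {
  k <- dictionary$kind[match(code, dictionary$code)]
  if (is.na(k))
    stop_streetaudit(sprintf("unknown feature code '%s'", code),
                     "streetaudit_bad_code")
  if (k != kind)
    stop_streetaudit(sprintf("feature '%s' has geometry kind '%s', not '%s'",
                             code, k, kind),
                     "streetaudit_kind_mismatch")
  invisible(TRUE)
}

#' Gap-fill merge of a council layer with an imagery-derived layer
#'
#' Plain union in the GIS-merge sense: council members are preserved
#' verbatim, imagery-derived members are appended, and provenance is
#' recorded per member. No cross-provenance deduplication is performed
#' (see [temporal_validate()] for the validation direction).
#'
#' @param council,gsv `feature_layer`s with the same code and kind.
#' @return merged `feature_layer` whose members are the concatenation.
#' @export
gap_fill_merge <- function(council, gsv) {
  if (council$code != gsv$code || council$kind != gsv$kind)
    stop_streetaudit("layers differ in feature code or geometry kind",
                     "streetaudit_merge_mismatch")
  a <- council$members
  b <- gsv$members
  cols <- union(names(a), names(b))
  for (col in setdiff(cols, names(a))) a[[col]] <- rep(NA, nrow(a))
  for (col in setdiff(cols, names(b))) b[[col]] <- rep(NA, nrow(b))
  m <- rbind(a[cols], b[cols])
  rownames(m) <- NULL
  feature_layer(council$code, council$kind, m)
}

#' Temporally validate council point data against imagery observations
#'
#' A council point is validated when at least one observation of the same
#' feature code lies within `match_radius` metres of it — i.e. the feature
#' was actually seen in date-filtered imagery, so it existed during the
#' study window. Returns per-feature provided/validated counts and rates
#' (nearest integer percent) with an overall row, plus the validated
#' layer.
#'
#' @param council data.frame of council points: `feature_id`, `code`,
#'   `x`, `y`.
#' @param observations observation table with coordinates.
#' @param match_radius matching tolerance in metres (default 20 m; when
#'   observations are made from imagery coordinates, use at least the
#'   coder visibility radius).
#' @return list with `report` (data.frame `code`, `n_provided`,
#'   `n_validated`, `rate_pct`) and `validated` (the validated subset of
#'   `council`).
#' @export
temporal_validate <- function(council, observations, match_radius = 20) {
  codes <- unique(council$code)
  ok <- logical(nrow(council))
  for (i in seq_len(nrow(council))) {
    obs <- observations[observations$feature_code == council$code[i], ,
                        drop = FALSE]
    if (nrow(obs) == 0L) next
    d2 <- (obs$x - council$x[i])^2 + (obs$y - council$y[i])^2
    ok[i] <- any(d2 <= match_radius^2)
  }
  per <- lapply(codes, function(cd) {
    sel <- council$code == cd
    data.frame(code = cd, n_provided = sum(sel), n_validated = sum(ok[sel]))
  })
  report <- do.call(rbind, per)
  report <- rbind(report,
                  data.frame(code = "total", n_provided = nrow(council),
                             n_validated = sum(ok)))
  report$rate_pct <- ifelse(report$n_provided > 0,
                            round_half_up(100 * report$n_validated /
                                          report$n_provided),
                            NA_real_)
  rownames(report) <- NULL
  list(report = report,
       validated = council[ok, , drop = FALSE])
}

#' Compile a food-outlet list from two open-source feeds
#'
#' Rows from the two feeds are concatenated with source priority
#' (first feed wins) and deduplicated: two rows are duplicates when their
#' normalised names match (case-folded, punctuation and whitespace
#' stripped) AND they lie within `dedup_radius` metres. The first
#' occurrence is kept.
#'
#' @param zenbu,places data.frames with columns `name`, `lon`, `lat`,
#'   `subtype`.
#' @param dedup_radius duplicate distance threshold in metres (default
#'   50 m, great-circle).
#' @return data.frame of all rows with `source`, logical `kept` and
#'   `dup_of` (index of the retained duplicate, NA for kept rows).
#' @export
compile_outlets <- function(zenbu, places, dedup_radius = 50) {
  zenbu$source <- "zenbu"
  places$source <- "places"
  cols <- c("name", "lon", "lat", "subtype", "source")
  all <- rbind(zenbu[cols], places[cols])
  rownames(all) <- NULL
  norm <- normalize_name(all$name)
  n <- nrow(all)
  kept <- logical(n)
  dup_of <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    prev <- which(kept & norm[seq_len(n)] == norm[i])
    prev <- prev[prev < i]
    if (length(prev)) {
      d <- geosphere::distHaversine(cbind(all$lon[prev], all$lat[prev]),
                                    c(all$lon[i], all$lat[i]))
      hit <- prev[d <= dedup_radius]
      if (length(hit)) {
        dup_of[i] <- hit[1]
        next
      }
    }
    kept[i] <- TRUE
  }
  all$kept <- kept
  all$dup_of <- dup_of
  all
}

normalize_name <- function(x) {
  x <- tolower(x)
  gsub("[^a-z0-9]", "", x)
}

#' Summarise features identified from imagery
#'
#' Per-feature counts of distinct coordinates at which the feature was
#' recorded, the row percentage of the column total (one decimal place,
#' half-up) and a total row.
#'
#' @param observations observation table.
#' @return data.frame `feature_code`, `n_coordinates`, `pct`.
#' @export
summarize_features <- function(observations) {
  if (nrow(observations) == 0L)
    return(data.frame(feature_code = "total", n_coordinates = 0L,
                      pct = NA_real_))
  per <- stats::aggregate(
    list(n_coordinates = observations$coordinate_id),
    by = list(feature_code = observations$feature_code),
    FUN = function(v) length(unique(v)))
  total <- sum(per$n_coordinates)
  out <- rbind(per, data.frame(feature_code = "total",
                               n_coordinates = total))
  out$pct <- round_half_up(100 * out$n_coordinates / total, 1)
  rownames(out) <- NULL
  out
}
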