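#' Plan street-level image requests for sampled coordinates
#'
#' Four images at fixed compass headings are requested per coordinate to
#' give a 360-degree view of each location; a calendar-year date window
#' (inclusive) defines which capture dates count as in range.
#'
#' @param points data.frame with `point_id`, `lon`, `lat` (see
#'   [to_geographic()]).
#' @param date_window integer length-2, inclusive calendar years.
#' @param headings compass headings in degrees; default `c(0, 90, 180,
#'   270)`.
#' @return data.frame of `image_request`s ordered by (coordinate id,
#'   heading): `request_id`, `point_id`, `lon`, `lat`, `heading`,
#'   `year_min`, `year_max`.
#' @export
plan_requests <- function(points, date_window = c(2012, 2016),
                          headings = c(0, 90, 180, 270)) {
  if (length(headings) == 0L)
    stop_streetaudit("heading set must be non-empty", "streetaudit_no_headings")
  if (nrow(points) > 0L && any(is.na(points$lon) | is.na(points$lat)))
    stop_streetaudit("points lack geographic coordinates; run to_geographic()",
                     "streetaudit_no_lonlat")
  headings <- sort(headings)
  idx <- rep(seq_len(nrow(points)), each = length(headings))
  out <- data.frame(
    point_id = points$point_id[idx],
    lon = points$lon[idx], lat = points$lat[idx],
    heading = rep(headings, times = nrow(points)),
    year_min = rep(date_window[1], length(idx)),
    year_max = rep(date_window[2], length(idx)))
  out <- out[order(out$point_id, out$heading), , drop = FALSE]
  out$request_id <- sprintf("%s_h%03d", out$point_id, out$heading)
  rownames(out) <- NULL
  out[c("request_id", "point_id", "lon", "lat", "heading",
        "year_min", "year_max")]
}

#' Panorama provider contract
#'
#' A provider exposes `query(lon, lat)` returning a data.frame of
#' available panoramas (`pano_id`, `year`, `month`) for that location
#' (zero rows when the location has no coverage), and optionally
#' `fetch(pano_id, heading)` returning image bytes. Queries must be
#' deterministic for fixed provider state. See [synthetic_provider()] and
#' [cached_provider()]; an adapter to a real street-imagery HTTP API would
#' implement the same contract.
#'
#' @param query function(lon, lat) -> data.frame(pano_id, year, month).
#' @param name provider label.
#' @param fetch optional function(pano_id, heading) -> raw.
#' @return an object of class `panorama_provider`.
#' @export
panorama_provider <- function(query, name = "custom", fetch = NULL) {
  structure(list(query = query, fetch = fetch, name = name),
            class = "panorama_provider")
}

#' @export
print.panorama_provider <- function(x, ...) {
  cat("<panorama_provider>", x$name, "\n")
  invisible(x)
}

#' Resolve planned requests against a panorama provider
#'
#' For each request the provider is queried at its coordinate. With no
#' panoramas the outcome is `unavailable`. Otherwise the panorama with the
#' latest capture date inside the window is selected (ties: larger month,
#' then first panorama id in lexicographic order) and the outcome is
#' `in_range`; if no panorama falls inside the window the outcome is
#' `out_of_range` and the nearest-dated panorama's year is recorded.
#' Provider errors are retried `retries` times, then recorded as
#' `unavailable`.
#'
#' @param requests data.frame from [plan_requests()].
#' @param provider a `panorama_provider`.
#' @param retries number of retries on provider failure.
#' @return data.frame of `image_record`s: `request_id`, `point_id`,
#'   `heading`, `lon`, `lat`, `outcome`, `pano_id`, `year`, `month`.
#' @export
resolve_requests <- function(requests, provider, retries = 2) {
  stopifnot(inherits(provider, "panorama_provider"))
  locs <- unique(requests[c("point_id", "lon", "lat",
                            "year_min", "year_max")])
  res <- lapply(seq_len(nrow(locs)), function(i) {
    pans <- NULL
    for (k in seq_len(retries + 1L)) {
      pans <- tryCatch(provider$query(locs$lon[i], locs$lat[i]),
                       error = function(e) e)
      if (!inherits(pans, "error")) break
    }
    if (inherits(pans, "error")) {
      warning(sprintf("provider failed at %s: %s", locs$point_id[i],
                      conditionMessage(pans)))
      pans <- data.frame(pano_id = character(0), year = integer(0),
                         month = integer(0))
    }
    select_panorama(pans, locs$year_min[i], locs$year_max[i])
  })
  sel <- do.call(rbind, res)
  m <- match(requests$point_id, locs$point_id)
  out <- data.frame(request_id = requests$request_id,
                    point_id = requests$point_id,
                    heading = requests$heading,
                    lon = requests$lon, lat = requests$lat,
                    outcome = sel$outcome[m],
                    pano_id = sel$pano_id[m],
                    year = sel$year[m], month = sel$month[m])
  rownames(out) <- NULL
  out
}

select_panorama <- function(pans, ymin, ymax) {
  if (nrow(pans) == 0L)
    return(data.frame(outcome = "unavailable", pano_id = NA_character_,
                      year = NA_integer_, month = NA_integer_))
  inw <- pans[pans$year >= ymin & pans$year <= ymax, , drop = FALSE]
  if (nrow(inw) > 0L) {
    ord <- order(-inw$year, -inw$month, inw$pano_id)
    b <- inw[ord[1], ]
    return(data.frame(outcome = "in_range", pano_id = b$pano_id,
                      year = as.integer(b$year), month = as.integer(b$month)))
  }
  gap <- pmax(ymin - pans$year, pans$year - ymax)
  b <- pans[order(gap, -pans$year, pans$pano_id)[1], ]
  data.frame(outcome = "out_of_range", pano_id = b$pano_id,
             year = as.integer(b$year), month = as.integer(b$month))
}

#' Write / read the image manifest CSV
#'
#' One row per request with the image id (coordinate id plus heading
#' suffix), the coordinates the image was taken from, the outcome, and the
#' capture year and month. Re-reading reproduces the records exactly.
#'
#' @param records data.frame from [resolve_requests()].
#' @param path file path.
#' @export
write_manifest <- function(records, path) {
  man <- data.frame(image_id = records$request_id,
                    lon = records$lon, lat = records$lat,
                    heading = records$heading,
                    outcome = records$outcome,
                    pano_id = records$pano_id,
                    year = records$year, month = records$month)
  utils::write.csv(man, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  man <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(image_id = "character",
                                        pano_id = "character",
                                        outcome = "character"))
  man$pano_id[man$pano_id == ""] <- NA_character_
  data.frame(request_id = man$image_id,
             point_id = sub("_h[0-9]{3}$", "", man$image_id),
             heading = man$heading,
             lon = man$lon, lat = man$lat,
             outcome = man$outcome, pano_id = man$pano_id,
             year = as.integer(man$year), month = as.integer(man$month))
}

#' Replay provider from a stored manifest
#'
#' Replays the panoramas recorded in an earlier manifest so a pipeline run
#' is repeatable offline. Queries are matched by coordinate (6-decimal
#' rounding).
#'
#' @param records data.frame of records ([resolve_requests()] output or
#'   [read_manifest()] result).
#' @return a `panorama_provider`.
#' @export
cached_provider <- function(records) {
  key <- sprintf("%.6f|%.6f", records$lon, records$lat)
  by_loc <- split(records[c("pano_id", "year", "month")], key)
  panorama_provider(name = "cached", query = function(lon, lat) {
    rows <- by_loc[[sprintf("%.6f|%.6f", lon, lat)]]
    if (is.null(rows))
      return(data.frame(pano_id = character(0), year = integer(0),
                        month = integer(0)))
    rows <- unique(rows[!is.na(rows$pano_id), , drop = FALSE])
    data.frame(pano_id = rows$pano_id, year = rows$year, month = rows$month)
  })
}

#' Summarise the in-range fraction of resolved requests
#'
#' @param records data.frame from [resolve_requests()].
#' @return list with `n_requested`, `n_in_range` and `pct_in_range`
#'   (nearest integer percent, half-up; `NA` when no requests were made).
#' @export
summarize_in_range <- function(records) {
  n <- nrow(records)
  k <- sum(records$outcome == "in_range")
  list(n_requested = n, n_in_range = k,
       pct_in_range = if (n == 0L) NA_real_ else round_half_up(100 * k / n))
}
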