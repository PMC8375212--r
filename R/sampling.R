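#' Sample audit coordinates at fixed intervals along a sub-network
#'
#' Generates points along every included edge portion at a fixed spacing.
#' Convention: each portion `[c0, c1]` yields points at chainages
#' `c0, c0 + s, c0 + 2s, ... <= c1` (no forced endpoint), so a portion of
#' length `L` starting a fresh edge carries exactly `floor(L / s) + 1`
#' points. Points coincident across edges (shared junctions, within
#' `dedup_tol`) are deduplicated keeping the smallest edge id. Ids are
#' assigned in (edge id, chainage) order and are stable and sortable.
#'
#' @param space a `sub_network` (e.g. an activity space's audit network).
#' @param spacing interval in metres (default 35 m).
#' @param space_id identifier recorded on every point.
#' @param dedup_tol junction deduplication radius in metres (default
#'   0.5 m, matching the node snap tolerance).
#' @return data.frame of sample points: `point_id`, `edge_id`, `chainage`,
#'   `x`, `y`, `lon`, `lat` (NA until [to_geographic()]), `space_id`.
#' @export
sample_points <- function(space, spacing = 35, space_id = "space1",
                          dedup_tol = 0.5) {
  if (spacing <= 0)
    stop_streetaudit("spacing must be > 0", "streetaudit_bad_spacing")
  net <- space$network
  ports <- space$portions
  ports <- ports[order(ports$edge_id, ports$c0), , drop = FALSE]
  rows <- lapply(seq_len(nrow(ports)), function(i) {
    ch <- seq(ports$c0[i], ports$c1[i] + 1e-9, by = spacing)
    ch <- ch[ch <= ports$c1[i] + 1e-9]
    data.frame(edge_id = ports$edge_id[i], chainage = pmin(ch, ports$c1[i]))
  })
  pts <- do.call(rbind, rows)
  if (is.null(pts) || nrow(pts) == 0L)
    return(empty_points(space_id))
  pts <- pts[order(pts$edge_id, pts$chainage), , drop = FALSE]
  xy <- points_at_chainage(net, pts)
  pts$x <- xy[, 1]
  pts$y <- xy[, 2]
  keep <- dedup_coincident(pts$x, pts$y, dedup_tol)
  pts <- pts[keep, , drop = FALSE]
  pts$point_id <- sprintf("pt%06d", seq_len(nrow(pts)))
  pts$lon <- NA_real_
  pts$lat <- NA_real_
  pts$space_id <- space_id
  rownames(pts) <- NULL
  pts[c("point_id", "edge_id", "chainage", "x", "y", "lon", "lat", "space_id")]
}

empty_points <- function(space_id = character(0)) {
  data.frame(point_id = character(0), edge_id = integer(0),
             chainage = numeric(0), x = numeric(0), y = numeric(0),
             lon = numeric(0), lat = numeric(0), space_id = character(0))
}

# Keep-first dedup of coordinates within `tol` (cell hashing); input order
# defines priority.
dedup_coincident <- function(x, y, tol) {
  n <- length(x)
  keep <- logical(n)
  cells <- new.env(parent = emptyenv())
  kx <- floor(x / tol)
  ky <- floor(y / tol)
  for (i in seq_len(n)) {
    dup <- FALSE
    for (dx in -1:1) {
      for (dy in -1:1) {
        key <- paste(kx[i] + dx, ky[i] + dy)
        ids <- cells[[key]]
        if (!is.null(ids) &&
            any((x[ids] - x[i])^2 + (y[ids] - y[i])^2 <= tol^2)) {
          dup <- TRUE
          break
        }
      }
      if (dup) break
    }
    if (!dup) {
      keep[i] <- TRUE
      key <- paste(kx[i], ky[i])
      cells[[key]] <- c(cells[[key]], i)
    }
  }
  keep
}

#' Sample a cohort of activity spaces, pooling coincident points
#'
#' Points shared between overlapping activity spaces are deduplicated by
#' coordinate; every owning space id is recorded (comma-separated).
#'
#' @param spaces named list of `activity_space` objects.
#' @param spacing interval in metres.
#' @param dedup_tol coordinate pooling radius in metres.
#' @return data.frame as [sample_points()], re-identified after pooling.
#' @export
sample_cohort_points <- function(spaces, spacing = 35, dedup_tol = 0.5) {
  if (length(spaces) == 0L) return(empty_points())
  parts <- lapply(names(spaces), function(nm)
    sample_points(spaces[[nm]]$audit, spacing = spacing, space_id = nm,
                  dedup_tol = dedup_tol))
  pts <- do.call(rbind, parts)
  pts <- pts[order(pts$edge_id, pts$chainage, pts$space_id), , drop = FALSE]
  keep <- dedup_coincident(pts$x, pts$y, dedup_tol)
  owners <- character(sum(keep))
  ki <- which(keep)
  for (j in seq_along(ki)) {
    i <- ki[j]
    near <- (pts$x - pts$x[i])^2 + (pts$y - pts$y[i])^2 <= dedup_tol^2
    owners[j] <- paste(sort(unique(pts$space_id[near])), collapse = ",")
  }
  pts <- pts[keep, , drop = FALSE]
  pts$space_id <- owners
  pts$point_id <- sprintf("pt%06d", seq_len(nrow(pts)))
  rownames(pts) <- NULL
  pts
}

#' Fill geographic coordinates for sampled points
#'
#' @param points data.frame from [sample_points()].
#' @param crs a `crs_transform` (see [identity_crs()]).
#' @param check round-trip tolerance in metres; exceeding it is an error
#'   (guards against an inconsistent transform).
#' @return `points` with `lon`/`lat` populated.
#' @export
to_geographic <- function(points, crs, check = 0.5) {
  if (!inherits(crs, "crs_transform"))
    stop_streetaudit("a crs_transform is required", "streetaudit_no_crs")
  if (nrow(points) == 0L) return(points)
  ll <- crs$to_geographic(cbind(points$x, points$y))
  back <- crs$to_planar(ll)
  err <- sqrt((back[, 1] - points$x)^2 + (back[, 2] - points$y)^2)
  if (any(err > check))
    stop_streetaudit(sprintf("CRS round-trip error up to %.3f m exceeds %.2f m",
                             max(err), check),
                     "streetaudit_crs_roundtrip")
  points$lon <- ll[, 1]
  points$lat <- ll[, 2]
  points
}

#' Spacing sensitivity analysis
#'
#' For each candidate spacing, samples the sub-network and reports the
#' number of points, the duplicate rate (fraction of points whose
#' visibility disc overlaps the previous point's disc on the same edge —
#' near-identical imagery) and the miss rate (fraction of ground-truth
#' features farther than the visibility radius from every point — features
#' that could not be seen from any image).
#'
#' @param space a `sub_network`.
#' @param features data.frame of ground-truth feature coordinates
#'   (`x`, `y`).
#' @param spacings candidate spacings in metres.
#' @param visibility_radius how far a feature can be from an image
#'   coordinate and still be coded (metres); the default 20 m matches the
#'   line-feature buffer used downstream.
#' @return data.frame sorted by spacing: `spacing`, `n_points`,
#'   `duplicate_rate`, `miss_rate`.
#' @export
spacing_sensitivity <- function(space, features,
                                spacings = c(10, 20, 30, 40, 50, 35),
                                visibility_radius = 20) {
  stopifnot(nrow(features) >= 1L)
  rows <- lapply(sort(spacings), function(s) {
    pts <- sample_points(space, spacing = s)
    dup <- duplicate_rate(pts, visibility_radius)
    miss <- miss_rate(pts, features, visibility_radius)
    data.frame(spacing = s, n_points = nrow(pts),
               duplicate_rate = dup, miss_rate = miss)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

duplicate_rate <- function(pts, v) {
  if (nrow(pts) == 0L) return(0)
  ord <- order(pts$edge_id, pts$chainage)
  pts <- pts[ord, ]
  same_edge <- c(FALSE, pts$edge_id[-1] == pts$edge_id[-nrow(pts)])
  d <- c(Inf, sqrt(diff(pts$x)^2 + diff(pts$y)^2))
  mean(same_edge & d < 2 * v)
}

miss_rate <- function(pts, features, v) {
  if (nrow(features) == 0L) return(0)
  if (nrow(pts) == 0L) return(1)
  missed <- vapply(seq_len(nrow(features)), function(i) {
    d2 <- (pts$x - features$x[i])^2 + (pts$y - features$y[i])^2
    min(d2) > v^2
  }, logical(1))
  mean(missed)
}

#' Write sampled points as CSV
#' @param points data.frame from [sample_points()].
#' @param path file path.
#' @export
write_points_csv <- function(points, path) {
  utils::write.csv(points, path, row.names = FALSE, na = "")
  invisible(path)
}
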