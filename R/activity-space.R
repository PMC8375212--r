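#' Nearest school by network distance
#'
#' Identifies the school closest to a home location. Distance is measured
#' along the road network by default (consistent with the network framing
#' of service-area buffers and routes); Euclidean distance is available as
#' a switch. Ties break to the smallest school id.
#'
#' @param net a `road_network`.
#' @param home a `network_location` (the snapped home address).
#' @param schools data.frame with columns `id`, `x`, `y`.
#' @param metric `"network"` or `"euclidean"`.
#' @return the selected school id.
#' @export
nearest_school <- function(net, home, schools, metric = c("network", "euclidean")) {
  metric <- match.arg(metric)
  stopifnot(nrow(schools) >= 1L)
  ord <- order(schools$id)
  schools <- schools[ord, , drop = FALSE]
  if (metric == "euclidean") {
    d <- sqrt((schools$x - home$point[1])^2 + (schools$y - home$point[2])^2)
  } else {
    locs <- lapply(seq_len(nrow(schools)), function(i)
      snap_to_network(c(schools$x[i], schools$y[i]), net))
    d <- network_distances(net, home, locs)
  }
  if (all(!is.finite(d)))
    stop_streetaudit(
      sprintf("no school reachable from home; unreachable ids: %s",
              paste(schools$id, collapse = ", ")),
      "streetaudit_unreachable")
  schools$id[which.min(d)]   # which.min takes the first (smallest id) on ties
}

#' Build a child-specific activity space
#'
#' An activity space is the union of three network components: a road
#' network buffer of radius `r_home` around the home, one of radius
#' `r_school` around the nearest school, and the portions of the network
#' lying within `corridor` metres (Euclidean) of the shortest home-school
#' route. The union is the audit sub-network along which imagery
#' coordinates are sampled; the three components are retained separately
#' for reporting.
#'
#' @param net a `road_network`.
#' @param participant list or one-row data.frame with `id`, `x`, `y`
#'   (home coordinates) and optionally `school_id` to force a school.
#' @param schools data.frame `id`, `x`, `y`.
#' @param r_home,r_school service-area radii in metres (defaults 800 m;
#'   `r_school` defaults to `r_home`).
#' @param corridor Euclidean half-width of the route corridor in metres
#'   (default 200 m); `corridor = 0` reduces the corridor component to the
#'   route's own edge portions.
#' @param school_metric distance metric for [nearest_school()].
#' @param corridor_step densification step (m) used when mapping the
#'   corridor polygon back onto network edges.
#' @return an `activity_space`: list with `participant_id`, `school_id`,
#'   `home_space`, `school_space`, `route`, `corridor_space`, `audit`
#'   (their union) and `params`.
#' @export
build_activity_space <- function(net, participant, schools,
                                 r_home = 800, r_school = r_home,
                                 corridor = 200,
                                 school_metric = "network",
                                 corridor_step = 1) {
  home_loc <- snap_to_network(c(participant$x, participant$y), net)
  sid <- participant$school_id %||% NULL
  if (is.null(sid) || is.na(sid))
    sid <- nearest_school(net, home_loc, schools, metric = school_metric)
  srow <- schools[match(sid, schools$id), ]
  school_loc <- snap_to_network(c(srow$x, srow$y), net)

  home_space <- network_buffer(net, home_loc, r_home)
  school_space <- network_buffer(net, school_loc, r_school)
  route <- shortest_route(net, home_loc, school_loc)
  corridor_space <- route_corridor(net, route, corridor, step = corridor_step)
  audit <- subnetwork_union(home_space, school_space, corridor_space)

  structure(list(participant_id = participant$id, school_id = sid,
                 home_space = home_space, school_space = school_space,
                 route = route, corridor_space = corridor_space,
                 audit = audit,
                 params = list(r_home = r_home, r_school = r_school,
                               corridor = corridor)),
            class = "activity_space")
}

# Edge portions within `corridor` metres (Euclidean) of the route
# polyline; the polyline is densified at `step` metres, so the corridor
# boundary is resolved to ~step/2.
route_corridor <- function(net, route, corridor, step = 1) {
  if (corridor <= 0)
    return(subnetwork(net, data.frame(
      edge_id = route$traversals$edge_id,
      c0 = pmin(route$traversals$c_from, route$traversals$c_to),
      c1 = pmax(route$traversals$c_from, route$traversals$c_to))))
  pts <- densify_polyline(route$geometry, step)
  iv <- edge_intervals_within(net, data.frame(x = pts[, 1], y = pts[, 2]),
                              corridor)
  subnetwork(net, iv)
}

densify_polyline <- function(g, step) {
  if (nrow(g) < 2L) return(g)
  pieces <- lapply(seq_len(nrow(g) - 1L), function(i) {
    l <- sqrt(sum((g[i + 1, ] - g[i, ])^2))
    n <- max(1L, ceiling(l / step))
    t <- seq(0, 1, length.out = n + 1L)[-(n + 1L)]
    cbind(g[i, 1] + t * (g[i + 1, 1] - g[i, 1]),
          g[i, 2] + t * (g[i + 1, 2] - g[i, 2]))
  })
  rbind(do.call(rbind, pieces), g[nrow(g), , drop = FALSE])
}

#' @export
print.activity_space <- function(x, ...) {
  cat(sprintf(
    "<activity_space> participant %s, school %s: audit %.1f m (home %.1f, school %.1f, corridor %.1f)\n",
    x$participant_id, x$school_id, subnetwork_length(x$audit),
    subnetwork_length(x$home_space), subnetwork_length(x$school_space),
    subnetwork_length(x$corridor_space)))
  invisible(x)
}

#' Build activity spaces for a cohort
#'
#' One space per participant; per-participant failures (e.g. an
#' unreachable school) are reported in the summary, not fatal.
#'
#' @param net a `road_network`.
#' @param participants data.frame `id`, `x`, `y` (home coordinates).
#' @param schools data.frame `id`, `x`, `y`.
#' @param ... passed to [build_activity_space()].
#' @return list with `spaces` (named list of `activity_space`) and
#'   `summary` (data.frame: participant id, school id, component and audit
#'   lengths, status), with the cohort total audit length as attribute
#'   `total_audit_m`.
#' @export
build_cohort_spaces <- function(net, participants, schools, ...) {
  spaces <- list()
  rows <- lapply(seq_len(nrow(participants)), function(i) {
    p <- as.list(participants[i, ])
    res <- tryCatch(build_activity_space(net, p, schools, ...),
                    streetaudit_error = function(e) e)
    if (inherits(res, "activity_space")) {
      spaces[[as.character(p$id)]] <<- res
      data.frame(participant_id = p$id, school_id = res$school_id,
                 audit_length_m = subnetwork_length(res$audit),
                 route_length_m = res$route$length,
                 status = "ok")
    } else {
      data.frame(participant_id = p$id, school_id = NA,
                 audit_length_m = 0, route_length_m = NA_real_,
                 status = conditionMessage(res))
    }
  })
  summary <- do.call(rbind, rows) %||%
    data.frame(participant_id = character(0), school_id = character(0),
               audit_length_m = numeric(0), route_length_m = numeric(0),
               status = character(0))
  attr(summary, "total_audit_m") <- sum(summary$audit_length_m)
  list(spaces = spaces, summary = summary)
}
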