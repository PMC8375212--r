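#' Sub-networks: whole and partial edges of a road network
#'
#' A `sub_network` is a set of edge portions (chainage intervals) of a
#' parent network: the result of a service-area buffer, a route corridor,
#' or a union of those. Portions are stored merged and disjoint per edge;
#' an edge whose single portion spans `[0, length]` counts as a whole edge.
#'
#' @param net a `road_network`.
#' @param portions data.frame with columns `edge_id`, `c0`, `c1`.
#' @return a `sub_network`.
#' @export
subnetwork <- function(net, portions) {
  portions <- portions[portions$c1 >= portions$c0 - 1e-12, , drop = FALSE]
  if (nrow(portions)) {
    parts <- lapply(split(portions, portions$edge_id), function(d) {
      L <- net$edges$length[match(d$edge_id[1], net$edges$edge_id)]
      m <- merge_intervals(d[c("c0", "c1")])
      m$c0 <- pmin(pmax(m$c0, 0), L)
      m$c1 <- pmin(pmax(m$c1, 0), L)
      data.frame(edge_id = d$edge_id[1], c0 = m$c0, c1 = m$c1)
    })
    portions <- do.call(rbind, parts)
    portions <- portions[order(portions$edge_id, portions$c0), , drop = FALSE]
    rownames(portions) <- NULL
  }
  structure(list(network = net, portions = portions),
            class = "sub_network")
}

#' @rdname subnetwork
#' @export
whole_network <- function(net) {
  subnetwork(net, data.frame(edge_id = net$edges$edge_id, c0 = 0,
                             c1 = net$edges$length))
}

#' @rdname subnetwork
#' @param s a `sub_network`.
#' @export
subnetwork_length <- function(s) sum(s$portions$c1 - s$portions$c0)

#' @rdname subnetwork
#' @export
whole_edges <- function(s) {
  L <- s$network$edges$length[match(s$portions$edge_id, s$network$edges$edge_id)]
  unique(s$portions$edge_id[s$portions$c0 <= 1e-9 &
                            s$portions$c1 >= L - 1e-9])
}

#' @rdname subnetwork
#' @export
partial_edges <- function(s) {
  w <- whole_edges(s)
  p <- s$portions[!(s$portions$edge_id %in% w), , drop = FALSE]
  rownames(p) <- NULL
  p
}

#' @rdname subnetwork
#' @param ... `sub_network`s sharing the same parent network.
#' @export
subnetwork_union <- function(...) {
  ss <- list(...)
  ss <- ss[!vapply(ss, is.null, logical(1))]
  stopifnot(length(ss) >= 1L)
  net <- ss[[1]]$network
  subnetwork(net, do.call(rbind, lapply(ss, function(s) s$portions)))
}

#' @export
print.sub_network <- function(x, ...) {
  cat(sprintf("<sub_network> %d edge portions (%d whole), %.1f m\n",
              nrow(x$portions), length(whole_edges(x)), subnetwork_length(x)))
  invisible(x)
}

# Augment the network graph with virtual vertices for mid-edge locations.
# Every edge of the returned graph carries attributes `edge_id`, `ch_t`
# and `ch_h`: the chainage (on the original edge) at its tail and head
# endpoints, enabling exact path reconstruction through virtual vertices.
virtual_graph <- function(net, locs, vnames) {
  g <- net$graph
  m <- match(igraph::E(g)$edge_id, net$edges$edge_id)
  igraph::E(g)$ch_t <- 0
  igraph::E(g)$ch_h <- net$edges$length[m]
  igraph::E(g)$tail_name <- as.character(net$edges$from[m])
  g <- igraph::add_vertices(g, length(locs), name = vnames)
  for (i in seq_along(locs)) {
    loc <- locs[[i]]
    e <- match(loc$edge_id, net$edges$edge_id)
    L <- net$edges$length[e]
    u <- as.character(net$edges$from[e])
    v <- as.character(net$edges$to[e])
    g <- igraph::add_edges(g, c(vnames[i], u),
                           attr = list(weight = loc$chainage,
                                       edge_id = loc$edge_id,
                                       ch_t = loc$chainage, ch_h = 0,
                                       tail_name = vnames[i]))
    g <- igraph::add_edges(g, c(vnames[i], v),
                           attr = list(weight = L - loc$chainage,
                                       edge_id = loc$edge_id,
                                       ch_t = loc$chainage, ch_h = L,
                                       tail_name = vnames[i]))
  }
  # direct along-edge links between virtual locations sharing an edge
  if (length(locs) > 1L) {
    eids <- vapply(locs, function(l) l$edge_id, numeric(1))
    for (i in seq_along(locs)) for (j in seq_along(locs)) {
      if (i < j && eids[i] == eids[j]) {
        g <- igraph::add_edges(g, c(vnames[i], vnames[j]),
                               attr = list(weight = abs(locs[[i]]$chainage -
                                                        locs[[j]]$chainage),
                                           edge_id = eids[i],
                                           ch_t = locs[[i]]$chainage,
                                           ch_h = locs[[j]]$chainage,
                                           tail_name = vnames[i]))
      }
    }
  }
  g
}

#' Network distances from one location to several others
#'
#' @param net a `road_network`.
#' @param from a `network_location`.
#' @param to list of `network_location`s.
#' @return numeric vector of shortest-path lengths in metres (`Inf` where
#'   unreachable).
#' @export
network_distances <- function(net, from, to) {
  vn <- c(".from.", paste0(".to.", seq_along(to)))
  g <- virtual_graph(net, c(list(from), to), vn)
  d <- igraph::distances(g, v = ".from.", to = vn[-1],
                         weights = igraph::E(g)$weight)
  as.numeric(d)
}

#' Shortest route between two network locations
#'
#' Minimum-length path by edge length (Dijkstra semantics), allowing
#' departure and arrival mid-edge. Deterministic for fixed inputs.
#'
#' @param net a `road_network`.
#' @param a,b `network_location`s (see [snap_to_network()]).
#' @return a `route`: list with `traversals` (data.frame `edge_id`,
#'   `c_from`, `c_to`), concatenated `geometry` polyline and `length` in
#'   metres.
#' @export
shortest_route <- function(net, a, b) {
  if (a$edge_id == b$edge_id && abs(a$chainage - b$chainage) < 1e-12) {
    p <- a$point
    return(structure(list(
      traversals = data.frame(edge_id = a$edge_id, c_from = a$chainage,
                              c_to = a$chainage),
      geometry = rbind(p, p), length = 0), class = "route"))
  }
  g <- virtual_graph(net, list(a, b), c(".a.", ".b."))
  sp <- suppressWarnings(
    igraph::shortest_paths(g, from = ".a.", to = ".b.",
                           weights = igraph::E(g)$weight,
                           output = "both"))
  vpath <- sp$vpath[[1]]
  if (length(vpath) == 0L) {
    comp <- igraph::components(net$graph)
    e <- function(loc) comp$membership[as.character(
      net$edges$from[match(loc$edge_id, net$edges$edge_id)])]
    stop_streetaudit(
      sprintf("no route: endpoints lie in different components (%d vs %d)",
              e(a), e(b)),
      "streetaudit_no_route")
  }
  vnames <- igraph::V(g)$name[as.integer(vpath)]
  epath <- sp$epath[[1]]
  eid <- igraph::edge_attr(g, "edge_id", epath)
  ch_t <- igraph::edge_attr(g, "ch_t", epath)
  ch_h <- igraph::edge_attr(g, "ch_h", epath)
  tails <- igraph::edge_attr(g, "tail_name", epath)
  n <- length(epath)
  c_from <- numeric(n)
  c_to <- numeric(n)
  for (i in seq_len(n)) {
    # orient each traversed edge by the vertex the path enters it from
    if (tails[i] == vnames[i]) {
      c_from[i] <- ch_t[i]; c_to[i] <- ch_h[i]
    } else {
      c_from[i] <- ch_h[i]; c_to[i] <- ch_t[i]
    }
  }
  trav <- data.frame(edge_id = eid, c_from = c_from, c_to = c_to)
  trav <- trav[abs(trav$c_to - trav$c_from) > 1e-12 | n == 1L, , drop = FALSE]
  geom <- route_geometry(net, trav)
  structure(list(traversals = trav, geometry = geom,
                 length = sum(abs(trav$c_to - trav$c_from))),
            class = "route")
}

route_geometry <- function(net, trav) {
  pieces <- lapply(seq_len(nrow(trav)), function(i) {
    lo <- min(trav$c_from[i], trav$c_to[i])
    hi <- max(trav$c_from[i], trav$c_to[i])
    m <- extract_subline(net, trav$edge_id[i], lo, hi)
    if (trav$c_from[i] > trav$c_to[i]) m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
    m
  })
  g <- do.call(rbind, pieces)
  rownames(g) <- NULL
  g
}

#' @export
print.route <- function(x, ...) {
  cat(sprintf("<route> %.1f m over %d edge traversal(s)\n",
              x$length, nrow(x$traversals)))
  invisible(x)
}

# Chainage intervals of one edge (endpoint network distances dA, dB,
# length L) reachable within network distance D.
interval_cover <- function(L, dA, dB, D) {
  iv <- data.frame(c0 = numeric(0), c1 = numeric(0))
  if (is.finite(dA) && dA <= D)
    iv <- rbind(iv, data.frame(c0 = 0, c1 = min(L, D - dA)))
  if (is.finite(dB) && dB <= D)
    iv <- rbind(iv, data.frame(c0 = max(0, L - (D - dB)), c1 = L))
  if (nrow(iv)) merge_intervals(iv) else iv
}

#' Network (service-area) buffer around an origin
#'
#' Computes the set of network locations whose shortest-path distance from
#' the origin is at most `distance` metres, with edges cut exactly at the
#' distance frontier (partial edges). This is the road-network analogue of
#' a Euclidean buffer: the canonical operationalisation of a walkable
#' neighbourhood around a home or school.
#'
#' @param net a `road_network`.
#' @param origin a `network_location`.
#' @param distance buffer distance in metres (>= 0).
#' @return a `sub_network`; `distance = 0` yields the origin point as one
#'   degenerate zero-width portion.
#' @export
network_buffer <- function(net, origin, distance) {
  if (distance < 0)
    stop_streetaudit("buffer distance must be >= 0", "streetaudit_bad_distance")
  e <- match(origin$edge_id, net$edges$edge_id)
  L <- net$edges$length[e]
  c0 <- origin$chainage
  g <- virtual_graph(net, list(origin), ".o.")
  d <- igraph::distances(g, v = ".o.", weights = igraph::E(g)$weight)[1, ]
  names(d) <- igraph::V(g)$name
  out <- vector("list", nrow(net$edges) + 1L)
  for (i in seq_len(nrow(net$edges))) {
    if (i == e) next
    du <- d[[as.character(net$edges$from[i])]]
    dv <- d[[as.character(net$edges$to[i])]]
    iv <- interval_cover(net$edges$length[i], du, dv, distance)
    if (nrow(iv))
      out[[i]] <- data.frame(edge_id = net$edges$edge_id[i],
                             c0 = iv$c0, c1 = iv$c1)
  }
  # origin edge: treat as two half-edges split at the origin
  du <- d[[as.character(net$edges$from[e])]]
  dv <- d[[as.character(net$edges$to[e])]]
  iv1 <- interval_cover(c0, du, 0, distance)             # [0, c0]
  iv2 <- interval_cover(L - c0, 0, dv, distance)          # [c0, L] shifted
  iv2$c0 <- iv2$c0 + c0
  iv2$c1 <- iv2$c1 + c0
  iv <- rbind(iv1, iv2)
  if (nrow(iv) == 0L) iv <- data.frame(c0 = c0, c1 = c0)  # distance 0
  out[[nrow(net$edges) + 1L]] <- data.frame(edge_id = net$edges$edge_id[e],
                                            c0 = iv$c0, c1 = iv$c1)
  subnetwork(net, do.call(rbind, out))
}
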