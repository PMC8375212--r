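#' Road network graph from polyline centerlines
#'
#' Builds an undirected planar graph from a collection of polyline
#' centerlines in a projected metric CRS. Nodes are created at polyline
#' endpoints; endpoints closer than `snap_tol` are merged into a single
#' node (and the polyline endpoint is moved onto the node coordinate so
#' edge geometry and graph topology agree exactly). Zero-length features
#' are dropped with a warning. Edge lengths are the exact polyline
#' geometric lengths.
#'
#' @param lines list of polyline geometries, each a numeric matrix with two
#'   columns (x, y) in metres, or the result of [read_lines_geojson()].
#' @param crs_tag identifier of the projected CRS the coordinates are in.
#' @param snap_tol node snap tolerance in metres. Endpoints within this
#'   distance collapse to one node; 0.5 m suits metre-scale centerline data
#'   while avoiding false merges.
#' @return an object of class `road_network` with components `nodes`
#'   (data.frame: `node_id`, `x`, `y`), `edges` (data.frame: `edge_id`,
#'   `from`, `to`, `length`), `geometry` (list of coordinate matrices,
#'   indexed by edge), `segments` (flat per-segment table used for
#'   snapping), `graph` (the underlying igraph object) and `crs_tag`.
#' @export
load_network <- function(lines, crs_tag = "local-metric", snap_tol = 0.5) {
  if (length(lines) == 0L)
    stop_streetaudit("no line features supplied", "streetaudit_empty_input")
  lines <- lapply(lines, function(g) {
    g <- as.matrix(g)
    storage.mode(g) <- "double"
    g
  })
  allc <- do.call(rbind, lines)
  span <- sqrt(diff(range(allc[, 1]))^2 + diff(range(allc[, 2]))^2)
  if (all(abs(allc[, 1]) <= 180) && all(abs(allc[, 2]) <= 90) && span <= 2)
    stop_streetaudit(
      paste0("coordinates look geographic (degrees), not projected metres; ",
             "reproject to a metric CRS before loading"),
      "streetaudit_crs_error")

  lens <- vapply(lines, polyline_length, numeric(1))
  if (any(lens <= snap_tol * 1e-6 + 0)) {
    drop <- lens == 0
    if (any(drop)) {
      warning(sprintf("dropping %d zero-length feature(s)", sum(drop)))
      lines <- lines[!drop]
      lens <- lens[!drop]
    }
  }
  if (length(lines) == 0L)
    stop_streetaudit("all features were zero-length", "streetaudit_empty_input")

  # endpoint merging within snap_tol (greedy, via 2-D cell hashing)
  node_x <- numeric(0)
  node_y <- numeric(0)
  cell_index <- new.env(parent = emptyenv())
  cell_of <- function(x, y) paste(floor(x / snap_tol), floor(y / snap_tol))
  find_or_add <- function(x, y) {
    cx <- floor(x / snap_tol)
    cy <- floor(y / snap_tol)
    for (dx in -1:1) for (dy in -1:1) {
      key <- paste(cx + dx, cy + dy)
      ids <- cell_index[[key]]
      if (!is.null(ids)) {
        d2 <- (node_x[ids] - x)^2 + (node_y[ids] - y)^2
        hit <- ids[d2 <= snap_tol^2]
        if (length(hit)) return(hit[1])
      }
    }
    id <- length(node_x) + 1L
    node_x[id] <<- x
    node_y[id] <<- y
    key <- cell_of(x, y)
    cell_index[[key]] <- c(cell_index[[key]], id)
    id
  }

  nl <- length(lines)
  from <- integer(nl)
  to <- integer(nl)
  for (i in seq_len(nl)) {
    g <- lines[[i]]
    from[i] <- find_or_add(g[1, 1], g[1, 2])
    to[i] <- find_or_add(g[nrow(g), 1], g[nrow(g), 2])
    # align polyline endpoints with the (possibly merged) node coordinates
    g[1, ] <- c(node_x[from[i]], node_y[from[i]])
    g[nrow(g), ] <- c(node_x[to[i]], node_y[to[i]])
    lines[[i]] <- g
  }
  lens <- vapply(lines, polyline_length, numeric(1))
  keep <- lens > 0
  if (any(!keep)) {
    warning(sprintf("dropping %d feature(s) collapsed to zero length by node snapping",
                    sum(!keep)))
    lines <- lines[keep]
    from <- from[keep]
    to <- to[keep]
    lens <- lens[keep]
  }

  nodes <- data.frame(node_id = seq_along(node_x), x = node_x, y = node_y)
  edges <- data.frame(edge_id = seq_along(lines), from = from, to = to,
                      length = lens)
  net <- structure(list(nodes = nodes, edges = edges, geometry = lines,
                        crs_tag = crs_tag),
                   class = "road_network")
  net$segments <- build_segment_table(net)
  net$graph <- build_graph(net)
  net
}

build_graph <- function(net) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(net$edges$from),
               to = as.character(net$edges$to)),
    directed = FALSE,
    vertices = data.frame(name = as.character(net$nodes$node_id)))
  igraph::E(g)$weight <- net$edges$length
  igraph::E(g)$edge_id <- net$edges$edge_id
  g
}

build_segment_table <- function(net) {
  parts <- lapply(seq_along(net$geometry), function(i) {
    g <- net$geometry[[i]]
    ns <- nrow(g) - 1L
    dx <- diff(g[, 1])
    dy <- diff(g[, 2])
    sl <- sqrt(dx^2 + dy^2)
    data.frame(edge_id = net$edges$edge_id[i], seg = seq_len(ns),
               x1 = g[-nrow(g), 1], y1 = g[-nrow(g), 2],
               x2 = g[-1, 1], y2 = g[-1, 2],
               seg_start = cumsum(c(0, sl))[seq_len(ns)], seg_len = sl)
  })
  do.call(rbind, parts)
}

polyline_length <- function(g) {
  if (nrow(g) < 2L) return(0)
  sum(sqrt(diff(g[, 1])^2 + diff(g[, 2])^2))
}

#' Total length of a road network
#' @param net a `road_network`.
#' @return total edge length in metres.
#' @export
network_length <- function(net) sum(net$edges$length)

#' @export
print.road_network <- function(x, ...) {
  cat(sprintf("<road_network> %d nodes, %d edges, %.1f m total [%s]\n",
              nrow(x$nodes), nrow(x$edges), network_length(x), x$crs_tag))
  invisible(x)
}

# Coordinate of the point at `chainage` metres along edge `edge_id`.
point_at_chainage <- function(net, edge_id, chainage) {
  g <- net$geometry[[match(edge_id, net$edges$edge_id)]]
  segl <- sqrt(diff(g[, 1])^2 + diff(g[, 2])^2)
  cum <- cumsum(c(0, segl))
  L <- cum[length(cum)]
  ch <- min(max(chainage, 0), L)
  i <- findInterval(ch, cum, rightmost.closed = TRUE)
  i <- min(i, length(segl))
  t <- if (segl[i] > 0) (ch - cum[i]) / segl[i] else 0
  c(g[i, 1] + t * (g[i + 1, 1] - g[i, 1]),
    g[i, 2] + t * (g[i + 1, 2] - g[i, 2]))
}

# Vectorised over rows of data.frame(edge_id, chainage).
points_at_chainage <- function(net, ref) {
  out <- matrix(NA_real_, nrow(ref), 2)
  for (i in seq_len(nrow(ref)))
    out[i, ] <- point_at_chainage(net, ref$edge_id[i], ref$chainage[i])
  colnames(out) <- c("x", "y")
  out
}

# Sub-polyline of an edge between chainages c0 <= c1 (coordinate matrix).
extract_subline <- function(net, edge_id, c0, c1) {
  g <- net$geometry[[match(edge_id, net$edges$edge_id)]]
  segl <- sqrt(diff(g[, 1])^2 + diff(g[, 2])^2)
  cum <- cumsum(c(0, segl))
  p0 <- point_at_chainage(net, edge_id, c0)
  p1 <- point_at_chainage(net, edge_id, c1)
  mid <- which(cum > c0 + 1e-12 & cum < c1 - 1e-12)
  rbind(p0, g[mid, , drop = FALSE], p1)
}

#' Snap a point to the nearest network location
#'
#' Finds the edge and chainage minimising the Euclidean distance from the
#' query point to the network. Ties are broken by smallest edge id, then
#' smallest chainage, so snapping is fully deterministic.
#'
#' @param point numeric length-2 (x, y) in the network's CRS.
#' @param net a `road_network`.
#' @return a `network_location`: list with `edge_id`, `chainage` (metres
#'   from the edge's first node along the polyline), `offset` (metres from
#'   the original point to the snapped point) and the snapped `point`.
#' @export
snap_to_network <- function(point, net) {
  s <- net$segments
  px <- point[1]
  py <- point[2]
  vx <- s$x2 - s$x1
  vy <- s$y2 - s$y1
  tt <- ((px - s$x1) * vx + (py - s$y1) * vy) / pmax(s$seg_len^2, 1e-300)
  tt <- pmin(pmax(tt, 0), 1)
  qx <- s$x1 + tt * vx
  qy <- s$y1 + tt * vy
  d2 <- (qx - px)^2 + (qy - py)^2
  ch <- s$seg_start + tt * s$seg_len
  ord <- order(d2, s$edge_id, ch)
  b <- ord[1]
  # exact-tie refinement: among segments within 1e-9 of the minimum
  tol <- 1e-9
  cand <- which(d2 <= d2[b] + tol)
  if (length(cand) > 1L) {
    o <- cand[order(s$edge_id[cand], ch[cand])]
    b <- o[1]
  }
  structure(list(edge_id = s$edge_id[b], chainage = ch[b],
                 offset = sqrt(d2[b]), point = c(qx[b], qy[b])),
            class = "network_location")
}

#' @export
print.network_location <- function(x, ...) {
  cat(sprintf("<network_location> edge %d @ %.2f m (offset %.2f m)\n",
              x$edge_id, x$chainage, x$offset))
  invisible(x)
}

#' Construct a network location from linear-referencing coordinates
#'
#' @param edge_id edge identifier.
#' @param chainage metres from the edge's first node along the polyline.
#' @param net the `road_network` the location lies on.
#' @param offset recorded snap offset in metres (0 for an exact location).
#' @return a `network_location`.
#' @export
network_location <- function(edge_id, chainage, net, offset = 0) {
  structure(list(edge_id = edge_id, chainage = chainage, offset = offset,
                 point = point_at_chainage(net, edge_id, chainage)),
            class = "network_location")
}

# Union of chainage intervals on edges within `radius` metres (Euclidean)
# of any of the supplied points. Exact per straight segment: the covered
# chainage sub-interval for one (segment, point) pair is the solution of a
# quadratic in the along-segment parameter.
edge_intervals_within <- function(net, pts, radius) {
  s <- net$segments
  if (nrow(pts) == 0L || radius < 0)
    return(data.frame(edge_id = integer(0), c0 = numeric(0), c1 = numeric(0)))
  ns <- nrow(s)
  np <- nrow(pts)
  si <- rep(seq_len(ns), times = np)
  pi_ <- rep(seq_len(np), each = ns)
  x1 <- s$x1[si]; y1 <- s$y1[si]
  ux <- (s$x2[si] - x1) / pmax(s$seg_len[si], 1e-300)
  uy <- (s$y2[si] - y1) / pmax(s$seg_len[si], 1e-300)
  px <- pts$x[pi_]; py <- pts$y[pi_]
  wx <- px - x1; wy <- py - y1
  tproj <- wx * ux + wy * uy                  # metres along segment
  d2perp <- (wx^2 + wy^2) - tproj^2
  disc <- radius^2 - d2perp
  ok <- disc >= 0
  if (!any(ok))
    return(data.frame(edge_id = integer(0), c0 = numeric(0), c1 = numeric(0)))
  half <- sqrt(pmax(disc[ok], 0))
  t0 <- pmax(tproj[ok] - half, 0)
  t1 <- pmin(tproj[ok] + half, s$seg_len[si][ok])
  keep <- t1 >= t0
  iv <- data.frame(edge_id = s$edge_id[si][ok][keep],
                   c0 = (s$seg_start[si][ok] + t0)[keep],
                   c1 = (s$seg_start[si][ok] + t1)[keep])
  parts <- lapply(split(iv, iv$edge_id), function(d) {
    m <- merge_intervals(d[c("c0", "c1")])
    data.frame(edge_id = d$edge_id[1], c0 = m$c0, c1 = m$c1)
  })
  out <- do.call(rbind, parts)
  out <- out[order(out$edge_id, out$c0), , drop = FALSE]
  rownames(out) <- NULL
  out
}
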