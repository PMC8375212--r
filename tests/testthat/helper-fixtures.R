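# Fixture builders and independent brute-force oracles used across tests.
# The oracles deliberately take a different computational route from the
# package (densified graphs, exhaustive enumeration, point-in-disc scans).

seg2 <- function(x0, y0, x1, y1) rbind(c(x0, y0), c(x1, y1))

grid_lines <- function(nx, ny, b = 100) {
  lines <- list()
  for (j in 0:(ny - 1)) for (i in 0:(nx - 2))
    lines[[length(lines) + 1L]] <- seg2(i * b, j * b, (i + 1) * b, j * b)
  for (j in 0:(ny - 2)) for (i in 0:(nx - 1))
    lines[[length(lines) + 1L]] <- seg2(i * b, j * b, i * b, (j + 1) * b)
  lines
}

make_grid_network <- function(nx, ny, b = 100)
  load_network(grid_lines(nx, ny, b))

single_edge_network <- function(L)
  load_network(list(seg2(0, 0, L, 0)))

# n disjoint horizontal edges with given lengths, far apart vertically
disjoint_edges_network <- function(lengths, gap = 10000)
  load_network(lapply(seq_along(lengths), function(i)
    seg2(0, i * gap, lengths[i], i * gap)))

# --- densified brute-force graph oracle -------------------------------------

# Build an igraph where every edge is cut into pieces of ~`step` metres.
# `extra_breaks` is a list edge_id -> chainages that must appear as vertices
# (e.g. an origin). Vertex names encode (edge, chainage); original nodes
# keep shared names so the graph is connected exactly like the network.
densified_graph <- function(net, step = 1, extra_breaks = list()) {
  vname <- function(eid, ch, L, from, to) {
    ifelse(abs(ch) < 1e-9, paste0("N", from),
           ifelse(abs(ch - L) < 1e-9, paste0("N", to),
                  sprintf("E%d@%.6f", eid, ch)))
  }
  ef <- list()
  coords <- list()
  for (i in seq_len(nrow(net$edges))) {
    eid <- net$edges$edge_id[i]
    L <- net$edges$length[i]
    br <- sort(unique(c(seq(0, L, by = step), L,
                        extra_breaks[[as.character(eid)]])))
    nm <- vname(eid, br, L, net$edges$from[i], net$edges$to[i])
    ef[[i]] <- data.frame(from = nm[-length(nm)], to = nm[-1],
                          weight = diff(br))
    coords[[i]] <- data.frame(name = nm, edge_id = eid, chainage = br)
  }
  ed <- do.call(rbind, ef)
  ed <- ed[ed$weight > 0, ]
  g <- igraph::graph_from_data_frame(ed, directed = FALSE)
  list(graph = g, vertices = do.call(rbind, coords))
}

# Brute-force service-area length: total length of densified sub-edges both
# of whose endpoints are within D of the origin (underestimates by at most
# one step per frontier cut).
brute_buffer_length <- function(net, origin_edge, origin_ch, D, step = 0.05) {
  dg <- densified_graph(net, step,
                        extra_breaks = setNames(list(origin_ch),
                                                as.character(origin_edge)))
  e <- match(origin_edge, net$edges$edge_id)
  L <- net$edges$length[e]
  oname <- if (abs(origin_ch) < 1e-9) paste0("N", net$edges$from[e])
           else if (abs(origin_ch - L) < 1e-9) paste0("N", net$edges$to[e])
           else sprintf("E%d@%.6f", origin_edge, origin_ch)
  d <- igraph::distances(dg$graph, v = oname,
                         weights = igraph::E(dg$graph)$weight)[1, ]
  ends <- igraph::ends(dg$graph, igraph::E(dg$graph), names = TRUE)
  w <- igraph::E(dg$graph)$weight
  # midpoint rule: a sub-edge counts when its midpoint is reachable, so
  # quantisation error is at most step/2 per frontier cut
  sum(w[pmin(d[ends[, 1]], d[ends[, 2]]) + w / 2 <= D])
}

# Brute-force shortest node-to-node distance on the densified graph (exact:
# densification preserves edge lengths).
brute_node_distance <- function(net, node_a, node_b, step = 1) {
  dg <- densified_graph(net, step)
  igraph::distances(dg$graph, v = paste0("N", node_a),
                    to = paste0("N", node_b),
                    weights = igraph::E(dg$graph)$weight)[1, 1]
}

# Exhaustive simple-path enumeration between two nodes (tiny graphs only).
enumerate_min_path_length <- function(net, node_a, node_b) {
  g <- net$graph
  paths <- igraph::all_simple_paths(g, from = as.character(node_a),
                                    to = as.character(node_b))
  best <- Inf
  for (p in paths) {
    vp <- as.integer(p)
    eids <- igraph::get_edge_ids(g, rbind(vp[-length(vp)], vp[-1]))
    best <- min(best, sum(igraph::E(g)$weight[eids]))
  }
  best
}

# Euclidean distance from a point to a polyline (own tiny implementation,
# independent of the package's segment machinery).
dist_point_polyline <- function(p, g) {
  best <- Inf
  for (i in seq_len(nrow(g) - 1)) {
    a <- g[i, ]; b <- g[i + 1, ]
    v <- b - a
    L2 <- sum(v^2)
    t <- if (L2 > 0) max(0, min(1, sum((p - a) * v) / L2)) else 0
    q <- a + t * v
    best <- min(best, sqrt(sum((p - q)^2)))
  }
  best
}

# Simple O(n^2) coincident-point dedup used as an oracle for small cases.
brute_dedup_count <- function(x, y, tol = 0.5) {
  keep <- rep(TRUE, length(x))
  for (i in seq_along(x)) {
    if (!keep[i]) next
    for (j in seq_along(x)) {
      if (j <= i) next
      if ((x[i] - x[j])^2 + (y[i] - y[j])^2 <= tol^2) keep[j] <- FALSE
    }
  }
  sum(keep)
}

make_loc <- function(net, edge_id, chainage)
  network_location(edge_id, chainage, net)
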