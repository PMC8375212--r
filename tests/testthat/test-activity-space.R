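schools_df <- function(...) {
  m <- rbind(...)
  data.frame(id = m[, 1], x = as.numeric(m[, 2]), y = as.numeric(m[, 3]))
}

test_that("nearest school is chosen by network distance with id tie-break", {
  net <- make_grid_network(4, 4, 100)
  home <- snap_to_network(c(0, 0), net)

  one <- schools_df(c("s1", 300, 0))
  expect_equal(nearest_school(net, home, one), "s1")

  # network distances 400 vs 900
  two <- schools_df(c("far", 300, 600), c("near", 400, 0))
  expect_equal(nearest_school(net, home, two), "near")

  # three schools: brute-force comparison via per-school routes
  three <- schools_df(c("a", 250, 100), c("b", 100, 250), c("c", 300, 300))
  d <- vapply(seq_len(3), function(i) {
    shortest_route(net, home,
                   snap_to_network(c(three$x[i], three$y[i]), net))$length
  }, numeric(1))
  expect_equal(nearest_school(net, home, three), three$id[which.min(d)])

  # exact tie: both schools 300 m away -> smallest id wins
  tie <- schools_df(c("zz", 300, 0), c("aa", 0, 300))
  expect_equal(nearest_school(net, home, tie), "aa")

  # euclidean switch can change the answer: parallel streets joined only
  # at the far end
  net2 <- load_network(list(seg2(0, 0, 1000, 0), seg2(0, 100, 1000, 100),
                            seg2(0, 0, 0, 100)))
  h2 <- snap_to_network(c(900, 0), net2)
  s2 <- schools_df(c("across", 900, 100), c("along", 500, 0))
  expect_equal(nearest_school(net2, h2, s2, metric = "network"), "along")
  expect_equal(nearest_school(net2, h2, s2, metric = "euclidean"), "across")
})

test_that("unreachable schools raise an informative error", {
  net <- disjoint_edges_network(c(500, 500))
  home <- make_loc(net, 1, 10)
  sch <- schools_df(c("island", 100, 20000))   # snaps to component 2
  expect_error(nearest_school(net, home, sch),
               class = "streetaudit_unreachable")
})

test_that("coincident home and school reduce the space to one buffer", {
  net <- make_grid_network(5, 5, 100)
  p <- list(id = "c1", x = 150, y = 200)
  sch <- schools_df(c("s1", 150, 200))
  as <- build_activity_space(net, p, sch, r_home = 300)
  ref <- network_buffer(net, snap_to_network(c(150, 200), net), 300)
  expect_equal(subnetwork_length(as$audit), subnetwork_length(ref),
               tolerance = 1e-9)
  expect_equal(as$route$length, 0)
})

test_that("short straight routes add no corridor beyond the buffers", {
  net <- single_edge_network(1500)
  p <- list(id = "c1", x = 100, y = 0)
  sch <- schools_df(c("s1", 1400, 0))
  as <- build_activity_space(net, p, sch, r_home = 800, corridor = 200)
  expect_equal(subnetwork_length(as$audit),
               subnetwork_length(subnetwork_union(as$home_space,
                                                  as$school_space)),
               tolerance = 1e-9)
})

test_that("audit length matches a densified brute-force union", {
  net <- make_grid_network(4, 4, 100)
  home_xy <- c(40, 0)
  school_xy <- c(300, 220)
  p <- list(id = "c1", x = home_xy[1], y = home_xy[2])
  sch <- schools_df(c("s1", school_xy[1], school_xy[2]))
  r_home <- 350
  corridor <- 60
  as <- build_activity_space(net, p, sch, r_home = r_home,
                             corridor = corridor)

  # oracle: walk every edge at 2 cm, include positions reachable within
  # r of home or school (densified Dijkstra) or within `corridor` of the
  # route polyline (point-to-segment scan)
  step <- 0.02
  hloc <- snap_to_network(home_xy, net)
  sloc <- snap_to_network(school_xy, net)
  dg <- densified_graph(net, step, extra_breaks = list())
  dh <- igraph::distances(dg$graph, v = paste0("N", net$edges$from[hloc$edge_id]),
                          weights = igraph::E(dg$graph)$weight)[1, ]
  # home/school snapped mid-edge: adjust by running from both end nodes
  dist_from <- function(loc) {
    e <- loc$edge_id
    du <- igraph::distances(dg$graph, v = paste0("N", net$edges$from[e]),
                            weights = igraph::E(dg$graph)$weight)[1, ]
    dv <- igraph::distances(dg$graph, v = paste0("N", net$edges$to[e]),
                            weights = igraph::E(dg$graph)$weight)[1, ]
    pmin(du + loc$chainage, dv + (net$edges$length[e] - loc$chainage))
  }
  dh <- dist_from(hloc)
  ds <- dist_from(sloc)
  vtab <- dg$vertices[!duplicated(dg$vertices$name), ]
  # correction on the origin edges themselves (direct along-edge path)
  own <- function(loc, d) {
    sel <- vtab$edge_id == loc$edge_id
    d[vtab$name[sel]] <- pmin(d[vtab$name[sel]],
                              abs(vtab$chainage[sel] - loc$chainage))
    d
  }
  dh <- own(hloc, dh)
  ds <- own(sloc, ds)
  vxy <- streetaudit:::points_at_chainage(
    net, data.frame(edge_id = vtab$edge_id, chainage = vtab$chainage))
  dcorr <- vapply(seq_len(nrow(vxy)), function(i)
    dist_point_polyline(vxy[i, ], as$route$geometry), numeric(1))
  names(dcorr) <- vtab$name
  inc <- (dh[vtab$name] <= r_home) | (ds[vtab$name] <= r_home) |
         (dcorr <= corridor)
  names(inc) <- vtab$name
  ends <- igraph::ends(dg$graph, igraph::E(dg$graph), names = TRUE)
  w <- igraph::E(dg$graph)$weight
  oracle_len <- sum(w[inc[ends[, 1]] & inc[ends[, 2]]])
  expect_lt(abs(subnetwork_length(as$audit) - oracle_len), 1.5)
})

test_that("activity spaces are deterministic and monotone in radius", {
  net <- make_grid_network(4, 4, 100)
  p <- list(id = "c1", x = 40, y = 0)
  sch <- schools_df(c("s1", 300, 220))
  a1 <- build_activity_space(net, p, sch, r_home = 300)
  a2 <- build_activity_space(net, p, sch, r_home = 300)
  expect_identical(a1$audit$portions, a2$audit$portions)

  lens <- vapply(c(100, 200, 300, 500, 800), function(r)
    subnetwork_length(build_activity_space(net, p, sch, r_home = r)$audit),
    numeric(1))
  expect_true(all(diff(lens) >= -1e-9))
})

test_that("a zero-width corridor is exactly the route's own portions", {
  net <- make_grid_network(4, 4, 100)
  p <- list(id = "c1", x = 40, y = 0)
  sch <- schools_df(c("s1", 300, 220))
  as <- build_activity_space(net, p, sch, r_home = 100, corridor = 0)
  route_sub <- subnetwork(net, data.frame(
    edge_id = as$route$traversals$edge_id,
    c0 = pmin(as$route$traversals$c_from, as$route$traversals$c_to),
    c1 = pmax(as$route$traversals$c_from, as$route$traversals$c_to)))
  expect_equal(as$corridor_space$portions, route_sub$portions)
})

test_that("cohort building reports per-space lengths additively", {
  net <- make_grid_network(4, 4, 100)
  sch <- schools_df(c("s1", 300, 220))

  empty <- build_cohort_spaces(net, data.frame(id = character(0),
                                               x = numeric(0), y = numeric(0)),
                               sch)
  expect_equal(length(empty$spaces), 0L)
  expect_equal(attr(empty$summary, "total_audit_m"), 0)

  parts <- data.frame(id = sprintf("c%d", 1:5),
                      x = c(40, 150, 220, 40, 310),
                      y = c(0, 100, 300, 0, 150))
  res <- build_cohort_spaces(net, parts, sch, r_home = 250)
  expect_equal(nrow(res$summary), 5L)
  expect_equal(attr(res$summary, "total_audit_m"),
               sum(res$summary$audit_length_m))
  # duplicate participants (rows 1 and 4) get identical spaces
  expect_identical(res$spaces[["c1"]]$audit$portions,
                   res$spaces[["c4"]]$audit$portions)
})
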