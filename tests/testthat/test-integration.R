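obs_xy <- function(id, code, x, y, subtype = "") {
  n <- max(length(id), length(x))
  data.frame(coordinate_id = rep(id, length.out = n),
             feature_code = rep(code, length.out = n),
             subtype = rep(subtype, length.out = n),
             coder = rep("ra1", n), batch = rep("b1", n),
             x = rep(x, length.out = n), y = rep(y, length.out = n))
}

test_that("point layers hold one member per distinct coordinate", {
  dict <- feature_dictionary()
  empty <- build_point_layer(obs_xy(character(0), character(0),
                                    numeric(0), numeric(0)),
                             "food_outlet", dict)
  expect_equal(nrow(empty$members), 0L)

  twice <- rbind(obs_xy("pt1", "food_outlet", 10, 0, "cafe"),
                 obs_xy("pt1", "food_outlet", 10, 0, "bakery"),
                 obs_xy("pt2", "food_outlet", 45, 0))
  lay <- build_point_layer(twice, "food_outlet", dict)
  expect_equal(nrow(lay$members), 2L)
  expect_true(all(lay$members$provenance == "gsv"))

  expect_error(build_point_layer(twice, "footpath", dict),
               class = "streetaudit_kind_mismatch")
})

test_that("line-layer clipping is exact on straight edges", {
  net <- single_edge_network(200)
  dict <- feature_dictionary()
  one <- build_line_layer(obs_xy("pt1", "footpath", 100, 0), "footpath",
                          net, buffer = 20, dictionary = dict)
  expect_equal(one$members$c0, 80)
  expect_equal(one$members$c1, 120)
  expect_equal(sum(one$members$c1 - one$members$c0), 40)

  # consecutive 35 m-spaced coordinates: 20 m discs overlap -> contiguous
  obs <- rbind(obs_xy("pt1", "footpath", 50, 0),
               obs_xy("pt2", "footpath", 85, 0),
               obs_xy("pt3", "footpath", 120, 0))
  merged <- build_line_layer(obs, "footpath", net, buffer = 20,
                             dictionary = dict)
  expect_equal(nrow(merged$members), 1L)
  expect_equal(merged$members$c0, 30)
  expect_equal(merged$members$c1, 140)

  expect_error(build_line_layer(obs, "food_outlet", net, dictionary = dict),
               class = "streetaudit_kind_mismatch")
})

test_that("clipped length agrees with a densified point-in-disc oracle", {
  net <- make_grid_network(3, 3, 100)
  dict <- feature_dictionary()
  withr::with_seed(11, {
    obs <- do.call(rbind, lapply(1:6, function(i)
      obs_xy(paste0("pt", i), "footpath",
             runif(1, 0, 200), runif(1, 0, 200))))
  })
  lay <- build_line_layer(obs, "footpath", net, buffer = 20,
                          dictionary = dict)
  step <- 0.02
  oracle <- 0
  for (i in seq_len(nrow(net$edges))) {
    ch <- seq(step / 2, net$edges$length[i], by = step)   # midpoints
    xy <- streetaudit:::points_at_chainage(
      net, data.frame(edge_id = i, chainage = ch))
    covered <- rep(FALSE, nrow(xy))
    for (k in seq_len(nrow(obs)))
      covered <- covered |
        ((xy[, 1] - obs$x[k])^2 + (xy[, 2] - obs$y[k])^2 <= 400)
    oracle <- oracle + sum(covered) * step
  }
  expect_lt(abs(sum(lay$members$c1 - lay$members$c0) - oracle), 0.5)
})

test_that("gap-fill merge preserves council members and provenance", {
  dict <- feature_dictionary()
  council <- feature_layer("public_transport", "point",
                           data.frame(feature_id = c("c1", "c2"),
                                      x = c(10, 50), y = c(0, 0)))
  gsv <- build_point_layer(obs_xy(c("pt1", "pt2"), "public_transport",
                                  c(10, 200), c(0, 0)),
                           "public_transport", dict)

  m1 <- gap_fill_merge(council, feature_layer("public_transport", "point",
                                              gsv$members[0, ],
                                              provenance = "gsv"))
  expect_equal(nrow(m1$members), 2L)

  m2 <- gap_fill_merge(feature_layer("public_transport", "point",
                                     council$members[0, ]), gsv)
  expect_equal(nrow(m2$members), 2L)

  m3 <- gap_fill_merge(council, gsv)
  expect_equal(nrow(m3$members), 4L)   # overlapping members both retained
  expect_equal(sum(m3$members$provenance == "council"), 2L)
  expect_equal(sum(m3$members$provenance == "gsv"), 2L)

  other <- feature_layer("food_outlet", "point", council$members)
  expect_error(gap_fill_merge(other, gsv),
               class = "streetaudit_merge_mismatch")
})

test_that("temporal validation matches by code within the radius", {
  council <- data.frame(feature_id = c("a", "b", "c"),
                        code = c("public_transport", "public_transport",
                                 "pedestrian_crossing"),
                        x = c(0, 100, 200), y = c(0, 0, 0))
  obs <- rbind(obs_xy("pt1", "public_transport", 5, 0),
               obs_xy("pt2", "pedestrian_crossing", 100, 0))  # wrong code at b
  res <- temporal_validate(council, obs, match_radius = 20)
  expect_equal(res$validated$feature_id, "a")
  rep <- res$report
  expect_equal(rep$n_validated[rep$code == "public_transport"], 1L)
  expect_equal(rep$n_validated[rep$code == "pedestrian_crossing"], 0L)
  expect_equal(rep$n_provided[rep$code == "total"], 3L)
  expect_equal(rep$rate_pct[rep$code == "total"], 33)

  none <- temporal_validate(council, obs[0, ], match_radius = 20)
  expect_true(all(none$report$rate_pct == 0))

  # monotone in radius
  rates <- vapply(c(1, 5, 50, 150, 300), function(r) {
    rp <- temporal_validate(council, obs, match_radius = r)$report
    rp$n_validated[rp$code == "total"]
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
})

test_that("outlet compilation dedups by name and proximity with priority", {
  deg30 <- 30 / 111319.49   # ~30 m of latitude
  deg80 <- 80 / 111319.49
  zen <- data.frame(name = c("Cafe One", "Burger Barn"),
                    lon = c(174.1, 174.2), lat = c(-39.1, -39.2),
                    subtype = c("cafe", "meal takeaway"))
  plc <- data.frame(name = c("cafe-one!", "Burger  Barn", "Sushi Stop"),
                    lon = c(174.1, 174.2, 174.3),
                    lat = c(-39.1 + deg30, -39.2 + deg80, -39.3),
                    subtype = c("cafe", "meal takeaway", "restaurant"))
  out <- compile_outlets(zen, plc, dedup_radius = 50)
  kept <- out[out$kept, ]
  # "cafe-one!" at 30 m merges into the zenbu row; "Burger Barn" at 80 m
  # does not
  expect_equal(nrow(kept), 4L)
  expect_equal(kept$source[kept$name == "Cafe One"], "zenbu")
  expect_equal(sum(grepl("Burger", kept$name)), 2L)
  expect_equal(out$dup_of[!out$kept], 1L)

  disjoint <- compile_outlets(zen, plc[3, , drop = FALSE])
  expect_equal(nrow(disjoint[disjoint$kept, ]), 3L)

  # identical row in both feeds: kept once, zenbu wins
  both <- compile_outlets(zen[1, , drop = FALSE],
                          transform(zen[1, , drop = FALSE], name = "CAFE ONE"))
  expect_equal(sum(both$kept), 1L)
  expect_equal(both$source[both$kept], "zenbu")
})

test_that("feature summaries count distinct coordinates with row percents", {
  obs <- rbind(obs_xy(c("p1", "p2", "p3"), "footpath", 1:3, 0),
               obs_xy("p1", "footpath", 1, 0),        # repeat coordinate
               obs_xy("p4", "food_outlet", 4, 0))
  s <- summarize_features(obs)
  expect_equal(s$n_coordinates[s$feature_code == "footpath"], 3L)
  expect_equal(s$n_coordinates[s$feature_code == "total"], 4L)
  expect_equal(s$pct[s$feature_code == "footpath"], 75.0)

  single <- summarize_features(obs_xy("p1", "cycleway", 0, 0))
  expect_equal(single$pct, c(100, 100))
})

test_that("observed layers match ground truth on an ideal small town", {
  sp <- town_spec(seed = 21, grid = c(5L, 5L), coverage_prob = 1,
                  miss_prob = 0, anachronism_frac = 0, visibility = 20)
  town <- generate_town(sp)
  pts <- to_geographic(sample_points(whole_network(town$network), 15),
                       town$crs)
  recs <- resolve_requests(plan_requests(pts),
                           synthetic_provider(2014, 1, seed = 21))
  obs <- join_observations(coder_oracle(town, recs), pts)
  dict <- feature_dictionary()
  f <- town$features
  for (cd in unique(f$code[f$kind == "point"])) {
    lay <- build_point_layer(obs, cd, dict)
    truth <- f[f$code == cd, ]
    # every ground-truth feature is near some layer member, and every
    # member is near some ground-truth feature (visibility = 20 m)
    for (i in seq_len(nrow(truth))) {
      d2 <- (lay$members$x - truth$x[i])^2 + (lay$members$y - truth$y[i])^2
      expect_lte(min(d2), 400 + 1e-9)
    }
    for (i in seq_len(nrow(lay$members))) {
      d2 <- (truth$x - lay$members$x[i])^2 + (truth$y - lay$members$y[i])^2
      expect_lte(min(d2), 400 + 1e-9)
    }
  }
})
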