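test_that("town generation is fully deterministic in the seed", {
  s <- town_spec(seed = 31, grid = c(6L, 6L))
  t1 <- generate_town(s)
  t2 <- generate_town(s)
  expect_identical(t1$features, t2$features)
  expect_identical(t1$network$edges, t2$network$edges)
  expect_identical(t1$participants, t2$participants)
  t3 <- generate_town(town_spec(seed = 32, grid = c(6L, 6L)))
  expect_false(identical(t1$features, t3$features))
})

test_that("zero densities and degenerate grids are handled", {
  s <- town_spec(seed = 1, grid = c(4L, 4L),
                 densities = c(food_outlet = 0, footpath = 0))
  expect_equal(nrow(generate_town(s)$features), 0L)
  expect_error(town_spec(grid = c(1L, 4L)))
})

test_that("feature counts are Poisson with mean density x network km", {
  net_spec <- town_spec(seed = 99, grid = c(6L, 6L), irregular_frac = 0,
                        densities = c(food_outlet = 5))
  net <- withr::with_seed(99, streetaudit:::town_network(net_spec))
  km <- network_length(net) / 1000
  dict <- feature_dictionary()
  counts <- withr::with_seed(1234, vapply(1:200, function(i)
    nrow(streetaudit:::town_features(net_spec, net, dict)), numeric(1)))
  mu <- 5 * km
  se <- sqrt(mu / 200)
  expect_lt(abs(mean(counts) - mu), 3 * se)
})

test_that("features sit near the network with well-ordered dates", {
  s <- town_spec(seed = 7, grid = c(6L, 6L))
  town <- generate_town(s)
  f <- town$features
  seg <- town$network$segments
  for (i in seq_len(nrow(f))) {
    d <- dist_point_polyline(c(f$x[i], f$y[i]),
                             town$network$geometry[[f$edge_id[i]]])
    expect_lte(d, s$max_offset + 1e-9)
  }
  expect_true(all(f$install_year[f$anachronistic] > s$window[2]))
  expect_true(all(f$install_year[!f$anachronistic] < s$window[1]))
})

test_that("council exports apply omission but keep anachronisms", {
  s <- town_spec(seed = 17, grid = c(6L, 6L))
  town <- generate_town(s)
  inw <- streetaudit:::present_in_window(town$features, s$window)

  all_in <- export_council(town, q = 0)
  expect_equal(nrow(all_in$points) + nrow(all_in$lines),
               nrow(town$features))
  expect_equal(nrow(all_in$omitted), 0L)

  none <- export_council(town, q = 1)
  expect_equal(nrow(none$points) + nrow(none$lines),
               sum(!inw))
  expect_equal(nrow(none$omitted), sum(inw))

  # exported + omitted partition the ground truth
  part <- export_council(town, q = 0.4)
  got <- sort(c(part$points$feature_id, part$lines$feature_id,
                part$omitted$feature_id))
  expect_equal(got, sort(town$features$feature_id))
  # no dates in the export
  expect_false(any(grepl("year", names(part$points))))
})

test_that("omission frequency matches its probability", {
  s <- town_spec(seed = 55, grid = c(10L, 10L), anachronism_frac = 0,
                 densities = c(food_outlet = 30))   # ~1000 features
  town <- generate_town(s)
  n <- nrow(town$features)
  expect_gt(n, 400)
  ex <- export_council(town, q = 0.3)
  frac <- nrow(ex$omitted) / n
  expect_lt(abs(frac - 0.3), 3 * sqrt(0.3 * 0.7 / n))
})

test_that("the synthetic provider is deterministic and honours p", {
  full <- synthetic_provider(2014, p = 1, seed = 2)
  q <- full$query(174.123456, -39.123456)
  expect_equal(q$year, 2014L)
  expect_identical(full$query(174.123456, -39.123456), q)

  none <- synthetic_provider(2008:2019, p = 0, seed = 2)
  expect_equal(nrow(none$query(174.1, -39.1)), 0L)
})

test_that("in-range frequency matches coverage probability at scale", {
  # 2500 locations x 4 headings = 10,000 requests; single in-window year
  pts <- data.frame(point_id = sprintf("pt%06d", 1:2500),
                    lon = 174 + seq_len(2500) * 1e-5, lat = rep(-39.4, 2500))
  prov <- synthetic_provider(2014, p = 0.82, seed = 6)
  recs <- resolve_requests(plan_requests(pts), prov)
  expect_equal(nrow(recs), 10000L)
  frac <- summarize_in_range(recs)$n_in_range / nrow(recs)
  expect_lt(abs(frac - 0.82), 3 * sqrt(0.82 * 0.18 / 2500))
})

test_that("the coder oracle records all, none, or a 1-m fraction", {
  s <- town_spec(seed = 41, grid = c(8L, 8L), coverage_prob = 1,
                 miss_prob = 0, anachronism_frac = 0, visibility = 20)
  town <- generate_town(s)
  pts <- to_geographic(sample_points(whole_network(town$network), 15),
                       town$crs)
  recs <- resolve_requests(plan_requests(pts),
                           synthetic_provider(2014, 1, seed = 41))

  none <- coder_oracle(town, recs, miss_prob = 1)
  expect_equal(nrow(none), 0L)

  all_obs <- coder_oracle(town, recs, miss_prob = 0)
  inw <- town$features
  # with full coverage, perfect coding and 15 m spacing every in-window
  # feature (offset <= 10 m) is observed at least once
  expect_true(all(inw$code %in% all_obs$feature_code))
  for (i in seq_len(nrow(inw))) {
    o <- all_obs[all_obs$feature_code == inw$code[i], ]
    xy <- town$crs$to_planar(as.matrix(
      pts[match(o$coordinate_id, pts$point_id), c("lon", "lat")]))
    d2 <- (xy[, 1] - inw$x[i])^2 + (xy[, 2] - inw$y[i])^2
    expect_lte(min(d2), s$visibility^2 + 1e-6)
  }

  # per-exposure recording frequency ~ 1 - miss_prob
  part <- coder_oracle(town, recs, miss_prob = 0.2, seed = 4242)
  n_exp <- nrow(all_obs)
  expect_gt(n_exp, 500)
  frac <- nrow(part) / n_exp
  expect_lt(abs(frac - 0.8), 3 * sqrt(0.8 * 0.2 / n_exp) + 0.02)
})

test_that("the town spec round-trips through YAML", {
  s <- town_spec(seed = 12, grid = c(5L, 7L), coverage_prob = 0.4)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_town_spec_yaml(s, path)
  back <- read_town_spec_yaml(path)
  expect_equal(back$seed, s$seed)
  expect_equal(back$grid, s$grid)
  expect_equal(back$densities, s$densities)
  expect_identical(generate_town(back)$features,
                   generate_town(s)$features)
})

test_that("ideal pipelines recover everything; additions stay precise", {
  # complete imagery and coding, no anachronisms: gap-fill recovers every
  # omitted feature
  s1 <- town_spec(seed = 61, grid = c(6L, 6L), anachronism_frac = 0,
                  omission_frac = 0.5, coverage_prob = 1, miss_prob = 0)
  r1 <- end_to_end_eval(s1)
  expect_equal(r1$gapfill_sensitivity, 1.0)
  expect_equal(r1$pct_in_range, 100)

  # nothing omitted: imagery-only additions all correspond to true
  # in-window features (specificity direction)
  s2 <- town_spec(seed = 62, grid = c(6L, 6L), anachronism_frac = 0.3,
                  omission_frac = 0, coverage_prob = 1, miss_prob = 0)
  r2 <- end_to_end_eval(s2)
  expect_equal(r2$gapfill_precision, 1.0)
})

test_that("cohort-audit evaluation restricts scoring to audited ground truth", {
  s <- town_spec(seed = 71, grid = c(8L, 8L), coverage_prob = 1,
                 miss_prob = 0, anachronism_frac = 0)
  r <- end_to_end_eval(s, audit = "cohort")
  expect_lte(r$n_omitted_scored,
             nrow(r$detail$council$omitted))
  if (r$n_omitted_scored > 0)
    expect_equal(r$gapfill_sensitivity, 1.0)
})
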