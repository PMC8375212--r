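#' Synthetic town specification
#'
#' Parameters of the seeded fixture generator that emulates the study's
#' inputs: a connected metric road network (a grid core with an irregular
#' fringe, emulating a mixed urban-rural town), ground-truth streetscape
#' features with installation dates, council exports with configurable
#' omission and anachronism rates, and per-location panorama availability
#' by capture year.
#'
#' Defaults describe the emulated study conditions: a 2012-2016 study
#' window; a provider whose per-year coverage probability of 0.30 over
#' capture years 2008-2019 yields an in-range rate of about 83 percent
#' (1 - 0.7^5), the scale observed for street imagery of this vintage; a
#' 30 percent council omission rate and 20 percent anachronism fraction
#' (features installed after the window), reflecting council layers that
#' are materially incomplete and undated; features placed within 10 m
#' laterally of the centerline; and a 40 m coder visibility radius (a
#' street-level panorama resolves streetscape furniture to roughly that
#' range).
#'
#' @param seed integer; every random draw in the town flows from it.
#' @param grid integer length-2, node counts of the street grid.
#' @param block block edge length in metres.
#' @param irregular_frac fraction of edges given irregular (bent, longer)
#'   geometry.
#' @param densities named numeric, expected features per km of network for
#'   each feature code.
#' @param window inclusive study years.
#' @param anachronism_frac probability a feature is installed after the
#'   window ends (temporally invalid for the study).
#' @param omission_frac probability a within-window feature is missing
#'   from the council export.
#' @param coverage_prob per-schedule-year probability a location has a
#'   panorama.
#' @param schedule_years candidate capture years.
#' @param visibility coder visibility radius in metres.
#' @param miss_prob probability the coder misses a visible feature.
#' @param max_offset maximum lateral offset of point features from the
#'   centerline (m).
#' @param n_participants,n_schools cohort sizes.
#' @return a validated `town_spec` list.
#' @export
town_spec <- function(seed = 1L,
                      grid = c(10L, 10L),
                      block = 100,
                      irregular_frac = 0.2,
                      densities = c(footpath = 3, cycleway = 0.5,
                                    public_transport = 0.5,
                                    pedestrian_crossing = 1,
                                    on_street_parking = 1.5,
                                    traffic_calming = 1,
                                    park_playground = 0.3,
                                    food_outlet = 1.5),
                      window = c(2012L, 2016L),
                      anachronism_frac = 0.2,
                      omission_frac = 0.3,
                      coverage_prob = 0.30,
                      schedule_years = 2008:2019,
                      visibility = 40,
                      miss_prob = 0.05,
                      max_offset = 10,
                      n_participants = 5L,
                      n_schools = 2L) {
  stopifnot(grid[1] >= 2L, grid[2] >= 2L, block > 0,
            anachronism_frac >= 0, anachronism_frac <= 1,
            omission_frac >= 0, omission_frac <= 1,
            coverage_prob >= 0, coverage_prob <= 1,
            miss_prob >= 0, miss_prob <= 1,
            all(densities >= 0), irregular_frac >= 0, irregular_frac <= 1)
  structure(list(seed = as.integer(seed), grid = as.integer(grid),
                 block = block, irregular_frac = irregular_frac,
                 densities = densities, window = as.integer(window),
                 anachronism_frac = anachronism_frac,
                 omission_frac = omission_frac,
                 coverage_prob = coverage_prob,
                 schedule_years = as.integer(schedule_years),
                 visibility = visibility, miss_prob = miss_prob,
                 max_offset = max_offset,
                 n_participants = as.integer(n_participants),
                 n_schools = as.integer(n_schools)),
            class = "town_spec")
}

#' Read / write a town spec as YAML
#' @param spec a `town_spec`.
#' @param path file path.
#' @export
write_town_spec_yaml <- function(spec, path) {
  v <- unclass(spec)
  v$densities <- as.list(v$densities)
  yaml::write_yaml(v, path)
  invisible(path)
}

#' @rdname write_town_spec_yaml
#' @export
read_town_spec_yaml <- function(path) {
  v <- yaml::read_yaml(path)
  v$densities <- unlist(v$densities)
  do.call(town_spec, v)
}

#' Generate a synthetic town
#'
#' Builds the road network and seeded ground truth from a [town_spec()]:
#' feature counts are Poisson(density x network km) per code; point
#' features are placed along edges (probability proportional to edge
#' length, weighted towards the grid core to emulate an urban-rural mix)
#' with a lateral offset; line features attach to whole edges.
#' Anachronistic features receive install years after the window's end;
#' the rest are installed before the window starts. Fixed seed implies an
#' identical town.
#'
#' @param spec a `town_spec`.
#' @param dictionary feature dictionary.
#' @return a `synthetic_town`: list with `spec`, `network`, `features`
#'   (data.frame: id, code, kind, geometry reference, install year,
#'   anachronism flag), `participants`, `schools` and `crs` (the declared
#'   pseudo-CRS transform).
#' @export
generate_town <- function(spec, dictionary = feature_dictionary()) {
  stopifnot(inherits(spec, "town_spec"))
  with_seed(spec$seed, {
    net <- town_network(spec)
    feats <- town_features(spec, net, dictionary)
    homes <- random_network_points(net, spec$n_participants, max_offset = 30)
    homes$id <- sprintf("child%02d", seq_len(nrow(homes)))
    schools <- random_network_points(net, spec$n_schools, max_offset = 30)
    schools$id <- sprintf("school%02d", seq_len(nrow(schools)))
    structure(list(spec = spec, network = net, features = feats,
                   participants = homes[c("id", "x", "y")],
                   schools = schools[c("id", "x", "y")],
                   crs = pseudo_crs()),
              class = "synthetic_town")
  })
}

#' @export
print.synthetic_town <- function(x, ...) {
  cat(sprintf(
    "<synthetic_town> seed %d: %.1f km network, %d features (%d anachronistic), %d participants\n",
    x$spec$seed, network_length(x$network) / 1000, nrow(x$features),
    sum(x$features$anachronistic), nrow(x$participants)))
  invisible(x)
}

town_network <- function(spec) {
  nx <- spec$grid[1]
  ny <- spec$grid[2]
  b <- spec$block
  lines <- list()
  for (j in 0:(ny - 1)) for (i in 0:(nx - 2))
    lines[[length(lines) + 1L]] <- rbind(c(i * b, j * b), c((i + 1) * b, j * b))
  for (j in 0:(ny - 2)) for (i in 0:(nx - 1))
    lines[[length(lines) + 1L]] <- rbind(c(i * b, j * b), c(i * b, (j + 1) * b))
  n_irr <- floor(spec$irregular_frac * length(lines))
  if (n_irr > 0) {
    irr <- sample(seq_along(lines), n_irr)
    for (k in irr) {
      g <- lines[[k]]
      mid <- (g[1, ] + g[2, ]) / 2
      d <- g[2, ] - g[1, ]
      perp <- c(-d[2], d[1]) / sqrt(sum(d^2))
      off <- stats::runif(1, 5, 25) * sample(c(-1, 1), 1)
      lines[[k]] <- rbind(g[1, ], mid + off * perp, g[2, ])
    }
  }
  load_network(lines, crs_tag = "synthetic-town-plane")
}

# Edge-selection weights: full weight in the central core, half on the
# fringe (urban-rural density contrast); total counts are unaffected.
edge_weights <- function(net) {
  mids <- t(vapply(net$geometry, function(g)
    (g[1, ] + g[nrow(g), ]) / 2, numeric(2)))
  rx <- range(net$nodes$x)
  ry <- range(net$nodes$y)
  core <- mids[, 1] >= rx[1] + diff(rx) / 4 & mids[, 1] <= rx[2] - diff(rx) / 4 &
          mids[, 2] >= ry[1] + diff(ry) / 4 & mids[, 2] <= ry[2] - diff(ry) / 4
  ifelse(core, 1, 0.5) * net$edges$length
}

town_features <- function(spec, net, dictionary) {
  km <- network_length(net) / 1000
  w <- edge_weights(net)
  rows <- list()
  fid <- 0L
  for (code in names(spec$densities)) {
    kind <- dictionary$kind[match(code, dictionary$code)]
    n <- stats::rpois(1, spec$densities[[code]] * km)
    if (n == 0L) next
    eidx <- sample(seq_len(nrow(net$edges)), n, replace = TRUE, prob = w)
    if (kind == "line") eidx <- unique(eidx)
    for (e in eidx) {
      fid <- fid + 1L
      L <- net$edges$length[e]
      if (kind == "point") {
        ch <- stats::runif(1, 0, L)
        base <- point_at_chainage(net, net$edges$edge_id[e], ch)
        ang <- heading_at(net, e, ch)
        off <- stats::runif(1, 0, spec$max_offset) * sample(c(-1, 1), 1)
        xy <- base + off * c(-ang[2], ang[1])
        c0 <- ch; c1 <- ch
      } else {
        mid <- point_at_chainage(net, net$edges$edge_id[e], L / 2)
        xy <- mid
        ch <- L / 2
        c0 <- 0; c1 <- L
      }
      ana <- stats::runif(1) < spec$anachronism_frac
      inst <- if (ana) sample(seq(spec$window[2] + 1L, spec$window[2] + 3L), 1)
              else sample(seq(spec$window[1] - 12L, spec$window[1] - 1L), 1)
      sub <- if (code == "food_outlet") sample(outlet_subtypes(), 1) else ""
      rows[[fid]] <- data.frame(
        feature_id = NA_character_, code = code, kind = kind,
        edge_id = net$edges$edge_id[e], chainage = ch, c0 = c0, c1 = c1,
        x = xy[1], y = xy[2], subtype = sub,
        install_year = as.integer(inst), removal_year = NA_integer_,
        anachronistic = ana)
    }
  }
  feats <- do.call(rbind, rows) %||% data.frame(
    feature_id = character(0), code = character(0), kind = character(0),
    edge_id = integer(0), chainage = numeric(0), c0 = numeric(0),
    c1 = numeric(0), x = numeric(0), y = numeric(0), subtype = character(0),
    install_year = integer(0), removal_year = integer(0),
    anachronistic = logical(0))
  if (nrow(feats))
    feats$feature_id <- sprintf("f%05d", seq_len(nrow(feats)))
  rownames(feats) <- NULL
  feats
}

heading_at <- function(net, eidx, ch) {
  g <- net$geometry[[eidx]]
  segl <- sqrt(diff(g[, 1])^2 + diff(g[, 2])^2)
  cum <- cumsum(c(0, segl))
  i <- min(max(findInterval(ch, cum, rightmost.closed = TRUE), 1),
           length(segl))
  d <- c(g[i + 1, 1] - g[i, 1], g[i + 1, 2] - g[i, 2])
  d / sqrt(sum(d^2))
}

random_network_points <- function(net, n, max_offset = 30) {
  if (n == 0L) return(data.frame(x = numeric(0), y = numeric(0)))
  eidx <- sample(seq_len(nrow(net$edges)), n, replace = TRUE,
                 prob = net$edges$length)
  rows <- lapply(eidx, function(e) {
    L <- net$edges$length[e]
    ch <- stats::runif(1, 0, L)
    base <- point_at_chainage(net, net$edges$edge_id[e], ch)
    ang <- heading_at(net, e, ch)
    off <- stats::runif(1, 5, max_offset) * sample(c(-1, 1), 1)
    data.frame(x = base[1] - off * ang[2], y = base[2] + off * ang[1])
  })
  do.call(rbind, rows)
}

# A feature existed at some point inside the study window?
present_in_window <- function(features, window) {
  features$install_year <= window[2] &
    (is.na(features$removal_year) | features$removal_year >= window[1])
}

#' Export council layers from ground truth
#'
#' Emulates an administrative data provision: each within-window feature
#' is omitted independently with probability `q`; anachronistic features
#' are included (they exist "now", at provision time); no dates appear in
#' the export.
#'
#' @param town a `synthetic_town`.
#' @param q omission probability (defaults to the town spec's).
#' @param seed RNG seed for the omission draws (defaults to spec seed + 1).
#' @return list with `points` (data.frame `feature_id`, `code`, `x`, `y`),
#'   `lines` (data.frame `feature_id`, `code`, `edge_id`, `c0`, `c1`) and
#'   `omitted` (the withheld within-window features, for scoring).
#' @export
export_council <- function(town, q = town$spec$omission_frac,
                           seed = town$spec$seed + 1L) {
  f <- town$features
  inw <- present_in_window(f, town$spec$window)
  keep <- with_seed(seed, inw & stats::runif(nrow(f)) >= q)
  keep <- keep | !inw          # anachronisms always included
  exported <- f[keep, , drop = FALSE]
  omitted <- f[!keep & inw, , drop = FALSE]
  pts <- exported[exported$kind == "point", c("feature_id", "code", "x", "y")]
  lns <- exported[exported$kind == "line",
                  c("feature_id", "code", "edge_id", "c0", "c1")]
  rownames(pts) <- rownames(lns) <- rownames(omitted) <- NULL
  list(points = pts, lines = lns, omitted = omitted)
}

#' Synthetic panorama provider
#'
#' Deterministic per (seed, location): the location's coordinates are
#' hashed with the seed to drive its availability draws, so repeated
#' queries (in any order) return identical panoramas. Each schedule year
#' carries a panorama with probability `p`.
#'
#' @param schedule_years candidate capture years.
#' @param p per-year coverage probability.
#' @param seed integer seed.
#' @return a `panorama_provider`.
#' @export
synthetic_provider <- function(schedule_years = 2008:2019, p = 0.30,
                               seed = 1L) {
  force(schedule_years); force(p); force(seed)
  panorama_provider(name = "synthetic", query = function(lon, lat) {
    h <- str_hash(sprintf("%.6f|%.6f", lon, lat), seed)
    with_seed(h, {
      avail <- stats::runif(length(schedule_years)) < p
      yrs <- schedule_years[avail]
      if (length(yrs) == 0L)
        return(data.frame(pano_id = character(0), year = integer(0),
                          month = integer(0)))
      data.frame(pano_id = sprintf("sp%08d_%d", h %% 100000000L, yrs),
                 year = as.integer(yrs),
                 month = sample(1:12, length(yrs), replace = TRUE))
    })
  })
}

#' Coder oracle: simulate feature coding from resolved imagery
#'
#' For every coordinate with an in-range image, each ground-truth feature
#' that was present during the study window and lies within the
#' visibility radius of the coordinate is recorded with probability
#' `1 - miss_prob` (line features count as visible when the coordinate is
#' within the radius of their edge geometry). Output follows the coder
#' checklist schema.
#'
#' @param town a `synthetic_town`.
#' @param records resolved image records ([resolve_requests()]).
#' @param visibility visibility radius in metres (default: spec's).
#' @param miss_prob per-exposure miss probability (default: spec's).
#' @param seed RNG seed (default: spec seed + 2).
#' @return observation table: `coordinate_id`, `feature_code`, `subtype`,
#'   `coder`, `batch`.
#' @export
coder_oracle <- function(town, records, visibility = town$spec$visibility,
                         miss_prob = town$spec$miss_prob,
                         seed = town$spec$seed + 2L) {
  inr <- records[records$outcome == "in_range", , drop = FALSE]
  coords <- unique(inr[c("point_id", "lon", "lat")])
  if (nrow(coords) == 0L)
    return(data.frame(coordinate_id = character(0),
                      feature_code = character(0), subtype = character(0),
                      coder = character(0), batch = character(0)))
  xy <- town$crs$to_planar(cbind(coords$lon, coords$lat))
  f <- town$features
  f <- f[present_in_window(f, town$spec$window), , drop = FALSE]
  fp <- f[f$kind == "point", , drop = FALSE]
  fl <- f[f$kind == "line", , drop = FALSE]
  seg <- town$network$segments
  rows <- list()
  for (k in seq_len(nrow(fp))) {
    vis <- (xy[, 1] - fp$x[k])^2 + (xy[, 2] - fp$y[k])^2 <= visibility^2
    if (any(vis))
      rows[[length(rows) + 1L]] <-
        data.frame(coordinate_id = coords$point_id[vis],
                   feature_code = fp$code[k], subtype = fp$subtype[k])
  }
  for (k in seq_len(nrow(fl))) {
    ss <- seg[seg$edge_id == fl$edge_id[k], , drop = FALSE]
    d2min <- rep(Inf, nrow(coords))
    for (j in seq_len(nrow(ss))) {
      vx <- ss$x2[j] - ss$x1[j]
      vy <- ss$y2[j] - ss$y1[j]
      tt <- ((xy[, 1] - ss$x1[j]) * vx + (xy[, 2] - ss$y1[j]) * vy) /
        max(ss$seg_len[j]^2, 1e-300)
      tt <- pmin(pmax(tt, 0), 1)
      d2min <- pmin(d2min, (ss$x1[j] + tt * vx - xy[, 1])^2 +
                           (ss$y1[j] + tt * vy - xy[, 2])^2)
    }
    vis <- d2min <= visibility^2
    if (any(vis))
      rows[[length(rows) + 1L]] <-
        data.frame(coordinate_id = coords$point_id[vis],
                   feature_code = fl$code[k], subtype = fl$subtype[k])
  }
  obs <- do.call(rbind, rows)
  if (!is.null(obs))
    obs <- obs[order(obs$coordinate_id, obs$feature_code, obs$subtype), ,
               drop = FALSE]
  if (is.null(obs) || nrow(obs) == 0L)
    return(data.frame(coordinate_id = character(0),
                      feature_code = character(0), subtype = character(0),
                      coder = character(0), batch = character(0)))
  keep <- with_seed(seed, stats::runif(nrow(obs)) >= miss_prob)
  obs <- obs[keep, , drop = FALSE]
  obs <- unique(obs)
  obs$coder <- rep("oracle", nrow(obs))
  obs$batch <- rep("sim1", nrow(obs))
  obs <- obs[order(obs$coordinate_id, obs$feature_code), , drop = FALSE]
  rownames(obs) <- NULL
  obs
}
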