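#' GeoJSON readers and writers
#'
#' Minimal GeoJSON (RFC 7946) support for the layer types the pipeline
#' exchanges: polyline collections (road centerlines, audit sub-networks)
#' and point tables (participants, schools, feature layers). The projected
#' CRS identifier travels as a top-level `crs_tag` foreign member, since
#' the layers are in a projected metric plane rather than WGS84.
#'
#' @param geoms list of two-column coordinate matrices.
#' @param path file path.
#' @param crs_tag CRS identifier string recorded in the file.
#' @param properties optional data.frame of per-feature properties.
#' @return `write_*` return `path` invisibly; `read_lines_geojson` returns
#'   a list with `lines` (list of coordinate matrices), `properties` and
#'   `crs_tag`; `read_points_geojson` returns a data.frame with `x`, `y`
#'   and any properties, plus a `crs_tag` attribute.
#' @export
write_lines_geojson <- function(geoms, path, crs_tag = "local-metric",
                                properties = NULL) {
  feats <- lapply(seq_along(geoms), function(i) {
    g <- geoms[[i]]
    props <- if (is.null(properties)) list(fid = i) else
      as.list(properties[i, , drop = FALSE])
    list(type = "Feature",
         properties = props,
         geometry = list(type = "LineString",
                         coordinates = lapply(seq_len(nrow(g)),
                                              function(r) c(g[r, 1], g[r, 2]))))
  })
  obj <- list(type = "FeatureCollection", crs_tag = crs_tag, features = feats)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_lines_geojson
#' @export
read_lines_geojson <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lines <- lapply(obj$features, function(f) {
    cc <- f$geometry$coordinates
    m <- matrix(unlist(cc), ncol = 2, byrow = TRUE)
    colnames(m) <- c("x", "y")
    m
  })
  props <- lapply(obj$features, function(f) as.data.frame(f$properties))
  props <- tryCatch(do.call(rbind, props), error = function(e) NULL)
  list(lines = lines, properties = props,
       crs_tag = obj$crs_tag %||% "unknown")
}

#' @rdname write_lines_geojson
#' @param df data.frame with columns `x`, `y` and any extra properties.
#' @export
write_points_geojson <- function(df, path, crs_tag = "local-metric") {
  prop_cols <- setdiff(names(df), c("x", "y"))
  feats <- lapply(seq_len(nrow(df)), function(i) {
    list(type = "Feature",
         properties = as.list(df[i, prop_cols, drop = FALSE]),
         geometry = list(type = "Point",
                         coordinates = c(df$x[i], df$y[i])))
  })
  obj <- list(type = "FeatureCollection", crs_tag = crs_tag, features = feats)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_lines_geojson
#' @export
read_points_geojson <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  rows <- lapply(obj$features, function(f) {
    cc <- f$geometry$coordinates
    cbind(data.frame(x = cc[[1]], y = cc[[2]]),
          as.data.frame(f$properties))
  })
  out <- do.call(rbind, rows)
  attr(out, "crs_tag") <- obj$crs_tag %||% "unknown"
  out
}

#' Write / read a road network as GeoJSON
#'
#' Round-trips exactly: reloading reproduces node and edge counts and total
#' length to floating precision.
#'
#' @param net a `road_network`.
#' @param path file path.
#' @export
write_network_geojson <- function(net, path) {
  write_lines_geojson(net$geometry, path, crs_tag = net$crs_tag,
                      properties = data.frame(edge_id = net$edges$edge_id))
}

#' @rdname write_network_geojson
#' @param snap_tol node snap tolerance passed to [load_network()].
#' @export
read_network_geojson <- function(path, snap_tol = 0.5) {
  obj <- read_lines_geojson(path)
  load_network(obj$lines, crs_tag = obj$crs_tag, snap_tol = snap_tol)
}
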