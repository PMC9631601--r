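## Plain-text I/O: encounter CSV, pond GeoJSON (Point features), road geometry
## (GeoJSON LineString or WKT LINESTRING), kernel JSON.

#' Write / read encounter records as CSV
#'
#' Columns: `individual_id, species, sex, date, session, x, y, pond_id`.
#'
#' @param records encounter data.frame.
#' @param path file path.
#' @return `read_encounters_csv` returns the records data.frame with `date`
#'   parsed as `Date`.
#' @export
write_encounters_csv <- function(records, path) {
  cols <- c("individual_id", "species", "sex", "date", "session", "x", "y",
            "pond_id")
  missing <- setdiff(cols, names(records))
  for (m in missing) records[[m]] <- NA
  write.csv(records[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_encounters_csv
#' @export
read_encounters_csv <- function(path) {
  rec <- read.csv(path, stringsAsFactors = FALSE)
  rec$date <- as.Date(rec$date)
  rec$pond_id <- as.character(rec$pond_id)
  rec$pond_id[rec$pond_id %in% c("", "NA")] <- NA_character_
  rec
}

#' Write / read a pond registry as GeoJSON Point features
#'
#' Feature properties carry `id`, `sector` and any extra pond columns (e.g.
#' per-species breeding flags).
#'
#' @param ponds pond registry data.frame (`id`, `x`, `y`, ...).
#' @param path file path.
#' @return `read_ponds_geojson` returns the pond data.frame.
#' @export
write_ponds_geojson <- function(ponds, path) {
  extra <- setdiff(names(ponds), c("x", "y"))
  features <- lapply(seq_len(nrow(ponds)), function(i) {
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(ponds$x[i], ponds$y[i])),
         properties = as.list(ponds[i, extra, drop = FALSE]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ponds_geojson
#' @export
read_ponds_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  stopifnot(identical(gj$type, "FeatureCollection"))
  rows <- lapply(gj$features, function(f) {
    stopifnot(identical(f$geometry$type, "Point"))
    props <- f$properties
    c(list(x = as.numeric(f$geometry$coordinates[[1]]),
           y = as.numeric(f$geometry$coordinates[[2]])),
      lapply(props, function(v) if (is.null(v)) NA else v))
  })
  out <- do.call(rbind, lapply(rows, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
  out[, c("id", "x", "y", setdiff(names(out), c("id", "x", "y"))), drop = FALSE]
}

#' Read a road polyline
#'
#' Accepts a GeoJSON file containing a LineString geometry (bare geometry,
#' Feature or FeatureCollection) or a WKT `LINESTRING (...)` string/file.
#'
#' @param x path to a `.geojson`/`.json` file, a WKT string, or a path to a
#'   file containing one.
#' @return two-column matrix of vertices.
#' @export
read_road <- function(x) {
  txt <- if (file.exists(x)) paste(readLines(x, warn = FALSE), collapse = "\n")
         else x
  if (grepl("^\\s*LINESTRING", txt, ignore.case = TRUE)) {
    body <- sub(".*\\(", "", sub("\\).*", "", txt))
    pts <- strsplit(trimws(strsplit(body, ",")[[1]]), "\\s+")
    return(do.call(rbind, lapply(pts, as.numeric)))
  }
  gj <- jsonlite::parse_json(txt)
  geom <- if (identical(gj$type, "FeatureCollection")) gj$features[[1]]$geometry
          else if (identical(gj$type, "Feature")) gj$geometry
          else gj
  stopifnot(identical(geom$type, "LineString"))
  do.call(rbind, lapply(geom$coordinates, function(c2) {
    c(as.numeric(c2[[1]]), as.numeric(c2[[2]]))
  }))
}

#' Serialize a fitted dispersal kernel to JSON
#'
#' @param kernel a `dispersal_kernel`.
#' @param path file path.
#' @return `read_kernel_json` returns the `dispersal_kernel`.
#' @export
write_kernel_json <- function(kernel, path) {
  jsonlite::write_json(
    list(family = kernel$family, params = as.list(kernel$params),
         n = kernel$n, loglik = kernel$loglik, aic = kernel$aic),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_kernel_json
#' @export
read_kernel_json <- function(path) {
  k <- jsonlite::read_json(path)
  structure(list(family = k$family, params = unlist(k$params),
                 n = k$n, loglik = k$loglik, aic = k$aic),
            class = "dispersal_kernel")
}

#' Export a graph's edges and metrics as CSV / GeoJSON
#'
#' @param graph a `pond_graph`.
#' @param path file path.
#' @return invisibly, the path.
#' @export
write_graph_edges_csv <- function(graph, path) {
  n <- nrow(graph$nodes)
  idx <- which(upper.tri(graph$p), arr.ind = TRUE)
  edges <- data.frame(
    i = graph$nodes$id[idx[, 1]], j = graph$nodes$id[idx[, 2]],
    distance_m = if (!is.null(graph$dist)) graph$dist[idx] else NA_real_,
    effective_distance_m = if (!is.null(graph$eff_dist)) graph$eff_dist[idx]
                           else NA_real_,
    p = graph$p[idx], stringsAsFactors = FALSE)
  write.csv(edges, path, row.names = FALSE)
  invisible(path)
}

#' @param metrics per-pond metrics data.frame with an `id` column, merged
#'   into the feature properties.
#' @rdname write_graph_edges_csv
#' @export
write_metrics_geojson <- function(graph, metrics, path) {
  nodes <- merge(graph$nodes, metrics, by = "id", sort = FALSE)
  if (!all(c("x", "y") %in% names(nodes))) {
    nodes$x <- NA_real_; nodes$y <- NA_real_
  }
  write_ponds_geojson(nodes, path)
}
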