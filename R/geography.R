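#' @import data.table
NULL

EARTH_RADIUS_KM <- 6371

#' Multi-level geography
#'
#' An `odt_geography` bundles one or more geographic levels (ordered from
#' finest to coarsest, e.g. `cbg < county < state`) with, per level, the
#' place polygons and a parent link to the next-coarser level. Place ids are
#' FIPS-style string codes; for nested FIPS codes the parent link agrees
#' with code-prefix truncation.
#'
#' @param levels character vector of level names ordered finest to coarsest.
#' @param places `data.frame` with columns `place_id`, `name`, `level`,
#'   `centroid_lat`, `centroid_lon`.
#' @param polygons named list (by `place_id`) of polygons; each polygon is a
#'   two-column matrix of vertices in `(lon, lat)` degrees (closed or open
#'   ring, either accepted).
#' @param parent named character vector mapping a child `place_id` to its
#'   parent `place_id` at the next-coarser level.
#'
#' @return An object of class `odt_geography`.
#' @export
odt_geography <- function(levels, places, polygons, parent = character()) {
  stopifnot(is.character(levels), length(levels) >= 1)
  places <- as.data.table(places)
  req <- c("place_id", "name", "level", "centroid_lat", "centroid_lon")
  if (!all(req %in% names(places))) {
    stop("places must have columns: ", paste(req, collapse = ", "))
  }
  if (anyDuplicated(places[, .(place_id, level)])) {
    stop("place_id must be unique within a level")
  }
  bad <- setdiff(unique(places$level), levels)
  if (length(bad)) stop("places reference unknown level(s): ",
                        paste(bad, collapse = ", "))
  geo <- structure(
    list(levels = levels, places = places, polygons = polygons,
         parent = parent),
    class = "odt_geography"
  )
  geo
}

#' @export
print.odt_geography <- function(x, ...) {
  cat("<odt_geography>\n")
  cat("  levels (fine -> coarse):", paste(x$levels, collapse = " < "), "\n")
  tab <- x$places[, .N, by = level]
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("  %s: %d places\n", tab$level[i], tab$N[i]))
  }
  invisible(x)
}

level_index <- function(geography, level) {
  i <- match(level, geography$levels)
  if (is.na(i)) stop("unknown level '", level, "'; known: ",
                     paste(geography$levels, collapse = ", "))
  i
}

#' Places at one level
#'
#' @param geography an `odt_geography`.
#' @param level level name.
#' @return `data.table` of places at that level.
#' @export
geo_places <- function(geography, level) {
  level_index(geography, level)
  keep <- which(geography$places$level == level) # plain vector: avoids NSE capture
  geography$places[keep]
}

validate_coords <- function(lat, lon) {
  if (any(!is.finite(lat)) || any(!is.finite(lon)) ||
      any(lat < -90) || any(lat > 90) || any(lon < -180) || any(lon > 180)) {
    stop("coordinate error: lat must be in [-90, 90], lon in [-180, 180]")
  }
  invisible(TRUE)
}

# Ray-casting point-in-polygon with boundary counted as inside.
# ring: two-column (lon, lat) matrix; open or closed ring accepted.
point_in_ring <- function(lon, lat, ring) {
  n <- nrow(ring)
  if (n >= 2 && ring[1, 1] == ring[n, 1] && ring[1, 2] == ring[n, 2]) {
    ring <- ring[-n, , drop = FALSE]
    n <- n - 1L
  }
  if (n < 3) return(FALSE)
  xs <- ring[, 1]; ys <- ring[, 2]
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- xs[i]; yi <- ys[i]; xj <- xs[j]; yj <- ys[j]
    # boundary: point on segment (i, j)
    cross <- (xj - xi) * (lat - yi) - (yj - yi) * (lon - xi)
    if (cross == 0 &&
        lon >= min(xi, xj) && lon <= max(xi, xj) &&
        lat >= min(yi, yj) && lat <= max(yi, yj)) {
      return(TRUE)
    }
    if ((yi > lat) != (yj > lat)) {
      xint <- xi + (lat - yi) * (xj - xi) / (yj - yi)
      if (lon < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

point_in_polygon <- function(lon, lat, polygon) {
  if (is.matrix(polygon)) polygon <- list(polygon)
  for (ring in polygon) {
    if (point_in_ring(lon, lat, ring)) return(TRUE)
  }
  FALSE
}

polygon_bbox <- function(polygon) {
  if (is.matrix(polygon)) polygon <- list(polygon)
  xs <- unlist(lapply(polygon, function(r) r[, 1]))
  ys <- unlist(lapply(polygon, function(r) r[, 2]))
  c(xmin = min(xs), ymin = min(ys), xmax = max(xs), ymax = max(ys))
}

#' Assign a point to the place containing it
#'
#' Point-in-polygon lookup against one geographic level. The polygon
#' boundary counts as inside; if several polygons claim a boundary point the
#' place with the lexicographically smallest id wins, so results are
#' reproducible. Points covered by no polygon return `NA`.
#'
#' @param lat,lon coordinates in degrees (vectors of equal length).
#' @param geography an `odt_geography`.
#' @param level level name; defaults to the finest level.
#' @return character vector of place ids (`NA` where uncovered).
#' @export
assign_place <- function(lat, lon, geography, level = geography$levels[1]) {
  validate_coords(lat, lon)
  ids <- sort(geo_places(geography, level)$place_id)
  polys <- geography$polygons[ids]
  bbox <- t(vapply(polys, polygon_bbox, numeric(4)))
  out <- rep(NA_character_, length(lat))
  for (k in seq_along(lat)) {
    cand <- which(lon[k] >= bbox[, "xmin"] & lon[k] <= bbox[, "xmax"] &
                  lat[k] >= bbox[, "ymin"] & lat[k] <= bbox[, "ymax"])
    for (i in cand) {
      if (point_in_polygon(lon[k], lat[k], polys[[i]])) {
        out[k] <- ids[i]
        break
      }
    }
  }
  out
}

#' Roll a place id up to a coarser level
#'
#' Follows parent links from `from_level` to `to_level`. For FIPS-style
#' nested codes this agrees with code-prefix truncation (12-digit block
#' group -> 5-digit county -> 2-digit state).
#'
#' @param place_id character vector of ids at `from_level`.
#' @param from_level,to_level level names; `to_level` must be the same or
#'   coarser.
#' @param geography an `odt_geography`.
#' @return character vector of ancestor ids at `to_level`.
#' @export
rollup_place <- function(place_id, from_level, to_level, geography) {
  i <- level_index(geography, from_level)
  j <- level_index(geography, to_level)
  if (j < i) stop("to_level '", to_level, "' is finer than from_level '",
                  from_level, "'")
  out <- place_id
  while (i < j) {
    nxt <- geography$parent[out]
    orphan <- is.na(nxt) & !is.na(out)
    if (any(orphan)) {
      stop("hierarchy error: no parent link for place(s) ",
           paste(unique(out[orphan]), collapse = ", "),
           " at level '", geography$levels[i], "'")
    }
    out <- unname(nxt)
    i <- i + 1L
  }
  out
}

#' Great-circle distance
#'
#' Haversine distance on a sphere of radius 6371 km.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in degrees (vectorised).
#' @return distance in kilometres.
#' @export
great_circle_distance <- function(lat1, lon1, lat2, lon2) {
  validate_coords(lat1, lon1)
  validate_coords(lat2, lon2)
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  a <- pmin(pmax(a, 0), 1)
  2 * EARTH_RADIUS_KM * asin(sqrt(a))
}

#' Mean center of a point set
#'
#' (Weighted) arithmetic mean of latitudes and of longitudes. Coordinates
#' are averaged in plain degrees, which is adequate for the small-extent
#' geographies this package targets; point sets straddling the antimeridian
#' are not handled.
#'
#' @param lat,lon coordinates in degrees.
#' @param weights optional non-negative weights, not all zero.
#' @return named numeric `c(lat = , lon = )`.
#' @export
mean_center <- function(lat, lon, weights = NULL) {
  if (length(lat) == 0) stop("empty input: mean center of no points")
  if (is.null(weights)) {
    c(lat = mean(lat), lon = mean(lon))
  } else {
    if (any(weights < 0) || sum(weights) == 0) {
      stop("weights must be non-negative and not all zero")
    }
    c(lat = sum(lat * weights) / sum(weights),
      lon = sum(lon * weights) / sum(weights))
  }
}

#' Read a geography from GeoJSON files
#'
#' One GeoJSON FeatureCollection per level, finest first. Feature
#' properties must carry `place_id` and `name`, and may carry `parent_id`
#' linking to the next-coarser level; alternatively pass the hierarchy as a
#' two-column `child_id,parent_id` CSV. GeoJSON coordinates are `(lon, lat)`
#' per the format; the API surface elsewhere is `(lat, lon)`.
#'
#' @param paths named character vector of file paths; names are level names
#'   ordered finest to coarsest.
#' @param hierarchy_csv optional path to a `child_id,parent_id` CSV.
#' @return an `odt_geography`.
#' @export
read_geography <- function(paths, hierarchy_csv = NULL) {
  stopifnot(!is.null(names(paths)), all(nzchar(names(paths))))
  levels <- names(paths)
  places <- list()
  polygons <- list()
  parent <- character()
  for (lv in levels) {
    fc <- jsonlite::fromJSON(paths[[lv]], simplifyVector = FALSE)
    if (is.null(fc$features)) stop("not a FeatureCollection: ", paths[[lv]])
    for (f in fc$features) {
      pid <- f$properties$place_id
      geom <- f$geometry
      rings <- switch(geom$type,
        Polygon = lapply(geom$coordinates, function(r) {
          do.call(rbind, lapply(r, function(xy) c(xy[[1]], xy[[2]])))
        }),
        MultiPolygon = unlist(lapply(geom$coordinates, function(p) {
          lapply(p, function(r) {
            do.call(rbind, lapply(r, function(xy) c(xy[[1]], xy[[2]])))
          })
        }), recursive = FALSE),
        stop("unsupported geometry type: ", geom$type)
      )
      polygons[[pid]] <- rings
      allv <- do.call(rbind, rings)
      places[[length(places) + 1L]] <- data.table(
        place_id = pid,
        name = f$properties$name %||% pid,
        level = lv,
        centroid_lat = mean(range(allv[, 2])),
        centroid_lon = mean(range(allv[, 1]))
      )
      if (!is.null(f$properties$parent_id)) {
        parent[pid] <- f$properties$parent_id
      }
    }
  }
  if (!is.null(hierarchy_csv)) {
    h <- fread(hierarchy_csv, colClasses = "character")
    parent[h[[1]]] <- h[[2]]
  }
  odt_geography(levels, rbindlist(places), polygons, parent)
}

#' Write a geography to GeoJSON files
#'
#' Inverse of [read_geography()]: one FeatureCollection per level with
#' `place_id`, `name` and `parent_id` properties. Deterministic output
#' (places sorted by id, fixed number formatting) so regeneration with the
#' same inputs is byte-identical.
#'
#' @param geography an `odt_geography`.
#' @param dir output directory; files are named `<level>.geojson`.
#' @return invisibly, the written file paths.
#' @export
write_geography <- function(geography, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- character()
  for (lv in geography$levels) {
    pl <- geo_places(geography, lv)
    pl <- pl[order(place_id)]
    feats <- lapply(seq_len(nrow(pl)), function(i) {
      pid <- pl$place_id[i]
      rings <- geography$polygons[[pid]]
      if (is.matrix(rings)) rings <- list(rings)
      coords <- lapply(rings, function(r) {
        if (!(r[1, 1] == r[nrow(r), 1] && r[1, 2] == r[nrow(r), 2])) {
          r <- rbind(r, r[1, ])
        }
        lapply(seq_len(nrow(r)), function(k) c(r[k, 1], r[k, 2]))
      })
      props <- list(place_id = pid, name = pl$name[i])
      par <- geography$parent[pid]
      if (!is.na(par) && length(par)) props$parent_id <- unname(par)
      list(type = "Feature", properties = props,
           geometry = list(type = "Polygon", coordinates = coords))
    })
    path <- file.path(dir, paste0(lv, ".geojson"))
    writeLines(jsonlite::toJSON(
      list(type = "FeatureCollection", features = feats),
      auto_unbox = TRUE, digits = NA
    ), path)
    out <- c(out, path)
  }
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
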