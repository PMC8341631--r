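library(data.table)

# ---- independent oracles (deliberately different algorithms from R/) ----

# winding-number point-in-polygon via signed angle summation; boundary-free
# random points only
oracle_in_ring <- function(lon, lat, ring) {
  n <- nrow(ring)
  if (ring[1, 1] == ring[n, 1] && ring[1, 2] == ring[n, 2]) {
    ring <- ring[-n, , drop = FALSE]
    n <- n - 1L
  }
  a <- atan2(ring[, 2] - lat, ring[, 1] - lon)
  d <- diff(c(a, a[1]))
  d <- ifelse(d > pi, d - 2 * pi, ifelse(d < -pi, d + 2 * pi, d))
  abs(sum(d)) > pi # ~2*pi inside, ~0 outside
}

oracle_assign <- function(lat, lon, geography, level) {
  ids <- sort(geo_places(geography, level)$place_id)
  out <- rep(NA_character_, length(lat))
  for (k in seq_along(lat)) {
    for (pid in ids) {
      rings <- geography$polygons[[pid]]
      if (is.matrix(rings)) rings <- list(rings)
      if (any(vapply(rings, function(r) oracle_in_ring(lon[k], lat[k], r),
                     logical(1)))) {
        out[k] <- pid
        break
      }
    }
  }
  out
}

# spherical law of cosines (alternative to haversine)
oracle_gcd <- function(lat1, lon1, lat2, lon2) {
  r <- pi / 180
  x <- sin(lat1 * r) * sin(lat2 * r) +
    cos(lat1 * r) * cos(lat2 * r) * cos((lon2 - lon1) * r)
  6371 * acos(pmin(pmax(x, -1), 1))
}

# brute-force entity-day eligibility by scanning every calendar day
oracle_eligibility <- function(events) {
  ev <- as.data.table(events)
  ev[, day := as.Date(timestamp, tz = "UTC")]
  single <- list(); cross <- list()
  for (eid in sort(unique(ev$entity_id))) {
    dd <- ev[entity_id == eid, day]
    for (d in seq(min(dd), max(dd), by = "day")) {
      d <- as.Date(d)
      n0 <- sum(dd == d); n1 <- sum(dd == d + 1)
      if (n0 >= 2) single[[length(single) + 1L]] <-
        data.table(entity_id = eid, day = d)
      if (n0 >= 1 && n1 >= 1) cross[[length(cross) + 1L]] <-
        data.table(entity_id = eid, day = d)
    }
  }
  list(single_day = if (length(single)) rbindlist(single) else
         data.table(entity_id = character(), day = as.Date(character())),
       cross_day = if (length(cross)) rbindlist(cross) else
         data.table(entity_id = character(), day = as.Date(character())))
}

# nested-loop cube accumulation from an entity-flow table
oracle_build_cells <- function(flows) {
  fl <- as.data.table(flows)
  keys <- unique(fl[, .(o_place, d_place, day)])
  out <- list()
  for (i in seq_len(nrow(keys))) {
    sel <- fl[o_place == keys$o_place[i] & d_place == keys$d_place[i] &
                day == keys$day[i]]
    out[[i]] <- data.table(o_place = keys$o_place[i],
                           d_place = keys$d_place[i], day = keys$day[i],
                           cnt = sum(sel$weight))
  }
  res <- rbindlist(out)
  setorder(res, o_place, d_place, day)
  res[]
}

# ---- fixture builders ----

# toy cube straight from a cell table (coords default to dummy grid points)
toy_cube <- function(cells, level = "county", source = "synthetic") {
  cells <- as.data.table(cells)
  if (!"o_lat" %in% names(cells)) {
    cells[, `:=`(o_lat = 30 + seq_len(.N) * 1e-3, o_lon = 10,
                 d_lat = 30, d_lon = 10 + seq_len(.N) * 1e-3)]
  }
  odt_cube(cells, level, source)
}

random_cube <- function(n_cells = 100, n_places = 8, n_days = 10,
                        start = as.Date("2020-03-01")) {
  places <- sprintf("P%02d", seq_len(n_places))
  cells <- data.table(
    o_place = sample(places, n_cells, replace = TRUE),
    d_place = sample(places, n_cells, replace = TRUE),
    day = start + sample.int(n_days, n_cells, replace = TRUE) - 1L,
    cnt = as.numeric(sample.int(50, n_cells, replace = TRUE))
  )
  cells <- cells[, .(cnt = sum(cnt)), by = .(o_place, d_place, day)]
  cells[, `:=`(o_lat = runif(.N, 30, 31), o_lon = runif(.N, 10, 11),
               d_lat = runif(.N, 30, 31), d_lon = runif(.N, 10, 11))]
  odt_cube(cells, "county", "synthetic")
}

# events table constructor for hand-built scenarios
mk_events <- function(entity_id, lat, lon, ts, source = "Mobile App A") {
  data.table(entity_id = entity_id, lat = lat, lon = lon,
             timestamp = as.POSIXct(ts, tz = "UTC"), source = source)
}

small_cfg <- function(seed = 1L, ...) {
  synth_config(seed = seed, n_entities = 12L, days = 8L, ...)
}
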