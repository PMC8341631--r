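#' Read a geotagged event table
#'
#' Delimited text with header columns `entity_id, lat, lon, timestamp,
#' source`; timestamps ISO-8601, interpreted in UTC. Gzipped files are read
#' transparently by [data.table::fread()].
#'
#' @param path CSV/TSV file path.
#' @return `data.table` of events with a POSIXct `timestamp` column.
#' @export
read_events <- function(path) {
  ev <- fread(path, colClasses = list(character = c("entity_id", "source")))
  req <- c("entity_id", "lat", "lon", "timestamp", "source")
  miss <- setdiff(req, names(ev))
  if (length(miss)) stop("event file missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!inherits(ev$timestamp, "POSIXct")) {
    ev[, timestamp := as.POSIXct(timestamp, tz = "UTC",
                                 tryFormats = c("%Y-%m-%dT%H:%M:%OS",
                                                "%Y-%m-%d %H:%M:%OS"))]
  } else {
    attr(ev$timestamp, "tzone") <- "UTC"
  }
  if (anyNA(ev$timestamp)) stop("unparseable timestamp(s) in ", path)
  validate_coords(ev$lat, ev$lon)
  ev[]
}

#' Filter events by posting source
#'
#' Bot traffic (automated weather or job-posting accounts) is identified by
#' its posting client string. Exactly one of an allow-list (keep only those
#' sources) or a deny-list (drop those sources) may be given; the number of
#' removed events is reported via `message()`.
#'
#' @param events event `data.table` (see [read_events()]).
#' @param allow,deny character vectors of source strings; at most one
#'   non-NULL.
#' @return filtered event table.
#' @export
filter_sources <- function(events, allow = NULL, deny = NULL) {
  if (!is.null(allow) && !is.null(deny)) {
    stop("configuration error: specify either an allow-list or a deny-list, not both")
  }
  events <- as.data.table(events)
  keep <- if (!is.null(allow)) {
    events$source %in% allow
  } else if (!is.null(deny)) {
    !(events$source %in% deny)
  } else {
    rep(TRUE, nrow(events))
  }
  n_drop <- sum(!keep)
  if (n_drop > 0) message("filter_sources: removed ", n_drop, " event(s)")
  events[keep]
}

# Calendar day of an event: UTC date, optionally shifted by a fixed offset
# in hours (the day boundary is a convention, not given by the data).
event_day <- function(timestamp, utc_offset_hours = 0) {
  as.Date(timestamp + utc_offset_hours * 3600, tz = "UTC")
}

#' Entity-day eligibility for flow extraction
#'
#' An entity contributes a single-day movement on a day with at least two
#' events, and a cross-day movement for each pair of consecutive days with
#' at least one event on each.
#'
#' @param events event table with a `day` (Date) column, or raw events plus
#'   `utc_offset_hours` to derive it.
#' @param utc_offset_hours fixed offset applied before taking the UTC date.
#' @return list with `single_day` (`data.table`: entity_id, day) and
#'   `cross_day` (`data.table`: entity_id, day — the earlier day `d` of the
#'   pair `(d, d+1)`).
#' @export
eligible_entity_days <- function(events, utc_offset_hours = 0) {
  events <- as.data.table(events)
  if (!"day" %in% names(events)) {
    events <- copy(events)[, day := event_day(timestamp, utc_offset_hours)]
  }
  counts <- events[, .N, by = .(entity_id, day)]
  single <- counts[N >= 2L, .(entity_id, day)][order(entity_id, day)]
  d1 <- counts[, .(entity_id, day)]
  d2 <- copy(d1)[, day := day - 1L]
  cross <- merge(d1, d2, by = c("entity_id", "day"))[order(entity_id, day)]
  list(single_day = single, cross_day = cross)
}

# Single-day movement of one entity on one day: origin at the first event,
# destination at the event farthest (great-circle) from that initial
# location, ties broken by earliest timestamp. NULL when the maximum
# distance is zero (no movement).
single_day_endpoints <- function(day_events) {
  ord <- order(day_events$timestamp, day_events$lat, day_events$lon)
  day_events <- day_events[ord, ]
  o_lat <- day_events$lat[1]; o_lon <- day_events$lon[1]
  d <- great_circle_distance(o_lat, o_lon, day_events$lat, day_events$lon)
  i <- which.max(d) # first max = earliest timestamp among ties
  if (d[i] == 0) return(NULL)
  list(o_lat = o_lat, o_lon = o_lon,
       d_lat = day_events$lat[i], d_lon = day_events$lon[i])
}

# Cross-day movement: shift of the daily mean center between day d and
# d+1. NULL when the shift distance is zero.
cross_day_endpoints <- function(events_d, events_d1) {
  mc0 <- mean_center(events_d$lat, events_d$lon)
  mc1 <- mean_center(events_d1$lat, events_d1$lon)
  if (great_circle_distance(mc0["lat"], mc0["lon"],
                            mc1["lat"], mc1["lon"]) == 0) {
    return(NULL)
  }
  list(o_lat = unname(mc0["lat"]), o_lon = unname(mc0["lon"]),
       d_lat = unname(mc1["lat"]), d_lon = unname(mc1["lon"]))
}

empty_entity_flows <- function() {
  data.table(entity_id = character(), o_place = character(),
             d_place = character(), day = as.Date(character()),
             o_lat = numeric(), o_lon = numeric(),
             d_lat = numeric(), d_lon = numeric(),
             kind = character(), weight = numeric())
}

#' Extract entity-level daily flows from geotagged events
#'
#' Applies source filtering, derives the calendar day of each event,
#' determines eligible entity-days, and emits single-day flows (origin at
#' the day's first event, destination at the farthest event of the day) and
#' cross-day flows (mean-center shift between consecutive days, dated to
#' the earlier day). Flow endpoints are assigned to places by
#' point-in-polygon at `level`; flows whose endpoints fall outside the
#' geography are dropped and tallied. Zero-distance movements are never
#' emitted. The result is presence-based per entity: a single-day and a
#' cross-day flow with identical `(entity, origin, destination, day)`
#' collapse to one row of weight 1.
#'
#' @param events event table (see [read_events()]).
#' @param geography an `odt_geography`.
#' @param level extraction level.
#' @param allow,deny source filter rules (see [filter_sources()]).
#' @param utc_offset_hours day-boundary offset in hours (default 0: UTC
#'   dates).
#' @return entity-flow `data.table` with columns `entity_id, o_place,
#'   d_place, day, o_lat, o_lon, d_lat, d_lon, kind, weight`, sorted; the
#'   number of endpoint-unassigned flows is attached as attribute
#'   `unassigned`.
#' @export
extract_entity_flows <- function(events, geography, level = geography$levels[1],
                                 allow = NULL, deny = NULL,
                                 utc_offset_hours = 0) {
  events <- filter_sources(as.data.table(events), allow = allow, deny = deny)
  if (nrow(events) == 0) {
    out <- empty_entity_flows()
    attr(out, "unassigned") <- 0L
    return(out)
  }
  events <- copy(events)[, day := event_day(timestamp, utc_offset_hours)]
  setorder(events, entity_id, timestamp, lat, lon)
  elig <- eligible_entity_days(events)

  rows <- list()
  ev_split <- split(events, by = c("entity_id", "day"), sep = "\r")
  key1 <- paste(elig$single_day$entity_id, elig$single_day$day, sep = "\r")
  for (k in key1) {
    de <- ev_split[[k]]
    ep <- single_day_endpoints(de)
    if (is.null(ep)) next
    rows[[length(rows) + 1L]] <- data.table(
      entity_id = de$entity_id[1], day = de$day[1],
      o_lat = ep$o_lat, o_lon = ep$o_lon,
      d_lat = ep$d_lat, d_lon = ep$d_lon, kind = "single_day")
  }
  for (i in seq_len(nrow(elig$cross_day))) {
    eid <- elig$cross_day$entity_id[i]
    d0 <- elig$cross_day$day[i]
    e0 <- ev_split[[paste(eid, d0, sep = "\r")]]
    e1 <- ev_split[[paste(eid, d0 + 1L, sep = "\r")]]
    ep <- cross_day_endpoints(e0, e1)
    if (is.null(ep)) next
    rows[[length(rows) + 1L]] <- data.table(
      entity_id = eid, day = d0,
      o_lat = ep$o_lat, o_lon = ep$o_lon,
      d_lat = ep$d_lat, d_lon = ep$d_lon, kind = "cross_day")
  }
  if (length(rows) == 0) {
    out <- empty_entity_flows()
    attr(out, "unassigned") <- 0L
    return(out)
  }
  fl <- rbindlist(rows)
  fl[, o_place := assign_place(o_lat, o_lon, geography, level)]
  fl[, d_place := assign_place(d_lat, d_lon, geography, level)]
  unassigned <- sum(is.na(fl$o_place) | is.na(fl$d_place))
  if (unassigned > 0) {
    message("extract_entity_flows: dropped ", unassigned,
            " flow(s) with endpoints outside the geography")
  }
  fl <- fl[!is.na(o_place) & !is.na(d_place)]
  # presence-based cube cell: one row per (entity, o, d, day); a single-day
  # flow wins over a cross-day flow with the same key
  fl[, kind_rank := fifelse(kind == "single_day", 0L, 1L)]
  setorder(fl, entity_id, day, o_place, d_place, kind_rank)
  fl <- fl[!duplicated(fl[, .(entity_id, o_place, d_place, day)])]
  fl[, kind_rank := NULL]
  fl[, weight := 1]
  setcolorder(fl, c("entity_id", "o_place", "d_place", "day",
                    "o_lat", "o_lon", "d_lat", "d_lon", "kind", "weight"))
  setorder(fl, entity_id, day, o_place, d_place)
  out <- fl[]
  setattr(out, "unassigned", unassigned)
  out
}

#' Roll an entity-flow table up to a coarser level
#'
#' Re-keys origin and destination places through the geography's parent
#' links. Presence-based flows (event-derived, weight 1) are
#' re-deduplicated per (entity, origin, destination, day) with single-day
#' movements taking precedence, so the result equals extraction run
#' directly at the coarser level; weighted flows (home-based records) keep
#' their weights and are summed.
#'
#' @param flows entity-flow table.
#' @param from_level,to_level level names.
#' @param geography an `odt_geography`.
#' @return entity-flow table at `to_level`.
#' @export
rollup_entity_flows <- function(flows, from_level, to_level, geography) {
  fl <- copy(as.data.table(flows))
  if (nrow(fl) == 0) return(fl)
  fl[, o_place := rollup_place(o_place, from_level, to_level, geography)]
  fl[, d_place := rollup_place(d_place, from_level, to_level, geography)]
  if (all(fl$kind %in% c("single_day", "cross_day"))) {
    fl[, kind_rank := fifelse(kind == "single_day", 0L, 1L)]
    setorder(fl, entity_id, day, o_place, d_place, kind_rank)
    fl <- fl[!duplicated(fl[, .(entity_id, o_place, d_place, day)])]
    fl[, kind_rank := NULL]
  } else {
    fl <- fl[, .(o_lat = sum(o_lat * weight) / sum(weight),
                 o_lon = sum(o_lon * weight) / sum(weight),
                 d_lat = sum(d_lat * weight) / sum(weight),
                 d_lon = sum(d_lon * weight) / sum(weight),
                 kind = kind[1], weight = sum(weight)),
             by = .(entity_id, o_place, d_place, day)]
    setcolorder(fl, c("entity_id", "o_place", "d_place", "day",
                      "o_lat", "o_lon", "d_lat", "d_lon", "kind", "weight"))
  }
  setorder(fl, entity_id, day, o_place, d_place)
  fl[]
}
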