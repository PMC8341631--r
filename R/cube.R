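#' Sparse origin-destination-time cube
#'
#' An `odt_cube` stores, at one geographic level, a sparse set of cells
#' `(o_place, d_place, day) -> cnt` together with the weighted mean centers
#' of the contributing flow origins and destinations (`o_lat, o_lon, d_lat,
#' d_lon`). Cells with zero count are never stored. Diagonal cells
#' (`o_place == d_place`) hold intra-place movements with positive
#' distance.
#'
#' @param cells `data.frame` with columns `o_place, d_place, day, cnt,
#'   o_lat, o_lon, d_lat, d_lon`.
#' @param level geographic level name of all place ids in `cells`.
#' @param source data-source label (e.g. `"twitter"`, `"safegraph"`,
#'   `"synthetic"`).
#' @return object of class `odt_cube`.
#' @export
odt_cube <- function(cells, level, source = "unknown") {
  cells <- as.data.table(cells)
  req <- c("o_place", "d_place", "day", "cnt",
           "o_lat", "o_lon", "d_lat", "d_lon")
  miss <- setdiff(req, names(cells))
  if (length(miss)) stop("cube cells missing column(s): ",
                         paste(miss, collapse = ", "))
  cells <- cells[, ..req]
  if (!inherits(cells$day, "Date")) cells[, day := as.Date(day)]
  if (any(cells$cnt <= 0)) stop("sparse cube: stored cells must have cnt > 0")
  coord <- unlist(cells[, .(o_lat, o_lon, d_lat, d_lon)])
  if (length(coord) && any(!is.finite(coord))) {
    stop("cube endpoint coordinates must be finite")
  }
  setorder(cells, o_place, d_place, day)
  structure(list(cells = cells[], level = level, source = source),
            class = "odt_cube")
}

#' @export
print.odt_cube <- function(x, ...) {
  cat(sprintf("<odt_cube> level=%s source=%s\n", x$level, x$source))
  cat(sprintf("  %d cells, total count %s\n", nrow(x$cells),
              format(cube_total(x))))
  if (nrow(x$cells)) {
    dr <- day_range(x)
    cat(sprintf("  days %s .. %s\n", dr[1], dr[2]))
  }
  invisible(x)
}

#' Total count mass of a cube
#' @param cube an `odt_cube`.
#' @return numeric scalar.
#' @export
cube_total <- function(cube) sum(cube$cells$cnt)

#' Day range covered by a cube
#' @param cube an `odt_cube`.
#' @return length-2 Date vector `c(min, max)` (NA for an empty cube).
#' @export
day_range <- function(cube) {
  if (nrow(cube$cells) == 0) return(as.Date(c(NA, NA)))
  range(cube$cells$day)
}

#' Aggregate entity flows into an ODT cube
#'
#' Cell count is the sum of entity weights for that `(origin, destination,
#' day)`; endpoint mean centers are weight-weighted arithmetic means of the
#' contributing flow endpoints. All flows must already be at `level`.
#'
#' @param entity_flows entity-flow table ([extract_entity_flows()],
#'   [sdm_entity_flows()]).
#' @param level geographic level of the flows.
#' @param geography optional `odt_geography`; when given, flow places are
#'   checked against it (a mixed-level table fails).
#' @param source data-source label stored on the cube.
#' @return an `odt_cube`.
#' @export
build_cube <- function(entity_flows, level, geography = NULL,
                       source = "unknown") {
  fl <- as.data.table(entity_flows)
  if (nrow(fl) && !is.null(geography)) {
    valid <- geo_places(geography, level)$place_id
    bad <- setdiff(unique(c(fl$o_place, fl$d_place)), valid)
    if (length(bad)) stop("level error: place id(s) not at level '", level,
                          "': ", paste(utils::head(bad, 5), collapse = ", "))
  }
  if (nrow(fl) == 0) {
    return(odt_cube(empty_entity_flows()[, .(
      o_place, d_place, day, cnt = weight,
      o_lat, o_lon, d_lat, d_lon)], level, source))
  }
  cells <- fl[, .(
    cnt = sum(weight),
    o_lat = sum(o_lat * weight) / sum(weight),
    o_lon = sum(o_lon * weight) / sum(weight),
    d_lat = sum(d_lat * weight) / sum(weight),
    d_lon = sum(d_lon * weight) / sum(weight)
  ), by = .(o_place, d_place, day)]
  odt_cube(cells, level, source)
}

#' Roll a cube up to a coarser geographic level
#'
#' Cells are re-keyed through the geography's parent links and summed;
#' endpoint mean centers are re-averaged by weight. Total count is
#' conserved.
#'
#' @param cube an `odt_cube`.
#' @param to_level target level (same or coarser than `cube$level`).
#' @param geography an `odt_geography` providing the hierarchy.
#' @return an `odt_cube` at `to_level`.
#' @export
rollup_spatial <- function(cube, to_level, geography) {
  if (to_level == cube$level) return(cube)
  cl <- copy(cube$cells)
  cl[, o_place := rollup_place(o_place, cube$level, to_level, geography)]
  cl[, d_place := rollup_place(d_place, cube$level, to_level, geography)]
  cells <- cl[, .(
    o_lat = sum(o_lat * cnt) / sum(cnt),
    o_lon = sum(o_lon * cnt) / sum(cnt),
    d_lat = sum(d_lat * cnt) / sum(cnt),
    d_lon = sum(d_lon * cnt) / sum(cnt),
    cnt = sum(cnt)
  ), by = .(o_place, d_place, day)]
  odt_cube(cells, to_level, cube$source)
}

# ISO-8601 year-week label, e.g. "2020-W05"
iso_week <- function(day) format(day, "%G-W%V")

temporal_bin <- function(day, granularity) {
  switch(granularity,
    day = as.character(day),
    week = iso_week(day),
    month = format(day, "%Y-%m"),
    stop("unknown granularity '", granularity,
         "'; use day, week or month"))
}

#' Temporal roll-up of a cube
#'
#' Sums cell counts within calendar bins: ISO weeks (`"week"`), calendar
#' months (`"month"`) or days (`"day"`, identity relabel). Endpoint mean
#' centers are re-averaged by weight.
#'
#' @param cube an `odt_cube`.
#' @param granularity `"day"`, `"week"` or `"month"`.
#' @return `data.table` with columns `o_place, d_place, period, cnt, o_lat,
#'   o_lon, d_lat, d_lon`.
#' @export
rollup_temporal <- function(cube, granularity = "week") {
  cl <- copy(cube$cells)
  if (nrow(cl) == 0) {
    return(data.table(o_place = character(), d_place = character(),
                      period = character(), cnt = numeric(),
                      o_lat = numeric(), o_lon = numeric(),
                      d_lat = numeric(), d_lon = numeric()))
  }
  cl[, period := temporal_bin(day, granularity)]
  out <- cl[, .(
    o_lat = sum(o_lat * cnt) / sum(cnt),
    o_lon = sum(o_lon * cnt) / sum(cnt),
    d_lat = sum(d_lat * cnt) / sum(cnt),
    d_lon = sum(d_lon * cnt) / sum(cnt),
    cnt = sum(cnt)
  ), by = .(o_place, d_place, period)]
  setcolorder(out, c("o_place", "d_place", "period", "cnt",
                     "o_lat", "o_lon", "d_lat", "d_lon"))
  setorder(out, o_place, d_place, period)
  out[]
}

#' Dice a cube into a subcube
#'
#' Restricts the cube to cells matching the origin filter, destination
#' filter and closed date interval. `NULL` filters mean no restriction.
#'
#' @param cube an `odt_cube`.
#' @param o_filter,d_filter character vectors of place ids, or `NULL` for
#'   all.
#' @param t_range length-2 Date vector `c(start, end)` (closed), or `NULL`
#'   for the full range.
#' @return an `odt_cube` (possibly empty).
#' @export
dice <- function(cube, o_filter = NULL, d_filter = NULL, t_range = NULL) {
  keep <- rep(TRUE, nrow(cube$cells))
  if (!is.null(o_filter)) keep <- keep & cube$cells$o_place %in% o_filter
  if (!is.null(d_filter)) keep <- keep & cube$cells$d_place %in% d_filter
  if (!is.null(t_range)) {
    t_range <- as.Date(t_range)
    if (t_range[1] > t_range[2]) stop("t_range start after end")
    keep <- keep & cube$cells$day >= t_range[1] & cube$cells$day <= t_range[2]
  }
  odt_cube(cube$cells[keep], cube$level, cube$source)
}

#' Slice a cube into an OD matrix
#'
#' Sums over days within the closed `t_range` (default: all days), giving
#' flows between places. Diagonal entries are intra-place movements.
#' Endpoint mean centers per pair are carried along.
#'
#' @param cube an `odt_cube`.
#' @param t_range length-2 Date vector or `NULL`.
#' @return `data.table` `o_place, d_place, cnt, o_lat, o_lon, d_lat, d_lon`.
#' @export
slice_od <- function(cube, t_range = NULL) {
  cl <- if (is.null(t_range)) cube$cells else dice(cube, t_range = t_range)$cells
  out <- cl[, .(
    o_lat = sum(o_lat * cnt) / sum(cnt),
    o_lon = sum(o_lon * cnt) / sum(cnt),
    d_lat = sum(d_lat * cnt) / sum(cnt),
    d_lon = sum(d_lon * cnt) / sum(cnt),
    cnt = sum(cnt)
  ), by = .(o_place, d_place)]
  setcolorder(out, c("o_place", "d_place", "cnt",
                     "o_lat", "o_lon", "d_lat", "d_lon"))
  setorder(out, o_place, d_place)
  out[]
}

#' Slice a cube into an origin-time (outflow) matrix
#'
#' Sums over destinations per `(origin, day)`: each entry is the total
#' outflow (including intra-place movement) leaving an origin that day.
#'
#' @param cube an `odt_cube`.
#' @return `data.table` `o_place, day, cnt`.
#' @export
slice_ot <- function(cube) {
  out <- cube$cells[, .(cnt = sum(cnt)), by = .(o_place, day)]
  setorder(out, o_place, day)
  out[]
}

#' Slice a cube into a destination-time (inflow) matrix
#'
#' Sums over origins per `(destination, day)`: each entry is the total
#' inflow (including intra-place movement) arriving at a destination that
#' day.
#'
#' @param cube an `odt_cube`.
#' @return `data.table` `d_place, day, cnt`.
#' @export
slice_dt <- function(cube) {
  out <- cube$cells[, .(cnt = sum(cnt)), by = .(d_place, day)]
  setorder(out, d_place, day)
  out[]
}

check_place <- function(cube, place, geography = NULL) {
  known <- unique(c(cube$cells$o_place, cube$cells$d_place))
  if (!is.null(geography)) {
    known <- union(known, geo_places(geography, cube$level)$place_id)
  }
  if (!place %in% known) {
    stop("place error: '", place, "' unknown at level '", cube$level, "'")
  }
  invisible(TRUE)
}

#' Daily flow series for one place
#'
#' Direction semantics: `inflow` counts movements from other places into
#' the place, `outflow` movements from the place to other places,
#' `intraflow` movements that stay within the place (the OD diagonal;
#' positive distance but not crossing the boundary), and `in_and_out` is
#' inflow + outflow — the diagonal is excluded from `in_and_out`.
#'
#' @param cube an `odt_cube`.
#' @param place place id at the cube's level.
#' @param direction `"inflow"`, `"outflow"`, `"intraflow"` or
#'   `"in_and_out"`.
#' @param geography optional, widens the known-place check.
#' @return `data.table` `day, cnt` covering every day in the cube's range
#'   (zero-filled).
#' @export
place_series <- function(cube, place,
                         direction = c("inflow", "outflow", "intraflow",
                                       "in_and_out"),
                         geography = NULL) {
  direction <- match.arg(direction)
  check_place(cube, place, geography)
  cl <- cube$cells
  sel <- switch(direction,
    inflow = cl[d_place == place & o_place != place],
    outflow = cl[o_place == place & d_place != place],
    intraflow = cl[o_place == place & d_place == place],
    in_and_out = cl[(d_place == place | o_place == place) &
                      o_place != d_place]
  )
  agg <- sel[, .(cnt = sum(cnt)), by = day]
  dr <- day_range(cube)
  if (is.na(dr[1])) return(data.table(day = as.Date(character()),
                                      cnt = numeric()))
  grid <- data.table(day = seq(dr[1], dr[2], by = "day"))
  out <- agg[grid, on = "day"]
  out[is.na(cnt), cnt := 0]
  setorder(out, day)
  out[]
}

#' Per-counterpart flow totals for one place
#'
#' Aggregates flows between `place` and every other place over a closed
#' time range (the choropleth-map scenario). The intra-place (diagonal)
#' total is excluded from counterpart totals and returned separately as
#' the `intra` attribute.
#'
#' @param cube an `odt_cube`.
#' @param place place id.
#' @param t_range length-2 Date vector or `NULL` for the full range.
#' @param direction `"inflow"`, `"outflow"` or `"in_and_out"`.
#' @param geography optional, widens the known-place check.
#' @return `data.table` `place, cnt` of counterpart totals, with attribute
#'   `intra` (numeric scalar).
#' @export
place_flows <- function(cube, place, t_range = NULL,
                        direction = c("inflow", "outflow", "in_and_out"),
                        geography = NULL) {
  direction <- match.arg(direction)
  check_place(cube, place, geography)
  sub <- dice(cube, t_range = t_range)
  cl <- sub$cells
  infl <- cl[d_place == place & o_place != place,
             .(cnt = sum(cnt)), by = .(place = o_place)]
  outf <- cl[o_place == place & d_place != place,
             .(cnt = sum(cnt)), by = .(place = d_place)]
  out <- switch(direction,
    inflow = infl,
    outflow = outf,
    in_and_out = rbindlist(list(infl, outf))[, .(cnt = sum(cnt)),
                                             by = place]
  )
  setorder(out, place)
  intra <- cl[o_place == place & d_place == place, sum(cnt)]
  res <- out[]
  setattr(res, "intra", intra)
  res
}

#' Minimum-count display filter
#'
#' Keeps rows whose `cnt` strictly exceeds the threshold (so a threshold of
#' 20 keeps counts of 21 and above), the convention used for decluttering
#' flow maps.
#'
#' @param x a flow/matrix `data.table` with a `cnt` column, or an
#'   `odt_cube`.
#' @param threshold non-negative number.
#' @return same type as `x`, filtered.
#' @export
min_count_filter <- function(x, threshold) {
  if (threshold < 0) stop("threshold must be >= 0")
  if (inherits(x, "odt_cube")) {
    return(odt_cube(x$cells[cnt > threshold], x$level, x$source))
  }
  as.data.table(x)[cnt > threshold]
}

#' Save a cube as a flat daily flow CSV
#'
#' The persistence format is the public daily export dialect (see
#' [write_flows()]), so save/load is a round-trip through the standard
#' format.
#'
#' @param cube an `odt_cube`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
save_cube <- function(cube, path) {
  tab <- cube$cells[, .(o_place, d_place,
                        year = as.integer(format(day, "%Y")),
                        month = as.integer(format(day, "%m")),
                        day = as.integer(format(day, "%d")),
                        cnt, o_lat, o_lon, d_lat, d_lon)]
  write_flows(tab, path, mode = "daily")
}

#' Load a cube from a daily flow CSV
#'
#' @param path file written by [save_cube()] or [write_flows()] in daily
#'   mode.
#' @param level,source metadata to stamp on the cube.
#' @return an `odt_cube`.
#' @export
load_cube <- function(path, level, source = "unknown") {
  rf <- read_flows(path)
  if (rf$mode != "daily") stop("expected a daily-mode flow file: ", path)
  tab <- rf$table
  cells <- tab[, .(o_place, d_place,
                   day = as.Date(sprintf("%04d-%02d-%02d", year, month, day)),
                   cnt, o_lat, o_lon, d_lat, d_lon)]
  odt_cube(cells, level, source)
}
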