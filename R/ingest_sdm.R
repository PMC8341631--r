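#' Read home-based mobility (SDM-style) records
#'
#' Parses a CSV with columns `origin_census_block_group` (12-digit FIPS),
#' `destination_cbgs` (a JSON object string mapping destination block-group
#' FIPS codes to positive device counts) and `date_range_start` (a date,
#' optionally with a time/zone suffix which is truncated). Extra columns
#' are ignored — real social-distancing-metrics tables carry many more
#' fields than the three used here.
#'
#' In `strict` mode any malformed record (bad FIPS length, non-positive
#' count, unparseable map) aborts with row context; in lenient mode it is
#' skipped with a message.
#'
#' @param path CSV file path.
#' @param strict abort on malformed records (default) or skip them.
#' @return `data.table` with one row per (origin, destination) pair:
#'   `origin_cbg, dest_cbg, count, day`.
#' @export
read_sdm <- function(path, strict = TRUE) {
  raw <- fread(path, colClasses = "character")
  req <- c("origin_census_block_group", "destination_cbgs", "date_range_start")
  miss <- setdiff(req, names(raw))
  if (length(miss)) stop("SDM file missing column(s): ",
                         paste(miss, collapse = ", "))
  parse_sdm_records(raw, strict = strict)
}

#' Parse raw SDM rows into per-destination records
#'
#' @param raw `data.frame` with the three SDM columns as character.
#' @param strict see [read_sdm()].
#' @return long `data.table`: `origin_cbg, dest_cbg, count, day`.
#' @export
parse_sdm_records <- function(raw, strict = TRUE) {
  raw <- as.data.table(raw)
  out <- vector("list", nrow(raw))
  n_bad <- 0L
  for (i in seq_len(nrow(raw))) {
    rec <- tryCatch(
      parse_sdm_record(raw$origin_census_block_group[i],
                       raw$destination_cbgs[i],
                       raw$date_range_start[i]),
      error = function(e) e
    )
    if (inherits(rec, "error")) {
      if (strict) stop("record error at row ", i, ": ",
                       conditionMessage(rec))
      n_bad <- n_bad + 1L
      next
    }
    out[[i]] <- rec
  }
  if (n_bad > 0) message("parse_sdm_records: skipped ", n_bad,
                         " malformed record(s)")
  res <- rbindlist(out)
  if (nrow(res) == 0) {
    res <- data.table(origin_cbg = character(), dest_cbg = character(),
                      count = numeric(), day = as.Date(character()))
  }
  res[]
}

#' Parse one SDM record
#'
#' @param origin_cbg 12-digit FIPS string of the home block group.
#' @param destination_cbgs JSON object string, e.g.
#'   `'{"450790103002":5,"450790104001":3}'`.
#' @param date_range_start date string; any `T...` time suffix is dropped.
#' @return `data.table` with one row per destination (zero rows for an
#'   empty map).
#' @export
parse_sdm_record <- function(origin_cbg, destination_cbgs, date_range_start) {
  if (!grepl("^[0-9]{12}$", origin_cbg)) {
    stop("origin_census_block_group is not a 12-digit FIPS code: '",
         origin_cbg, "'")
  }
  day <- as.Date(sub("[T ].*$", "", date_range_start))
  if (is.na(day)) stop("unparseable date_range_start: '", date_range_start, "'")
  m <- tryCatch(jsonlite::fromJSON(destination_cbgs),
                error = function(e) stop("unparseable destination_cbgs map: ",
                                         conditionMessage(e)))
  if (length(m) == 0) {
    return(data.table(origin_cbg = character(), dest_cbg = character(),
                      count = numeric(), day = as.Date(character())))
  }
  keys <- names(m)
  counts <- as.numeric(unlist(m, use.names = FALSE))
  bad_key <- !grepl("^[0-9]{12}$", keys)
  if (any(bad_key)) stop("destination key not a 12-digit FIPS code: '",
                         keys[which(bad_key)[1]], "'")
  if (any(!is.finite(counts) | counts < 1 | counts != floor(counts))) {
    stop("destination counts must be positive integers")
  }
  data.table(origin_cbg = origin_cbg, dest_cbg = keys, count = counts,
             day = day)
}

#' Entity-level flows from SDM records
#'
#' Each record yields one weighted flow per destination: the entity is the
#' home block group, the origin is the home block group rolled up to
#' `level`, the destination the destination block group rolled up
#' likewise, dated by `date_range_start`. Unlike event-derived flows these
#' are device counts, not distinct entities, so weights sum under
#' aggregation — a visitor may be counted several times at coarser levels.
#' Endpoint coordinates are the place centroids at `level`.
#'
#' @param records long record table from [read_sdm()] /
#'   [parse_sdm_records()].
#' @param geography an `odt_geography` whose finest level holds the block
#'   groups.
#' @param level target level (`geography` level name; the finest level
#'   leaves codes untouched).
#' @return entity-flow `data.table` (same schema as
#'   [extract_entity_flows()], `kind = "sdm"`); one row per
#'   (entity, o_place, d_place, day) with summed weight.
#' @export
sdm_entity_flows <- function(records, geography, level = geography$levels[1]) {
  records <- as.data.table(records)
  if (nrow(records) == 0) return(empty_entity_flows())
  fine <- geography$levels[1]
  fl <- records[, .(
    entity_id = origin_cbg,
    o_place = rollup_place(origin_cbg, fine, level, geography),
    d_place = rollup_place(dest_cbg, fine, level, geography),
    day = day,
    weight = count
  )]
  fl <- fl[, .(weight = sum(weight)),
           by = .(entity_id, o_place, d_place, day)]
  cent <- geo_places(geography, level)
  fl[cent, on = c(o_place = "place_id"),
     `:=`(o_lat = i.centroid_lat, o_lon = i.centroid_lon)]
  fl[cent, on = c(d_place = "place_id"),
     `:=`(d_lat = i.centroid_lat, d_lon = i.centroid_lon)]
  fl[, kind := "sdm"]
  setcolorder(fl, c("entity_id", "o_place", "d_place", "day",
                    "o_lat", "o_lon", "d_lat", "d_lon", "kind", "weight"))
  setorder(fl, entity_id, day, o_place, d_place)
  fl[]
}
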