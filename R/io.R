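FLOW_COLS_DAILY <- c("o_place", "d_place", "year", "month", "day",
                     "cnt", "o_lat", "o_lon", "d_lat", "d_lon")
FLOW_COLS_AGG <- c("o_place", "d_place", "cnt",
                   "o_lat", "o_lon", "d_lat", "d_lon")

#' Write a flow table in the flat CSV dialect
#'
#' Each row of a daily export carries origin place (`o_place`),
#' destination place (`d_place`), the date split into `year, month, day`
#' integer columns, the number of users/devices moved (`cnt`) and the mean
#' centers of the flow origins (`o_lat, o_lon`) and destinations (`d_lat,
#' d_lon`). Aggregated exports drop the date columns; the covered range
#' may be recorded in a leading `#`-prefixed metadata line. UTF-8, LF line
#' endings, coordinates printed with fixed 6 decimals so write/read
#' round-trips are bit-stable.
#'
#' @param table `data.frame` with the columns of the chosen mode.
#' @param path output file.
#' @param mode `"daily"` or `"aggregated"`.
#' @param t_range optional length-2 Date vector noted in a `#` metadata
#'   line (aggregated mode).
#' @return invisibly, `path`.
#' @export
write_flows <- function(table, path, mode = c("daily", "aggregated"),
                        t_range = NULL) {
  mode <- match.arg(mode)
  cols <- if (mode == "daily") FLOW_COLS_DAILY else FLOW_COLS_AGG
  table <- as.data.table(table)
  miss <- setdiff(cols, names(table))
  if (length(miss)) {
    stop("export error (", mode, " mode): missing column(s) ",
         paste(miss, collapse = ", "), "; have ",
         paste(names(table), collapse = ", "))
  }
  tab <- table[, ..cols]
  fmt <- function(x) sprintf("%.6f", x)
  lines <- character()
  if (mode == "aggregated" && !is.null(t_range)) {
    lines <- sprintf("# t_range=%s/%s", t_range[1], t_range[2])
  }
  lines <- c(lines, paste(cols, collapse = ","))
  if (nrow(tab)) {
    body_cols <- lapply(cols, function(cn) {
      x <- tab[[cn]]
      if (cn %in% c("o_lat", "o_lon", "d_lat", "d_lon")) fmt(x)
      else if (is.numeric(x)) format(x, scientific = FALSE, trim = TRUE)
      else as.character(x)
    })
    lines <- c(lines, do.call(paste, c(body_cols, sep = ",")))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a flow CSV, auto-detecting its mode
#'
#' @param path file in the dialect of [write_flows()].
#' @return list with `table` (`data.table`), `mode` (`"daily"` or
#'   `"aggregated"`) and `t_range` (Date vector or `NULL`, from the `#`
#'   metadata line).
#' @export
read_flows <- function(path) {
  first <- readLines(path, n = 2)
  t_range <- NULL
  skip <- 0L
  if (length(first) && startsWith(first[1], "#")) {
    m <- regmatches(first[1],
                    regexec("t_range=([0-9-]+)/([0-9-]+)", first[1]))[[1]]
    if (length(m) == 3) t_range <- as.Date(m[2:3])
    skip <- 1L
    first <- first[-1]
  }
  header <- strsplit(first[1], ",", fixed = TRUE)[[1]]
  mode <- if (identical(header, FLOW_COLS_DAILY)) {
    "daily"
  } else if (identical(header, FLOW_COLS_AGG)) {
    "aggregated"
  } else {
    bad <- header[which(header != FLOW_COLS_DAILY[seq_along(header)])[1]]
    stop("format error: unrecognised flow header (first unexpected column: '",
         if (is.na(bad)) "<truncated>" else bad, "')")
  }
  tab <- fread(path, skip = skip, header = TRUE,
               colClasses = list(character = c("o_place", "d_place")))
  if (any(tab$cnt <= 0)) stop("format error: cnt must be positive")
  coords <- unlist(tab[, .(o_lat, o_lon, d_lat, d_lon)])
  if (length(coords) && any(!is.finite(coords))) {
    stop("format error: non-finite coordinates")
  }
  list(table = tab[], mode = mode, t_range = t_range)
}

#' Run a portal-style query against a cube store
#'
#' A query spec names a data source, a geographic level, one of the four
#' scenarios and its parameters; the matching cube is looked up in the
#' store and the query dispatched to [scenario_tables()].
#'
#' @param spec list (parseable from JSON/YAML) with fields `source`,
#'   `level`, `scenario`, and scenario parameters (`place`, `direction`,
#'   `t_range`, `bbox`, `min_count`, `aggregation`).
#' @param store named list of `odt_cube` objects keyed `"<source>:<level>"`,
#'   or a single `odt_cube`.
#' @param geography optional `odt_geography` for bbox queries.
#' @return `data.table` result.
#' @export
run_query <- function(spec, store, geography = NULL) {
  if (inherits(store, "odt_cube")) {
    cube <- store
  } else {
    key <- paste0(spec$source, ":", spec$level)
    cube <- store[[key]]
    if (is.null(cube)) {
      stop("availability error: no cube for '", key, "'; known: ",
           paste(names(store), collapse = ", "))
    }
  }
  if (!is.null(spec$t_range)) spec$t_range <- as.Date(unlist(spec$t_range))
  if (identical(spec$scenario, "extract") &&
      identical(spec$aggregation, "aggregated")) {
    sub <- dice(cube, o_filter = spec$o_places, d_filter = spec$d_places,
                t_range = spec$t_range)
    tab <- slice_od(sub)
    if (!is.null(spec$min_count)) tab <- min_count_filter(tab, spec$min_count)
    return(tab)
  }
  scenario_tables(cube, spec, geography = geography)
}
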