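#' Monthly mobility reduction rate against a baseline month
#'
#' For each period i with flow mass M_i and a baseline mass M_base, the
#' reduction rate is R_i = (M_i - M_base) / M_base: 0 at the baseline,
#' negative when mobility dropped (-0.5 at half the baseline mass), +1 at
#' double. The rate is dimensionless and invariant to uniform rescaling of
#' all masses.
#'
#' @param monthly_mass named numeric vector (names are period labels, e.g.
#'   `"2020-01"`) or a two-column `data.frame` (period, mass).
#' @param baseline period label of the baseline month.
#' @return `data.table` with columns `period, mass, rate`, plus attributes
#'   `baseline` and `baseline_mass`.
#' @export
reduction_rate <- function(monthly_mass, baseline) {
  if (is.data.frame(monthly_mass)) {
    tab <- as.data.table(monthly_mass)
    setnames(tab, c("period", "mass"))
  } else {
    tab <- data.table(period = names(monthly_mass),
                      mass = as.numeric(monthly_mass))
  }
  if (!baseline %in% tab$period) {
    stop("baseline error: period '", baseline, "' absent from the series")
  }
  m_base <- tab$mass[tab$period == baseline][1]
  if (!is.finite(m_base) || m_base <= 0) {
    stop("baseline error: baseline mass must be > 0 (got ", m_base, ")")
  }
  tab[, rate := (mass - m_base) / m_base]
  setorder(tab, period)
  out <- tab[]
  setattr(out, "baseline", baseline)
  setattr(out, "baseline_mass", m_base)
  out
}

#' Read a case-count table
#'
#' CSV with columns `place_id, date, cumulative_cases`.
#'
#' @param path file path.
#' @return `data.table` with a Date `date` column.
#' @export
read_cases <- function(path) {
  cs <- fread(path, colClasses = list(character = "place_id"))
  req <- c("place_id", "date", "cumulative_cases")
  miss <- setdiff(req, names(cs))
  if (length(miss)) stop("case file missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!inherits(cs$date, "Date")) cs[, date := as.Date(date)]
  cs[]
}

#' Outflow vector of a focal place over a time window
#'
#' Sum of flows from the focal place to each other place at the cube's
#' level over a closed date window. Places with no observed flow are
#' included with zero: absence of a sparse cell means no movement was
#' observed, not missing data.
#'
#' @param cube an `odt_cube`.
#' @param focal_place origin place id.
#' @param flow_window length-2 Date vector (closed).
#' @param places optional character vector of destination places to report
#'   (defaults to every place seen in the cube except the focal one).
#' @return named numeric vector of outflow totals per destination place.
#' @export
outflow_vector <- function(cube, focal_place, flow_window, places = NULL) {
  check_place(cube, focal_place)
  if (is.null(places)) {
    places <- sort(setdiff(unique(c(cube$cells$o_place, cube$cells$d_place)),
                           focal_place))
  }
  fl <- place_flows(cube, focal_place, t_range = flow_window,
                    direction = "outflow")
  v <- stats::setNames(rep(0, length(places)), places)
  hit <- intersect(fl$place, places)
  v[hit] <- fl$cnt[match(hit, fl$place)]
  v
}

#' Daily correlation between a fixed outflow vector and evolving case counts
#'
#' Computes the outflows from a focal place to every other place over a
#' fixed window (e.g. the last days before a lockdown), then for each
#' evaluation day correlates that vector against the cumulative confirmed
#' cases of the destination places on that day. Rising correlations
#' indicate that places receiving more travellers from the focal place
#' accumulate more cases.
#'
#' @param cube an `odt_cube`.
#' @param focal_place origin place id.
#' @param flow_window length-2 Date vector over which outflows are summed.
#' @param cases case table (`place_id, date, cumulative_cases`), cumulative
#'   per place.
#' @param eval_days Date vector of evaluation days (default: all days in
#'   `cases`).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return `data.table` with columns `day, r, n_places`; `r` is `NA` when
#'   fewer than 3 paired places are available or either vector is
#'   constant.
#' @export
outflow_case_correlation <- function(cube, focal_place, flow_window, cases,
                                     eval_days = NULL,
                                     method = c("pearson", "spearman")) {
  method <- match.arg(method)
  cases <- as.data.table(cases)
  if (is.null(eval_days)) eval_days <- sort(unique(cases$date))
  v_flow <- outflow_vector(cube, focal_place, flow_window)
  out <- vector("list", length(eval_days))
  for (i in seq_along(eval_days)) {
    d <- eval_days[i]
    cd <- cases[date == d & place_id != focal_place]
    paired <- intersect(names(v_flow), cd$place_id)
    n <- length(paired)
    if (n < 3) {
      message("outflow_case_correlation: insufficient data on ", d,
              " (", n, " paired place(s))")
      r <- NA_real_
    } else {
      x <- v_flow[paired]
      y <- cd$cumulative_cases[match(paired, cd$place_id)]
      if (stats::sd(x) == 0 || stats::sd(y) == 0) {
        r <- NA_real_
      } else {
        r <- stats::cor(x, y, method = method)
      }
    }
    out[[i]] <- data.table(day = d, r = r, n_places = n)
  }
  rbindlist(out)[]
}

#' Scenario tables: the four portal query patterns
#'
#' Dispatches a named query to the cube-layer primitive behind each portal
#' scenario and returns a flat table ready for export:
#'
#' * `place_flows` — aggregated flows between one place and all others
#'   over a period (choropleth map).
#' * `daily_movements` — daily in/out/intra series for one place (time
#'   series chart).
#' * `od_matrix` — flows among all (or selected) places over a period
#'   (flow map).
#' * `extract` — a diced subcube in daily form (download).
#'
#' An area of interest may be given as `bbox = c(lat_min, lon_min,
#' lat_max, lon_max)`: places whose centroid falls inside the (closed) box
#' are selected; this needs `geography` for the centroids.
#'
#' @param cube an `odt_cube`.
#' @param query a list with `scenario` plus its parameters: `place`,
#'   `direction`, `t_range`, `o_places`/`d_places`, `bbox`, `min_count`.
#' @param geography optional `odt_geography` (required for `bbox`).
#' @return a `data.table`.
#' @export
scenario_tables <- function(cube, query, geography = NULL) {
  if (is.null(query$scenario)) stop("validation error: query$scenario missing")
  sc <- query$scenario
  bad <- function(...) stop("validation error in scenario '", sc, "': ", ...)
  bbox_places <- function() {
    if (is.null(geography)) bad("bbox requires a geography")
    b <- query$bbox
    if (length(b) != 4) bad("bbox must be c(lat_min, lon_min, lat_max, lon_max)")
    pl <- geo_places(geography, cube$level)
    pl[centroid_lat >= b[1] & centroid_lat <= b[3] &
         centroid_lon >= b[2] & centroid_lon <= b[4], place_id]
  }
  tab <- switch(sc,
    place_flows = {
      if (is.null(query$place)) bad("'place' missing")
      place_flows(cube, query$place, t_range = query$t_range,
                  direction = query$direction %||% "in_and_out",
                  geography = geography)
    },
    daily_movements = {
      if (is.null(query$place)) bad("'place' missing")
      s <- place_series(cube, query$place,
                        direction = query$direction %||% "in_and_out",
                        geography = geography)
      if (!is.null(query$t_range)) {
        tr <- as.Date(query$t_range)
        s <- s[day >= tr[1] & day <= tr[2]]
      }
      s
    },
    od_matrix = {
      sub <- cube
      if (!is.null(query$bbox)) {
        ids <- bbox_places()
        sub <- dice(sub, o_filter = ids, d_filter = ids)
      }
      slice_od(sub, t_range = query$t_range)
    },
    extract = {
      sub <- cube
      if (!is.null(query$bbox)) {
        ids <- bbox_places()
        sub <- dice(sub, o_filter = ids, d_filter = ids)
      }
      sub <- dice(sub, o_filter = query$o_places, d_filter = query$d_places,
                  t_range = query$t_range)
      sub$cells[, .(o_place, d_place,
                    year = as.integer(format(day, "%Y")),
                    month = as.integer(format(day, "%m")),
                    day = as.integer(format(day, "%d")),
                    cnt, o_lat, o_lon, d_lat, d_lon)]
    },
    bad("unknown scenario (use place_flows, daily_movements, od_matrix, extract)")
  )
  if (!is.null(query$min_count)) tab <- min_count_filter(tab, query$min_count)
  tab
}
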