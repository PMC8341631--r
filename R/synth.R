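#' Configuration for the synthetic-data generator
#'
#' Describes a small world with known ground truth: a 3-level nested grid
#' geography (block-group-like, county-like, state-like cells with
#' FIPS-style nested ids), a population of random walkers emitting
#' geotagged events (a fraction of them bots posting from known automated
#' sources), home-based device-count records, and case counts with a
#' planted linear dependence on inflows.
#'
#' Defaults describe the stated world once: 50 walkers over 30 days on a
#' 12x12 fine grid (2x2 states, 3x3 counties per state, 2x2 block groups
#' per county), 2 events per walker-day on average, walkers staying put
#' between events with probability 0.6 and otherwise stepping at most 2
#' fine cells, 10% bots.
#'
#' @param seed integer; fixes all randomness.
#' @param coarse_side states per side.
#' @param mid_per_coarse counties per state side.
#' @param fine_per_mid block groups per county side.
#' @param cell_deg fine-cell side in degrees.
#' @param origin_lat,origin_lon south-west corner of the grid (kept far
#'   from poles and antimeridian).
#' @param n_entities number of walkers.
#' @param days number of simulated days.
#' @param start_day first simulated day.
#' @param event_rate Poisson mean events per walker-day.
#' @param stay_prob probability a walker does not move before an event.
#' @param max_step maximum move distance in fine cells (Chebyshev).
#' @param bot_fraction fraction of walkers that are bots.
#' @param bot_sources,human_sources posting-client strings.
#' @param sdm_records_per_day home-based records generated per day.
#' @param sdm_dest_mean Poisson mean of extra destinations per record.
#' @param sdm_count_mean Poisson mean of the device count minus one.
#' @param case_a linear coefficient of planted case dependence on flows.
#' @param case_noise_sd standard deviation of daily case noise.
#' @return a list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         coarse_side = 2L, mid_per_coarse = 3L,
                         fine_per_mid = 2L, cell_deg = 0.05,
                         origin_lat = 30, origin_lon = 10,
                         n_entities = 50L, days = 30L,
                         start_day = as.Date("2020-03-01"),
                         event_rate = 2, stay_prob = 0.6, max_step = 2L,
                         bot_fraction = 0.1,
                         bot_sources = c("TweetMyJOBS", "AutoWeatherBot"),
                         human_sources = c("Mobile App A", "Mobile App B",
                                           "Web Client"),
                         sdm_records_per_day = 20L, sdm_dest_mean = 3,
                         sdm_count_mean = 4,
                         case_a = 1, case_noise_sd = 0) {
  stopifnot(coarse_side >= 1, mid_per_coarse >= 1, fine_per_mid >= 1,
            cell_deg > 0, n_entities >= 0, days >= 1,
            bot_fraction >= 0, bot_fraction <= 1)
  structure(as.list(environment()), class = "synth_config")
}

# id builders: 2-digit state, 2+3 county, 2+3+7 block group — prefix
# truncation of the 12-digit code recovers county (5) and state (2)
synth_state_id <- function(s) sprintf("%02d", s)
synth_county_id <- function(s, c) sprintf("%02d%03d", s, c)
synth_cbg_id <- function(s, c, b) sprintf("%02d%03d%07d", s, c, b)

# fine-cell (ix, iy), zero-based, -> ids at the three levels
synth_cell_ids <- function(ix, iy, cfg) {
  mid_side <- cfg$coarse_side * cfg$mid_per_coarse
  fx <- ix %/% cfg$fine_per_mid; fy <- iy %/% cfg$fine_per_mid # county cell
  sx <- fx %/% cfg$mid_per_coarse; sy <- fy %/% cfg$mid_per_coarse
  s <- sy * cfg$coarse_side + sx + 1L
  c_in_s <- (fy %% cfg$mid_per_coarse) * cfg$mid_per_coarse +
    (fx %% cfg$mid_per_coarse) + 1L
  b_in_c <- (iy %% cfg$fine_per_mid) * cfg$fine_per_mid +
    (ix %% cfg$fine_per_mid) + 1L
  list(state = synth_state_id(s),
       county = synth_county_id(s, c_in_s),
       cbg = synth_cbg_id(s, c_in_s, b_in_c))
}

#' Build the nested grid geography
#'
#' Three levels named `cbg < county < state`: square cells in lon/lat
#' degrees with FIPS-like nested ids, so code-prefix truncation agrees
#' with geometric containment. Deterministic: the same config always
#' yields the identical object.
#'
#' @param cfg a [synth_config()].
#' @return an `odt_geography`.
#' @export
make_geography <- function(cfg) {
  n_fine <- cfg$coarse_side * cfg$mid_per_coarse * cfg$fine_per_mid
  cell <- cfg$cell_deg
  square <- function(ix, iy, span) {
    x0 <- cfg$origin_lon + ix * cell
    y0 <- cfg$origin_lat + iy * cell
    x1 <- x0 + span * cell; y1 <- y0 + span * cell
    matrix(c(x0, y0, x1, y0, x1, y1, x0, y1, x0, y0),
           ncol = 2, byrow = TRUE)
  }
  places <- list(); polygons <- list(); parent <- character()
  add_place <- function(pid, lv, ring, par = NULL) {
    polygons[[pid]] <<- list(ring)
    places[[length(places) + 1L]] <<- data.table(
      place_id = pid, name = pid, level = lv,
      centroid_lat = mean(range(ring[, 2])),
      centroid_lon = mean(range(ring[, 1])))
    if (!is.null(par)) parent[pid] <<- par
  }
  for (iy in seq_len(n_fine) - 1L) for (ix in seq_len(n_fine) - 1L) {
    ids <- synth_cell_ids(ix, iy, cfg)
    add_place(ids$cbg, "cbg", square(ix, iy, 1L), ids$county)
  }
  mid_side <- cfg$coarse_side * cfg$mid_per_coarse
  for (fy in seq_len(mid_side) - 1L) for (fx in seq_len(mid_side) - 1L) {
    ids <- synth_cell_ids(fx * cfg$fine_per_mid, fy * cfg$fine_per_mid, cfg)
    add_place(ids$county, "county",
              square(fx * cfg$fine_per_mid, fy * cfg$fine_per_mid,
                     cfg$fine_per_mid), ids$state)
  }
  span_s <- cfg$mid_per_coarse * cfg$fine_per_mid
  for (sy in seq_len(cfg$coarse_side) - 1L) {
    for (sx in seq_len(cfg$coarse_side) - 1L) {
      ids <- synth_cell_ids(sx * span_s, sy * span_s, cfg)
      add_place(ids$state, "state", square(sx * span_s, sy * span_s, span_s))
    }
  }
  odt_geography(c("cbg", "county", "state"), rbindlist(places),
                polygons, parent)
}

# jittered point inside a fine cell, kept >= 10% of the cell away from
# every cell boundary so float noise can never flip a containment test
synth_jitter_point <- function(ix, iy, cfg) {
  u <- stats::runif(2, 0.1, 0.9)
  c(lat = cfg$origin_lat + (iy + u[1]) * cfg$cell_deg,
    lon = cfg$origin_lon + (ix + u[2]) * cfg$cell_deg)
}

#' Simulate geotagged event streams with ground truth
#'
#' Walkers start at seeded home cells and move between events: with
#' probability `stay_prob` an event is posted from the current cell,
#' otherwise the walker first steps to a uniformly chosen cell at most
#' `max_step` fine cells away (clipped to the grid). Event counts per
#' walker-day are Poisson; event coordinates are jittered inside the cell;
#' timestamps are distinct seconds within the day. Bot walkers post from
#' the configured automated sources.
#'
#' The returned ground truth re-derives the expected flows from the raw
#' itineraries in deliberately independent straight-line code (arithmetic
#' cell assignment, spherical law of cosines distances, explicit loops) so
#' it can serve as an oracle for the extraction pipeline.
#'
#' @param cfg a [synth_config()].
#' @param geography the matching [make_geography()] output (only used for
#'   validation of the grid extent).
#' @return list with `events` (a `data.table` in the event schema) and
#'   `truth` (see [truth_flows()]).
#' @export
simulate_events <- function(cfg, geography = NULL) {
  set.seed(cfg$seed)
  n_fine <- cfg$coarse_side * cfg$mid_per_coarse * cfg$fine_per_mid
  days <- seq(cfg$start_day, by = "day", length.out = cfg$days)
  n_bots <- round(cfg$bot_fraction * cfg$n_entities)
  is_bot <- rep(c(TRUE, FALSE),
                c(n_bots, cfg$n_entities - n_bots))
  rows <- list()
  for (e in seq_len(cfg$n_entities)) {
    eid <- sprintf("u%04d", e)
    pos <- c(sample.int(n_fine, 1) - 1L, sample.int(n_fine, 1) - 1L)
    srcs <- if (is_bot[e]) cfg$bot_sources else cfg$human_sources
    for (d in seq_along(days)) {
      k <- stats::rpois(1, cfg$event_rate)
      if (k == 0) next
      secs <- sort(sample.int(86400L, k))
      for (j in seq_len(k)) {
        if (stats::runif(1) > cfg$stay_prob) {
          step <- sample(seq(-cfg$max_step, cfg$max_step), 2, replace = TRUE)
          pos <- pmin(pmax(pos + step, 0L), n_fine - 1L)
        }
        pt <- synth_jitter_point(pos[1], pos[2], cfg)
        rows[[length(rows) + 1L]] <- data.table(
          entity_id = eid, lat = pt["lat"], lon = pt["lon"],
          timestamp = as.POSIXct(days[d], tz = "UTC") + secs[j],
          source = srcs[(j - 1L) %% length(srcs) + 1L])
      }
    }
  }
  events <- if (length(rows)) rbindlist(rows) else data.table(
    entity_id = character(), lat = numeric(), lon = numeric(),
    timestamp = as.POSIXct(character(), tz = "UTC"), source = character())
  truth <- truth_movements(events[!(source %in% cfg$bot_sources)], cfg)
  list(events = events[], truth = truth)
}

# ---- independent ground-truth oracle -------------------------------------
# Straight-line re-derivation of the daily movement rules from raw
# itineraries. Shares no code with the extraction path: distances use the
# spherical law of cosines, place assignment is arithmetic on the grid,
# means are explicit sums.

truth_dist_km <- function(lat1, lon1, lat2, lon2) {
  if (lat1 == lat2 && lon1 == lon2) return(0)
  r <- pi / 180
  x <- sin(lat1 * r) * sin(lat2 * r) +
    cos(lat1 * r) * cos(lat2 * r) * cos((lon2 - lon1) * r)
  6371 * acos(min(max(x, -1), 1))
}

truth_cell_of <- function(lat, lon, cfg, level) {
  ix <- floor((lon - cfg$origin_lon) / cfg$cell_deg)
  iy <- floor((lat - cfg$origin_lat) / cfg$cell_deg)
  n_fine <- cfg$coarse_side * cfg$mid_per_coarse * cfg$fine_per_mid
  if (ix < 0 || iy < 0 || ix >= n_fine || iy >= n_fine) return(NA_character_)
  synth_cell_ids(ix, iy, cfg)[[level]]
}

truth_movements <- function(events, cfg) {
  ev <- as.data.table(events)
  out <- list()
  if (nrow(ev)) {
    ev <- copy(ev)[, day := as.Date(timestamp, tz = "UTC")]
    setorder(ev, entity_id, timestamp, lat, lon)
    for (eid in unique(ev$entity_id)) {
      ee <- ev[entity_id == eid]
      days <- sort(unique(ee$day))
      for (kd in seq_along(days)) {
        d <- days[kd]
        de <- ee[day == d]
        if (nrow(de) >= 2) {
          best <- 1L; bestd <- 0
          for (i in seq_len(nrow(de))) {
            di <- truth_dist_km(de$lat[1], de$lon[1], de$lat[i], de$lon[i])
            if (di > bestd) { bestd <- di; best <- i }
          }
          if (bestd > 0) {
            out[[length(out) + 1L]] <- data.table(
              entity_id = eid, day = d, kind = "single_day",
              o_lat = de$lat[1], o_lon = de$lon[1],
              d_lat = de$lat[best], d_lon = de$lon[best])
          }
        }
        if ((d + 1L) %in% days) {
          d0 <- ee[day == d]; d1 <- ee[day == d + 1L]
          m0la <- 0; m0lo <- 0
          for (i in seq_len(nrow(d0))) {
            m0la <- m0la + d0$lat[i]; m0lo <- m0lo + d0$lon[i]
          }
          m0la <- m0la / nrow(d0); m0lo <- m0lo / nrow(d0)
          m1la <- 0; m1lo <- 0
          for (i in seq_len(nrow(d1))) {
            m1la <- m1la + d1$lat[i]; m1lo <- m1lo + d1$lon[i]
          }
          m1la <- m1la / nrow(d1); m1lo <- m1lo / nrow(d1)
          if (truth_dist_km(m0la, m0lo, m1la, m1lo) > 0) {
            out[[length(out) + 1L]] <- data.table(
              entity_id = eid, day = d, kind = "cross_day",
              o_lat = m0la, o_lon = m0lo, d_lat = m1la, d_lon = m1lo)
          }
        }
      }
    }
  }
  mv <- if (length(out)) rbindlist(out) else data.table(
    entity_id = character(), day = as.Date(character()), kind = character(),
    o_lat = numeric(), o_lon = numeric(),
    d_lat = numeric(), d_lon = numeric())
  structure(list(movements = mv, cfg = cfg), class = "odt_truth")
}

#' Expected entity flows from the ground truth
#'
#' Assigns the recorded movement endpoints to grid cells arithmetically at
#' the requested level and deduplicates per (entity, origin, destination,
#' day) with single-day movements taking precedence — the same contract
#' the extraction pipeline implements, derived by independent code.
#'
#' @param truth the `truth` component of [simulate_events()].
#' @param level `"cbg"`, `"county"` or `"state"`.
#' @return entity-flow `data.table`.
#' @export
truth_flows <- function(truth, level = "cbg") {
  mv <- truth$movements
  cfg <- truth$cfg
  if (nrow(mv) == 0) return(empty_entity_flows())
  rows <- list()
  for (i in seq_len(nrow(mv))) {
    op <- truth_cell_of(mv$o_lat[i], mv$o_lon[i], cfg, level)
    dp <- truth_cell_of(mv$d_lat[i], mv$d_lon[i], cfg, level)
    if (is.na(op) || is.na(dp)) next
    rows[[length(rows) + 1L]] <- data.table(
      entity_id = mv$entity_id[i], o_place = op, d_place = dp,
      day = mv$day[i], o_lat = mv$o_lat[i], o_lon = mv$o_lon[i],
      d_lat = mv$d_lat[i], d_lon = mv$d_lon[i], kind = mv$kind[i],
      weight = 1)
  }
  if (length(rows) == 0) return(empty_entity_flows())
  fl <- rbindlist(rows)
  fl[, kind_rank := fifelse(kind == "single_day", 0L, 1L)]
  setorder(fl, entity_id, day, o_place, d_place, kind_rank)
  fl <- fl[!duplicated(fl[, .(entity_id, o_place, d_place, day)])]
  fl[, kind_rank := NULL]
  setorder(fl, entity_id, day, o_place, d_place)
  fl[]
}

#' Simulate home-based (SDM-style) mobility records with ground truth
#'
#' Each simulated day draws origin block groups and, per record, a set of
#' destination block groups (possibly including the home cell as a
#' self-loop) with positive device counts. The ground truth is the direct
#' group-by of code-prefix-truncated origin/destination pairs.
#'
#' @param cfg a [synth_config()].
#' @param geography the matching geography.
#' @return list with `records` (raw SDM-style rows: one line per origin
#'   with a JSON `destination_cbgs` map), `long` (the parsed long form)
#'   and `truth_weights(level)` giving expected per-(o, d, day) weights.
#' @export
simulate_sdm <- function(cfg, geography) {
  set.seed(cfg$seed + 1L)
  cbgs <- sort(geo_places(geography, "cbg")$place_id)
  days <- seq(cfg$start_day, by = "day", length.out = cfg$days)
  raw <- list(); long <- list()
  for (d in seq_along(days)) {
    n <- min(cfg$sdm_records_per_day, length(cbgs))
    origins <- sample(cbgs, n)
    for (o in origins) {
      ndest <- 1L + stats::rpois(1, cfg$sdm_dest_mean)
      dests <- sample(cbgs, min(ndest, length(cbgs)))
      counts <- 1L + stats::rpois(length(dests), cfg$sdm_count_mean)
      mp <- paste0("{", paste(sprintf('"%s":%d', dests, counts),
                              collapse = ","), "}")
      raw[[length(raw) + 1L]] <- data.table(
        origin_census_block_group = o, destination_cbgs = mp,
        date_range_start = format(days[d], "%Y-%m-%dT00:00:00-05:00"))
      long[[length(long) + 1L]] <- data.table(
        origin_cbg = o, dest_cbg = dests, count = as.numeric(counts),
        day = days[d])
    }
  }
  long_dt <- rbindlist(long)
  truth_weights <- function(level = "cbg") {
    trunc_to <- function(x) switch(level, cbg = x,
                                   county = substr(x, 1, 5),
                                   state = substr(x, 1, 2))
    tw <- long_dt[, .(cnt = sum(count)),
                  by = .(o_place = trunc_to(origin_cbg),
                         d_place = trunc_to(dest_cbg), day)]
    setorder(tw, o_place, d_place, day)
    tw[]
  }
  list(records = rbindlist(raw)[], long = long_dt[],
       truth_weights = truth_weights)
}

#' Simulate cumulative case counts with planted flow dependence
#'
#' Destination places of a focal place's outflows accumulate cases whose
#' daily increments are `intercept + a * outflow + noise`, clamped at zero
#' and cumulated, so cumulative counts are non-decreasing. With zero noise
#' and `a > 0` the cumulative cases on every day are an exact positive
#' linear function of the outflow vector.
#'
#' @param cube an `odt_cube`.
#' @param focal_place origin place of the planted dependence.
#' @param flow_window length-2 Date window over which outflows are summed.
#' @param eval_days Date vector of reporting days.
#' @param a linear coefficient.
#' @param noise_sd Gaussian noise sd of daily increments.
#' @param seed integer seed.
#' @param intercept baseline daily increment (default `5 * noise_sd`, so
#'   clamping is rare).
#' @return case `data.table` (`place_id, date, cumulative_cases`).
#' @export
simulate_cases <- function(cube, focal_place, flow_window, eval_days,
                           a = 1, noise_sd = 0, seed = 1L,
                           intercept = 5 * noise_sd) {
  set.seed(seed)
  v <- outflow_vector(cube, focal_place, flow_window)
  out <- list()
  for (j in names(v)) {
    inc <- intercept + a * v[[j]] +
      stats::rnorm(length(eval_days), 0, noise_sd)
    inc <- pmax(inc, 0)
    out[[length(out) + 1L]] <- data.table(
      place_id = j, date = eval_days, cumulative_cases = cumsum(inc))
  }
  res <- rbindlist(out)
  setorder(res, place_id, date)
  res[]
}
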