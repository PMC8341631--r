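test_that("build_cube counts entities and matches a nested-loop oracle", {
  day <- as.Date("2020-03-01")
  fl <- data.table(
    entity_id = c("a", "b", "c"), o_place = "A", d_place = "B", day = day,
    o_lat = 30.1, o_lon = 10.1, d_lat = 30.2, d_lon = 10.2,
    kind = "single_day", weight = 1)
  cube <- build_cube(fl, "county")
  expect_identical(nrow(cube$cells), 1L)
  expect_identical(cube$cells$cnt, 3)
  # empty flow table -> empty cube
  expect_identical(nrow(build_cube(fl[0], "county")$cells), 0L)
  # random flow tables vs independent nested-loop accumulation
  set.seed(23)
  for (rep in 1:5) {
    rf <- data.table(
      entity_id = sample(letters, 80, replace = TRUE),
      o_place = sample(c("A", "B", "C"), 80, replace = TRUE),
      d_place = sample(c("A", "B", "C"), 80, replace = TRUE),
      day = day + sample.int(5, 80, replace = TRUE),
      o_lat = runif(80, 30, 31), o_lon = runif(80, 10, 11),
      d_lat = runif(80, 30, 31), d_lon = runif(80, 10, 11),
      kind = "sdm", weight = sample.int(9, 80, replace = TRUE))
    got <- build_cube(rf, "county")$cells[, .(o_place, d_place, day, cnt)]
    expect_equal(got, oracle_build_cells(rf))
  }
})

test_that("build_cube validates places against the geography level", {
  geo <- make_geography(synth_config())
  fl <- data.table(entity_id = "a", o_place = "01001", d_place = "nope",
                   day = as.Date("2020-03-01"), o_lat = 30, o_lon = 10,
                   d_lat = 30, d_lon = 10, kind = "sdm", weight = 1)
  expect_error(build_cube(fl, "county", geo), "level error.*nope")
})

test_that("rollup_spatial sums children, conserves mass and is identity at own level", {
  geo <- make_geography(synth_config())
  day <- as.Date("2020-03-01")
  cells <- data.table(
    o_place = c("010010000001", "010010000002"),
    d_place = c("010020000001", "010020000001"),
    day = day, cnt = c(2, 3),
    o_lat = c(30.02, 30.04), o_lon = c(10.02, 10.04),
    d_lat = 30.08, d_lon = 10.08)
  cube <- odt_cube(cells, "cbg")
  up <- rollup_spatial(cube, "county", geo)
  expect_identical(nrow(up$cells), 1L)
  expect_identical(up$cells$cnt, 5)
  expect_identical(up$cells$o_place, "01001")
  # weighted endpoint mean: (2*30.02 + 3*30.04)/5
  expect_equal(up$cells$o_lat, (2 * 30.02 + 3 * 30.04) / 5)
  expect_identical(rollup_spatial(cube, "cbg", geo), cube)
  expect_identical(cube_total(up), cube_total(cube))
})

test_that("spatial roll-up of a cube equals building from rolled-up entity flows", {
  cfg <- small_cfg(seed = 41L)
  geo <- make_geography(cfg)
  sdm <- simulate_sdm(cfg, geo)
  fl <- sdm_entity_flows(parse_sdm_records(sdm$records), geo, "cbg")
  path1 <- rollup_spatial(build_cube(fl, "cbg", geo), "county", geo)
  path2 <- build_cube(rollup_entity_flows(fl, "cbg", "county", geo),
                      "county", geo)
  expect_identical(path1$cells[, .(o_place, d_place, day, cnt)],
                   path2$cells[, .(o_place, d_place, day, cnt)])
  expect_equal(path1$cells, path2$cells, tolerance = 1e-12)
})

test_that("rollup_temporal bins by ISO week and calendar month, conserving mass", {
  # 7 daily unit cells spanning one ISO week (2020-03-02 is a Monday)
  days <- seq(as.Date("2020-03-02"), by = "day", length.out = 7)
  cells <- data.table(o_place = "A", d_place = "B", day = days, cnt = 1,
                      o_lat = 30, o_lon = 10, d_lat = 30.5, d_lon = 10.5)
  cube <- odt_cube(cells, "county")
  wk <- rollup_temporal(cube, "week")
  expect_identical(nrow(wk), 1L)
  expect_identical(wk$cnt, 7)
  expect_identical(wk$period, "2020-W10")
  # single-day cube: any granularity keeps totals
  one <- odt_cube(cells[1], "county")
  for (g in c("day", "week", "month")) {
    expect_identical(sum(rollup_temporal(one, g)$cnt), 1)
  }
  # random cube: monthly totals equal brute-force date filtering
  set.seed(5)
  rc <- random_cube(300, n_days = 70)
  mo <- rollup_temporal(rc, "month")
  for (m in unique(mo$period)) {
    expect_identical(sum(mo[period == m, cnt]),
                     sum(rc$cells[format(day, "%Y-%m") == m, cnt]))
  }
  expect_identical(sum(mo$cnt), cube_total(rc))
})

test_that("dice restricts by origin, destination and closed date range", {
  set.seed(31)
  cube <- random_cube(200)
  dr <- day_range(cube)
  # identity
  expect_identical(dice(cube, t_range = dr)$cells, cube$cells)
  expect_identical(dice(cube)$cells, cube$cells)
  # absent origin -> empty
  expect_identical(nrow(dice(cube, o_filter = "XX")$cells), 0L)
  expect_error(dice(cube, t_range = c(dr[2], dr[1])), "start after end")
  # random filters vs a row-wise predicate scan
  for (rep in 1:10) {
    of <- sample(unique(cube$cells$o_place), 3)
    df <- sample(unique(cube$cells$d_place), 4)
    tr <- sort(sample(seq(dr[1], dr[2], by = "day"), 2))
    got <- dice(cube, of, df, tr)$cells
    want <- cube$cells[o_place %in% of & d_place %in% df &
                         day >= tr[1] & day <= tr[2]]
    expect_identical(got, want)
    # dice of dice with intersected filters equals one dice
    of2 <- sample(unique(cube$cells$o_place), 5)
    expect_identical(
      dice(dice(cube, o_filter = of2), o_filter = of, t_range = tr)$cells,
      dice(cube, o_filter = intersect(of2, of), t_range = tr)$cells)
  }
})

test_that("slices agree on single cells, totals and the diagonal", {
  day <- as.Date("2020-03-07")
  cube <- toy_cube(data.table(o_place = "A", d_place = "B", day = day,
                              cnt = 4))
  expect_identical(slice_od(cube)$cnt, 4)
  expect_identical(slice_ot(cube)[, .(o_place, day, cnt)],
                   data.table(o_place = "A", day = day, cnt = 4))
  expect_identical(slice_dt(cube)[, .(d_place, day, cnt)],
                   data.table(d_place = "B", day = day, cnt = 4))
  # total mass identical across all three slices of a random cube
  set.seed(61)
  rc <- random_cube(400)
  expect_identical(sum(slice_od(rc)$cnt), cube_total(rc))
  expect_identical(sum(slice_ot(rc)$cnt), cube_total(rc))
  expect_identical(sum(slice_dt(rc)$cnt), cube_total(rc))
  # a purely diagonal cube has its whole mass on the OD diagonal
  diag_cube <- toy_cube(data.table(o_place = c("A", "B"),
                                   d_place = c("A", "B"),
                                   day = day, cnt = c(2, 3)))
  od <- slice_od(diag_cube)
  expect_identical(sum(od[o_place == d_place, cnt]), cube_total(diag_cube))
})

test_that("place_series decomposes directions as defined", {
  day <- as.Date("2020-03-07")
  cube <- toy_cube(data.table(
    o_place = c("A", "B", "B"), d_place = c("B", "A", "B"),
    day = day, cnt = c(2, 3, 5)))
  expect_identical(place_series(cube, "B", "inflow")$cnt, 2)
  expect_identical(place_series(cube, "B", "outflow")$cnt, 3)
  expect_identical(place_series(cube, "B", "intraflow")$cnt, 5)
  # in&out excludes the diagonal
  expect_identical(place_series(cube, "B", "in_and_out")$cnt, 5)
  # place with no incident cells: all-zero series
  expect_identical(place_series(cube, "A", "intraflow")$cnt, 0)
  expect_error(place_series(cube, "ZZ", "inflow"), "place error")
  # random cubes vs brute-force scans
  set.seed(71)
  for (rep in 1:5) {
    rc <- random_cube(150)
    p <- sample(unique(rc$cells$o_place), 1)
    days <- seq(day_range(rc)[1], day_range(rc)[2], by = "day")
    for (dir in c("inflow", "outflow", "intraflow", "in_and_out")) {
      got <- place_series(rc, p, dir)
      want <- vapply(days, function(d) {
        cl <- rc$cells[day == d]
        switch(dir,
          inflow = sum(cl[d_place == p & o_place != p, cnt]),
          outflow = sum(cl[o_place == p & d_place != p, cnt]),
          intraflow = sum(cl[o_place == p & d_place == p, cnt]),
          in_and_out = sum(cl[d_place == p & o_place != p, cnt]) +
            sum(cl[o_place == p & d_place != p, cnt]))
      }, numeric(1))
      expect_identical(got$cnt, want)
    }
  }
})

test_that("place_flows totals counterparts and reports intra separately", {
  day <- as.Date("2020-03-07")
  cube <- toy_cube(data.table(o_place = "A", d_place = "B", day = day,
                              cnt = 4))
  infl <- place_flows(cube, "B", direction = "inflow")
  expect_identical(infl$place, "A")
  expect_identical(infl$cnt, 4)
  set.seed(81)
  rc <- random_cube(150)
  p <- sample(unique(rc$cells$o_place), 1)
  io <- place_flows(rc, p, direction = "in_and_out")
  i1 <- place_flows(rc, p, direction = "inflow")
  o1 <- place_flows(rc, p, direction = "outflow")
  manual <- merge(i1, o1, by = "place", all = TRUE)
  manual[is.na(cnt.x), cnt.x := 0][is.na(cnt.y), cnt.y := 0]
  expect_identical(io$cnt, manual$cnt.x + manual$cnt.y)
  expect_identical(attr(io, "intra"),
                   sum(rc$cells[o_place == p & d_place == p, cnt]))
})

test_that("min_count_filter is strict and mass-safe at zero", {
  tab <- data.table(place = c("A", "B"), cnt = c(20, 21))
  expect_identical(min_count_filter(tab, 20)$place, "B")
  expect_identical(min_count_filter(tab, 0), tab)
  expect_error(min_count_filter(tab, -1), ">= 0")
  set.seed(91)
  rc <- random_cube(150)
  thr <- 25
  expect_identical(min_count_filter(rc, thr)$cells,
                   rc$cells[cnt > thr])
})

test_that("slicing a diced cube is consistent with place_series decomposition", {
  set.seed(101)
  rc <- random_cube(200)
  p <- sample(unique(rc$cells$o_place), 1)
  ot <- slice_ot(dice(rc, o_filter = p))
  days <- seq(day_range(rc)[1], day_range(rc)[2], by = "day")
  outf <- place_series(rc, p, "outflow")
  intra <- place_series(rc, p, "intraflow")
  want <- data.table(day = days, cnt = outf$cnt + intra$cnt)[cnt > 0]
  expect_identical(ot[, .(day, cnt)][order(day)], want)
})

test_that("cube save/load round-trips through the daily export dialect", {
  set.seed(111)
  rc <- random_cube(120)
  # quantize coordinates to the dialect's 6-decimal lattice first
  cl <- copy(rc$cells)
  for (cn in c("o_lat", "o_lon", "d_lat", "d_lon")) {
    cl[, (cn) := round(get(cn), 6)]
  }
  rc6 <- odt_cube(cl, rc$level, rc$source)
  path <- withr::local_tempfile(fileext = ".csv")
  save_cube(rc6, path)
  back <- load_cube(path, rc$level, rc$source)
  expect_equal(back$cells$cnt, rc6$cells$cnt, ignore_attr = TRUE)
  expect_identical(back$cells[, .(o_place, d_place, day)],
                   rc6$cells[, .(o_place, d_place, day)])
  expect_equal(back$cells[, .(o_lat, o_lon, d_lat, d_lon)],
               rc6$cells[, .(o_lat, o_lon, d_lat, d_lon)])
})
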