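test_that("haversine distance has the closed-form great-circle values", {
  expect_identical(haversine_km(-8, 38.8, -8, 38.8), 0)
  # antipodal points: half the circumference
  expect_equal(haversine_km(0, 0, 180, 0), pi * 6371.0088, tolerance = 1e-9)
  # one degree along the equator
  expect_equal(haversine_km(0, 0, 1, 0), 2 * pi * 6371.0088 / 360,
               tolerance = 1e-9)
  expect_equal(haversine_km(0, 0, 1, 0), 111.195, tolerance = 1e-5)
  # symmetry and non-negativity on random pairs; geosphere as oracle
  withr::with_seed(3, {
    lon <- runif(20, -180, 180); lat <- runif(20, -89, 89)
    lon2 <- runif(20, -180, 180); lat2 <- runif(20, -89, 89)
  })
  d1 <- haversine_km(lon, lat, lon2, lat2)
  d2 <- haversine_km(lon2, lat2, lon, lat)
  expect_equal(d1, d2)
  expect_true(all(d1 >= 0))
  ref <- geosphere::distHaversine(cbind(lon, lat), cbind(lon2, lat2),
                                  r = 6371008.8) / 1000
  expect_equal(d1, ref, tolerance = 1e-9)
  expect_error(haversine_km(200, 0, 0, 0), class = "ciconia_input_error")
})

test_that("track cleaning removes duplicates and teleports, keeps clean tracks", {
  sim <- simulate_track("local", 2018, seed = 2)
  expect_equal(clean_track(sim$fixes), dplyr::arrange(sim$fixes, timestamp))

  fx <- sim$fixes[1:50, ]
  teleported <- fx
  teleported$lon[25] <- teleported$lon[25] + 10   # ~870 km in 20 min
  cleaned <- clean_track(teleported)
  expect_equal(nrow(cleaned), 49)
  expect_false(any(abs(cleaned$lon - (-8)) > 5))

  dup <- rbind(fx[1:10, ], fx[5, ])
  dup$lat[11] <- 0  # the duplicate carries junk; the first fix wins
  cleaned2 <- clean_track(dup)
  expect_equal(nrow(cleaned2), 10)
  expect_equal(cleaned2$lat[5], fx$lat[5])
})

test_that("total displacement sums consecutive great-circle legs", {
  still <- tibble::tibble(
    timestamp = as.POSIXct("2019-01-01", tz = "UTC") + (0:5) * 1200,
    lon = rep(1.5, 6), lat = rep(40, 6))
  expect_equal(total_displacement(still), 0)
  expect_warning(total_displacement(still[1, ]), "fewer than 2")

  # three collinear equatorial fixes one degree apart
  eq <- tibble::tibble(
    timestamp = as.POSIXct("2019-01-01", tz = "UTC") + (0:2) * 86400,
    lon = c(0, 1, 2), lat = c(0, 0, 0))
  expect_equal(total_displacement(eq), 222.39, tolerance = 1e-4)

  # additivity over concatenation and the straight-line lower bound
  withr::with_seed(5, {
    rw <- tibble::tibble(
      timestamp = as.POSIXct("2019-01-01", tz = "UTC") + (0:49) * 3600,
      lon = cumsum(rnorm(50, 0, 0.1)), lat = 40 + cumsum(rnorm(50, 0, 0.1)))
  })
  a <- rw[1:20, ]; b <- rw[21:50, ]
  link <- haversine_km(a$lon[20], a$lat[20], b$lon[1], b$lat[1])
  expect_equal(total_displacement(a) + total_displacement(b) + link,
               total_displacement(rw), tolerance = 1e-9)
  expect_gte(total_displacement(rw),
             haversine_km(rw$lon[1], rw$lat[1], rw$lon[50], rw$lat[50]))
  # dropping fixes never increases the summed path length
  thin <- rw[seq(1, 50, by = 2), ]
  expect_lte(total_displacement(thin), total_displacement(rw) + 1e-12)
})

test_that("daily roosts take the nocturnal median with evening-date assignment", {
  # stationary bird: the roost is that point
  dates <- seq(as.Date("2019-02-01"), by = "day", length.out = 5)
  fx <- make_roost_fixes(dates, rep(0.5, 5), rep(39.5, 5))
  r <- daily_roosts(fx)
  expect_equal(nrow(r), 5)
  expect_equal(r$lon, rep(0.5, 5))
  expect_equal(r$date, dates)

  # a single nocturnal fix is its own roost; post-midnight fixes belong
  # to the previous evening
  one <- tibble::tibble(individual = "b",
                        timestamp = as.POSIXct("2019-02-02 02:30:00", tz = "UTC"),
                        lon = 0, lat = 40)
  r1 <- daily_roosts(one)
  expect_equal(r1$date, as.Date("2019-02-01"))
  expect_equal(r1$lat, 40)

  # synthetic migrant: roost jumps match the generator's daily legs
  sim <- simulate_track("nw_africa", 2018, seed = 4)
  r2 <- daily_roosts(sim$fixes)
  truth <- sim$truth$roosts
  joined <- merge(r2, truth, by = "date", suffixes = c("", "_true"))
  err_km <- haversine_km(joined$lon, joined$lat, joined$lon_true, joined$lat_true)
  expect_lt(stats::quantile(err_km, 0.99), 1)
})

test_that("migration windows need three consecutive >60 km roost days", {
  dates <- seq(as.Date("2018-08-04"), by = "day", length.out = 40)
  lat <- rep(39, 40)
  # two consecutive long-displacement days only: not a migration
  lat[20:21] <- c(38, 37)
  fx <- make_roost_fixes(dates, rep(0, 40), lat)
  w <- detect_migration_windows(daily_roosts(fx))
  expect_null(w$autumn)
  expect_null(w$spring)

  # three consecutive days qualify, and the window is exact
  lat2 <- rep(39, 40)
  lat2[20:22] <- c(38, 37, 36); lat2[23:40] <- 36
  fx2 <- make_roost_fixes(dates, rep(0, 40), lat2)
  w2 <- detect_migration_windows(daily_roosts(fx2))
  expect_equal(w2$autumn, c(dates[20], dates[22]))
  expect_null(w2$spring)

  # a calendar gap breaks the run
  fx3 <- make_roost_fixes(dates[-21], rep(0, 39), lat2[-21])
  w3 <- detect_migration_windows(daily_roosts(fx3))
  expect_null(w3$autumn)

  sim <- simulate_track("local", 2018, seed = 6)
  wr <- detect_migration_windows(daily_roosts(sim$fixes))
  expect_null(wr$autumn)
  expect_null(wr$spring)
})

test_that("strategy classification applies the distance and latitude rules", {
  dates <- seq(as.Date("2018-08-04"), length.out = 365, by = "day")
  nest <- c(0, 39)
  # all roosts within 10 km of the nest -> local
  withr::with_seed(8, {
    fx <- make_roost_fixes(dates, rnorm(365, 0, 0.05), 39 + rnorm(365, 0, 0.05))
  })
  cl <- classify_strategy(fx, nest)
  expect_equal(cl$strategy, "local")
  expect_equal(cl$group, "resident")

  # excursion to 300 km away, never south of 35.9 N -> regional
  lat <- rep(39, 365); lon <- rep(0, 365)
  lon[100:200] <- 3.5
  fx2 <- make_roost_fixes(dates, lon, lat)
  expect_equal(classify_strategy(fx2, nest)$strategy, "regional")

  # wintering between the lines -> NW Africa; south of 20 N -> sub-Saharan
  mk_migrant <- function(w_lat) {
    lat <- rep(39, 365)
    out_lat <- seq(39, w_lat, length.out = 12)
    lat[31:42] <- out_lat
    lat[43:170] <- w_lat
    lat[171:182] <- rev(out_lat)
    make_roost_fixes(dates, rep(0, 365), lat)
  }
  expect_equal(classify_strategy(mk_migrant(33), nest)$strategy, "nw_africa")
  expect_equal(classify_strategy(mk_migrant(15), nest)$strategy, "sub_saharan")

  expect_error(classify_strategy(fx, NULL), class = "ciconia_input_error")
})

test_that("season partitions use the fixed resident dates and tile the cycle", {
  p <- partition_seasons("regional", NULL, 2018)
  expect_equal(p$start, as.Date(c("2018-08-04", "2018-09-06", "2018-12-13",
                                  "2019-01-23")))
  expect_equal(p$end, as.Date(c("2018-09-05", "2018-12-12", "2019-01-22",
                                "2019-08-03")))
  expect_equal(p$season, c("autumn", "wintering", "spring", "breeding"))
  # contiguous, non-overlapping, tiling the full cycle
  expect_equal(p$start[-1], p$end[-4] + 1)
  expect_equal(sum(as.integer(p$end - p$start) + 1L), 365L)

  w <- list(autumn = as.Date(c("2018-08-20", "2018-09-02")),
            spring = as.Date(c("2019-01-12", "2019-01-25")))
  pm <- partition_seasons("sub_saharan", w, 2018)
  expect_equal(pm$start[1], w$autumn[1])
  expect_equal(pm$end[3], w$spring[2])
  expect_equal(pm$start[-1], pm$end[-4] + 1)
  expect_equal(sum(as.integer(pm$end - pm$start) + 1L), 365L)

  overlapping <- list(autumn = as.Date(c("2018-08-20", "2019-01-15")),
                      spring = as.Date(c("2019-01-12", "2019-01-25")))
  expect_error(partition_seasons("sub_saharan", overlapping, 2018),
               class = "ciconia_consistency_error")
  expect_error(partition_seasons("nw_africa", NULL, 2018),
               class = "ciconia_input_error")
})

test_that("nest occupation needs three consecutive attendance days", {
  nest <- c(0, 39)
  day_at_nest <- function(d) {
    tibble::tibble(individual = "b",
                   timestamp = as.POSIXct(paste(d, "23:00:00"), tz = "UTC"),
                   lon = 0, lat = 39)
  }
  far_day <- function(d) {
    tibble::tibble(individual = "b",
                   timestamp = as.POSIXct(paste(d, "23:00:00"), tz = "UTC"),
                   lon = 0.5, lat = 39)
  }
  d0 <- as.Date("2019-01-10")
  fx <- dplyr::bind_rows(lapply(0:9, function(k) day_at_nest(d0 + k)))
  expect_equal(nest_occupation_date(fx, nest), d0)

  # visits on d and d+2 only never qualify
  gappy <- dplyr::bind_rows(day_at_nest(d0), far_day(d0 + 1), day_at_nest(d0 + 2),
                            far_day(d0 + 3), day_at_nest(d0 + 4))
  expect_warning(res <- nest_occupation_date(gappy, nest), "no 3-consecutive")
  expect_true(is.na(res))

  # migrants return (and occupy) later than residents on synthetic tracks
  res_sim <- simulate_track("local", 2018, seed = 9)
  mig_sim <- simulate_track("sub_saharan", 2018, seed = 9)
  after <- as.Date("2018-12-01")
  occ_res <- nest_occupation_date(res_sim$fixes, c(-8, 38.8), search_start = after)
  occ_mig <- nest_occupation_date(mig_sim$fixes, c(-8, 38.8), search_start = after)
  expect_equal(occ_res, res_sim$truth$nest_occupation)
  expect_equal(occ_mig, mig_sim$truth$nest_occupation)
  expect_gt(as.numeric(occ_mig - occ_res), 0)
})
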