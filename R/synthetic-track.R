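# Synthetic annual GPS tracks.
#
# The movement model works at roost scale: one roost position per
# calendar day, drawn per phase (breeding attraction at the nest, travel
# legs of 100-300 km/day, wintering attraction around a strategy-specific
# centroid), with 20-min within-day fixes interpolated between
# consecutive roosts plus jitter. Geography is abstracted to the nest
# point and two latitude lines (Gibraltar, Sahara): only roost-scale
# geometry feeds the downstream classification rules.

km_per_deg_lat <- 111.32

offset_deg <- function(lon, lat, dx_km, dy_km) {
  c(lon + dx_km / (km_per_deg_lat * cos(lat * pi / 180)),
    lat + dy_km / km_per_deg_lat)
}

# Interpolated travel route roosts: n_days legs from `from` to `to`,
# each leg of roughly equal length with multiplicative jitter, plus
# small lateral scatter.
travel_roosts <- function(from, to, n_days, lateral_km = 10) {
  w <- runif(n_days, 0.85, 1.15)
  f <- cumsum(w) / sum(w)
  lon <- from[1] + f * (to[1] - from[1])
  lat <- from[2] + f * (to[2] - from[2])
  lat_mid <- mean(c(from[2], to[2]))
  lon <- lon + rnorm(n_days, 0, lateral_km / (km_per_deg_lat * cos(lat_mid * pi / 180)))
  lat[-n_days] <- lat[-n_days] + rnorm(n_days - 1, 0, lateral_km / km_per_deg_lat)
  cbind(lon, lat)
}

#' Simulate one annual GPS track with ground truth
#'
#' Generates an annual cycle (Aug 4 of `year` to Aug 3 of `year + 1`) of
#' GPS fixes every `cfg$gps_interval_min` minutes for one bird following
#' a given migratory strategy, together with a truth record used by
#' recovery tests. Local birds never leave a 50-km radius of the nest;
#' regional birds range farther across Southwest Europe but never cross
#' the Gibraltar line (travel in at most 2-day hops, so they never
#' qualify as migrating); Northwest-Africa migrants winter between the
#' Gibraltar and Sahara lines; sub-Saharan migrants winter in the Sahel,
#' south of the Sahara line. Migrants travel in daily legs of
#' 100-300 km, always at least 3 consecutive days over 60 km.
#'
#' @param strategy one of `local, regional, nw_africa, sub_saharan`.
#' @param year starting year of the annual cycle.
#' @param cfg a [sim_config()].
#' @param seed RNG seed (defaults to `cfg$seed`).
#' @param individual identifier string.
#' @return list with `fixes` (tibble: individual, timestamp, lon, lat)
#'   and `truth` (list: strategy, nest, autumn/spring windows, wintering
#'   centroid, nest occupation date, daily roosts).
#' @export
simulate_track <- function(strategy, year = 2018, cfg = sim_config(),
                           seed = cfg$seed, individual = "stork_001") {
  if (!is.character(strategy) || length(strategy) != 1 || !strategy %in% STRATEGIES) {
    stop_input("unknown strategy: ", paste(strategy, collapse = ","))
  }
  withr::with_seed(seed, simulate_track_impl(strategy, year, cfg, individual))
}

simulate_track_impl <- function(strategy, year, cfg, individual) {
  nest <- c(cfg$nest_lon, cfg$nest_lat)
  dates <- seq(as.Date(sprintf("%d-08-04", year)),
               as.Date(sprintf("%d-08-03", year + 1)), by = "day")
  n_days <- length(dates)
  rlon <- rep(nest[1], n_days)
  rlat <- rep(nest[2], n_days)
  day_idx <- function(d) as.integer(d - dates[1]) + 1L

  truth <- list(individual = individual, strategy = strategy, nest = nest,
                autumn_window = NULL, spring_window = NULL,
                wintering_centroid = NULL, nest_occupation = NULL)

  nest_jitter <- function(n) {
    cbind(nest[1] + rnorm(n, 0, 0.02 / 111), nest[2] + rnorm(n, 0, 0.02 / 111.32))
  }
  site_jitter <- function(site, n, sd_km) {
    cbind(site[1] + rnorm(n, 0, sd_km / (km_per_deg_lat * cos(site[2] * pi / 180))),
          site[2] + rnorm(n, 0, sd_km / km_per_deg_lat))
  }

  if (strategy_group(strategy) == "resident") {
    # post-breeding dispersal window and winter return to nest attraction
    disperse_start <- dates[1] + round(runif(1, 10, 30))
    nest_return <- as.Date(sprintf("%d-01-%02d", year + 1, round(runif(1, 5, 20))))
    truth$nest_occupation <- nest_return
    if (strategy == "local") {
      # a couple of foraging/roosting sites within 25 km of the nest
      sites <- lapply(1:3, function(i) {
        ang <- runif(1, 0, 2 * pi); d <- runif(1, 5, 25)
        offset_deg(nest[1], nest[2], d * cos(ang), d * sin(ang))
      })
      mid <- dates >= disperse_start & dates < nest_return
      pick <- sample.int(3, sum(mid), replace = TRUE)
      for (k in 1:3) {
        ii <- which(mid)[pick == k]
        if (length(ii)) {
          jj <- site_jitter(sites[[k]], length(ii), 1)
          rlon[ii] <- jj[, 1]; rlat[ii] <- jj[, 2]
        }
      }
    } else {  # regional: a distant non-breeding area, reached in <= 2-day hops
      repeat {
        dx <- runif(1, -150, 400); dy <- runif(1, -150, 300)
        d <- sqrt(dx^2 + dy^2)
        site <- offset_deg(nest[1], nest[2], dx, dy)
        if (d >= 80 && d <= 400 && site[2] > cfg$gibraltar_lat + 1.2) break
      }
      out_days <- if (haversine_km(nest[1], nest[2], site[1], site[2]) > 110) 2L else 1L
      mid <- which(dates >= disperse_start & dates < nest_return)
      away <- mid[seq_len(length(mid) - out_days)]
      if (out_days == 2L) {
        half <- offset_deg(nest[1], nest[2], dx / 2, dy / 2)
        rlon[away[1]] <- half[1]; rlat[away[1]] <- half[2]
        away <- away[-1]
      }
      jj <- site_jitter(site, length(away), 5)
      rlon[away] <- jj[, 1]; rlat[away] <- jj[, 2]
      ret <- mid[(length(mid) - out_days + 1L):length(mid)]
      if (out_days == 2L) {
        half <- offset_deg(nest[1], nest[2], dx / 2, dy / 2)
        rlon[ret[1]] <- half[1]; rlat[ret[1]] <- half[2]
      }
      truth$range_site <- site
    }
    at_nest <- dates < disperse_start | dates >= nest_return
    jj <- nest_jitter(sum(at_nest))
    rlon[at_nest] <- jj[, 1]; rlat[at_nest] <- jj[, 2]
  } else {
    if (strategy == "nw_africa") {
      wcentroid <- c(runif(1, -8, -4), runif(1, 31, 34))
      autumn_dep <- dates[1] + round(runif(1, 11, 37))   # ~Aug 15 - Sep 10
      spring_dep <- as.Date(sprintf("%d-01-%02d", year + 1, round(runif(1, 10, 31))))
    } else {
      wcentroid <- c(runif(1, -8, -1), runif(1, 13, 16))
      autumn_dep <- dates[1] + round(runif(1, 6, 32))    # ~Aug 10 - Sep 5
      spring_dep <- as.Date(sprintf("%d-01-%02d", year + 1, round(runif(1, 5, 25))))
    }
    d_total <- haversine_km(nest[1], nest[2], wcentroid[1], wcentroid[2])
    leg_target <- runif(2, 150, 220)
    n_out <- max(cfg$migration_days, ceiling(d_total / leg_target[1]))
    n_back <- max(cfg$migration_days, ceiling(d_total / leg_target[2]))
    out_route <- travel_roosts(nest, wcentroid, n_out)
    back_route <- travel_roosts(wcentroid, nest, n_back)
    arrive_w <- autumn_dep + n_out - 1
    arrive_nest <- spring_dep + n_back - 1
    stopifnot(arrive_w < spring_dep, arrive_nest <= dates[n_days])

    ii <- day_idx(seq(autumn_dep, by = "day", length.out = n_out))
    rlon[ii] <- out_route[, 1]; rlat[ii] <- out_route[, 2]
    wint <- which(dates > arrive_w & dates < spring_dep)
    jj <- site_jitter(wcentroid, length(wint), 8)
    rlon[wint] <- jj[, 1]; rlat[wint] <- jj[, 2]
    ii <- day_idx(seq(spring_dep, by = "day", length.out = n_back))
    rlon[ii] <- back_route[, 1]; rlat[ii] <- back_route[, 2]
    at_nest <- dates < autumn_dep | dates > arrive_nest
    jj <- nest_jitter(sum(at_nest))
    rlon[at_nest] <- jj[, 1]; rlat[at_nest] <- jj[, 2]
    # the final return leg ends at the nest itself
    ii <- day_idx(arrive_nest)
    jj <- nest_jitter(1)
    rlon[ii] <- jj[1]; rlat[ii] <- jj[2]

    truth$autumn_window <- c(autumn_dep, arrive_w)
    truth$spring_window <- c(spring_dep, arrive_nest)
    truth$wintering_centroid <- wcentroid
    truth$nest_occupation <- arrive_nest
  }

  # ---- expand daily roosts into a 20-min fix series -------------------
  # Schedule in nest-local solar time: at the previous night's roost
  # until 08:00, en route 08:00-20:00, at the new roost from 20:00.
  step_s <- cfg$gps_interval_min * 60
  t0 <- as.POSIXct(sprintf("%d-08-04 00:00:00", year), tz = "UTC") - nest[1] * 240
  ts <- seq(t0, by = step_s, length.out = n_days * (86400 %/% step_s))
  loc_num <- as.numeric(ts) + nest[1] * 240       # seconds since epoch, nest-local
  day_num <- floor(loc_num / 86400)
  hl <- (loc_num - day_num * 86400) / 3600
  day1 <- as.numeric(as.POSIXct(paste(dates[1], "00:00:00"), tz = "UTC")) / 86400
  di <- pmin(pmax(as.integer(day_num - day1) + 1L, 1L), n_days)
  prev <- pmax(di - 1L, 1L)
  f <- pmin(pmax((hl - 8) / 12, 0), 1)
  lon <- rlon[prev] + f * (rlon[di] - rlon[prev])
  lat <- rlat[prev] + f * (rlat[di] - rlat[prev])
  night <- hl < 8 | hl >= 20
  n_fix <- length(ts)
  gps_sd_deg <- ifelse(night, 1e-4, 9e-3)
  lon <- lon + rnorm(n_fix, 0, gps_sd_deg)
  lat <- lat + rnorm(n_fix, 0, gps_sd_deg)

  truth$roosts <- tibble::tibble(date = dates, lon = rlon, lat = rlat)
  fixes <- tibble::tibble(individual = individual, timestamp = ts,
                          lon = lon, lat = lat)
  list(fixes = fixes, truth = truth)
}

#' Simulate a population of annual tracks
#'
#' Draws a strategy per bird from `cfg$strategy_mix` (or uses the given
#' vector) and simulates each track with an independent seed derived
#' from `seed`.
#'
#' @param cfg a [sim_config()].
#' @param year cycle start year.
#' @param seed master seed.
#' @param strategies optional explicit vector of strategies (overrides
#'   the mix; its length sets the population size).
#' @return list with `fixes` (one bound tibble) and `truth` (list per
#'   bird, named by individual).
#' @export
simulate_population <- function(cfg = sim_config(), year = 2018, seed = cfg$seed,
                                strategies = NULL) {
  if (is.null(strategies)) {
    strategies <- withr::with_seed(seed,
      sample(STRATEGIES, cfg$n_individuals, replace = TRUE, prob = cfg$strategy_mix))
  }
  n <- length(strategies)
  ids <- sprintf("stork_%03d", seq_len(n))
  sims <- lapply(seq_len(n), function(i) {
    simulate_track(strategies[i], year = year, cfg = cfg,
                   seed = seed + 1000L + i, individual = ids[i])
  })
  list(fixes = dplyr::bind_rows(lapply(sims, `[[`, "fixes")),
       truth = setNames(lapply(sims, `[[`, "truth"), ids))
}
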