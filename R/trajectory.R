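#' Great-circle distance (haversine)
#'
#' Haversine distance on a sphere of radius 6371.0088 km (IUGG mean
#' Earth radius). Vectorised over coordinates.
#'
#' @param lon1,lat1,lon2,lat2 coordinates in decimal degrees (WGS84).
#' @return distance in kilometres.
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  ok <- function(lon, lat) {
    all(is.finite(lon)) && all(is.finite(lat)) &&
      all(abs(lon) <= 180) && all(abs(lat) <= 90)
  }
  if (!ok(lon1, lat1) || !ok(lon2, lat2)) {
    stop_input("coordinates must be finite, |lon| <= 180, |lat| <= 90")
  }
  r <- 6371.0088
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad / 2
  dlon <- (lon2 - lon1) * to_rad / 2
  a <- sin(dlat)^2 + cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

#' Clean a GPS track
#'
#' Drops duplicated timestamps (first fix kept) and fixes implying a
#' sustained speed above `speed_cap_kmh` relative to the previous
#' retained fix. Deterministic: a single forward pass per individual.
#'
#' @param fixes tibble with columns `individual`, `timestamp` (POSIXct,
#'   UTC), `lon`, `lat`.
#' @param speed_cap_kmh maximum plausible sustained speed.
#' @return the cleaned tibble, sorted by individual and timestamp.
#' @export
clean_track <- function(fixes, speed_cap_kmh = 120) {
  fixes <- dplyr::arrange(fixes, .data$individual, .data$timestamp)
  clean_one <- function(df) {
    dup <- duplicated(df$timestamp)
    df <- df[!dup, , drop = FALSE]
    n <- nrow(df)
    if (n < 2) return(df)
    keep <- logical(n)
    keep[1] <- TRUE
    last <- 1L
    for (i in 2:n) {
      dt_h <- as.numeric(difftime(df$timestamp[i], df$timestamp[last], units = "hours"))
      d_km <- haversine_km(df$lon[last], df$lat[last], df$lon[i], df$lat[i])
      if (dt_h > 0 && d_km / dt_h <= speed_cap_kmh) {
        keep[i] <- TRUE
        last <- i
      }
    }
    df[keep, , drop = FALSE]
  }
  out <- dplyr::group_modify(dplyr::group_by(fixes, .data$individual),
                             ~ clean_one(.x))
  out <- dplyr::ungroup(out)
  if (nrow(out) == 0) warning("clean_track: no fixes retained")
  dplyr::relocate(out, "individual")
}

#' Total displacement along a track
#'
#' Sum of great-circle distances between consecutive fixes, the "sum of
#' all distances moved" over a period. Always at least the straight-line
#' distance between the first and last fix.
#'
#' @param fixes tibble for a single individual (columns `timestamp`,
#'   `lon`, `lat`), assumed cleaned and time-sorted.
#' @param start,end optional interval (Date or POSIXct) restricting the
#'   fixes used, both ends inclusive.
#' @return displacement in km (0, with a warning, for fewer than 2 fixes).
#' @export
total_displacement <- function(fixes, start = NULL, end = NULL) {
  if (!is.null(start)) fixes <- fixes[as.Date(fixes$timestamp, tz = "UTC") >= as.Date(start), ]
  if (!is.null(end)) fixes <- fixes[as.Date(fixes$timestamp, tz = "UTC") <= as.Date(end), ]
  n <- nrow(fixes)
  if (n < 2) {
    warning("total_displacement: fewer than 2 fixes in interval")
    return(0)
  }
  fixes <- fixes[order(fixes$timestamp), ]
  sum(haversine_km(fixes$lon[-n], fixes$lat[-n], fixes$lon[-1], fixes$lat[-1]))
}

#' Nightly roost positions
#'
#' One roost per individual and calendar date: the median position of
#' fixes in the nocturnal window (22:00-04:00 local solar time, computed
#' from longitude alone). Fixes after midnight are assigned to the
#' previous evening's date. Dates with no nocturnal fix are skipped.
#'
#' @param fixes cleaned fixes tibble.
#' @return tibble with columns `individual`, `date`, `lon`, `lat`.
#' @export
daily_roosts <- function(fixes) {
  hr <- solar_hour(fixes$timestamp, fixes$lon)
  nocturnal <- hr >= 22 | hr < 4
  df <- fixes[nocturnal, , drop = FALSE]
  if (nrow(df) == 0) {
    return(tibble::tibble(individual = character(), date = as.Date(character()),
                          lon = double(), lat = double()))
  }
  hr <- hr[nocturnal]
  date <- solar_date(df$timestamp, df$lon)
  date[hr < 4] <- date[hr < 4] - 1
  df$date <- date
  out <- dplyr::summarise(dplyr::group_by(df, .data$individual, .data$date),
                          lon = median(.data$lon), lat = median(.data$lat),
                          .groups = "drop")
  dplyr::arrange(out, .data$individual, .data$date)
}

# Maximal runs of consecutive migration days (> threshold km between
# consecutive-calendar-date roosts). Returns a data.frame of runs with
# start/end dates, length, and net latitude change.
migration_runs <- function(roosts, threshold_km = 60) {
  n <- nrow(roosts)
  if (n < 2) return(NULL)
  d_km <- haversine_km(roosts$lon[-n], roosts$lat[-n], roosts$lon[-1], roosts$lat[-1])
  gap <- as.integer(diff(roosts$date))
  move <- d_km > threshold_km & gap == 1L  # move[i]: day roosts$date[i+1] was a migration day
  if (!any(move)) return(NULL)
  idx <- which(move)
  # group move-days whose dates are consecutive
  brk <- cumsum(c(1L, as.integer(diff(roosts$date[idx + 1L]) != 1L)))
  runs <- lapply(split(idx, brk), function(ii) {
    list(start = roosts$date[ii[1] + 1L],
         end = roosts$date[ii[length(ii)] + 1L],
         length = length(ii),
         dlat = roosts$lat[ii[length(ii)] + 1L] - roosts$lat[ii[1]])
  })
  do.call(rbind, lapply(runs, function(r) {
    data.frame(start = r$start, end = r$end, length = r$length, dlat = r$dlat)
  }))
}

#' Detect autumn and spring migration windows
#'
#' A migration day moves the roost by more than `threshold_km` relative
#' to the previous calendar date's roost; a qualifying run is at least
#' `min_run_days` consecutive such days (a missing roost date breaks a
#' run). The autumn window spans the first to the last qualifying
#' southbound run (net latitude decrease, leading out of the breeding
#' range); the spring window spans the qualifying northbound runs that
#' follow (leaving the wintering range). Residents yield no windows.
#'
#' @param roosts roost tibble for one individual, from [daily_roosts()].
#' @param threshold_km daily displacement threshold (default 60 km).
#' @param min_run_days run length needed to qualify (default 3).
#' @return list with elements `autumn` and `spring`, each either `NULL`
#'   or a length-2 Date vector `c(start, end)`.
#' @export
detect_migration_windows <- function(roosts, threshold_km = 60, min_run_days = 3) {
  roosts <- roosts[order(roosts$date), ]
  runs <- migration_runs(roosts, threshold_km)
  empty <- list(autumn = NULL, spring = NULL)
  if (is.null(runs)) return(empty)
  runs <- runs[runs$length >= min_run_days, , drop = FALSE]
  if (nrow(runs) == 0) return(empty)
  south <- runs[runs$dlat < 0, , drop = FALSE]
  autumn <- NULL
  if (nrow(south) > 0) {
    autumn <- c(south$start[1], south$end[nrow(south)])
    # only southbound runs before the first northbound run belong to autumn
    north_after <- runs[runs$dlat > 0 & runs$start > south$start[1], , drop = FALSE]
    if (nrow(north_after) > 0) {
      pre <- south[south$end < north_after$start[1], , drop = FALSE]
      if (nrow(pre) > 0) autumn <- c(pre$start[1], pre$end[nrow(pre)])
    }
  }
  spring <- NULL
  north <- runs[runs$dlat > 0, , drop = FALSE]
  if (!is.null(autumn)) north <- north[north$start > autumn[2], , drop = FALSE]
  if (nrow(north) > 0) spring <- c(north$start[1], north$end[nrow(north)])
  list(autumn = autumn, spring = spring)
}

#' Classify an annual track into a migratory strategy
#'
#' Residents stay north of the Gibraltar line all year; a bird is a
#' migrant as soon as any roost lies south of it. Residents are `local`
#' if every roost stays within `local_km` of the nest, else `regional`.
#' Migrants are `sub_saharan` if the centroid of their wintering-period
#' roosts lies south of the Sahara line, else `nw_africa`. The wintering
#' period is taken between the detected migration windows, falling back
#' to all roosts south of the Gibraltar line when windows are missing.
#'
#' @param fixes cleaned annual fixes for one individual.
#' @param nest length-2 numeric `c(lon, lat)` of the nest.
#' @param gibraltar_lat,sahara_lat geography lines (degrees N).
#' @param local_km local-residency radius (km).
#' @param threshold_km,min_run_days migration-window rule, see
#'   [detect_migration_windows()].
#' @return list of class `strategy_classification` with elements
#'   `strategy`, `group` (resident/migrant), `windows`, `roosts`.
#' @export
classify_strategy <- function(fixes, nest, gibraltar_lat = 35.9,
                              sahara_lat = 20.0, local_km = 50,
                              threshold_km = 60, min_run_days = 3) {
  if (is.null(nest) || length(nest) != 2 || any(!is.finite(nest))) {
    stop_input("nest must be a finite c(lon, lat)")
  }
  roosts <- daily_roosts(fixes)
  if (nrow(roosts) == 0) stop_input("no roosts could be derived from fixes")
  windows <- detect_migration_windows(roosts, threshold_km, min_run_days)
  migrant <- any(roosts$lat < gibraltar_lat)
  if (migrant) {
    wint <- roosts
    if (!is.null(windows$autumn) && !is.null(windows$spring)) {
      wint <- roosts[roosts$date > windows$autumn[2] & roosts$date < windows$spring[1], ]
    }
    if (nrow(wint) == 0 || all(wint$lat >= gibraltar_lat)) {
      wint <- roosts[roosts$lat < gibraltar_lat, ]
    }
    strategy <- if (mean(wint$lat) < sahara_lat) "sub_saharan" else "nw_africa"
  } else {
    dist_nest <- haversine_km(nest[1], nest[2], roosts$lon, roosts$lat)
    strategy <- if (all(dist_nest < local_km)) "local" else "regional"
  }
  structure(list(strategy = strategy,
                 group = strategy_group(strategy),
                 windows = windows,
                 roosts = roosts),
            class = "strategy_classification")
}

#' @export
print.strategy_classification <- function(x, ...) {
  cat(sprintf("<strategy: %s (%s)>\n", x$strategy, x$group))
  for (s in c("autumn", "spring")) {
    w <- x$windows[[s]]
    if (!is.null(w)) cat(sprintf("  %s migration: %s to %s\n", s, w[1], w[2]))
  }
  invisible(x)
}

#' Partition an annual cycle into four seasons
#'
#' Residents use the population's fixed dates (autumn Aug 4 - Sep 5,
#' wintering Sep 6 - Dec 12, spring Dec 13 - Jan 22, breeding Jan 23 -
#' Aug 3), anchored on `year`. Migrants use their detected migration
#' windows: autumn and spring are the windows themselves, wintering lies
#' between them, and breeding is the remainder of a 365-day cycle
#' anchored at the autumn departure. Both ends of every interval are
#' inclusive; the four intervals are contiguous and tile the cycle.
#'
#' @param strategy one of the four strategy labels.
#' @param windows migration windows from [detect_migration_windows()]
#'   (required for migrants, ignored for residents).
#' @param year the year in which the cycle starts (its autumn year).
#' @return tibble with columns `season`, `start`, `end`.
#' @export
partition_seasons <- function(strategy, windows = NULL, year) {
  if (!strategy %in% STRATEGIES) stop_input("unknown strategy: ", strategy)
  if (strategy_group(strategy) == "resident") {
    y <- as.integer(year)
    out <- tibble::tibble(
      season = SEASONS,
      start = as.Date(c(sprintf("%d-08-04", y), sprintf("%d-09-06", y),
                        sprintf("%d-12-13", y), sprintf("%d-01-23", y + 1L))),
      end = as.Date(c(sprintf("%d-09-05", y), sprintf("%d-12-12", y),
                      sprintf("%d-01-22", y + 1L), sprintf("%d-08-03", y + 1L)))
    )
  } else {
    if (is.null(windows) || is.null(windows$autumn) || is.null(windows$spring)) {
      stop_input("migrant season partition requires detected autumn and spring windows")
    }
    a <- windows$autumn; s <- windows$spring
    if (a[2] >= s[1]) {
      stop(errorCondition("autumn and spring windows overlap",
                          class = c("ciconia_consistency_error", "error")))
    }
    out <- tibble::tibble(
      season = SEASONS,
      start = c(a[1], a[2] + 1, s[1], s[2] + 1),
      end = c(a[2], s[1] - 1, s[2], a[1] + 364)
    )
  }
  stopifnot(all(out$start <= out$end),
            all(out$start[-1] == out$end[-4] + 1))
  out
}

#' Nest occupation date
#'
#' The first day of the first run of three consecutive calendar days
#' (local solar dates) each having at least one fix within `radius_m` of
#' the nest. Because the annual cycle opens at the nest in August, the
#' search starts by default at Dec 1 of the cycle so that the date
#' reflects the post-winter return to the nest.
#'
#' @param fixes cleaned fixes for one individual.
#' @param nest `c(lon, lat)`.
#' @param radius_m attendance radius in metres (default 75).
#' @param search_start earliest Date considered; `NULL` searches the
#'   whole track.
#' @return a Date, or `NA` (with a warning) if no qualifying run exists.
#' @export
nest_occupation_date <- function(fixes, nest, radius_m = 75, search_start = NULL) {
  if (is.null(nest) || length(nest) != 2 || any(!is.finite(nest))) {
    stop_input("nest must be a finite c(lon, lat)")
  }
  d_m <- haversine_km(nest[1], nest[2], fixes$lon, fixes$lat) * 1000
  dates <- solar_date(fixes$timestamp, fixes$lon)
  hit_dates <- sort(unique(dates[d_m <= radius_m]))
  if (!is.null(search_start)) hit_dates <- hit_dates[hit_dates >= as.Date(search_start)]
  if (length(hit_dates) >= 3) {
    gaps <- c(1L, as.integer(diff(hit_dates)))
    run_id <- cumsum(gaps != 1L)
    for (g in unique(run_id)) {
      run <- hit_dates[run_id == g]
      if (length(run) >= 3) return(run[1])
    }
  }
  warning("no 3-consecutive-day nest attendance run found")
  as.Date(NA)
}
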