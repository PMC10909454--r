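# Synthetic tri-axial acceleration bursts.
#
# Generative model: a static gravity vector (unit norm, near-vertical
# with random small tilt) plus a behaviour-specific dynamic process:
#   resting  - near-zero white noise
#   foraging - irregular mid-amplitude white noise
#   flapping - periodic heave (sinusoid at cfg$flap_hz) + noise, the
#              largest dynamic amplitude
#   soaring  - slow smooth drift of the gravity orientation (banking in
#              a thermal), static-dominated
# This is the minimal process the burst feature set can separate.

#' Construct an acceleration burst
#'
#' @param x,y,z equal-length numeric sample vectors (surge, sway, heave)
#'   in g.
#' @param rate_hz sampling rate in Hz (> 0).
#' @param individual,timestamp optional metadata.
#' @param tag_type optional tag family label, carried through outputs.
#' @return object of class `accel_burst`.
#' @export
accel_burst <- function(x, y, z, rate_hz, individual = NA_character_,
                        timestamp = as.POSIXct(NA, tz = "UTC"),
                        tag_type = NA_character_) {
  n <- length(x)
  if (n < 1 || length(y) != n || length(z) != n) {
    stop_input("axes must be equal-length vectors of length >= 1")
  }
  if (!is.finite(rate_hz) || rate_hz <= 0) stop_input("rate_hz must be > 0")
  if (any(!is.finite(c(x, y, z)))) stop_input("acceleration samples must be finite")
  structure(list(x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
                 rate_hz = rate_hz, individual = individual,
                 timestamp = timestamp, tag_type = tag_type),
            class = "accel_burst")
}

#' @export
print.accel_burst <- function(x, ...) {
  cat(sprintf("<accel_burst: %d samples @ %g Hz (%.1f s)>\n",
              length(x$x), x$rate_hz, length(x$x) / x$rate_hz))
  invisible(x)
}

#' Simulate one behaviour-specific acceleration burst
#'
#' @param behavior one of `foraging, resting, soaring, flapping`.
#' @param cfg a [sim_config()]; uses `burst_rate_hz`, `burst_duration_s`,
#'   `noise_g`, `flap_amp_g`, `flap_hz`.
#' @param seed RNG seed (defaults to `cfg$seed`).
#' @param individual,timestamp metadata passed to the burst.
#' @return an [accel_burst()].
#' @export
simulate_burst <- function(behavior, cfg = sim_config(), seed = cfg$seed,
                           individual = NA_character_,
                           timestamp = as.POSIXct(NA, tz = "UTC")) {
  if (!is.character(behavior) || length(behavior) != 1 || !behavior %in% BEHAVIORS) {
    stop_input("unknown behavior: ", paste(behavior, collapse = ","))
  }
  withr::with_seed(seed, simulate_burst_impl(behavior, cfg, individual, timestamp))
}

simulate_burst_impl <- function(behavior, cfg, individual, timestamp) {
  n <- max(2L, round(cfg$burst_rate_hz * cfg$burst_duration_s))
  t <- (seq_len(n) - 1) / cfg$burst_rate_hz
  # static gravity: unit vector with a small random tilt from vertical
  tilt <- runif(1, 0, 0.35)
  az <- runif(1, 0, 2 * pi)
  g0 <- c(sin(tilt) * cos(az), sin(tilt) * sin(az), cos(tilt))
  sdn <- cfg$noise_g[[behavior]]
  dyn <- switch(behavior,
    resting = ,
    foraging = cbind(rnorm(n, 0, sdn), rnorm(n, 0, sdn), rnorm(n, 0, sdn)),
    flapping = {
      ph <- runif(1, 0, 2 * pi)
      heave <- cfg$flap_amp_g * sin(2 * pi * cfg$flap_hz * t + ph)
      surge <- 0.35 * cfg$flap_amp_g * sin(2 * pi * cfg$flap_hz * t + ph + pi / 2)
      cbind(surge + rnorm(n, 0, sdn), rnorm(n, 0, sdn), heave + rnorm(n, 0, sdn))
    },
    soaring = {
      # slow banking: gravity orientation drifts over a period several
      # times the burst length; smooth, little high-frequency power
      per <- runif(1, 3, 6) * (n / cfg$burst_rate_hz)
      ph <- runif(1, 0, 2 * pi)
      amp <- runif(1, 0.1, 0.25)
      drift <- amp * sin(2 * pi * t / per + ph)
      cbind(drift * cos(az) + rnorm(n, 0, sdn),
            drift * sin(az) + rnorm(n, 0, sdn),
            -drift * sin(tilt) + rnorm(n, 0, sdn))
    })
  accel_burst(g0[1] + dyn[, 1], g0[2] + dyn[, 2], g0[3] + dyn[, 3],
              rate_hz = cfg$burst_rate_hz, individual = individual,
              timestamp = timestamp)
}

#' Simulate a labelled burst corpus
#'
#' Balanced set of bursts for classifier training/evaluation.
#'
#' @param n_per_class bursts per behaviour.
#' @param cfg a [sim_config()].
#' @param seed master seed.
#' @return list with `bursts` (list of `accel_burst`) and `labels`
#'   (character vector).
#' @export
simulate_burst_corpus <- function(n_per_class = 250, cfg = sim_config(),
                                  seed = cfg$seed) {
  labels <- rep(BEHAVIORS, each = n_per_class)
  bursts <- withr::with_seed(seed, lapply(labels, function(b) {
    simulate_burst_impl(b, cfg, NA_character_, as.POSIXct(NA, tz = "UTC"))
  }))
  list(bursts = bursts, labels = labels)
}

#' Simulate a behaviour schedule for an annual track
#'
#' Assigns a true behaviour to burst times over the annual cycle:
#' nocturnal bursts are resting; on migration days the daytime mix is
#' soaring-heavy with some flapping; otherwise a foraging/resting mix
#' with occasional soaring and flapping. Used to feed the ODBA/budget
#' stages with structured truth.
#'
#' @param truth a truth record from [simulate_track()].
#' @param cfg a [sim_config()].
#' @param seed RNG seed.
#' @param step_min minutes between bursts (default 120 keeps annual
#'   series compact; field schedule is 20).
#' @return tibble: `individual`, `timestamp`, `behavior`.
#' @export
simulate_behavior_schedule <- function(truth, cfg = sim_config(), seed = cfg$seed,
                                       step_min = 120) {
  dates <- truth$roosts$date
  t0 <- as.POSIXct(paste(dates[1], "00:00:00"), tz = "UTC") - cfg$nest_lon * 240
  ts <- seq(t0, by = step_min * 60,
            length.out = length(dates) * ((24 * 60) %/% step_min))
  loc_num <- as.numeric(ts) + cfg$nest_lon * 240
  hl <- (loc_num %% 86400) / 3600
  day <- as.Date(as.POSIXct(loc_num, origin = "1970-01-01", tz = "UTC"), tz = "UTC")
  mig_days <- as.Date(character())
  for (w in list(truth$autumn_window, truth$spring_window)) {
    if (!is.null(w)) mig_days <- c(mig_days, seq(w[1], w[2], by = "day"))
  }
  withr::with_seed(seed, {
    night <- hl < 6 | hl >= 21
    on_mig <- day %in% mig_days & !night
    n <- length(ts)
    beh <- character(n)
    beh[night] <- "resting"
    beh[on_mig] <- sample(BEHAVIORS, sum(on_mig), replace = TRUE,
                          prob = c(0.1, 0.05, 0.6, 0.25))
    rest <- !night & !on_mig
    beh[rest] <- sample(BEHAVIORS, sum(rest), replace = TRUE,
                        prob = c(0.45, 0.3, 0.15, 0.1))
    tibble::tibble(individual = truth$individual, timestamp = ts, behavior = beh)
  })
}

#' Simulate bursts along a schedule and compute per-burst ODBA
#'
#' @param schedule tibble from [simulate_behavior_schedule()].
#' @param cfg a [sim_config()].
#' @param seed master seed.
#' @return tibble: `individual`, `timestamp`, `behavior`, `odba`.
#' @export
simulate_odba_series <- function(schedule, cfg = sim_config(), seed = cfg$seed) {
  odba <- withr::with_seed(seed, vapply(schedule$behavior, function(b) {
    compute_odba(simulate_burst_impl(b, cfg, NA_character_,
                                     as.POSIXct(NA, tz = "UTC")))
  }, numeric(1), USE.NAMES = FALSE))
  tibble::tibble(individual = schedule$individual,
                 timestamp = schedule$timestamp,
                 behavior = schedule$behavior,
                 odba = odba)
}
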