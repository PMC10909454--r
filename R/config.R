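#' Simulation and pipeline configuration
#'
#' Bundles the study-design constants used throughout the pipeline: GPS
#' duty cycle, burst geometry, behaviour-specific acceleration noise,
#' population phenotype distribution, and the simplified geography (a
#' nest point plus two latitude lines standing in for the Strait of
#' Gibraltar and the southern edge of the Sahara).
#'
#' Defaults reflect the tracked population the pipeline was designed
#' around: loggers recording a GPS position every 20 min and a 9-s
#' tri-axial burst at 1 Hz; a colony in southern Portugal; a strategy mix
#' of 9 local, 42 regional, 6 Northwest-Africa and 10 sub-Saharan birds
#' out of 67 with a fixed annual strategy; adult wing length around
#' 580 mm (SD 20 mm) with larger birds less likely to migrate.
#'
#' @param n_individuals number of birds to simulate.
#' @param strategy_mix named probabilities over the four strategies;
#'   must sum to 1.
#' @param gps_interval_min minutes between GPS fixes (> 0).
#' @param burst_rate_hz accelerometer sampling rate within a burst (Hz).
#' @param burst_duration_s burst length in seconds.
#' @param noise_g named per-behaviour dynamic noise scale, in g.
#' @param flap_amp_g heave amplitude of flapping, in g.
#' @param flap_hz wing-beat frequency of the flapping generator, in Hz;
#'   must lie below the Nyquist limit `burst_rate_hz / 2`.
#' @param wing_mean_mm,wing_sd_mm wing-length distribution (mm).
#' @param wing_logit_slope change in log-odds of migrating per mm of
#'   wing length; negative means larger birds migrate less.
#' @param migrant_logit_intercept log-odds of migrating at the mean wing
#'   length.
#' @param nest_lon,nest_lat colony/nest coordinates (decimal degrees).
#' @param gibraltar_lat latitude line whose crossing defines a migrant.
#' @param sahara_lat latitude line separating Northwest-Africa from
#'   sub-Saharan (Sahel) wintering grounds.
#' @param local_km radius around the nest within which a resident is
#'   "local" (km).
#' @param migration_km daily roost-to-roost displacement threshold for a
#'   migration day (km).
#' @param migration_days consecutive migration days required to open or
#'   close a migration window.
#' @param nest_radius_m nest-attendance radius for occupation (m).
#' @param speed_cap_kmh sustained-speed cap used by track cleaning.
#' @param seed default RNG seed used when an operation is not given one.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 40,
                       strategy_mix = c(local = 9, regional = 42,
                                        nw_africa = 6, sub_saharan = 10) / 67,
                       gps_interval_min = 20,
                       burst_rate_hz = 1,
                       burst_duration_s = 9,
                       noise_g = c(foraging = 0.25, resting = 0.01,
                                   soaring = 0.05, flapping = 0.15),
                       flap_amp_g = 0.8,
                       flap_hz = 0.3,
                       wing_mean_mm = 580,
                       wing_sd_mm = 20,
                       wing_logit_slope = -0.05,
                       migrant_logit_intercept = qlogis(16 / 75),
                       nest_lon = -8.0,
                       nest_lat = 38.8,
                       gibraltar_lat = 35.9,
                       sahara_lat = 20.0,
                       local_km = 50,
                       migration_km = 60,
                       migration_days = 3,
                       nest_radius_m = 75,
                       speed_cap_kmh = 120,
                       seed = 1L) {
  if (length(strategy_mix) != 4L || !setequal(names(strategy_mix), STRATEGIES)) {
    stop_input("strategy_mix must be named over ", paste(STRATEGIES, collapse = ", "))
  }
  strategy_mix <- strategy_mix[STRATEGIES]
  assert_prob(strategy_mix, "strategy_mix")
  if (abs(sum(strategy_mix) - 1) > 1e-12) stop_input("strategy_mix must sum to 1")
  if (!is.finite(gps_interval_min) || gps_interval_min <= 0) {
    stop_input("gps_interval_min must be > 0")
  }
  if (burst_rate_hz <= 0 || burst_duration_s <= 0) {
    stop_input("burst rate and duration must be positive")
  }
  if (!setequal(names(noise_g), BEHAVIORS)) {
    stop_input("noise_g must be named over the four behaviours")
  }
  if (flap_hz <= 0 || flap_hz >= burst_rate_hz / 2) {
    stop_input("flap_hz must lie in (0, burst_rate_hz / 2)")
  }
  if (wing_logit_slope > 0) {
    stop_input("wing_logit_slope must be <= 0 (larger birds migrate less)")
  }
  for (nm in c("local_km", "migration_km", "migration_days", "nest_radius_m",
               "speed_cap_kmh")) {
    if (get(nm) <= 0) stop_input(nm, " must be positive")
  }
  structure(list(
    n_individuals = as.integer(n_individuals),
    strategy_mix = strategy_mix,
    gps_interval_min = gps_interval_min,
    burst_rate_hz = burst_rate_hz,
    burst_duration_s = burst_duration_s,
    noise_g = noise_g[BEHAVIORS],
    flap_amp_g = flap_amp_g,
    flap_hz = flap_hz,
    wing_mean_mm = wing_mean_mm,
    wing_sd_mm = wing_sd_mm,
    wing_logit_slope = wing_logit_slope,
    migrant_logit_intercept = migrant_logit_intercept,
    nest_lon = nest_lon,
    nest_lat = nest_lat,
    gibraltar_lat = gibraltar_lat,
    sahara_lat = sahara_lat,
    local_km = local_km,
    migration_km = migration_km,
    migration_days = migration_days,
    nest_radius_m = nest_radius_m,
    speed_cap_kmh = speed_cap_kmh,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d individuals; GPS every %g min; bursts %g s @ %g Hz\n",
              x$n_individuals, x$gps_interval_min, x$burst_duration_s,
              x$burst_rate_hz))
  cat(sprintf("  strategy mix: %s\n",
              paste(sprintf("%s=%.3f", names(x$strategy_mix), x$strategy_mix),
                    collapse = ", ")))
  cat(sprintf("  nest (%.3f, %.3f); Gibraltar %.1fN; Sahara %.1fN\n",
              x$nest_lon, x$nest_lat, x$gibraltar_lat, x$sahara_lat))
  invisible(x)
}

#' Read or write a configuration as a YAML file
#'
#' Round-trips losslessly through [sim_config()]: unknown keys are
#' rejected, missing keys fall back to defaults.
#'
#' @param path file path.
#' @param cfg a `sim_config`.
#' @return `read_config` returns a `sim_config`; `write_config` the path,
#'   invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop_input("unknown config keys: ", paste(bad, collapse = ", "))
  for (nm in c("strategy_mix", "noise_g")) {
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  }
  do.call(sim_config, raw)
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "sim_config"))
  out <- unclass(cfg)
  out$strategy_mix <- as.list(out$strategy_mix)
  out$noise_g <- as.list(out$noise_g)
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}
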