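#' Season-level summary table
#'
#' The model-ready table feeding downstream mixed models: one row per
#' individual x season with displacement (sum of consecutive-fix
#' distances within the season; boundary links between seasons are not
#' counted), number of fixes, season duration, overall and per-behaviour
#' mean ODBA, behavioural proportions (per-day averaged), and the
#' strategy label.
#'
#' @param fixes cleaned fixes tibble (may hold several individuals).
#' @param odba_series tibble with `individual`, `timestamp`, `behavior`,
#'   `odba` per burst (e.g. from [simulate_odba_series()] or from
#'   [compute_odba()] + [classify_burst()] on field bursts).
#' @param partitions tibble with `individual`, `season`, `start`, `end`
#'   (one partition per individual, see [partition_seasons()]).
#' @param strategies tibble with `individual`, `strategy`.
#' @return tibble, one row per individual x season present in the data.
#' @export
seasonal_summary <- function(fixes, odba_series, partitions, strategies) {
  rows <- list()
  for (ind in unique(partitions$individual)) {
    part <- partitions[partitions$individual == ind, ]
    fx <- fixes[fixes$individual == ind, ]
    ob <- odba_series[odba_series$individual == ind, ]
    strat <- strategies$strategy[strategies$individual == ind][1]
    for (k in seq_len(nrow(part))) {
      s0 <- part$start[k]; s1 <- part$end[k]
      fx_day <- as.Date(fx$timestamp, tz = "UTC")
      fx_s <- fx[fx_day >= s0 & fx_day <= s1, ]
      ob_day <- as.Date(ob$timestamp, tz = "UTC")
      ob_s <- ob[ob_day >= s0 & ob_day <= s1, ]
      if (nrow(fx_s) == 0 && nrow(ob_s) == 0) {
        warning(sprintf("seasonal_summary: no data for %s / %s; row omitted",
                        ind, part$season[k]))
        next
      }
      disp <- if (nrow(fx_s) >= 2) total_displacement(fx_s) else 0
      budget <- suppressWarnings(behavioral_budget(ob_s))
      odba_by <- vapply(BEHAVIORS, function(b) {
        v <- ob_s$odba[ob_s$behavior == b]
        if (length(v)) mean(v) else NA_real_
      }, numeric(1))
      row <- tibble::tibble(
        individual = ind, season = part$season[k],
        start = s0, end = s1,
        duration_days = as.integer(s1 - s0) + 1L,
        n_fixes = nrow(fx_s), n_bursts = nrow(ob_s),
        displacement_km = disp,
        mean_odba = if (nrow(ob_s)) mean(ob_s$odba) else NA_real_,
        strategy = strat
      )
      for (b in BEHAVIORS) {
        row[[paste0("odba_", b)]] <- odba_by[[b]]
        row[[paste0("prop_", b)]] <- budget$proportion[budget$behavior == b]
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  dplyr::bind_rows(rows)
}
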