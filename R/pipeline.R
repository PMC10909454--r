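#' Run the full synthetic pipeline end to end
#'
#' simulate -> odba -> classify -> segment -> summarize -> survival, all
#' driven by one configuration and one seed. Writes the Movebank-dialect
#' fix CSV, per-burst ODBA/behaviour CSV, strategy and phenology CSV,
#' season summary CSV, encounter histories, and the survival estimate
#' and model-comparison tables into `out_dir`.
#'
#' Intended as the integration surface (and integration test) of the
#' package; each stage is equally usable on its own.
#'
#' @param cfg a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @param seed master seed; every stochastic stage derives from it.
#' @param year cycle start year.
#' @param n_corpus labelled bursts per class for classifier training.
#' @param c_hat overdispersion coefficient for QAICc.
#' @return invisibly, a list with the in-memory products (`strategies`,
#'   `summary`, `fit`, `comparison`, `classifier`) and `files`.
#' @export
run_pipeline <- function(cfg = sim_config(n_individuals = 8), out_dir = tempdir(),
                         seed = cfg$seed, year = 2018, n_corpus = 150,
                         c_hat = 2.52) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)

  # simulate
  pop <- simulate_population(cfg, year = year, seed = seed)
  write_fixes(pop$fixes, p("fixes.csv"))

  # odba + classify: train on a labelled corpus, apply to scheduled bursts
  corpus <- simulate_burst_corpus(n_corpus, cfg, seed = seed + 1L)
  clf <- train_classifier(corpus$bursts, corpus$labels, seed = seed + 2L)
  odba_series <- dplyr::bind_rows(lapply(seq_along(pop$truth), function(i) {
    truth <- pop$truth[[i]]
    sched <- simulate_behavior_schedule(truth, cfg, seed = seed + 100L + i,
                                        step_min = 180)
    simulate_odba_series(sched, cfg, seed = seed + 500L + i)
  }))
  write_table(odba_series, p("odba.csv"))

  # segment
  nest <- c(cfg$nest_lon, cfg$nest_lat)
  fixes <- clean_track(pop$fixes, cfg$speed_cap_kmh)
  ids <- names(pop$truth)
  seg <- lapply(ids, function(id) {
    fx <- fixes[fixes$individual == id, ]
    cl <- classify_strategy(fx, nest, cfg$gibraltar_lat, cfg$sahara_lat,
                            cfg$local_km, cfg$migration_km, cfg$migration_days)
    part <- partition_seasons(cl$strategy, cl$windows, year)
    occ <- suppressWarnings(
      nest_occupation_date(fx, nest, cfg$nest_radius_m,
                           search_start = as.Date(sprintf("%d-12-01", year))))
    list(id = id, cl = cl, part = part, occ = occ)
  })
  strategies <- tibble::tibble(
    individual = ids,
    strategy = vapply(seg, function(s) s$cl$strategy, character(1)),
    group = vapply(seg, function(s) s$cl$group, character(1)),
    nest_occupation = as.Date(vapply(seg, function(s) as.character(s$occ),
                                     character(1))))
  write_table(strategies, p("strategies.csv"))
  partitions <- dplyr::bind_rows(lapply(seg, function(s) {
    tibble::tibble(individual = s$id, s$part)
  }))
  write_table(partitions, p("seasons.csv"))

  # summarize
  summary_tbl <- seasonal_summary(fixes, odba_series, partitions, strategies)
  write_table(summary_tbl, p("season_summary.csv"))

  # survival: encounter histories under the fitted population's group mix
  hist <- simulate_encounter_histories(
    n = max(75, cfg$n_individuals), occasions = 6,
    phi = 0.91, lambda = 0.3,
    p_ai = c(resident = 0.63, migrant = 0.14),
    strategy_mix = cfg$strategy_mix, seed = seed + 9L)
  write_histories(hist, p("encounter_histories.txt"))
  fit_null <- fit_multievent(hist, phi_by = "constant", p_by = "group",
                             c_hat = c_hat, seed = seed + 10L)
  fit_full <- fit_multievent(hist, phi_by = "group", p_by = "group",
                             c_hat = c_hat, seed = seed + 11L)
  comparison <- compare_models(null = fit_null, strategy_survival = fit_full)
  write_table(fit_null$estimates, p("survival_estimates.csv"))
  write_table(comparison, p("model_comparison.csv"))

  invisible(list(strategies = strategies, summary = summary_tbl,
                 fit = fit_null, comparison = comparison, classifier = clf,
                 files = list.files(out_dir, full.names = TRUE)))
}
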