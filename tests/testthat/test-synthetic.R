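test_that("simulations are reproducible given a seed", {
  a <- simulate_track("regional", 2018, seed = 42)
  b <- simulate_track("regional", 2018, seed = 42)
  expect_identical(a$fixes, b$fixes)
  expect_identical(a$truth$roosts, b$truth$roosts)
  c <- simulate_track("regional", 2018, seed = 43)
  expect_false(identical(a$fixes$lon, c$fixes$lon))

  b1 <- simulate_burst("flapping", seed = 7)
  b2 <- simulate_burst("flapping", seed = 7)
  expect_identical(b1$z, b2$z)

  h1 <- simulate_encounter_histories(30, 5, 0.9, 0.2, 0.5, seed = 3)
  h2 <- simulate_encounter_histories(30, 5, 0.9, 0.2, 0.5, seed = 3)
  expect_identical(h1, h2)
})

test_that("tracks honour the geometric contracts of their strategy", {
  cfg <- sim_config()
  nest <- c(cfg$nest_lon, cfg$nest_lat)

  loc <- simulate_track("local", 2018, cfg, seed = 1)
  d <- haversine_km(nest[1], nest[2], loc$fixes$lon, loc$fixes$lat)
  expect_lt(max(d), 50)

  reg <- simulate_track("regional", 2018, cfg, seed = 1)
  dreg <- haversine_km(nest[1], nest[2], reg$fixes$lon, reg$fixes$lat)
  expect_gt(max(dreg), 50)
  expect_true(all(daily_roosts(reg$fixes)$lat > cfg$gibraltar_lat))

  nw <- simulate_track("nw_africa", 2018, cfg, seed = 1)
  expect_gt(nw$truth$wintering_centroid[2], cfg$sahara_lat)
  expect_lt(nw$truth$wintering_centroid[2], cfg$gibraltar_lat)

  ss <- simulate_track("sub_saharan", 2018, cfg, seed = 1)
  expect_lt(ss$truth$wintering_centroid[2], cfg$sahara_lat)
  wr <- daily_roosts(ss$fixes)
  wint <- wr[wr$date > ss$truth$autumn_window[2] &
               wr$date < ss$truth$spring_window[1], ]
  expect_lt(mean(wint$lat), cfg$sahara_lat)

  # migratory tracks contain >= 3 consecutive >60 km roost days per passage
  for (sim in list(nw, ss)) {
    w <- detect_migration_windows(daily_roosts(sim$fixes))
    expect_false(is.null(w$autumn))
    expect_false(is.null(w$spring))
    expect_gte(as.integer(w$autumn[2] - w$autumn[1]) + 1L, 3L)
  }

  # the spec example: a generated regional track classifies as regional
  reg7 <- simulate_track("regional", 2018, cfg, seed = 7)
  expect_equal(classify_strategy(reg7$fixes, nest)$strategy, "regional")

  expect_error(simulate_track("nomadic", 2018, cfg), class = "ciconia_input_error")
})

test_that("burst dynamics order behaviours and carry the flap frequency", {
  cfg <- sim_config()
  expect_lt(compute_odba(simulate_burst("resting", cfg, seed = 1)),
            compute_odba(simulate_burst("flapping", cfg, seed = 1)))
  # across many seeds the amplitude ordering resting < soaring-ish < flapping
  odbas <- sapply(1:20, function(s) {
    c(resting = compute_odba(simulate_burst("resting", cfg, seed = s)),
      flapping = compute_odba(simulate_burst("flapping", cfg, seed = s)))
  })
  expect_true(all(odbas["resting", ] < odbas["flapping", ]))

  # at 10 Hz, FFT of a flapping burst peaks inside the configured band
  cfg10 <- sim_config(burst_rate_hz = 10, flap_hz = 3.5)
  b <- simulate_burst("flapping", cfg10, seed = 2)
  expect_equal(length(b$z), 90)
  f <- extract_features(b)
  expect_gt(unname(f["dom_freq_z"]), 3.0)
  expect_lt(unname(f["dom_freq_z"]), 4.0)

  # default 1 Hz geometry: 9 samples over 9 s
  b1 <- simulate_burst("foraging", cfg, seed = 3)
  expect_equal(length(b1$x), 9)
  expect_equal(b1$rate_hz, 1)

  # soaring is recovered end-to-end by a classifier trained on the corpus
  corpus <- simulate_burst_corpus(60, cfg, seed = 5)
  clf <- train_classifier(corpus$bursts, corpus$labels, seed = 5)
  expect_equal(classify_burst(clf, simulate_burst("soaring", cfg, seed = 3)),
               "soaring")

  expect_error(sim_config(burst_rate_hz = -1), class = "ciconia_input_error")
  expect_error(simulate_burst("swimming", cfg), class = "ciconia_input_error")
})

test_that("encounter histories follow the state/event laws", {
  # no death, no signal loss: all histories stay all-1
  h <- simulate_encounter_histories(50, 5, phi = 1, lambda = 0, p_ai = 0.5,
                                    seed = 1)
  expect_true(all(h$history == "11111"))

  # certain death with certain recovery: event 3 at occasion 2 for everyone
  h0 <- simulate_encounter_histories(50, 4, phi = 0, lambda = 0.5, p_ai = 0.5,
                                     seed = 2)
  expect_true(all(substr(h0$history, 1, 2) == "13"))
  expect_true(all(substr(h0$history, 3, 4) == "00"))

  # dead recoveries only ever come from state Ra
  h1 <- simulate_encounter_histories(400, 6, phi = 0.8, lambda = 0.3,
                                     p_ai = c(resident = 0.6, migrant = 0.2),
                                     seed = 3)
  ev <- do.call(rbind, lapply(strsplit(h1$history, ""), as.integer))
  st <- do.call(rbind, strsplit(h1$states, "-"))
  expect_true(all(st[ev == 3L] == "Ra"))
  expect_true(all(ev[, 1] == 1L))
  expect_true(all(st[, 1] == "Aa"))

  expect_error(simulate_encounter_histories(10, 1, 0.9, 0.1, 0.5),
               class = "ciconia_input_error")
  expect_error(simulate_encounter_histories(10, 4, 1.4, 0.1, 0.5),
               class = "ciconia_input_error")
})

test_that("event frequencies match forward-propagated marginals", {
  phi <- 0.85; lambda <- 0.25; p <- 0.5
  occ <- 5; n <- 5000
  h <- simulate_encounter_histories(n, occ, phi, lambda,
                                    p_ai = c(resident = p, migrant = p),
                                    seed = 17)
  ev <- do.call(rbind, lapply(strsplit(h$history, ""), as.integer))
  tr <- transition_matrix(phi, lambda)
  em <- event_matrix(p)
  state_dist <- c(1, 0, 0, 0)
  for (t in 2:occ) {
    state_dist <- as.numeric(state_dist %*% tr)
    expected <- as.numeric(state_dist %*% em)
    counts <- tabulate(ev[, t] + 1L, nbins = 4)
    keep <- expected > 0
    chi <- suppressWarnings(
      stats::chisq.test(counts[keep], p = expected[keep] / sum(expected[keep])))
    expect_gt(chi$p.value, 1e-3)
  }
})

test_that("wing length drives migration propensity with a negative slope", {
  cfg <- sim_config()
  ph <- simulate_phenotypes(1000, cfg, seed = 5)
  terc <- cut(ph$wing_mm, stats::quantile(ph$wing_mm, c(0, 1/3, 2/3, 1)),
              include.lowest = TRUE)
  frac <- tapply(ph$migrant, terc, mean)
  expect_true(all(diff(frac) < 0))

  # logistic fit recovers the sign of the slope
  fit <- stats::glm(migrant ~ wing_mm, family = stats::binomial(), data = ph)
  expect_lt(unname(stats::coef(fit)["wing_mm"]), 0)
  expect_lt(summary(fit)$coefficients["wing_mm", "Pr(>|z|)"], 0.01)

  # zero slope: migration independent of size
  cfg0 <- sim_config(wing_logit_slope = 0)
  ph0 <- simulate_phenotypes(1000, cfg0, seed = 6)
  fit0 <- stats::glm(migrant ~ wing_mm, family = stats::binomial(), data = ph0)
  expect_gt(summary(fit0)$coefficients["wing_mm", "Pr(>|z|)"], 0.05)
  expect_true(all(ph0$p_migrant == ph0$p_migrant[1]))

  expect_error(sim_config(wing_logit_slope = 0.1), class = "ciconia_input_error")
})
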