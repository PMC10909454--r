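#' Simulate wing lengths and migration propensity
#'
#' Wing length (a body-size proxy) is drawn from a normal distribution;
#' the probability of being a migrant follows a logistic curve with a
#' non-positive slope in wing length, so larger birds are more likely to
#' be resident.
#'
#' @param n number of birds (default `cfg$n_individuals`).
#' @param cfg a [sim_config()]; uses `wing_mean_mm`, `wing_sd_mm`,
#'   `wing_logit_slope`, `migrant_logit_intercept`.
#' @param seed RNG seed.
#' @return tibble: `individual`, `wing_mm`, `p_migrant`, `migrant`
#'   (logical).
#' @export
simulate_phenotypes <- function(n = cfg$n_individuals, cfg = sim_config(),
                                seed = cfg$seed) {
  if (cfg$wing_logit_slope > 0) stop_input("wing_logit_slope must be <= 0")
  withr::with_seed(seed, {
    wing <- rnorm(n, cfg$wing_mean_mm, cfg$wing_sd_mm)
    p <- plogis(cfg$migrant_logit_intercept +
                  cfg$wing_logit_slope * (wing - cfg$wing_mean_mm))
    tibble::tibble(individual = sprintf("stork_%03d", seq_len(n)),
                   wing_mm = wing,
                   p_migrant = p,
                   migrant = rbinom(n, 1, p) == 1)
  })
}
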