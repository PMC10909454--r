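# Multievent capture-recapture hidden Markov model.
#
# Biological states: Aa (alive, active GPS), Ai (alive, inactive GPS),
# Ra (recently dead, active GPS), LD (long dead).
# Field events:     0 (not observed), 1 (seen with active GPS),
#                   2 (resighted alive without GPS signal), 3 (recovered
#                   dead).
# Fixed by design of the study: initial state is Aa with certainty
# (tau_Aa = 1), birds with an active tag are always detected (p_Aa = 1),
# dead birds with an active tag are always recovered (r = 1).
# Transitions compose survival first, then tag fate, so Ra is reachable
# exactly when death occurs while the tag is still active; a bird whose
# tag fails in the same interval it dies resolves to Ra (death takes
# precedence). Ra persists a single occasion, then LD absorbs.

ME_STATES <- c("Aa", "Ai", "Ra", "LD")
ME_EVENTS <- 0:3

#' State transition matrix of the multievent model
#'
#' Row-stochastic 4x4 matrix over (Aa, Ai, Ra, LD), composing annual
#' survival `phi` and GPS signal loss `lambda`:
#' Aa stays Aa with phi(1-lambda), moves to Ai with phi*lambda, to Ra
#' with 1-phi; Ai survives to Ai with phi, else LD; Ra and LD go to LD.
#'
#' @param phi survival probability.
#' @param lambda per-occasion probability of losing the GPS signal.
#' @return 4x4 matrix with dimnames over the states.
#' @export
transition_matrix <- function(phi, lambda) {
  assert_prob(phi, "phi"); assert_prob(lambda, "lambda")
  m <- rbind(c(phi * (1 - lambda), phi * lambda, 1 - phi, 0),
             c(0, phi, 0, 1 - phi),
             c(0, 0, 0, 1),
             c(0, 0, 0, 1))
  dimnames(m) <- list(ME_STATES, ME_STATES)
  m
}

#' Event (observation) matrix of the multievent model
#'
#' Row-stochastic 4x4 matrix of states x events (0, 1, 2, 3): Aa always
#' yields event 1 (p_Aa = 1); Ai yields event 2 with resighting
#' probability `p_ai`, else 0; Ra always yields event 3 (r = 1); LD is
#' never observed.
#'
#' @param p_ai probability of resighting a live bird whose GPS signal
#'   is lost.
#' @return 4x4 matrix, rows = states, columns = events `"0".."3"`.
#' @export
event_matrix <- function(p_ai) {
  assert_prob(p_ai, "p_ai")
  m <- rbind(c(0, 1, 0, 0),
             c(1 - p_ai, 0, p_ai, 0),
             c(0, 0, 0, 1),
             c(1, 0, 0, 0))
  dimnames(m) <- list(ME_STATES, as.character(ME_EVENTS))
  m
}

#' Log-likelihood of one encounter history
#'
#' Forward algorithm over the hidden states, conditioned on release in
#' state Aa at the first occasion (tau_Aa = 1). Impossible histories
#' (e.g. a live resighting after a dead recovery) return `-Inf` rather
#' than raising an error.
#'
#' @param events integer vector of event codes (0-3), first element at
#'   the release occasion (must be 1 for a possible history).
#' @param phi,lambda,p_ai model parameters, see [transition_matrix()]
#'   and [event_matrix()].
#' @return the log-likelihood contribution (a finite number or `-Inf`).
#' @export
history_loglik <- function(events, phi, lambda, p_ai) {
  events <- as.integer(events)
  if (any(is.na(events)) || any(!events %in% ME_EVENTS)) {
    stop_input("events must be codes in {0, 1, 2, 3}")
  }
  tr <- transition_matrix(phi, lambda)
  em <- event_matrix(p_ai)
  alpha <- c(1, 0, 0, 0) * em[, events[1] + 1L]
  if (length(events) > 1) {
    for (t in 2:length(events)) {
      alpha <- as.numeric(alpha %*% tr) * em[, events[t] + 1L]
    }
  }
  p <- sum(alpha)
  if (p <= 0) return(-Inf)
  log(p)
}

# Vectorised forward log-likelihood for a matrix of equal-length
# histories (rows) sharing one parameter set. Returns a vector.
forward_loglik_matrix <- function(ev_mat, phi, lambda, p_ai) {
  tr <- transition_matrix(phi, lambda)
  em_t <- t(event_matrix(p_ai))          # events x states
  n <- nrow(ev_mat)
  alpha <- matrix(0, n, 4)
  alpha[, 1] <- 1
  alpha <- alpha * em_t[ev_mat[, 1] + 1L, , drop = FALSE]
  if (ncol(ev_mat) > 1) {
    for (t in 2:ncol(ev_mat)) {
      alpha <- (alpha %*% tr) * em_t[ev_mat[, t] + 1L, , drop = FALSE]
    }
  }
  log(rowSums(alpha))
}

parse_histories <- function(histories) {
  h <- histories$history
  if (!all(grepl("^[0-3]+$", h))) {
    stop_input("histories must be digit strings over 0-3")
  }
  len <- unique(nchar(h))
  if (length(len) != 1) stop_input("all histories must have equal length")
  ev <- do.call(rbind, lapply(strsplit(h, ""), as.integer))
  if (any(ev[, 1] != 1L)) {
    stop_input("every history must start with event 1 (release with active tag)")
  }
  ev
}

#' Simulate encounter histories from the multievent model
#'
#' Every bird is released in state Aa at occasion 1 (event 1); states
#' then evolve by the transition matrix and events are drawn from the
#' event matrix, so dead recoveries (event 3) occur only from state Ra.
#'
#' @param n number of individuals.
#' @param occasions number of annual occasions (>= 2).
#' @param phi survival; either a single value or a named vector over the
#'   groups implied by `strategy_mix` (`resident`/`migrant` or the four
#'   strategies).
#' @param lambda GPS signal-loss probability.
#' @param p_ai named vector `c(resident = , migrant = )` of resighting
#'   probabilities without GPS signal.
#' @param strategy_mix probabilities over the four strategies (default
#'   `sim_config()$strategy_mix`).
#' @param seed RNG seed.
#' @return tibble: `id`, `strategy` (4-level), `group`
#'   (resident/migrant), `history` (digit string), `states` (true state
#'   string, truth record).
#' @export
simulate_encounter_histories <- function(n, occasions, phi, lambda, p_ai,
                                         strategy_mix = sim_config()$strategy_mix,
                                         seed = 1L) {
  if (occasions < 2) stop_input("occasions must be >= 2")
  assert_prob(phi, "phi"); assert_prob(lambda, "lambda")
  assert_prob(p_ai, "p_ai"); assert_prob(strategy_mix, "strategy_mix")
  if (is.null(names(p_ai))) p_ai <- c(resident = p_ai[[1]], migrant = p_ai[[1]])
  withr::with_seed(seed, {
    strategy <- sample(STRATEGIES, n, replace = TRUE, prob = strategy_mix)
    group <- strategy_group(strategy)
    phi_i <- if (length(phi) == 1) rep(phi, n) else {
      if (all(c("resident", "migrant") %in% names(phi))) unname(phi[group])
      else unname(phi[strategy])
    }
    p_i <- unname(p_ai[group])
    states <- matrix(1L, n, occasions)        # 1=Aa 2=Ai 3=Ra 4=LD
    events <- matrix(1L, n, occasions)        # release event
    for (t in 2:occasions) {
      s <- states[, t - 1L]
      u1 <- runif(n); u2 <- runif(n)
      new_s <- integer(n)
      aa <- s == 1L
      dead_now <- u1 >= phi_i                  # survival resolved first
      new_s[aa & dead_now] <- 3L               # died with active tag -> Ra
      new_s[aa & !dead_now] <- ifelse(u2[aa & !dead_now] < lambda, 2L, 1L)
      ai <- s == 2L
      new_s[ai] <- ifelse(dead_now[ai], 4L, 2L)
      new_s[s >= 3L] <- 4L                     # Ra and LD absorb into LD
      states[, t] <- new_s
      e <- integer(n)
      e[new_s == 1L] <- 1L
      e[new_s == 2L] <- ifelse(runif(n)[new_s == 2L] < p_i[new_s == 2L], 2L, 0L)
      e[new_s == 3L] <- 3L
      e[new_s == 4L] <- 0L
      events[, t] <- e
    }
    tibble::tibble(
      id = sprintf("ind_%04d", seq_len(n)),
      strategy = strategy,
      group = group,
      history = apply(events, 1, paste0, collapse = ""),
      states = apply(matrix(ME_STATES[states], n), 1, paste0, collapse = "-")
    )
  })
}

# -- maximum-likelihood fitting ---------------------------------------

me_group_levels <- function(histories, by) {
  switch(by,
         constant = rep("all", nrow(histories)),
         group = histories$group,
         strategy4 = histories$strategy,
         stop_input("unknown grouping: ", by))
}

#' Fit the multievent model by maximum likelihood
#'
#' Maximises the joint forward-algorithm likelihood of all encounter
#' histories on the logit scale with seeded multi-start quasi-Newton
#' optimisation. Survival can be constant, differ between residents and
#' migrants (`phi_by = "group"`), or between the four strategies
#' (`phi_by = "strategy4"`); resighting without signal can be constant
#' or group-specific; signal loss `lambda` is a single shared
#' parameter. Fixed constants of the study design (tau_Aa, p_Aa, r)
#' never move. Confidence intervals are Wald on the logit scale,
#' back-transformed.
#'
#' @param histories tibble with columns `history` (digit string, first
#'   event 1), `group` (resident/migrant), and, for
#'   `phi_by = "strategy4"`, `strategy`.
#' @param phi_by `"constant"`, `"group"` or `"strategy4"`.
#' @param p_by `"constant"` or `"group"`.
#' @param c_hat overdispersion coefficient (>= 1) used for QAICc; taken
#'   as an input, typically from external goodness-of-fit testing.
#' @param n_starts number of random optimisation starts.
#' @param seed seed for the start draws.
#' @param n_eff effective sample size for QAICc (default: number of
#'   individuals).
#' @return object of class `me_fit`: `estimates` (tibble with point
#'   estimates and 95% CIs), `loglik`, `deviance`, `K`, `n_eff`,
#'   `c_hat`, `qaicc`, `convergence`, `phi_by`, `p_by`.
#' @export
fit_multievent <- function(histories, phi_by = c("constant", "group", "strategy4"),
                           p_by = c("group", "constant"),
                           c_hat = 1, n_starts = 10, seed = 1L, n_eff = NULL) {
  phi_by <- match.arg(phi_by)
  p_by <- match.arg(p_by)
  ev <- parse_histories(histories)
  phi_g <- me_group_levels(histories, phi_by)
  p_g <- me_group_levels(histories, if (p_by == "group") "group" else "constant")
  phi_levels <- sort(unique(phi_g))
  p_levels <- sort(unique(p_g))
  if (p_by == "group" && length(p_levels) < 2) {
    stop_input("p_by = 'group' needs histories from both groups")
  }

  # pool identical (history, phi group, p group) rows
  key <- paste(histories$history, phi_g, p_g)
  uniq <- !duplicated(key)
  counts <- as.numeric(table(key)[key[uniq]])
  ev_u <- ev[uniq, , drop = FALSE]
  cell <- interaction(factor(phi_g[uniq], phi_levels),
                      factor(p_g[uniq], p_levels), drop = FALSE)

  n_phi <- length(phi_levels)
  n_p <- length(p_levels)
  K <- n_phi + 1L + n_p
  unpack <- function(par) {
    list(phi = setNames(plogis(par[seq_len(n_phi)]), phi_levels),
         lambda = plogis(par[n_phi + 1L]),
         p = setNames(plogis(par[n_phi + 1L + seq_len(n_p)]), p_levels))
  }
  negll <- function(par) {
    pr <- unpack(par)
    ll <- 0
    for (cl in levels(cell)) {
      ii <- which(cell == cl)
      if (!length(ii)) next
      parts <- strsplit(cl, ".", fixed = TRUE)[[1]]
      lv <- forward_loglik_matrix(ev_u[ii, , drop = FALSE],
                                  pr$phi[[parts[1]]], pr$lambda,
                                  pr$p[[parts[2]]])
      ll <- ll + sum(counts[ii] * lv)
    }
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  starts <- withr::with_seed(seed,
    matrix(runif(n_starts * K, qlogis(0.15), qlogis(0.95)), n_starts, K))
  best <- NULL
  conv_any <- FALSE
  for (s in seq_len(n_starts)) {
    opt <- tryCatch(optim(starts[s, ], negll, method = "BFGS",
                          control = list(maxit = 500)),
                    error = function(e) NULL)
    if (is.null(opt)) next
    conv_any <- conv_any || opt$convergence == 0
    if (is.null(best) || opt$value < best$value - 1e-9) best <- opt
  }
  if (is.null(best)) {
    stop(errorCondition("multievent fit failed in every start",
                        class = c("ciconia_fit_error", "error")))
  }
  if (!conv_any) warning("no optimisation start reported convergence; best attempt returned")

  hess <- tryCatch(optimHess(best$par, negll), error = function(e) NULL)
  se <- rep(NA_real_, K)
  if (!is.null(hess)) {
    vc <- tryCatch(solve(hess), error = function(e) NULL)
    if (!is.null(vc)) {
      dv <- diag(vc)
      se[dv > 0] <- sqrt(dv[dv > 0])
    }
  }
  pr <- unpack(best$par)
  param <- c(rep("phi", n_phi), "lambda", rep("p_ai", n_p))
  grp <- c(phi_levels, "all", p_levels)
  est <- tibble::tibble(
    parameter = param, group = grp,
    estimate = unname(c(pr$phi, pr$lambda, pr$p)),
    lcl = plogis(best$par - 1.96 * se),
    ucl = plogis(best$par + 1.96 * se),
    logit_estimate = best$par, logit_se = se
  )
  loglik <- -best$value
  n_eff <- n_eff %||% nrow(histories)
  structure(list(estimates = est, loglik = loglik, deviance = -2 * loglik,
                 K = K, n_eff = n_eff, c_hat = c_hat,
                 qaicc = qaicc(loglik, K, c_hat, n_eff),
                 convergence = conv_any, phi_by = phi_by, p_by = p_by,
                 n_histories = nrow(histories)),
            class = "me_fit")
}

#' @export
print.me_fit <- function(x, ...) {
  cat(sprintf("<me_fit: phi ~ %s, p_ai ~ %s; K = %d, logLik = %.3f, QAICc = %.2f>\n",
              x$phi_by, x$p_by, x$K, x$loglik, x$qaicc))
  print(as.data.frame(x$estimates[, c("parameter", "group", "estimate", "lcl", "ucl")]),
        digits = 3, row.names = FALSE)
  invisible(x)
}

#' Quasi-likelihood AICc
#'
#' `QAIC = -2 logLik / c_hat + 2K`, with the small-sample correction
#' `QAICc = QAIC + 2K(K + 1) / (n_eff - K - 1)`.
#'
#' @param loglik maximised log-likelihood.
#' @param K number of estimated parameters.
#' @param c_hat overdispersion coefficient (>= 1).
#' @param n_eff effective sample size (> K + 1); conventionally the
#'   number of individuals.
#' @return the QAICc value.
#' @export
qaicc <- function(loglik, K, c_hat, n_eff) {
  if (!is.finite(c_hat) || c_hat < 1) stop_input("c_hat must be >= 1")
  if (!is.finite(n_eff) || n_eff <= K + 1) stop_input("n_eff must exceed K + 1")
  -2 * loglik / c_hat + 2 * K + 2 * K * (K + 1) / (n_eff - K - 1)
}

#' Compare fitted multievent models by QAICc
#'
#' @param ... named `me_fit` objects (or a single named list of them).
#' @return tibble sorted by QAICc with `delta_qaicc`.
#' @export
compare_models <- function(...) {
  fits <- list(...)
  if (length(fits) == 1 && !inherits(fits[[1]], "me_fit")) fits <- fits[[1]]
  if (is.null(names(fits)) || any(names(fits) == "")) {
    names(fits) <- paste0("model_", seq_along(fits))
  }
  out <- tibble::tibble(
    model = names(fits),
    loglik = unname(vapply(fits, `[[`, numeric(1), "loglik")),
    K = unname(vapply(fits, function(f) as.numeric(f$K), numeric(1))),
    c_hat = unname(vapply(fits, `[[`, numeric(1), "c_hat")),
    qaicc = unname(vapply(fits, `[[`, numeric(1), "qaicc"))
  )
  out <- out[order(out$qaicc), ]
  out$delta_qaicc <- out$qaicc - out$qaicc[1]
  out
}
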