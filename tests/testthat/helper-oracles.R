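# Independent brute-force oracles used to check the package's vectorised
# implementations. Deliberately written as plain loops over the defining
# formulas, sharing no code with the implementation.

# truncated centred windowed mean, extra sample trailing for even widths
brute_running_mean <- function(x, window_s, rate_hz) {
  w <- max(1L, round(window_s * rate_hz))
  left <- (w - 1L) %/% 2L
  right <- w - 1L - left
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    out[i] <- mean(x[max(1, i - left):min(n, i + right)])
  }
  out
}

# mean over samples of the 3-axis absolute dynamic sum
brute_odba <- function(x, y, z, rate_hz, window_s = 4) {
  n <- length(x)
  tot <- 0
  for (i in seq_len(n)) {
    for (a in list(x, y, z)) {
      sm <- brute_running_mean(a, window_s, rate_hz)
      tot <- tot + abs(a[i] - sm[i])
    }
  }
  tot / n
}

# exhaustive path enumeration of the multievent likelihood
# states 1=Aa 2=Ai 3=Ra 4=LD; release in Aa at first occasion
brute_history_loglik <- function(events, phi, lambda, p_ai) {
  tr <- transition_matrix(phi, lambda)
  em <- event_matrix(p_ai)
  Tn <- length(events)
  if (Tn == 1) {
    p <- em[1, events[1] + 1]
    return(if (p <= 0) -Inf else log(p))
  }
  paths <- as.matrix(expand.grid(rep(list(1:4), Tn - 1)))
  tot <- 0
  for (r in seq_len(nrow(paths))) {
    s <- c(1L, paths[r, ])
    p <- em[1, events[1] + 1]
    for (t in 2:Tn) {
      p <- p * tr[s[t - 1], s[t]] * em[s[t], events[t] + 1]
    }
    tot <- tot + p
  }
  if (tot <= 0) -Inf else log(tot)
}

# fixes series that roosts at a given position each night (23:00 UTC at
# lon 0 is 23:00 solar); one nocturnal + one midday fix per date
make_roost_fixes <- function(dates, lon, lat, individual = "bird_1") {
  stopifnot(length(lon) == length(dates), length(lat) == length(dates))
  night <- as.POSIXct(paste(dates, "23:00:00"), tz = "UTC")
  noon <- as.POSIXct(paste(dates, "12:00:00"), tz = "UTC")
  tibble::tibble(
    individual = individual,
    timestamp = sort(c(noon, night)),   # interleaves noon/night per date
    lon = rep(lon, each = 2),
    lat = rep(lat, each = 2)
  )
}

tiny_cfg <- function(...) sim_config(n_individuals = 4, ...)
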