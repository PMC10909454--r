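#' Centred running mean
#'
#' Smooths a sample vector with a centred moving-average window of
#' `round(window_s * rate_hz)` samples, truncated at the series edges
#' (no padding: near the edges the mean is taken over the available
#' samples only). For an even window width the extra sample sits on the
#' trailing side. A constant series is returned unchanged.
#'
#' @param x numeric sample vector.
#' @param window_s window length in seconds (default 4).
#' @param rate_hz sampling rate in Hz.
#' @return smoothed vector, same length as `x`.
#' @export
running_mean <- function(x, window_s = 4, rate_hz = 1) {
  if (length(x) == 0) stop_input("empty series")
  if (any(!is.finite(x))) stop_input("series contains non-finite values")
  w <- max(1L, round(window_s * rate_hz))
  if (w < 1) stop_input("window_s * rate_hz must be >= 1")
  n <- length(x)
  if (min(x) == max(x)) return(x)  # constant series is its own smoothing, exactly
  left <- (w - 1L) %/% 2L
  right <- w - 1L - left
  i <- seq_len(n)
  lo <- pmax(i - left, 1L)
  hi <- pmin(i + right, n)
  cs <- cumsum(c(0, x))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Overall dynamic body acceleration (ODBA) of a burst
#'
#' The dynamic component of each axis is the raw signal minus its
#' running-mean smoothing (the static, gravitational part); ODBA is the
#' mean over samples of the sum over the three axes of the absolute
#' dynamic component. Averaging (rather than summing) over samples makes
#' values comparable across burst durations and sampling rates. ODBA is
#' non-negative, zero for any constant burst, and invariant to adding a
#' per-axis constant offset.
#'
#' @param burst an [accel_burst()].
#' @param window_s smoothing window in seconds (default 4).
#' @return ODBA in g.
#' @export
compute_odba <- function(burst, window_s = 4) {
  stopifnot(inherits(burst, "accel_burst"))
  if (any(!is.finite(c(burst$x, burst$y, burst$z)))) {
    stop_input("burst contains non-finite samples")
  }
  dyn <- vapply(c("x", "y", "z"), function(ax) {
    a <- burst[[ax]]
    abs(a - running_mean(a, window_s, burst$rate_hz))
  }, numeric(length(burst$x)))
  if (is.null(dim(dyn))) dyn <- matrix(dyn, nrow = 1)
  mean(rowSums(dyn))
}

#' Burst classification features
#'
#' Fixed-order numeric summary of a burst: per-axis mean and SD, ODBA,
#' per-axis range, pairwise axis correlations (0 by convention when an
#' axis is constant), dominant heave frequency (FFT peak excluding DC,
#' in Hz; 0 for a constant heave), and the spectral power ratio of the
#' heave axis (share of non-DC power above a quarter of the sampling
#' rate — high for noise-like signals, low for smooth drift).
#'
#' @param burst an [accel_burst()] with at least 2 samples.
#' @return named numeric vector of 15 features, constant order.
#' @export
extract_features <- function(burst) {
  stopifnot(inherits(burst, "accel_burst"))
  n <- length(burst$x)
  if (n < 2) stop_input("burst must have at least 2 samples")
  ax <- list(x = burst$x, y = burst$y, z = burst$z)
  mean3 <- vapply(ax, mean, numeric(1))
  sd3 <- vapply(ax, sd, numeric(1))
  rng3 <- vapply(ax, function(a) diff(range(a)), numeric(1))
  safe_cor <- function(a, b) {
    if (sd(a) == 0 || sd(b) == 0) 0 else cor(a, b)
  }
  z <- burst$z - mean(burst$z)
  pw <- Mod(fft(z))^2
  freqs <- (seq_len(n) - 1) / n * burst$rate_hz
  half <- freqs > 0 & freqs <= burst$rate_hz / 2
  dom_freq <- 0
  spec_ratio <- 0
  if (any(half) && sum(pw[half]) > 0) {
    dom_freq <- freqs[half][which.max(pw[half])]
    hi <- half & freqs >= burst$rate_hz / 4
    spec_ratio <- sum(pw[hi]) / sum(pw[half])
  }
  c(mean_x = mean3[["x"]], mean_y = mean3[["y"]], mean_z = mean3[["z"]],
    sd_x = sd3[["x"]], sd_y = sd3[["y"]], sd_z = sd3[["z"]],
    odba = compute_odba(burst),
    range_x = rng3[["x"]], range_y = rng3[["y"]], range_z = rng3[["z"]],
    cor_xy = safe_cor(burst$x, burst$y),
    cor_xz = safe_cor(burst$x, burst$z),
    cor_yz = safe_cor(burst$y, burst$z),
    dom_freq_z = dom_freq,
    spec_ratio_z = spec_ratio)
}

#' Train a behaviour classifier on labelled bursts
#'
#' Random forest over [extract_features()], with a seeded stratified
#' held-out split for honest accuracy reporting. Deterministic given the
#' seed. Two independent classifier instances (e.g. one per tag family)
#' can be trained by calling this twice on the respective subsets.
#'
#' @param bursts list of [accel_burst()] objects.
#' @param labels character vector of behaviours, same length.
#' @param seed RNG seed (split and forest).
#' @param holdout fraction held out for evaluation (default 0.25).
#' @param num_trees forest size.
#' @return object of class `behavior_classifier` with the fitted forest,
#'   overall `accuracy`, `per_class_accuracy`, and split sizes.
#' @export
train_classifier <- function(bursts, labels, seed = 1L, holdout = 0.25,
                             num_trees = 500) {
  if (length(bursts) != length(labels)) stop_input("bursts and labels differ in length")
  if (!all(labels %in% BEHAVIORS)) stop_input("labels must be among the four behaviours")
  if (length(unique(labels)) < 2) stop_input("training set must contain >= 2 classes")
  feats <- t(vapply(bursts, extract_features, numeric(15)))
  df <- as.data.frame(feats)
  df$behavior <- factor(labels, levels = sort(unique(labels)))
  test_idx <- withr::with_seed(seed, {
    unlist(lapply(split(seq_along(labels), labels), function(ii) {
      sample(ii, max(1L, round(length(ii) * holdout)))
    }), use.names = FALSE)
  })
  train_df <- df[-test_idx, , drop = FALSE]
  test_df <- df[test_idx, , drop = FALSE]
  rf <- ranger::ranger(behavior ~ ., data = train_df, num.trees = num_trees,
                       seed = seed, probability = FALSE)
  pred <- predict(rf, data = test_df)$predictions
  acc <- mean(as.character(pred) == as.character(test_df$behavior))
  per_class <- vapply(split(as.character(pred) == as.character(test_df$behavior),
                            as.character(test_df$behavior)),
                      mean, numeric(1))
  structure(list(forest = rf, feature_names = colnames(feats),
                 accuracy = acc, per_class_accuracy = per_class,
                 n_train = nrow(train_df), n_test = nrow(test_df),
                 seed = seed),
            class = "behavior_classifier")
}

#' @export
print.behavior_classifier <- function(x, ...) {
  cat(sprintf("<behavior_classifier: held-out accuracy %.3f (n_train = %d, n_test = %d)>\n",
              x$accuracy, x$n_train, x$n_test))
  print(round(x$per_class_accuracy, 3))
  invisible(x)
}

#' Classify bursts into behaviours
#'
#' @param classifier a [train_classifier()] result.
#' @param bursts one `accel_burst` or a list of them.
#' @return character vector of behaviour labels.
#' @export
classify_burst <- function(classifier, bursts) {
  stopifnot(inherits(classifier, "behavior_classifier"))
  if (inherits(bursts, "accel_burst")) bursts <- list(bursts)
  feats <- t(vapply(bursts, extract_features, numeric(15)))
  df <- as.data.frame(feats)
  as.character(predict(classifier$forest, data = df)$predictions)
}

#' Behavioural time budget
#'
#' Proportion of time per behaviour over a period, computed as the
#' proportion of bursts (bursts are equally spaced, so burst shares are
#' time shares): per-day proportions first, then averaged across the
#' days of the period, so unevenly sampled days weigh equally.
#'
#' @param labels tibble with columns `timestamp` and `behavior` (and
#'   optionally `lon` for solar dates; UTC dates are used otherwise).
#' @param start,end optional period bounds (Dates, inclusive).
#' @return tibble with `behavior` and `proportion` over all four
#'   behaviours (zeros included); proportions sum to 1.
#' @export
behavioral_budget <- function(labels, start = NULL, end = NULL) {
  day <- as.Date(labels$timestamp, tz = "UTC")
  keep <- rep(TRUE, length(day))
  if (!is.null(start)) keep <- keep & day >= as.Date(start)
  if (!is.null(end)) keep <- keep & day <= as.Date(end)
  labels <- labels[keep, , drop = FALSE]
  day <- day[keep]
  if (nrow(labels) == 0) {
    warning("behavioral_budget: no bursts in period")
    return(tibble::tibble(behavior = BEHAVIORS, proportion = NA_real_))
  }
  beh <- factor(labels$behavior, levels = BEHAVIORS)
  per_day <- table(day, beh)
  per_day <- per_day / rowSums(per_day)
  tibble::tibble(behavior = BEHAVIORS,
                 proportion = as.numeric(colMeans(per_day)))
}
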