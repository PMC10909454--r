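# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @importFrom stats median sd cor qlogis plogis rnorm runif rbinom optim optimHess setNames quantile fft predict
#' @importFrom utils read.csv write.csv head tail
#' @importFrom dplyr .data
NULL

stop_input <- function(...) {
  stop(errorCondition(paste0(...), class = c("ciconia_input_error", "error")))
}

assert_prob <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop_input(name, " must lie in [0, 1]")
  }
  invisible(x)
}

# Local solar time from longitude only: 4 minutes per degree east.
solar_time <- function(timestamp, lon) {
  timestamp + lon * 240
}

solar_hour <- function(timestamp, lon) {
  st <- solar_time(timestamp, lon)
  as.numeric(format(st, "%H", tz = "UTC")) +
    as.numeric(format(st, "%M", tz = "UTC")) / 60 +
    as.numeric(format(st, "%S", tz = "UTC")) / 3600
}

solar_date <- function(timestamp, lon) {
  as.Date(solar_time(timestamp, lon), tz = "UTC")
}

BEHAVIORS <- c("foraging", "resting", "soaring", "flapping")
STRATEGIES <- c("local", "regional", "nw_africa", "sub_saharan")
SEASONS <- c("autumn", "wintering", "spring", "breeding")

#' Map a four-level migratory strategy to resident/migrant
#'
#' Residents are `local` and `regional` birds (they stay in Southwest
#' Europe); migrants are `nw_africa` and `sub_saharan` birds (they cross
#' the Strait of Gibraltar).
#'
#' @param strategy character vector of strategies among
#'   `local, regional, nw_africa, sub_saharan`.
#' @return character vector, `"resident"` or `"migrant"`.
#' @export
strategy_group <- function(strategy) {
  if (!all(strategy %in% STRATEGIES)) {
    stop_input("unknown strategy: ", paste(setdiff(strategy, STRATEGIES), collapse = ", "))
  }
  ifelse(strategy %in% c("local", "regional"), "resident", "migrant")
}
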