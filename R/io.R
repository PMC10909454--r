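# Readers and writers for the Movebank-dialect CSV and pipeline tables.
# Writers are deterministic given their inputs; readers invert writers
# on valid files. Timestamps are ISO-8601 UTC throughout.

MOVEBANK_COLS <- c("timestamp", "location-long", "location-lat",
                   "individual-local-identifier")

iso8601 <- function(ts) format(ts, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

parse_ts <- function(x) {
  out <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%OSZ", tz = "UTC")
  fallback <- is.na(out)
  if (any(fallback)) {
    out[fallback] <- as.POSIXct(x[fallback], format = "%Y-%m-%d %H:%M:%OS", tz = "UTC")
  }
  out
}

#' Read and write GPS fixes (Movebank dialect)
#'
#' Columns: `timestamp` (ISO-8601 UTC), `location-long`, `location-lat`,
#' `individual-local-identifier`. Malformed rows (unparseable timestamp
#' or non-finite coordinates) are dropped with a warning giving their
#' count; fixes are returned sorted per individual by time.
#'
#' @param path CSV file path.
#' @param fixes tibble with `individual`, `timestamp`, `lon`, `lat`.
#' @return `read_fixes`: the fixes tibble; `write_fixes`: `path`,
#'   invisibly.
#' @export
read_fixes <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  missing <- setdiff(MOVEBANK_COLS, names(df))
  if (length(missing)) {
    stop(errorCondition(paste("missing required columns:",
                              paste(missing, collapse = ", ")),
                        class = c("ciconia_format_error", "error")))
  }
  if (nrow(df) == 0) {
    warning("read_fixes: empty file")
    return(tibble::tibble(individual = character(),
                          timestamp = as.POSIXct(character(), tz = "UTC"),
                          lon = double(), lat = double()))
  }
  ts <- parse_ts(df$timestamp)
  lon <- suppressWarnings(as.numeric(df[["location-long"]]))
  lat <- suppressWarnings(as.numeric(df[["location-lat"]]))
  bad <- is.na(ts) | !is.finite(lon) | !is.finite(lat) | abs(lon) > 180 | abs(lat) > 90
  if (any(bad)) warning(sprintf("read_fixes: dropped %d malformed row(s)", sum(bad)))
  out <- tibble::tibble(individual = as.character(df[["individual-local-identifier"]][!bad]),
                        timestamp = ts[!bad], lon = lon[!bad], lat = lat[!bad])
  dplyr::arrange(out, .data$individual, .data$timestamp)
}

#' @rdname read_fixes
#' @export
write_fixes <- function(fixes, path) {
  out <- data.frame(check.names = FALSE,
    timestamp = iso8601(fixes$timestamp),
    `location-long` = fixes$lon,
    `location-lat` = fixes$lat,
    `individual-local-identifier` = fixes$individual)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write acceleration bursts (long CSV)
#'
#' Long format with columns `timestamp`, `individual-local-identifier`,
#' `sample-index` (0-based), `acc-x`, `acc-y`, `acc-z` (g). The sampling
#' rate is not represented in the format and must be supplied when
#' reading.
#'
#' @param path CSV file path.
#' @param bursts list of [accel_burst()] objects.
#' @param rate_hz sampling rate to attach to the bursts read.
#' @return `read_bursts`: list of `accel_burst`, sorted by individual
#'   and timestamp; `write_bursts`: `path`, invisibly.
#' @export
read_bursts <- function(path, rate_hz) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("timestamp", "individual-local-identifier", "sample-index",
            "acc-x", "acc-y", "acc-z")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop(errorCondition(paste("missing required columns:",
                              paste(missing, collapse = ", ")),
                        class = c("ciconia_format_error", "error")))
  }
  key <- paste(df[["individual-local-identifier"]], df$timestamp)
  lapply(split(seq_len(nrow(df)), factor(key, unique(key))), function(ii) {
    sub <- df[ii[order(df[["sample-index"]][ii])], ]
    accel_burst(sub[["acc-x"]], sub[["acc-y"]], sub[["acc-z"]],
                rate_hz = rate_hz,
                individual = sub[["individual-local-identifier"]][1],
                timestamp = parse_ts(sub$timestamp[1]))
  })
}

#' @rdname read_bursts
#' @export
write_bursts <- function(bursts, path) {
  if (inherits(bursts, "accel_burst")) bursts <- list(bursts)
  rows <- lapply(bursts, function(b) {
    n <- length(b$x)
    data.frame(check.names = FALSE,
      timestamp = iso8601(rep(b$timestamp, n)),
      `individual-local-identifier` = rep(b$individual, n),
      `sample-index` = seq_len(n) - 1L,
      `acc-x` = b$x, `acc-y` = b$y, `acc-z` = b$z)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write encounter histories
#'
#' Plain text, one individual per line: a digit string over `0-3`
#' followed by whitespace and the strategy group. Invalid characters are
#' rejected with the offending line number.
#'
#' @param path file path.
#' @param histories tibble with `history` and `group` columns.
#' @return `read_histories`: tibble with `id`, `history`, `group`;
#'   `write_histories`: `path`, invisibly.
#' @export
read_histories <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[[:space:]]+")
  for (i in seq_along(parts)) {
    if (length(parts[[i]]) != 2 || !grepl("^[0-3]+$", parts[[i]][1])) {
      stop(errorCondition(sprintf("invalid encounter history on line %d: '%s'",
                                  i, lines[i]),
                          class = c("ciconia_format_error", "error")))
    }
  }
  tibble::tibble(id = sprintf("ind_%04d", seq_along(parts)),
                 history = vapply(parts, `[[`, character(1), 1),
                 group = vapply(parts, `[[`, character(1), 2))
}

#' @rdname read_histories
#' @export
write_histories <- function(histories, path) {
  writeLines(paste(histories$history, histories$group), path)
  invisible(path)
}

#' Write a pipeline table deterministically
#'
#' CSV writer with fixed column order (as given), no row names, no
#' quoting surprises; byte-stable for identical inputs.
#'
#' @param rows data frame or tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path) {
  df <- as.data.frame(rows)
  for (nm in names(df)) {
    if (inherits(df[[nm]], "POSIXct")) df[[nm]] <- iso8601(df[[nm]])
    if (inherits(df[[nm]], "Date")) df[[nm]] <- format(df[[nm]], "%Y-%m-%d")
  }
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
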