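#' Read an hourly behavior CSV
#'
#' Reads the package's CSV dialect: one row per cow-hour with columns
#' `cow_id`, `timestamp` (ISO-8601, hour resolution), one column per
#' cataloged activity (minutes of that hour), and an optional 0/1 `event`
#' column flagging the hour of the absorbing event. Column matching is
#' case-insensitive.
#'
#' @param path path to the CSV file.
#' @param activities activity catalog; see [default_activities()].
#' @param gap_policy what to do when consecutive timestamps are more than
#'   one hour apart: `"reject"` (default) raises an error, `"fill"`
#'   forward-fills the missing hours with the preceding row's budget.
#' @return A single [behavior_series()] if the file holds one cow, otherwise
#'   a named list of `behavior_series`, one per `cow_id`.
#' @export
read_behavior_csv <- function(path, activities = default_activities(),
                              gap_policy = c("reject", "fill")) {
  gap_policy <- match.arg(gap_policy)
  activities <- activity_catalog(activities)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lc <- tolower(names(df))
  need <- c("cow_id", "timestamp", tolower(activities))
  miss <- setdiff(need, lc)
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  names(df) <- lc
  out <- lapply(split(df, df$cow_id), parse_one_cow,
                activities = activities, gap_policy = gap_policy)
  if (length(out) == 1L) out[[1L]] else out
}

parse_one_cow <- function(df, activities, gap_policy) {
  ts <- as.POSIXct(df$timestamp, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                                  "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M"))
  if (anyNA(ts)) stop("unparseable timestamp(s) for cow ", df$cow_id[1L],
                      call. = FALSE)
  o <- order(ts)
  df <- df[o, , drop = FALSE]
  ts <- ts[o]
  if (anyDuplicated(ts))
    stop("duplicated hour for cow ", df$cow_id[1L], call. = FALSE)
  vals <- as.matrix(df[, tolower(activities), drop = FALSE])
  ev <- if ("event" %in% names(df)) as.integer(df$event) else
    integer(nrow(df))
  steps <- as.numeric(difftime(ts[-1L], ts[-length(ts)], units = "hours"))
  if (length(steps) && any(steps != 1)) {
    if (gap_policy == "reject") {
      g <- which(steps != 1)[1L]
      stop(sprintf("gap in hourly record for cow %s after %s (%g h step)",
                   df$cow_id[1L], format(ts[g], "%Y-%m-%d %H:%M"), steps[g]),
           call. = FALSE)
    }
    full <- seq(ts[1L], ts[length(ts)], by = "hour")
    idx <- findInterval(as.numeric(full), as.numeric(ts))
    vals <- vals[idx, , drop = FALSE]
    ev_full <- integer(length(full))
    ev_full[match(as.numeric(ts), as.numeric(full))] <- ev
    ev <- ev_full
    ts <- full
  }
  event_hour <- if (any(ev == 1L)) which(ev == 1L)[1L] else NULL
  dimnames(vals) <- list(NULL, activities)
  behavior_series(vals, cow_id = df$cow_id[1L], start_time = ts[1L],
                  event_hour = event_hour, activities = activities)
}

#' Write an hourly behavior CSV
#'
#' Inverse of [read_behavior_csv()]; the round trip reproduces the series
#' values exactly.
#'
#' @param series a [behavior_series()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_behavior_csv <- function(series, path) {
  stopifnot(inherits(series, "behavior_series"))
  T_ <- nrow(series$values)
  ev <- integer(T_)
  if (!is.null(series$event_hour)) ev[series$event_hour] <- 1L
  df <- data.frame(
    cow_id = series$cow_id,
    timestamp = format(series$start_time + 3600 * (seq_len(T_) - 1L),
                       "%Y-%m-%dT%H:%M:%S"),
    series$values,
    event = ev,
    check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a state sequence as CSV
#'
#' Two columns: `hour_index` and `state`, plus an `event` flag column when
#' the sequence carries an absorbing-event hour.
#'
#' @param seq a [state_sequence()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_state_csv <- function(seq, path) {
  stopifnot(inherits(seq, "state_sequence"))
  ev <- integer(length(seq$states))
  if (!is.null(seq$event_hour)) ev[seq$event_hour] <- 1L
  df <- data.frame(hour_index = seq_along(seq$states), state = seq$states,
                   event = ev)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a state sequence from CSV
#'
#' @param path CSV written by [write_state_csv()] (columns `hour_index`,
#'   `state`, optional `event`).
#' @param K number of transient states.
#' @return A [state_sequence()].
#' @export
read_state_csv <- function(path, K = length(default_activities())) {
  df <- utils::read.csv(path)
  if (!all(c("hour_index", "state") %in% names(df)))
    stop("state CSV needs columns hour_index and state", call. = FALSE)
  df <- df[order(df$hour_index), , drop = FALSE]
  ev <- if ("event" %in% names(df) && any(df$event == 1L))
    which(df$event == 1L)[1L] else NULL
  state_sequence(df$state, K = K, event_hour = ev)
}
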