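#' Canonical activity catalog
#'
#' The six behavior categories tracked for a periparturient cow, in the
#' canonical state order used by every downstream matrix: feeding (state 1),
#' moving (2), standing in rest (3), lying in rest (4), rumination while
#' lying (5), rumination while standing (6). Minutes of the hour not covered
#' by these six (an implicit "other" category, `60 - rowSums`) are permitted
#' but never form a state.
#'
#' @return Character vector of activity labels; its order defines the state
#'   indices `1..K`.
#' @export
#' @examples
#' default_activities()
default_activities <- function() {
  c("feeding", "moving", "standing_rest", "lying_rest",
    "rumination_lying", "rumination_standing")
}

#' Validate an activity catalog
#'
#' @param activities character vector of activity labels.
#' @return The validated catalog, invisibly usable as-is.
#' @export
activity_catalog <- function(activities = default_activities()) {
  if (!is.character(activities) || length(activities) < 2L)
    stop("activity catalog must be a character vector of length >= 2",
         call. = FALSE)
  if (anyDuplicated(activities))
    stop("activity labels must be unique", call. = FALSE)
  activities
}

#' Hourly behavior series for one cow
#'
#' Container for an hourly multivariate activity budget: a `T x K` matrix of
#' minutes per hour spent in each cataloged activity, plus an optional
#' absorbing-event marker (the hour the cow was moved to the calving pen, or
#' calved, depending on the subsystem).
#'
#' @param values numeric matrix or data frame, `T` rows (hours) by `K`
#'   activity columns. Column names, when present, are matched
#'   (case-insensitively) against `activities` and reordered.
#' @param cow_id identifier for the animal.
#' @param start_time `POSIXct` (or coercible string) timestamp of the first
#'   hour. Defaults to an arbitrary origin; only hour offsets matter.
#' @param event_hour optional integer in `[1, T]`: the hour index at which
#'   the absorbing event (move to pen / calving) was observed.
#' @param activities activity catalog; see [default_activities()].
#' @return An object of class `behavior_series` with elements `cow_id`,
#'   `start_time`, `values` (matrix with activity column names),
#'   `event_hour`, `activities`.
#' @details Invariants enforced: all values nonnegative; each row sums to at
#'   most 60 minutes (slack is unobserved "other" time); `event_hour`, if
#'   given, lies within the series.
#' @export
#' @examples
#' m <- matrix(10, nrow = 3, ncol = 6,
#'             dimnames = list(NULL, default_activities()))
#' behavior_series(m, cow_id = "cow1")
behavior_series <- function(values, cow_id = "cow",
                            start_time = as.POSIXct("2023-01-01 00:00:00",
                                                    tz = "UTC"),
                            event_hour = NULL,
                            activities = default_activities()) {
  activities <- activity_catalog(activities)
  K <- length(activities)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (ncol(values) != K)
    stop(sprintf("expected %d activity columns, got %d", K, ncol(values)),
         call. = FALSE)
  if (!is.null(colnames(values))) {
    idx <- match(tolower(activities), tolower(colnames(values)))
    if (anyNA(idx))
      stop("column names do not match the activity catalog: missing ",
           paste(activities[is.na(idx)], collapse = ", "), call. = FALSE)
    values <- values[, idx, drop = FALSE]
  }
  colnames(values) <- activities
  if (anyNA(values))
    stop("activity minutes contain NA", call. = FALSE)
  neg <- which(apply(values < 0, 1L, any))
  if (length(neg))
    stop(sprintf("negative minutes in row %d", neg[1L]), call. = FALSE)
  rs <- rowSums(values)
  over <- which(rs > 60 + 1e-9)
  if (length(over))
    stop(sprintf("row %d sums to %.6g minutes (> 60)", over[1L], rs[over[1L]]),
         call. = FALSE)
  if (!is.null(event_hour)) {
    event_hour <- as.integer(event_hour)
    if (length(event_hour) != 1L || is.na(event_hour) ||
        event_hour < 1L || event_hour > nrow(values))
      stop("event_hour must be a single integer in [1, T]", call. = FALSE)
  }
  structure(
    list(cow_id = as.character(cow_id)[1L],
         start_time = as.POSIXct(start_time, tz = "UTC"),
         values = values, event_hour = event_hour, activities = activities),
    class = "behavior_series")
}

#' @export
print.behavior_series <- function(x, ...) {
  cat("Hourly behavior series: cow", x$cow_id, "\n")
  cat(sprintf("  %d hours x %d activities, starting %s\n", nrow(x$values),
              length(x$activities), format(x$start_time, "%Y-%m-%d %H:%M")))
  if (!is.null(x$event_hour))
    cat("  absorbing event observed at hour", x$event_hour, "\n")
  invisible(x)
}

#' @export
dim.behavior_series <- function(x) dim(x$values)

#' Per-activity mean and standard deviation
#'
#' The first-moment summary of an activity budget series: the mean and
#' sample standard deviation (denominator `n - 1`) of the minutes spent in
#' each activity per hour. These are the building blocks of the
#' mean-plus-k-SD reference points used for dominant-activity labeling.
#'
#' @param series a [behavior_series()].
#' @return A list with numeric vectors `mean` and `sd`, both named by
#'   activity, each of length `K`.
#' @export
activity_summary <- function(series) {
  stopifnot(inherits(series, "behavior_series"))
  if (nrow(series$values) < 2L)
    stop("need at least 2 hours to compute a standard deviation",
         call. = FALSE)
  list(mean = colMeans(series$values),
       sd = apply(series$values, 2L, stats::sd))
}

#' @export
summary.behavior_series <- function(object, ...) {
  s <- activity_summary(object)
  out <- data.frame(activity = object$activities,
                    mean = unname(s$mean), sd = unname(s$sd))
  class(out) <- c("summary.behavior_series", class(out))
  out
}

#' Plot an activity fluctuation pattern
#'
#' Minutes per hour for one activity across the series, with horizontal
#' reference lines at the activity mean and at mean + k SD (the dominance
#' threshold used for state labeling). Approaching the event, restlessness-
#' associated activities drift upward toward the reference line.
#'
#' @param x a [behavior_series()].
#' @param activity activity label or index to plot.
#' @param k_sd multiplier on the standard deviation for the reference line.
#' @param ... further arguments passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.behavior_series <- function(x, activity = "lying_rest", k_sd = 1, ...) {
  if (is.character(activity)) activity <- match(activity, x$activities)
  stopifnot(!is.na(activity), activity >= 1, activity <= ncol(x$values))
  v <- x$values[, activity]
  s <- activity_summary(x)
  graphics::plot(seq_along(v), v, type = "l", xlab = "hour",
                 ylab = sprintf("%s (min/h)", x$activities[activity]), ...)
  graphics::abline(h = s$mean[activity], lty = 2)
  graphics::abline(h = s$mean[activity] + k_sd * s$sd[activity], lty = 3)
  if (!is.null(x$event_hour)) graphics::abline(v = x$event_hour, col = 2)
  invisible(x)
}
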