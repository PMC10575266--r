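#' Expected-time report
#'
#' Human- and machine-readable summary of an absorption solution: the
#' grand-sum expected time in hours and days, the per-starting-state
#' expected hours, and the absorption probability (always 1 with a single
#' absorbing state — stated explicitly rather than silently assumed).
#'
#' @param solution an [fundamental_solution()] result, or a single number of
#'   hours.
#' @return An object of class `calving_report` (a list with elements
#'   `expected_time_total_hours`, `expected_time_total_days`,
#'   `expected_time_by_start_hours`, `expected_time_p0_hours`,
#'   `absorption_probability`).
#' @export
#' @examples
#' format(expected_times_report(192.57))  # "192.57 hours = 8.02 days"
expected_times_report <- function(solution) {
  if (is.numeric(solution) && length(solution) == 1L) {
    rep <- list(expected_time_total_hours = as.numeric(solution),
                expected_time_total_days = as.numeric(solution) / 24,
                expected_time_by_start_hours = NULL,
                expected_time_p0_hours = NULL,
                absorption_probability = 1)
  } else {
    stopifnot(inherits(solution, "absorption_solution"))
    rep <- list(expected_time_total_hours = solution$expected_time_total,
                expected_time_total_days = solution$expected_time_total / 24,
                expected_time_by_start_hours = solution$expected_time_by_start,
                expected_time_p0_hours = solution$expected_time_p0,
                absorption_probability = solution$absorption_prob)
  }
  structure(rep, class = "calving_report")
}

#' @export
format.calving_report <- function(x, ...) {
  sprintf("%.2f hours = %.2f days",
          x$expected_time_total_hours, x$expected_time_total_days)
}

#' @export
print.calving_report <- function(x, ...) {
  cat("Expected time to absorption (grand sum over starting states):",
      format(x), "\n")
  if (!is.null(x$expected_time_by_start_hours)) {
    cat("Expected hours by starting state:\n")
    print(round(x$expected_time_by_start_hours, 2))
    cat(sprintf("Initial-distribution-weighted mean: %.2f hours\n",
                x$expected_time_p0_hours))
  }
  cat(sprintf(paste0("Absorption probability: %.6f (certain by ",
                     "construction with one absorbing state)\n"),
              x$absorption_probability))
  invisible(x)
}

#' Difference between two expected absorption times
#'
#' The in-pen residence interpretation: subtracting the expected time to
#' the move-to-pen event from the expected time to calving gives the
#' expected hours a cow spends in the pen before calving.
#'
#' @param a,b absorption solutions, reports, fitted `calving_chain` objects,
#'   or plain hour values; the result is `a - b` in hours.
#' @return Difference in hours (numeric scalar).
#' @export
#' @examples
#' expected_time_difference(211.67, 192.57)  # 19.1
expected_time_difference <- function(a, b) {
  as_hours <- function(z) {
    if (is.numeric(z) && length(z) == 1L) return(as.numeric(z))
    if (inherits(z, "calving_chain")) return(z$solution$expected_time_total)
    if (inherits(z, "absorption_solution")) return(z$expected_time_total)
    if (inherits(z, "calving_report")) return(z$expected_time_total_hours)
    stop("cannot interpret input as an expected time in hours",
         call. = FALSE)
  }
  as_hours(a) - as_hours(b)
}

#' Write a report (and optionally the matrices) as JSON
#'
#' @param report a `calving_report` (or object coercible via
#'   [expected_times_report()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  if (!inherits(report, "calving_report"))
    report <- expected_times_report(report)
  out <- list(
    expected_time_total_hours = report$expected_time_total_hours,
    expected_time_total_days = report$expected_time_total_days,
    expected_time_by_start_hours =
      as.list(report$expected_time_by_start_hours),
    absorption_probability = report$absorption_probability)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a labeled matrix as CSV
#'
#' Writes `C`, `P` or the augmented matrix with state labels as header row
#' and first column; the augmented matrix carries `MTC` as its final label.
#'
#' @param m matrix with dimnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(m, path) {
  utils::write.csv(as.data.frame(m), path, row.names = TRUE, quote = FALSE)
  invisible(path)
}
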