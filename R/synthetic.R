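#' Configuration for the synthetic behavior-series generator
#'
#' Describes one emulated periparturient cow. The defaults encode the two
#' study scenarios the package targets:
#'
#' * `"pre_move"` — a 240-hour (10-day) window before the expected due
#'   date, ending with the move to the calving pen. Baseline budgets follow
#'   typical dry-cow time budgets (about 13.5 h/day lying, 7 h/day
#'   ruminating, 3 h/day feeding); a linear restlessness drift transfers
#'   minutes from lying rest and rumination-in-lying toward moving and
#'   standing rest as the event approaches, and the hourly move hazard is
#'   negligible until it ramps up over the final 24 hours.
#' * `"in_pen"` — a 72-hour window starting at pen entry, ending at
#'   calving. The same baseline with the drift compressed into the shorter
#'   horizon, and a calving hazard rising from pen entry so that calving
#'   typically occurs within roughly a day of a well-timed move.
#'
#' @param scenario `"pre_move"` or `"in_pen"`; sets all defaults below.
#' @param horizon_hours length of the generated series.
#' @param baseline_budget expected minutes/hour per activity at hour 1
#'   (length `K`, sum at most 60).
#' @param restlessness_drift per-hour change of the expected budget
#'   (length `K`); applied linearly, clamped at 0 and renormalized so each
#'   hour's expectation stays within 60 minutes.
#' @param dispersion Dirichlet concentration of the hourly compositional
#'   draw; larger is less noisy, `Inf` is noiseless. The draw is
#'   compositional because the six activities compete for the same 60
#'   minutes, which induces the negative covariances the labeling stage's
#'   covariance matrix is built on.
#' @param event_hazard per-hour probability that the absorbing event (move
#'   or calving) fires; vector of length `horizon_hours`.
#' @param activities activity catalog.
#' @return An object of class `synthetic_cow_config`.
#' @export
synthetic_cow_config <- function(scenario = c("pre_move", "in_pen"),
                                 horizon_hours = NULL,
                                 baseline_budget = NULL,
                                 restlessness_drift = NULL,
                                 dispersion = 60,
                                 event_hazard = NULL,
                                 activities = default_activities()) {
  scenario <- match.arg(scenario)
  activities <- activity_catalog(activities)
  K <- length(activities)
  if (is.null(horizon_hours))
    horizon_hours <- if (scenario == "pre_move") 240L else 72L
  horizon_hours <- as.integer(horizon_hours)
  stopifnot(horizon_hours >= 2L)
  if (is.null(baseline_budget))
    baseline_budget <- c(feeding = 8, moving = 4, standing_rest = 8,
                         lying_rest = 22, rumination_lying = 12,
                         rumination_standing = 5)[seq_len(K)]
  if (any(baseline_budget < 0) || sum(baseline_budget) > 60)
    stop("baseline_budget must be nonnegative with sum <= 60 minutes",
         call. = FALSE)
  if (is.null(restlessness_drift))
    restlessness_drift <-
      c(0, 8, 6, -10, -4, 0)[seq_len(K)] / horizon_hours
  if (is.null(event_hazard)) {
    event_hazard <- if (scenario == "pre_move") {
      ramp <- min(24L, horizon_hours)
      c(rep(0.001, horizon_hours - ramp),
        seq(0.01, 0.2, length.out = ramp))
    } else {
      pmin(0.02 + 0.012 * seq_len(horizon_hours), 0.5)
    }
  }
  if (length(event_hazard) == 1L)
    event_hazard <- rep(event_hazard, horizon_hours)
  if (length(event_hazard) != horizon_hours ||
      any(event_hazard < 0) || any(event_hazard > 1))
    stop("event_hazard must be length horizon_hours with entries in [0, 1]",
         call. = FALSE)
  structure(list(scenario = scenario, horizon_hours = horizon_hours,
                 baseline_budget = baseline_budget,
                 restlessness_drift = restlessness_drift,
                 dispersion = dispersion, event_hazard = event_hazard,
                 activities = activities),
            class = "synthetic_cow_config")
}

# round x to integers summing to round(sum(x)) by largest remainder
round_preserving_sum <- function(x) {
  target <- round(sum(x))
  fl <- floor(x)
  rem <- target - sum(fl)
  if (rem > 0) {
    o <- order(x - fl, decreasing = TRUE)
    fl[o[seq_len(rem)]] <- fl[o[seq_len(rem)]] + 1
  }
  fl
}

#' Generate a synthetic hourly behavior series
#'
#' Draws one cow under a [synthetic_cow_config()]. For each hour `t` the
#' expected budget is `baseline + drift * (t - 1)`, clamped at zero and
#' scaled back into the 60-minute hour if needed; the realized minutes are
#' a Dirichlet draw over the `K` activities plus the implicit "other"
#' remainder, scaled to 60 minutes and rounded to integers by
#' largest-remainder apportionment so each row sums to exactly 60. The
#' absorbing event fires at the first hour whose uniform draw falls below
#' the hazard schedule. Deterministic under a fixed seed.
#'
#' @param config a [synthetic_cow_config()].
#' @param seed optional integer seed.
#' @param cow_id identifier for the generated cow.
#' @return A [behavior_series()] of `horizon_hours` rows, with `event_hour`
#'   set when the hazard fired within the horizon.
#' @export
generate_behavior_series <- function(config, seed = NULL,
                                     cow_id = "synthetic_cow") {
  stopifnot(inherits(config, "synthetic_cow_config"))
  if (!is.null(seed)) set.seed(seed)
  K <- length(config$activities)
  T_ <- config$horizon_hours
  vals <- matrix(0, T_, K, dimnames = list(NULL, config$activities))
  for (t in seq_len(T_)) {
    m <- pmax(config$baseline_budget +
                config$restlessness_drift * (t - 1), 0)
    if (sum(m) == 0)
      stop("restlessness_drift drives the whole budget to zero at hour ", t,
           call. = FALSE)
    if (sum(m) > 60) m <- m * (60 / sum(m))
    full <- c(m, 60 - sum(m))          # K activities + implicit "other"
    if (is.finite(config$dispersion)) {
      g <- stats::rgamma(K + 1L, shape = config$dispersion * full / 60)
      if (sum(g) == 0) g <- full       # degenerate draw guard
      mins <- 60 * g / sum(g)
    } else {
      mins <- full
    }
    vals[t, ] <- round_preserving_sum(mins)[seq_len(K)]
  }
  u <- stats::runif(T_)
  fired <- which(u < config$event_hazard)
  event_hour <- if (length(fired)) fired[1L] else NULL
  behavior_series(vals, cow_id = cow_id, event_hour = event_hour,
                  activities = config$activities)
}

#' Generate a cohort of synthetic cows
#'
#' Convenience wrapper drawing `n` independent cows from one configuration,
#' with per-cow seeds derived reproducibly from `seed`. Series are
#' truncated at each cow's event hour (monitoring stops at the move /
#' calving), matching how field data would arrive.
#'
#' @param config a [synthetic_cow_config()].
#' @param n number of cows.
#' @param seed integer seed for the whole cohort.
#' @param truncate_at_event drop hours after the event (default `TRUE`).
#' @return A list of [behavior_series()].
#' @export
generate_cohort <- function(config, n = 10L, seed = 1L,
                            truncate_at_event = TRUE) {
  stopifnot(n >= 1L)
  lapply(seq_len(n), function(i) {
    s <- generate_behavior_series(config,
                                  seed = (seed + i * 9973) %% 2147483647,
                                  cow_id = sprintf("synthetic_cow_%02d", i))
    if (truncate_at_event && !is.null(s$event_hour) &&
        s$event_hour < nrow(s$values) && s$event_hour >= 2L)
      s <- behavior_series(s$values[seq_len(s$event_hour), , drop = FALSE],
                           cow_id = s$cow_id, start_time = s$start_time,
                           event_hour = s$event_hour,
                           activities = s$activities)
    s
  })
}

#' Run the full pipeline on one synthetic cow
#'
#' Generation, dominant-activity labeling, chain estimation, absorbing
#' augmentation and the fundamental-matrix solution in one call, returning
#' every intermediate for inspection and testing.
#'
#' @param config a [synthetic_cow_config()].
#' @param k_sd labeling criterion multiplier (1 = move-time subsystem,
#'   2 = in-pen calving-time subsystem).
#' @param alpha optional manual absorption vector; default estimates it
#'   from the generated event via [estimate_alpha()].
#' @param seed integer seed.
#' @return List with `series`, `states`, `chain` (a `chain_estimate`),
#'   `alpha`, `absorbing` (an `absorbing_chain`) and `solution`.
#' @export
pipeline_fixture <- function(config = synthetic_cow_config(), k_sd = 1,
                             alpha = NULL, seed = 1L) {
  series <- generate_behavior_series(config, seed = seed)
  states <- label_states(series, k_sd = k_sd)
  chain <- estimate_chain(states)
  if (is.null(alpha)) alpha <- estimate_alpha(states)
  absorbing <- augment_chain(chain$P, alpha)
  solution <- fundamental_solution(absorbing)
  list(series = series, states = states, chain = chain, alpha = alpha,
       absorbing = absorbing, solution = solution)
}
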