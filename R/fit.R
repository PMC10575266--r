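#' Fit an absorbing behavior chain to cow activity data
#'
#' The package's front door. Takes hourly activity budgets for one or more
#' cows (or pre-labeled state sequences), labels each hour with its
#' dominant activity by the mean + `k_sd` SD nearest-reference Mahalanobis
#' criterion, pools the consecutive-pair counts into a co-occurrence matrix
#' `C`, row-normalizes to the transition matrix `P`, augments with the
#' absorbing move-to-pen / calving state ("MTC") using per-state absorption
#' probabilities `alpha` (estimated from observed events unless supplied),
#' and solves for the fundamental matrix `N = (I - Q)^-1` and the expected
#' hours to absorption.
#'
#' Use `k_sd = 1` for the move-time subsystem (when should the cow be moved
#' to the pen?) and `k_sd = 2` for the in-pen calving-time subsystem (how
#' long until calving once moved?).
#'
#' @param data a [behavior_series()], a [state_sequence()], or a list of
#'   either (all of one kind).
#' @param k_sd dominance criterion multiplier passed to [label_states()].
#' @param ridge covariance ridge for labeling; see [activity_covariance()].
#' @param alpha manual length-`K` absorption-probability vector; default
#'   `NULL` estimates it from the data's event hours via [estimate_alpha()].
#' @param p0 initial distribution over transient states: `"uniform"`
#'   (default), `"empirical"` (the observed distribution of first states),
#'   or a numeric probability vector of length `K`.
#' @param zero_row policy for unobserved transition origins; see
#'   [transition_matrix()].
#' @return An object of class `calving_chain` with components `states`
#'   (list of state sequences), `C`, `P`, `alpha`, `absorbing`
#'   (the augmented chain), `solution` (the [fundamental_solution()]),
#'   `k_sd`, `p0`, `activities`, `series`, `call`. Methods: `print`,
#'   `summary`, `coef`, `predict`, `simulate`, `plot`.
#' @seealso [expected_times_report()], [expected_time_difference()],
#'   [simulate_absorption_times()]
#' @export
#' @examples
#' cohort <- generate_cohort(synthetic_cow_config(), n = 4, seed = 42)
#' fit <- calving_chain(cohort, k_sd = 1)
#' fit
#' predict(fit)
calving_chain <- function(data, k_sd = 1, ridge = NULL, alpha = NULL,
                          p0 = "uniform",
                          zero_row = c("uniform", "selfloop")) {
  cl <- match.call()
  if (inherits(data, "behavior_series") ||
      inherits(data, "state_sequence")) data <- list(data)
  stopifnot(is.list(data), length(data) >= 1L)
  series <- NULL
  if (all(vapply(data, inherits, logical(1L), "behavior_series"))) {
    series <- data
    seqs <- lapply(data, label_states, k_sd = k_sd, ridge = ridge)
    activities <- data[[1L]]$activities
  } else if (all(vapply(data, inherits, logical(1L), "state_sequence"))) {
    seqs <- data
    activities <- seqs[[1L]]$activities
  } else {
    stop("data must be behavior series or state sequences (not a mix)",
         call. = FALSE)
  }
  K <- seqs[[1L]]$K
  est <- estimate_chain(seqs, K = K, zero_row = zero_row)
  if (is.null(alpha)) alpha <- estimate_alpha(seqs, K = K)
  absorbing <- augment_chain(est$P, alpha)
  if (is.character(p0)) {
    p0 <- match.arg(p0, c("uniform", "empirical"))
    p0 <- if (p0 == "uniform") rep(1 / K, K) else {
      first <- vapply(seqs, function(s) s$states[1L], integer(1L))
      tabulate(first, nbins = K) / length(first)
    }
  }
  solution <- fundamental_solution(absorbing, p0 = p0)
  structure(
    list(states = seqs, C = est$C, P = est$P, zero_rows = est$zero_rows,
         alpha = absorbing$alpha, absorbing = absorbing,
         solution = solution, k_sd = k_sd, p0 = p0,
         activities = activities, series = series, call = cl),
    class = "calving_chain")
}

#' @export
print.calving_chain <- function(x, ...) {
  cat("Absorbing behavior chain fit",
      sprintf("(dominance criterion: mean + %g SD)\n", x$k_sd))
  cat(sprintf("  %d sequence(s), %d transitions, %d transient states + MTC\n",
              length(x$states), sum(x$C), ncol(x$P)))
  cat("  Expected time to absorption:",
      format(expected_times_report(x$solution)), "\n")
  invisible(x)
}

#' @rdname calving_chain
#' @param object,x a fitted `calving_chain`.
#' @param ... unused.
#' @export
summary.calving_chain <- function(object, ...) {
  structure(list(fit = object,
                 report = expected_times_report(object$solution)),
            class = "summary.calving_chain")
}

#' @export
print.summary.calving_chain <- function(x, ...) {
  print(x$fit)
  cat("\nCo-occurrence counts C:\n")
  print(x$fit$C)
  cat("\nTransition matrix P:\n")
  print(round(x$fit$P, 3))
  cat("\nAbsorption probabilities alpha:\n")
  print(signif(x$fit$alpha, 4))
  cat("\n")
  print(x$report)
  invisible(x)
}

#' @rdname calving_chain
#' @param type which coefficients: the transition matrix `P`
#'   (`"transition"`), the augmented matrix `A` (`"augmented"`), or the
#'   absorption vector (`"absorption"`).
#' @export
coef.calving_chain <- function(object,
                               type = c("transition", "augmented",
                                        "absorption"), ...) {
  switch(match.arg(type),
         transition = object$P,
         augmented = object$absorbing$A,
         absorption = object$alpha)
}

#' Predict expected hours to absorption
#'
#' @param object a fitted [calving_chain()].
#' @param from starting state(s) as indices or labels, a probability
#'   vector over the `K` transient states, or `NULL` (default) for the
#'   fit's initial distribution `p0`.
#' @param units `"hours"` or `"days"`.
#' @param ... unused.
#' @return Expected time(s) to the absorbing event, numeric.
#' @export
predict.calving_chain <- function(object, from = NULL,
                                  units = c("hours", "days"), ...) {
  units <- match.arg(units)
  by_start <- object$solution$expected_time_by_start
  K <- length(by_start)
  out <- if (is.null(from)) {
    drop(object$p0 %*% by_start)
  } else if (is.character(from)) {
    idx <- match(from, object$activities)
    if (anyNA(idx)) idx <- match(from, names(by_start))
    if (anyNA(idx)) stop("unknown starting state label", call. = FALSE)
    by_start[idx]
  } else if (length(from) == K && all(from >= 0) &&
             abs(sum(from) - 1) < 1e-9 && !all(from %in% c(0, 1))) {
    drop(as.numeric(from) %*% by_start)
  } else {
    by_start[as.integer(from)]
  }
  if (units == "days") out / 24 else out
}

#' Simulate absorption times from a fitted chain
#'
#' Monte Carlo draws of the hours-to-event under the fitted augmented
#' chain, starting from the fit's initial distribution.
#'
#' @param object a fitted [calving_chain()].
#' @param nsim number of simulated trajectories.
#' @param seed optional integer seed.
#' @param max_steps trajectory cap; see [simulate_absorption_times()].
#' @param ... unused.
#' @return Numeric vector of simulated absorption times (hours); censored
#'   draws, if any, are dropped with a warning.
#' @export
simulate.calving_chain <- function(object, nsim = 1, seed = NULL,
                                   max_steps = 100000L, ...) {
  simulate_absorption_times(object$absorbing, n = nsim, p0 = object$p0,
                            max_steps = max_steps, seed = seed)$times
}

#' @rdname calving_chain
#' @param activity activity to display; see [plot.behavior_series()].
#' @export
plot.calving_chain <- function(x, activity = "lying_rest", ...) {
  if (is.null(x$series))
    stop("fit was built from state sequences; no activity series to plot",
         call. = FALSE)
  plot(x$series[[1L]], activity = activity, k_sd = x$k_sd, ...)
}
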