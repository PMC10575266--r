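#' Ridge-regularized activity covariance matrix
#'
#' Sample covariance of the hourly activity budget (denominator `n - 1`),
#' plus `ridge` times the identity. Activity budgets are compositional —
#' the six columns compete for the same 60 minutes — so the raw covariance
#' is frequently near-singular; a small ridge restores invertibility
#' without materially changing distances.
#'
#' @param series a [behavior_series()] or a plain numeric matrix of hourly
#'   budgets.
#' @param ridge nonnegative regularization added to the diagonal. The
#'   default `NULL` uses `1e-6 * mean(diag(S))` where `S` is the raw sample
#'   covariance.
#' @return A `K x K` symmetric positive-definite matrix (verified by
#'   Cholesky factorization).
#' @export
activity_covariance <- function(series, ridge = NULL) {
  x <- if (inherits(series, "behavior_series")) series$values else
    as.matrix(series)
  if (nrow(x) < 2L)
    stop("need at least 2 hours to estimate a covariance", call. = FALSE)
  S <- stats::cov(x)
  if (is.null(ridge)) {
    base <- mean(diag(S))
    # zero-variance series (e.g. two identical hours) fall back to an
    # absolute ridge so distances are defined (and all equal)
    ridge <- if (base > 0) 1e-6 * base else 1e-6
  }
  if (ridge < 0) stop("ridge must be nonnegative", call. = FALSE)
  S <- S + diag(ridge, ncol(S))
  ok <- tryCatch({ chol(S); TRUE }, error = function(e) FALSE)
  if (!ok)
    stop("covariance matrix is singular even after ridge regularization; ",
         "increase `ridge` (the activity columns are collinear)",
         call. = FALSE)
  S
}

#' Squared Mahalanobis distance between two vectors
#'
#' The quadratic form `(x - y)' Sigma^-1 (x - y)`. The squared form is used
#' throughout: dominant-activity labeling takes an argmin, which the
#' monotone square root cannot change.
#'
#' @param x,y numeric vectors of equal length `K`.
#' @param sigma invertible `K x K` covariance matrix.
#' @return A single nonnegative number; zero iff `x == y`.
#' @export
#' @examples
#' mahalanobis_sq(c(3, 4), c(0, 0), diag(2))  # 25
mahalanobis_sq <- function(x, y, sigma) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y))
    stop("x and y must have the same length", call. = FALSE)
  sigma <- as.matrix(sigma)
  if (nrow(sigma) != length(x) || ncol(sigma) != length(x))
    stop("sigma must be K x K with K = length(x)", call. = FALSE)
  d <- x - y
  drop(crossprod(d, solve(sigma, d)))
}

#' Dominant-activity state sequence
#'
#' @param states integer vector of state labels in `1..K`.
#' @param K number of transient states.
#' @param event_hour optional hour index of the absorbing event.
#' @param activities optional activity labels (length `K`).
#' @return An object of class `state_sequence`.
#' @export
state_sequence <- function(states, K, event_hour = NULL, activities = NULL) {
  states <- as.integer(states)
  if (anyNA(states) || any(states < 1L) || any(states > K))
    stop("states must be integers in [1, K]", call. = FALSE)
  if (!is.null(event_hour)) {
    event_hour <- as.integer(event_hour)
    if (event_hour < 1L || event_hour > length(states))
      stop("event_hour outside the sequence", call. = FALSE)
  }
  structure(list(states = states, K = as.integer(K),
                 event_hour = event_hour, activities = activities),
            class = "state_sequence")
}

#' @export
print.state_sequence <- function(x, ...) {
  cat(sprintf("State sequence: %d hours, %d states\n", length(x$states), x$K))
  show <- utils::head(x$states, 20L)
  cat(" ", paste0("s", show, collapse = " "),
      if (length(x$states) > 20L) "...", "\n")
  if (!is.null(x$event_hour))
    cat("  absorbing event at hour", x$event_hour, "\n")
  invisible(x)
}

#' @export
length.state_sequence <- function(x) length(x$states)

#' Label each hour with its dominant activity
#'
#' Converts an hourly activity budget into a state sequence. For each
#' activity `j` a reference point `r_j` is built: the activity-mean vector
#' with the j-th component raised to `mean_j + k_sd * sd_j` (the dominance
#' threshold). Hour `t` is labeled with the state whose reference point is
#' nearest under squared Mahalanobis distance; ties go to the lowest state
#' index, so labeling is deterministic.
#'
#' `k_sd = 1` is the move-to-pen criterion, `k_sd = 2` the stricter
#' imminent-calving criterion used once the cow is in the pen.
#'
#' @param series a [behavior_series()].
#' @param k_sd positive multiplier on the per-activity standard deviation.
#' @param ridge covariance ridge, passed to [activity_covariance()].
#' @param sigma optional pre-computed (e.g. pooled across cows) covariance
#'   matrix; overrides the per-series estimate.
#' @return A [state_sequence()] of the same length as the series, carrying
#'   the series' `event_hour`. Attributes `mean`, `sd` and `sigma` record
#'   the labeling statistics.
#' @export
label_states <- function(series, k_sd = 1, ridge = NULL, sigma = NULL) {
  stopifnot(inherits(series, "behavior_series"))
  if (k_sd <= 0) stop("k_sd must be positive", call. = FALSE)
  s <- activity_summary(series)
  if (is.null(sigma)) sigma <- activity_covariance(series, ridge = ridge)
  K <- length(series$activities)
  refs <- matrix(s$mean, nrow = K, ncol = K, byrow = TRUE)
  diag(refs) <- s$mean + k_sd * s$sd
  Sinv <- chol2inv(chol(sigma))
  X <- series$values
  md <- matrix(NA_real_, nrow = nrow(X), ncol = K)
  for (j in seq_len(K)) {
    E <- sweep(X, 2L, refs[j, ])
    md[, j] <- rowSums((E %*% Sinv) * E)
  }
  states <- max.col(-md, ties.method = "first")
  out <- state_sequence(states, K = K, event_hour = series$event_hour,
                        activities = series$activities)
  attr(out, "mean") <- s$mean
  attr(out, "sd") <- s$sd
  attr(out, "sigma") <- sigma
  out
}
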