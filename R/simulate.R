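#' Monte Carlo absorption times
#'
#' Simulates independent discrete-time walks on the augmented matrix `A`:
#' each replicate starts from a state drawn from `p0` over the transient
#' states and steps hourly until the absorbing state is entered; the hitting
#' time (number of steps) is recorded. This is the independent cross-check
#' of the fundamental-matrix solution, not a replacement for it.
#'
#' Replicates still transient after `max_steps` steps are counted as
#' censored, reported, and excluded from the mean with a warning; censored
#' plus uncensored always equals `n`.
#'
#' @param chain an [augment_chain()] result.
#' @param n number of replicates.
#' @param p0 initial distribution over transient states; default uniform.
#' @param max_steps cap on trajectory length (hours).
#' @param seed optional integer seed for reproducibility.
#' @return List with `times` (uncensored hitting times, hours), `n`,
#'   `n_censored`, `mean`, `se` (standard error of the mean).
#' @export
simulate_absorption_times <- function(chain, n = 10000L, p0 = NULL,
                                      max_steps = 100000L, seed = NULL) {
  stopifnot(inherits(chain, "absorbing_chain"), n >= 1L, max_steps >= 1L)
  if (!is.null(seed)) set.seed(seed)
  K <- chain$K
  if (is.null(p0)) p0 <- rep(1 / K, K)
  if (length(p0) != K || any(p0 < 0) || abs(sum(p0) - 1) > 1e-9)
    stop("p0 must be a probability distribution over the transient states",
         call. = FALSE)
  # cumulative transition law per transient state, absorbing column last
  cum <- t(apply(chain$A[seq_len(K), , drop = FALSE], 1L, cumsum))
  state <- sample.int(K, n, replace = TRUE, prob = p0)
  time <- integer(n)
  active <- seq_len(n)
  step <- 0L
  while (length(active) && step < max_steps) {
    step <- step + 1L
    u <- stats::runif(length(active))
    cur <- state[active]
    nxt <- integer(length(active))
    for (i in seq_len(K)) {
      sel <- cur == i
      if (any(sel))
        nxt[sel] <- findInterval(u[sel], cum[i, ], left.open = TRUE) + 1L
    }
    absorbed <- nxt == K + 1L
    time[active[absorbed]] <- step
    state[active[!absorbed]] <- nxt[!absorbed]
    active <- active[!absorbed]
  }
  n_censored <- length(active)
  times <- time[time > 0L]
  if (n_censored == n)
    stop("all replicates censored at max_steps; increase max_steps",
         call. = FALSE)
  if (n_censored > 0L)
    warning(sprintf("%d of %d replicates censored at max_steps = %d and excluded from the mean",
                    n_censored, n, max_steps), call. = FALSE)
  list(times = as.numeric(times), n = as.integer(n),
       n_censored = as.integer(n_censored),
       mean = mean(times),
       se = stats::sd(times) / sqrt(length(times)))
}

#' Simulate a state sequence from a transition matrix
#'
#' Draws a length-`n` realization of the discrete-time chain with
#' row-stochastic transition matrix `P` (no absorbing state). Used for
#' parameter-recovery checks: a long simulated sequence re-estimated with
#' [estimate_chain()] should recover `P`.
#'
#' @param P row-stochastic `K x K` matrix.
#' @param n sequence length.
#' @param init initial state (integer) or distribution; default uniform.
#' @param seed optional integer seed.
#' @return A [state_sequence()] of length `n`.
#' @export
simulate_markov_sequence <- function(P, n, init = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  P <- as.matrix(P)
  K <- nrow(P)
  stopifnot(ncol(P) == K, n >= 1L)
  if (max(abs(rowSums(P) - 1)) > 1e-9)
    stop("P must be row-stochastic", call. = FALSE)
  s <- integer(n)
  s[1L] <- if (is.null(init)) sample.int(K, 1L)
           else if (length(init) == 1L) as.integer(init)
           else sample.int(K, 1L, prob = init)
  for (t in seq_len(n - 1L))
    s[t + 1L] <- sample.int(K, 1L, prob = P[s[t], ])
  state_sequence(s, K = K)
}
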