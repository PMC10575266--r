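#' Co-occurrence matrix of consecutive state pairs
#'
#' Counts ordered consecutive pairs `(s_t, s_{t+1})` in one or several state
#' sequences; `C[i, j]` is the number of hours in state `i` followed
#' immediately by state `j`. For a single uninterrupted sequence of length
#' `T`, `sum(C) == T - 1`.
#'
#' @param seqs a [state_sequence()] or a list of them (counts are pooled).
#' @param K number of states; defaults to the sequences' own `K`.
#' @return A `K x K` integer matrix with state labels `s1..sK` on both
#'   dimensions.
#' @export
#' @examples
#' sq <- state_sequence(c(1, 1, 3, 5, 4, 4, 1, 6), K = 6)
#' state_cooccurrence(sq)
state_cooccurrence <- function(seqs, K = NULL) {
  if (inherits(seqs, "state_sequence")) seqs <- list(seqs)
  stopifnot(length(seqs) >= 1L,
            all(vapply(seqs, inherits, logical(1L), "state_sequence")))
  if (is.null(K)) K <- max(vapply(seqs, function(s) s$K, integer(1L)))
  C <- matrix(0L, K, K)
  for (sq in seqs) {
    s <- sq$states
    if (length(s) < 2L)
      stop("a state sequence must have length >= 2 to count transitions",
           call. = FALSE)
    C <- C + unclass(table(factor(s[-length(s)], levels = seq_len(K)),
                           factor(s[-1L], levels = seq_len(K))))
  }
  storage.mode(C) <- "integer"
  dimnames(C) <- list(paste0("s", seq_len(K)), paste0("s", seq_len(K)))
  C
}

#' Row-normalize a co-occurrence matrix into a transition matrix
#'
#' `P[i, j] = C[i, j] / sum_j C[i, j]`. States never observed as a
#' transition origin (all-zero rows of `C`) carry no information; by
#' default they are given a uniform row `1/K` (with a warning and a
#' `zero_rows` attribute), or a self-loop row under
#' `zero_row = "selfloop"`.
#'
#' @param C nonnegative `K x K` count matrix.
#' @param zero_row policy for all-zero rows: `"uniform"` (default) or
#'   `"selfloop"`.
#' @return A row-stochastic `K x K` matrix with attribute `zero_rows`
#'   listing the patched row indices (possibly empty).
#' @export
transition_matrix <- function(C, zero_row = c("uniform", "selfloop")) {
  zero_row <- match.arg(zero_row)
  C <- as.matrix(C)
  if (any(C < 0)) stop("co-occurrence counts must be nonnegative",
                       call. = FALSE)
  K <- nrow(C)
  rs <- rowSums(C)
  zr <- unname(which(rs == 0))
  P <- C / ifelse(rs == 0, 1, rs)
  if (length(zr)) {
    warning(sprintf("state(s) %s never observed as transition origin; using %s row(s)",
                    paste(rownames(C)[zr], collapse = ", "), zero_row),
            call. = FALSE)
    for (i in zr)
      P[i, ] <- if (zero_row == "uniform") rep(1 / K, K) else
        replace(numeric(K), i, 1)
  }
  dimnames(P) <- dimnames(C)
  structure(P, zero_rows = zr)
}

#' Estimate the behavior chain from state sequences
#'
#' Convenience wrapper: pooled co-occurrence counts plus the row-stochastic
#' transition matrix.
#'
#' @inheritParams state_cooccurrence
#' @inheritParams transition_matrix
#' @return An object of class `chain_estimate`: list with `C`, `P`,
#'   `zero_rows`, `K`.
#' @export
estimate_chain <- function(seqs, K = NULL,
                           zero_row = c("uniform", "selfloop")) {
  C <- state_cooccurrence(seqs, K = K)
  P <- transition_matrix(C, zero_row = zero_row)
  structure(list(C = C, P = structure(P, zero_rows = NULL),
                 zero_rows = attr(P, "zero_rows"), K = nrow(C)),
            class = "chain_estimate")
}

#' @export
print.chain_estimate <- function(x, ...) {
  cat(sprintf("Behavior chain estimate: %d states, %d transitions observed\n",
              x$K, sum(x$C)))
  print(round(x$P, 3))
  invisible(x)
}

#' Per-state absorption probabilities from observed events
#'
#' Exposure-based estimate of the hourly probability that the absorbing
#' event (move to pen / calving) fires from each behavior state:
#' `alpha_i = events observed in state i / hours spent in state i`. States
#' never visited receive the pooled event rate (total events over total
#' hours). Estimates are clipped to `[eps, 1 - eps]` so the augmented chain
#' keeps every transient row substochastic.
#'
#' @param seqs a [state_sequence()] or list of them; at least one must carry
#'   an `event_hour`.
#' @param K number of states.
#' @param eps clipping bound, default `1e-6`.
#' @return Numeric vector `alpha` of length `K`, named `s1..sK`.
#' @export
estimate_alpha <- function(seqs, K = NULL, eps = 1e-6) {
  if (inherits(seqs, "state_sequence")) seqs <- list(seqs)
  if (is.null(K)) K <- max(vapply(seqs, function(s) s$K, integer(1L)))
  exposure <- numeric(K)
  events <- numeric(K)
  for (sq in seqs) {
    exposure <- exposure + tabulate(sq$states, nbins = K)
    if (!is.null(sq$event_hour))
      events[sq$states[sq$event_hour]] <-
        events[sq$states[sq$event_hour]] + 1
  }
  if (sum(events) == 0)
    stop("no absorbing events observed in any sequence; supply alpha ",
         "manually", call. = FALSE)
  pooled <- sum(events) / sum(exposure)
  alpha <- ifelse(exposure > 0, events / exposure, pooled)
  alpha <- pmin(pmax(alpha, eps), 1 - eps)
  names(alpha) <- paste0("s", seq_len(K))
  alpha
}

#' Augment a transition matrix with the absorbing move-to-pen state
#'
#' Builds the `(K+1) x (K+1)` augmented matrix `A`: transient rows are the
#' original transition probabilities rescaled by `1 - alpha_i` with
#' `alpha_i` placed in the final ("MTC", moved-to-calving-pen) column; the
#' final row is the unit vector on the absorbing state. Proportional
#' rescaling preserves the relative structure of the observed behavior
#' transitions while making every row sum exactly 1.
#'
#' @param P row-stochastic `K x K` matrix (or a `chain_estimate`).
#' @param alpha length-`K` vector of per-state absorption probabilities,
#'   each in `[0, 1)`, at least one positive.
#' @return An object of class `absorbing_chain`: list with the augmented
#'   matrix `A`, the transient block `Q`, absorption column `R`, `alpha`,
#'   and `K`. The spectral radius of `Q` is verified to be below 1 so
#'   absorption is certain from every state.
#' @export
#' @examples
#' augment_chain(matrix(1), alpha = 0.5)$A
augment_chain <- function(P, alpha) {
  if (inherits(P, "chain_estimate")) P <- P$P
  P <- as.matrix(P)
  K <- nrow(P)
  stopifnot(ncol(P) == K)
  if (max(abs(rowSums(P) - 1)) > 1e-9)
    stop("P must be row-stochastic", call. = FALSE)
  alpha <- as.numeric(alpha)
  if (length(alpha) != K)
    stop("alpha must have length K = ", K, call. = FALSE)
  if (any(alpha < 0) || any(alpha >= 1))
    stop("alpha entries must lie in [0, 1)", call. = FALSE)
  if (all(alpha == 0))
    stop("all alpha are zero: the absorbing state is unreachable",
         call. = FALSE)
  A <- matrix(0, K + 1L, K + 1L)
  A[seq_len(K), seq_len(K)] <- (1 - alpha) * P
  A[seq_len(K), K + 1L] <- alpha
  A[K + 1L, K + 1L] <- 1
  labs <- c(if (!is.null(rownames(P))) rownames(P) else
    paste0("s", seq_len(K)), "MTC")
  dimnames(A) <- list(labs, labs)
  Q <- A[seq_len(K), seq_len(K), drop = FALSE]
  sr <- max(abs(eigen(Q, only.values = TRUE)$values))
  if (sr >= 1 - 1e-12)
    stop(sprintf("spectral radius of Q is %.6f; absorption not certain", sr),
         call. = FALSE)
  if (max(abs(rowSums(A) - 1)) > 1e-12)
    stop("internal error: augmented rows do not sum to 1", call. = FALSE)
  structure(list(A = A, Q = Q, R = A[seq_len(K), K + 1L], alpha = alpha,
                 K = K, spectral_radius = sr),
            class = "absorbing_chain")
}

#' @export
print.absorbing_chain <- function(x, ...) {
  cat(sprintf("Absorbing behavior chain: %d transient states + MTC\n", x$K))
  print(round(x$A, 3))
  invisible(x)
}

#' Fundamental-matrix solution of the absorbing chain
#'
#' Computes the fundamental matrix `N = (I - Q)^-1` by a linear solve.
#' `N[i, j]` is the expected number of hours spent in state `j` before
#' absorption when starting in state `i`; row sums are therefore the
#' expected hours to absorption by starting state. Two aggregate
#' conventions are reported: the grand sum of all entries of `N` (the
#' headline expected-time figure, equal to the sum over starting states of
#' the per-start expectations) and the initial-distribution-weighted mean
#' `p0' N 1`. With a single absorbing state, absorption is certain:
#' `N R = 1` elementwise and the absorption probability `p0' N R` is 1 for
#' every stochastic `p0` — this is verified, not assumed.
#'
#' @param chain an [augment_chain()] result.
#' @param p0 initial distribution over the transient states; default
#'   uniform.
#' @return An object of class `absorption_solution`: `N`,
#'   `expected_time_by_start` (row sums, hours), `expected_time_total`
#'   (grand sum, hours), `expected_time_p0` (p0-weighted mean, hours),
#'   `absorption_prob`, `p0`.
#' @export
fundamental_solution <- function(chain, p0 = NULL) {
  stopifnot(inherits(chain, "absorbing_chain"))
  K <- chain$K
  if (is.null(p0)) p0 <- rep(1 / K, K)
  p0 <- as.numeric(p0)
  if (length(p0) != K || any(p0 < 0) || abs(sum(p0) - 1) > 1e-9)
    stop("p0 must be a probability distribution over the K transient states",
         call. = FALSE)
  IQ <- diag(K) - chain$Q
  N <- tryCatch(solve(IQ), error = function(e) {
    near <- which(rowSums(chain$Q) > 1 - 1e-10)
    stop(sprintf("(I - Q) is numerically singular; near-recurrent state(s): %s",
                 paste(rownames(chain$Q)[near], collapse = ", ")),
         call. = FALSE)
  })
  dimnames(N) <- dimnames(chain$Q)
  by_start <- rowSums(N)
  NR <- drop(N %*% chain$R)
  if (max(abs(NR - 1)) > 1e-9)
    stop("absorption not certain: N R deviates from the all-ones vector",
         call. = FALSE)
  structure(
    list(N = N,
         expected_time_by_start = by_start,
         expected_time_total = sum(N),
         expected_time_p0 = drop(p0 %*% by_start),
         absorption_prob = drop(p0 %*% NR),
         p0 = p0),
    class = "absorption_solution")
}

#' @export
print.absorption_solution <- function(x, ...) {
  print(expected_times_report(x))
  invisible(x)
}
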