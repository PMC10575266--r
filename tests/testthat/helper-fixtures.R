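# shared fixture builders; all randomness is locally seeded

acts <- default_activities()

# T x 6 series from a list/matrix of rows; pads unspecified activities with 0
make_series <- function(rows, event_hour = NULL) {
  m <- do.call(rbind, rows)
  colnames(m) <- acts[seq_len(ncol(m))]
  if (ncol(m) < 6L) {
    m <- cbind(m, matrix(0, nrow(m), 6L - ncol(m)))
    colnames(m) <- acts
  }
  behavior_series(m, cow_id = "fix", event_hour = event_hour)
}

# random row-stochastic K x K matrix
random_stochastic <- function(K = 6L, seed = 1L) {
  set.seed(seed)
  P <- matrix(stats::rgamma(K * K, shape = 1), K, K)
  P / rowSums(P)
}

# random absorbing chain with alpha drawn in [lo, hi]
random_absorbing <- function(K = 6L, seed = 1L, lo = 0.05, hi = 0.3) {
  P <- random_stochastic(K, seed)
  set.seed(seed + 7L)
  augment_chain(P, alpha = stats::runif(K, lo, hi))
}

# low-noise series whose hours are clustered around per-activity levels,
# with enough spread to give a well-conditioned covariance
noisy_series <- function(T_ = 50L, seed = 1L, event_hour = NULL) {
  set.seed(seed)
  base <- c(6, 5, 7, 10, 8, 6)  # sums to 42; +-3 noise keeps rows within 60
  m <- t(replicate(T_, pmax(base + sample(-3:3, 6, replace = TRUE), 0)))
  colnames(m) <- acts
  behavior_series(m, cow_id = "noisy", event_hour = event_hour)
}
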