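test_that("co-occurrence counts of the worked dominant-activity sequence", {
  sq <- state_sequence(c(1, 1, 3, 5, 4, 4, 1, 6), K = 6)
  C <- state_cooccurrence(sq)

  # independent brute-force pair count
  oracle <- matrix(0L, 6, 6)
  s <- sq$states
  for (t in seq_len(length(s) - 1L))
    oracle[s[t], s[t + 1L]] <- oracle[s[t], s[t + 1L]] + 1L
  expect_equal(unname(unclass(C)), oracle)

  # the seven unit counts, spelled out
  expect_identical(C["s1", "s1"], 1L)
  expect_identical(C["s1", "s3"], 1L)
  expect_identical(C["s3", "s5"], 1L)
  expect_identical(C["s5", "s4"], 1L)
  expect_identical(C["s4", "s4"], 1L)
  expect_identical(C["s4", "s1"], 1L)
  expect_identical(C["s1", "s6"], 1L)
  expect_identical(sum(C), 7L)
})

test_that("transition matrix row-normalizes and patches zero rows", {
  sq <- state_sequence(c(1, 1, 1, 1), K = 2)
  C <- state_cooccurrence(sq, K = 2)
  expect_equal(unname(C[1, ]), c(3L, 0L))
  expect_warning(P <- transition_matrix(C), "never observed")
  expect_equal(unname(P[1, ]), c(1, 0))
  expect_equal(unname(P[2, ]), c(0.5, 0.5))
  expect_identical(attr(P, "zero_rows"), 2L)

  self <- suppressWarnings(transition_matrix(C, zero_row = "selfloop"))
  expect_equal(unname(self[2, ]), c(0, 1))

  set.seed(31)
  sq6 <- state_sequence(sample.int(6, 300, replace = TRUE), K = 6)
  P6 <- transition_matrix(state_cooccurrence(sq6))
  expect_equal(unname(rowSums(P6)), rep(1, 6), tolerance = 1e-12)
  expect_error(state_cooccurrence(state_sequence(1, K = 6)), "length >= 2")
})

test_that("augmentation rescales rows and keeps the chain stochastic", {
  ch <- augment_chain(matrix(1), alpha = 0.5)
  expect_equal(unname(ch$A), rbind(c(0.5, 0.5), c(0, 1)))

  P <- random_stochastic(6, seed = 2)
  set.seed(3)
  a <- runif(6, 0.01, 0.4)
  ch6 <- augment_chain(P, a)
  expect_equal(unname(rowSums(ch6$A)), rep(1, 7), tolerance = 1e-12)
  expect_equal(unname(ch6$A[7, ]), c(rep(0, 6), 1))
  expect_equal(unname(ch6$Q), unname(ch6$A[1:6, 1:6]))
  expect_equal(unname(ch6$R), unname(ch6$A[1:6, 7]))

  # one zero alpha with an irreducible P still reaches absorption
  a0 <- a; a0[4] <- 0
  ch0 <- augment_chain(P, a0)
  # independent power-iteration bound on the spectral radius
  v <- rep(1, 6)
  for (i in 1:200) { v <- ch0$Q %*% v; v <- v / max(v) }
  lam <- max((ch0$Q %*% v) / v)
  expect_lt(lam, 1)
  expect_equal(ch0$spectral_radius, lam, tolerance = 1e-6)

  expect_error(augment_chain(P, rep(0, 6)), "unreachable")
  expect_error(augment_chain(P, c(1, a[-1])), "\\[0, 1\\)")
  expect_error(augment_chain(matrix(2), alpha = 0.5), "row-stochastic")
})

test_that("alpha is estimated from event exposure with pooling and clipping", {
  # single cow, 10 hours all in state 2, event fires at the last hour
  sq <- state_sequence(rep(2, 10), K = 6, event_hour = 10)
  a <- estimate_alpha(sq)
  expect_equal(unname(a[2]), 1 / 10)
  expect_equal(unname(a[1]), 1 / 10)  # unvisited states get the pooled rate
  expect_equal(unname(a[6]), 1 / 10)

  # two cows, events from states 1 and 3; hand-tallied exposures
  s1 <- state_sequence(c(1, 2, 1, 1, 2), K = 3, event_hour = 4)  # ends in 1
  s2 <- state_sequence(c(3, 3, 2, 3), K = 3, event_hour = 4)     # ends in 3
  a2 <- estimate_alpha(list(s1, s2), K = 3)
  expect_equal(unname(a2), c(1 / 3, 1e-6, 1 / 3))  # state 2: 0 events / 3 h

  # a state absorbed on its only visit clips to 1 - eps, never exactly 1
  s3 <- state_sequence(c(2, 2, 1), K = 2, event_hour = 3)
  a3 <- estimate_alpha(s3)
  expect_equal(unname(a3[1]), 1 - 1e-6)

  expect_error(estimate_alpha(state_sequence(c(1, 2), K = 2)), "no absorbing")
})

test_that("fundamental matrix solves the closed forms", {
  # single transient state: geometric absorption, N = 1 / (1 - q)
  ch <- augment_chain(matrix(1), alpha = 0.5)
  sol <- fundamental_solution(ch)
  expect_equal(unname(sol$N), matrix(2))
  expect_equal(sol$expected_time_total, 2)

  # hand-inverted 2x2: Q = [[0, .5], [0, 0]] arises from P = [[0,1],[0,1]]
  # with alpha = (.5, 1 - 1e-6); check N against the exact inverse
  P2 <- rbind(c(0, 1), c(0, 1))
  ch2 <- augment_chain(P2, c(0.5, 1 - 1e-6))
  sol2 <- fundamental_solution(ch2)
  expect_equal(unname(sol2$N), rbind(c(1, 0.5), c(0, 1)), tolerance = 1e-5)
  expect_equal(sol2$expected_time_total, 2.5, tolerance = 1e-5)
  expect_equal(sol2$expected_time_total, sum(sol2$expected_time_by_start))
})

test_that("solution agrees with a truncated Neumann-series oracle", {
  for (seed in 1:4) {
    ch <- random_absorbing(6, seed = seed, lo = 0.1, hi = 0.4)
    sol <- fundamental_solution(ch)
    Nsum <- diag(6); Qp <- diag(6)
    for (t in 1:300) { Qp <- Qp %*% ch$Q; Nsum <- Nsum + Qp }
    expect_equal(unname(sol$N), unname(Nsum), tolerance = 1e-8)
  }
})

test_that("raising every absorption probability shortens every expected time", {
  P <- random_stochastic(6, seed = 13)
  set.seed(14)
  a <- runif(6, 0.05, 0.2)
  t1 <- fundamental_solution(augment_chain(P, a))$expected_time_by_start
  t2 <- fundamental_solution(augment_chain(P, a * 1.5))$expected_time_by_start
  expect_true(all(t2 < t1))
})

test_that("a near-recurrent chain is reported by name", {
  P <- diag(6)  # pure self-loops
  a <- c(1e-14, rep(1e-14, 5))
  expect_error(augment_chain(P, a), "spectral radius")
})

test_that("a long simulated sequence recovers its transition matrix", {
  P <- random_stochastic(6, seed = 99)
  sq <- simulate_markov_sequence(P, n = 10000, seed = 7)
  Phat <- estimate_chain(sq)$P
  expect_lt(max(abs(Phat - P)), 0.03)
})
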