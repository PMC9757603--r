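# Shared fixture builders. Everything is generated in code; no files.

# one-sample dataset from explicit pieces
one_sample <- function(qdot, J, xdot = NULL) {
  J <- matrix(J, nrow = 1L)
  if (is.null(xdot)) xdot <- as.numeric(J %*% qdot)
  kin_data(matrix(qdot, ncol = 1L), matrix(xdot, ncol = 1L), J)
}

# random full-row-rank Jacobian (m x n, n >= m)
rand_jacobian <- function(m, n) {
  repeat {
    J <- matrix(rnorm(m * n), m, n)
    if (rcond(J %*% t(J)) > 1e-6) return(J)
  }
}

# random strictly positive, max-normalized weights
rand_weights <- function(n, lower = 0.1) {
  w <- runif(n, lower, 1)
  w / max(w)
}

# square-chain dataset (n = m): no redundancy at all
square_dataset <- function(n = 3L, K = 20L, seed = 42L) {
  set.seed(seed)
  Jarr <- array(0, dim = c(n, n, K))
  Qd <- matrix(rnorm(n * K), n, K)
  Xd <- matrix(0, n, K)
  for (k in seq_len(K)) {
    J <- rand_jacobian(n, n)
    Jarr[, , k] <- J
    Xd[, k] <- J %*% Qd[, k]
  }
  kin_data(Qd, Xd, Jarr)
}

# dataset whose third joint column leaves the span of the others across
# the whole recording: joints 1-2 act (proportionally, hence redundantly)
# on task dimension 1 only, joint 3 alone on dimension 2
overspecified_dataset <- function(K = 40L, w12 = c(1, 0.5), seed = 7L) {
  set.seed(seed)
  Jarr <- array(0, dim = c(2, 3, K))
  Qd <- matrix(0, 3, K)
  Xd <- matrix(0, 2, K)
  for (k in seq_len(K)) {
    a <- rnorm(1, sd = 1) + 2
    J <- rbind(c(a, 0.5 * a, 0), c(0, 0, rnorm(1) + 2))
    xd <- rnorm(2)
    task <- weighted_pseudoinverse(J, c(w12, 1)) %*% xd
    Jarr[, , k] <- J
    Qd[, k] <- task
    Xd[, k] <- xd
  }
  kin_data(Qd, Xd, Jarr)
}

# synthetic multi-participant cohort with known per-participant weights
synthetic_cohort <- function(w_by_participant, conditions = "A",
                             trials_per = 2L, n = 4L, m = 2L, K = 120L,
                             sigma = 0, seed = 1L) {
  trials <- list(); idx <- NULL
  t_no <- 0L
  for (p in names(w_by_participant)) for (cond in conditions)
    for (tr in seq_len(trials_per)) {
      t_no <- t_no + 1L
      trials[[t_no]] <- random_benchmark(
        n = n, m = m, K = K, w_star = w_by_participant[[p]],
        sigma = sigma, seed = seed + 131L * t_no)
      idx <- rbind(idx, data.frame(participant = p, condition = cond,
                                   trial = tr))
    }
  kin_cohort(trials, idx)
}
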