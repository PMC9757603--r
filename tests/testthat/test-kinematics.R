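test_that("weighted pseudo-inverse reproduces the two-prismatic-joint example", {
  J <- matrix(c(1, 1), 1)
  expect_equal(weighted_pseudoinverse(J, c(1, 1)), matrix(c(0.5, 0.5), 2),
               tolerance = 1e-12)
  expect_equal(weighted_pseudoinverse(J, c(1, 1 / 9)),
               matrix(c(0.1, 0.9), 2), tolerance = 1e-12)
})

test_that("pseudo-inverse of a square full-rank Jacobian is the plain inverse", {
  set.seed(5)
  for (n in 2:4) {
    J <- rand_jacobian(n, n)
    expect_equal(weighted_pseudoinverse(J, rand_weights(n)), solve(J),
                 tolerance = 1e-9)
  }
})

test_that("pseudo-inverse is invariant to a common scaling of the weights", {
  set.seed(6)
  for (rep in 1:10) {
    J <- rand_jacobian(2, 4)
    w <- rand_weights(4)
    for (s in c(1e-3, 0.5, 7, 1e4))
      expect_equal(weighted_pseudoinverse(J, s * w),
                   weighted_pseudoinverse(J, w), tolerance = 1e-8)
  }
})

test_that("generalized-inverse identities hold on random instances", {
  set.seed(7)
  for (rep in 1:20) {
    m <- sample(1:3, 1); n <- m + sample(1:3, 1)
    J <- rand_jacobian(m, n)
    Js <- weighted_pseudoinverse(J, rand_weights(n))
    expect_equal(J %*% Js %*% J, J, tolerance = 1e-8)
    expect_equal(Js %*% J %*% Js, Js, tolerance = 1e-8)
    expect_equal(J %*% Js, diag(m), tolerance = 1e-8)
  }
})

test_that("null-space projector matches hand-computed values and is a projector", {
  J <- matrix(c(1, 1), 1)
  expect_equal(null_space_projector(J, c(1, 1)),
               matrix(c(0.5, -0.5, -0.5, 0.5), 2), tolerance = 1e-12)
  expect_equal(null_space_projector(J, c(1, 1 / 9)),
               matrix(c(0.9, -0.9, -0.1, 0.1), 2), tolerance = 1e-12)
  set.seed(8)
  for (rep in 1:10) {
    m <- sample(1:2, 1); n <- m + sample(1:3, 1)
    J <- rand_jacobian(m, n)
    N <- null_space_projector(J, rand_weights(n))
    expect_equal(N %*% N, N, tolerance = 1e-8)
    expect_equal(J %*% N, matrix(0, m, n), tolerance = 1e-8)
  }
  Jsq <- rand_jacobian(3, 3)
  expect_equal(null_space_projector(Jsq, rand_weights(3)), matrix(0, 3, 3),
               tolerance = 1e-8)
})

test_that("velocity decomposition reproduces the worked example exactly", {
  d1 <- decompose_velocity(c(0, 1), matrix(c(1, 1), 1), c(1, 1))
  expect_equal(d1$task, c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(d1$null, c(-0.5, 0.5), tolerance = 1e-12)
  d2 <- decompose_velocity(c(0, 1), matrix(c(1, 1), 1), c(1, 1 / 9))
  expect_equal(d2$task, c(0.1, 0.9), tolerance = 1e-12)
  expect_equal(d2$null, c(-0.1, 0.1), tolerance = 1e-12)
})

test_that("decomposition conserves the joint velocity and annihilates the null part", {
  set.seed(9)
  for (rep in 1:10) {
    m <- sample(1:3, 1); n <- m + sample(1:3, 1)
    J <- rand_jacobian(m, n)
    w <- rand_weights(n)
    qd <- rnorm(n)
    d <- decompose_velocity(qd, J, w)
    expect_equal(d$task + d$null, qd, tolerance = 1e-10)
    expect_equal(as.numeric(J %*% d$null), rep(0, m), tolerance = 1e-10)
    # a purely task-space velocity has no null component
    qd_task <- as.numeric(d$pseudo_inverse %*% rnorm(m))
    d2 <- decompose_velocity(qd_task, J, w)
    expect_equal(d2$null, rep(0, n), tolerance = 1e-10)
  }
})

test_that("task component minimizes the weighted cost among feasible solutions", {
  set.seed(10)
  for (rep in 1:10) {
    m <- sample(1:2, 1); n <- m + sample(1:2, 1)
    J <- rand_jacobian(m, n)
    w <- rand_weights(n)
    xd <- rnorm(m)
    task <- as.numeric(weighted_pseudoinverse(J, w) %*% xd)
    N <- null_space_projector(J, w)
    cost <- sum(w * task^2)
    Z <- matrix(rnorm(n * 200), n)
    alt <- task + N %*% Z
    alt_costs <- colSums(w * alt^2)
    expect_true(all(cost <= alt_costs + 1e-10))
  }
})

test_that("modeling error scales the null component by one minus gamma", {
  J <- matrix(c(1, 1), 1)
  expect_equal(modeling_error(c(0, 1), J, c(1, 1), gamma = 0.5),
               c(-0.25, 0.25), tolerance = 1e-12)
  set.seed(11)
  J2 <- rand_jacobian(2, 4); qd <- rnorm(4); w <- rand_weights(4)
  expect_equal(modeling_error(qd, J2, w, gamma = 1), rep(0, 4),
               tolerance = 1e-12)
  expect_equal(modeling_error(qd, J2, w, gamma = 0),
               decompose_velocity(qd, J2, w)$null, tolerance = 1e-12)
})

test_that("rank-deficient Jacobians raise a classed singularity error", {
  J <- matrix(c(1, 1, 2, 2), 2, byrow = TRUE)  # duplicated rows
  expect_error(weighted_pseudoinverse(J, c(1, 1)), class = "ikw_singular")
  expect_error(null_space_projector(J, c(1, 1)), class = "ikw_singular")
  # dataset path reports the offending sample index
  d <- suppressWarnings(kin_data(matrix(0, 2, 1), matrix(0, 2, 1),
                                 array(J, c(2, 2, 1))))
  err <- tryCatch(suppressWarnings(ik_fit(d, gamma = 0.5)),
                  error = identity)
  expect_s3_class(err, "ikw_singular")
  expect_match(conditionMessage(err), "sample 1")
})

test_that("kin_data validates dimensions and forward-kinematic consistency", {
  J <- matrix(c(1, 1), 1)
  expect_error(kin_data(matrix(0, 2, 3), matrix(0, 1, 2),
                        array(J, c(1, 2, 3))),
               "same number of samples")
  expect_error(kin_data(c(0, 1, 2), 1, J), "do not match")
  # inconsistent sample: strict rejects, lenient warns
  expect_error(kin_data(c(0, 1), 5, J, strict = TRUE), "violate")
  expect_warning(kin_data(c(0, 1), 5, J), "violate")
  d <- kin_data(c(0, 1), 1, J)
  expect_s3_class(d, "kin_data")
  expect_identical(c(n_joints(d), task_dim(d), n_samples(d)), c(2L, 1L, 1L))
})

test_that("weight vectors are validated and max-normalized", {
  expect_equal(as.numeric(ik_weights(c(2, 1))), c(1, 0.5))
  expect_error(ik_weights(c(1, 0)), "strictly positive")
  expect_error(ik_weights(c(1, -1)), "strictly positive")
  expect_error(ik_weights(c(1, 1e-9)), "lower bound")
  expect_equal(max(ik_weights(runif(5, 0.2, 0.9))), 1)
})

test_that("datasets subset and concatenate consistently", {
  a <- random_benchmark(n = 4, m = 2, K = 10, w_star = rep(1, 4),
                        sigma = 0.1, seed = 1)
  b <- random_benchmark(n = 4, m = 2, K = 5, w_star = rep(1, 4),
                        sigma = 0.1, seed = 2)
  ab <- c(a, b)
  expect_equal(n_samples(ab), 15L)
  expect_equal(ab$qdot[, 11:15], b$qdot)
  expect_equal(ab$jacobian[, , 3], a$jacobian[, , 3])
  sub <- ab[11:15]
  expect_equal(sub$xdot, b$xdot)
  expect_error(c(a, random_benchmark(n = 5, m = 2, K = 5,
                                     w_star = rep(1, 5), seed = 3)),
               "share")
})
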