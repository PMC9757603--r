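#' Random redundant-chain benchmark
#'
#' Generates a dataset from a known ("nominal") weight vector so that the
#' estimator can be scored against ground truth. Per sample, a Jacobian
#' with iid standard-normal entries and a latent task velocity with iid
#' standard-normal entries are drawn; the emitted joint velocity is the
#' nominal minimum-cost solution `J#(w*) xdot` plus Gaussian noise of
#' scale `sigma` projected onto the sample's null space through the
#' nominal projector. The construction guarantees `xdot = J qdot` exactly
#' and makes `w*` the identifiable generating parameter; the null noise is
#' uncorrelated with the task, which is the easiest regime for small
#' projection ratios.
#'
#' Rank-deficient random Jacobians (a measure-zero event, but numerically
#' possible) are resampled; the count is recorded in the labels.
#'
#' @param n joints; must exceed `m`.
#' @param m task dimensions.
#' @param K samples.
#' @param w_star nominal weight vector of length `n` (positive, max 1).
#' @param sigma standard deviation of the raw null-space noise.
#' @param seed optional RNG seed (identical spec + seed reproduce the
#'   dataset bit for bit).
#' @param rcond_tol resampling threshold for near-singular Jacobians.
#' @return A [kin_data] with labels recording the generator settings.
#' @examples
#' d <- random_benchmark(n = 5, m = 3, K = 50, sigma = 0, seed = 1)
#' @export
random_benchmark <- function(n = 5, m = 3, K = 500,
                             w_star = c(1, 0.8, 0.6, 0.4, 0.2),
                             sigma = 0.2, seed = NULL, rcond_tol = 1e-10) {
  stopifnot(n > m, m >= 1, K >= 1, sigma >= 0)
  w <- check_weights(w_star, n)
  if (!is.null(seed)) set.seed(seed)
  Qd <- matrix(0, n, K)
  Xd <- matrix(0, m, K)
  Jarr <- array(0, dim = c(m, n, K))
  resampled <- 0L
  for (k in seq_len(K)) {
    repeat {
      J <- matrix(stats::rnorm(m * n), m, n)
      WiJt <- t(J) / w
      M <- J %*% WiJt
      if (is.finite(rcond(M)) && rcond(M) >= rcond_tol) break
      resampled <- resampled + 1L
    }
    xd <- stats::rnorm(m)
    task <- WiJt %*% solve(M, xd)
    v <- if (sigma > 0) {
      N <- diag(n) - WiJt %*% solve(M, J)
      as.numeric(N %*% stats::rnorm(n, sd = sigma))
    } else rep(0, n)
    Qd[, k] <- task + v
    Xd[, k] <- xd
    Jarr[, , k] <- J
  }
  kin_data(Qd, Xd, Jarr,
           labels = list(generator = "random_benchmark", w_star = w,
                         sigma = sigma, seed = seed, resampled = resampled))
}

#' Two-joint prismatic chain with goal switching
#'
#' Simulates the minimal redundant system: two serial prismatic joints and
#' a one-dimensional task, so `J = [1, 1]` at all times. The chain tracks
#' a piecewise-constant goal position with a proportional controller in
#' task space; the nominal weights (`[1, 0.01]` by default) make the
#' second joint do nearly all the task work. On top of that, a null-space
#' policy injects self-motion: the raw drive `[-null_gain, q1]` (a
#' constant pull on joint 1 plus a position-coupled term) is projected
#' onto the null space with the unweighted projector, which moves joint 1
#' down toward zero over the run without disturbing the end-effector.
#' Setting `null_gain = 0` disables the policy altogether.
#'
#' Because the initial position already satisfies the first goal, the
#' opening segment contains pure self-motion; and throughout the run the
#' null velocities are correlated with the joint velocities. This is the
#' regime where estimating with a small projection ratio misattributes
#' the self-motion to the task and flips the recovered weight ordering,
#' while ratios of 0.6 and above recover the nominal weights.
#'
#' @param w_star nominal weights (length 2).
#' @param dt integration step, seconds.
#' @param duration total time, seconds; `duration/dt` must be an integer
#'   sample count.
#' @param q0 initial joint positions.
#' @param goals data frame with columns `time` and `target`: the goal
#'   active from each onset time onward.
#' @param kp proportional task-tracking gain, 1/s.
#' @param null_gain magnitude of the null-space policy's constant joint-1
#'   drive; `0` turns the policy off.
#' @return A [kin_data] with `K = duration/dt` samples, joint positions
#'   attached.
#' @examples
#' d <- two_joint_sim()
#' n_samples(d)  # 60
#' @export
two_joint_sim <- function(w_star = c(1, 0.01), dt = 0.1, duration = 6,
                          q0 = c(0.5, 0.5),
                          goals = data.frame(time = c(0, 2, 3),
                                             target = c(1, 1.5, 0.5)),
                          kp = 2, null_gain = 0.1) {
  stopifnot(dt > 0, duration > 0, length(q0) == 2L,
            is.data.frame(goals), all(c("time", "target") %in% names(goals)))
  K <- duration / dt
  if (abs(K - round(K)) > 1e-9) stop("duration/dt must be an integer")
  K <- as.integer(round(K))
  w <- check_weights(w_star, 2L)
  J <- matrix(c(1, 1), 1L, 2L)
  Jsharp <- weighted_pseudoinverse(J, w)
  Nproj <- diag(2L) - weighted_pseudoinverse(J, c(1, 1)) %*% J

  q <- q0
  Qp <- matrix(0, 2L, K); Qd <- matrix(0, 2L, K); Xd <- matrix(0, 1L, K)
  for (k in seq_len(K)) {
    t_k <- (k - 1L) * dt
    xg <- goals$target[max(which(goals$time <= t_k + 1e-12))]
    xdes <- kp * (xg - sum(q))
    vnull <- if (null_gain == 0) c(0, 0) else
      as.numeric(Nproj %*% c(-null_gain, q[1L]))
    qd <- as.numeric(Jsharp %*% xdes) + vnull
    Qp[, k] <- q
    Qd[, k] <- qd
    Xd[, k] <- sum(qd)
    q <- q + dt * qd
  }
  kin_data(Qd, Xd, array(J, dim = c(1L, 2L, K)), q = Qp, dt = dt,
           labels = list(generator = "two_joint_sim", w_star = w,
                         kp = kp, null_gain = null_gain))
}

#' Virtual prosthetic-elbow scenario
#'
#' Simulates a three-joint planar chain (hip, shoulder, elbow in the
#' sagittal plane) in which the first two joints are driven by a scripted
#' human reaching motion while the third, a virtual prosthetic elbow, is
#' governed by one of four control modes:
#'
#' * `"assistive"` (default): the elbow is controlled by an assistive law
#'   (details below);
#' * `"natural"`: the elbow is directly driven — the human commands all
#'   three joints through their own weighted IK;
#' * `"locked"`: the elbow is frozen and the human achieves the task with
#'   hip and shoulder alone;
#' * `"coupled"`: the elbow copies the shoulder velocity, a simple fixed
#'   synergy.
#'
#' In the assistive mode the elbow is it takes the elbow row of a weighted
#' pseudo-inverse applied to a low-pass-filtered end-effector velocity
#' (`vdot = -alpha * (v - xdot)`), minus a null-space posture term
#' `N_3 K (q - q_hat)` that discourages compensatory proximal postures.
#' The human driver tracks minimum-jerk end-point segments toward a cycle
#' of planar targets: the commanded velocity is the reference profile
#' plus proportional feedback on the position error. The command is
#' distributed over the joints by a weighted IK expressing the driver's
#' natural proximal-to-distal cost gradient (`driver_weights`: hip
#' costliest, elbow cheapest); only the hip and shoulder components are
#' realizable — the human cannot move the virtual elbow, whose share of
#' the intent is discarded. The position feedback closes the
#' leader-follower loop: as the virtual elbow contributes end-effector
#' velocity, the human command shrinks by the same amount, so the
#' division of labor emerges dynamically, as with a real assistive
#' prosthesis.
#'
#' @param condition elbow control mode: `"assistive"`, `"natural"`,
#'   `"locked"` or `"coupled"`.
#' @param weights controller IK weights for (hip, shoulder, elbow), used
#'   by the assistive law.
#' @param gains posture-gain diagonal `K`.
#' @param rest rest posture `q_hat`, rad.
#' @param alpha low-pass filter rate, 1/s.
#' @param elbow_limits admissible elbow range, rad.
#' @param lengths link lengths (trunk, upper arm, forearm), m.
#' @param q0 initial joint configuration, rad.
#' @param dt integration step, s.
#' @param segment_time duration of each reaching segment, s.
#' @param kp proportional gain of the driver's position feedback, 1/s.
#' @param driver_weights the driver's own natural IK weights (hip,
#'   shoulder, elbow) used to distribute the commanded velocity.
#' @param targets matrix of planar targets (one row per reach); defaults
#'   to a cycle of reachable points.
#' @param seed optional RNG seed used only when jittering default targets.
#' @return A [kin_data] over the full movement sequence with joint
#'   positions attached.
#' @export
assistive_elbow_sim <- function(condition = c("assistive", "natural",
                                              "locked", "coupled"),
                                weights = c(1, 1, 0.15),
                                gains = c(2, 0.2, 0),
                                rest = c(0, -2.7, 0),
                                alpha = 40,
                                elbow_limits = c(0, pi),
                                lengths = c(0.5, 0.3, 0.25),
                                q0 = c(0.3, -1.8, 1.2),
                                dt = 0.01, segment_time = 1.5, kp = 5,
                                driver_weights = c(1, 0.5, 0.1),
                                targets = NULL, seed = NULL) {
  stopifnot(alpha > 0, dt > 0, segment_time > dt,
            length(weights) == 3L, length(lengths) == 3L,
            elbow_limits[1L] < elbow_limits[2L])
  condition <- match.arg(condition)
  w <- check_weights(weights, 3L)
  wd <- check_weights(driver_weights, 3L)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(targets)) {
    # cycle of reachable end-points around the start posture
    base <- planar_fk(q0, lengths)
    ang <- seq(0, 2 * pi, length.out = 7L)[-7L]
    targets <- cbind(base[1L] + 0.12 * cos(ang), base[2L] + 0.12 * sin(ang))
  }
  targets <- as.matrix(targets)
  if (ncol(targets) != 2L) stop("'targets' must have two columns (x, y)")

  steps_seg <- as.integer(round(segment_time / dt))
  K <- steps_seg * nrow(targets)
  q <- q0
  v <- c(0, 0)
  Qp <- matrix(0, 3L, K); Qd <- matrix(0, 3L, K); Xd <- matrix(0, 2L, K)
  Jarr <- array(0, dim = c(2L, 3L, K))
  k <- 0L
  for (s in seq_len(nrow(targets))) {
    x0 <- planar_fk(q, lengths)
    xg <- targets[s, ]
    for (j in seq_len(steps_seg)) {
      k <- k + 1L
      tau <- (j - 1L) / steps_seg
      # minimum-jerk position/velocity reference along the segment
      pos <- 10 * tau^3 - 15 * tau^4 + 6 * tau^5
      vmag <- (30 * tau^2 - 60 * tau^3 + 30 * tau^4) / segment_time
      x_ref <- x0 + (xg - x0) * pos
      xdes_dot <- (xg - x0) * vmag + kp * (x_ref - planar_fk(q, lengths))
      J <- planar_jacobian(q, lengths)
      qd <- switch(condition,
        natural = as.numeric(weighted_pseudoinverse(J, wd) %*% xdes_dot),
        locked = c(solve(J[, 1:2], xdes_dot), 0),
        coupled = {
          # elbow copies the shoulder: effective 2-joint chain
          q12 <- solve(cbind(J[, 1L], J[, 2L] + J[, 3L]), xdes_dot)
          c(q12, q12[2L])
        },
        assistive = {
          # human intent through natural weighted IK; the elbow share of
          # the intent is unrealizable and discarded
          qd12 <- as.numeric(weighted_pseudoinverse(J, wd) %*% xdes_dot)[1:2]
          Jsharp <- weighted_pseudoinverse(J, w)
          N <- diag(3L) - Jsharp %*% J
          qd3 <- as.numeric(Jsharp[3L, ] %*% v -
                              N[3L, ] %*% (gains * (q - rest)))
          # respect elbow limits: no motion further into a saturated bound
          if ((q[3L] <= elbow_limits[1L] && qd3 < 0) ||
              (q[3L] >= elbow_limits[2L] && qd3 > 0)) qd3 <- 0
          c(qd12, qd3)
        })
      xd <- as.numeric(J %*% qd)
      Qp[, k] <- q; Qd[, k] <- qd; Xd[, k] <- xd; Jarr[, , k] <- J
      q <- q + dt * qd
      q[3L] <- min(max(q[3L], elbow_limits[1L]), elbow_limits[2L])
      v <- v + dt * (-alpha) * (v - xd)
    }
  }
  kin_data(Qd, Xd, Jarr, q = Qp, dt = dt,
           labels = list(generator = "assistive_elbow_sim",
                         condition = condition, weights = w,
                         gains = gains, alpha = alpha))
}

# planar 3-link forward kinematics and Jacobian (absolute angles cumulate)
planar_fk <- function(q, lengths) {
  th <- cumsum(q)
  c(sum(lengths * cos(th)), sum(lengths * sin(th)))
}

planar_jacobian <- function(q, lengths) {
  th <- cumsum(q)
  J <- matrix(0, 2L, 3L)
  for (j in 1:3) {
    idx <- j:3
    J[1L, j] <- -sum(lengths[idx] * sin(th[idx]))
    J[2L, j] <- sum(lengths[idx] * cos(th[idx]))
  }
  J
}
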