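#' Weighted pseudo-inverse of a Jacobian
#'
#' Computes `J# = W^-1 J' (J W^-1 J')^-1` for a full-row-rank Jacobian `J`
#' and a diagonal weight matrix `W = diag(w)`. Among all joint velocities
#' reproducing a given end-effector velocity (`J qdot = xdot`), `J# xdot`
#' is the one minimizing the weighted cost `qdot' W qdot`, so the weights
#' encode how costly each joint is in contributing to the task. Scaling all
#' weights by a common factor leaves `J#` unchanged.
#'
#' No damping is applied: if `J W^-1 J'` is numerically singular
#' (reciprocal condition number below `rcond_tol`) an error of class
#' `ikw_singular` is raised, because a damped inverse would silently change
#' the minimum-cost semantics the weight estimator relies on.
#'
#' @param jacobian numeric `m x n` matrix (rows = task dimensions).
#' @param weights strictly positive weight vector of length `n` (any
#'   positive scale; see [ik_weights()]).
#' @param rcond_tol reciprocal-condition-number threshold for declaring
#'   `J W^-1 J'` singular.
#' @param sample optional sample index, included in singularity errors so
#'   the offending time-step can be traced.
#' @return The `n x m` weighted pseudo-inverse.
#' @examples
#' weighted_pseudoinverse(matrix(c(1, 1), 1), c(1, 1))      # 0.5 0.5
#' weighted_pseudoinverse(matrix(c(1, 1), 1), c(1, 1 / 9))  # 0.1 0.9
#' @export
weighted_pseudoinverse <- function(jacobian, weights, rcond_tol = 1e-10,
                                   sample = NULL) {
  J <- as.matrix(jacobian)
  w <- check_weights(w = weights, n = ncol(J))
  WiJt <- t(J) / w                      # W^-1 J', rows scaled by 1/w
  M <- J %*% WiJt                       # J W^-1 J', m x m
  check_rank(M, rcond_tol, sample)
  WiJt %*% solve(M)
}

#' Null-space projector of a weighted pseudo-inverse
#'
#' Returns `N = I - J# J`, the projector onto joint-velocity directions
#' that produce no end-effector motion under the weighted pseudo-inverse
#' `J#`. `N` is idempotent and satisfies `J N = 0`; for a square full-rank
#' Jacobian the null space is empty and `N = 0`.
#'
#' @inheritParams weighted_pseudoinverse
#' @return The `n x n` projector matrix.
#' @export
null_space_projector <- function(jacobian, weights, rcond_tol = 1e-10,
                                 sample = NULL) {
  J <- as.matrix(jacobian)
  Jsharp <- weighted_pseudoinverse(J, weights, rcond_tol, sample)
  diag(ncol(J)) - Jsharp %*% J
}

#' Decompose a joint velocity into task- and null-space components
#'
#' Splits an observed joint velocity into `qdot_task = J# xdot`, the
#' minimum-cost velocity producing the observed end-effector motion, and
#' `qdot_null = qdot - qdot_task = N qdot`, the self-motion that leaves the
#' end-effector still. The split depends entirely on the assumed weights:
#' under identity weights all joints are presumed to contribute equally,
#' which can attribute most of a recording to the null space; under
#' well-chosen weights the task component explains the bulk of the motion.
#'
#' @param qdot joint velocity: a length-`n` vector, an `n x K` matrix, or a
#'   [kin_data] object (in which case `jacobian`/`xdot` are taken from it).
#' @param jacobian `m x n` Jacobian (single sample) or `m x n x K` array.
#' @param weights positive weight vector of length `n`.
#' @param xdot optional end-effector velocity; defaults to `J qdot`.
#' @param rcond_tol singularity threshold, see [weighted_pseudoinverse()].
#' @return An object of class `vel_decomp`: list with `task` and `null`
#'   (vectors, or `n x K` matrices for multi-sample input), and for
#'   single-sample input the generating `pseudo_inverse` and `projector`.
#' @examples
#' d <- decompose_velocity(c(0, 1), matrix(c(1, 1), 1), c(1, 1))
#' d$task   # 0.5 0.5
#' d$null   # -0.5 0.5
#' @export
decompose_velocity <- function(qdot, jacobian = NULL, weights,
                               xdot = NULL, rcond_tol = 1e-10) {
  if (inherits(qdot, "kin_data")) {
    data <- qdot
    return(decompose_dataset(data, weights, rcond_tol))
  }
  J <- as.matrix(jacobian)
  qdot <- as.numeric(qdot)
  if (length(qdot) != ncol(J))
    stop("length of 'qdot' must equal the number of Jacobian columns")
  if (is.null(xdot)) xdot <- J %*% qdot
  Jsharp <- weighted_pseudoinverse(J, weights, rcond_tol)
  task <- as.numeric(Jsharp %*% xdot)
  structure(
    list(task = task, null = qdot - task,
         pseudo_inverse = Jsharp,
         projector = diag(ncol(J)) - Jsharp %*% J),
    class = "vel_decomp")
}

decompose_dataset <- function(data, weights, rcond_tol = 1e-10) {
  n <- n_joints(data); K <- n_samples(data)
  w <- check_weights(weights, n)
  task <- matrix(0, n, K)
  for (k in seq_len(K)) {
    J <- jac_slice(data, k)
    WiJt <- t(J) / w
    M <- J %*% WiJt
    check_rank(M, rcond_tol, k)
    task[, k] <- WiJt %*% solve(M, data$xdot[, k])
  }
  structure(list(task = task, null = data$qdot - task), class = "vel_decomp")
}

#' @export
print.vel_decomp <- function(x, digits = 4L, ...) {
  if (is.matrix(x$task)) {
    cat(sprintf("<vel_decomp> %d joints x %d samples\n",
                nrow(x$task), ncol(x$task)))
    cat(sprintf("  RMS task: %.4g   RMS null: %.4g\n",
                sqrt(mean(x$task^2)), sqrt(mean(x$null^2))))
  } else {
    cat("task:", format(x$task, digits = digits), "\n")
    cat("null:", format(x$null, digits = digits), "\n")
  }
  invisible(x)
}

#' Modeling error of the partially null-space-attributed IK model
#'
#' During estimation the observed joint velocity is modeled as
#' `J# xdot + gamma * N qdot`, attributing only a fraction `gamma` of the
#' projected velocity to the null space. The unexplained remainder is
#' `(1 - gamma) N qdot`: zero when `gamma = 1` (any weight matrix then fits
#' perfectly) and equal to the full null component when `gamma = 0`.
#'
#' @inheritParams decompose_velocity
#' @param gamma null-space projection ratio in `[0, 1]`.
#' @return Length-`n` numeric error vector.
#' @export
modeling_error <- function(qdot, jacobian, weights, gamma,
                           rcond_tol = 1e-10) {
  stopifnot(is.numeric(gamma), length(gamma) == 1L, gamma >= 0, gamma <= 1)
  d <- decompose_velocity(qdot, jacobian, weights, rcond_tol = rcond_tol)
  (1 - gamma) * d$null
}

# ---- shared validation helpers ------------------------------------------

check_weights <- function(w, n) {
  w <- as.numeric(w)
  if (length(w) != n)
    stop(sprintf("expected %d weights, got %d", n, length(w)))
  if (!all(is.finite(w)) || any(w <= 0))
    stop("IK weights must be finite and strictly positive")
  w
}

check_rank <- function(M, rcond_tol, sample = NULL) {
  rc <- rcond(M)
  if (!is.finite(rc) || rc < rcond_tol) {
    where <- if (is.null(sample)) "" else sprintf(" at sample %d", sample)
    stop(structure(
      class = c("ikw_singular", "error", "condition"),
      list(message = sprintf(
        "J W^-1 J' is numerically singular%s (rcond = %.3g < %g); the Jacobian is rank-deficient or near a singular configuration",
        where, rc, rcond_tol),
        call = sys.call(-1L))))
  }
  invisible(rc)
}
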