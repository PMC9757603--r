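#' Assemble the weight-update quadratic program
#'
#' One update step of the weight estimator linearizes the (nonlinear)
#' dependence of the IK model on the weight matrix. Writing the weighted
#' pseudo-inverse relation per sample as `W (qdot_k - v_k) = u_k` with the
#' auxiliary variable `u_k = J_k' (J_k W^-1 J_k')^-1 xdot_k` evaluated at
#' the current weights, summing over samples gives the matrix equation
#' `W Psi = Omega` with `Psi = (Qdot - V) Qdot'` and `Omega = U Qdot'`.
#' Because `W` is diagonal this rearranges column-wise into the tall linear
#' system `Psi_tilde w = Omega_tilde` (`Psi_tilde` is `n^2 x n`, block `j`
#' being `diag` of column `j` of `Psi`), whose least-squares form is the
#' quadratic cost `0.5 w' H w + F' w` with `H = Psi_tilde' Psi_tilde` and
#' `F = -Psi_tilde' Omega_tilde`.
#'
#' Samples whose end-effector speed falls below `xdot_floor` can be
#' excluded from the sums (the count excluded is returned); by default
#' every sample is kept, since rest-period samples carry pure self-motion
#' and inform the null-space side of the fit.
#'
#' @param data a [kin_data] dataset.
#' @param weights current weight estimate (length `n`, strictly positive).
#' @param null_velocities `n x K` matrix of current null-velocity
#'   estimates (`V`); defaults to zero.
#' @param xdot_floor end-effector speed below which a sample is dropped
#'   from the assembly.
#' @param rcond_tol singularity threshold per sample.
#' @return A list of class `ikw_qp`: `H` (`n x n`, PSD), `F` (length `n`),
#'   the intermediate `Psi`, `Omega`, `Psi_tilde`, `Omega_tilde`, and
#'   `dropped` (count of floored samples).
#' @export
assemble_weight_qp <- function(data, weights, null_velocities = NULL,
                               xdot_floor = 0, rcond_tol = 1e-10) {
  stopifnot(inherits(data, "kin_data"))
  n <- n_joints(data); K <- n_samples(data)
  w <- check_weights(weights, n)
  V <- if (is.null(null_velocities)) matrix(0, n, K) else
    as.matrix(null_velocities)
  if (!all(dim(V) == c(n, K)))
    stop("'null_velocities' must be an n x K matrix")

  U <- matrix(0, n, K)
  keep <- rep(TRUE, K)
  for (k in seq_len(K)) {
    xk <- data$xdot[, k]
    if (sqrt(sum(xk^2)) < xdot_floor) { keep[k] <- FALSE; next }
    J <- jac_slice(data, k)
    M <- J %*% (t(J) / w)
    check_rank(M, rcond_tol, k)
    U[, k] <- crossprod(J, solve(M, xk))
  }
  Qd <- data$qdot[, keep, drop = FALSE]
  Psi <- (Qd - V[, keep, drop = FALSE]) %*% t(Qd)
  Omega <- U[, keep, drop = FALSE] %*% t(Qd)

  Psi_tilde <- stack_diagonal(Psi)
  Omega_tilde <- as.numeric(Omega)      # stacked columns
  structure(
    list(H = crossprod(Psi_tilde), F = -as.numeric(crossprod(Psi_tilde, Omega_tilde)),
         Psi = Psi, Omega = Omega,
         Psi_tilde = Psi_tilde, Omega_tilde = Omega_tilde,
         dropped = sum(!keep)),
    class = "ikw_qp")
}

# Rearrange an n x n matrix A into the n^2 x n block matrix whose j-th
# n-row block is diag(A[, j]); then B %*% w == as.numeric(diag(w) %*% A).
stack_diagonal <- function(A) {
  n <- nrow(A)
  B <- matrix(0, n * n, n)
  for (j in seq_len(n))
    B[cbind((j - 1L) * n + seq_len(n), seq_len(n))] <- A[, j]
  B
}

#' Solve a box-constrained convex quadratic program
#'
#' Minimizes `0.5 w' H w + F' w` subject to `lower <= w_i <= upper` by
#' cyclic coordinate descent with exact per-coordinate minimization and
#' clipping. For convex `H` (positive semi-definite) and box-only
#' constraints this converges to the global minimum; for the weight-update
#' problems produced by [assemble_weight_qp()] `H` is diagonal and a single
#' sweep is exact.
#'
#' @param H `n x n` symmetric positive semi-definite matrix.
#' @param F length-`n` linear term.
#' @param lower,upper box bounds, scalars or length-`n` vectors.
#' @param tol stopping tolerance on the sup-norm coordinate step.
#' @param max_sweeps sweep budget.
#' @param start optional feasible starting point.
#' @return Length-`n` solution vector with attribute `sweeps`; an error of
#'   class `ikw_qp_failure` (carrying the sweep count) if the sweep budget
#'   is exhausted before the step tolerance is met.
#' @examples
#' solve_box_qp(diag(2), -c(0.3, 0.7), 1e-6, 1)  # 0.3 0.7
#' @export
solve_box_qp <- function(H, F, lower = 1e-6, upper = 1,
                         tol = 1e-10, max_sweeps = 10000L, start = NULL) {
  H <- as.matrix(H)
  n <- length(F)
  stopifnot(nrow(H) == n, ncol(H) == n)
  lower <- rep_len(lower, n); upper <- rep_len(upper, n)
  if (any(lower > upper)) stop("infeasible box: lower > upper")
  w <- if (is.null(start)) pmin(pmax((lower + upper) / 2, lower), upper)
       else pmin(pmax(rep_len(start, n), lower), upper)
  hd <- diag(H)
  for (s in seq_len(max_sweeps)) {
    delta <- 0
    for (i in seq_len(n)) {
      g <- F[i] + sum(H[i, ] * w)       # partial derivative at current w
      wi_new <- if (hd[i] > 0) {
        min(max(w[i] - g / hd[i], lower[i]), upper[i])
      } else if (g > 0) lower[i] else if (g < 0) upper[i] else w[i]
      delta <- max(delta, abs(wi_new - w[i]))
      w[i] <- wi_new
    }
    if (delta < tol) {
      attr(w, "sweeps") <- s
      return(w)
    }
  }
  stop(structure(
    class = c("ikw_qp_failure", "error", "condition"),
    list(message = sprintf(
      "box-QP coordinate descent did not reach step tolerance %g within %d sweeps",
      tol, max_sweeps), call = sys.call(-1L))))
}
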