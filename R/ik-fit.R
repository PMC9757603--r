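#' Identify inverse-kinematics weights from observed kinematics
#'
#' Fits the diagonal weight matrix of a weighted Jacobian pseudo-inverse to
#' a recorded (or simulated) dataset of joint velocities, end-effector
#' velocities and Jacobians. The model explains each observed joint
#' velocity as `qdot_k = J_k#(W) xdot_k + v_k`, the minimum-cost task
#' solution plus a null-space self-motion `v_k`; the estimator seeks the
#' weights under which the task part explains the data with as little
#' reliance on the null space as possible.
#'
#' Each iteration has two parts. *Evaluation*: with the current weights,
#' every sample is decomposed; a fraction `gamma` (the null-space
#' projection ratio) of the projected velocity is attributed to the null
#' space, leaving the per-sample modeling error `(1 - gamma) N qdot_k`
#' whose mean norm is the convergence criterion. *Update*: the pseudo-
#' inverse relation is linearized through the auxiliary variable
#' `u_k = J_k'(J_k W^-1 J_k')^-1 xdot_k` and the weights are re-estimated
#' by a box-constrained quadratic program (see [assemble_weight_qp()] and
#' [solve_box_qp()]), then max-normalized so the costliest joint sits at 1.
#'
#' `gamma` trades identifiability against speed: at `gamma = 1` any weight
#' matrix fits perfectly and no update occurs; at `gamma = 0` genuine
#' self-motion is forced into the task model and can invert the recovered
#' weight ordering when null and task velocities are correlated. A rising
#' schedule (`lambda > 0`, `gamma <- gamma + lambda * (1 - gamma)` after
#' each update) combines fast early progress with late-stage optimality.
#'
#' The first entry of the error trace is the fit of the initial guess
#' (identity weights), so the trace doubles as a comparison against the
#' conventional unweighted pseudo-inverse.
#'
#' @param data a [kin_data] dataset (`K` samples, `n` joints, `m` task
#'   dimensions). A warning is issued when `K < n^2` (weakly determined
#'   fit).
#' @param gamma null-space projection ratio in `[0, 1]`; a scalar, or a
#'   numeric vector giving an explicit per-iteration schedule (last value
#'   is held).
#' @param lambda schedule rate in `[0, 1]`; `0` keeps `gamma` fixed.
#' @param epsilon stopping threshold on the mean per-sample residual norm.
#' @param max_iter maximum number of weight updates.
#' @param lower lower box bound on the weights (strictly positive so that
#'   `W^-1` exists; indistinguishable from 0 at reporting precision).
#' @param w_tol stationarity tolerance: stop when the sup-norm weight
#'   change between consecutive updates falls below it.
#' @param qp_tol coordinate-step tolerance passed to [solve_box_qp()].
#' @param overspecified optional integer indices of over-specified joints
#'   (Jacobian column outside the span of the others, weight not
#'   identifiable). Their weight is pinned back to 1 right after each QP
#'   solve and they are excluded from the max-normalization. See
#'   [detect_overspecified()].
#' @param xdot_floor samples with end-effector speed below this are
#'   excluded from the update assembly. The default 0 keeps every sample:
#'   rest-period samples carry pure self-motion and are informative about
#'   the null space. Raise the floor to discard rest periods of noisy
#'   recordings.
#' @param rcond_tol per-sample singularity threshold.
#' @return An object of class `ik_fit` with components `weights`
#'   ([ik_weights]), `beta` (contribution coefficients), `error_trace`
#'   (mean residual per iteration, entry 1 = identity-weight fit),
#'   `weight_trace` (`n x` iterations matrix), `iterations` (updates
#'   performed), `converged`, `convergence` (`"residual"`,
#'   `"stationary"` or `"max_iter"`), `null_velocities` (`n x K`, the
#'   attributed null components `v_k` at convergence), `residuals`,
#'   `fitted`, `dropped`, `gamma_trace` and the call. Methods: `print`,
#'   `summary`, `coef`, `residuals`, `fitted`, `predict`, `plot`,
#'   `simulate`.
#' @examples
#' set.seed(1)
#' d <- random_benchmark(n = 4, m = 2, K = 200, w_star = c(1, 0.6, 0.3, 0.9),
#'                       sigma = 0)
#' fit <- ik_fit(d, gamma = 0.6)
#' coef(fit)
#' @export
ik_fit <- function(data, gamma = 0.9, lambda = 0, epsilon = 1e-3,
                   max_iter = 100L, lower = 1e-6, w_tol = 1e-4,
                   qp_tol = 1e-8, overspecified = NULL,
                   xdot_floor = 0, rcond_tol = 1e-10) {
  stopifnot(inherits(data, "kin_data"))
  n <- n_joints(data); K <- n_samples(data)
  if (!is.numeric(gamma) || !length(gamma) ||
      any(gamma < 0) || any(gamma > 1))
    stop("'gamma' must lie in [0, 1]")
  stopifnot(length(lambda) == 1L, lambda >= 0, lambda <= 1,
            epsilon > 0, max_iter >= 1L, lower > 0, lower <= 1)
  os <- as.integer(overspecified)
  if (length(os) && (any(os < 1L) || any(os > n)))
    stop("'overspecified' indices out of range")
  free <- setdiff(seq_len(n), os)
  if (!length(free)) stop("all joints declared over-specified")
  if (K < n^2)
    warning(sprintf(
      "only K = %d samples for n^2 = %d effective unknowns; the fit may be poorly determined",
      K, n^2), call. = FALSE)

  gam <- if (length(gamma) > 1L) gamma[1L] else gamma
  gamma_explicit <- if (length(gamma) > 1L) gamma else NULL
  w <- rep(1, n)
  e_trace <- numeric(0)
  g_trace <- numeric(0)
  w_trace <- matrix(NA_real_, n, 0L)
  w_change <- Inf
  converged <- FALSE
  reason <- "max_iter"
  dropped <- 0L
  ev <- NULL

  t <- 1L
  repeat {
    ev <- ikw_evaluate(data, w, gam, rcond_tol)
    e_trace[t] <- ev$e
    g_trace[t] <- gam
    w_trace <- cbind(w_trace, w)
    if (ev$e < epsilon) { converged <- TRUE; reason <- "residual"; break }
    if (w_change < w_tol) { converged <- TRUE; reason <- "stationary"; break }
    if (t > max_iter) { reason <- "max_iter"; break }

    # assemble directly from the evaluation pass (U is already available)
    keep <- sqrt(colSums(data$xdot^2)) >= xdot_floor
    dropped <- sum(!keep)
    Qk <- data$qdot[, keep, drop = FALSE]
    Psi <- (Qk - ev$V[, keep, drop = FALSE]) %*% t(Qk)
    Omega <- ev$U[, keep, drop = FALSE] %*% t(Qk)
    Pt <- stack_diagonal(Psi)
    w_new <- as.numeric(solve_box_qp(crossprod(Pt),
                                     -as.numeric(crossprod(Pt, as.numeric(Omega))),
                                     lower = lower, upper = 1,
                                     tol = qp_tol, start = w))
    if (length(os)) w_new[os] <- 1
    w_new[free] <- w_new[free] / max(w_new[free])
    w_change <- max(abs(w_new - w))
    w <- w_new
    if (!is.null(gamma_explicit))
      gam <- gamma_explicit[min(t + 1L, length(gamma_explicit))]
    else if (lambda > 0)
      gam <- gam + lambda * (1 - gam)
    t <- t + 1L
  }

  weights <- ik_weights(w, normalize = FALSE, lower = lower / 2)
  structure(
    list(weights = weights,
         beta = contribution_coefficients(w),
         error_trace = e_trace,
         weight_trace = w_trace,
         gamma_trace = g_trace,
         iterations = t - 1L,
         converged = converged,
         convergence = reason,
         null_velocities = ev$V,
         residuals = ev$resid,
         fitted = ev$Qhat,
         task_velocities = ev$task,
         dropped = dropped,
         overspecified = os,
         epsilon = epsilon, lower = lower,
         n = n, m = task_dim(data), K = K,
         data = data,
         call = match.call()),
    class = "ik_fit")
}

# One evaluation pass: decompose every sample under weights w, attribute
# gamma of the projected velocity to the null space, accumulate the
# auxiliary variable and the per-sample residual norms. Compiled hot path;
# ikw_evaluate_r is the plain-R reference used in the tests.
ikw_evaluate <- function(data, w, gamma, rcond_tol) {
  out <- ikw_eval_cpp(data$qdot, data$xdot, data$jacobian, w, gamma,
                      rcond_tol)
  if (!is.null(out$singular)) {
    stop(structure(
      class = c("ikw_singular", "error", "condition"),
      list(message = sprintf(
        "J W^-1 J' is numerically singular at sample %d (rcond = %.3g < %g)",
        out$singular, out$rcond, rcond_tol),
        call = sys.call(-1L))))
  }
  out$resid <- as.numeric(out$resid)
  out$Qhat <- out$task + out$V
  out
}

ikw_evaluate_r <- function(data, w, gamma, rcond_tol) {
  n <- n_joints(data); K <- n_samples(data)
  Qd <- data$qdot; Xd <- data$xdot
  V <- matrix(0, n, K)
  U <- matrix(0, n, K)
  task <- matrix(0, n, K)
  resid <- numeric(K)
  for (k in seq_len(K)) {
    J <- matrix(data$jacobian[, , k], ncol = n)
    WiJt <- t(J) / w
    M <- J %*% WiJt
    check_rank(M, rcond_tol, k)
    qk <- Qd[, k]
    S <- solve(M, cbind(Xd[, k], J %*% qk))   # (J W^-1 J')^-1 [xdot, J qdot]
    Tk <- WiJt %*% S
    task[, k] <- Tk[, 1L]
    U[, k] <- crossprod(J, S[, 1L])
    vk <- gamma * (qk - Tk[, 2L])             # gamma * N qdot
    V[, k] <- vk
    r <- qk - Tk[, 1L] - vk
    resid[k] <- sqrt(sum(r * r))
  }
  list(e = mean(resid), V = V, U = U, task = task,
       Qhat = task + V, resid = resid)
}

#' Contribution coefficients from IK weights
#'
#' Transforms weights (relative costs, costliest joint at 1) into
#' contribution coefficients `beta_i = w_i^-1 / sum_k w_k^-1`, which sum
#' to one and read directly as each joint's share of the task: low-cost
#' joints carry large shares. Easier to compare across conditions than the
#' weights themselves, whose max-normalization anchor can move.
#'
#' @param weights strictly positive weight vector, or an [ik_fit] object.
#' @return Numeric vector summing to 1, anti-monotone in the weights.
#' @examples
#' contribution_coefficients(c(1, 1 / 9))  # 0.1 0.9
#' @export
contribution_coefficients <- function(weights) {
  if (inherits(weights, "ik_fit")) weights <- weights$weights
  w <- as.numeric(weights)
  if (!length(w) || !all(is.finite(w)) || any(w <= 0))
    stop("contribution coefficients require strictly positive weights")
  (1 / w) / sum(1 / w)
}

#' Build a rising null-space projection-ratio schedule
#'
#' Returns the explicit sequence `gamma_{t+1} = gamma_t + lambda *
#' (1 - gamma_t)`, which approaches 1 geometrically. Passing the result as
#' the `gamma` argument of [ik_fit()] is equivalent to `gamma = gamma0,
#' lambda = lambda`.
#'
#' @param gamma0 starting ratio.
#' @param lambda rate in `[0, 1]`.
#' @param length_out number of iterations to tabulate.
#' @return Numeric vector of ratios.
#' @export
gamma_schedule <- function(gamma0 = 0.6, lambda = 0.6, length_out = 50L) {
  stopifnot(gamma0 >= 0, gamma0 <= 1, lambda >= 0, lambda <= 1)
  g <- numeric(length_out)
  g[1L] <- gamma0
  for (t in seq_len(length_out - 1L)) g[t + 1L] <- g[t] + lambda * (1 - g[t])
  g
}

#' Flag joints whose Jacobian column leaves the span of the others
#'
#' A joint is over-specified when, at every recorded configuration, its
#' Jacobian column cannot be written as a linear combination of the other
#' joints' columns: its effect on the end-effector is unique, so its IK
#' weight does not influence the pseudo-inverse solution and is not
#' identifiable (it is pinned to 1 by convention). Detection regresses the
#' joint's column on the other columns sample by sample and flags joints
#' whose mean relative residual across the dataset exceeds `tol`. For a
#' generic redundant chain the other columns span the whole task space and
#' every residual is zero; a persistent residual means the remaining
#' joints are collectively rank-deficient in that direction.
#'
#' @param data a [kin_data] dataset.
#' @param tol mean relative least-squares residual above which a joint is
#'   flagged.
#' @return Integer vector of flagged joint indices (possibly empty).
#' @export
detect_overspecified <- function(data, tol = 1e-6) {
  stopifnot(inherits(data, "kin_data"))
  n <- n_joints(data); K <- n_samples(data)
  rel <- matrix(0, K, n)
  for (k in seq_len(K)) {
    J <- jac_slice(data, k)
    for (j in seq_len(n)) {
      y <- J[, j]
      X <- J[, -j, drop = FALSE]
      co <- qr.coef(qr(X), y)
      co[is.na(co)] <- 0
      r <- y - X %*% co
      rel[k, j] <- sqrt(sum(r^2)) / max(sqrt(sum(y^2)), .Machine$double.eps)
    }
  }
  which(colMeans(rel) > tol)
}

# ---- methods -------------------------------------------------------------

#' @export
print.ik_fit <- function(x, digits = 4L, ...) {
  cat("Inverse-kinematics weight fit\n")
  cat(sprintf("  %d joints, %d task dims, %d samples; %d update%s\n",
              x$n, x$m, x$K, x$iterations, if (x$iterations == 1L) "" else "s"))
  cat("  weights:", paste(format(unclass(x$weights), digits = digits),
                          collapse = " "), "\n")
  cat("  contributions:", paste(format(x$beta, digits = digits),
                                collapse = " "), "\n")
  cat(sprintf("  mean residual: %.4g (started at %.4g); %s\n",
              utils::tail(x$error_trace, 1L), x$error_trace[1L],
              if (x$converged) paste0("converged (", x$convergence, ")")
              else "did not converge"))
  invisible(x)
}

#' @export
summary.ik_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.ik_fit")
}

#' @export
print.summary.ik_fit <- function(x, digits = 4L, ...) {
  f <- x$fit
  print(f, digits = digits)
  tab <- rbind(weight = as.numeric(f$weights), beta = f$beta)
  colnames(tab) <- paste0("joint", seq_len(f$n))
  if (length(f$overspecified))
    cat("  over-specified (pinned to 1):",
        paste(f$overspecified, collapse = ", "), "\n")
  cat("\n")
  print(round(tab, digits))
  cat(sprintf("\nError trace (%d evaluations): first %.4g, last %.4g\n",
              length(f$error_trace), f$error_trace[1L],
              utils::tail(f$error_trace, 1L)))
  if (f$dropped > 0L)
    cat(sprintf("%d near-rest samples excluded from the update assembly\n",
                f$dropped))
  invisible(x)
}

#' @export
coef.ik_fit <- function(object, ...) as.numeric(object$weights)

#' @export
residuals.ik_fit <- function(object, ...) object$residuals

#' @export
fitted.ik_fit <- function(object, ...) object$fitted

#' Decompose new data under the fitted weights
#'
#' @param object an [ik_fit].
#' @param newdata a [kin_data] dataset sharing the joint count; defaults
#'   to the training data.
#' @param ... unused.
#' @return A `vel_decomp` with `n x K` `task` and `null` matrices.
#' @export
predict.ik_fit <- function(object, newdata = NULL, ...) {
  data <- if (is.null(newdata)) object$data else newdata
  decompose_velocity(data, weights = as.numeric(object$weights))
}

#' @export
plot.ik_fit <- function(x, which = c("trace", "weights"), ...) {
  which <- match.arg(which)
  it <- seq_along(x$error_trace) - 1L
  if (which == "trace") {
    graphics::plot(it, x$error_trace, type = "b", log = "y",
                   xlab = "iteration", ylab = "mean residual norm",
                   main = "Estimation error trace", ...)
    graphics::abline(h = x$epsilon, lty = 3)
  } else {
    graphics::matplot(it, t(x$weight_trace), type = "l", lty = 1,
                      xlab = "iteration", ylab = "weight",
                      main = "Weight trajectories", ...)
  }
  invisible(x)
}

#' Simulate datasets from a fitted IK model
#'
#' Parametric resampling: keeps the recorded end-effector velocities and
#' Jacobians, regenerates joint velocities as the fitted task component
#' plus Gaussian noise projected onto each sample's null space, with the
#' noise scale matched to the RMS of the extracted null velocities.
#'
#' @param object an [ik_fit].
#' @param nsim number of datasets.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return A list of `nsim` [kin_data] objects.
#' @export
simulate.ik_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  data <- object$data
  w <- as.numeric(object$weights)
  n <- object$n; K <- object$K
  sigma <- stats::sd(as.numeric(object$null_velocities))
  lapply(seq_len(nsim), function(s) {
    qd <- matrix(0, n, K)
    for (k in seq_len(K)) {
      J <- jac_slice(data, k)
      N <- null_space_projector(J, w)
      qd[, k] <- object$task_velocities[, k] +
        N %*% stats::rnorm(n, sd = sigma)
    }
    kin_data(qd, apply_jacobian(data, qd), data$jacobian,
             dt = data$dt, labels = data$labels)
  })
}

apply_jacobian <- function(data, qdot) {
  K <- n_samples(data)
  xd <- matrix(0, task_dim(data), K)
  for (k in seq_len(K)) xd[, k] <- jac_slice(data, k) %*% qdot[, k]
  xd
}
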