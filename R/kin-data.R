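#' Kinematic dataset
#'
#' Bundles a sequence of time-step samples from a kinematic chain: joint
#' velocities, end-effector velocities and the (configuration-dependent)
#' Jacobian matrix at every step. This is the input to [ik_fit()] and to the
#' velocity-decomposition tools.
#'
#' Samples are stored column-wise: `qdot` is `n x K` (one column per
#' time-step), `xdot` is `m x K`, and `jacobian` is an `m x n x K` array.
#' Every sample must satisfy the forward-kinematics relation
#' `xdot = J %*% qdot` up to measurement noise; the constructor computes the
#' relative consistency residual per sample and, in strict mode, rejects
#' samples whose residual exceeds `tol`. In lenient mode (the default,
#' appropriate for numerically differentiated recordings) a single warning
#' reports the worst offender.
#'
#' @param qdot numeric `n x K` matrix of joint velocities (rad/s or m/s),
#'   or a length-`n` vector for a single sample.
#' @param xdot numeric `m x K` matrix of end-effector velocities (m/s).
#' @param jacobian `m x n x K` array of Jacobians (rows = task dimensions,
#'   columns = joints), or a single `m x n` matrix recycled across samples.
#' @param q optional `n x K` matrix of joint positions.
#' @param dt optional sampling interval in seconds.
#' @param labels optional named list of metadata (participant, condition,
#'   target, trial, joint names, ...).
#' @param strict logical; reject inconsistent samples rather than warn.
#' @param tol relative consistency tolerance on `||xdot - J qdot||`.
#' @return An object of class `kin_data`.
#' @examples
#' d <- kin_data(qdot = c(0, 1), xdot = 1, jacobian = matrix(c(1, 1), 1))
#' d
#' @seealso [ik_fit()], [decompose_velocity()], [random_benchmark()]
#' @export
kin_data <- function(qdot, xdot, jacobian, q = NULL, dt = NULL,
                     labels = list(), strict = FALSE, tol = 1e-6) {
  if (is.vector(qdot)) qdot <- matrix(qdot, ncol = 1L)
  if (is.vector(xdot)) xdot <- matrix(xdot, ncol = ncol(qdot))
  qdot <- as.matrix(qdot)
  xdot <- as.matrix(xdot)
  n <- nrow(qdot)
  m <- nrow(xdot)
  K <- ncol(qdot)
  if (ncol(xdot) != K)
    stop("'qdot' and 'xdot' must have the same number of samples (columns)")
  if (is.matrix(jacobian))
    jacobian <- array(jacobian, dim = c(nrow(jacobian), ncol(jacobian), K))
  if (length(dim(jacobian)) != 3L)
    stop("'jacobian' must be an m x n x K array or an m x n matrix")
  if (dim(jacobian)[1L] != m || dim(jacobian)[2L] != n)
    stop(sprintf(
      "Jacobian dimensions (%d x %d) do not match task dimension m = %d and joint count n = %d",
      dim(jacobian)[1L], dim(jacobian)[2L], m, n))
  if (dim(jacobian)[3L] != K)
    stop("number of Jacobian slices does not match the number of samples")
  if (!is.null(q)) {
    q <- as.matrix(q)
    if (!all(dim(q) == c(n, K)))
      stop("'q' must be an n x K matrix of joint positions")
  }
  if (!all(is.finite(qdot)) || !all(is.finite(xdot)) || !all(is.finite(jacobian)))
    stop("kinematic data must be finite")

  # forward-kinematics consistency ||xdot - J qdot|| per sample
  res <- vapply(seq_len(K), function(k) {
    r <- xdot[, k] - jacobian[, , k, drop = FALSE][, , 1L] %*% qdot[, k]
    sqrt(sum(r^2)) / max(1, sqrt(sum(xdot[, k]^2)))
  }, numeric(1L))
  bad <- which(res > tol)
  if (length(bad)) {
    msg <- sprintf(
      "%d of %d samples violate xdot = J qdot beyond tol = %g (worst: sample %d, relative residual %.3g)",
      length(bad), K, tol, bad[which.max(res[bad])], max(res))
    if (strict) stop(msg) else warning(msg, call. = FALSE)
  }

  structure(
    list(qdot = qdot, xdot = xdot, jacobian = jacobian, q = q,
         dt = dt, labels = labels, consistency = res),
    class = "kin_data")
}

#' @export
print.kin_data <- function(x, ...) {
  cat(sprintf("<kin_data> %d samples, %d joints, %d task dimension%s\n",
              n_samples(x), n_joints(x), task_dim(x),
              if (task_dim(x) > 1L) "s" else ""))
  if (!is.null(x$dt)) cat(sprintf("  dt = %g s (%.2f s total)\n",
                                  x$dt, x$dt * n_samples(x)))
  if (length(x$labels)) {
    lab <- vapply(x$labels, function(v) paste(format(v), collapse = ","),
                  character(1L))
    cat("  labels:", paste(names(lab), lab, sep = "=", collapse = ", "), "\n")
  }
  cat(sprintf("  max consistency residual: %.3g\n", max(x$consistency)))
  invisible(x)
}

#' Dimensions of a kinematic dataset
#'
#' @param x a [kin_data] object.
#' @return An integer: the number of joints `n`, task dimensions `m`, or
#'   samples `K`.
#' @export
n_joints <- function(x) nrow(x$qdot)

#' @rdname n_joints
#' @export
task_dim <- function(x) nrow(x$xdot)

#' @rdname n_joints
#' @export
n_samples <- function(x) ncol(x$qdot)

#' @export
`[.kin_data` <- function(x, i, ...) {
  i <- seq_len(n_samples(x))[i]
  kin_data(x$qdot[, i, drop = FALSE], x$xdot[, i, drop = FALSE],
           x$jacobian[, , i, drop = FALSE],
           q = if (!is.null(x$q)) x$q[, i, drop = FALSE],
           dt = x$dt, labels = x$labels)
}

#' Concatenate kinematic datasets
#'
#' Joins datasets column-wise (in time order of the arguments). All parts
#' must share the joint count and the task dimension; this is how multiple
#' trials or targets are pooled into one estimation dataset.
#'
#' @param ... `kin_data` objects.
#' @return A single `kin_data` object.
#' @export
c.kin_data <- function(...) {
  parts <- list(...)
  stopifnot(all(vapply(parts, inherits, logical(1L), "kin_data")))
  n <- unique(vapply(parts, n_joints, integer(1L)))
  m <- unique(vapply(parts, task_dim, integer(1L)))
  if (length(n) != 1L || length(m) != 1L)
    stop("all datasets must share the joint count and task dimension")
  dts <- unique(unlist(lapply(parts, `[[`, "dt")))
  qs <- lapply(parts, `[[`, "q")
  kin_data(
    qdot = do.call(cbind, lapply(parts, `[[`, "qdot")),
    xdot = do.call(cbind, lapply(parts, `[[`, "xdot")),
    jacobian = array(unlist(lapply(parts, `[[`, "jacobian")),
                     dim = c(m, n, sum(vapply(parts, n_samples, integer(1L))))),
    q = if (!any(vapply(qs, is.null, logical(1L)))) do.call(cbind, qs),
    dt = if (length(dts) == 1L) dts,
    labels = parts[[1L]]$labels)
}

# single-sample accessor used by internal loops
jac_slice <- function(x, k) {
  matrix(x$jacobian[, , k], nrow = task_dim(x), ncol = n_joints(x))
}

#' Inverse-kinematics weight vector
#'
#' Validates (and by default max-normalizes) a vector of diagonal IK
#' weights. Weights are dimensionless relative costs: joint `i` with a
#' larger `w[i]` is more costly to move and contributes less to the task.
#' Only ratios matter, so weights are scaled to lie in `(0, 1]` with the
#' largest element exactly 1. A strictly positive lower bound keeps the
#' inverse weight matrix well-defined.
#'
#' @param w numeric vector of positive weights.
#' @param normalize divide by the maximum so that `max(w) == 1`.
#' @param lower smallest admissible weight (after normalization).
#' @return A numeric vector of class `ik_weights`.
#' @examples
#' ik_weights(c(2, 1))     # -> 1.0 0.5
#' @export
ik_weights <- function(w, normalize = TRUE, lower = 1e-6) {
  w <- as.numeric(w)
  if (!length(w) || !all(is.finite(w)))
    stop("weights must be a non-empty finite numeric vector")
  if (any(w <= 0))
    stop("IK weights must be strictly positive (W^-1 must exist)")
  if (normalize) w <- w / max(w)
  if (any(w < lower))
    stop(sprintf("normalized weights fall below the lower bound %g", lower))
  if (any(w > 1 + 1e-12))
    stop("normalized weights must lie in (0, 1]")
  structure(w, class = "ik_weights")
}

#' @export
print.ik_weights <- function(x, digits = 4L, ...) {
  cat("IK weights:", paste(format(unclass(x), digits = digits),
                           collapse = " "), "\n")
  invisible(x)
}
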