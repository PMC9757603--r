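#' Write and read kinematic trials in the plain-text interchange format
#'
#' A trial is one directory holding three CSV tables plus a JSON sidecar:
#' `joint_velocities.csv` (`K x n`, one row per time-step),
#' `endeffector_velocities.csv` (`K x m`), `jacobians.csv`
#' (`K x (m*n)`, each Jacobian flattened row-major), optionally
#' `joint_positions.csv` (`K x n`), and `meta.json` recording `n`, `m`,
#' `dt` and free-form labels. Values are written with 17 significant
#' digits so that a round trip preserves the numbers exactly.
#'
#' @param data a [kin_data] object.
#' @param path directory to create/read.
#' @param strict passed to [kin_data()] on read.
#' @return `write_kin_data` returns `path` invisibly; `read_kin_data`
#'   returns a [kin_data].
#' @export
write_kin_data <- function(data, path) {
  stopifnot(inherits(data, "kin_data"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  n <- n_joints(data); m <- task_dim(data); K <- n_samples(data)
  write_num_csv(t(data$qdot), file.path(path, "joint_velocities.csv"),
                paste0("q", seq_len(n)))
  write_num_csv(t(data$xdot), file.path(path, "endeffector_velocities.csv"),
                paste0("x", seq_len(m)))
  Jflat <- t(apply(data$jacobian, 3L, function(J) as.numeric(t(J))))
  if (K == 1L) Jflat <- matrix(Jflat, nrow = 1L)
  write_num_csv(Jflat, file.path(path, "jacobians.csv"),
                paste0("J", rep(seq_len(m), each = n), seq_len(n)))
  if (!is.null(data$q))
    write_num_csv(t(data$q), file.path(path, "joint_positions.csv"),
                  paste0("pos", seq_len(n)))
  meta <- list(n = n, m = m, K = K, dt = data$dt,
               labels = if (length(data$labels)) data$labels else NULL)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_kin_data
#' @export
read_kin_data <- function(path, strict = FALSE) {
  need <- c("joint_velocities.csv", "endeffector_velocities.csv",
            "jacobians.csv", "meta.json")
  missing <- need[!file.exists(file.path(path, need))]
  if (length(missing))
    stop(sprintf("not a kinematic trial directory: '%s' is missing %s",
                 path, paste(missing, collapse = ", ")))
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  n <- meta$n; m <- meta$m
  qdot <- t(read_num_csv(file.path(path, "joint_velocities.csv")))
  xdot <- t(read_num_csv(file.path(path, "endeffector_velocities.csv")))
  if (nrow(qdot) != n || nrow(xdot) != m)
    stop(sprintf(
      "dimension mismatch in '%s': meta declares n = %d, m = %d but tables have %d and %d columns",
      path, n, m, nrow(qdot), nrow(xdot)))
  K <- ncol(qdot)
  Jflat <- read_num_csv(file.path(path, "jacobians.csv"))
  if (nrow(Jflat) != K || ncol(Jflat) != m * n)
    stop(sprintf("jacobians.csv in '%s' must be K x (m*n) = %d x %d", path,
                 K, m * n))
  Jarr <- array(0, dim = c(m, n, K))
  for (k in seq_len(K))
    Jarr[, , k] <- matrix(Jflat[k, ], m, n, byrow = TRUE)
  qpath <- file.path(path, "joint_positions.csv")
  q <- if (file.exists(qpath)) t(read_num_csv(qpath))
  labels <- meta$labels
  kin_data(qdot, xdot, Jarr, q = q, dt = meta$dt,
           labels = if (is.null(labels)) list() else as.list(labels),
           strict = strict)
}

write_num_csv <- function(mat, file, colnames) {
  mat <- as.matrix(mat)
  txt <- apply(mat, 2L, function(col) sprintf("%.17g", col))
  if (nrow(mat) == 1L) txt <- matrix(txt, nrow = 1L)
  utils::write.table(txt, file, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = colnames)
}

read_num_csv <- function(file) {
  m <- as.matrix(utils::read.csv(file, colClasses = "numeric",
                                 check.names = FALSE))
  dimnames(m) <- NULL
  m
}

#' Read an estimation configuration from YAML or JSON
#'
#' The file may set any of the [ik_fit()] arguments (`gamma`, `lambda`,
#' `epsilon`, `max_iter`, `lower`, `w_tol`, `qp_tol`, `overspecified`,
#' `xdot_floor`, `rcond_tol`); unknown fields raise an error so that typos
#' are caught rather than silently ignored.
#'
#' @param path file ending in `.yaml`/`.yml` or `.json`.
#' @return Named list suitable for `do.call(ik_fit, c(list(data), cfg))`.
#' @export
read_ik_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file '%s' not found", path))
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else stop("config must be a .yaml/.yml or .json file")
  if (is.null(cfg)) cfg <- list()
  allowed <- c("gamma", "lambda", "epsilon", "max_iter", "lower", "w_tol",
               "qp_tol", "overspecified", "xdot_floor", "rcond_tol")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    stop(sprintf("unknown config field(s): %s (allowed: %s)",
                 paste(unknown, collapse = ", "),
                 paste(allowed, collapse = ", ")))
  cfg
}

#' Write estimation results to JSON (and the trace to CSV)
#'
#' The JSON report carries the weights, contribution coefficients,
#' convergence information and the per-iteration error trace; optionally
#' the trace is also written as a two-column CSV.
#'
#' @param fit an [ik_fit].
#' @param json_path output JSON file.
#' @param csv_path optional CSV file for the per-iteration trace.
#' @return `json_path`, invisibly.
#' @export
write_ik_result <- function(fit, json_path, csv_path = NULL) {
  stopifnot(inherits(fit, "ik_fit"))
  out <- list(weights = as.numeric(fit$weights),
              beta = fit$beta,
              converged = fit$converged,
              convergence = fit$convergence,
              iterations = fit$iterations,
              error_trace = fit$error_trace,
              gamma_trace = fit$gamma_trace,
              overspecified = if (length(fit$overspecified))
                fit$overspecified else NULL,
              n = fit$n, m = fit$m, K = fit$K)
  jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  if (!is.null(csv_path))
    utils::write.csv(
      data.frame(iteration = seq_along(fit$error_trace) - 1L,
                 mean_residual = fit$error_trace,
                 gamma = fit$gamma_trace),
      csv_path, row.names = FALSE)
  invisible(json_path)
}
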