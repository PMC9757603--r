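#' Cohort of kinematic recordings
#'
#' A cohort bundles many trials, each a [kin_data], keyed by participant,
#' condition, and optionally target and trial number. All trials of one
#' participant must share the joint count and task dimension.
#'
#' @param trials list of [kin_data] objects.
#' @param index data frame with one row per trial; must contain columns
#'   `participant` and `condition`, optionally `target` and `trial`.
#' @param metadata optional named list (experiment id, joint names, ...).
#' @return An object of class `kin_cohort`.
#' @export
kin_cohort <- function(trials, index, metadata = list()) {
  stopifnot(is.list(trials), is.data.frame(index),
            nrow(index) == length(trials),
            all(c("participant", "condition") %in% names(index)))
  if (!all(vapply(trials, inherits, logical(1L), "kin_data")))
    stop("all trials must be kin_data objects")
  for (p in unique(index$participant)) {
    rows <- which(index$participant == p)
    ns <- unique(vapply(trials[rows], n_joints, integer(1L)))
    ms <- unique(vapply(trials[rows], task_dim, integer(1L)))
    if (length(ns) != 1L || length(ms) != 1L)
      stop(sprintf("participant '%s': trials disagree on n or m", p))
  }
  structure(list(trials = trials, index = index, metadata = metadata),
            class = "kin_cohort")
}

#' @export
print.kin_cohort <- function(x, ...) {
  cat(sprintf("<kin_cohort> %d trials, %d participants, conditions: %s\n",
              length(x$trials), length(unique(x$index$participant)),
              paste(unique(x$index$condition), collapse = ", ")))
  invisible(x)
}

#' Write/read a cohort as a tree of interchange-format trial directories
#'
#' Layout: `root/<participant>/<condition>[/<target>]/trial_<k>/`, each
#' leaf a trial directory as produced by [write_kin_data()]. The key
#' columns are also embedded in each trial's labels, so reading only needs
#' the directory tree.
#'
#' @param cohort a [kin_cohort].
#' @param path root directory.
#' @param strict passed to [read_kin_data()].
#' @return `write_cohort` returns `path` invisibly; `read_cohort` a
#'   [kin_cohort].
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "kin_cohort"))
  idx <- cohort$index
  for (i in seq_len(nrow(idx))) {
    parts <- c(path, idx$participant[i], idx$condition[i])
    if ("target" %in% names(idx)) parts <- c(parts, idx$target[i])
    trial_no <- if ("trial" %in% names(idx)) idx$trial[i] else i
    parts <- c(parts, sprintf("trial_%03d", as.integer(trial_no)))
    d <- cohort$trials[[i]]
    d$labels[c("participant", "condition")] <-
      list(idx$participant[i], idx$condition[i])
    if ("target" %in% names(idx)) d$labels$target <- idx$target[i]
    d$labels$trial <- as.integer(trial_no)
    write_kin_data(d, do.call(file.path, as.list(parts)))
  }
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path, strict = FALSE) {
  metas <- list.files(path, pattern = "^meta\\.json$", recursive = TRUE,
                      full.names = TRUE)
  if (!length(metas))
    stop(sprintf("no interchange-format trials found under '%s'", path))
  dirs <- sort(dirname(metas))
  trials <- lapply(dirs, read_kin_data, strict = strict)
  grab <- function(d, field, default)
    if (!is.null(d$labels[[field]])) d$labels[[field]] else default
  index <- data.frame(
    participant = vapply(trials, grab, character(1L), "participant", NA_character_),
    condition = vapply(trials, grab, character(1L), "condition", NA_character_),
    stringsAsFactors = FALSE)
  tg <- lapply(trials, function(d) d$labels$target)
  if (!all(vapply(tg, is.null, logical(1L))))
    index$target <- vapply(tg, function(v) if (is.null(v)) NA_character_
                           else as.character(v), character(1L))
  tr <- lapply(trials, function(d) d$labels$trial)
  if (!all(vapply(tr, is.null, logical(1L))))
    index$trial <- vapply(tr, function(v) if (is.null(v)) NA_integer_
                          else as.integer(v), integer(1L))
  if (anyNA(index$participant))
    stop("trial labels missing 'participant'; cannot index the cohort")
  kin_cohort(trials, index)
}

#' Estimate IK weights per participant and condition
#'
#' Runs [ik_fit()] on each `(participant, condition)` cell, either on the
#' trials concatenated in time (the default, pooling targets and trials
#' into one dataset) or separately per trial. Contribution coefficients
#' are computed alongside.
#'
#' @param cohort a [kin_cohort].
#' @param grouping `"concatenated"` (one fit per participant x condition)
#'   or `"per-trial"`.
#' @param gamma null-space projection ratio: cohort analyses require an
#'   explicit choice (no default), since the appropriate ratio depends on
#'   how correlated null and task velocities are in the recordings.
#' @param ... further arguments passed to [ik_fit()] (notably
#'   `overspecified` for chains with an over-specified joint).
#' @return A data frame with one row per fit: the key columns, `w1..wn`,
#'   `beta1..betan`, `iterations`, `converged`. The list of full
#'   [ik_fit] objects is attached as attribute `fits`.
#' @export
estimate_cohort_weights <- function(cohort, gamma,
                                    grouping = c("concatenated", "per-trial"),
                                    ...) {
  stopifnot(inherits(cohort, "kin_cohort"))
  grouping <- match.arg(grouping)
  idx <- cohort$index
  if (grouping == "concatenated") {
    key <- interaction(idx$participant, idx$condition, drop = TRUE)
    groups <- split(seq_len(nrow(idx)), key)
    keys <- do.call(rbind, lapply(groups, function(rows)
      idx[rows[1L], c("participant", "condition"), drop = FALSE]))
    datasets <- lapply(groups, function(rows)
      do.call(c, cohort$trials[rows]))
  } else {
    keys <- idx
    datasets <- cohort$trials
  }
  fits <- vector("list", length(datasets))
  rows <- vector("list", length(datasets))
  for (i in seq_along(datasets)) {
    fit <- tryCatch(
      ik_fit(datasets[[i]], gamma = gamma, ...),
      error = function(e) stop(sprintf(
        "estimation failed for %s: %s",
        paste(unlist(keys[i, ]), collapse = "/"), conditionMessage(e)),
        call. = FALSE))
    fits[[i]] <- fit
    w <- as.numeric(fit$weights)
    row <- cbind(keys[i, , drop = FALSE],
                 as.data.frame(as.list(stats::setNames(
                   c(w, fit$beta),
                   c(paste0("w", seq_along(w)),
                     paste0("beta", seq_along(w)))))),
                 iterations = fit$iterations, converged = fit$converged)
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  out
}

#' Aggregate cohort weights into group-level contribution coefficients
#'
#' Two routes are supported: aggregate the per-participant weights across
#' the cohort (median or mean) and then transform to contribution
#' coefficients, or transform each participant first and aggregate the
#' coefficients (`"transform-then-aggregate"`, re-normalized to sum to 1).
#'
#' @param weight_table output of [estimate_cohort_weights()].
#' @param aggregate `"median"`, `"mean"`, or `"transform-then-aggregate"`
#'   (median of per-participant coefficients).
#' @return Data frame: one row per condition, columns `beta1..betan`.
#' @export
cohort_contributions <- function(weight_table,
                                 aggregate = c("median", "mean",
                                               "transform-then-aggregate")) {
  aggregate <- match.arg(aggregate)
  wcols <- grep("^w[0-9]+$", names(weight_table), value = TRUE)
  bcols <- grep("^beta[0-9]+$", names(weight_table), value = TRUE)
  out <- lapply(split(weight_table, weight_table$condition), function(g) {
    beta <- switch(aggregate,
      median = contribution_coefficients(apply(g[wcols], 2L, stats::median)),
      mean = contribution_coefficients(colMeans(g[wcols])),
      `transform-then-aggregate` = {
        b <- apply(g[bcols], 2L, stats::median)
        b / sum(b)
      })
    as.data.frame(as.list(stats::setNames(beta, bcols)))
  })
  cbind(data.frame(condition = names(out)),
        do.call(rbind, out), row.names = NULL)
}

#' Null-space utilization under estimated vs identity weights
#'
#' For every trial, decomposes the recorded joint velocities twice: under
#' the participant/condition's estimated weights and under identity
#' weights (the conventional unweighted pseudo-inverse). Returns per-trial
#' null-velocity RMS values and, when all trials share a common length,
#' per-time-step mean and SD profiles of the null velocities aggregated
#' across participants and trials.
#'
#' @param cohort a [kin_cohort].
#' @param weight_table output of [estimate_cohort_weights()] (concatenated
#'   grouping), providing the weights per participant x condition.
#' @return List with `rms` (data frame: key columns, `weighting`,
#'   `rms_null`) and `profiles` (data frame: `condition`, `weighting`,
#'   `joint`, `step`, `mean`, `sd`; `NULL` if trial lengths differ).
#' @export
nullspace_utilization <- function(cohort, weight_table) {
  stopifnot(inherits(cohort, "kin_cohort"))
  idx <- cohort$index
  wcols <- grep("^w[0-9]+$", names(weight_table), value = TRUE)
  lookup <- function(p, cond) {
    row <- weight_table$participant == p & weight_table$condition == cond
    if (!any(row)) stop(sprintf("no weights for participant '%s', condition '%s'",
                                p, cond))
    as.numeric(weight_table[which(row)[1L], wcols])
  }
  rms_rows <- list(); prof_rows <- list()
  Ks <- vapply(cohort$trials, n_samples, integer(1L))
  common_K <- length(unique(Ks)) == 1L
  for (i in seq_along(cohort$trials)) {
    d <- cohort$trials[[i]]
    n <- n_joints(d)
    for (weighting in c("estimated", "identity")) {
      w <- if (weighting == "estimated")
        lookup(idx$participant[i], idx$condition[i]) else rep(1, n)
      dec <- decompose_velocity(d, weights = w)
      stopifnot(max(abs(dec$task + dec$null - d$qdot)) < 1e-8)
      rms_rows[[length(rms_rows) + 1L]] <- cbind(
        idx[i, , drop = FALSE], weighting = weighting,
        rms_null = sqrt(mean(dec$null^2)))
      if (common_K)
        prof_rows[[length(prof_rows) + 1L]] <- data.frame(
          condition = idx$condition[i], weighting = weighting,
          joint = rep(seq_len(n), times = ncol(dec$null)),
          step = rep(seq_len(ncol(dec$null)), each = n),
          value = as.numeric(dec$null))
    }
  }
  rms <- do.call(rbind, rms_rows); rownames(rms) <- NULL
  profiles <- NULL
  if (common_K) {
    long <- do.call(rbind, prof_rows)
    profiles <- stats::aggregate(
      value ~ condition + weighting + joint + step, data = long,
      FUN = function(v) c(mean = mean(v), sd = stats::sd(v)))
    profiles <- cbind(profiles[setdiff(names(profiles), "value")],
                      mean = profiles$value[, "mean"],
                      sd = profiles$value[, "sd"])
  }
  list(rms = rms, profiles = profiles)
}
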