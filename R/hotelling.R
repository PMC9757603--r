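#' Paired Hotelling T-squared contrast between two conditions
#'
#' Multivariate paired comparison of weight components measured on the
#' same participants under two conditions. With `d_i` the per-participant
#' difference vectors (length `p`), `N` participants, mean difference
#' `dbar` and sample covariance `S` of the differences, the statistic is
#' `T2 = N * dbar' S^-1 dbar`, referred to an F distribution through
#' `F = (N - p) / (p * (N - 1)) * T2` with `(p, N - p)` degrees of
#' freedom. Components whose paired differences are (numerically)
#' degenerate make `S` singular; such components — e.g. weights pinned to
#' 1 by the max-normalization convention — must be excluded before
#' calling.
#'
#' @param x,y numeric `N x p` matrices (participants x components), rows
#'   paired; or vectors for `p = 1`.
#' @return An object of classes `ik_contrast` and `htest` with
#'   `statistic` (`T2`), `f_statistic`, `parameter` (numerator/denominator
#'   df), `p.value`, `estimate` (mean differences) and the difference
#'   matrix in `differences`.
#' @examples
#' set.seed(1)
#' a <- matrix(rnorm(34), 17, 2)
#' paired_hotelling(a, a + 0.5)
#' @export
paired_hotelling <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (!all(dim(x) == dim(y)))
    stop("'x' and 'y' must be paired matrices of identical dimension")
  d <- x - y
  N <- nrow(d); p <- ncol(d)
  if (N <= p)
    stop(sprintf(
      "need more participants (N = %d) than components (p = %d)", N, p))
  dbar <- colMeans(d)
  if (all(d == 0)) {
    # exactly identical conditions: no difference to test
    return(structure(
      list(statistic = c(T2 = 0), f_statistic = c(F = 0),
           parameter = c(num.df = p, den.df = N - p), p.value = 1,
           estimate = stats::setNames(dbar, paste0("mean.diff", seq_len(p))),
           method = "Paired Hotelling T-squared contrast",
           data.name = sprintf("%d paired observations of %d components",
                               N, p),
           differences = d),
      class = c("ik_contrast", "htest")))
  }
  S <- stats::cov(d)
  rc <- rcond(S)
  if (!is.finite(rc) || rc < 1e-12)
    stop(sprintf(
      "singular covariance of paired differences (rcond = %.3g); drop degenerate components (e.g. weights pinned at 1) and retry",
      rc))
  T2 <- as.numeric(N * crossprod(dbar, solve(S, dbar)))
  Fstat <- (N - p) / (p * (N - 1)) * T2
  pval <- stats::pf(Fstat, p, N - p, lower.tail = FALSE)
  structure(
    list(statistic = c(T2 = T2),
         f_statistic = c(F = Fstat),
         parameter = c(num.df = p, den.df = N - p),
         p.value = pval,
         estimate = stats::setNames(dbar, paste0("mean.diff", seq_len(p))),
         method = "Paired Hotelling T-squared contrast",
         data.name = sprintf("%d paired observations of %d components", N, p),
         differences = d),
    class = c("ik_contrast", "htest"))
}

#' @export
print.ik_contrast <- function(x, digits = 4L, ...) {
  cat("\n\t", x$method, "\n\n")
  cat("data: ", x$data.name, "\n")
  pshow <- if (x$p.value < 1e-4) "p < 0.001"
           else sprintf("p = %.4g", x$p.value)
  cat(sprintf("T2 = %.4g, F(%d, %d) = %.4g, %s\n",
              x$statistic, x$parameter["num.df"], x$parameter["den.df"],
              x$f_statistic, pshow))
  cat("mean differences:",
      paste(format(x$estimate, digits = digits), collapse = " "), "\n\n")
  invisible(x)
}

#' Contrast two conditions of a cohort weight table
#'
#' Convenience wrapper: extracts the chosen weight components for two
#' conditions from the output of [estimate_cohort_weights()], pairs rows
#' by participant, and runs [paired_hotelling()].
#'
#' @param weight_table output of [estimate_cohort_weights()]
#'   (concatenated grouping: one row per participant x condition).
#' @param conditions character vector of the two condition names.
#' @param components integer indices of the weight components to compare.
#'   Components pinned by convention (over-specified joints, or the joint
#'   anchoring the max-normalization in every fit) have degenerate paired
#'   differences and must be left out.
#' @return An `ik_contrast` (see [paired_hotelling()]).
#' @export
contrast_conditions <- function(weight_table, conditions, components) {
  stopifnot(length(conditions) == 2L, length(components) >= 1L)
  wcols <- paste0("w", components)
  a <- weight_table[weight_table$condition == conditions[1L], ]
  b <- weight_table[weight_table$condition == conditions[2L], ]
  common <- intersect(a$participant, b$participant)
  if (length(common) < 2L)
    stop("fewer than two participants present in both conditions")
  a <- a[match(common, a$participant), wcols, drop = FALSE]
  b <- b[match(common, b$participant), wcols, drop = FALSE]
  paired_hotelling(as.matrix(a), as.matrix(b))
}
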