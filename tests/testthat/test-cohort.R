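test_that("interchange format round-trips a trial exactly", {
  d <- random_benchmark(n = 4, m = 2, K = 12, w_star = c(1, 0.7, 0.3, 0.9),
                        sigma = 0.15, seed = 40)
  d$labels <- list(participant = "p1", condition = "Natural")
  dir <- withr::local_tempdir()
  write_kin_data(d, file.path(dir, "trial"))
  r <- read_kin_data(file.path(dir, "trial"))
  expect_equal(r$qdot, d$qdot, tolerance = 0)
  expect_equal(r$xdot, d$xdot, tolerance = 0)
  expect_equal(r$jacobian, d$jacobian, tolerance = 0)
  expect_equal(r$labels$condition, "Natural")
  # missing table is reported by name
  file.remove(file.path(dir, "trial", "jacobians.csv"))
  expect_error(read_kin_data(file.path(dir, "trial")), "jacobians.csv")
})

test_that("cohorts round-trip through the directory tree", {
  co <- synthetic_cohort(list(p1 = c(1, 0.6, 0.3, 0.9),
                              p2 = c(1, 0.4, 0.8, 0.7)),
                         conditions = c("A", "B"), trials_per = 2,
                         K = 15)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  r <- read_cohort(dir)
  expect_equal(length(r$trials), length(co$trials))
  expect_setequal(unique(r$index$participant), c("p1", "p2"))
  expect_setequal(unique(r$index$condition), c("A", "B"))
  key <- function(idx) paste(idx$participant, idx$condition, idx$trial)
  reord <- match(key(co$index), key(r$index))
  for (i in seq_along(co$trials))
    expect_equal(r$trials[[reord[i]]]$qdot, co$trials[[i]]$qdot,
                 tolerance = 0)
  expect_error(read_cohort(file.path(dir, "nope")), "no interchange")
})

test_that("cohort estimation recovers each participant's nominal weights", {
  truth <- list(p1 = c(1, 0.6, 0.3, 0.9), p2 = c(1, 0.35, 0.75, 0.5))
  co <- synthetic_cohort(truth, trials_per = 3, K = 150, sigma = 0)
  tab <- estimate_cohort_weights(co, gamma = 0.6, max_iter = 200)
  expect_equal(nrow(tab), 2L)
  for (p in names(truth)) {
    w <- as.numeric(tab[tab$participant == p, paste0("w", 1:4)])
    expect_equal(w, truth[[p]], tolerance = 0.02)
  }
  expect_equal(rowSums(tab[paste0("beta", 1:4)]), rep(1, 2),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("per-trial and concatenated estimates agree on noise-free data", {
  truth <- list(p1 = c(1, 0.5, 0.25, 0.8))
  co <- synthetic_cohort(truth, trials_per = 2, K = 150, sigma = 0)
  conc <- estimate_cohort_weights(co, gamma = 0.6, max_iter = 200)
  per <- estimate_cohort_weights(co, gamma = 0.6, grouping = "per-trial",
                                 max_iter = 200)
  expect_equal(nrow(per), 2L)
  for (i in 1:2)
    expect_equal(as.numeric(per[i, paste0("w", 1:4)]),
                 as.numeric(conc[1, paste0("w", 1:4)]), tolerance = 0.02)
})

test_that("null-space utilization is near zero under nominal weights, larger under identity", {
  truth <- list(p1 = c(1, 0.5, 0.25, 0.8))
  co <- synthetic_cohort(truth, trials_per = 2, K = 120, sigma = 0)
  tab <- estimate_cohort_weights(co, gamma = 0.6, max_iter = 200)
  nu <- nullspace_utilization(co, tab)
  est <- nu$rms$rms_null[nu$rms$weighting == "estimated"]
  idn <- nu$rms$rms_null[nu$rms$weighting == "identity"]
  expect_true(all(est < 1e-2))
  expect_true(all(idn > 10 * est))
  expect_s3_class(nu$profiles, "data.frame")
  expect_setequal(unique(nu$profiles$weighting), c("estimated", "identity"))
})

test_that("group contributions aggregate per condition under each documented rule", {
  truth <- list(p1 = c(1, 0.6, 0.3, 0.9), p2 = c(1, 0.5, 0.35, 0.85))
  co <- synthetic_cohort(truth, trials_per = 2, K = 150, sigma = 0)
  tab <- estimate_cohort_weights(co, gamma = 0.6, max_iter = 200)
  for (rule in c("median", "mean", "transform-then-aggregate")) {
    g <- cohort_contributions(tab, aggregate = rule)
    expect_equal(nrow(g), 1L)
    expect_equal(sum(g[paste0("beta", 1:4)]), 1, tolerance = 1e-10)
  }
})

test_that("paired Hotelling matches the textbook one-sample formula", {
  set.seed(44)
  for (rep in 1:5) {
    x <- matrix(rnorm(34), 17, 2)
    y <- x + matrix(rnorm(34, mean = 0.3, sd = 0.5), 17, 2)
    ct <- paired_hotelling(x, y)
    # independent oracle: explicit inverse and Mahalanobis form
    d <- x - y; N <- nrow(d); p <- ncol(d)
    T2 <- N * mahalanobis(colMeans(d), rep(0, p), cov(d))
    Fs <- (N - p) / (p * (N - 1)) * T2
    expect_equal(unname(ct$statistic), T2, tolerance = 1e-10)
    expect_equal(unname(ct$f_statistic), Fs, tolerance = 1e-10)
    expect_equal(ct$p.value, pf(Fs, p, N - p, lower.tail = FALSE),
                 tolerance = 1e-12)
    expect_identical(unname(ct$parameter), c(2L, 15L))
  }
})

test_that("degenerate paired differences are handled as specified", {
  x <- matrix(rnorm(20), 10, 2)
  expect_equal(unname(paired_hotelling(x, x)$statistic), 0)
  expect_equal(paired_hotelling(x, x)$p.value, 1)
  # constant non-zero differences: zero variance, singular covariance
  expect_error(paired_hotelling(matrix(1:4, 4, 1), matrix(0:3, 4, 1)),
               "singular covariance")
  expect_error(paired_hotelling(matrix(rnorm(4), 2, 2),
                                matrix(rnorm(4), 2, 2)),
               "more participants")
})

test_that("condition contrasts pair participants and respect the df convention", {
  set.seed(45)
  tab <- data.frame(participant = rep(sprintf("p%02d", 1:17), 2),
                    condition = rep(c("Natural", "Viscous"), each = 17),
                    w1 = 1, w2 = runif(34, 0.2, 1),
                    w3 = runif(34, 0.2, 1), w4 = 1)
  ct <- contrast_conditions(tab, c("Natural", "Viscous"), components = 2:3)
  expect_identical(unname(ct$parameter), c(2L, 15L))
  expect_true(ct$p.value >= 0 && ct$p.value <= 1)
  expect_output(print(ct), "T2")
  # a pinned component alongside a varying one degenerates the covariance
  expect_error(contrast_conditions(tab, c("Natural", "Viscous"),
                                   components = c(1, 2)),
               "singular covariance")
  # two fully pinned components: identical pairs, nothing to test
  ct0 <- contrast_conditions(tab, c("Natural", "Viscous"),
                             components = c(1, 4))
  expect_equal(unname(ct0$statistic), 0)
  expect_equal(ct0$p.value, 1)
})
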