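test_that("Kruskal-Wallis handles identical groups, matches the rank formula, and validates input", {
  same <- kruskal_wallis(list(a = c(5, 5), b = c(5, 5), c = c(5, 5)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  groups <- list(g1 = c(1, 2), g2 = c(3, 4), g3 = c(5, 6))
  res <- kruskal_wallis(groups, metric = "fd_percent")
  # direct rank-sum arithmetic: H = 12/(N(N+1)) sum R_i^2/n_i - 3(N+1)
  n <- 6; rsums <- c(3, 7, 11)
  h <- 12 / (n * (n + 1)) * sum(rsums^2 / 2) - 3 * (n + 1)
  expect_equal(res$statistic, h)
  expect_equal(res$p_value, pchisq(h, df = 2, lower.tail = FALSE))

  # relabelling equal-sized identical groups leaves H unchanged
  perm <- kruskal_wallis(groups[c(3, 1, 2)])
  expect_equal(perm$statistic, res$statistic)

  expect_error(kruskal_wallis(list(a = 1, b = c(2, 3), c = c(4, 5))),
               "at least 2")
})

test_that("Mann-Whitney matches exact enumeration, is symmetric, and degenerates to p = 1", {
  res <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 0.1)
  expect_equal(res$p_value, oracle_mw_exact_p(c(1, 2, 3), c(4, 5, 6)))

  withr::local_seed(30)
  a <- runif(5); b <- runif(4) + 0.3
  expect_equal(mann_whitney(a, b)$p_value,
               oracle_mw_exact_p(a, b))
  expect_equal(mann_whitney(a, b)$p_value, mann_whitney(b, a)$p_value)

  same <- mann_whitney(c(2, 4, 6), c(2, 4, 6))
  expect_equal(same$p_value, 1)
  expect_error(mann_whitney(numeric(0), 1), "nonempty")

  # above the exact-enumeration regime the normal approximation is used
  big_a <- rnorm(10); big_b <- rnorm(10) + 1
  approx <- mann_whitney(big_a, big_b)
  expect_true(approx$p_value > 0 && approx$p_value < 1)
})

test_that("Welch t matches the hand formula and honours degenerate-variance conventions", {
  a <- c(1, 2, 3); b <- c(1, 2, 3, 4, 5)
  res <- welch_t(a, b)
  se2 <- var(a) / 3 + var(b) / 5
  t_hand <- (mean(a) - mean(b)) / sqrt(se2)
  df_hand <- se2^2 / ((var(a) / 3)^2 / 2 + (var(b) / 5)^2 / 4)
  expect_equal(res$statistic, t_hand)
  expect_equal(res$p_value, 2 * pt(-abs(t_hand), df_hand))

  expect_equal(welch_t(a, a)$statistic, 0)
  expect_equal(welch_t(a, a)$p_value, 1)
  expect_equal(welch_t(10 * a, 10 * b)$statistic, res$statistic)

  expect_equal(welch_t(c(2, 2), c(2, 2))$p_value, 1)
  expect_error(welch_t(c(2, 2), c(3, 3)), "undefined")
})

make_records <- function(n, seed, metric_fun) {
  set.seed(seed)
  d <- data.frame(
    radius_px = 8L,
    age = runif(n, 30, 70),
    treatment_duration = runif(n, 1, 25),
    daily_dose_mg_per_kg = runif(n, 3, 8),
    cumulative_dose_g = runif(n, 500, 3000))
  d$fd_percent <- metric_fun(d)
  d
}

test_that("regression recovers a noiseless linear signal to machine tolerance", {
  rec <- make_records(50, 31, function(d) 5 + 0.8 * d$age)
  # a noiseless fit legitimately trips summary.lm's perfect-fit warning
  tab <- suppressWarnings(fd_regression(rec, "fd_percent", 8))
  est <- tab$estimate[tab$term == "age"]
  expect_equal(est, 0.8, tolerance = 1e-8)
  expect_lt(tab$p_value[tab$term == "age"], 1e-8)
})

test_that("regression finds no covariate signal under the null in most seeds", {
  hits <- sapply(1:10, function(s) {
    rec <- make_records(200, 100 + s, function(d) rnorm(nrow(d)))
    tab <- fd_regression(rec, "fd_percent", 8)
    all(tab$p_value[tab$term != "(Intercept)"] > 0.01)
  })
  expect_gte(sum(hits), 9)
})

test_that("rank-deficient designs raise a singularity error naming the collinear column", {
  rec <- make_records(30, 32, function(d) rnorm(nrow(d)))
  rec$cumulative_dose_g <- rec$daily_dose_mg_per_kg
  expect_error(fd_regression(rec, "fd_percent", 8),
               "collinear.*cumulative_dose_g")
  expect_error(fd_regression(rec[1:4, ], "fd_percent", 8), "at least 2 more")
})

test_that("p-values stay in [0, 1] under random inputs and identifier relabelling", {
  withr::local_seed(33)
  for (i in 1:20) {
    vals <- list(a = rnorm(sample(2:8, 1)), b = rnorm(sample(2:8, 1)),
                 c = rnorm(sample(2:8, 1)))
    p <- c(kruskal_wallis(vals)$p_value,
           mann_whitney(vals$a, vals$b)$p_value,
           welch_t(vals$a, vals$b)$p_value)
    expect_true(all(p >= 0 & p <= 1))
  }
})
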