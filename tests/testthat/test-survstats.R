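# independent product-limit oracle: naive loop over distinct times,
# events-first at ties
km_oracle <- function(time, event, eval_times) {
  s <- 1
  out <- numeric(length(eval_times))
  for (k in seq_along(eval_times)) {
    tk <- eval_times[k]
    s <- 1
    for (u in sort(unique(time[time <= tk]))) {
      d <- sum(time == u & event == 1)
      n <- sum(time >= u)
      if (d > 0) s <- s * (1 - d / n)
    }
    out[k] <- s
  }
  out
}

test_that("Kaplan-Meier estimate matches hand product-limit values", {
  km <- km_curve(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km$surv[km$time == 1], 2 / 3, tolerance = 1e-12)
  expect_equal(km$surv[km$time == 3], 0, tolerance = 1e-12)

  all_cens <- km_curve(c(4, 8, 15), c(0, 0, 0))
  expect_true(all(all_cens$surv == 1))

  one <- km_curve(5, 1)
  expect_equal(one$surv, 0)

  expect_error(km_curve(c(-1, 2), c(1, 1)), "non-negative")
  expect_error(km_curve(c(1, 2), c(1, 2)), "0 .*or 1")
})

test_that("Kaplan-Meier agrees with an independent product-limit oracle", {
  set.seed(41)
  for (rep in 1:5) {
    time <- round(rexp(40, 0.1), 1)
    event <- rbinom(40, 1, 0.6)
    km <- km_curve(time, event)
    expect_equal(km$surv, km_oracle(time, event, km$time), tolerance = 1e-10)
  }
})

test_that("log-rank test reproduces the hand O/E/V computation", {
  # per event time: O - E = 7/6, V = 17/36, statistic = 49/17
  lr <- logrank_test(c(1, 2, 3, 4), c(1, 1, 1, 1), c("A", "A", "B", "B"))
  expect_equal(lr$statistic, 49 / 17, tolerance = 1e-10)
  expect_lt(abs(lr$statistic - 2.8824), 5e-5)
  expect_lt(abs(lr$p_value - 0.08956), 5e-5)
  expect_equal(sum(lr$observed), 4)
  expect_equal(sum(lr$observed), sum(lr$expected), tolerance = 1e-9)
})

test_that("log-rank is zero for identical groups and symmetric in labels", {
  time <- c(1, 3, 5, 7, 1, 3, 5, 7)
  event <- c(1, 0, 1, 1, 1, 0, 1, 1)
  grp <- rep(c("A", "B"), each = 4)
  lr <- logrank_test(time, event, grp)
  expect_equal(lr$statistic, 0, tolerance = 1e-12)
  expect_equal(lr$p_value, 1, tolerance = 1e-12)

  set.seed(2)
  t2 <- rexp(30); e2 <- rbinom(30, 1, 0.7)
  g2 <- rep(c("A", "B"), 15)
  lr_ab <- logrank_test(t2, e2, g2)
  lr_ba <- logrank_test(t2, e2, ifelse(g2 == "A", "B", "A"))
  expect_equal(lr_ab$statistic, lr_ba$statistic, tolerance = 1e-12)
  expect_equal(lr_ab$p_value, lr_ba$p_value, tolerance = 1e-12)

  expect_error(logrank_test(c(1, 2), c(0, 0), c("A", "B")), "at least one")
  expect_error(logrank_test(1:3, c(1, 1, 1), c("A", "A", "A")), "2 groups")
})

test_that("chi-square independence matches hand arithmetic and brute force", {
  res <- chi_square_independence(matrix(c(30, 10, 10, 30), 2))
  expect_equal(res$statistic, 20, tolerance = 1e-10)
  expect_equal(res$df, 1)
  expect_equal(res$p_value, 7.744e-6, tolerance = 1e-3)
  expect_true(all(res$expected == 20))

  prop <- chi_square_independence(matrix(c(10, 20, 30, 60), 2))
  expect_equal(prop$statistic, 0, tolerance = 1e-12)

  tab <- matrix(c(12, 5, 9, 14, 8, 3), 2, 3)
  expect_equal(chi_square_independence(tab)$statistic,
               chi_square_independence(t(tab))$statistic, tolerance = 1e-12)

  # brute force sum (O-E)^2 / E on random tables
  set.seed(19)
  for (i in 1:10) {
    rt <- matrix(rpois(6, 15) + 1, 2, 3)
    res_i <- chi_square_independence(rt)
    e <- outer(rowSums(rt), colSums(rt)) / sum(rt)
    expect_equal(res_i$statistic, sum((rt - e)^2 / e), tolerance = 1e-10)
    expect_equal(rowSums(res_i$expected), rowSums(rt), tolerance = 1e-9)
  }

  expect_error(chi_square_independence(matrix(c(0, 0, 5, 5), 2)), "margin")
  expect_error(chi_square_independence(matrix(c(1.5, 2, 3, 4), 2)), "integer")
})

test_that("Pearson correlation hits exact values and validates input", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_correlation(x, 2 * x + 1), 1, tolerance = 1e-12)
  expect_equal(pearson_correlation(x, -x), -1, tolerance = 1e-12)
  expect_equal(pearson_correlation(c(1, 2, 3), c(1, 3, 2)), 0.5,
               tolerance = 1e-12)
  expect_error(pearson_correlation(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(pearson_correlation(1:3, 1:4), "equal length")
  expect_error(pearson_correlation(1:2, 2:1), "at least 3")
})
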