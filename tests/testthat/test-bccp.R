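test_that("t-statistic weights match hand arithmetic", {
  # one gene: positive class (1, 2), negative class (-1, -2)
  x <- matrix(c(1, 2, -1, -2), 1, 4,
              dimnames = list("G1", paste0("S", 1:4)))
  fit <- bccp(x, c("P", "P", "N", "N"), positive = "P")
  expect_equal(unname(coef(fit)["G1"]), 4.2426, tolerance = 1e-4)

  # equal class means give zero weight
  x2 <- rbind(x, G2 = c(1, -1, 1, -1))
  fit2 <- bccp(x2, c("P", "P", "N", "N"), positive = "P")
  expect_equal(unname(coef(fit2)["G2"]), 0)
})

test_that("swapping the positive class negates weights and flips posteriors", {
  d <- make_two_class(n_genes = 30, n_per_class = 10, delta = 1, seed = 5)
  z <- standardize_genes(d$x)
  fit_soh <- bccp(z, d$labels, positive = "SOH")
  fit_ah <- bccp(z, d$labels, positive = "AH")
  expect_equal(coef(fit_ah), -coef(fit_soh), tolerance = 1e-12)
  expect_equal(fit_ah$score_stats$mean,
               -rev(fit_soh$score_stats$mean), tolerance = 1e-12)
  p_soh <- predict(fit_soh, z)$posterior
  p_ah <- predict(fit_ah, z)$posterior
  expect_equal(p_ah, 1 - p_soh, tolerance = 1e-12)
})

test_that("compound scores are the weighted sum and behave linearly", {
  fake <- fake_bccp(2, -2, 1)
  fake$genes <- c("G1", "G2")
  fake$weights <- c(G1 = 2, G2 = -1)
  nd <- matrix(c(1, 3), 2, 1, dimnames = list(c("G1", "G2"), "S1"))
  expect_equal(unname(compound_score(fake, nd, min_coverage = 0)["S1"]), -1)

  zero <- matrix(0, 2, 1, dimnames = list(c("G1", "G2"), "S0"))
  expect_equal(unname(compound_score(fake, zero)["S0"]), 0)

  doubled <- fake
  doubled$weights <- 2 * fake$weights
  set.seed(9)
  nd2 <- matrix(rnorm(10), 2, 5,
                dimnames = list(c("G1", "G2"), paste0("S", 1:5)))
  expect_equal(compound_score(doubled, nd2), 2 * compound_score(fake, nd2),
               tolerance = 1e-12, ignore_attr = TRUE)
  # additivity in the expression vector
  nd3 <- matrix(rnorm(10), 2, 5,
                dimnames = list(c("G1", "G2"), paste0("S", 1:5)))
  expect_equal(compound_score(fake, nd2 + nd3),
               compound_score(fake, nd2) + compound_score(fake, nd3),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("posterior probabilities match hand-computed Gaussian ratios", {
  # symmetric case: score at the midpoint -> exactly 0.5, tie called negative
  sym <- predict(fake_bccp(2, -2, 1), score_matrix(0))
  expect_equal(sym$posterior, 0.5)
  expect_equal(sym$label, "AH")

  # equal variances: logistic closed form 1/(1+exp(-8))
  p1 <- predict(fake_bccp(2, -2, 1), score_matrix(2))$posterior
  expect_equal(p1, 0.999665, tolerance = 1e-6)

  # unequal variances: ratio of Gaussian densities
  p2 <- predict(fake_bccp(1, -1, 1, 2), score_matrix(0))$posterior
  expect_equal(p2, 0.5789, tolerance = 1e-4)
})

test_that("posteriors agree with the logistic closed form when SDs are equal", {
  set.seed(13)
  for (i in 1:200) {
    mu_p <- rnorm(1, 2, 3); mu_n <- rnorm(1, -2, 3)
    sigma <- runif(1, 0.2, 4); c0 <- rnorm(1, 0, 5)
    post <- predict(fake_bccp(mu_p, mu_n, sigma), score_matrix(c0))$posterior
    closed <- 1 / (1 + exp(-(mu_p - mu_n) * (c0 - (mu_p + mu_n) / 2) / sigma^2))
    expect_lt(abs(post - closed), 1e-10)
    expect_gte(post, 0); expect_lte(post, 1)
  }
})

test_that("leave-one-out cross-validation is 0 on separable data and symmetric", {
  d <- make_two_class(n_genes = 50, n_per_class = 20, delta = 3, seed = 21)
  z <- standardize_genes(d$x)
  rate <- loocv_error(z, d$labels, positive = "SOH")
  expect_equal(as.numeric(rate), 0)
  calls <- attr(rate, "calls")
  expect_named(calls, colnames(z))

  rate_swapped <- loocv_error(z, d$labels, positive = "AH")
  expect_equal(as.numeric(rate_swapped), as.numeric(rate))
})

test_that("degenerate inputs raise the documented errors", {
  d <- make_two_class(n_genes = 10, n_per_class = 5, delta = 1, seed = 2)
  z <- standardize_genes(d$x)
  expect_error(bccp(z, rep("SOH", 10)), "exactly 2 classes")
  expect_error(bccp(z[, 1:6], c("SOH", rep("AH", 5))), "at least 2 samples")
  expect_error(bccp(z, d$labels, genes = c("NOPE1", "NOPE2")),
               "none of the signature genes")

  # constant within-class scores: identical samples in both classes
  xc <- matrix(rep(c(1, 1, 0, 0), each = 3), 3, 4,
               dimnames = list(paste0("G", 1:3), paste0("S", 1:4)))
  expect_error(bccp(xc, c("P", "P", "N", "N"), positive = "P"), "constant")

  fake <- fake_bccp(1, -1, 1)
  off <- matrix(0, 1, 1, dimnames = list("OTHER", "S1"))
  expect_error(compound_score(fake, off), "no model genes")

  expect_error(loocv_error(z[, 1:7], c(rep("SOH", 2), rep("AH", 5))),
               "at least 3 samples")
})

test_that("signature genes missing from the target are tolerated up to coverage", {
  d <- make_two_class(n_genes = 20, n_per_class = 10, delta = 2, seed = 4)
  z <- standardize_genes(d$x)
  fit <- bccp(z, d$labels)
  part <- z[1:12, , drop = FALSE]   # 60% coverage
  pr <- predict(fit, part)
  expect_equal(attr(pr, "coverage"), 0.6)
  tiny <- z[1:4, , drop = FALSE]    # 20% coverage
  expect_error(predict(fit, tiny), "below the minimum")
})

test_that("summary and simulate methods reflect the fitted score model", {
  d <- make_two_class(n_genes = 50, n_per_class = 20, delta = 3, seed = 8)
  z <- standardize_genes(d$x)
  fit <- bccp(z, d$labels)
  s <- summary(fit)
  expect_gte(s$resubstitution_accuracy, 0.99)
  sim <- simulate(fit, nsim = 500, seed = 1)
  expect_equal(nrow(sim), 500)
  expect_true(all(sim$class %in% c("SOH", "AH")))
  # simulated scores should straddle the two fitted class means
  ms <- tapply(sim$score, sim$class, mean)
  expect_gt(ms["SOH"], ms["AH"])
})
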