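test_that("two-level repeated-measures ANOVA reduces to the paired t-test", {
  set.seed(31)
  d <- tidyr::expand_grid(s = factor(1:12), cond = factor(c("a", "b")))
  d$y <- rnorm(nrow(d)) + (d$cond == "b") * 0.8
  fit <- tidy(rm_anova(d, "y", "cond", "s"))
  a <- d$y[d$cond == "a"]; b <- d$y[d$cond == "b"]
  tt <- paired_t(a, b)
  expect_equal(fit$statistic, tt$statistic^2, tolerance = 1e-10)
  expect_equal(fit$p_value, tt$p_value, tolerance = 1e-10)
  expect_true(is.na(fit$epsilon_hf))  # 1-df effect needs no correction
})

test_that("F, epsilon and p match an independent oracle on a 5 x 3 table", {
  skip_if_not_installed("car")
  set.seed(42)
  n <- 5; k <- 3
  Y <- matrix(rnorm(n * k, mean = rep(c(10, 12, 15), each = n)), n, k)
  Y[2, ] <- Y[2, ] + 3
  d <- data.frame(s = factor(rep(1:n, k)), cond = factor(rep(1:k, each = n)),
                  y = as.vector(Y))
  fit <- tidy(rm_anova(d, "y", "cond", "s"))

  m <- stats::lm(Y ~ 1)
  aov_car <- car::Anova(m, idata = data.frame(cond = factor(1:k)),
                        idesign = ~cond, type = 3)
  s <- suppressWarnings(summary(aov_car, multivariate = FALSE))
  ut <- s$univariate.tests
  expect_equal(fit$statistic, unname(ut["cond", "F value"]), tolerance = 1e-8)
  expect_equal(fit$ss_effect, unname(ut["cond", "Sum Sq"]), tolerance = 1e-8)
  expect_equal(fit$ss_error, unname(ut["cond", "Error SS"]), tolerance = 1e-8)
  hf_car <- min(1, unname(s$pval.adjustments["cond", "HF eps"]))
  expect_equal(fit$epsilon_hf, hf_car, tolerance = 1e-8)
})

test_that("three-factor decomposition matches the oracle and is location invariant", {
  skip_if_not_installed("car")
  set.seed(8)
  n <- 6
  d <- tidyr::expand_grid(s = factor(1:n), A = factor(1:2), B = factor(1:4),
                          C = factor(1:3))
  d$y <- rnorm(nrow(d)) + as.integer(d$A) + 0.5 * as.integer(d$B) *
    as.integer(d$C) + rep(rnorm(n), each = 1)
  fit <- tidy(rm_anova(d, "y", c("A", "B", "C"), "s"))
  expect_equal(nrow(fit), 7)

  do <- d[order(d$A, d$B, d$C, d$s), ]
  Y <- matrix(do$y, nrow = n)
  idata <- tidyr::expand_grid(A = factor(1:2), B = factor(1:4), C = factor(1:3))
  m <- stats::lm(Y ~ 1)
  aov_car <- car::Anova(m, idata = as.data.frame(idata), idesign = ~A * B * C,
                        type = 3)
  s <- suppressWarnings(summary(aov_car, multivariate = FALSE))
  ut <- s$univariate.tests
  for (eff in c("A", "B", "C", "A:B", "A:C", "B:C", "A:B:C")) {
    expect_equal(fit$statistic[fit$effect == eff],
                 unname(ut[eff, "F value"]), tolerance = 1e-8)
  }

  d2 <- d; d2$y <- d2$y + 100  # adding a constant changes nothing
  fit2 <- tidy(rm_anova(d2, "y", c("A", "B", "C"), "s"))
  expect_equal(fit2$statistic, fit$statistic, tolerance = 1e-8)
  expect_equal(fit2$epsilon_hf, fit$epsilon_hf, tolerance = 1e-8)
})

test_that("epsilon is one for spherical contrast covariance by construction", {
  set.seed(5)
  n <- 30; k <- 3
  # build cell data whose orthonormal-contrast scores have exactly the
  # identity covariance: Greenhouse-Geisser epsilon is then exactly 1 and
  # the Huynh-Feldt correction clamps at 1
  C <- qr.Q(qr(stats::contr.helmert(k)))
  Z0 <- matrix(rnorm(n * (k - 1)), n, k - 1)
  Z0 <- sweep(Z0, 2, colMeans(Z0))
  Z <- Z0 %*% solve(chol(cov(Z0)))
  Y <- Z %*% t(C)
  d <- data.frame(s = factor(rep(1:n, k)), cond = factor(rep(1:k, each = n)),
                  y = as.vector(Y))
  fit <- tidy(rm_anova(d, "y", "cond", "s"))
  expect_equal(fit$epsilon_hf, 1)
})

test_that("degenerate inputs are signalled", {
  d <- tidyr::expand_grid(s = factor(1:4), cond = factor(1:2))
  d$y <- as.integer(d$cond)  # zero subject-by-condition variability
  expect_warning(rm_anova(d, "y", "cond", "s"), "zero error")
  d2 <- d[-1, ]
  expect_error(rm_anova(d2, "y", "cond", "s"), "incomplete")
})

test_that("paired t handles identity, degeneracy and direction", {
  a <- c(1, 2, 3, 4)
  expect_equal(paired_t(a, a)$statistic, 0)
  expect_equal(paired_t(a, a)$p_value, 1)
  expect_error(paired_t(a, a + 1), "not finite")
  set.seed(2)
  x <- rnorm(20); y <- x + rnorm(20, 1)
  tt <- paired_t(x, y)
  ref <- t.test(y, x, paired = TRUE)
  expect_equal(tt$statistic, unname(ref$statistic))
  expect_equal(tt$p_value, ref$p.value)
  expect_equal(tt$d_z, mean(y - x) / sd(y - x))
  expect_gt(paired_t(x, y, "greater")$statistic, 0)
})

test_that("bonferroni alpha is a plain division with guard", {
  expect_equal(round(bonferroni_alpha(0.05, 7), 4), 0.0071)
  expect_equal(round(bonferroni_alpha(0.05, 4), 4), 0.0125)
  expect_equal(bonferroni_alpha(0.05, 1), 0.05)
  expect_error(bonferroni_alpha(0.05, 0), "at least 1")
})

test_that("Harrell-Davis estimates match a quadrature oracle", {
  # oracle: HD(q) = integral over u of Q_n(u) * dbeta(u, a, b), with the
  # stepwise empirical quantile function Q_n
  hd_oracle <- function(x, q) {
    n <- length(x)
    xs <- sort(x)
    a <- (n + 1) * q; b <- (n + 1) * (1 - q)
    u <- seq(0, 1, length.out = 200001)[-1]
    qn <- xs[pmin(n, ceiling(u * n))]
    sum(qn * dbeta(u - 0.5 / 200001, a, b)) / 200000
  }
  x <- 1:9
  for (q in c(0.25, 0.5, 0.75)) {
    expect_equal(harrell_davis_quantile(x, q), hd_oracle(x, q),
                 tolerance = 1e-4)
  }
  # constant sample returns the constant at every q
  expect_equal(harrell_davis_quantile(rep(7, 12), c(0.25, 0.5, 0.75)),
               rep(7, 3))
  # symmetric sample: the median estimate sits at the centre of symmetry
  x <- c(-3, -1, 0, 1, 3)
  expect_equal(harrell_davis_quantile(x, 0.5), 0)
  # estimates stay inside the sample range
  set.seed(9)
  for (i in 1:20) {
    x <- rnorm(sample(5:40, 1))
    hd <- harrell_davis_quantile(x, runif(1, 0.01, 0.99))
    expect_gte(hd, min(x)); expect_lte(hd, max(x))
  }
  expect_error(harrell_davis_quantile(numeric(0), 0.5), "empty")
  expect_error(harrell_davis_quantile(1:5, 0), "inside")
})

test_that("shift functions recover null and constant shifts", {
  set.seed(12)
  a <- rnorm(33, 100, 15)
  sf0 <- shift_function_dependent(a, a, seed = 5)
  tb <- tidy(sf0)
  expect_equal(tb$difference, rep(0, 3))
  expect_true(all(tb$ci_lower <= 0 & tb$ci_upper >= 0))

  covered <- 0
  for (r in 1:20) {
    a <- rnorm(33, 100, 15)
    sf <- shift_function_dependent(a, a + 50, n_boot = 500, seed = r)
    tb <- tidy(sf)
    expect_equal(tb$difference, rep(50, 3), tolerance = 1e-10)
    covered <- covered + all(tb$ci_lower <= 50 & tb$ci_upper >= 50)
  }
  expect_gte(covered, 19)  # a pure location shift is essentially always covered
  expect_error(shift_function_dependent(1:3, 2:4), "at least 5")
})

test_that("shift function bootstrap is seed-stable", {
  set.seed(4)
  a <- rnorm(33); b <- a + rnorm(33, 0.3)
  sf1 <- shift_function_dependent(a, b, seed = 123)
  sf2 <- shift_function_dependent(a, b, seed = 123)
  expect_identical(tidy(sf1), tidy(sf2))
  sf3 <- shift_function_dependent(a, b, seed = 124)
  expect_false(identical(tidy(sf1)$ci_lower, tidy(sf3)$ci_lower))
})

test_that("power analysis reproduces the noncentral-t sample sizes", {
  expect_identical(required_n_paired_t(0.50, 0.85, 0.05, "one.sided"), 31L)
  # two-sided requires strictly more pairs (oracle: direct power scan)
  n2 <- required_n_paired_t(0.50, 0.85, 0.05, "two.sided")
  pow2 <- function(n) {
    crit <- qt(0.975, n - 1)
    1 - pt(crit, n - 1, ncp = 0.5 * sqrt(n)) + pt(-crit, n - 1, ncp = 0.5 * sqrt(n))
  }
  expect_gt(n2, 31L)
  expect_gte(pow2(n2), 0.85)
  expect_lt(pow2(n2 - 1), 0.85)
  # vanishing power demands: the minimum admissible pair count
  expect_identical(required_n_paired_t(0.5, 0.001, 0.05, "one.sided"), 2L)
  expect_error(required_n_paired_t(-1, 0.85), "positive")
})

test_that("Monte-Carlo power of the paired t matches the noncentral oracle", {
  # d_z = 0.5, n = 33, one-tailed alpha = 0.05: analytic power ~ 0.88
  analytic <- paired_t_power(33, 0.5, 0.05, "one.sided")
  expect_equal(analytic, 0.879, tolerance = 0.005)
  set.seed(1234)
  reps <- 10000
  D <- matrix(rnorm(reps * 33, 0.5, 1), reps, 33)
  tstat <- rowMeans(D) / (apply(D, 1, sd) / sqrt(33))
  mc_power <- mean(tstat > qt(0.95, 32))
  expect_equal(mc_power, analytic, tolerance = 0.02)
})
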