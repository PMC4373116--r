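test_that("intercept-only null fit returns the case fraction", {
  y <- rep(c(1, 0), c(40, 60))
  null <- fit_null_logistic(y)
  expect_equal(null$p0, rep(0.4, 100), tolerance = 1e-8)
  expect_error(fit_null_logistic(phenotype(rep(1, 10))),
               "one case and one control")
})

test_that("one balanced binary covariate recovers the 2x2 log-odds", {
  x <- rep(c(0, 1), each = 40)
  # P(case|x=0)=0.25, P(case|x=1)=0.75 exactly in the sample
  y <- c(rep(c(1, 0), c(10, 30)), rep(c(1, 0), c(30, 10)))
  null <- fit_null_logistic(phenotype(y, covariates = cbind(x = x)))
  expect_equal(unname(null$alpha[1]), log(0.25 / 0.75), tolerance = 1e-6)
  expect_equal(unname(null$alpha[2]), log(3) - log(1 / 3), tolerance = 1e-6)
})

test_that("linear kernel builds G diag(w) G' and validates weights", {
  G <- cbind(c(0, 1, 2))
  K <- skat_kernel(G)
  expect_equal(K, tcrossprod(c(0, 1, 2)))
  expect_equal(K[3, 3], 4)
  expect_equal(skat_kernel(G, 0), matrix(0, 3, 3))
  expect_error(skat_kernel(G, -1), "non-negative")
  G2 <- random_genotypes(10, 4, seed = 71)
  w <- c(0.5, 2, 0, 1.3)
  expect_equal(skat_kernel(G2, w), G2 %*% diag(w) %*% t(G2), tolerance = 1e-12)
})

test_that("Q statistic matches the halved quadratic form", {
  null <- list(p0 = c(0.5, 0.5))
  expect_equal(q_statistic(diag(2), c(1, 0), null), 0.25)
  expect_equal(q_statistic(matrix(0, 2, 2), c(1, 0), null), 0)
  nullb <- list(p0 = c(1, 0))
  expect_equal(q_statistic(diag(2), c(1, 0), nullb), 0)
})

test_that("kernel and score forms of Q agree to 1e-10", {
  for (seed in 1:6) {
    G <- random_genotypes(25, 6, seed = seed + 200)
    y <- balanced_y(25)
    null <- fit_null_logistic(y)
    set.seed(seed)
    w <- runif(6, 0, 4)
    Q_kernel <- q_statistic(skat_kernel(G, w), y, null)
    s <- crossprod(G, y - null$p0)
    expect_equal(Q_kernel, 0.5 * sum(w * s^2), tolerance = 1e-10)
  }
})

test_that("Satterthwaite moments satisfy their defining identities", {
  G <- random_genotypes(40, 5, seed = 81)
  null <- fit_null_logistic(balanced_y(40))
  mom <- skat_null_moments(skat_kernel(G), null)
  expect_equal(mom$kappa * mom$nu, mom$mu, tolerance = 1e-12)
  expect_equal(2 * mom$kappa^2 * mom$nu, mom$sigma2, tolerance = 1e-12)
})

test_that("fast p-space moments equal the kernel-space computation", {
  for (seed in 1:4) {
    G <- random_genotypes(30, 5, seed = seed + 300)
    x <- rnorm(30)
    null <- fit_null_logistic(phenotype(balanced_y(30), covariates = cbind(x)))
    set.seed(seed)
    w <- runif(5, 0, 2)
    a <- skat_null_moments(skat_kernel(G, w), null)
    b <- tagassoc:::skat_moments_linear(G, w, null)
    expect_equal(a$mu, b$mu, tolerance = 1e-10)
    expect_equal(a$sigma2, b$sigma2, tolerance = 1e-10)
  }
})

test_that("a rank-1 kernel drives the degrees of freedom toward 1", {
  set.seed(91)
  g <- rbinom(60, 2, 0.4)
  null <- fit_null_logistic(balanced_y(60))
  mom <- skat_null_moments(skat_kernel(cbind(g)), null)
  expect_equal(mom$nu, 1, tolerance = 1e-8)
})

test_that("analytic p-values are invariant to rescaling all weights", {
  G <- random_genotypes(50, 6, seed = 101)
  y <- balanced_y(50)
  null <- fit_null_logistic(y)
  set.seed(5)
  w <- runif(6, 0.1, 3)
  skat_analytic <- function(wv) {
    mom <- tagassoc:::skat_moments_linear(G, wv, null)
    s <- crossprod(G, y - null$p0)
    Q <- 0.5 * sum(wv * s^2)
    stats::pchisq(Q / mom$kappa, mom$nu, lower.tail = FALSE)
  }
  mom1 <- tagassoc:::skat_moments_linear(G, w, null)
  mom2 <- tagassoc:::skat_moments_linear(G, 2 * w, null)
  expect_equal(mom2$kappa, 2 * mom1$kappa, tolerance = 1e-12)
  expect_equal(mom2$nu, mom1$nu, tolerance = 1e-12)
  expect_equal(skat_analytic(w), skat_analytic(2 * w), tolerance = 1e-12)
})

test_that("constant SNP columns never change the analytic p-value", {
  G <- random_genotypes(40, 4, seed = 111)
  y <- balanced_y(40)
  p_base <- skat_test(G, y)$p.value
  p_aug0 <- skat_test(cbind(G, 0), y)$p.value
  p_aug2 <- skat_test(cbind(G, 2), y)$p.value
  expect_equal(p_aug0, p_base, tolerance = 1e-10)
  expect_equal(p_aug2, p_base, tolerance = 1e-10)
})

test_that("the scaled chi-squared null calibrates the 0.05 tail (Monte Carlo)", {
  set.seed(121)
  n <- 120
  G <- matrix(rbinom(n * 4, 2, 0.35), n, 4)
  p0 <- 0.45
  null <- list(p0 = rep(p0, n), X = matrix(1, n, 1))
  mom <- skat_null_moments(skat_kernel(G), null)
  q95 <- mom$kappa * qchisq(0.95, mom$nu)
  Y <- matrix(rbinom(n * 10000, 1, p0), n)
  # the moments assume the intercept-only null is refit to each dataset,
  # so residuals are centred at each simulation's own case fraction
  Yc <- sweep(Y, 2L, colMeans(Y))
  Q <- 0.5 * colSums(crossprod(G, Yc)^2)
  rate <- mean(Q > q95)
  expect_lt(abs(rate - 0.05), 0.01)
})

test_that("skat_test is seed-deterministic and its two p-value routes agree", {
  set.seed(131)
  n <- 200
  G <- matrix(rbinom(n * 5, 2, 0.3), n, 5)
  y <- balanced_y(n)
  r1 <- skat_test(G, y, weighted = TRUE, n_perm = 99, seed = 3)
  r2 <- skat_test(G, y, weighted = TRUE, n_perm = 99, seed = 3)
  expect_identical(r1$p.value, r2$p.value)

  pa <- skat_test(G, y, pvalue = "analytic")$p.value
  pp <- skat_test(G, y, pvalue = "permutation", n_perm = 1999, seed = 4)$p.value
  expect_lt(abs(pa - pp), 0.05)
})
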