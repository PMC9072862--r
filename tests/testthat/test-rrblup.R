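random_instance <- function(n, m, seed, sd_noise = 1) {
  set.seed(seed)
  X <- matrix(sample(c(-1, 1), n * m, replace = TRUE), n, m)
  a <- rnorm(m, 0, 0.3)
  p <- 5 + drop(X %*% a) + rnorm(n, 0, sd_noise)
  list(X = X, p = p)
}

test_that("constant phenotypes shrink all effects to zero", {
  X <- matrix(sample(c(-1, 1), 40, replace = TRUE), 8, 5)
  fit <- fit_rrblup(X, rep(3.5, 8), mode = "fixed_lambda", lambda = 1)
  expect_equal(fit$effects, rep(0, 5))
  expect_equal(fit$mu, 3.5)
  expect_false(fit$converged)
  expect_equal(predict(fit, X)$y, rep(3.5, 8))
})

test_that("fixed-lambda fit matches the closed-form ridge solution", {
  # 5-line x 3-marker toy, lambda = 1, oracle by explicit matrix inversion
  # of the mixed-model equations
  inst <- random_instance(5, 3, seed = 1)
  X <- inst$X; p <- inst$p
  W <- cbind(1, X)
  C <- crossprod(W) + diag(c(0, 1, 1, 1))
  sol <- solve(C) %*% crossprod(W, p)

  fit <- fit_rrblup(X, p, mode = "fixed_lambda", lambda = 1, solver = "primal")
  expect_equal(fit$mu, sol[1], tolerance = 1e-10)
  expect_equal(fit$effects, drop(sol[-1]), tolerance = 1e-10)
})

test_that("dual (kernel) and primal (marker) solutions agree", {
  for (seed in 1:5) {
    inst <- random_instance(12, 30, seed = seed)
    fd <- fit_rrblup(inst$X, inst$p, mode = "fixed_lambda", lambda = 2.5,
                     solver = "dual")
    fp <- fit_rrblup(inst$X, inst$p, mode = "fixed_lambda", lambda = 2.5,
                     solver = "primal")
    expect_equal(fd$mu, fp$mu, tolerance = 1e-8)
    expect_equal(fd$effects, fp$effects, tolerance = 1e-8)
  }
})

test_that("RR-BLUP equals GBLUP with kernel XX' and matched variance ratio", {
  for (seed in 1:5) {
    inst <- random_instance(15, 40, seed = seed + 10)
    lam <- 3
    fit <- fit_rrblup(inst$X, inst$p, mode = "fixed_lambda", lambda = lam)
    y <- predict(fit, inst$X)$y
    # GBLUP oracle: mu from GLS under H = K + lambda I, ghat = K H^-1 (p - mu)
    K <- tcrossprod(inst$X)
    H <- K + diag(lam, nrow(K))
    Hi1 <- solve(H, rep(1, nrow(K)))
    mu <- sum(Hi1 * inst$p) / sum(Hi1)
    y_gblup <- mu + drop(K %*% solve(H, inst$p - mu))
    expect_equal(y, y_gblup, tolerance = 1e-8)
  }
})

test_that("the ridge limits behave: interpolation at lambda -> 0, mu at lambda -> Inf", {
  inst <- random_instance(10, 25, seed = 99)
  lo <- fit_rrblup(inst$X, inst$p, mode = "fixed_lambda", lambda = 1e-8)
  expect_equal(predict(lo, inst$X)$y, inst$p, tolerance = 1e-5)
  hi <- fit_rrblup(inst$X, inst$p, mode = "fixed_lambda", lambda = 1e10)
  expect_equal(predict(hi, inst$X)$y, rep(hi$mu, 10), tolerance = 1e-5)
})

test_that("shrinkage is monotone in lambda", {
  inst <- random_instance(20, 50, seed = 5)
  lams <- 10^seq(-2, 4, length.out = 10)
  vv <- vapply(lams, function(l) {
    f <- fit_rrblup(inst$X, inst$p, mode = "fixed_lambda", lambda = l)
    var(predict(f, inst$X)$y - f$mu)
  }, numeric(1))
  expect_true(all(diff(vv) <= 1e-10))
})

test_that("REML is scale-equivariant and estimates a sensible lambda", {
  inst <- random_instance(60, 120, seed = 7, sd_noise = 2)
  f1 <- fit_rrblup(inst$X, inst$p, mode = "reml")
  f2 <- fit_rrblup(inst$X, inst$p * 10, mode = "reml")
  expect_equal(f2$lambda, f1$lambda, tolerance = 1e-3)
  expect_equal(f2$effects, 10 * f1$effects, tolerance = 1e-4)
  expect_true(f1$converged)
  expect_gt(f1$sigma_a2, 0)
  expect_equal(f1$sigma_e2 / f1$sigma_a2, f1$lambda, tolerance = 1e-10)
  # true ratio sigma_e2 / sigma_a2 = 4 / 0.09 ~ 44; REML on one draw should
  # land within an order of magnitude
  expect_gt(f1$lambda, 4)
  expect_lt(f1$lambda, 400)
})

test_that("prediction validates the marker set", {
  inst <- random_instance(10, 20, seed = 8)
  fit <- fit_rrblup(inst$X, inst$p, mode = "fixed_lambda", lambda = 1)
  expect_error(predict(fit, inst$X[, 1:10]), "marker set")
  expect_error(fit_rrblup(inst$X, inst$p[1:5]), "length")
  expect_error(fit_rrblup(inst$X, inst$p, mode = "fixed_lambda"), "lambda")
})
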