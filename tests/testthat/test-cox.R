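test_that("partial log-likelihood matches closed forms and enumeration", {
  ch2 <- cohort(c(1, 2), c(1, 0), cbind(x = c(1, 0)))
  expect_equal(partial_loglik(0, ch2$covariates, ch2), -log(2))

  ch0 <- cohort(c(1, 2, 3), c(0, 0, 0), cbind(x = c(1, 0, 2)))
  expect_identical(partial_loglik(0.7, ch0$covariates, ch0), 0)

  ch4 <- cohort(c(1, 2, 3, 4), c(1, 1, 0, 1), cbind(x = c(1, 0, 1, 0)))
  expect_equal(partial_loglik(0.5, ch4$covariates, ch4),
               naive_partial_loglik(0.5, ch4$covariates, ch4$time, ch4$status))

  # random data, random beta, with offset and with tied event times
  set.seed(41)
  for (rep in 1:5) {
    n <- 25
    tt <- sample(1:8, n, replace = TRUE)  # forces ties
    st <- rbinom(n, 1, 0.6)
    X <- cbind(rnorm(n), rbinom(n, 2, 0.4))
    off <- rnorm(n, sd = 0.5)
    b <- rnorm(2)
    ch <- cohort(tt, st, X)
    expect_equal(partial_loglik(b, X, ch, offset = off),
                 naive_partial_loglik(b, X, tt, st, off))
  }
})

test_that("likelihood is invariant to constant offset shifts", {
  set.seed(7)
  ch <- make_test_cohort(40)
  b <- c(0.4, -0.1)
  base <- partial_loglik(b, ch$covariates, ch, offset = 0)
  for (const in c(-3, 1e4)) {
    expect_equal(partial_loglik(b, ch$covariates, ch, offset = const), base)
  }
})

test_that("score and information match hand enumeration and the gradient", {
  ch2 <- cohort(c(1, 2), c(1, 0), cbind(x = c(1, 0)))
  si <- score_and_information(0, ch2$covariates, ch2)
  expect_equal(unname(si$U), 0.5)
  expect_equal(si$I, matrix(0.25, 1, 1))

  # matches a central-difference gradient/Hessian of the log-likelihood
  set.seed(12)
  ch <- make_test_cohort(30)
  X <- cbind(ch$covariates, g = rbinom(30, 2, 0.4))
  b <- c(0.2, -0.3, 0.4)
  off <- rnorm(30, sd = 0.3)
  si <- score_and_information(b, X, ch, offset = off)
  h <- 1e-5
  for (j in 1:3) {
    e <- rep(0, 3); e[j] <- h
    num <- (partial_loglik(b + e, X, ch, off) -
              partial_loglik(b - e, X, ch, off)) / (2 * h)
    expect_equal(unname(si$U[j]), num, tolerance = 1e-6)
    numI <- -(partial_loglik(b + e, X, ch, off) +
                partial_loglik(b - e, X, ch, off) -
                2 * partial_loglik(b, X, ch, off)) / h^2
    expect_equal(si$I[j, j], numI, tolerance = 1e-3)
  }
  # information is symmetric positive semidefinite
  expect_equal(si$I, t(si$I))
  expect_true(all(eigen(si$I, symmetric = TRUE, only.values = TRUE)$values > -1e-10))
  # agreement of the 1-d path with the naive risk-set enumeration
  si1 <- score_and_information(0, X[, 3, drop = FALSE], ch, offset = off)
  ref <- naive_score_info_1d(X[, 3], ch$time, ch$status, off)
  expect_equal(unname(si1$U), unname(ref["U"]))
  expect_equal(si1$I[1, 1], unname(ref["I"]))
})

test_that("a constant covariate has zero score and information", {
  set.seed(3)
  ch <- make_test_cohort(20)
  X <- cbind(const = rep(2, 20), x = rnorm(20))
  si <- score_and_information(c(0, 0), X, ch)
  expect_equal(unname(si$U[1]), 0)
  expect_equal(si$I[1, 1], 0)
})

test_that("fit_cox agrees with survival::coxph to 1e-5", {
  skip_if_not_installed("survival")
  set.seed(100)
  ch <- make_test_cohort(100)
  G <- rbinom(100, 2, 0.35)
  X <- cbind(ch$covariates, snp = G)
  fit <- fit_cox(X, ch)
  ref <- survival::coxph(survival::Surv(ch$time, ch$status) ~ X,
                         ties = "breslow")
  expect_true(fit$converged)
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-5)
  expect_equal(unname(fit$se), unname(sqrt(diag(vcov(ref)))), tolerance = 1e-5)
  expect_equal(fit$loglik, ref$loglik[2], tolerance = 1e-7)

  # with offset
  off <- 0.25 * ch$covariates[, 1]
  fit2 <- fit_cox(cbind(snp = G), ch, offset = off)
  ref2 <- survival::coxph(survival::Surv(ch$time, ch$status) ~ G + offset(off),
                          ties = "breslow")
  expect_equal(unname(fit2$coefficients), unname(coef(ref2)), tolerance = 1e-5)
})

test_that("fit_cox handles degenerate calls as specified", {
  set.seed(5)
  ch <- make_test_cohort(30)
  # zero covariates: empty fit, offset-only likelihood
  f0 <- fit_cox(matrix(numeric(0), 30, 0), ch, offset = rep(0.1, 30))
  expect_length(f0$coefficients, 0)
  expect_equal(f0$loglik,
               partial_loglik(numeric(0), matrix(numeric(0), 30, 0), ch,
                              offset = rep(0.1, 30)))
  # constant column is an error
  expect_error(fit_cox(cbind(c = rep(1, 30)), ch), "constant")
  # refitting at the optimum as offset gives a ~zero increment
  f1 <- fit_cox(ch$covariates, ch)
  off <- as.vector(ch$covariates %*% f1$coefficients)
  f2 <- fit_cox(ch$covariates, ch, offset = off)
  expect_lt(max(abs(f2$coefficients)), 1e-6)
})

test_that("fit_cox is equivariant under column rescaling", {
  set.seed(9)
  ch <- make_test_cohort(60)
  X <- ch$covariates
  f <- fit_cox(X, ch)
  Xs <- X
  Xs[, 1] <- X[, 1] * 10
  fs <- fit_cox(Xs, ch)
  expect_equal(fs$coefficients[1] * 10, f$coefficients[1], tolerance = 1e-6)
  expect_equal(fs$coefficients[2], f$coefficients[2], tolerance = 1e-6)
})

test_that("Wald p-values follow the standard normal reference", {
  expect_equal(wald_pvalue(0, 1), 1)
  expect_equal(wald_pvalue(1.959964, 1), 0.05, tolerance = 1e-6)
  expect_equal(wald_pvalue(3, 1), 0.0026998, tolerance = 1e-4)
  expect_error(wald_pvalue(1, -1), "positive")
})

test_that("cohort construction validates its inputs", {
  expect_error(cohort(c(1, -1), c(1, 0)), "positive")
  expect_error(cohort(c(1, 2), c(1, 2)), "status")
  expect_error(cohort(c(1, 2), c(1, 0), matrix(0, 3, 1)), "row per subject")
  ch <- cohort(c(1, 2, 3), c(1, 0, 1))
  expect_equal(ch$r, 0)
})
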