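test_that("zero boosting steps reproduce the plain mandatory fit", {
  set.seed(14)
  ch <- make_test_cohort(50)
  G <- make_test_genotypes(50, 8)
  fit <- boost_fit(ch, G, n_steps = 0)
  expect_true(all(fit$snp_coefficients == 0))
  ref <- fit_cox(ch$covariates, ch)
  expect_equal(fit$mandatory_coefficients, ref$coefficients, tolerance = 1e-8)
  expect_length(fit$selected, 0)
})

test_that("one boosting step matches brute-force candidate enumeration", {
  set.seed(33)
  ch <- make_test_cohort(20)
  G <- make_test_genotypes(20, 5)
  lambda <- 30
  fit <- boost_fit(ch, G, lambda = lambda, n_steps = 1)

  # enumerate all candidates independently: offset is the mandatory fit,
  # score statistic U^2/I at gamma = 0, update U/(I + lambda)
  mand <- fit_cox(ch$covariates, ch)
  off <- as.vector(ch$covariates %*% mand$coefficients)
  stats <- t(vapply(seq_len(5), function(j) {
    naive_score_info_1d(G[, j], ch$time, ch$status, off)
  }, c(U = 0, I = 0)))
  jstar <- which.max(stats[, "U"]^2 / stats[, "I"])
  expect_equal(fit$steps$snp_id, colnames(G)[jstar])
  expect_equal(fit$steps$gamma,
               unname(stats[jstar, "U"] / (stats[jstar, "I"] + lambda)),
               tolerance = 1e-10)
  # the selected coefficient is the only nonzero one
  expect_equal(sum(fit$snp_coefficients != 0), 1)
})

test_that("an overwhelming penalty freezes all SNP coefficients", {
  set.seed(3)
  ch <- make_test_cohort(40)
  G <- make_test_genotypes(40, 6)
  fit <- boost_fit(ch, G, lambda = 1e9, n_steps = 20)
  expect_lt(max(abs(fit$snp_coefficients)), 1e-6)
})

test_that("selection is scale-invariant but the update is equivariant", {
  # recoding one SNP from 0/1 to 0/2 must not change which SNP wins the
  # score-statistic selection, while its fitted update halves
  set.seed(52)
  n <- 80
  ch <- make_test_cohort(n)
  G <- matrix(rbinom(n * 6, 1, 0.4), n, 6)
  storage.mode(G) <- "integer"
  colnames(G) <- paste0("s", 1:6)
  fit1 <- boost_fit(ch, G, lambda = 0.01, n_steps = 1)
  jstar <- fit1$steps$snp_id
  G2 <- G
  G2[, jstar] <- G2[, jstar] * 2L
  fit2 <- boost_fit(ch, G2, lambda = 0.01, n_steps = 1)
  expect_equal(fit2$steps$snp_id, jstar)
  # at near-zero penalty the one-step update is ~ the Newton step, which is
  # exactly halved under doubling of the covariate
  expect_equal(fit2$steps$gamma, fit1$steps$gamma / 2, tolerance = 5e-3)
})

test_that("the training partial likelihood is non-decreasing along the path", {
  set.seed(71)
  ch <- make_test_cohort(60)
  G <- make_test_genotypes(60, 15)
  fit <- boost_fit(ch, G, n_steps = 40)
  expect_true(all(diff(fit$loglik_path) >= -1e-10))
  # sparsity contract: never more nonzero SNPs than steps
  for (m in c(1, 5, 20, 40)) {
    expect_lte(length(selected_at(fit, m)), m)
  }
})

test_that("cross-validated step selection behaves and reproduces", {
  set.seed(99)
  ch <- make_test_cohort(60)
  G <- make_test_genotypes(60, 10)
  # degenerate grid
  cv0 <- cv_select_steps(ch, G, step_grid = 0)
  expect_equal(cv0$best_steps, 0)
  # determinism under a fixed seed
  set.seed(4); a <- cv_select_steps(ch, G, max_steps = 10, cv_folds = 4)
  set.seed(4); b <- cv_select_steps(ch, G, max_steps = 10, cv_folds = 4)
  expect_identical(a$folds, b$folds)
  expect_equal(a$best_steps, b$best_steps)
  expect_equal(a$cvpl, b$cvpl)
  expect_error(cv_select_steps(ch, G, step_grid = c(5, 10)), "start at 0")
})

test_that("cross-validation detects a strong signal", {
  # one SNP with log-HR 2 among 50: CV must choose a positive step count in
  # nearly all replicates
  set.seed(123)
  pos <- 0L
  n_rep <- 10L
  for (r in seq_len(n_rep)) {
    n <- 300
    G <- make_test_genotypes(n, 50, maf = 0.3)
    Z <- cbind(z1 = rnorm(n), z2 = rbinom(n, 1, 0.5))
    tt <- rexp(n, 0.1 * exp(2 * G[, 25]))
    cc <- runif(n, 0, 10)
    ch <- cohort(pmin(tt, cc), as.integer(tt <= cc), Z)
    cv <- cv_select_steps(ch, G, max_steps = 30, cv_folds = 5)
    if (cv$best_steps > 0) pos <- pos + 1L
  }
  expect_gte(pos, 9L)
})

test_that("boosted estimates shrink toward but not past a moderate effect", {
  # single informative SNP of log-HR 0.5 at large n: the CV-tuned boosted
  # coefficient lands in [0.2, 0.5] in median over replicates
  set.seed(321)
  est <- numeric(10)
  for (r in 1:10) {
    n <- 800
    G <- make_test_genotypes(n, 30, maf = 0.4)
    Z <- cbind(z1 = rnorm(n), z2 = rbinom(n, 1, 0.5))
    tt <- rexp(n, 0.1 * exp(0.5 * G[, 7]))
    cc <- runif(n, 0, 10)
    ch <- cohort(pmin(tt, cc), as.integer(tt <= cc), Z)
    cv <- cv_select_steps(ch, G, max_steps = 80, cv_folds = 5)
    fit <- boost_fit(ch, G, n_steps = cv$best_steps)
    est[r] <- fit$snp_coefficients[7]
  }
  expect_gte(median(est), 0.2)
  expect_lte(median(est), 0.5)
})

test_that("lambda auto resolves to nine times the event count", {
  set.seed(2)
  ch <- make_test_cohort(40)
  fit <- boost_fit(ch, make_test_genotypes(40, 5), n_steps = 1)
  expect_equal(fit$lambda, 9 * sum(ch$status))
  expect_error(boost_fit(ch, make_test_genotypes(40, 5), lambda = -2,
                         n_steps = 1), "lambda")
})
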