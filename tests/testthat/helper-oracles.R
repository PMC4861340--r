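# Independent reference implementations used as oracles. These deliberately
# use direct enumeration / textbook definitions, not the package's code paths.

# Breslow partial log-likelihood by explicit risk-set enumeration.
naive_partial_loglik <- function(beta, X, time, status, offset = 0) {
  X <- as.matrix(X)
  offset <- rep_len(offset, length(time))
  eta <- if (ncol(X)) as.vector(X %*% beta) + offset else offset
  total <- 0
  for (i in seq_along(time)) {
    if (status[i] == 1) {
      risk <- which(time >= time[i])
      total <- total + eta[i] - log(sum(exp(eta[risk])))
    }
  }
  total
}

# One-dimensional score and information at gamma = 0 given an offset,
# by explicit risk-set means and variances.
naive_score_info_1d <- function(x, time, status, offset = 0) {
  offset <- rep_len(offset, length(time))
  w <- exp(offset)
  U <- 0
  I <- 0
  for (i in seq_along(time)) {
    if (status[i] == 1) {
      risk <- which(time >= time[i])
      m1 <- sum(w[risk] * x[risk]) / sum(w[risk])
      m2 <- sum(w[risk] * x[risk]^2) / sum(w[risk])
      U <- U + x[i] - m1
      I <- I + m2 - m1^2
    }
  }
  c(U = U, I = I)
}

# Benjamini-Hochberg step-up by its definition: largest k with
# p_(k) <= k/m * q is the rejection rank; adjusted values by the
# running-minimum formula.
naive_bh <- function(p, level) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= seq_len(m) / m * level)
  rejected_sorted <- if (length(k)) seq_len(max(k)) else integer(0)
  adj_sorted <- rev(cummin(rev(pmin(1, m * ps / seq_len(m)))))
  adjusted <- numeric(m)
  adjusted[o] <- adj_sorted
  list(adjusted = adjusted, selected = sort(o[rejected_sorted]))
}

# Pure-R generator for one gene of block-correlated genotypes (copy-else-
# fresh), used to cross-check the compiled generator and as an independent
# draw of the informative-SNP distribution.
naive_gene_genotypes <- function(n, n_blocks, block_size, maf, p_within,
                                 p_boundary) {
  L <- n_blocks * block_size
  G <- matrix(0L, n, L)
  G[, 1] <- rbinom(n, 2, maf)
  for (j in 2:L) {
    p_copy <- if ((j - 1) %% block_size == 0) p_boundary else p_within
    copy <- runif(n) < p_copy
    fresh <- rbinom(n, 2, maf)
    G[, j] <- ifelse(copy, G[, j - 1], fresh)
  }
  G
}

# Small random survival data with two clinical covariates.
make_test_cohort <- function(n, seed = NULL, beta_z = c(0.3, -0.2),
                             censor_max = 12) {
  if (!is.null(seed)) set.seed(seed)
  Z <- cbind(z1 = rnorm(n), z2 = rbinom(n, 1, 0.5))
  tt <- rexp(n, 0.1 * exp(as.vector(Z %*% beta_z)))
  cc <- runif(n, 0, censor_max)
  cohort(pmin(tt, cc), as.integer(tt <= cc), Z)
}

make_test_genotypes <- function(n, L, maf = 0.3, prefix = "rs") {
  G <- matrix(rbinom(n * L, 2, maf), n, L)
  storage.mode(G) <- "integer"
  colnames(G) <- paste0(prefix, seq_len(L))
  rownames(G) <- paste0("p", seq_len(n))
  G
}

# Build a stability report directly from hand-chosen selection sets.
fake_stability_report <- function(sets, universe, method = "univariate_fdr") {
  snp_if <- stats::setNames(integer(length(universe)), universe)
  tab <- table(unlist(sets))
  snp_if[names(tab)] <- as.integer(tab)
  structure(
    list(snp_if = snp_if, sets = sets, set_sizes = lengths(sets),
         n_subsamples = length(sets), method = method, n_failed = 0L,
         gene_if = NULL),
    class = "stability_report"
  )
}
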