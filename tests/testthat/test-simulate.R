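test_that("design arithmetic and truth partition are exact", {
  d <- sim_design()
  expect_equal(d$L, 300000)
  truth <- classify_snps(d)
  expect_equal(nrow(truth$informative), 6)
  expect_length(truth$cor_noise, 24)
  expect_length(truth$uncor_noise, 299970)
  map <- gene_map_from_design(d)
  expect_equal(length(unique(map$gene_id)), 100)
  expect_true(all(table(map$gene_id) == 3000))
  expect_equal(map$gene_id[c(3000, 3001, 3023)],
               c("gene1", "gene2", "gene2"))
  # the partition covers all SNPs exactly once
  expect_equal(nrow(truth$informative) + length(truth$cor_noise) +
                 length(truth$uncor_noise), d$L)

  d0 <- sim_design(n_genes = 1, blocks_per_gene = 2,
                   informative = data.frame(position = integer(0),
                                            effect = numeric(0)))
  t0 <- classify_snps(d0)
  expect_length(t0$cor_noise, 0)
  expect_length(t0$uncor_noise, 20)
  expect_error(sim_design(n_genes = 1, blocks_per_gene = 1,
                          informative = data.frame(position = 11, effect = 1)),
               "positions")
})

test_that("genotypes keep the Binomial(2, maf) marginal and block correlation", {
  d <- sim_design(n = 20000, n_genes = 1, blocks_per_gene = 3,
                  informative = data.frame(position = 2, effect = 0.5))
  set.seed(606)
  G <- simulate_genotypes(d)
  expect_equal(dim(G), c(20000, 30))
  expect_true(all(G %in% 0:2))
  # per-SNP means near 2 * maf = 0.8 (3 MC-SE band; var of one genotype =
  # 2 * maf * (1-maf) = 0.48)
  se_mean <- sqrt(0.48 / 20000)
  expect_true(all(abs(colMeans(G) - 0.8) < 3 * se_mean + 0.01))
  # adjacent within-block correlation ~ copy probability
  within_pairs <- setdiff(1:29, c(10, 20))
  cors <- vapply(within_pairs, function(j) cor(G[, j], G[, j + 1]), 0)
  expect_true(all(abs(cors - 0.75) < 0.03))
  # block-boundary correlation ~ 0.50
  expect_lt(abs(cor(G[, 10], G[, 11]) - 0.50), 0.03)
  expect_lt(abs(cor(G[, 20], G[, 21]) - 0.50), 0.03)
  # lag-2 within block ~ 0.75^2
  expect_lt(abs(cor(G[, 2], G[, 4]) - 0.5625), 0.03)
  # genotype frequencies match the binomial exactly (chi-square GoF)
  pfit <- chisq.test(table(factor(G[, 15], levels = 0:2)),
                     p = c(0.36, 0.48, 0.16))
  expect_gt(pfit$p.value, 0.01)
})

test_that("distinct genes are generated independently", {
  d <- sim_design(n = 20000, n_genes = 2, blocks_per_gene = 1,
                  informative = data.frame(position = 2, effect = 0.5))
  set.seed(77)
  G <- simulate_genotypes(d)
  # last SNP of gene 1 vs first SNP of gene 2
  expect_lt(abs(cor(G[, 10], G[, 11])), 0.03)
})

test_that("survival generation follows the inverted exponential model", {
  d <- sim_design(n = 20000, n_genes = 1, blocks_per_gene = 2,
                  informative = data.frame(position = integer(0),
                                           effect = numeric(0)),
                  censor_max = Inf)
  set.seed(42)
  G <- simulate_genotypes(d)
  ch <- simulate_survival(d, G)
  # no effects, no censoring: exponential with rate h0 = 0.1, mean 10
  expect_true(all(ch$status == 1L))
  expect_lt(abs(mean(ch$time) - 10), 3 * 10 / sqrt(20000))
  # definition check: status = 1 exactly when the latent time wins
  d2 <- sim_design(n = 5000, n_genes = 1, blocks_per_gene = 2,
                   informative = data.frame(position = 2, effect = 0.5))
  set.seed(43)
  G2 <- simulate_genotypes(d2)
  ch2 <- simulate_survival(d2, G2)
  lat <- attr(ch2, "latent_time")
  cen <- attr(ch2, "censor_time")
  expect_identical(ch2$status, as.integer(lat <= cen))
  expect_equal(ch2$time, pmin(lat, cen))
  expect_true(all(cen <= d2$censor_max))
})

test_that("identical design and seed give identical data", {
  d <- sim_design(n = 50, n_genes = 2, blocks_per_gene = 2,
                  informative = data.frame(position = 3, effect = -0.5))
  a <- simulate_dataset(d, seed = 31)
  b <- simulate_dataset(d, seed = 31)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$cohort$time, b$cohort$time)
  expect_identical(a$cohort$covariates, b$cohort$covariates)
})

test_that("compiled and plain-R generators agree in distribution", {
  # same copy-else-fresh law: compare genotype-pair transition frequencies
  set.seed(55)
  d <- sim_design(n = 8000, n_genes = 1, blocks_per_gene = 2,
                  informative = data.frame(position = 2, effect = 0.5))
  G <- simulate_genotypes(d)
  R <- naive_gene_genotypes(8000, 2, 10, 0.4, 0.75, 0.5)
  # equal-neighbour frequency within blocks and across the boundary
  eqc <- function(M, j) mean(M[, j] == M[, j + 1])
  expect_lt(abs(eqc(G, 4) - eqc(R, 4)), 0.03)
  expect_lt(abs(eqc(G, 10) - eqc(R, 10)), 0.03)
  expect_lt(abs(mean(G) - mean(R)), 0.02)
})
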