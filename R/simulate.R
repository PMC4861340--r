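# Synthetic cohorts with a known truth: block-correlated genotypes arranged
# in genes, proportional-hazards survival driven by a handful of informative
# SNPs, uniform censoring and two clinical adjustment covariates.

#' Simulation design for block-correlated SNP survival cohorts
#'
#' Defines every generator parameter. Genotypes are arranged in
#' `n_genes` genes of `blocks_per_gene` blocks with `block_size` SNPs each;
#' within a block each SNP copies its left neighbor's genotype value with
#' probability `copy_prob_within` (at block boundaries `copy_prob_boundary`),
#' otherwise it is drawn fresh as Binomial(2, `maf`); the first SNP of a
#' gene is always fresh and genes are independent. Survival times follow a
#' Cox model with constant baseline hazard `baseline_hazard` and linear
#' predictor built from the `informative` SNPs; censoring times are
#' Uniform(0, `censor_max`). Two clinical covariates (binary and standard
#' normal) are generated for adjustment, with zero effect by default so the
#' adjustment machinery is exercised without confounding.
#'
#' The defaults place five informative SNPs on gene 1 (three of effect +0.5
#' in the block starting at SNP 1, two of effect -0.5 in the block starting
#' at SNP 31) and one of effect -0.5 on gene 2, within a genome of 100 genes
#' x 3000 SNPs = 300000 SNPs at MAF 0.4.
#'
#' @param n number of subjects.
#' @param n_genes,blocks_per_gene,block_size genome layout; the number of
#'   SNPs is their product.
#' @param maf risk-allele frequency of every SNP.
#' @param copy_prob_within,copy_prob_boundary left-neighbor copy
#'   probabilities inside a block and at block boundaries.
#' @param informative data.frame with columns `position` (1-based SNP index)
#'   and `effect` (log hazard ratio per risk allele).
#' @param baseline_hazard constant baseline hazard of the generating Cox
#'   model.
#' @param censor_max upper end of the Uniform(0, censor_max) censoring
#'   distribution; `Inf` disables censoring.
#' @param clinical list with `binary_prob`, `binary_effect`,
#'   `continuous_effect` for the two adjustment covariates.
#' @return An object of class `"sim_design"`.
#' @export
sim_design <- function(n = 500, n_genes = 100, blocks_per_gene = 300,
                       block_size = 10, maf = 0.4, copy_prob_within = 0.75,
                       copy_prob_boundary = 0.50,
                       informative = data.frame(
                         position = c(2L, 5L, 9L, 33L, 37L, 3023L),
                         effect = c(0.5, 0.5, 0.5, -0.5, -0.5, -0.5)),
                       baseline_hazard = 0.1, censor_max = 10,
                       clinical = list(binary_prob = 0.5, binary_effect = 0,
                                       continuous_effect = 0)) {
  stopifnot(n >= 2, n_genes >= 1, blocks_per_gene >= 1, block_size >= 1,
            maf > 0, maf < 1, copy_prob_within >= 0, copy_prob_within <= 1,
            copy_prob_boundary >= 0, copy_prob_boundary <= 1,
            baseline_hazard > 0, censor_max > 0)
  L <- n_genes * blocks_per_gene * block_size
  informative <- as.data.frame(informative)
  if (nrow(informative) > 0) {
    if (!all(c("position", "effect") %in% colnames(informative))) {
      stop("'informative' needs columns 'position' and 'effect'")
    }
    informative$position <- as.integer(informative$position)
    if (any(informative$position < 1L | informative$position > L)) {
      stop("informative positions must lie in [1, ", L, "]")
    }
    if (anyDuplicated(informative$position)) {
      stop("duplicated informative positions")
    }
  }
  structure(
    list(n = as.integer(n), n_genes = as.integer(n_genes),
         blocks_per_gene = as.integer(blocks_per_gene),
         block_size = as.integer(block_size), L = as.integer(L),
         maf = maf, copy_prob_within = copy_prob_within,
         copy_prob_boundary = copy_prob_boundary, informative = informative,
         baseline_hazard = baseline_hazard, censor_max = censor_max,
         clinical = clinical),
    class = "sim_design"
  )
}

#' @export
print.sim_design <- function(x, ...) {
  cat(sprintf("Simulation design: n = %d, %d SNPs (%d genes x %d blocks x %d), MAF %g\n",
              x$n, x$L, x$n_genes, x$blocks_per_gene, x$block_size, x$maf))
  cat(sprintf("copy probabilities %g within / %g at boundaries; h0 = %g, censoring U(0, %g)\n",
              x$copy_prob_within, x$copy_prob_boundary, x$baseline_hazard,
              x$censor_max))
  if (nrow(x$informative)) {
    cat("informative SNPs:",
        paste(sprintf("SNP%d (%+.2f)", x$informative$position,
                      x$informative$effect), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Preset simulation designs
#'
#' `"full"` is the full-scale design (n = 500, 100 genes, 300000 SNPs);
#' `"desk"` shrinks the genome to 10 genes (30000 SNPs) while keeping the
#' cohort size, block structure and informative SNPs, for interactive work
#' and testing.
#'
#' @param preset `"full"` or `"desk"`.
#' @return A [sim_design()] object.
#' @export
design_preset <- function(preset = c("full", "desk")) {
  preset <- match.arg(preset)
  switch(preset,
         full = sim_design(),
         desk = sim_design(n_genes = 10))
}

snp_ids_for <- function(L) paste0("SNP", seq_len(L))

#' Simulate block-correlated genotypes
#'
#' @param design a [sim_design()] object.
#' @return Integer matrix (n x L) of 0/1/2 genotypes with SNP ids `SNP1..L`
#'   in columns. Under the copy-else-fresh scheme every SNP keeps the exact
#'   Binomial(2, maf) marginal, while adjacent within-block SNPs have
#'   correlation equal to the copy probability.
#' @export
simulate_genotypes <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  G <- cpp_sim_genotypes(design$n, design$n_genes, design$blocks_per_gene,
                         design$block_size, design$maf,
                         design$copy_prob_within, design$copy_prob_boundary)
  dimnames(G) <- list(paste0("sample", seq_len(design$n)),
                      snp_ids_for(design$L))
  G
}

#' Simulate survival endpoint and clinical covariates for given genotypes
#'
#' Draws the two clinical covariates, builds the linear predictor from the
#' design's informative SNPs (plus any clinical effects), inverts the
#' exponential survival function implied by the constant baseline hazard
#' (`T = -log(U) / (h0 * exp(eta))`), censors at `C ~ Uniform(0,
#' censor_max)` and returns the observed data.
#'
#' @param design a [sim_design()] object.
#' @param genotypes matrix from [simulate_genotypes()] (or compatible).
#' @return A [cohort()] with covariates `clin_bin`, `clin_cont` and
#'   attributes `latent_time` and `censor_time` holding the uncensored draws.
#' @export
simulate_survival <- function(design, genotypes) {
  stopifnot(inherits(design, "sim_design"))
  n <- nrow(genotypes)
  if (ncol(genotypes) < max(0L, design$informative$position)) {
    stop("genotype matrix lacks the design's informative positions")
  }
  zb <- rbinom(n, 1L, design$clinical$binary_prob)
  zc <- rnorm(n)
  Z <- cbind(clin_bin = zb, clin_cont = zc)
  eta <- Z %*% c(design$clinical$binary_effect,
                 design$clinical$continuous_effect)
  if (nrow(design$informative) > 0) {
    eta <- eta + genotypes[, design$informative$position, drop = FALSE] %*%
      design$informative$effect
  }
  eta <- as.vector(eta)
  latent <- -log(runif(n)) / (design$baseline_hazard * exp(eta))
  cens <- if (is.finite(design$censor_max)) {
    runif(n, 0, design$censor_max)
  } else {
    rep(Inf, n)
  }
  ch <- cohort(pmin(latent, cens), as.integer(latent <= cens), Z)
  attr(ch, "latent_time") <- latent
  attr(ch, "censor_time") <- cens
  ch
}

#' Gene map implied by a simulation design
#'
#' SNP j belongs to gene `ceiling(j / (blocks_per_gene * block_size))`: a
#' bijective partition with no overlapping annotations.
#'
#' @param design a [sim_design()] object.
#' @return data.frame with columns `snp_id`, `gene_id`.
#' @export
gene_map_from_design <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  gene_size <- design$blocks_per_gene * design$block_size
  data.frame(
    snp_id = snp_ids_for(design$L),
    gene_id = paste0("gene", ceiling(seq_len(design$L) / gene_size)),
    stringsAsFactors = FALSE
  )
}

#' Partition the simulated SNPs into truth groups
#'
#' Splits all SNPs into the informative set, the correlated-noise set
#' (non-informative SNPs sharing a block with an informative SNP) and the
#' uncorrelated-noise set (everything else). Under the default design these
#' have sizes 6, 24 and 299970.
#'
#' @param design a [sim_design()] object.
#' @return List of class `"sim_truth"` with `informative` (data.frame:
#'   snp_id, position, effect), `cor_noise` and `uncor_noise` (SNP id
#'   vectors), and `positions` (the informative positions).
#' @export
classify_snps <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  ids <- snp_ids_for(design$L)
  pos <- design$informative$position
  block_of <- function(j) ceiling(j / design$block_size)
  info_blocks <- unique(block_of(pos))
  in_info_block <- block_of(seq_len(design$L)) %in% info_blocks
  cor_idx <- setdiff(which(in_info_block), pos)
  uncor_idx <- which(!in_info_block)
  structure(
    list(informative = data.frame(snp_id = ids[pos], position = pos,
                                  effect = design$informative$effect,
                                  stringsAsFactors = FALSE),
         cor_noise = ids[cor_idx], uncor_noise = ids[uncor_idx],
         positions = pos),
    class = "sim_truth"
  )
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("SNP truth groups: %d informative, %d correlated-noise, %d uncorrelated-noise\n",
              nrow(x$informative), length(x$cor_noise), length(x$uncor_noise)))
  invisible(x)
}

#' Truth table for export
#' @param x a [classify_snps()] result.
#' @param ... unused.
#' @return data.frame with one row per SNP: `snp_id`, `group`, `effect`.
#' @export
as.data.frame.sim_truth <- function(x, ...) {
  rbind(
    data.frame(snp_id = x$informative$snp_id, group = "informative",
               effect = x$informative$effect, stringsAsFactors = FALSE),
    data.frame(snp_id = x$cor_noise, group = "cor_noise", effect = 0,
               stringsAsFactors = FALSE),
    data.frame(snp_id = x$uncor_noise, group = "uncor_noise", effect = 0,
               stringsAsFactors = FALSE)
  )
}

#' Simulate a complete data set
#'
#' Genotypes, survival endpoint, gene map and truth groups in one call.
#'
#' @param design a [sim_design()] object.
#' @param seed optional integer seed set before generation.
#' @return List with elements `genotypes`, `cohort`, `map`, `truth`,
#'   `design`.
#' @export
simulate_dataset <- function(design, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  G <- simulate_genotypes(design)
  ch <- simulate_survival(design, G)
  list(genotypes = G, cohort = ch, map = gene_map_from_design(design),
       truth = classify_snps(design), design = design)
}
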