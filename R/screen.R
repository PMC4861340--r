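# Track 1: one adjusted Cox model per SNP, Wald p-values, BH-FDR selection.

check_genotypes <- function(genotypes, cohort = NULL) {
  if (!is.matrix(genotypes)) stop("'genotypes' must be a matrix")
  if (anyNA(genotypes)) {
    stop("genotypes contain missing values; see impute_genotypes()")
  }
  if (!is.integer(genotypes)) {
    if (any(genotypes != round(genotypes))) stop("genotypes must be coded 0/1/2")
    storage.mode(genotypes) <- "integer"
  }
  rng <- range(genotypes)
  if (rng[1] < 0L || rng[2] > 2L) stop("genotypes must be coded 0/1/2")
  if (!is.null(cohort) && nrow(genotypes) != cohort$n) {
    stop("genotype rows must match cohort size")
  }
  if (is.null(colnames(genotypes))) {
    colnames(genotypes) <- paste0("SNP", seq_len(ncol(genotypes)))
  }
  genotypes
}

#' Minor allele frequency per SNP
#'
#' The risk-allele frequency of a 0/1/2-coded SNP is its mean genotype over
#' two; the MAF folds this onto (0, 0.5].
#'
#' @param genotypes integer matrix of 0/1/2 counts, samples x SNPs; `NA`
#'   entries are ignored per SNP (an all-missing SNP yields `NA`).
#' @return Named numeric vector of MAFs.
#' @examples
#' compute_maf(cbind(s1 = c(0L, 1L, 2L, 1L), s2 = c(2L, 2L, 2L, 1L)))
#' @export
compute_maf <- function(genotypes) {
  if (!is.matrix(genotypes)) genotypes <- as.matrix(genotypes)
  f <- colMeans(genotypes, na.rm = TRUE) / 2
  f[is.nan(f)] <- NA_real_
  pmin(f, 1 - f)
}

#' Benjamini-Hochberg FDR adjustment and selection
#'
#' Step-up FDR adjustment of a p-value vector with `NA`-aware ranking: `NA`
#' entries (untestable SNPs) are excluded, so the multiplicity m counts only
#' testable hypotheses.
#'
#' @param pvalues numeric vector in \[0, 1\], `NA` allowed.
#' @param level selection level; the selected set is every index with
#'   adjusted value at or below it.
#' @return List with `adjusted` (same length as input, `NA` preserved) and
#'   `selected` (integer indices).
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.90), level = 0.05)
#' @export
bh_fdr <- function(pvalues, level = 0.05) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1)) stop("p-values must be in [0,1]")
  adjusted <- rep(NA_real_, length(pvalues))
  adjusted[ok] <- p.adjust(pvalues[ok], method = "BH")
  selected <- which(!is.na(adjusted) & adjusted <= level)
  list(adjusted = adjusted, selected = selected)
}

#' Univariate Cox screen over all SNPs, adjusted for mandatory covariates
#'
#' Fits one Cox model per SNP and reports the SNP's Wald test together with
#' BH-FDR adjusted values. Two modes are available:
#' \describe{
#'   \item{`joint`}{(default) each SNP is fit jointly with the mandatory
#'     covariates, so the adjustment is re-estimated per SNP.}
#'   \item{`offset_fast`}{the mandatory model is fit once and its linear
#'     predictor enters every one-dimensional SNP fit as a fixed offset. This
#'     approximation makes genome-wide screens (hundreds of thousands of
#'     SNPs) practical; with moderate SNP effects the two modes give nearly
#'     identical p-values.}
#' }
#' SNPs with zero variance, non-identifiable with the covariates, or with
#' non-converging fits get `NA` p-values and are excluded from the FDR
#' ranking.
#'
#' @param cohort a [cohort()] object.
#' @param genotypes complete integer matrix of 0/1/2 counts, samples x SNPs.
#' @param mode `"joint"` or `"offset_fast"`.
#' @param level FDR level defining the `selected` column.
#' @param warn emit a warning summarizing untestable SNPs?
#' @return A data.frame of class `"snp_screen"` with columns `snp_id`,
#'   `beta`, `se`, `p`, `fdr`, `maf`, `converged`, `selected`; attributes
#'   `mode`, `level` and `n_untestable`.
#' @export
screen_snps <- function(cohort, genotypes, mode = c("joint", "offset_fast"),
                        level = 0.05, warn = TRUE) {
  mode <- match.arg(mode)
  genotypes <- check_genotypes(genotypes, cohort)
  L <- ncol(genotypes)
  Z <- cohort$covariates
  if (mode == "offset_fast") {
    offset <- if (cohort$r > 0) {
      fit0 <- fit_cox(Z, cohort)
      as.vector(Z %*% fit0$coefficients)
    } else {
      numeric(cohort$n)
    }
    prep <- cox_prep(cohort$time, cohort$status)
    res <- cpp_uni_cox_all(genotypes, prep$ord0, prep$time_s, prep$status_s,
                           offset_weights(offset, prep), 1e-8, 25L)
    beta <- res$beta
    se <- res$se
    converged <- res$converged
  } else {
    beta <- se <- rep(NA_real_, L)
    converged <- logical(L)
    for (l in seq_len(L)) {
      x <- as.numeric(genotypes[, l])
      if (var(x) == 0) next
      Xl <- cbind(Z, .snp = x)
      if (qr(Xl)$rank < ncol(Xl)) next  # collinear with mandatory covariates
      fit <- tryCatch(fit_cox(Xl, cohort), error = function(e) NULL)
      if (is.null(fit) || !fit$converged) next
      q <- length(fit$coefficients)
      beta[l] <- fit$coefficients[q]
      se[l] <- fit$se[q]
      converged[l] <- TRUE
    }
  }
  p <- rep(NA_real_, L)
  ok <- converged & !is.na(beta) & !is.na(se) & se > 0
  p[ok] <- wald_pvalue(beta[ok], se[ok])
  n_untestable <- sum(!ok)
  if (warn && n_untestable > 0L) {
    warning(sprintf("%d SNP(s) untestable (zero variance, collinear or non-converged); excluded from FDR ranking",
                    n_untestable))
  }
  fdr <- bh_fdr(p, level)
  out <- data.frame(
    snp_id = colnames(genotypes), beta = beta, se = se, p = p,
    fdr = fdr$adjusted, maf = compute_maf(genotypes), converged = ok,
    selected = seq_len(L) %in% fdr$selected,
    stringsAsFactors = FALSE, row.names = NULL
  )
  class(out) <- c("snp_screen", "data.frame")
  attr(out, "mode") <- mode
  attr(out, "level") <- level
  attr(out, "n_untestable") <- n_untestable
  out
}

#' @export
print.snp_screen <- function(x, n = 10L, ...) {
  cat(sprintf("Univariate Cox screen of %d SNPs (mode = %s): %d selected at FDR <= %g\n",
              nrow(x), attr(x, "mode"), sum(x$selected), attr(x, "level")))
  ord <- order(x$p)
  print.data.frame(head(x[ord, ], n), digits = 4)
  invisible(x)
}

#' SNP ids selected by a screen
#' @param screen result of [screen_snps()].
#' @return Character vector of selected SNP ids.
#' @export
selected_snps <- function(screen) {
  screen$snp_id[screen$selected]
}
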